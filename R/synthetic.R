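# Seeded generators with planted ground truth. These stand in for benchmark
# and expression datasets: class-conditional Gaussian informative features,
# noisy monotone transforms as redundant copies, independent Gaussian noise,
# and configurable class imbalance.

#' Generate a dataset with planted informative/redundant/noise features
#'
#' Informative features are class-conditional Gaussians whose class means
#' are spaced \code{classSep} noise-SDs apart; redundant features are noisy
#' monotone transforms (affine, cube, or exp rescaled) of randomly chosen
#' informative features; noise features are independent standard Gaussians.
#' Class sizes follow \code{imbalanceRatio}: the first class is the
#' majority and the remaining classes are scaled down by the ratio.
#' Deterministic per seed.
#'
#' @param spec a [PlantSpec-class].
#' @return list with \code{dataset} (a [TabularDataset-class]) and
#'   \code{truth}: disjoint index sets \code{informative}, \code{redundant},
#'   \code{noise} partitioning the feature axis.
#' @examples
#' out <- makePlantedDataset(plantSpec(nSamples = 50, seed = 7))
#' lengths(out$truth)
#' @export
makePlantedDataset <- function(spec) {
    validObject(spec)
    nI <- spec@nInformative; nR <- spec@nRedundant; nN <- spec@nNoise
    p <- nI + nR + nN
    if (p < 1L) stop("spec yields no features", call. = FALSE)
    withSeed(spec@seed, {
        # class sizes: majority first, minorities scaled by the ratio
        w <- c(1, rep(spec@imbalanceRatio, spec@nClasses - 1L))
        counts <- pmax(1L, as.integer(round(spec@nSamples * w / sum(w))))
        counts[1L] <- spec@nSamples - sum(counts[-1L])
        if (any(counts < 1L))
            stop("imbalance ratio yields an empty class", call. = FALSE)
        labels <- factor(rep(paste0("c", seq_len(spec@nClasses)), counts))
        n <- length(labels)
        values <- matrix(0, n, p)
        cls <- as.integer(labels)
        for (f in seq_len(nI)) {
            mu <- spec@classSep * (cls - 1L)
            values[, f] <- stats::rnorm(n, mean = mu, sd = 1)
        }
        src <- if (nR > 0L) sample.int(nI, nR, replace = TRUE) else integer(0)
        transforms <- list(function(z) 2 * z + 1,
                           function(z) z^3 / 3,
                           function(z) exp(z / 2))
        for (r in seq_len(nR)) {
            tf <- transforms[[((r - 1L) %% length(transforms)) + 1L]]
            values[, nI + r] <- tf(values[, src[r]]) +
                stats::rnorm(n, sd = 0.1)
        }
        for (f in seq_len(nN))
            values[, nI + nR + f] <- stats::rnorm(n)
        colnames(values) <- c(sprintf("inf%02d", seq_len(nI)),
                              sprintf("red%02d", seq_len(nR)),
                              sprintf("noise%02d", seq_len(nN)))[seq_len(p)]
        list(dataset = tabularDataset(values, labels),
             truth = list(informative = seq_len(nI),
                          redundant = nI + seq_len(nR),
                          noise = nI + nR + seq_len(nN)))
    })
}

#' Generate a functional (x, y) pair for dependence testing
#'
#' y = f(x) + Gaussian noise for the functional kinds (x uniform on the
#' stated domain); \code{independent} draws two independent uniforms.
#' With \code{noiseSd = 0}, y is exactly f(x).
#'
#' @param kind one of \code{"linear"}, \code{"quadratic"}, \code{"sine"}
#'   (one full period), \code{"checkerboard"}, \code{"independent"}.
#' @param n sample count (>= 8).
#' @param noiseSd Gaussian noise SD added to y.
#' @param seed RNG seed.
#' @return list with numeric vectors \code{x} and \code{y}.
#' @export
makeFunctionalPair <- function(kind = c("linear", "quadratic", "sine",
                                        "checkerboard", "independent"),
                               n, noiseSd = 0, seed = 1L) {
    kind <- match.arg(kind)
    stopifnot(n >= 8L)
    withSeed(seed, {
        x <- stats::runif(n, -1, 1)
        y <- switch(kind,
            linear = 2 * x,
            quadratic = x^2,
            sine = sin(2 * pi * (x + 1) / 2),
            checkerboard = {
                # 4x4 alternating-cell density: dependent but non-functional
                cx <- sample(0:3, n, replace = TRUE)
                cy <- (cx + 2L * sample(0:1, n, replace = TRUE)) %% 4L
                x <- (cx + stats::runif(n)) / 4
                (cy + stats::runif(n)) / 4
            },
            independent = stats::runif(n, -1, 1))
        if (noiseSd > 0) y <- y + stats::rnorm(n, sd = noiseSd)
        list(x = x, y = y)
    })
}

#' Generate an imbalanced two-or-more-class dataset
#'
#' Convenience wrapper around [makePlantedDataset()] for testing class
#' balancing: class counts follow the spec's imbalance ratio exactly
#' (after integer rounding).
#'
#' @param spec a [PlantSpec-class] with \code{imbalanceRatio < 1}.
#' @return a [TabularDataset-class].
#' @export
makeImbalanced <- function(spec) {
    makePlantedDataset(spec)$dataset
}
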