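#' Grid budget for MIC
#'
#' B(n) = floor(n^bExponent). A defined MIC needs B(n) >= 4 so that at least
#' the 2x2 grid is admissible (i, j >= 2, i*j <= B(n)).
#'
#' @param n sample count.
#' @param config an [AssociationConfig-class].
#' @return integer grid budget.
#' @export
micBudget <- function(n, config = associationConfig()) {
    as.integer(floor(n^config@bExponent))
}

minimumSamplesFor <- function(config) {
    n <- 4L
    while (floor(n^config@bExponent) < 4) n <- n + 1L
    n
}

checkPair <- function(x, y, config) {
    if (length(x) != length(y))
        stop(sprintf("sequence lengths differ: %d vs %d",
                     length(x), length(y)), call. = FALSE)
    if (length(x) == 0L)
        stop("empty sequences", call. = FALSE)
    if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
        stop("non-finite values are not allowed", call. = FALSE)
    B <- micBudget(length(x), config)
    if (B < 4L)
        stop(sprintf(paste0("n = %d admits no grid: B(n) = floor(n^%g) = %d ",
                            "< 4; the minimum usable n at this exponent is %d"),
                     length(x), config@bExponent, B,
                     minimumSamplesFor(config)), call. = FALSE)
    B
}

#' Mutual information of two discrete sequences
#'
#' Plug-in (empirical) mutual information
#' \eqn{I(X,Y)=\sum p(x,y)\log[p(x,y)/(p(x)p(y))]} over the observed joint
#' cells, in units of \code{log(logBase)} (bits by default).
#'
#' @param x,y equal-length sequences of categorical codes.
#' @param logBase logarithm base (default 2: result in bits).
#' @return non-negative scalar; symmetric in its arguments and bounded by
#'   min(H(x), H(y)).
#' @examples
#' mutualInfoDiscrete(c(0, 1, 0, 1), c(0, 1, 0, 1))  # 1 bit
#' @export
mutualInfoDiscrete <- function(x, y, logBase = 2) {
    if (length(x) != length(y))
        stop(sprintf("sequence lengths differ: %d vs %d",
                     length(x), length(y)), call. = FALSE)
    if (length(x) == 0L)
        stop("empty sequences", call. = FALSE)
    joint <- table(x, y) / length(x)
    px <- rowSums(joint)
    py <- colSums(joint)
    outer_p <- outer(px, py)
    pos <- joint > 0
    sum(joint[pos] * log(joint[pos] / outer_p[pos], base = logBase))
}

# Plug-in entropy in the configured base (internal; used by tests via :::)
entropyDiscrete <- function(x, logBase = 2) {
    p <- table(x) / length(x)
    -sum(p * log(p, base = logBase))
}

# Exhaustive raw grid-MI matrix (nats): enumerate every axis partition with
# cuts at distinct-value boundaries. Small n only; the oracle for approx mode.
exhaustiveRaw <- function(x, y, B) {
    n <- length(x)
    maxD <- B %/% 2L
    groupOf <- function(v) {
        s <- sort(unique(v))
        match(v, s)
    }
    gx <- groupOf(x); Gx <- max(gx)
    gy <- groupOf(y); Gy <- max(gy)
    # partitions of an axis into k bins: choose k-1 of the G-1 boundaries
    partitions <- function(G, k) {
        if (k == 1L) return(list(integer(0)))
        if (G - 1L < k - 1L) return(list())
        asplit(utils::combn(G - 1L, k - 1L), 2L)
    }
    comboCount <- function(G, k) choose(G - 1L, k - 1L)
    total <- 0
    for (i in 2:maxD) for (j in 2:maxD)
        if (i * j <= B) total <- total + comboCount(Gx, i) * comboCount(Gy, j)
    if (total > 5e6)
        stop("exhaustive mode is infeasible at this n; use mode = 'approx'",
             call. = FALSE)
    rawMI <- function(xb, yb) {
        joint <- table(xb, yb) / n
        px <- rowSums(joint); py <- colSums(joint)
        op <- outer(px, py)
        pos <- joint > 0
        sum(joint[pos] * log(joint[pos] / op[pos]))
    }
    raw <- matrix(NA_real_, maxD - 1L, maxD - 1L)
    for (i in 2:maxD) {
        xparts <- partitions(Gx, i)
        for (j in 2:maxD) {
            if (i * j > B) next
            best <- 0
            yparts <- partitions(Gy, j)
            for (cx in xparts) {
                xb <- findInterval(gx, c(cx + 0.5))
                for (cy in yparts) {
                    yb <- findInterval(gy, c(cy + 0.5))
                    v <- rawMI(xb, yb)
                    if (v > best) best <- v
                }
            }
            raw[i - 1L, j - 1L] <- best
        }
    }
    # empty-cell monotonicity, as in approx mode
    for (i in 2:maxD) for (j in 2:maxD) {
        if (i * j > B) next
        v <- raw[i - 1L, j - 1L]
        if (i > 2L) v <- max(v, raw[i - 2L, j - 1L])
        if (j > 2L) v <- max(v, raw[i - 1L, j - 2L])
        raw[i - 1L, j - 1L] <- v
    }
    raw
}

#' Characteristic matrix of a real-valued pair
#'
#' Entry (i, j) is the maximal empirical mutual information over i-by-j
#' axis-aligned grids of the scatter (x, y), normalised by log(min(i, j)).
#' Admissible dimensions satisfy i, j >= 2 and i*j <= B(n) =
#' floor(n^bExponent); other entries are NA. MIC is the maximum entry.
#'
#' In \code{approx} mode one axis is cut by mass equipartition (all candidate
#' cuts are enumerated for 2-bin pivots) and the other is optimised exactly
#' by dynamic programming over clump boundaries, in both orientations; in
#' \code{exhaustive} mode every partition is enumerated (small n only).
#' Tied values are never split across grid lines in either mode.
#'
#' @param x,y equal-length real sequences without non-finite values.
#' @param config an [AssociationConfig-class].
#' @return a [CharacteristicMatrix-class]. A constant input yields an
#'   all-zero matrix with \code{constantInput = TRUE} rather than an error.
#' @export
characteristicMatrix <- function(x, y, config = associationConfig()) {
    B <- checkPair(x, y, config)
    maxD <- B %/% 2L
    dn <- list(i = as.character(2:maxD), j = as.character(2:maxD))
    constant <- (length(unique(x)) < 2L || length(unique(y)) < 2L)
    if (constant) {
        entries <- matrix(0, maxD - 1L, maxD - 1L, dimnames = dn)
        for (i in 2:maxD) for (j in 2:maxD)
            if (i * j > B) entries[i - 1L, j - 1L] <- NA_real_
        return(new("CharacteristicMatrix", entries = entries,
                   n = length(x), config = config, constantInput = TRUE))
    }
    raw <- if (config@mode == "exhaustive") {
        exhaustiveRaw(as.numeric(x), as.numeric(y), B)
    } else {
        .micRawCpp(as.numeric(x), as.numeric(y), B, config@clumpFactor)
    }
    norm <- log(pmin(matrix(2:maxD, maxD - 1L, maxD - 1L),
                     matrix(2:maxD, maxD - 1L, maxD - 1L, byrow = TRUE)))
    entries <- pmin(pmax(raw / norm, 0), 1)
    dimnames(entries) <- dn
    new("CharacteristicMatrix", entries = entries, n = length(x),
        config = config, constantInput = FALSE)
}

#' Maximal information coefficient
#'
#' The maximum entry of the characteristic matrix over admissible grid
#' dimensions: a dependence measure in [0, 1] reaching 1 for noiseless
#' functional relationships and 0 for independence, symmetric in x and y.
#'
#' @inheritParams characteristicMatrix
#' @return scalar in [0, 1].
#' @examples
#' x <- seq_len(20)
#' mic(x, x)          # 1: monotone bijection
#' @export
mic <- function(x, y, config = associationConfig()) {
    cm <- characteristicMatrix(x, y, config)
    if (cm@constantInput) return(0)
    max(cm@entries, na.rm = TRUE)
}

#' Association of a real feature with a class label
#'
#' MIC between a feature and integer-coded class labels; the coding follows
#' the sorted unique labels so results are reproducible regardless of input
#' order. A single-class label vector yields 0 with a warning.
#'
#' @param x real feature values.
#' @param labels class labels (any atomic type or factor).
#' @param config an [AssociationConfig-class].
#' @return scalar in [0, 1].
#' @export
associationToLabel <- function(x, labels, config = associationConfig()) {
    codes <- labelCodes(labels)
    if (max(codes) == min(codes)) {
        warning("labels contain a single class; association is 0")
        return(0)
    }
    mic(x, codes, config)
}

labelCodes <- function(labels) {
    u <- sort(unique(as.character(labels)))
    match(as.character(labels), u)
}

#' All-pairs association table
#'
#' Computes MIC for every pair of target features (and, optionally, each
#' feature against the class label). Work may be split across forked workers
#' but results are reduced in a fixed order, so the output is identical for
#' any \code{workers} value.
#'
#' @param dataset a [TabularDataset-class].
#' @param targets feature indices or names (default: all features).
#' @param config an [AssociationConfig-class].
#' @param workers forked worker count (1 = serial).
#' @param includeLabel also compute feature-label associations.
#' @return symmetric numeric matrix over the targets; when
#'   \code{includeLabel} the per-feature label association is attached as
#'   attribute \code{"labelAssociation"}. Diagonal entries are the
#'   self-association, 1 by convention for non-constant features and 0 for
#'   constant ones.
#' @rdname pairwiseAssociation
#' @export
setMethod("pairwiseAssociation", "TabularDataset",
    function(dataset, targets = NULL, config = associationConfig(),
             workers = 1L, includeLabel = TRUE) {
    v <- dataset@values
    if (is.null(targets)) targets <- seq_len(ncol(v))
    if (is.character(targets)) targets <- match(targets, colnames(v))
    if (anyNA(targets) || any(targets < 1L | targets > ncol(v)))
        stop("invalid feature indices in 'targets'")
    t <- length(targets)
    pairs <- which(upper.tri(matrix(0, t, t)), arr.ind = TRUE)
    onePair <- function(k) {
        i <- targets[pairs[k, 1L]]
        j <- targets[pairs[k, 2L]]
        mic(v[, i], v[, j], config)
    }
    vals <- if (workers > 1L) {
        unlist(parallel::mclapply(seq_len(nrow(pairs)), onePair,
                                  mc.cores = workers, mc.preschedule = TRUE))
    } else {
        vapply(seq_len(nrow(pairs)), onePair, numeric(1))
    }
    S <- matrix(0, t, t, dimnames = list(colnames(v)[targets],
                                         colnames(v)[targets]))
    S[upper.tri(S)] <- vals
    S <- S + t(S)
    diag(S) <- vapply(targets, function(i) {
        if (length(unique(v[, i])) < 2L) 0 else 1
    }, numeric(1))
    if (includeLabel) {
        codes <- labelCodes(dataset@labels)
        la <- if (workers > 1L) {
            unlist(parallel::mclapply(targets, function(i)
                mic(v[, i], codes, config), mc.cores = workers))
        } else {
            vapply(targets, function(i) mic(v[, i], codes, config),
                   numeric(1))
        }
        names(la) <- colnames(v)[targets]
        attr(S, "labelAssociation") <- la
    }
    S
})
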