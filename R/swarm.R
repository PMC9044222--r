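# Particle swarm wrapper search over feature subsets. Positions are
# continuous in [0, 1]^d; a dimension is part of the candidate subset when
# its position exceeds the decode threshold. The fitness is
# alpha * Verror + beta * Nselected / Nall with Verror the KNN
# cross-validation error of the decoded subset under one fold assignment
# fixed for the whole run, so fitness is a pure function of position.

#' Decode a particle position into a feature subset
#'
#' @param position numeric vector in [0, 1]^d.
#' @param threshold cutoff; dimension d is included iff
#'   \code{position[d] > threshold} (strict).
#' @return integer indices of the selected dimensions.
#' @examples
#' decodeSubset(c(0.2, 0.7, 0.5), 0.5)  # 2
#' @export
decodeSubset <- function(position, threshold = 0.5) {
    stopifnot(all(is.finite(position)))
    which(position > threshold)
}

#' KNN cross-validation error of a feature subset
#'
#' Mean misclassification rate of a k-nearest-neighbour classifier
#' (Euclidean distance on min-max-scaled features, majority vote, ties
#' broken deterministically toward the lowest training index / class code)
#' across the folds of a fixed assignment. Deterministic given the
#' assignment.
#'
#' @param dataset a [TabularDataset-class].
#' @param subset non-empty feature indices.
#' @param fitness a [FitnessConfig-class] (supplies knnK).
#' @param foldAssignment integer fold id per sample, as produced by one call
#'   to the stratified-fold helper; computed once per wrapper run.
#' @return error rate in [0, 1].
#' @export
knnError <- function(dataset, subset, fitness = fitnessConfig(),
                     foldAssignment) {
    if (length(subset) == 0L)
        stop("empty subset; the wrapper assigns worst-case error by convention",
             call. = FALSE)
    x <- minMaxScale(dataset@values[, subset, drop = FALSE])
    yCodes <- as.integer(dataset@labels) - 1L
    knnErrorScaled(x, yCodes, nlevels(dataset@labels), fitness@knnK,
                   foldAssignment)
}

knnErrorScaled <- function(x, yCodes, nClasses, k, foldAssignment) {
    folds <- sort(unique(foldAssignment))
    errs <- vapply(folds, function(f) {
        tr <- foldAssignment != f
        if (sum(tr) < k)
            stop(sprintf("training fold has %d samples but k = %d",
                         sum(tr), k), call. = FALSE)
        pred <- .knnPredictCpp(x[tr, , drop = FALSE], yCodes[tr],
                               x[!tr, , drop = FALSE], k, nClasses)
        mean(pred != yCodes[!tr])
    }, numeric(1))
    mean(errs)
}

#' Wrapper cost of a particle position
#'
#' \code{cost = alpha * Verror + beta * Nselected / Nall}. An empty decoded
#' subset is assigned Verror = 1 (worst case), so its cost is alpha.
#'
#' @param position particle position vector.
#' @param dataset a [TabularDataset-class] whose features span the search
#'   space.
#' @param fitness a [FitnessConfig-class]; \code{nAll} defaults to the
#'   dataset's feature count when NA.
#' @param foldAssignment fixed fold assignment (see [knnError()]).
#' @param threshold decode threshold.
#' @return scalar cost with the error component attached as attribute
#'   \code{"errorComponent"}.
#' @export
fitnessCost <- function(position, dataset, fitness = fitnessConfig(),
                        foldAssignment, threshold = 0.5) {
    nAll <- if (is.na(fitness@nAll)) ncol(dataset@values) else fitness@nAll
    subset <- decodeSubset(position, threshold)
    err <- if (length(subset) == 0L) 1.0
           else knnError(dataset, subset, fitness, foldAssignment)
    cost <- fitness@alpha * err + fitness@beta * length(subset) / nAll
    attr(cost, "errorComponent") <- err
    cost
}

#' Velocity update
#'
#' \code{v' = omega*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)} with r1, r2
#' fresh uniform[0, 1] draws per dimension (taken from the current RNG
#' stream unless supplied), then clamped elementwise to [-vMax, vMax].
#'
#' @param velocity,position,pbest,gbest numeric vectors of equal length.
#' @param config a [SwarmConfig-class].
#' @param r1,r2 optional fixed random vectors (recycled); mainly for tests.
#' @return the new velocity vector.
#' @export
updateVelocity <- function(velocity, position, pbest, gbest,
                           config = swarmConfig(), r1 = NULL, r2 = NULL) {
    d <- length(position)
    if (is.null(r1)) r1 <- stats::runif(d)
    if (is.null(r2)) r2 <- stats::runif(d)
    v <- config@omega * velocity +
        config@c1 * r1 * (pbest - position) +
        config@c2 * r2 * (gbest - position)
    pmin(pmax(v, -config@vMax), config@vMax)
}

#' Position update
#'
#' \code{x' = x + v'}, clamped elementwise to [0, 1].
#'
#' @param position current position.
#' @param velocity the already-updated velocity.
#' @return the new position vector.
#' @export
updatePosition <- function(position, velocity) {
    pmin(pmax(position + velocity, 0), 1)
}

#' Run the particle swarm wrapper search
#'
#' Initialises positions uniformly in [0, 1]^d and velocities in [-1, 1]^d
#' from the seeded RNG, fixes one stratified fold assignment for the whole
#' run, then iterates synchronous personal-best/global-best tracking with
#' [updateVelocity()] and [updatePosition()] for the configured number of
#' iterations. Fully reproducible from (seed, config, data). Fitness values
#' are memoised per decoded subset, since distinct positions frequently
#' decode to the same subset.
#'
#' @param dataset the search space: a [TabularDataset-class] restricted to
#'   the candidate features (e.g. the top-K of a ranking).
#' @param swarm a [SwarmConfig-class].
#' @param fitness a [FitnessConfig-class].
#' @return a [SelectionResult-class]; \code{trace} holds the global-best
#'   cost after each iteration and is non-increasing.
#' @rdname runPSO
#' @export
setMethod("runPSO", "TabularDataset",
    function(dataset, swarm = swarmConfig(), fitness = fitnessConfig()) {
    labels <- dataset@labels
    if (nlevels(droplevels(labels)) < 2L)
        stop("degenerate dataset: fewer than two classes")
    if (min(table(droplevels(labels))) < fitness@folds)
        stop(sprintf("degenerate dataset: smallest class (%d) below fold count (%d)",
                     min(table(droplevels(labels))), fitness@folds))
    d <- ncol(dataset@values)
    nAll <- if (is.na(fitness@nAll)) d else fitness@nAll
    seed <- if (is.na(swarm@seed)) NULL else swarm@seed
    x <- minMaxScale(dataset@values)
    yCodes <- as.integer(labels) - 1L
    nClasses <- nlevels(labels)

    withSeed(seed, {
        fold <- stratifiedFolds(labels, fitness@folds)
        if (min(tabulate(fold, fitness@folds)) < 1L ||
            length(labels) - max(tabulate(fold, fitness@folds)) < fitness@knnK)
            stop("degenerate dataset: folds too small for the KNN neighbour count")

        cache <- new.env(parent = emptyenv())
        evalPosition <- function(pos) {
            subset <- decodeSubset(pos, swarm@decodeThreshold)
            key <- paste0("s", paste(subset, collapse = ","))
            got <- cache[[key]]
            if (is.null(got)) {
                err <- if (length(subset) == 0L) 1.0
                       else knnErrorScaled(x[, subset, drop = FALSE], yCodes,
                                           nClasses, fitness@knnK, fold)
                got <- c(fitness@alpha * err +
                         fitness@beta * length(subset) / nAll, err)
                cache[[key]] <- got
            }
            got  # c(cost, error)
        }

        pop <- swarm@population
        X <- matrix(stats::runif(pop * d), pop, d)
        V <- matrix(stats::runif(pop * d, -1, 1), pop, d)
        ev <- t(apply(X, 1L, evalPosition))
        pbestX <- X
        pbestCost <- ev[, 1L]
        pbestErr <- ev[, 2L]
        g <- which.min(pbestCost)
        gbestX <- pbestX[g, ]
        gbestCost <- pbestCost[g]
        gbestErr <- pbestErr[g]

        trace <- numeric(swarm@iterations)
        for (it in seq_len(swarm@iterations)) {
            for (i in seq_len(pop)) {
                V[i, ] <- updateVelocity(V[i, ], X[i, ], pbestX[i, ], gbestX,
                                         swarm)
                X[i, ] <- updatePosition(X[i, ], V[i, ])
                e <- evalPosition(X[i, ])
                if (e[1L] < pbestCost[i]) {
                    pbestCost[i] <- e[1L]
                    pbestErr[i] <- e[2L]
                    pbestX[i, ] <- X[i, ]
                }
            }
            g <- which.min(pbestCost)
            if (pbestCost[g] < gbestCost) {
                gbestCost <- pbestCost[g]
                gbestErr <- pbestErr[g]
                gbestX <- pbestX[g, ]
            }
            trace[it] <- gbestCost
        }

        selected <- decodeSubset(gbestX, swarm@decodeThreshold)
        new("SelectionResult", selected = as.integer(selected),
            selectedNames = colnames(dataset@values)[selected],
            cost = gbestCost, errorComponent = gbestErr, trace = trace,
            gbestPosition = gbestX, swarmConfig = swarm,
            fitnessConfig = fitness)
    })
})
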