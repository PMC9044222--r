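# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb user RNG.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else {
                assign(".Random.seed", old, envir = globalenv())
            }
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Stratified k-fold assignment: within each class, samples are shuffled and
# dealt round-robin so fold class proportions match the data as closely as
# integer counts allow. Returns an integer vector of fold ids in 1..k.
stratifiedFolds <- function(labels, k, seed = NULL) {
    labels <- as.factor(labels)
    n <- length(labels)
    stopifnot(k >= 2L, n >= k)
    withSeed(seed, {
        fold <- integer(n)
        offset <- 0L
        for (cl in levels(labels)) {
            idx <- which(labels == cl)
            idx <- idx[sample.int(length(idx))]
            # continue the round-robin across classes so small classes do not
            # all land in the low-numbered folds
            fold[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
            offset <- offset + length(idx)
        }
        fold
    })
}

# Min-max scale columns to [0,1] using ranges from `ref` (defaults to x).
# Constant columns map to 0 rather than NaN.
minMaxScale <- function(x, ref = x) {
    lo <- apply(ref, 2L, min)
    hi <- apply(ref, 2L, max)
    span <- hi - lo
    span[span == 0] <- 1
    sweep(sweep(x, 2L, lo, "-"), 2L, span, "/")
}

assertScalarNumber <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
    x
}
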