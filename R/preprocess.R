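# Preprocessing: sparse-feature removal and class balancing by random
# oversampling. In the expression use case the sparsity filter drops genes
# that are zero in a large share of samples; oversampling duplicates
# minority-class samples until all classes match the majority count.

#' Remove features dominated by zeros
#'
#' A feature is kept iff its fraction of exact zeros is at most
#' \code{maxZeroFraction}; sample rows are untouched. The removed feature
#' names are attached for the audit trail.
#'
#' @param dataset a [TabularDataset-class].
#' @param maxZeroFraction maximum tolerated zero fraction in [0, 1]
#'   (default 0.5).
#' @return the filtered [TabularDataset-class] with attribute
#'   \code{"removedFeatures"} (character).
#' @rdname filterSparseFeatures
#' @export
setMethod("filterSparseFeatures", "TabularDataset",
    function(dataset, maxZeroFraction = 0.5) {
    stopifnot(maxZeroFraction >= 0, maxZeroFraction <= 1)
    zf <- colMeans(dataset@values == 0)
    keep <- zf <= maxZeroFraction
    if (!any(keep))
        stop(paste0("all features exceed the zero-fraction threshold ",
                    maxZeroFraction, "; raise 'maxZeroFraction'"),
             call. = FALSE)
    out <- dataset[, which(keep)]
    attr(out, "removedFeatures") <- colnames(dataset@values)[!keep]
    out
})

#' Balance classes by random oversampling
#'
#' Randomly copies minority-class samples (drawn with replacement, seeded)
#' until every class count equals the majority count. All original rows are
#' retained and every added row is an exact copy of an original row of the
#' same class.
#'
#' @param dataset a [TabularDataset-class] with at least two classes.
#' @param seed RNG seed for the draws (NULL: use the caller's RNG state).
#' @return the balanced [TabularDataset-class]; already-balanced input is
#'   returned row-identical.
#' @rdname randomOversample
#' @export
setMethod("randomOversample", "TabularDataset",
    function(dataset, seed = NULL) {
    labels <- droplevels(dataset@labels)
    if (nlevels(labels) < 2L)
        stop("oversampling requires at least two classes", call. = FALSE)
    counts <- table(labels)
    target <- max(counts)
    if (all(counts == target)) return(dataset)
    withSeed(seed, {
        extra <- unlist(lapply(levels(labels), function(cl) {
            idx <- which(labels == cl)
            deficit <- target - length(idx)
            if (deficit == 0L) return(integer(0))
            idx[sample.int(length(idx), deficit, replace = TRUE)]
        }), use.names = FALSE)
        keep <- c(seq_along(labels), extra)
        new("TabularDataset", values = dataset@values[keep, , drop = FALSE],
            labels = dataset@labels[keep])
    })
})
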