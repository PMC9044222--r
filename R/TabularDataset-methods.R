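#' @rdname TabularDataset-class
setMethod("nSamples", "TabularDataset", function(x) nrow(x@values))

#' @rdname TabularDataset-class
setMethod("nFeatures", "TabularDataset", function(x) ncol(x@values))

#' @rdname TabularDataset-class
setMethod("featureNames", "TabularDataset", function(x) colnames(x@values))

#' @rdname TabularDataset-class
setMethod("featureValues", "TabularDataset", function(x) x@values)

#' @rdname TabularDataset-class
setMethod("classLabels", "TabularDataset", function(x) x@labels)

#' Subset a TabularDataset
#'
#' \code{x[i, j]} keeps samples \code{i} and features \code{j}; labels follow
#' the sample subset. Factor levels are preserved.
#'
#' @param x a \code{TabularDataset}.
#' @param i sample indices.
#' @param j feature indices or names.
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{TabularDataset}.
#' @export
setMethod("[", "TabularDataset", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@values))
    if (missing(j)) j <- seq_len(ncol(x@values))
    new("TabularDataset", values = x@values[i, j, drop = FALSE],
        labels = x@labels[i])
})

setMethod("show", "TabularDataset", function(object) {
    tab <- table(object@labels)
    cat(sprintf("TabularDataset: %d samples x %d features\n",
                nrow(object@values), ncol(object@values)))
    cat("class counts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
})

#' Convert a SummarizedExperiment to a TabularDataset
#'
#' Transposes an assay (features x samples in SummarizedExperiment
#' convention) into the samples x features layout used here and takes the
#' class label from a colData column.
#'
#' @param se a \code{SummarizedExperiment} (the package is only suggested;
#'   this helper errors when it is not installed).
#' @param labelCol name of the colData column holding the class label.
#' @param assay assay index or name (default first).
#' @return a [TabularDataset-class].
#' @export
asTabularDataset <- function(se, labelCol, assay = 1L) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
        stop("the SummarizedExperiment package is required for this coercion")
    mat <- t(SummarizedExperiment::assay(se, assay))
    cd <- SummarizedExperiment::colData(se)
    if (!labelCol %in% colnames(cd))
        stop(sprintf("label column '%s' not found in colData (available: %s)",
                     labelCol, paste(colnames(cd), collapse = ", ")))
    tabularDataset(mat, cd[[labelCol]])
}

setMethod("show", "RankingResult", function(object) {
    cat(sprintf("RankingResult (%s): %d features ranked (K=%d%s)\n",
                object@measure, length(object@order), object@K,
                if (object@capped) ", capped" else ""))
    k <- min(5L, length(object@order))
    if (k > 0L)
        cat("top:", paste(object@featureNames[seq_len(k)], collapse = ", "),
            "\n")
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d features, cost %.4f (error %.4f)\n",
                length(object@selected), object@cost, object@errorComponent))
})

setMethod("show", "EvaluationReport", function(object) {
    cat(sprintf("EvaluationReport: %.2f%% accuracy over %d folds (%d features)\n",
                object@accuracy, object@folds, length(object@subset)))
})

setMethod("show", "PanelModel", function(object) {
    cat(sprintf("PanelModel: intercept %.5f + %d features%s\n",
                object@constant, length(object@coefficients),
                if (object@separationFlagged) " [separation flagged]" else ""))
})

setMethod("show", "RunManifest", function(object) {
    cat("RunManifest\n")
    cat(sprintf("  removed by sparsity filter: %d\n",
                length(object@removedFeatures)))
    cat(sprintf("  ranked: %d; selected: %d; accuracy: %.2f%%\n",
                length(object@ranking@order),
                length(object@selection@selected), object@report@accuracy))
})
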