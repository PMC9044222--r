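# Delimited-text IO and the end-to-end pipeline:
# preprocess -> rank -> swarm search -> evaluate.

#' Load a labelled dataset from delimited text
#'
#' Reads a CSV/TSV file with a header row, takes one column as the class
#' label and parses every other column as numeric. Missing or unparseable
#' cells are rejected with their coordinates.
#'
#' @param path file path.
#' @param labelCol name of the label column.
#' @param delimiter field delimiter (default ",").
#' @return a [TabularDataset-class].
#' @export
loadDataset <- function(path, labelCol, delimiter = ",") {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (!labelCol %in% colnames(df))
        stop(sprintf("label column '%s' not found; available columns: %s",
                     labelCol, paste(colnames(df), collapse = ", ")),
             call. = FALSE)
    labels <- df[[labelCol]]
    df[[labelCol]] <- NULL
    values <- suppressWarnings(
        vapply(df, function(col) as.numeric(col), numeric(nrow(df))))
    values <- matrix(values, nrow = nrow(df),
                     dimnames = list(NULL, colnames(df)))
    bad <- which(is.na(values), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
        loc <- sprintf("row %d, column '%s'",
                       bad[1L, 1L], colnames(values)[bad[1L, 2L]])
        stop(sprintf("%d missing/unparseable cell(s); first at %s",
                     nrow(bad), loc), call. = FALSE)
    }
    if (anyNA(labels))
        stop("missing values in the label column", call. = FALSE)
    tabularDataset(values, labels)
}

#' Write a dataset to delimited text
#'
#' Inverse of [loadDataset()]: features as numeric columns plus one label
#' column, with a header row.
#'
#' @param dataset a [TabularDataset-class].
#' @param path output path.
#' @param labelCol label column name (default "label").
#' @param delimiter field delimiter.
#' @export
writeDataset <- function(dataset, path, labelCol = "label",
                         delimiter = ",") {
    df <- as.data.frame(dataset@values, check.names = FALSE)
    df[[labelCol]] <- as.character(dataset@labels)
    utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Run the full feature-selection pipeline
#'
#' Chains the method's three stages plus validation: (1) sparse-feature
#' filtering and optional random oversampling; (2) mRMR/MIC ranking to the
#' top K features (all features pass through when p <= K); (3) particle
#' swarm wrapper search over the top-K restriction; (4) stratified SVM
#' cross-validation of the selected subset. Every stochastic stage is
#' seeded from \code{seed}, and the returned manifest reproduces the run
#' exactly.
#'
#' @param dataset a [TabularDataset-class].
#' @param K ranking cutoff handed to the wrapper (default 100).
#' @param maxZeroFraction sparsity-filter threshold.
#' @param oversample balance classes before ranking (default TRUE; a
#'   no-op on balanced data).
#' @param association an [AssociationConfig-class].
#' @param swarm a [SwarmConfig-class]; its seed is overridden from
#'   \code{seed}.
#' @param fitness a [FitnessConfig-class].
#' @param evalFolds validation CV folds (default 10).
#' @param seed master seed for oversampling, swarm and validation folds.
#' @param workers forked workers for the pairwise association stage.
#' @return a [RunManifest-class].
#' @export
runPipeline <- function(dataset, K = 100L, maxZeroFraction = 0.5,
                        oversample = TRUE,
                        association = associationConfig(),
                        swarm = swarmConfig(), fitness = fitnessConfig(),
                        evalFolds = 10L, seed = 1L, workers = 1L) {
    t0 <- Sys.time()
    seeds <- c(oversample = seed, swarm = seed + 1L, folds = seed + 2L)
    checksum <- sprintf("%d:%d:%.6g:%s", nrow(dataset@values),
                        ncol(dataset@values), sum(dataset@values),
                        paste(levels(dataset@labels), collapse = "|"))

    filtered <- filterSparseFeatures(dataset, maxZeroFraction)
    removed <- attr(filtered, "removedFeatures")
    balanced <- if (oversample)
        randomOversample(filtered, seed = seeds[["oversample"]])
    else filtered

    ranking <- if (ncol(balanced@values) <= K) {
        rankFeatures(balanced, K = ncol(balanced@values),
                     config = association, workers = workers)
    } else {
        rankFeatures(balanced, K = K, config = association,
                     workers = workers)
    }

    swarm@seed <- as.integer(seeds[["swarm"]])
    top <- balanced[, ranking@order]
    selection <- runPSO(top, swarm = swarm, fitness = fitness)
    # map back into the original feature space through the ranking
    originalIdx <- match(selection@selectedNames, colnames(dataset@values))
    selection@selected <- as.integer(originalIdx)

    report <- cvAccuracy(balanced, subset = selection@selectedNames,
                         folds = evalFolds, seed = seeds[["folds"]])
    new("RunManifest",
        config = list(K = K, maxZeroFraction = maxZeroFraction,
                      oversample = oversample, association = association,
                      swarm = swarm, fitness = fitness,
                      evalFolds = as.integer(evalFolds)),
        seeds = vapply(seeds, as.integer, integer(1)),
        inputChecksum = checksum,
        removedFeatures = as.character(removed),
        ranking = ranking, selection = selection, report = report,
        timestamps = c(t0, Sys.time()))
}
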