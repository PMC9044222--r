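#' @import methods
NULL

#' TabularDataset: a labelled sample-by-feature matrix
#'
#' The universal currency of the package: a numeric matrix with samples in
#' rows and named features in columns, plus a categorical class label per
#' sample. Gene-expression use: rows are biosamples, columns are genes,
#' labels are e.g. tumor/normal.
#'
#' @slot values numeric matrix, samples x features; column names are the
#'   feature names and must be unique.
#' @slot labels factor of length \code{nrow(values)}.
#'
#' @seealso [tabularDataset()], [asTabularDataset()]
#' @exportClass TabularDataset
setClass("TabularDataset",
    slots = c(values = "matrix", labels = "factor"))

setValidity("TabularDataset", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (anyNA(v) || any(!is.finite(v)))
        return("'values' must not contain missing or non-finite entries")
    if (is.null(colnames(v)))
        return("'values' must have column (feature) names")
    if (anyDuplicated(colnames(v)))
        return("feature names must be unique")
    if (length(object@labels) != nrow(v))
        return(sprintf("length(labels) [%d] != number of samples [%d]",
                       length(object@labels), nrow(v)))
    TRUE
})

#' Construct a TabularDataset
#'
#' @param values numeric matrix (samples x features). A data.frame of numeric
#'   columns is accepted and converted.
#' @param labels class label per sample (coerced to factor).
#' @param featureNames optional character vector overriding column names;
#'   required when \code{values} has none.
#' @return A [TabularDataset-class] object.
#' @examples
#' d <- tabularDataset(matrix(rnorm(20), 10, 2,
#'                            dimnames = list(NULL, c("g1", "g2"))),
#'                     rep(c("a", "b"), 5))
#' nSamples(d)
#' @export
tabularDataset <- function(values, labels, featureNames = NULL) {
    if (is.data.frame(values))
        values <- as.matrix(values)
    if (!is.null(featureNames))
        colnames(values) <- featureNames
    if (is.null(colnames(values)))
        colnames(values) <- paste0("f", seq_len(ncol(values)))
    new("TabularDataset", values = values, labels = as.factor(labels))
}

#' Configuration for MIC estimation
#'
#' @slot bExponent power defining the grid budget B(n) = floor(n^bExponent).
#' @slot clumpFactor positive integer bounding candidate axis partitions to
#'   clumpFactor x (maximum cells on that axis).
#' @slot logBase base of all logarithms; applied identically to the grid
#'   mutual information and its normaliser, so MIC itself is base-invariant.
#' @slot mode \code{"approx"} (dynamic-programming estimator) or
#'   \code{"exhaustive"} (enumerate every admissible grid; small n only).
#' @exportClass AssociationConfig
setClass("AssociationConfig",
    slots = c(bExponent = "numeric", clumpFactor = "integer",
              logBase = "numeric", mode = "character"))

setValidity("AssociationConfig", function(object) {
    if (object@bExponent <= 0 || object@bExponent >= 1)
        return("'bExponent' must lie in (0, 1)")
    if (object@clumpFactor < 1L)
        return("'clumpFactor' must be >= 1")
    if (object@logBase <= 1)
        return("'logBase' must be > 1")
    if (!object@mode %in% c("approx", "exhaustive"))
        return("'mode' must be 'approx' or 'exhaustive'")
    TRUE
})

#' @param bExponent,clumpFactor,logBase,mode see the class slots.
#' @rdname AssociationConfig-class
#' @export
associationConfig <- function(bExponent = 0.6, clumpFactor = 15L,
                              logBase = 2, mode = c("approx", "exhaustive")) {
    new("AssociationConfig",
        bExponent = assertScalarNumber(bExponent, "bExponent"),
        clumpFactor = as.integer(clumpFactor),
        logBase = assertScalarNumber(logBase, "logBase"),
        mode = match.arg(mode))
}

#' Characteristic matrix of normalised maximal grid informations
#'
#' Entry (i, j) holds the maximal mutual information over i-by-j axis-aligned
#' grids, divided by log(min(i, j)); MIC is its maximum over admissible
#' (i, j) with i*j <= B(n). Inadmissible entries are NA.
#'
#' @slot entries numeric matrix; dimnames give the grid dimensions i, j >= 2.
#' @slot n sample count.
#' @slot config the [AssociationConfig-class] used.
#' @slot constantInput TRUE when either input sequence was constant (all
#'   entries are then zero by convention).
#' @exportClass CharacteristicMatrix
setClass("CharacteristicMatrix",
    slots = c(entries = "matrix", n = "integer",
              config = "AssociationConfig", constantInput = "logical"))

setValidity("CharacteristicMatrix", function(object) {
    e <- object@entries[!is.na(object@entries)]
    if (length(e) && (min(e) < -1e-9 || max(e) > 1 + 1e-9))
        return("entries must lie in [0, 1]")
    TRUE
})

#' mRMR ranking result
#'
#' Greedy forward ranking of features under the maximum-relevance
#' minimum-redundancy quotient criterion. Scores are the values that won each
#' greedy step, recorded at selection time.
#'
#' @slot order integer feature indices, best first.
#' @slot featureNames names aligned with \code{order}.
#' @slot scores per-rank step score (label association for the first pick,
#'   relevance/redundancy quotient afterwards).
#' @slot relevance per-rank label association of the picked feature.
#' @slot redundancy per-rank mean association of the picked feature with the
#'   previously selected set (0 for the first pick).
#' @slot K requested list length.
#' @slot capped TRUE when K exceeded the feature count and was capped.
#' @slot measure association measure used: "mic" or "mi".
#' @exportClass RankingResult
setClass("RankingResult",
    slots = c(order = "integer", featureNames = "character",
              scores = "numeric", relevance = "numeric",
              redundancy = "numeric", K = "integer", capped = "logical",
              measure = "character"))

setValidity("RankingResult", function(object) {
    if (anyDuplicated(object@order))
        return("'order' must not contain duplicates")
    n <- length(object@order)
    if (length(object@scores) != n || length(object@relevance) != n ||
        length(object@redundancy) != n || length(object@featureNames) != n)
        return("per-rank vectors must align with 'order'")
    TRUE
})

#' Particle swarm settings
#'
#' Defaults follow the study conditions: population 100, 50 iterations,
#' learning factors c1 = c2 = 2, inertia weight 0.9.
#'
#' @slot population particle count.
#' @slot iterations iteration count.
#' @slot c1,c2 cognitive and social learning factors.
#' @slot omega inertia weight.
#' @slot vMax velocity clamp magnitude.
#' @slot decodeThreshold position cutoff above which a dimension is selected.
#' @slot seed RNG seed for the run (NA allowed: caller's RNG state is used).
#' @exportClass SwarmConfig
setClass("SwarmConfig",
    slots = c(population = "integer", iterations = "integer",
              c1 = "numeric", c2 = "numeric", omega = "numeric",
              vMax = "numeric", decodeThreshold = "numeric",
              seed = "integer"))

setValidity("SwarmConfig", function(object) {
    if (object@population < 1L) return("'population' must be >= 1")
    if (object@iterations < 1L) return("'iterations' must be >= 1")
    if (object@omega < 0) return("'omega' must be >= 0")
    if (object@vMax <= 0) return("'vMax' must be > 0")
    if (object@decodeThreshold <= 0 || object@decodeThreshold >= 1)
        return("'decodeThreshold' must lie in (0, 1)")
    TRUE
})

#' @param population,iterations,c1,c2,omega,vMax,decodeThreshold,seed see slots.
#' @rdname SwarmConfig-class
#' @export
swarmConfig <- function(population = 100L, iterations = 50L, c1 = 2, c2 = 2,
                        omega = 0.9, vMax = 4, decodeThreshold = 0.5,
                        seed = NA_integer_) {
    new("SwarmConfig", population = as.integer(population),
        iterations = as.integer(iterations), c1 = c1, c2 = c2, omega = omega,
        vMax = vMax, decodeThreshold = decodeThreshold,
        seed = as.integer(seed))
}

#' Subset-cost settings for the wrapper search
#'
#' The wrapper cost is \code{alpha * Verror + beta * Nselected / Nall}, with
#' Verror the k-nearest-neighbour cross-validation error of the decoded
#' subset. alpha and beta must sum to 1; defaults 0.95 / 0.05.
#'
#' @slot alpha error weight.
#' @slot beta subset-size weight.
#' @slot knnK neighbour count.
#' @slot folds internal CV folds used to estimate the error.
#' @slot nAll total feature count of the search space (set by the runner).
#' @exportClass FitnessConfig
setClass("FitnessConfig",
    slots = c(alpha = "numeric", beta = "numeric", knnK = "integer",
              folds = "integer", nAll = "integer"))

setValidity("FitnessConfig", function(object) {
    if (object@alpha < 0 || object@beta < 0)
        return("'alpha' and 'beta' must be >= 0")
    if (abs(object@alpha + object@beta - 1) > 1e-9)
        return("'alpha' + 'beta' must equal 1")
    if (object@knnK < 1L) return("'knnK' must be >= 1")
    if (object@folds < 2L) return("'folds' must be >= 2")
    TRUE
})

#' @param alpha,beta,knnK,folds,nAll see slots.
#' @rdname FitnessConfig-class
#' @export
fitnessConfig <- function(alpha = 0.95, beta = 0.05, knnK = 5L, folds = 5L,
                          nAll = NA_integer_) {
    new("FitnessConfig", alpha = alpha, beta = beta, knnK = as.integer(knnK),
        folds = as.integer(folds), nAll = as.integer(nAll))
}

#' Result of one PSO wrapper run
#'
#' @slot selected integer indices of the selected features in the dataset the
#'   swarm searched (mapped back through the ranking by the pipeline).
#' @slot selectedNames feature names of \code{selected}.
#' @slot cost final global-best cost.
#' @slot errorComponent KNN CV error at the optimum.
#' @slot trace global-best cost after each iteration (non-increasing).
#' @slot gbestPosition continuous position decoding to \code{selected}.
#' @slot swarmConfig,fitnessConfig configuration snapshots.
#' @exportClass SelectionResult
setClass("SelectionResult",
    slots = c(selected = "integer", selectedNames = "character",
              cost = "numeric", errorComponent = "numeric",
              trace = "numeric", gbestPosition = "numeric",
              swarmConfig = "SwarmConfig", fitnessConfig = "FitnessConfig"))

#' Logistic biomarker-panel model
#'
#' Realises the panel probability PP = 1 / (1 + exp(-(constant +
#' sum(coefficient_i * expression_i)))): a logistic score for combining a
#' small gene panel into a single diagnostic probability.
#'
#' @slot constant intercept.
#' @slot coefficients named per-feature coefficients.
#' @slot table coefficient table (Variable, Coefficient, Std..Error, Wald,
#'   P.value) as produced by the maximum-likelihood fit.
#' @slot converged TRUE when IRLS converged.
#' @slot separationFlagged TRUE when (quasi-)perfect separation was detected;
#'   coefficients are then reported with a warning attached.
#' @exportClass PanelModel
setClass("PanelModel",
    slots = c(constant = "numeric", coefficients = "numeric",
              table = "data.frame", converged = "logical",
              separationFlagged = "logical"))

setValidity("PanelModel", function(object) {
    if (length(object@coefficients) &&
        (is.null(names(object@coefficients)) ||
         anyDuplicated(names(object@coefficients))))
        return("'coefficients' must have unique names")
    TRUE
})

#' Cross-validation accuracy report
#'
#' @slot accuracy overall accuracy in percent (mean of per-fold accuracies).
#' @slot perFold accuracy per fold, percent.
#' @slot folds fold count.
#' @slot subset feature names evaluated.
#' @slot classifier settings snapshot (list).
#' @slot seed fold-assignment seed.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
    slots = c(accuracy = "numeric", perFold = "numeric", folds = "integer",
              subset = "character", classifier = "list", seed = "integer"))

setValidity("EvaluationReport", function(object) {
    if (abs(object@accuracy - mean(object@perFold)) > 1e-9)
        return("'accuracy' must equal the mean of 'perFold'")
    if (object@accuracy < 0 || object@accuracy > 100)
        return("'accuracy' must lie in [0, 100]")
    TRUE
})

#' Ground-truth specification for planted synthetic datasets
#'
#' @slot nSamples,nInformative,nRedundant,nNoise,nClasses counts.
#' @slot classSep mean shift between adjacent classes, in noise-SD units.
#' @slot imbalanceRatio minority/majority class-size fraction in (0, 1].
#' @slot seed RNG seed.
#' @exportClass PlantSpec
setClass("PlantSpec",
    slots = c(nSamples = "integer", nInformative = "integer",
              nRedundant = "integer", nNoise = "integer",
              nClasses = "integer", classSep = "numeric",
              imbalanceRatio = "numeric", seed = "integer"))

setValidity("PlantSpec", function(object) {
    if (object@nSamples < 2L) return("'nSamples' must be >= 2")
    if (min(object@nInformative, object@nRedundant, object@nNoise) < 0L)
        return("feature counts must be >= 0")
    if (object@nRedundant > 0L && object@nInformative == 0L)
        return("redundant features require at least one informative feature")
    if (object@nClasses < 2L) return("'nClasses' must be >= 2")
    if (object@imbalanceRatio <= 0 || object@imbalanceRatio > 1)
        return("'imbalanceRatio' must lie in (0, 1]")
    TRUE
})

#' @param nSamples,nInformative,nRedundant,nNoise,classSep,imbalanceRatio,nClasses,seed
#'   see slots.
#' @rdname PlantSpec-class
#' @export
plantSpec <- function(nSamples = 100L, nInformative = 2L, nRedundant = 0L,
                      nNoise = 5L, classSep = 2, imbalanceRatio = 1,
                      nClasses = 2L, seed = 1L) {
    new("PlantSpec", nSamples = as.integer(nSamples),
        nInformative = as.integer(nInformative),
        nRedundant = as.integer(nRedundant), nNoise = as.integer(nNoise),
        nClasses = as.integer(nClasses), classSep = classSep,
        imbalanceRatio = imbalanceRatio, seed = as.integer(seed))
}

#' Manifest of one end-to-end pipeline run
#'
#' Records every stage output plus the configuration and seeds needed to
#' reproduce the run exactly.
#'
#' @slot config list of configuration snapshots per stage.
#' @slot seeds named integer seeds per stochastic stage.
#' @slot inputChecksum checksum of the input matrix and labels.
#' @slot removedFeatures features dropped by the sparsity filter.
#' @slot ranking the [RankingResult-class].
#' @slot selection the [SelectionResult-class] (indices in original space).
#' @slot report the [EvaluationReport-class] for the final subset.
#' @slot timestamps POSIXct start/end.
#' @exportClass RunManifest
setClass("RunManifest",
    slots = c(config = "list", seeds = "integer", inputChecksum = "character",
              removedFeatures = "character", ranking = "RankingResult",
              selection = "SelectionResult", report = "EvaluationReport",
              timestamps = "POSIXct"))
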