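#' @rdname TabularDataset-class
#' @param x,object a \code{TabularDataset}.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname TabularDataset-class
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname TabularDataset-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname TabularDataset-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname TabularDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @export
#' @rdname pairwiseAssociation
setGeneric("pairwiseAssociation",
    function(dataset, targets = NULL, config = associationConfig(),
             workers = 1L, includeLabel = TRUE)
        standardGeneric("pairwiseAssociation"))

#' @export
#' @rdname rankFeatures
setGeneric("rankFeatures",
    function(dataset, K = 100L, config = associationConfig(),
             measure = c("mic", "mi"), workers = 1L)
        standardGeneric("rankFeatures"))

#' @export
#' @rdname runPSO
setGeneric("runPSO",
    function(dataset, swarm = swarmConfig(), fitness = fitnessConfig())
        standardGeneric("runPSO"))

#' @export
#' @rdname filterSparseFeatures
setGeneric("filterSparseFeatures",
    function(dataset, maxZeroFraction = 0.5)
        standardGeneric("filterSparseFeatures"))

#' @export
#' @rdname randomOversample
setGeneric("randomOversample",
    function(dataset, seed = NULL) standardGeneric("randomOversample"))

#' @export
#' @rdname cvAccuracy
setGeneric("cvAccuracy",
    function(dataset, subset = NULL, folds = 10L, seed = 1L, cost = 1,
             gamma = NULL) standardGeneric("cvAccuracy"))

#' @export
#' @rdname fitPanel
setGeneric("fitPanel",
    function(dataset, subset = NULL) standardGeneric("fitPanel"))

#' @export
#' @rdname panelProbability
setGeneric("panelProbability",
    function(model, expression) standardGeneric("panelProbability"))
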