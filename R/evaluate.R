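# Final-subset validation: SVM cross-validation accuracy, logistic
# biomarker-panel scoring, and ROC/AUC.

#' Stratified SVM cross-validation accuracy
#'
#' Accuracy (percent) of a soft-margin RBF-kernel SVM over stratified k-fold
#' cross-validation, trained on the min-max-scaled selected features.
#' Multi-class data use the SVM library's one-vs-one scheme. The fold
#' assignment is seeded and recorded so that competing feature subsets can
#' be compared on identical folds.
#'
#' @param dataset a [TabularDataset-class].
#' @param subset non-empty feature indices or names (default: all features).
#' @param folds fold count (default 10).
#' @param seed fold-assignment seed.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF width (default 1/d for d selected features).
#' @return an [EvaluationReport-class].
#' @rdname cvAccuracy
#' @export
setMethod("cvAccuracy", "TabularDataset",
    function(dataset, subset = NULL, folds = 10L, seed = 1L, cost = 1,
             gamma = NULL) {
    if (is.null(subset)) subset <- seq_len(ncol(dataset@values))
    subset <- resolveIndices(dataset, subset)
    labels <- droplevels(dataset@labels)
    folds <- as.integer(folds)
    if (nlevels(labels) < 2L || min(table(labels)) < folds)
        stop(sprintf(paste0("labels cannot be stratified into %d folds ",
                            "(smallest class: %d)"),
                     folds, min(table(labels))), call. = FALSE)
    x <- minMaxScale(dataset@values[, subset, drop = FALSE])
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    fold <- stratifiedFolds(labels, folds, seed = seed)
    perFold <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        fit <- e1071::svm(x[tr, , drop = FALSE], labels[tr],
                          kernel = "radial", cost = cost, gamma = gamma,
                          scale = FALSE)
        pred <- stats::predict(fit, x[!tr, , drop = FALSE])
        100 * mean(pred == labels[!tr])
    }, numeric(1))
    new("EvaluationReport", accuracy = mean(perFold), perFold = perFold,
        folds = folds, subset = colnames(dataset@values)[subset],
        classifier = list(type = "svm-rbf", cost = cost, gamma = gamma),
        seed = as.integer(seed))
})

#' Panel probability score
#'
#' The logistic panel score
#' \deqn{PP = 1/(1 + \exp(-(constant + \sum_i coefficient_i \cdot
#' expression_i)))},
#' a per-sample disease probability from a fitted biomarker panel.
#'
#' @param model a [PanelModel-class].
#' @param expression named numeric vector, or a matrix/data.frame with one
#'   column per panel feature; names must cover the model's features.
#' @return probability (vector) in (0, 1).
#' @rdname panelProbability
#' @export
setMethod("panelProbability", "PanelModel", function(model, expression) {
    feats <- names(model@coefficients)
    if (is.null(dim(expression))) {
        if (length(feats)) {
            if (is.null(names(expression)))
                stopifnot(length(expression) == length(feats))
            else if (!all(feats %in% names(expression)))
                stop(sprintf("expression values missing for: %s",
                             paste(setdiff(feats, names(expression)),
                                   collapse = ", ")), call. = FALSE)
            else expression <- expression[feats]
            lin <- model@constant + sum(model@coefficients * expression)
        } else lin <- model@constant
        return(stats::plogis(lin))
    }
    expression <- as.matrix(expression)
    if (!all(feats %in% colnames(expression)))
        stop(sprintf("expression columns missing for: %s",
                     paste(setdiff(feats, colnames(expression)),
                           collapse = ", ")), call. = FALSE)
    stats::plogis(model@constant +
        drop(expression[, feats, drop = FALSE] %*% model@coefficients))
})

#' Fit a logistic biomarker panel
#'
#' Maximum-likelihood logistic regression (IRLS, convergence tolerance 1e-8,
#' at most 100 iterations) of a binary class label on the selected features.
#' The second factor level is modelled as the positive class. Reports the
#' coefficient table (Variable, Coefficient, Std. Error, Wald, P value);
#' (quasi-)perfect separation is flagged and the coefficients are still
#' returned with a warning.
#'
#' @param dataset a [TabularDataset-class] with binary labels.
#' @param subset feature indices or names; NULL for all, integer(0) for an
#'   intercept-only fit (whose constant is then log(p/(1-p)) of the class
#'   ratio).
#' @return a [PanelModel-class].
#' @rdname fitPanel
#' @export
setMethod("fitPanel", "TabularDataset", function(dataset, subset = NULL) {
    labels <- droplevels(dataset@labels)
    if (nlevels(labels) != 2L)
        stop("panel fitting requires binary labels", call. = FALSE)
    if (is.null(subset)) subset <- seq_len(ncol(dataset@values))
    subset <- if (length(subset)) resolveIndices(dataset, subset)
              else integer(0)
    y <- as.integer(labels) - 1L
    df <- as.data.frame(dataset@values[, subset, drop = FALSE])
    feats <- colnames(dataset@values)[subset]
    colnames(df) <- feats
    df$.y <- y
    fit <- withCallingHandlers(
        stats::glm(.y ~ ., data = df, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)),
        warning = function(w) invokeRestart("muffleWarning"))
    separated <- !fit$converged ||
        any(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8)
    if (separated)
        warning("(quasi-)perfect separation detected; coefficients unstable")
    cf <- summary(fit)$coefficients
    wald <- cf[, "z value"]^2
    tab <- data.frame(Variable = c(feats, "Constant"),
                      Coefficient = unname(c(cf[-1L, 1L], cf[1L, 1L])),
                      Std.Error = unname(c(cf[-1L, 2L], cf[1L, 2L])),
                      Wald = unname(c(wald[-1L], wald[1L])),
                      P.value = unname(c(cf[-1L, 4L], cf[1L, 4L])),
                      stringsAsFactors = FALSE)
    coefs <- stats::setNames(cf[-1L, 1L], feats)
    new("PanelModel", constant = unname(cf[1L, 1L]),
        coefficients = coefs, table = tab,
        converged = fit$converged, separationFlagged = separated)
})

#' ROC curve and AUC
#'
#' Area under the ROC curve via the tie-aware rank (Mann-Whitney) formula —
#' concordant pairs plus half-credit for ties over all positive/negative
#' pairs — together with the (FPR, TPR) points of the full threshold sweep
#' (trapezoidal integration of these points gives the same area).
#'
#' @param scores per-sample real scores (higher = more positive).
#' @param labels binary labels; the second sorted unique value (or second
#'   factor level) is the positive class.
#' @return list with \code{auc} and \code{curve} (data.frame of fpr, tpr).
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.factor(labels)
    labels <- droplevels(labels)
    if (nlevels(labels) != 2L)
        stop("ROC requires exactly two classes present", call. = FALSE)
    pos <- labels == levels(labels)[2L]
    n1 <- sum(pos); n0 <- sum(!pos)
    r <- rank(scores)  # average ranks: ties get half credit
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    ord <- order(scores, decreasing = TRUE)
    uniq <- !duplicated(scores[ord], fromLast = TRUE)
    tpr <- c(0, cumsum(pos[ord])[uniq] / n1)
    fpr <- c(0, cumsum(!pos[ord])[uniq] / n0)
    list(auc = auc, curve = data.frame(fpr = fpr, tpr = tpr))
}
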