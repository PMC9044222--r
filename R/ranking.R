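# mRMR ranking under the relevance/redundancy quotient criterion, with MIC
# as the association measure (discrete MI available as a baseline on
# already-discrete data).

# Memoised association accessor. For measure "mic" the self-association is 1
# for non-constant features (0 for constant); for "mi" the self-term is the
# plug-in entropy, which is what the literal double sum produces.
assocCache <- function(dataset, config, measure) {
    v <- dataset@values
    codes <- labelCodes(dataset@labels)
    memo <- new.env(parent = emptyenv())
    pairRaw <- function(i, j) {
        if (measure == "mic") {
            if (i == j)
                return(if (length(unique(v[, i])) < 2L) 0 else 1)
            mic(v[, i], v[, j], config)
        } else {
            mutualInfoDiscrete(v[, i], v[, j], logBase = config@logBase)
        }
    }
    pair <- function(i, j) {
        key <- paste(min(i, j), max(i, j))
        got <- memo[[key]]
        if (is.null(got)) {
            got <- pairRaw(i, j)
            memo[[key]] <- got
        }
        got
    }
    labelAssoc <- local({
        cache <- rep(NA_real_, ncol(v))
        function(i) {
            if (is.na(cache[i])) {
                cache[i] <<- if (measure == "mic") {
                    if (max(codes) == min(codes)) 0
                    else mic(v[, i], codes, config)
                } else {
                    mutualInfoDiscrete(v[, i], codes,
                                       logBase = config@logBase)
                }
            }
            cache[i]
        }
    })
    list(pair = pair, label = labelAssoc)
}

resolveIndices <- function(dataset, candidates) {
    if (is.character(candidates))
        candidates <- match(candidates, colnames(dataset@values))
    if (length(candidates) == 0L)
        stop("empty candidate set", call. = FALSE)
    if (anyNA(candidates) ||
        any(candidates < 1L | candidates > ncol(dataset@values)))
        stop("invalid feature indices", call. = FALSE)
    as.integer(candidates)
}

#' Relevance of a candidate feature set
#'
#' Mean association between the class label and each feature of the set:
#' \eqn{V = |S|^{-1} \sum_{x_i \in S} assoc(y; x_i)}.
#'
#' @param candidates feature indices or names (non-empty).
#' @param dataset a [TabularDataset-class].
#' @param config an [AssociationConfig-class].
#' @param measure \code{"mic"} (default) or \code{"mi"} (treats feature
#'   values as categorical codes; intended for already-discrete data).
#' @return scalar relevance V.
#' @export
relevance <- function(candidates, dataset, config = associationConfig(),
                      measure = c("mic", "mi")) {
    measure <- match.arg(measure)
    idx <- resolveIndices(dataset, candidates)
    a <- assocCache(dataset, config, measure)
    mean(vapply(idx, a$label, numeric(1)))
}

#' Redundancy of a candidate feature set
#'
#' Mean pairwise association over all ordered pairs of the set, including
#' the self-terms: \eqn{W = |S|^{-2} \sum_{x_i, x_j \in S} assoc(x_i; x_j)}.
#' At \code{|S| = 1} with the MIC measure this is the self-association 1.
#'
#' @inheritParams relevance
#' @return scalar redundancy W.
#' @export
redundancy <- function(candidates, dataset, config = associationConfig(),
                       measure = c("mic", "mi")) {
    measure <- match.arg(measure)
    idx <- resolveIndices(dataset, candidates)
    a <- assocCache(dataset, config, measure)
    s <- 0
    for (i in idx) for (j in idx) s <- s + a$pair(i, j)
    s / length(idx)^2
}

#' Greedy step score of the quotient criterion
#'
#' The standard incremental realisation of argmax V/W: a candidate's label
#' association divided by its mean association with the already-selected
#' features, floored at 1e-12 (the quotient is undefined at zero
#' redundancy; the floor makes non-redundant candidates win by a large
#' finite margin). With an empty selected set the score is the label
#' association itself.
#'
#' @param candidate a single feature index or name, not in \code{selected}.
#' @param selected previously selected feature indices or names (may be
#'   empty).
#' @inheritParams relevance
#' @return scalar step score.
#' @export
incrementalMiqScore <- function(candidate, selected, dataset,
                                config = associationConfig(),
                                measure = c("mic", "mi")) {
    measure <- match.arg(measure)
    cand <- resolveIndices(dataset, candidate)
    stopifnot(length(cand) == 1L)
    a <- assocCache(dataset, config, measure)
    if (length(selected) == 0L)
        return(a$label(cand))
    sel <- resolveIndices(dataset, selected)
    if (cand %in% sel)
        stop("candidate already selected", call. = FALSE)
    red <- mean(vapply(sel, function(s) a$pair(cand, s), numeric(1)))
    a$label(cand) / max(red, 1e-12)
}

#' Rank features by greedy mRMR with the quotient criterion
#'
#' Picks the feature with maximal label association first, then repeatedly
#' picks the candidate maximising [incrementalMiqScore()] until min(K, p)
#' features are ranked. Deterministic: ties are broken by the lowest feature
#' index. The per-step winning scores, relevances and redundancies are
#' recorded at selection time. K larger than the feature count caps the
#' list with a warning (all features are then ranked).
#'
#' @param dataset a preprocessed [TabularDataset-class].
#' @param K requested list length (the wrapper default downstream is 100).
#' @param config an [AssociationConfig-class].
#' @param measure association measure, \code{"mic"} or \code{"mi"}.
#' @param workers forked workers for the label-association pass.
#' @return a [RankingResult-class].
#' @rdname rankFeatures
#' @export
setMethod("rankFeatures", "TabularDataset",
    function(dataset, K = 100L, config = associationConfig(),
             measure = c("mic", "mi"), workers = 1L) {
    measure <- match.arg(measure)
    K <- as.integer(K)
    stopifnot(K >= 1L)
    p <- ncol(dataset@values)
    capped <- K > p
    if (capped)
        warning(sprintf("K = %d exceeds the %d available features; ranking all",
                        K, p))
    m <- min(K, p)
    a <- assocCache(dataset, config, measure)
    labA <- if (workers > 1L) {
        unlist(parallel::mclapply(seq_len(p), a$label, mc.cores = workers))
    } else {
        vapply(seq_len(p), a$label, numeric(1))
    }
    ord <- integer(m); sc <- numeric(m); rel <- numeric(m); red <- numeric(m)
    remaining <- seq_len(p)
    redSum <- numeric(p)  # sum of assoc(candidate, s) over selected s
    # first pick: maximal relevance, lowest index on ties
    first <- remaining[which.max(labA[remaining])]
    ord[1L] <- first; sc[1L] <- labA[first]; rel[1L] <- labA[first]
    red[1L] <- 0
    remaining <- setdiff(remaining, first)
    if (m > 1L) for (step in 2:m) {
        last <- ord[step - 1L]
        for (c in remaining) redSum[c] <- redSum[c] + a$pair(c, last)
        meanRed <- redSum[remaining] / (step - 1L)
        score <- labA[remaining] / pmax(meanRed, 1e-12)
        pick <- remaining[which.max(score)]
        ord[step] <- pick
        sc[step] <- score[match(pick, remaining)]
        rel[step] <- labA[pick]
        red[step] <- meanRed[match(pick, remaining)]
        remaining <- setdiff(remaining, pick)
    }
    new("RankingResult", order = ord,
        featureNames = colnames(dataset@values)[ord],
        scores = sc, relevance = rel, redundancy = red, K = K,
        capped = capped, measure = measure)
})
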