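# Shared fixtures and independent oracles, built in code at test time.

# Two well-separated Gaussian blobs (binary labels).
makeBlobs <- function(n = 100, d = 2, sep = 10, seed = 1) {
    set.seed(seed)
    half <- n %/% 2
    labels <- rep(c("a", "b"), c(half, n - half))
    centers <- ifelse(labels == "a", -sep / 2, sep / 2)
    values <- sapply(seq_len(d), function(j) rnorm(n, mean = centers))
    colnames(values) <- paste0("f", seq_len(d))
    tabularDataset(values, labels)
}

# Direct plug-in MI (nats or bits) from a 2-D count table: the oracle for
# mutualInfoDiscrete and for grid MI.
handMI <- function(counts, logBase = 2) {
    p <- counts / sum(counts)
    px <- rowSums(p); py <- colSums(p)
    s <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
        if (p[i, j] > 0)
            s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]), base = logBase)
    s
}

# Brute-force AUC by concordant-pair counting with half-credit ties.
handAUC <- function(scores, labels) {
    labels <- as.factor(labels)
    pos <- which(labels == levels(labels)[2])
    neg <- which(labels != levels(labels)[2])
    s <- 0
    for (i in pos) for (j in neg)
        s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    s / (length(pos) * length(neg))
}

# Independent greedy mRMR-quotient oracle working from a full pairwise
# association table (feature-feature matrix S, label vector la).
handGreedyMIQ <- function(S, la, K) {
    p <- length(la)
    remaining <- seq_len(p)
    order <- integer(0)
    for (step in seq_len(min(K, p))) {
        score <- sapply(remaining, function(c) {
            if (length(order) == 0) return(la[c])
            la[c] / max(mean(S[c, order]), 1e-12)
        })
        pick <- remaining[which.max(score)]
        order <- c(order, pick)
        remaining <- setdiff(remaining, pick)
    }
    order
}
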