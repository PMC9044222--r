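rankingFixture <- function(seed = 17, n = 40, nInf = 2, nRed = 1, nNoise = 3) {
    makePlantedDataset(plantSpec(nSamples = n, nInformative = nInf,
                                 nRedundant = nRed, nNoise = nNoise,
                                 classSep = 3, seed = seed))$dataset
}

test_that("relevance is the mean label association of the set", {
    d <- rankingFixture()
    v <- featureValues(d)
    a1 <- associationToLabel(v[, 1], classLabels(d))
    a2 <- associationToLabel(v[, 2], classLabels(d))
    expect_equal(relevance(1, d), a1)
    expect_equal(relevance(c(1, 2), d), (a1 + a2) / 2)
    S <- pairwiseAssociation(d, targets = 1:4)
    la <- attr(S, "labelAssociation")
    expect_equal(relevance(1:4, d), mean(la))
    expect_error(relevance(integer(0), d), "empty")
})

test_that("redundancy is the literal double sum including self-terms", {
    d <- rankingFixture()
    expect_equal(redundancy(3, d), 1)  # MIC self-term over |S|^2 = 1
    S <- pairwiseAssociation(d, includeLabel = FALSE)
    idx <- c(1, 2, 5)
    brute <- sum(S[idx, idx]) / length(idx)^2
    expect_equal(redundancy(idx, d), brute)
    # two near-independent noise features: diagonal terms dominate, ~0.5
    expect_lt(abs(redundancy(c(4, 5), d) -
                  (2 + 2 * S[4, 5]) / 4), 1e-12)
})

test_that("the greedy step score follows the quotient rule", {
    d <- rankingFixture()
    v <- featureValues(d)
    la1 <- associationToLabel(v[, 1], classLabels(d))
    expect_equal(incrementalMiqScore(1, integer(0), d), la1)
    S <- pairwiseAssociation(d, includeLabel = FALSE)
    expected <- associationToLabel(v[, 4], classLabels(d)) /
        max(mean(c(S[4, 1], S[4, 2])), 1e-12)
    expect_equal(incrementalMiqScore(4, c(1, 2), d), expected)
    expect_error(incrementalMiqScore(1, c(1, 2), d), "already selected")
})

test_that("greedy ranking matches an independent argmax oracle (p = 6)", {
    for (seed in c(17, 31)) {
        d <- rankingFixture(seed = seed)
        S <- pairwiseAssociation(d, includeLabel = FALSE)
        la <- attr(pairwiseAssociation(d), "labelAssociation")
        oracle <- handGreedyMIQ(S, la, K = 6)
        r <- rankFeatures(d, K = 6)
        expect_equal(r@order, as.integer(oracle))
        expect_equal(r@relevance, unname(la[r@order]))
    }
})

test_that("rankings are prefix-consistent in K and cap K at p", {
    d <- rankingFixture(seed = 23)
    full <- rankFeatures(d, K = 6)
    for (k in 1:5)
        expect_equal(rankFeatures(d, K = k)@order, full@order[1:k])
    expect_warning(capped <- rankFeatures(d, K = 10), "exceeds")
    expect_true(capped@capped)
    expect_equal(length(capped@order), 6L)
})

test_that("a duplicate of the selected feature is deferred behind less
           redundant informative candidates", {
    set.seed(43)
    labels <- rep(c(0, 1), each = 15)
    v <- cbind(f1 = labels + rnorm(30, sd = 0.5), dup = 0,
               f2 = labels + rnorm(30, sd = 0.5),
               n1 = rnorm(30), n2 = rnorm(30))
    v[, "dup"] <- v[, "f1"]  # perfectly redundant copy of f1
    d <- tabularDataset(v, labels)
    r <- rankFeatures(d, K = 5)
    expect_equal(r@featureNames[1], "f1")
    # dup's quotient is capped at la(f1)/1 while f2 scores la/red > that
    expect_lt(match("f2", r@featureNames), match("dup", r@featureNames))

    # exact label copy wins the first pick on the lowest-index tie-break
    d2 <- tabularDataset(cbind(a = labels + 0.0, b = labels + 0.0,
                               c = rnorm(30)), labels)
    expect_equal(rankFeatures(d2, K = 3)@order[1], 1L)
})

test_that("mi-measure ranking reproduces a hand-checkable discrete case", {
    # 4 discrete features: f1 = label, f2 = noisy label, f3 = f1 copy,
    # f4 = independent
    y <- rep(c(0, 1), each = 8)
    f1 <- y
    f2 <- y; f2[c(1, 9)] <- 1 - f2[c(1, 9)]
    f3 <- y
    f4 <- rep(c(0, 1), 8)
    d <- tabularDataset(cbind(f1 = f1, f2 = f2, f3 = f3, f4 = f4), y)
    r <- rankFeatures(d, K = 4, measure = "mi")
    la <- sapply(list(f1, f2, f3, f4),
                 function(f) mutualInfoDiscrete(f, y))
    S <- outer(1:4, 1:4, Vectorize(function(i, j)
        mutualInfoDiscrete(list(f1, f2, f3, f4)[[i]],
                           list(f1, f2, f3, f4)[[j]])))
    expect_equal(r@order, as.integer(handGreedyMIQ(S, la, 4)))
    expect_equal(r@order[1], 1L)
})
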