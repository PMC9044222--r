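test_that("discrete mutual information matches closed forms and hand sums", {
    expect_equal(mutualInfoDiscrete(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
    expect_equal(mutualInfoDiscrete(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
    # 2x2 counts {(0,0):2, (0,1):1, (1,0):1, (1,1):2}
    x <- c(0, 0, 0, 1, 1, 1)
    y <- c(0, 0, 1, 0, 1, 1)
    expect_equal(mutualInfoDiscrete(x, y),
                 handMI(matrix(c(2, 1, 1, 2), 2)))
    expect_equal(mutualInfoDiscrete(x, y), mutualInfoDiscrete(y, x))
    expect_error(mutualInfoDiscrete(1:3, 1:4), "lengths differ")
    expect_error(mutualInfoDiscrete(integer(0), integer(0)), "empty")
})

test_that("MI equals the entropy decomposition on random discrete pairs", {
    set.seed(11)
    for (rep in 1:20) {
        x <- sample(0:3, 60, replace = TRUE)
        y <- sample(0:2, 60, replace = TRUE)
        hx <- mmpso:::entropyDiscrete(x)
        hy <- mmpso:::entropyDiscrete(y)
        hxy <- mmpso:::entropyDiscrete(paste(x, y))
        expect_equal(mutualInfoDiscrete(x, y), hx + hy - hxy,
                     tolerance = 1e-12)
    }
})

test_that("characteristic matrix handles bijections, constants and small n", {
    cm <- characteristicMatrix(1:16, 1:16)
    expect_equal(cm@entries["2", "2"], 1)
    expect_true(all(cm@entries >= 0 & cm@entries <= 1, na.rm = TRUE))

    cm0 <- characteristicMatrix(1:16, rep(3, 16))
    expect_true(cm0@constantInput)
    expect_true(all(cm0@entries == 0, na.rm = TRUE))

    # floor(10^0.6) = 3 < 4: no admissible grid at the default exponent
    expect_error(characteristicMatrix(1:10, 1:10), "minimum usable n")
    expect_error(characteristicMatrix(1:5, 1:4), "lengths differ")
    expect_error(characteristicMatrix(c(1:15, NA), 1:16), "non-finite")
})

test_that("mic calibration: perfect dependence, constants, symmetry", {
    set.seed(3)
    x <- rnorm(20)
    expect_equal(mic(x, x), 1)
    expect_equal(mic(x, rep(1, 20)), 0)
    y <- rnorm(20)
    expect_equal(mic(x, y), mic(y, x))
    cfgE <- associationConfig(mode = "exhaustive")
    expect_equal(mic(x, y, cfgE), mic(y, x, cfgE))
})

test_that("approx mode equals the exhaustive-enumeration oracle", {
    set.seed(21)
    cfgA <- associationConfig()
    cfgE <- associationConfig(mode = "exhaustive")
    for (rep in 1:10) {
        n <- sample(11:12, 1)
        x <- runif(n)
        y <- if (rep %% 2) runif(n) else x + rnorm(n, sd = 0.3)
        expect_equal(mic(x, y, cfgA), mic(x, y, cfgE), tolerance = 1e-12)
        mA <- characteristicMatrix(x, y, cfgA)@entries
        mE <- characteristicMatrix(x, y, cfgE)@entries
        expect_equal(mA, mE, tolerance = 1e-12)
    }
    # wider budget exercises (2,3)/(3,2) grids as well
    cfgA8 <- associationConfig(bExponent = 0.8)
    cfgE8 <- associationConfig(bExponent = 0.8, mode = "exhaustive")
    for (rep in 1:10) {
        x <- runif(10); y <- x^2 + rnorm(10, sd = 0.2)
        expect_equal(mic(x, y, cfgA8), mic(x, y, cfgE8), tolerance = 1e-12)
    }
})

test_that("mic is invariant under strictly monotone transforms of an axis", {
    set.seed(5)
    x <- rnorm(50)
    base <- mic(x, x)
    expect_equal(mic(x, exp(x)), base)
    expect_equal(mic(x, x^3), base)
    expect_equal(mic(exp(x), x^3), base)
})

test_that("noiseless functional relationships reach mic close to 1", {
    for (kind in c("linear", "quadratic", "sine")) {
        p <- makeFunctionalPair(kind, n = 1000, noiseSd = 0, seed = 9)
        expect_gte(mic(p$x, p$y), 0.99)
    }
})

test_that("label association separates classes and flags degenerate labels", {
    labels <- rep(c("n", "t"), each = 10)
    x <- c(rnorm(10, -5), rnorm(10, 5))
    expect_equal(associationToLabel(x, labels), 1)
    expect_equal(associationToLabel(rep(1:5, 4), labels), 0)
    expect_warning(r <- associationToLabel(rnorm(20), rep("t", 20)),
                   "single class")
    expect_equal(r, 0)
})

test_that("pairwise association is worker-invariant and matches single calls", {
    out <- makePlantedDataset(plantSpec(nSamples = 40, nInformative = 2,
                                        nRedundant = 1, nNoise = 2,
                                        classSep = 2, seed = 13))
    d <- out$dataset
    S1 <- pairwiseAssociation(d, workers = 1L)
    S2 <- pairwiseAssociation(d, workers = 2L)
    expect_identical(S1, S2)
    expect_equal(unname(diag(S1)), rep(1, 5))
    v <- featureValues(d)
    expect_equal(S1["inf01", "noise02"], mic(v[, "inf01"], v[, "noise02"]))
    expect_equal(S1["inf02", "red01"], mic(v[, "inf02"], v[, "red01"]))
    la <- attr(S1, "labelAssociation")
    expect_equal(unname(la["inf01"]),
                 associationToLabel(v[, "inf01"], classLabels(d)))
})
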