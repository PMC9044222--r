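test_that("position decoding uses a strict threshold", {
    expect_equal(decodeSubset(rep(0, 5)), integer(0))
    expect_equal(decodeSubset(rep(1, 5)), 1:5)
    expect_equal(decodeSubset(c(0.2, 0.7, 0.5), 0.5), 2L)
})

test_that("knn error is zero on separated blobs and traceable at tiny n", {
    d <- makeBlobs(n = 100, sep = 10, seed = 2)
    fold <- mmpso:::stratifiedFolds(classLabels(d), 5, seed = 3)
    expect_equal(knnError(d, 1:2, fitnessConfig(), fold), 0)
    expect_error(knnError(d, integer(0), fitnessConfig(), fold), "empty")

    # hand-traced 1-NN, 2 folds: feature is 1-D, folds fixed by hand
    v <- matrix(c(0, 1, 10, 11, 0.4, 1.4, 10.4, 11.4), ncol = 1,
                dimnames = list(NULL, "f"))
    labels <- c("a", "a", "b", "b", "a", "a", "b", "b")
    toy <- tabularDataset(v, labels)
    fold <- c(1, 1, 1, 1, 2, 2, 2, 2)
    # every held-out point's nearest neighbour in the other fold shares its
    # class, so the traced error is 0
    expect_equal(knnError(toy, 1, fitnessConfig(knnK = 1, folds = 2), fold),
                 0)
    # relabel fold 1 to b,a,a,b: tracing each held-out point's nearest
    # neighbour gives errors (1,0,1,0) in each fold
    labels2 <- c("b", "a", "a", "b", "a", "a", "b", "b")
    toy2 <- tabularDataset(v, labels2)
    expect_equal(knnError(toy2, 1, fitnessConfig(knnK = 1, folds = 2), fold),
                 mean(c(mean(c(1, 0, 1, 0)), mean(c(1, 0, 1, 0)))))
})

test_that("knn error is near chance under permuted labels", {
    set.seed(5)
    errs <- replicate(10, {
        d <- makeBlobs(n = 100, sep = 10, seed = sample.int(1e6, 1))
        shuffled <- tabularDataset(featureValues(d),
                                   sample(as.character(classLabels(d))))
        fold <- mmpso:::stratifiedFolds(classLabels(shuffled), 5,
                                        seed = sample.int(1e6, 1))
        knnError(shuffled, 1:2, fitnessConfig(), fold)
    })
    # binomial 3-sigma band around 0.5 for n = 100, averaged over 10 runs
    expect_lt(abs(mean(errs) - 0.5), 3 * 0.05 / sqrt(10) + 0.05)
})

test_that("the wrapper cost is the weighted error plus size penalty", {
    d <- makeBlobs(n = 60, sep = 10, seed = 7)
    fold <- mmpso:::stratifiedFolds(classLabels(d), 5, seed = 1)
    fc <- fitnessConfig()
    cost <- fitnessCost(c(0.9, 0.2), d, fc, fold)
    err <- attr(cost, "errorComponent")
    expect_equal(as.numeric(cost), 0.95 * err + 0.05 * 1 / 2)
    # empty decoding: worst-case error by convention, cost = alpha
    costEmpty <- fitnessCost(c(0.1, 0.2), d, fc, fold)
    expect_equal(as.numeric(costEmpty), 0.95)
    expect_equal(attr(costEmpty, "errorComponent"), 1)
    # direct substitution: error 0.2, 10 of 100 features
    expect_equal(0.95 * 0.2 + 0.05 * 10 / 100, 0.195)
})

test_that("velocity and position updates follow the swarm equations", {
    cfg <- swarmConfig(omega = 0.9, c1 = 2, c2 = 2, vMax = 4)
    # forced r1 = r2 = 0: pure inertia
    expect_equal(updateVelocity(1.5, 0.2, 0.4, 0.8, cfg, r1 = 0, r2 = 0),
                 0.9 * 1.5)
    # converged particle stays put
    expect_equal(updateVelocity(0, 0.5, 0.5, 0.5, cfg, r1 = 0.3, r2 = 0.7),
                 0)
    # scalar hand substitution: 0.9*1 + 2*0.5*0.2 + 2*0.5*0.4 = 1.5
    expect_equal(updateVelocity(1, 0, 0.2, 0.4, cfg, r1 = 0.5, r2 = 0.5),
                 1.5)
    # clamping at vMax
    expect_equal(updateVelocity(10, 0, 1, 1, cfg, r1 = 1, r2 = 1), 4)

    expect_equal(updatePosition(0.3, 0.2), 0.5)
    expect_equal(updatePosition(0.9, 0.5), 1)
    expect_equal(updatePosition(0.4, -0.9), 0)
    expect_equal(updatePosition(0.7, 0), 0.7)
})

test_that("a motionless one-particle swarm returns its initial decoding", {
    d <- makeBlobs(n = 60, d = 4, sep = 10, seed = 9)
    res <- runPSO(d, swarmConfig(population = 1, iterations = 1,
                                 c1 = 0, c2 = 0, omega = 0, seed = 4),
                  fitnessConfig())
    expect_length(res@trace, 1)
    expect_equal(res@selected,
                 decodeSubset(res@gbestPosition, 0.5))
    fold <- NULL  # decomposition identity checked from the slots
    expect_equal(res@cost,
                 0.95 * res@errorComponent +
                 0.05 * length(res@selected) / 4, tolerance = 1e-12)
})

test_that("runs are reproducible, traces decrease, bounds hold", {
    out <- makePlantedDataset(plantSpec(nSamples = 80, nInformative = 2,
                                        nRedundant = 0, nNoise = 8,
                                        classSep = 3, seed = 15))
    cfg <- swarmConfig(population = 10, iterations = 8, seed = 99)
    r1 <- runPSO(out$dataset, cfg, fitnessConfig())
    r2 <- runPSO(out$dataset, cfg, fitnessConfig())
    expect_identical(r1, r2)
    expect_false(is.unsorted(rev(r1@trace)))
    expect_true(all(r1@gbestPosition >= 0 & r1@gbestPosition <= 1))
    expect_equal(r1@cost,
                 0.95 * r1@errorComponent + 0.05 * length(r1@selected) / 10,
                 tolerance = 1e-12)
    expect_error(runPSO(tabularDataset(matrix(rnorm(20), 10, 2,
                            dimnames = list(NULL, c("a", "b"))),
                            rep("x", 10)),
                        cfg, fitnessConfig()),
                 "fewer than two classes")
})

test_that("with beta = 0 a perfectly separating feature reaches zero error", {
    set.seed(33)
    labels <- rep(c("a", "b"), each = 30)
    v <- cbind(sep = ifelse(labels == "a", 0, 10) + rnorm(60, sd = 0.5),
               n1 = rnorm(60), n2 = rnorm(60), n3 = rnorm(60))
    d <- tabularDataset(v, labels)
    res <- runPSO(d, swarmConfig(population = 20, iterations = 15,
                                 seed = 5),
                  fitnessConfig(alpha = 1, beta = 0))
    expect_equal(res@errorComponent, 0)
    expect_true(1L %in% res@selected)
})
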