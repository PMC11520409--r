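# small, fast training fixtures: 6x6 grids, narrow network
smallSim <- function(seed = 1, ...) {
    simLayeredPair(syntheticConfig(gridShape = c(6, 6), nLayers = 3,
                                   gTotal = 30, genesPerLayer = 6,
                                   seed = seed, ...))
}
smallCfg <- function(seed = 0, ...) {
    trainConfig(epochs = 60, warmupEpochs = 20, hiddenDims = c(16, 8),
                planRefreshEvery = 5, seed = seed, ...)
}

test_that("gamma = 0 reduces training to the pure autoencoder", {
    sim <- smallSim()
    r0 <- trainPair(sim$sliceX, sim$sliceY, config = smallCfg(gamma = 0))
    expect_true(all(trainingHistory(r0)$lossUOT == 0))
    expect_true(all(trainingHistory(r0)$lossTotal ==
                    trainingHistory(r0)$lossRecon))
    # the post-hoc plan still exists and carries mass
    expect_gt(sum(transportMatrix(transportPlan(r0))), 0.1)
})

test_that("training is bit-reproducible under a fixed seed", {
    sim <- smallSim()
    cfg <- smallCfg()
    r1 <- trainPair(sim$sliceX, sim$sliceY, config = cfg)
    r2 <- trainPair(sim$sliceX, sim$sliceY, config = cfg)
    expect_identical(trainingHistory(r1), trainingHistory(r2))
    expect_identical(embedding(r1), embedding(r2))
    expect_identical(transportMatrix(transportPlan(r1)),
                     transportMatrix(transportPlan(r2)))
    r3 <- trainPair(sim$sliceX, sim$sliceY, config = smallCfg(seed = 1))
    expect_false(identical(embedding(r1), embedding(r3)))
})

test_that("training reduces the reconstruction loss", {
    for (seed in 1:3) {
        sim <- smallSim(seed = seed)
        res <- trainPair(sim$sliceX, sim$sliceY, config = smallCfg())
        h <- trainingHistory(res)
        expect_lt(h$lossRecon[nrow(h)], h$lossRecon[1])
        expect_true(all(is.finite(as.matrix(h[, -1]))))
        expect_equal(nrow(h), 60L)
    }
})

test_that("self-alignment of identical slices recovers the identity matching", {
    sim <- simLayeredPair(syntheticConfig(gridShape = c(8, 8),
                                          batchShift = 0, gTotal = 40,
                                          seed = 3))
    twin <- STSlice(coords = spatialCoords(sim$sliceX),
                    logcounts = SummarizedExperiment::assay(sim$sliceX,
                                                            "logcounts"),
                    labels = spotLabels(sim$sliceX), sliceId = "twin")
    res <- trainPair(sim$sliceX, twin,
                     config = trainConfig(epochs = 100, warmupEpochs = 30,
                                          hiddenDims = c(32, 16), seed = 0))
    m <- maxProbMatching(transportPlan(res))
    expect_gte(mean(matchIndices(m) == seq_len(64)), 0.95)
})

test_that("slices must share the gene list", {
    sim <- smallSim()
    trimmed <- sim$sliceY[-1, ]
    expect_error(trainPair(sim$sliceX, trimmed, config = smallCfg()),
                 "gene list")
})

test_that("integrating a new slice: frozen model, embedding reuse, ids", {
    sim <- smallSim(seed = 2)
    res <- trainPair(sim$sliceX, sim$sliceY, config = smallCfg())
    # frozen model: parameters bit-identical before/after
    thBefore <- SliceOT:::.flatten_params(trainedModel(res))
    newSlice <- STSlice(coords = spatialCoords(sim$sliceY),
                        logcounts = SummarizedExperiment::assay(sim$sliceY,
                                                                "logcounts"),
                        labels = spotLabels(sim$sliceY), sliceId = "new")
    r2 <- integrateNewSlice(res, newSlice,
                            config = smallCfg(fineTuneEpochs = 0))
    expect_identical(SliceOT:::.flatten_params(trainedModel(r2)), thBefore)
    # a slice identical to a training slice lands on that slice's embedding
    nNew <- nSpots(newSlice)
    zNew <- embedding(r2)[sliceIds(r2) == "new", ]
    zY <- embedding(res)[sliceIds(res) == "sliceY", ]
    expect_equal(zNew, zY, tolerance = 1e-10)
    expect_equal(levels(sliceIds(r2)), c("sliceX", "sliceY", "new"))
    expect_equal(nrow(embedding(r2)), nrow(embedding(res)) + nNew)
    # plan couples the new slice to the requested reference slice
    expect_equal(dim(transportMatrix(transportPlan(r2))),
                 c(nNew, sum(sliceIds(res) == "sliceX")))
    expect_error(integrateNewSlice(res, newSlice[-1, ]), "mismatch")
    expect_error(integrateNewSlice(res, newSlice, referenceId = "ghost",
                                   config = smallCfg(fineTuneEpochs = 0)),
                 "not present")
})

test_that("fine-tuning adapts the model to the new slice", {
    sim <- smallSim(seed = 4)
    res <- trainPair(sim$sliceX, sim$sliceY, config = smallCfg())
    other <- smallSim(seed = 9)$sliceX
    other2 <- STSlice(coords = spatialCoords(other),
                      logcounts = SummarizedExperiment::assay(other,
                                                              "logcounts"),
                      sliceId = "other")
    r2 <- integrateNewSlice(res, other2,
                            config = smallCfg(fineTuneEpochs = 10))
    expect_false(identical(SliceOT:::.flatten_params(trainedModel(r2)),
                           SliceOT:::.flatten_params(trainedModel(res))))
})

test_that("training configuration is validated", {
    expect_error(trainConfig(gamma = 1.5), "gamma")
    expect_error(trainConfig(epochs = 0), "epochs")
    expect_error(trainConfig(lr = 0), "lr")
    cfg <- trainConfig(partial = TRUE)
    expect_identical(cfg$rho1, Inf)
    expect_identical(cfg$rho2, 0.01)
})
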