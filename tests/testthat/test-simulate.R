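test_that("layered pair: noiseless twins, rigidity, band counts", {
    cfg <- syntheticConfig(noiseSd = 0, batchShift = 0, seed = 1)
    sim <- simLayeredPair(cfg)
    expect_identical(
        SummarizedExperiment::assay(sim$sliceX, "logcounts")[, 1:400],
        SummarizedExperiment::assay(sim$sliceY, "logcounts")[, 1:400],
        ignore_attr = TRUE)
    expect_equal(unname(table(spotLabels(sim$sliceX))),
                 rep(100L, 4), ignore_attr = TRUE)  # 20x20, 4 layers
    cfg2 <- syntheticConfig(rotationDeg = 90, seed = 2)
    sim2 <- simLayeredPair(cfg2)
    expect_equal(as.matrix(dist(spatialCoords(sim2$sliceY))),
                 as.matrix(dist(spatialCoords(sim2$sliceX))),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_identical(sim$truth, 1:400)
    # planted motion composed with ground truth reproduces coordinates
    cfg3 <- syntheticConfig(rotationDeg = 35, translation = c(2, -1),
                            seed = 3)
    sim3 <- simLayeredPair(cfg3)
    expect_equal(SliceOT:::.rigid2d(spatialCoords(sim3$sliceX), 35,
                                    c(2, -1)),
                 spatialCoords(sim3$sliceY)[sim3$truth, ],
                 tolerance = 1e-10)
})

test_that("marker genes are elevated by layerEffect inside their band", {
    cfg <- syntheticConfig(gridShape = c(40, 40), nLayers = 4,
                           layerEffect = 1, batchShift = 0, noiseSd = 0.3,
                           seed = 4)
    sim <- simLayeredPair(cfg)
    lc <- t(SummarizedExperiment::assay(sim$sliceX, "logcounts"))
    band <- spotLabels(sim$sliceX)
    marker1 <- 1:10                     # layer-1 markers
    inBand <- colMeans(lc[band == "layer1", marker1])
    outBand <- colMeans(lc[band != "layer1", marker1])
    # difference ~ layerEffect; t-statistic at this n makes 0.1 slack safe
    expect_equal(mean(inBand - outBand), 1, tolerance = 0.1)
})

test_that("partial pair crops by columns with the documented overlap", {
    cfg <- syntheticConfig(gridShape = c(10, 10), overlapFraction = 0.7,
                           seed = 5)
    sim <- simPartialPair(cfg)
    expect_equal(nSpots(sim$sliceX), 70L)
    expect_equal(nSpots(sim$sliceY), 70L)
    expect_equal(sum(!is.na(sim$truth)), 40L)   # shared middle = 40%
    # ground truth maps shared spots onto identical coordinates (after
    # undoing the planted motion; default motion is identity)
    ok <- !is.na(sim$truth)
    expect_equal(spatialCoords(sim$sliceX)[ok, ],
                 spatialCoords(sim$sliceY)[sim$truth[ok], ],
                 tolerance = 1e-10)
    full <- syntheticConfig(gridShape = c(10, 10), overlapFraction = 1,
                            seed = 5)
    simF <- simPartialPair(full)
    expect_equal(nSpots(simF$sliceX), 100L)
    expect_equal(simF$truth, 1:100)
    expect_error(simPartialPair(syntheticConfig(overlapFraction = 0.5)),
                 "shared")
})

test_that("multi-stack: label drift, determinism, independent motions", {
    cfg <- syntheticConfig(gridShape = c(8, 8), seed = 6, rotationDeg = 15)
    st <- simMultiStack(cfg, nSlices = 3)
    expect_length(st$slices, 3L)
    labSets <- lapply(st$slices, function(s) levels(spotLabels(s)))
    expect_true(all(vapply(labSets, identical, TRUE, labSets[[1]])))
    drift <- simMultiStack(cfg, nSlices = 3, labelDrift = TRUE)
    sizes <- vapply(drift$slices,
                    function(s) nlevels(spotLabels(s)), 0L)
    expect_true(all(diff(sizes) > 0))
    st2 <- simMultiStack(cfg, nSlices = 3)
    expect_identical(
        SummarizedExperiment::assay(st$slices[[2]], "logcounts"),
        SummarizedExperiment::assay(st2$slices[[2]], "logcounts"))
    expect_identical(st$truth[[2]], seq_len(64))
})

test_that("count mode produces integer counts usable by preprocessing", {
    cfg <- syntheticConfig(gridShape = c(6, 6), countMode = TRUE, seed = 7)
    sim <- simLayeredPair(cfg)
    cn <- SummarizedExperiment::assay(sim$sliceX, "counts")
    expect_true(all(cn >= 0 & cn == round(cn)))
    out <- normalizeAndIntersect(list(sim$sliceX, sim$sliceY), nHVG = 30)
    expect_identical(rownames(out[[1]]), rownames(out[[2]]))
    expect_lte(nrow(out[[1]]), 30L)
})

test_that("config validation rejects impossible settings", {
    expect_error(syntheticConfig(nLayers = 30, gridShape = c(10, 10)),
                 "grid rows")
    expect_error(syntheticConfig(overlapFraction = 0), "overlapFraction")
    expect_error(syntheticConfig(noiseSd = -1), "nonnegative")
})
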