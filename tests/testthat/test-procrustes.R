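rot2 <- function(deg) {
    th <- deg * pi / 180
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

test_that("identity registration from a diagonal plan", {
    xy <- as.matrix(expand.grid(0:3, 0:3))
    tr <- weightedProcrustes(xy, xy, diag(16) / 16)
    expect_equal(tr@rotation, diag(2), tolerance = 1e-10)
    expect_equal(tr@translation, c(0, 0), tolerance = 1e-10)
})

test_that("planted rotations and translations are recovered exactly", {
    xy <- as.matrix(expand.grid(0:4, 0:4))
    W <- diag(25) / 25
    for (deg in c(30, 90, 180)) {
        target <- xy %*% t(rot2(deg)) + matrix(c(5, -3), 25, 2, byrow = TRUE)
        tr <- weightedProcrustes(xy, target, W)
        angErr <- abs(rotationAngle(tr) - deg * pi / 180)
        angErr <- min(angErr, abs(angErr - 2 * pi))
        expect_lt(angErr, 1e-6)
        expect_equal(tr@translation, c(5, -3), tolerance = 1e-6)
        expect_equal(applyTransform(xy, tr), target, tolerance = 1e-6)
    }
})

test_that("reflections are projected out unless explicitly allowed", {
    xy <- as.matrix(expand.grid(0:3, 0:3)) * 1.0
    mirrored <- xy %*% diag(c(-1, 1))
    tr <- weightedProcrustes(xy, mirrored, diag(16) / 16)
    expect_equal(det(tr@rotation), 1, tolerance = 1e-10)
    resid <- sum((applyTransform(xy, tr) - mirrored)^2)
    expect_gt(resid, 1)                          # a flip cannot be fixed
    trRef <- weightedProcrustes(xy, mirrored, diag(16) / 16,
                                allowReflection = TRUE)
    expect_equal(det(trRef@rotation), -1, tolerance = 1e-10)
    expect_equal(applyTransform(xy, trRef), mirrored, tolerance = 1e-8)
})

test_that("registration reduces the weighted residual for non-identity motions", {
    set.seed(5)
    xy <- matrix(runif(40, 0, 10), 20, 2)
    W <- diag(20) / 20
    target <- xy %*% t(rot2(40)) + matrix(c(2, 1), 20, 2, byrow = TRUE)
    tr <- weightedProcrustes(xy, target, W)
    residAfter <- sum(W * as.matrix(dist(rbind(applyTransform(xy, tr),
                                               target)))[1:20, 21:40]^2)
    residBefore <- sum(W * as.matrix(dist(rbind(xy, target)))[1:20, 21:40]^2)
    expect_lt(residAfter, residBefore)
    expect_lt(residAfter, 1e-12)
})

test_that("transforms apply, invert and preserve distances", {
    tr <- new("RigidTransform", rotation = rot2(73), translation = c(-2, 9))
    xy <- matrix(rnorm(30), 15, 2)
    idt <- new("RigidTransform", rotation = diag(2), translation = c(0, 0))
    expect_equal(applyTransform(xy, idt), xy)
    back <- applyTransform(applyTransform(xy, tr), invertTransform(tr))
    expect_equal(back, xy, tolerance = 1e-10)
    expect_equal(as.matrix(dist(applyTransform(xy, tr))),
                 as.matrix(dist(xy)), tolerance = 1e-10)
})

test_that("weighted solve handles zero mass and degenerate geometry", {
    xy <- as.matrix(expand.grid(0:2, 0:2)) * 1.0
    expect_error(weightedProcrustes(xy, xy, matrix(0, 9, 9)), "zero total mass")
    expect_error(weightedProcrustes(xy, xy, matrix(1, 3, 3)), "shape")
    line <- cbind(0:8, 0)                       # collinear points
    expect_warning(weightedProcrustes(line, line, diag(9) / 9,
                                      sparsify = FALSE), "rank-deficient")
})

test_that("3D stacking registers each slice onto the reference", {
    cfg <- syntheticConfig(gridShape = c(6, 6), noiseSd = 0, batchShift = 0,
                           seed = 2)
    base <- simLayeredPair(cfg)$sliceX
    mk <- function(id, deg, tx, ty) {
        STSlice(coords = SliceOT:::.rigid2d(spatialCoords(base), deg,
                                            c(tx, ty)),
                logcounts = SummarizedExperiment::assay(base, "logcounts"),
                labels = spotLabels(base), sliceId = id)
    }
    slices <- list(mk("a", 25, 1, 2), mk("ref", 0, 0, 0), mk("b", -60, 4, 0))
    idPlan <- planOf(diag(36) / 36)
    st <- stackSlices(slices, list(a = idPlan, b = idPlan), "ref",
                      zSpacing = 10)
    expect_equal(st$ref$transform@rotation, diag(2))
    for (nm in c("a", "ref", "b"))
        expect_equal(st[[nm]]$coords[, 1:2], spatialCoords(base),
                     tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(vapply(st, function(s) s$coords[1, "z"], 0),
                 c(a = 0, ref = 10, b = 20))
    # single slice -> identity stack
    st1 <- stackSlices(slices[2], list(), "ref")
    expect_equal(st1$ref$coords[, 1:2], spatialCoords(base),
                 ignore_attr = TRUE)
    expect_error(stackSlices(slices, list(a = idPlan), "ref"),
                 "missing transport plan")
    expect_error(stackSlices(slices, list(), "nope"), "not among")
})
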