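test_that("attention rows are softmax-normalized over neighbor sets", {
    set.seed(2)
    g <- gridGraph(3, 3)
    model <- initGATModel(4, c(3), seed = 5)
    H <- matrix(rnorm(36), 9, 4)
    att <- attentionWeights(model, H, g, layer = 1)
    expect_equal(unname(Matrix::rowSums(att)), rep(1, 9), tolerance = 1e-6)
    # support equals self-inclusive neighbor sets
    ns <- neighborSets(g)
    for (i in seq_len(9)) {
        expect_setequal(which(att[i, ] != 0), ns[[i]])
    }
    # isolated spot: singleton softmax -> att_ii = 1
    iso <- isolatedGraph(3)
    a2 <- attentionWeights(model, H[1:3, ], iso, layer = 1)
    expect_equal(as.matrix(a2), diag(3), ignore_attr = TRUE)
    # all-zero attention vectors -> uniform over S_i
    m0 <- model; m0@vs[[1]] <- numeric(3); m0@vr[[1]] <- numeric(3)
    a3 <- attentionWeights(m0, H, g, layer = 1)
    for (i in seq_len(9))
        expect_equal(unname(a3[i, ns[[i]]]),
                     rep(1 / length(ns[[i]]), length(ns[[i]])),
                     tolerance = 1e-12)
})

test_that("identity configuration reproduces the input through the autoencoder", {
    g <- 5
    model <- identityModel(g)
    iso <- isolatedGraph(4)
    H0 <- matrix(rnorm(20), 4, g)
    z <- gatEncode(model, H0, iso)
    expect_equal(unname(z[seq_len(4), ]), H0, tolerance = 1e-12)
    hhat <- gatDecode(model, z, iso)
    expect_equal(unname(hhat), H0, tolerance = 1e-12)
})

test_that("orthogonal square weights give lossless reconstruction on isolated spots", {
    set.seed(3)
    g <- 4
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
    model <- initGATModel(g, g, activation = "linear", seed = 1)
    model@W[[1]] <- Q
    iso <- isolatedGraph(5)
    H0 <- matrix(rnorm(20), 5, g)
    z <- gatEncode(model, H0, iso)
    hhat <- gatDecode(model, z, iso)
    expect_equal(unname(hhat), H0, tolerance = 1e-6)
})

test_that("spot permutation equivariance of the encoder", {
    set.seed(8)
    xy <- matrix(runif(24), 12, 2)
    H0 <- matrix(rnorm(12 * 6), 12, 6)
    model <- initGATModel(6, c(4, 2), seed = 2)
    p <- sample(12)
    z1 <- gatEncode(model, H0, buildSpatialGraph(xy, 0.4))
    z2 <- gatEncode(model, H0[p, ], buildSpatialGraph(xy[p, ], 0.4))
    expect_equal(z2[, ], z1[p, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("no cross-slice message passing through the block-diagonal graph", {
    set.seed(9)
    g1 <- gridGraph(2, 3); g2 <- gridGraph(2, 2)
    H0 <- matrix(rnorm(10 * 5), 10, 5)
    model <- initGATModel(5, c(4, 3), seed = 3)
    z <- unname(gatEncode(model, H0, list(g1, g2)))
    H0b <- H0
    H0b[7:10, ] <- H0b[7:10, ] + matrix(rnorm(20, 0, 5), 4, 5)
    zb <- unname(gatEncode(model, H0b, list(g1, g2)))
    expect_equal(zb[1:6, ], z[1:6, ], tolerance = 1e-12)
    expect_gt(max(abs(zb[7:10, ] - z[7:10, ])), 1e-3)
})

test_that("parameter count equals the encoder's (tied decoder)", {
    model <- initGATModel(60, c(16, 8), seed = 0)
    expect_equal(nParams(model),
                 16 * 60 + 8 * 16 +    # W
                 16 + 8 +              # vs
                 16 + 8)               # vr
})

test_that("reconstruction loss: zero residual, unit residual, symmetry", {
    A <- matrix(rnorm(12), 3, 4)
    expect_equal(reconstructionLoss(A, A, "sum"), 0)
    expect_equal(reconstructionLoss(matrix(c(1, 0), 1), matrix(c(0, 0), 1),
                                    "sum"), 1)
    B <- matrix(rnorm(12), 3, 4)
    p <- c(3, 1, 2)
    expect_equal(reconstructionLoss(A, B, "sum"),
                 reconstructionLoss(A[p, ], B[p, ], "sum"))
    expect_equal(reconstructionLoss(A, B, "mean_spot") * 3,
                 reconstructionLoss(A, B, "sum"))
    expect_error(reconstructionLoss(A, B[1:2, ]), "shape")
})

test_that("analytic gradients match finite differences on a 5-spot toy", {
    set.seed(42)
    g1 <- buildSpatialGraph(rbind(c(0, 0), c(1, 0), c(0, 1)), radius = 1.5)
    g2 <- buildSpatialGraph(rbind(c(0, 0), c(1, 1)), radius = 2)
    edges <- SliceOT:::.as_edge_list(list(g1, g2))
    H0 <- matrix(rnorm(20), 5, 4)
    model <- initGATModel(4, c(3, 2), seed = 7)
    Tm <- matrix(runif(6), 3, 2); Tm <- Tm / sum(Tm)
    plan <- planOf(Tm)
    for (case in list(list(p = NULL, gam = 0),      # pure reconstruction
                      list(p = plan, gam = 1),      # pure transport term
                      list(p = plan, gam = 0.2))) { # combined objective
        lg <- SliceOT:::.gat_loss_grad(model, H0, edges, 3, plan = case$p,
                                       gamma = case$gam)
        th <- SliceOT:::.flatten_params(model)
        an <- SliceOT:::.flatten_grads(lg$grads)
        fd <- vapply(seq_along(th), function(i) {
            e <- 1e-5
            tp <- th; tp[i] <- tp[i] + e
            tm <- th; tm[i] <- tm[i] - e
            (SliceOT:::.gat_loss_grad(
                SliceOT:::.unflatten_params(model, tp), H0, edges, 3,
                plan = case$p, gamma = case$gam, wantGrads = FALSE)$loss -
             SliceOT:::.gat_loss_grad(
                SliceOT:::.unflatten_params(model, tm), H0, edges, 3,
                plan = case$p, gamma = case$gam, wantGrads = FALSE)$loss) /
                (2 * e)
        }, numeric(1))
        expect_lt(max(abs(an - fd) / pmax(abs(fd), 1e-6)), 1e-4)
    }
})

test_that("checkpoint serialization restores the model exactly", {
    model <- initGATModel(6, c(4, 2), seed = 11)
    f <- tempfile(fileext = ".yaml")
    saveCheckpoint(model, f)
    back <- loadCheckpoint(f)
    expect_equal(back@W, model@W, tolerance = 1e-15)
    expect_equal(back@vs, model@vs, tolerance = 1e-15)
    expect_identical(back@layerDims, model@layerDims)
})
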