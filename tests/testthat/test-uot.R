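test_that("latent cost is the pairwise Euclidean distance", {
    z <- matrix(rnorm(12), 4, 3)
    C <- latentCost(z, z)
    expect_equal(diag(C), rep(0, 4))
    expect_equal(latentCost(matrix(c(0, 0), 1), matrix(c(3, 4), 1))[1, 1], 5)
    # invariance under a common orthogonal transform
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    z2 <- matrix(rnorm(15), 5, 3)
    expect_equal(latentCost(z %*% Q, z2 %*% Q), latentCost(z, z2),
                 tolerance = 1e-10)
    expect_equal(latentCost(z, z2, squared = TRUE), latentCost(z, z2)^2,
                 tolerance = 1e-10)
    expect_equal(max(latentCost(z, z2, normalize = TRUE)), 1)
    expect_error(latentCost(z, matrix(0, 2, 2)), "dimension")
})

test_that("forced-mass and cost-indifferent limits of the solver", {
    pl <- solveUOT(matrix(0, 1, 1), epsilon = 0.05, rho1 = 100, rho2 = 100,
                   a = 1, b = 1)
    expect_equal(transportMatrix(pl)[1, 1], 1, tolerance = 1e-4)
    # constant cost, near-balanced -> outer product of marginals
    pl2 <- solveUOT(matrix(0.7, 3, 4), epsilon = 0.05, rho1 = 1e3,
                    rho2 = 1e3)
    expect_lt(max(abs(transportMatrix(pl2) -
                      outer(rep(1 / 3, 3), rep(1 / 4, 4)))), 1e-4)
})

test_that("solver objective matches direct numerical minimization", {
    worst <- 0
    for (s in 1:8) {
        set.seed(s)
        nx <- sample(2:4, 1); ny <- sample(2:4, 1)
        C <- matrix(runif(nx * ny), nx, ny)
        a <- rep(1 / nx, nx); b <- rep(1 / ny, ny)
        pl <- solveUOT(C, epsilon = 0.1, rho1 = 1, rho2 = 1)
        ours <- uotObjective(C, pl)
        ref <- uotOracleValue(C, 0.1, 1, 1, a, b)
        worst <- max(worst, abs(ours - ref) / abs(ref))
    }
    expect_lt(worst, 1e-3)
})

test_that("marginal laws: hard rows under rho1 = Inf, balanced large-rho limit", {
    for (s in 1:10) {
        set.seed(s)
        C <- matrix(runif(20), 4, 5)
        pl <- solveUOT(C, epsilon = 0.05, rho1 = Inf, rho2 = 0.01)
        expect_lt(max(abs(rowSums(transportMatrix(pl)) - pl@a)), 1e-6)
        # columns deviate strongly from b (partial-alignment mechanism)
        expect_gt(max(abs(colSums(transportMatrix(pl)) - pl@b)), 0.01)
    }
    set.seed(99)
    C <- matrix(runif(12), 3, 4)
    pl <- solveUOT(C, epsilon = 0.05, rho1 = 1e3, rho2 = 1e3)
    expect_lt(max(abs(rowSums(transportMatrix(pl)) - pl@a)), 1e-3)
    expect_lt(max(abs(colSums(transportMatrix(pl)) - pl@b)), 1e-3)
    # balanced-limit error decreases in rho
    err <- vapply(c(10, 100, 1000), function(r) {
        Tm <- transportMatrix(solveUOT(C, epsilon = 0.05, rho1 = r,
                                       rho2 = r))
        max(abs(rowSums(Tm) - 1 / 3), abs(colSums(Tm) - 1 / 4))
    }, numeric(1))
    expect_true(all(diff(err) < 0))
})

test_that("entropic limit concentrates on the optimal permutation (log domain)", {
    z <- matrix(c(0, 1, 2, 3), 4, 1)
    C <- latentCost(z, z) / 3
    pl <- solveUOT(C, epsilon = 0.005, rho1 = 1e4, rho2 = 1e4,
                   nOuter = 200)
    Tm <- transportMatrix(pl)
    expect_lt(sum(Tm) - sum(diag(Tm)), 1e-4)     # off-diagonal mass -> 0
    expect_equal(diag(Tm), rep(0.25, 4), tolerance = 1e-3)
})

test_that("kernel refresh anneals toward the unregularized optimum", {
    set.seed(4)
    C <- matrix(runif(9), 3, 3)
    ent <- solveUOT(C, epsilon = 0.1, rho1 = 1, rho2 = 1)
    prox <- solveUOT(C, epsilon = 0.1, rho1 = 1, rho2 = 1,
                     kernelRefresh = TRUE, nOuter = 200)
    # the annealed plan has lower linear-plus-KL (entropy-free) objective
    noEnt <- function(Tm) uotObjective(C, Tm, epsilon = 1e-300, rho1 = 1,
                                       rho2 = 1, a = rep(1 / 3, 3),
                                       b = rep(1 / 3, 3))
    expect_lt(noEnt(transportMatrix(prox)),
              noEnt(transportMatrix(ent)) + 1e-10)
    # and the entropic solver attains the lower entropic objective
    expect_lt(uotObjective(C, ent),
              uotObjective(C, transportMatrix(prox), epsilon = 0.1,
                           rho1 = 1, rho2 = 1, a = rep(1 / 3, 3),
                           b = rep(1 / 3, 3)) + 1e-10)
})

test_that("solver input validation", {
    expect_error(solveUOT(matrix(-1, 2, 2)), "nonnegative")
    expect_error(solveUOT(matrix(1, 2, 2), epsilon = 0), "epsilon")
    expect_error(solveUOT(matrix(1, 2, 2), rho1 = 0), "rho")
    expect_error(solveUOT(matrix(1, 2, 2), a = c(1, 1, 1)), "shape")
})

test_that("transport loss is the plan-weighted cost sum", {
    expect_equal(uotLoss(matrix(0, 2, 2), planOf(matrix(0.25, 2, 2))), 0)
    C <- matrix(c(1, 3, 2, 4), 2, 2)     # row-major [[1,2],[3,4]]
    Tm <- matrix(c(0.5, 0, 0, 0.5), 2, 2)
    expect_equal(uotLoss(C, planOf(Tm)), 2.5)
    expect_equal(uotLoss(3 * C, planOf(Tm)), 7.5)   # linear in the cost
    expect_error(uotLoss(C, planOf(matrix(1, 3, 2))), "shape")
})

test_that("maximum probability matching: argmax, threshold, tie rule", {
    m <- maxProbMatching(planOf(diag(2) / 2))
    expect_equal(matchIndices(m), c(1L, 2L))
    expect_equal(matchingMatrix(m), diag(2), ignore_attr = TRUE)
    # row max below threshold -> unmatched sentinel
    Tm <- rbind(c(0.4, 0.1), c(0.01, 0.02))
    m2 <- maxProbMatching(planOf(Tm), minMass = 0.1)
    expect_equal(matchIndices(m2), c(1L, NA))
    expect_equal(matchedPairs(m2)$source, 1L)
    # tie -> smallest index
    m3 <- maxProbMatching(planOf(rbind(c(0.3, 0.3, 0.1))))
    expect_equal(matchIndices(m3), 1L)
})
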