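# deterministic toy fixtures built in code

toySlice <- function(n = 4, g = 5, seed = 1, counts = FALSE,
                     labels = NULL, id = "toy") {
    set.seed(seed)
    xy <- cbind(x = rep(seq_len(ceiling(sqrt(n))), length.out = n),
                y = rep(seq_len(ceiling(sqrt(n))), each = ceiling(sqrt(n)))[seq_len(n)])
    m <- matrix(abs(rnorm(g * n, 2, 1)), g, n,
                dimnames = list(sprintf("g%02d", seq_len(g)),
                                sprintf("%s_s%d", id, seq_len(n))))
    if (counts)
        STSlice(coords = xy, counts = matrix(rpois(g * n, 8), g, n,
                                             dimnames = dimnames(m)),
                labels = labels, sliceId = id)
    else
        STSlice(coords = xy, logcounts = m, labels = labels, sliceId = id)
}

# model with identity weights, zero attention vectors, linear activations
identityModel <- function(g) {
    m <- initGATModel(g, g, activation = "linear",
                      gateActivation = "sigmoid", seed = 0L)
    m@W[[1]] <- diag(g)
    m@vs[[1]] <- numeric(g)
    m@vr[[1]] <- numeric(g)
    m
}

# graph with no edges (isolated spots)
isolatedGraph <- function(n) {
    xy <- cbind(seq_len(n) * 100, 0)
    buildSpatialGraph(xy, radius = 1)
}

gridGraph <- function(rows, cols, radius = 1.1) {
    xy <- as.matrix(expand.grid(x = seq_len(cols), y = seq_len(rows)))
    buildSpatialGraph(xy, radius = radius)
}

planOf <- function(Tm, epsilon = 0.05, rho1 = 1, rho2 = 1) {
    new("TransportPlan", plan = as.matrix(Tm), epsilon = epsilon,
        rho1 = rho1, rho2 = rho2,
        a = rep(1 / nrow(Tm), nrow(Tm)), b = rep(1 / ncol(Tm), ncol(Tm)),
        nIterUsed = 1L, converged = TRUE)
}

matchingOf <- function(idx, nTarget) {
    new("SpotMatching", matchIdx = as.integer(idx),
        nTarget = as.integer(nTarget), minMass = 0)
}

# direct numerical minimizer of the unbalanced entropic objective
# (independent oracle: L-BFGS-B on log-parameterized plans with the
# analytic gradient of the objective itself)
uotOracleValue <- function(C, eps, r1, r2, a, b) {
    nx <- nrow(C); ny <- ncol(C)
    obj <- function(L) {
        Tm <- matrix(exp(L), nx, ny)
        r <- rowSums(Tm); cl <- colSums(Tm)
        sum(C * Tm) + eps * sum(Tm * (log(Tm) - 1)) +
            r1 * sum(r * log(r / a) - r + a) +
            r2 * sum(cl * log(cl / b) - cl + b)
    }
    grad <- function(L) {
        Tm <- matrix(exp(L), nx, ny)
        G <- C + eps * log(Tm) + r1 * log(rowSums(Tm) / a) +
            matrix(r2 * log(colSums(Tm) / b), nx, ny, byrow = TRUE)
        as.vector(G * Tm)
    }
    stats::optim(rep(log(1 / (nx * ny)), nx * ny), obj, grad,
                 method = "L-BFGS-B",
                 control = list(maxit = 5000, factr = 1e1))$value
}
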