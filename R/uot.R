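#' Latent-space transport cost
#'
#' Pairwise Euclidean distance between the latent vectors of two slices,
#' C_ij = ||z_x_i - z_y_j||. \code{squared = TRUE} uses the squared distance
#' instead; \code{normalize = TRUE} divides by max(C) for scale stability
#' (useful before solving with a fixed epsilon).
#'
#' @param zx,zy latent matrices (n_x x k and n_y x k).
#' @param squared use squared Euclidean distance.
#' @param normalize divide by the maximum entry.
#' @return nonnegative n_x x n_y cost matrix.
#' @export
latentCost <- function(zx, zy, squared = FALSE, normalize = FALSE) {
    zx <- as.matrix(zx); zy <- as.matrix(zy)
    if (ncol(zx) != ncol(zy))
        stop("latent dimensions differ between the two embeddings")
    D2 <- outer(rowSums(zx^2), rowSums(zy^2), "+") - 2 * zx %*% t(zy)
    D2[D2 < 0] <- 0
    C <- if (squared) D2 else sqrt(D2)
    if (normalize && max(C) > 0) C <- C / max(C)
    C
}

#' Solve unbalanced entropic optimal transport by proximal-point Sinkhorn
#'
#' Minimizes \deqn{<C,T> - \epsilon H(T) + \rho_1 KL(T 1 || a) +
#' \rho_2 KL(T^T 1 || b)} over nonnegative matrices, where
#' \eqn{H(T) = -\sum_{ij} T_{ij}(\log T_{ij} - 1)} and KL is the generalized
#' Kullback-Leibler divergence. The solver runs proximal scaling sweeps
#' \eqn{\alpha = (a / G\beta)^{\rho_1/(\rho_1+\epsilon)}},
#' \eqn{\beta = (b / G^T\alpha)^{\rho_2/(\rho_2+\epsilon)}} on the kernel
#' \eqn{G_{ij} = T^{(0)}_{ij} \exp(-C_{ij}/\epsilon)}. With the default
#' all-ones proximal reference the fixed point is exactly the minimizer of
#' the entropic objective above; \code{kernelRefresh = TRUE} re-builds the
#' kernel from the current plan after every block of sweeps, which anneals
#' the entropy away toward the unregularized unbalanced optimum. A
#' \code{rho} of \code{Inf} makes the exponent exactly 1 and enforces the
#' corresponding marginal: every block ends with a final \eqn{\alpha}
#' refresh, so with \code{rho1 = Inf} the row marginals equal \code{a} to
#' machine precision. The partial-alignment regime is \code{rho1 = Inf,
#' rho2 = 0.01}.
#'
#' By default the \eqn{\beta} update uses the freshly computed \eqn{\alpha}
#' (Gauss-Seidel); \code{jacobi = TRUE} uses the previous \eqn{\alpha}
#' instead. When \code{epsilon < 0.01} the scaling runs in the log domain to
#' avoid underflow.
#'
#' @param C nonnegative cost matrix (n_x x n_y).
#' @param epsilon entropic regularization (> 0).
#' @param rho1,rho2 marginal KL penalties; positive, possibly \code{Inf}.
#' @param a,b reference marginals; default uniform 1/n_x and 1/n_y.
#' @param tInit optional nonnegative initial plan (proximal reference for
#'   the first kernel; all-ones when NULL, i.e. the plain entropic kernel).
#' @param nOuter,nInner outer kernel blocks and inner scaling sweeps; the
#'   total sweep budget is their product.
#' @param tol stop when the max-abs change of T between blocks falls below
#'   this.
#' @param jacobi use the strictly alternating (printed) update order.
#' @param kernelRefresh re-build the kernel from the current plan after
#'   every block (the printed proximal refresh). This anneals the entropy
#'   away and converges to the unregularized unbalanced optimum; the
#'   default (FALSE) keeps the kernel fixed and converges to the entropic
#'   optimum itself.
#' @return a \linkS4class{TransportPlan}.
#' @examples
#' C <- matrix(c(0, 1, 1, 0), 2, 2)
#' pl <- solveUOT(C, epsilon = 0.05, rho1 = 100, rho2 = 100)
#' round(transportMatrix(pl), 3)   # mass concentrates on the diagonal
#' @export
solveUOT <- function(C, epsilon = 0.05, rho1 = 1, rho2 = 1,
                     a = NULL, b = NULL, tInit = NULL,
                     nOuter = 50L, nInner = 10L, tol = 1e-6,
                     jacobi = FALSE, kernelRefresh = FALSE) {
    C <- as.matrix(C)
    nx <- nrow(C); ny <- ncol(C)
    if (any(!is.finite(C)) || any(C < 0))
        stop("validation error: cost matrix must be finite and nonnegative")
    if (epsilon <= 0) stop("parameter error: epsilon must be positive")
    if (rho1 <= 0 || rho2 <= 0)
        stop("parameter error: rho1 and rho2 must be positive (Inf allowed)")
    if (is.null(a)) a <- rep(1 / nx, nx)
    if (is.null(b)) b <- rep(1 / ny, ny)
    if (any(a < 0) || any(b < 0))
        stop("validation error: marginals must be nonnegative")
    if (length(a) != nx || length(b) != ny)
        stop("shape error: marginal lengths must match the cost matrix")
    if (!is.null(tInit) && any(tInit < 0))
        stop("validation error: tInit must be nonnegative")
    # proximal reference inside the kernel: all-ones by default (plain
    # entropic kernel); in refresh mode the current plan, starting uniform
    Tref <- if (!is.null(tInit)) as.matrix(tInit)
        else if (kernelRefresh) matrix(1 / (nx * ny), nx, ny)
        else matrix(1, nx, ny)
    Tm <- matrix(1 / (nx * ny), nx, ny)
    e1 <- if (is.infinite(rho1)) 1 else rho1 / (rho1 + epsilon)
    e2 <- if (is.infinite(rho2)) 1 else rho2 / (rho2 + epsilon)
    logDomain <- epsilon < 0.01
    converged <- FALSE
    iter <- 0L
    if (logDomain) {
        logG <- log(pmax(Tref, .Machine$double.xmin)) - C / epsilon
        logG[Tref == 0] <- -Inf
        lb <- rep(log(1 / ny), ny)
        la <- rep(0, nx)
    } else {
        G <- Tref * exp(-C / epsilon)
        if (all(G == 0))
            stop("numerical underflow in the transport kernel; ",
                 "increase epsilon")
        beta <- rep(1 / ny, ny)
        alpha <- rep(1, nx)
    }
    for (l in seq_len(nOuter)) {
        iter <- l
        if (logDomain) {
            for (it in seq_len(nInner)) {
                laNew <- e1 * (log(a) - .lse_rows(sweep(logG, 2L, lb, "+")))
                lbSrc <- if (jacobi) la else laNew
                lb <- e2 * (log(b) - .lse_cols(logG + lbSrc))
                la <- laNew
            }
            la <- e1 * (log(a) - .lse_rows(sweep(logG, 2L, lb, "+")))
            Tnew <- exp((la + logG) + rep(lb, each = nx))
        } else {
            for (it in seq_len(nInner)) {
                Gb <- drop(G %*% beta)
                alphaNew <- (a / pmax(Gb, .Machine$double.xmin))^e1
                aSrc <- if (jacobi) alpha else alphaNew
                Ga <- drop(crossprod(G, aSrc))
                beta <- (b / pmax(Ga, .Machine$double.xmin))^e2
                alpha <- alphaNew
            }
            Gb <- drop(G %*% beta)
            alpha <- (a / pmax(Gb, .Machine$double.xmin))^e1
            Tnew <- alpha * G * rep(beta, each = nx)
        }
        if (any(!is.finite(Tnew)))
            stop("numerical underflow/overflow in the scaling iterations; ",
                 "increase epsilon")
        delta <- max(abs(Tnew - Tm))
        Tm <- Tnew
        if (delta < tol) { converged <- TRUE; break }
        if (kernelRefresh) {    # printed proximal refresh: anneal entropy
            if (logDomain) {
                logG <- log(pmax(Tm, .Machine$double.xmin)) - C / epsilon
                logG[Tm == 0] <- -Inf
                lb <- rep(log(1 / ny), ny)
                la <- rep(0, nx)
            } else {
                G <- Tm * exp(-C / epsilon)
                beta <- rep(1 / ny, ny)
                alpha <- rep(1, nx)
            }
        }
    }
    new("TransportPlan", plan = Tm, epsilon = epsilon, rho1 = rho1,
        rho2 = rho2, a = a, b = b, nIterUsed = iter, converged = converged)
}

.lse_rows <- function(L) {   # log sum exp over each row
    m <- apply(L, 1L, max)
    m[!is.finite(m)] <- 0
    m + log(rowSums(exp(L - m)))
}
.lse_cols <- function(L) {
    m <- apply(L, 2L, max)
    m[!is.finite(m)] <- 0
    m + log(colSums(exp(sweep(L, 2L, m))))
}

#' Objective value of the unbalanced entropic transport problem
#'
#' Evaluates \eqn{<C,T> - \epsilon H(T) + \rho_1 KL(T1||a) + \rho_2
#' KL(T^T 1||b)} at a given plan (used for diagnostics and oracle
#' comparisons). Infinite rho terms contribute 0 when the corresponding
#' marginal matches exactly and Inf otherwise (within \code{marginTol}).
#'
#' @param C cost matrix.
#' @param plan a \linkS4class{TransportPlan} or plain matrix.
#' @param epsilon,rho1,rho2,a,b parameters; default taken from the plan.
#' @param marginTol tolerance for hard-constraint checking.
#' @return scalar objective value.
#' @export
uotObjective <- function(C, plan, epsilon = NULL, rho1 = NULL, rho2 = NULL,
                         a = NULL, b = NULL, marginTol = 1e-6) {
    if (is(plan, "TransportPlan")) {
        if (is.null(epsilon)) epsilon <- plan@epsilon
        if (is.null(rho1)) rho1 <- plan@rho1
        if (is.null(rho2)) rho2 <- plan@rho2
        if (is.null(a)) a <- plan@a
        if (is.null(b)) b <- plan@b
        Tm <- plan@plan
    } else Tm <- as.matrix(plan)
    xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
    H <- -sum(xlogx(Tm) - Tm)
    klGen <- function(u, v) sum(ifelse(u > 0, u * log(u / v), 0) - u + v)
    r <- rowSums(Tm); cl <- colSums(Tm)
    t1 <- if (is.infinite(rho1)) {
        if (max(abs(r - a)) > marginTol) Inf else 0
    } else rho1 * klGen(r, a)
    t2 <- if (is.infinite(rho2)) {
        if (max(abs(cl - b)) > marginTol) Inf else 0
    } else rho2 * klGen(cl, b)
    sum(C * Tm) - epsilon * H + t1 + t2
}

#' Transport loss
#'
#' \eqn{L_{UOT} = \sum_{ij} C_{ij} T_{ij}} with the plan treated as a
#' constant: during training its gradient flows only through the cost.
#'
#' @param C cost matrix.
#' @param plan \linkS4class{TransportPlan} or matrix of matching shape.
#' @return nonnegative scalar.
#' @export
uotLoss <- function(C, plan) {
    Tm <- if (is(plan, "TransportPlan")) plan@plan else as.matrix(plan)
    if (!all(dim(C) == dim(Tm)))
        stop("shape error: cost and plan dimensions differ")
    sum(C * Tm)
}

#' Maximum probability matching
#'
#' Hard spot correspondence \eqn{\pi(i) = argmax_j T_{ij}} when that maximum
#' reaches \code{minMass}, otherwise unmatched (NA). Ties break to the
#' smallest target index.
#'
#' @param plan a \linkS4class{TransportPlan}.
#' @param minMass minimum row-max mass required to call a match.
#' @return a \linkS4class{SpotMatching}.
#' @export
maxProbMatching <- function(plan, minMass = 0) {
    Tm <- transportMatrix(plan)
    best <- max.col(Tm, ties.method = "first")
    mx <- Tm[cbind(seq_len(nrow(Tm)), best)]
    idx <- ifelse(mx >= minMass & mx > 0, best, NA_integer_)
    new("SpotMatching", matchIdx = as.integer(idx),
        nTarget = ncol(Tm), minMass = minMass)
}

#' @rdname TransportPlan-accessors
#' @export
setGeneric("transportMatrix", function(x) standardGeneric("transportMatrix"))

#' Accessors for TransportPlan / SpotMatching
#'
#' \code{transportMatrix} returns the coupling matrix; \code{matchIndices}
#' the per-source-row matched target index (NA = unmatched);
#' \code{matchedPairs} a data.frame of matched (source, target) pairs;
#' \code{matchingMatrix} the binary matrix M.
#'
#' @param x a \linkS4class{TransportPlan} or \linkS4class{SpotMatching}.
#' @name TransportPlan-accessors
NULL

#' @rdname TransportPlan-accessors
#' @export
setMethod("transportMatrix", "TransportPlan", function(x) x@plan)

#' @rdname TransportPlan-accessors
#' @export
setGeneric("matchIndices", function(x) standardGeneric("matchIndices"))
#' @rdname TransportPlan-accessors
#' @export
setMethod("matchIndices", "SpotMatching", function(x) x@matchIdx)

#' @rdname TransportPlan-accessors
#' @export
matchedPairs <- function(x) {
    stopifnot(is(x, "SpotMatching"))
    ok <- !is.na(x@matchIdx)
    data.frame(source = which(ok), target = x@matchIdx[ok])
}

#' @rdname TransportPlan-accessors
#' @export
matchingMatrix <- function(x) {
    stopifnot(is(x, "SpotMatching"))
    M <- matrix(0L, length(x@matchIdx), x@nTarget)
    ok <- !is.na(x@matchIdx)
    M[cbind(which(ok), x@matchIdx[ok])] <- 1L
    M
}

#' @export
setMethod("show", "TransportPlan", function(object) {
    cat(sprintf(
        "TransportPlan %d x %d: mass %.4f, epsilon %.3g, rho1 %.3g, rho2 %.3g\n",
        nrow(object@plan), ncol(object@plan), sum(object@plan),
        object@epsilon, object@rho1, object@rho2))
    cat(sprintf("  %d outer iterations, converged: %s\n", object@nIterUsed,
                object@converged))
})

#' @export
setMethod("show", "SpotMatching", function(object) {
    ok <- sum(!is.na(object@matchIdx))
    cat(sprintf("SpotMatching: %d / %d source spots matched (minMass %.3g)\n",
                ok, length(object@matchIdx), object@minMass))
})
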