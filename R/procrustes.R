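#' Weighted rigid registration from a transport plan
#'
#' Solves the weighted Procrustes problem: with weights w_ij taken from the
#' transport plan, find the rotation R (det +1) and translation t minimizing
#' \eqn{\sum_{ij} w_{ij} || R x_i + t - y_j ||^2}. The closed-form solution
#' uses the SVD of the weighted cross-covariance H = sum_ij w_ij
#' (x_i - mu_x)(y_j - mu_y)^T with weighted centroids mu_x, mu_y:
#' R = V diag(1, det(V U^T)) U^T, t = mu_y - R mu_x. Because the plan already
#' provides soft correspondences, a single solve implements the weighted ICP
#' step; \code{iterate > 0} optionally re-estimates nearest-neighbor
#' correspondences after transforming and re-solves (classical ICP).
#'
#' @param coordsX source coordinates (n_x x 2).
#' @param coordsY target coordinates (n_y x 2).
#' @param plan \linkS4class{TransportPlan} (or weight matrix) with
#'   n_x x n_y entries; weights below \code{1/(10 n_x n_y)} are dropped for
#'   speed (set \code{sparsify = FALSE} to keep all).
#' @param allowReflection if TRUE the determinant correction is skipped and
#'   an improper rotation may be returned.
#' @param iterate number of additional hard-correspondence ICP refinement
#'   rounds (default 0).
#' @param sparsify drop negligible weights before solving.
#' @return a \linkS4class{RigidTransform} mapping source onto target.
#' @examples
#' xy <- as.matrix(expand.grid(0:3, 0:3))
#' th <- pi / 2
#' Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
#' target <- xy %*% t(Rm) + matrix(c(5, -3), 16, 2, byrow = TRUE)
#' tr <- weightedProcrustes(xy, target, diag(16) / 16)
#' rotationAngle(tr) * 180 / pi    # 90
#' @export
weightedProcrustes <- function(coordsX, coordsY, plan,
                               allowReflection = FALSE, iterate = 0L,
                               sparsify = TRUE) {
    X <- as.matrix(coordsX); Y <- as.matrix(coordsY)
    W <- if (is(plan, "TransportPlan")) transportMatrix(plan) else
        as.matrix(plan)
    if (nrow(W) != nrow(X) || ncol(W) != nrow(Y))
        stop("shape error: plan dimensions must match coordinate counts")
    if (sparsify)
        W[W < 1 / (10 * length(W))] <- 0
    tw <- sum(W)
    if (tw <= 0) stop("transport plan has zero total mass")
    sol <- .kabsch(X, Y, W, allowReflection)
    for (it in seq_len(iterate)) {
        Xt <- sweep(X %*% t(sol$R), 2L, sol$t, "+")
        # hard nearest-neighbor correspondences, weighted by row mass
        d2 <- outer(rowSums(Xt^2), rowSums(Y^2), "+") - 2 * Xt %*% t(Y)
        nn <- max.col(-d2, ties.method = "first")
        Wh <- matrix(0, nrow(X), nrow(Y))
        Wh[cbind(seq_len(nrow(X)), nn)] <- rowSums(W)
        sol <- .kabsch(X, Y, Wh, allowReflection)
    }
    new("RigidTransform", rotation = sol$R, translation = sol$t)
}

.kabsch <- function(X, Y, W, allowReflection) {
    tw <- sum(W)
    rw <- rowSums(W); cw <- colSums(W)
    mx <- drop(crossprod(X, rw)) / tw
    my <- drop(crossprod(Y, cw)) / tw
    Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
    H <- crossprod(Xc, W %*% Yc)        # 2 x 2 cross-covariance
    sv <- svd(H)
    if (min(sv$d) < 1e-12 * max(sv$d, 1e-300))
        warning("rank-deficient cross-covariance (collinear points); ",
                "rotation may be poorly determined")
    d <- det(sv$v %*% t(sv$u))
    S <- if (allowReflection) diag(2) else diag(c(1, sign(d)))
    R <- sv$v %*% S %*% t(sv$u)
    list(R = R, t = drop(my - R %*% mx))
}

#' Apply / invert / summarize rigid transforms
#'
#' \code{applyTransform} maps coordinates through R x + t rowwise;
#' \code{invertTransform} returns the inverse transform (R^T, -R^T t);
#' \code{rotationAngle} the signed rotation angle in radians.
#'
#' @param coords n x 2 coordinate matrix.
#' @param transform a \linkS4class{RigidTransform}.
#' @return transformed n x 2 matrix.
#' @export
applyTransform <- function(coords, transform) {
    X <- as.matrix(coords)
    sweep(X %*% t(transform@rotation), 2L, transform@translation, "+")
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
    Rt <- t(transform@rotation)
    new("RigidTransform", rotation = Rt,
        translation = drop(-Rt %*% transform@translation))
}

#' @rdname applyTransform
#' @export
rotationAngle <- function(transform) {
    atan2(transform@rotation[2, 1], transform@rotation[1, 1])
}

#' @rdname applyTransform
#' @export
setMethod("show", "RigidTransform", function(object) {
    cat(sprintf("RigidTransform: angle %.4f deg, t = (%.4g, %.4g), det %.0f\n",
                rotationAngle(object) * 180 / pi, object@translation[1],
                object@translation[2], det(object@rotation)))
})

#' Write a transform as a 6-number text record (R row-major, then t)
#' @param transform a \linkS4class{RigidTransform}.
#' @param path output file.
#' @export
writeTransform <- function(transform, path) {
    v <- c(t(transform@rotation), transform@translation)
    writeLines(paste(format(v, digits = 17), collapse = " "), path)
    invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
    v <- scan(path, quiet = TRUE)
    stopifnot(length(v) == 6L)
    new("RigidTransform", rotation = matrix(v[1:4], 2, 2, byrow = TRUE),
        translation = v[5:6])
}

#' Stack multiple slices into a 3D coordinate framework
#'
#' One slice acts as the reference template (identity transform); every
#' other slice is rigidly registered onto it through its transport plan via
#' [weightedProcrustes()], and a z offset of (ordinal position - 1) x
#' \code{zSpacing} is attached, preserving the input slice order.
#'
#' @param slices list of \linkS4class{STSlice}s.
#' @param plans named list of \linkS4class{TransportPlan}s, one per
#'   non-reference slice (names = slice ids), each mapping that slice
#'   (rows) onto the reference (columns).
#' @param referenceId slice id of the reference.
#' @param zSpacing positive spacing between consecutive slices.
#' @return a list with one entry per slice: \code{sliceId}, \code{coords}
#'   (transformed n x 3 matrix including the z column) and
#'   \code{transform}.
#' @export
stackSlices <- function(slices, plans, referenceId, zSpacing = 10) {
    ids <- vapply(slices, sliceId, "")
    if (!referenceId %in% ids)
        stop("reference slice '", referenceId, "' not among the slices")
    if (zSpacing <= 0) stop("parameter error: zSpacing must be positive")
    ref <- slices[[match(referenceId, ids)]]
    out <- vector("list", length(slices))
    for (s in seq_along(slices)) {
        sl <- slices[[s]]
        if (ids[s] == referenceId) {
            tr <- new("RigidTransform", rotation = diag(2),
                      translation = c(0, 0))
        } else {
            if (!ids[s] %in% names(plans))
                stop("missing transport plan for slice '", ids[s], "'")
            tr <- weightedProcrustes(spatialCoords(sl), spatialCoords(ref),
                                     plans[[ids[s]]])
        }
        xy <- applyTransform(spatialCoords(sl), tr)
        out[[s]] <- list(sliceId = ids[s],
                         coords = cbind(xy, z = (s - 1) * zSpacing),
                         transform = tr)
    }
    names(out) <- ids
    out
}
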