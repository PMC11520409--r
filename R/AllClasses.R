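#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t drop0
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' STSlice: one spatial transcriptomics slice
#'
#' An \code{STSlice} holds a single tissue section: a gene x spot expression
#' matrix (raw counts and/or log-normalized values, as assays), per-spot 2D
#' coordinates, and optional categorical spot annotations. It extends
#' \linkS4class{SingleCellExperiment}, so all the usual assay/colData
#' machinery applies; the spatial coordinates live in a dedicated slot.
#'
#' @slot sliceId single character identifier of the slice.
#' @slot spatialCoords numeric matrix with one row per spot and exactly two
#'   columns (slice-local spatial units; z offsets are added only at 3D
#'   stacking time).
#'
#' @seealso [STSlice()] for the constructor, [spatialCoords()],
#'   [spotLabels()], [sliceId()].
#' @export
setClass("STSlice",
    contains = "SingleCellExperiment",
    representation(sliceId = "character", spatialCoords = "matrix"))

setValidity("STSlice", function(object) {
    msg <- NULL
    if (length(object@sliceId) != 1L || is.na(object@sliceId))
        msg <- c(msg, "'sliceId' must be a single non-NA string")
    sc <- object@spatialCoords
    if (!is.numeric(sc) || ncol(sc) != 2L)
        msg <- c(msg, "'spatialCoords' must be a numeric matrix with 2 columns")
    else if (nrow(sc) != ncol(object))
        msg <- c(msg, sprintf(
            "number of coordinate rows (%d) differs from number of spots (%d)",
            nrow(sc), ncol(object)))
    else if (any(!is.finite(sc)))
        msg <- c(msg, "'spatialCoords' must be finite")
    if ("logcounts" %in% SummarizedExperiment::assayNames(object)) {
        e <- SummarizedExperiment::assay(object, "logcounts")
        if (any(!is.finite(e)))
            msg <- c(msg, "'logcounts' contains non-finite values")
    }
    if (is.null(msg)) TRUE else msg
})

#' SpatialGraph: radius neighbor graph over the spots of one slice
#'
#' Binary symmetric adjacency built from spot coordinates: spots i and j are
#' connected iff their Euclidean distance is strictly less than \code{radius}.
#' The diagonal is zero; neighbor sets used during message passing always
#' include the spot itself (self-inclusion), so an isolated spot still
#' aggregates its own features.
#'
#' @slot adjacency sparse symmetric 0/1 matrix (\code{dgCMatrix}), zero diagonal.
#' @slot radius positive numeric, same units as the coordinates.
#' @export
setClass("SpatialGraph",
    representation(adjacency = "dgCMatrix", radius = "numeric"))

setValidity("SpatialGraph", function(object) {
    A <- object@adjacency
    if (nrow(A) != ncol(A)) return("adjacency must be square")
    if (length(object@radius) != 1L || object@radius <= 0)
        return("radius must be a single positive number")
    if (length(A@x) && any(A@x != 1)) return("adjacency entries must be 0/1")
    if (any(Matrix::diag(A) != 0)) return("adjacency diagonal must be zero")
    if (!Matrix::isSymmetric(A, tol = 0)) return("adjacency must be symmetric")
    TRUE
})

#' GATModel: parameters of the tied-weight graph attention autoencoder
#'
#' Encoder layer k maps d_{k-1} -> d_k through a weight matrix W_k and a pair
#' of attention vectors (v_s, v_r) defining self/neighbor logits. The decoder
#' stores nothing: it reuses W_k transposed and the transposed encoder
#' attention per layer (weight tying), so the parameter count of the full
#' autoencoder equals that of the encoder alone.
#'
#' @slot layerDims integer vector (g, d_1, ..., d_K); the latent dimension is
#'   the last entry.
#' @slot W list of K matrices, \code{W[[k]]} of shape d_k x d_{k-1}.
#' @slot vs,vr lists of K numeric vectors of length d_k (attention weights).
#' @slot activation name of the feature nonlinearity ("elu" or "linear");
#'   the final encoder layer and the final decoder output are always linear.
#' @slot gateActivation name of the nonlinearity applied to attention logits
#'   ("sigmoid" by default, a bounded gate that stabilizes the softmax).
#' @slot seed integer seed used for initialization.
#' @export
setClass("GATModel",
    representation(layerDims = "integer", W = "list", vs = "list",
                   vr = "list", activation = "character",
                   gateActivation = "character", seed = "integer"))

setValidity("GATModel", function(object) {
    K <- length(object@layerDims) - 1L
    if (K < 1L) return("need at least one layer")
    if (length(object@W) != K || length(object@vs) != K || length(object@vr) != K)
        return("W, vs, vr must each have one element per layer")
    for (k in seq_len(K)) {
        d_out <- object@layerDims[k + 1L]; d_in <- object@layerDims[k]
        if (!all(dim(object@W[[k]]) == c(d_out, d_in)))
            return(sprintf("W[[%d]] must be %d x %d", k, d_out, d_in))
        if (length(object@vs[[k]]) != d_out || length(object@vr[[k]]) != d_out)
            return(sprintf("vs/vr[[%d]] must have length %d", k, d_out))
    }
    TRUE
})

#' TransportPlan: unbalanced entropic optimal transport plan between two slices
#'
#' Nonnegative coupling T (n_x x n_y) between the spots of a source and a
#' target slice, together with the regularization parameters it was solved
#' under. Row/column marginal penalties are KL divergences with strengths
#' rho1/rho2; either may be \code{Inf}, which enforces the corresponding
#' marginal exactly (the partial-alignment regime of the method is
#' rho1 = Inf, rho2 = 0.01).
#'
#' @slot plan nonnegative numeric matrix n_x x n_y.
#' @slot epsilon entropic regularization strength.
#' @slot rho1,rho2 marginal KL penalties (positive, possibly \code{Inf}).
#' @slot a,b reference marginals (probability vectors).
#' @slot nIterUsed number of outer proximal iterations performed.
#' @slot converged TRUE if the plan change dropped below tolerance before the
#'   iteration budget was exhausted.
#' @export
setClass("TransportPlan",
    representation(plan = "matrix", epsilon = "numeric", rho1 = "numeric",
                   rho2 = "numeric", a = "numeric", b = "numeric",
                   nIterUsed = "integer", converged = "logical"))

setValidity("TransportPlan", function(object) {
    Tm <- object@plan
    if (any(!is.finite(Tm)) || any(Tm < 0))
        return("plan must be finite and nonnegative")
    if (length(object@a) != nrow(Tm) || length(object@b) != ncol(Tm))
        return("marginal lengths must match plan dimensions")
    if (object@epsilon <= 0) return("epsilon must be positive")
    TRUE
})

#' SpotMatching: hard spot correspondence derived from a transport plan
#'
#' Row-wise maximum probability matching: spot i of the source slice is
#' matched to the target spot carrying the largest plan mass in row i,
#' provided that mass reaches \code{minMass}; otherwise the spot is left
#' unmatched (NA). Ties break to the smallest target index.
#'
#' @slot matchIdx integer vector of length n_x; NA marks an unmatched spot.
#' @slot nTarget number of target spots.
#' @slot minMass mass threshold used.
#' @export
setClass("SpotMatching",
    representation(matchIdx = "integer", nTarget = "integer",
                   minMass = "numeric"))

setValidity("SpotMatching", function(object) {
    ok <- object@matchIdx[!is.na(object@matchIdx)]
    if (length(ok) && (min(ok) < 1L || max(ok) > object@nTarget))
        return("matchIdx out of range")
    TRUE
})

#' RigidTransform: rotation + translation in the plane
#'
#' @slot rotation 2x2 orthogonal matrix with det +1 (reflections rejected
#'   unless explicitly allowed at construction).
#' @slot translation numeric length-2 vector.
#' @export
setClass("RigidTransform",
    representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(2L, 2L))) return("rotation must be 2x2")
    if (max(abs(crossprod(R) - diag(2))) > 1e-8)
        return("rotation must be orthogonal (R^T R = I within 1e-8)")
    if (length(object@translation) != 2L)
        return("translation must have length 2")
    TRUE
})

#' IntegrationResult: output of joint autoencoder/transport training
#'
#' @slot embedding numeric matrix (total spots x latent dim), rows ordered as
#'   the concatenated input slices.
#' @slot sliceIds factor mapping embedding rows to their slice of origin.
#' @slot plan the final \linkS4class{TransportPlan} between the pair (or the
#'   last integrated pair).
#' @slot model trained \linkS4class{GATModel}.
#' @slot history data.frame with one row per epoch: epoch, lossRecon, lossUOT,
#'   lossTotal.
#' @slot config the training configuration list used.
#' @export
setClass("IntegrationResult",
    representation(embedding = "matrix", sliceIds = "factor",
                   plan = "TransportPlan", model = "GATModel",
                   history = "data.frame", config = "list"))

setValidity("IntegrationResult", function(object) {
    if (nrow(object@embedding) != length(object@sliceIds))
        return("sliceIds must map every embedding row")
    if (any(!is.finite(object@embedding)))
        return("embedding must be finite")
    TRUE
})
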