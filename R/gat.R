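## Graph attention autoencoder with tied weights.
##
## Encoder layer k:  h_i^(k) = act( sum_{j in S_i} att_ij^(k) W_k h_j^(k-1) )
## with attention logits e_ij = gate( vs.(W_k h_i) + vr.(W_k h_j) ) softmaxed
## over the neighbor set S_i (self-inclusive). The decoder reuses W_k
## transposed and the transposed attention of the same layer, so it carries
## no parameters of its own. The final encoder layer and the decoder output
## are linear.

.act <- function(x, name) {
    switch(name,
        elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
        linear = x,
        stop("unknown activation: ", name))
}
.act_grad <- function(x, name) {
    switch(name,
        elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
        linear = 1,
        stop("unknown activation: ", name))
}
.gate <- function(x, name) {
    switch(name,
        sigmoid = 1 / (1 + exp(-x)),
        linear = x,
        stop("unknown gate activation: ", name))
}
.gate_grad <- function(g, name) {   # takes the gate OUTPUT
    switch(name, sigmoid = g * (1 - g), linear = 1)
}

.rowsum <- function(x, grp, n) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
    out <- rowsum(x, grp)
    stopifnot(nrow(out) == n)
    unname(out)
}

# segment max over edge values grouped by sorted `grp`
.seg_max <- function(x, splitIdx) {
    vapply(splitIdx, function(ii) max(x[ii]), numeric(1))
}

#' Initialize a graph attention autoencoder
#'
#' Weights use Glorot-uniform initialization; attention vectors likewise.
#' Defaults follow the two-layer architecture (input -> 512 -> 30) of the
#' graph-attention backbone commonly used for spatial transcriptomics, with
#' ELU feature activation and a sigmoid gate on the attention logits.
#'
#' @param inputDim number of genes g (first layer width).
#' @param hiddenDims widths of the encoder layers after the input; the last
#'   entry is the latent dimension.
#' @param activation feature nonlinearity ("elu" or "linear"); the last
#'   encoder layer and the decoder output are always linear.
#' @param gateActivation nonlinearity on attention logits ("sigmoid" or
#'   "linear").
#' @param seed integer seed for reproducible initialization.
#' @return a \linkS4class{GATModel}.
#' @export
initGATModel <- function(inputDim, hiddenDims = c(512, 30),
                         activation = c("elu", "linear"),
                         gateActivation = c("sigmoid", "linear"),
                         seed = 0L) {
    activation <- match.arg(activation)
    gateActivation <- match.arg(gateActivation)
    layerDims <- as.integer(c(inputDim, hiddenDims))
    if (any(layerDims < 1L)) stop("layer dimensions must be positive")
    set.seed(as.integer(seed))
    K <- length(layerDims) - 1L
    W <- vs <- vr <- vector("list", K)
    for (k in seq_len(K)) {
        din <- layerDims[k]; dout <- layerDims[k + 1L]
        lim <- sqrt(6 / (din + dout))
        W[[k]] <- matrix(stats::runif(dout * din, -lim, lim), dout, din)
        limv <- sqrt(6 / (dout + 1))
        vs[[k]] <- stats::runif(dout, -limv, limv)
        vr[[k]] <- stats::runif(dout, -limv, limv)
    }
    new("GATModel", layerDims = layerDims, W = W, vs = vs, vr = vr,
        activation = activation, gateActivation = gateActivation,
        seed = as.integer(seed))
}

#' @export
setMethod("show", "GATModel", function(object) {
    cat("GATModel:", paste(object@layerDims, collapse = " -> "),
        sprintf("(%s features, %s gate, %d parameters)\n",
                object@activation, object@gateActivation, nParams(object)))
})

#' Number of trainable parameters
#'
#' The decoder is fully tied (transposed weights and transposed attention),
#' so this equals the encoder's parameter count.
#' @param model a \linkS4class{GATModel}.
#' @export
nParams <- function(model) {
    sum(vapply(model@W, length, 0L)) +
        sum(vapply(model@vs, length, 0L)) +
        sum(vapply(model@vr, length, 0L))
}

.flatten_params <- function(model) {
    unlist(c(model@W, model@vs, model@vr), use.names = FALSE)
}

.unflatten_params <- function(model, theta) {
    pos <- 0L
    take <- function(n) {
        out <- theta[pos + seq_len(n)]; pos <<- pos + n; out
    }
    for (k in seq_along(model@W)) {
        d <- dim(model@W[[k]])
        model@W[[k]] <- matrix(take(prod(d)), d[1L], d[2L])
    }
    for (k in seq_along(model@vs)) model@vs[[k]] <- take(length(model@vs[[k]]))
    for (k in seq_along(model@vr)) model@vr[[k]] <- take(length(model@vr[[k]]))
    stopifnot(pos == length(theta))
    model
}

.as_edge_list <- function(graphs) {
    if (is(graphs, "SpatialGraph")) graphs <- list(graphs)
    if (is.list(graphs) && !is.null(graphs$i) && !is.null(graphs$j))
        return(graphs)                     # already an edge structure
    e <- .graph_edges(graphs)
    e$splitIdx <- split(seq_along(e$i), e$i)
    e
}

# full forward pass; returns z, hhat and all caches needed for backprop
.gat_forward <- function(model, H0, edges) {
    K <- length(model@W)
    if (ncol(H0) != model@layerDims[1L])
        stop(sprintf("config error: input has %d features but layerDims[1] = %d",
                     ncol(H0), model@layerDims[1L]))
    if (nrow(H0) != edges$n)
        stop("shape error: input rows must match graph size")
    ei <- edges$i; ej <- edges$j; n <- edges$n
    enc <- vector("list", K)
    H <- H0
    for (k in seq_len(K)) {
        W <- model@W[[k]]
        P <- H %*% t(W)
        s <- drop(P %*% model@vs[[k]])
        r <- drop(P %*% model@vr[[k]])
        u <- s[ei] + r[ej]
        g <- .gate(u, model@gateActivation)
        m <- .seg_max(g, edges$splitIdx)
        ex <- exp(g - m[ei])
        denom <- drop(.rowsum(ex, ei, n))
        att <- ex / denom[ei]
        Apre <- .rowsum(att * P[ej, , drop = FALSE], ei, n)
        actName <- if (k == K) "linear" else model@activation
        Hnew <- .act(Apre, actName)
        enc[[k]] <- list(Hprev = H, P = P, g = g, att = att, Apre = Apre,
                         actName = actName)
        H <- Hnew
    }
    z <- H
    dec <- vector("list", K)
    Hd <- z
    for (k in rev(seq_len(K))) {
        W <- model@W[[k]]
        Q <- Hd %*% W
        Apre <- .rowsum(enc[[k]]$att * Q[ei, , drop = FALSE], ej, n)
        actName <- if (k == 1L) "linear" else model@activation
        Hnew <- .act(Apre, actName)
        dec[[k]] <- list(Hin = Hd, Q = Q, Apre = Apre, actName = actName)
        Hd <- Hnew
    }
    list(z = z, hhat = Hd, enc = enc, dec = dec, edges = edges)
}

# backprop: dz = extra gradient on the latent (e.g. transport term),
# dHhat = gradient on the reconstruction output. Returns grads (same
# structure as params) and gradient wrt H0.
.gat_backward <- function(model, fw, dz, dHhat) {
    K <- length(model@W)
    edges <- fw$edges
    ei <- edges$i; ej <- edges$j; n <- edges$n
    gW <- lapply(model@W, function(w) array(0, dim(w)))
    gvs <- lapply(model@vs, function(v) numeric(length(v)))
    gvr <- lapply(model@vr, function(v) numeric(length(v)))
    dattDec <- vector("list", K)

    # decoder backward: decoder executed k = K..1, so backprop k = 1..K
    dH <- dHhat
    for (k in seq_len(K)) {
        cache <- fw$dec[[k]]
        W <- model@W[[k]]
        dApre <- dH * .act_grad(cache$Apre, cache$actName)
        att <- fw$enc[[k]]$att
        dQ <- .rowsum(att * dApre[ej, , drop = FALSE], ei, n)
        dattDec[[k]] <- rowSums(cache$Q[ei, , drop = FALSE] *
                                dApre[ej, , drop = FALSE])
        gW[[k]] <- gW[[k]] + t(cache$Hin) %*% dQ
        dH <- dQ %*% t(W)
    }
    dz_total <- dH + dz

    # encoder backward: k = K..1
    dH <- dz_total
    for (k in rev(seq_len(K))) {
        cache <- fw$enc[[k]]
        W <- model@W[[k]]
        att <- cache$att; P <- cache$P
        dApre <- dH * .act_grad(cache$Apre, cache$actName)
        datt <- rowSums(dApre[ei, , drop = FALSE] * P[ej, , drop = FALSE]) +
            dattDec[[k]]
        dP <- .rowsum(att * dApre[ei, , drop = FALSE], ej, n)
        S <- drop(.rowsum(att * datt, ei, n))
        de <- att * (datt - S[ei])
        du <- de * .gate_grad(cache$g, model@gateActivation)
        ds <- drop(.rowsum(du, ei, n))
        dr <- drop(.rowsum(du, ej, n))
        gvs[[k]] <- gvs[[k]] + drop(t(P) %*% ds)
        gvr[[k]] <- gvr[[k]] + drop(t(P) %*% dr)
        dP <- dP + outer(ds, model@vs[[k]]) + outer(dr, model@vr[[k]])
        gW[[k]] <- gW[[k]] + t(dP) %*% cache$Hprev
        dH <- dP %*% W
    }
    list(W = gW, vs = gvs, vr = gvr, dH0 = dH)
}

#' Encode concatenated slices into the latent space
#'
#' Runs the graph-attention encoder on the row-concatenation of the
#' normalized expression of one or more slices over the block-diagonal union
#' of their spatial graphs (no cross-slice edges, hence no cross-slice
#' message passing).
#'
#' @param model a \linkS4class{GATModel}.
#' @param h0 numeric matrix (total spots x genes) of normalized expression,
#'   rows ordered slice by slice.
#' @param graphs a \linkS4class{SpatialGraph} or list of them (one per slice,
#'   in row order).
#' @return the latent matrix z (total spots x latent dim) with the forward
#'   cache attached as attribute \code{"forwardCache"} (needed by
#'   [gatDecode()]).
#' @export
gatEncode <- function(model, h0, graphs) {
    edges <- .as_edge_list(graphs)
    fw <- .gat_forward(model, as.matrix(h0), edges)
    z <- fw$z
    attr(z, "forwardCache") <- fw
    z
}

#' Decode a latent embedding back to expression space
#'
#' Mirrors the encoder using transposed weights and transposed per-layer
#' attention (weight tying); the output layer is linear. Requires the
#' forward cache produced by [gatEncode()] with the same model and graphs.
#'
#' @param model a \linkS4class{GATModel}.
#' @param embedding latent matrix from [gatEncode()].
#' @param graphs the same graphs used to encode (consistency-checked).
#' @return reconstruction matrix of the same shape as the encoder input.
#' @export
gatDecode <- function(model, embedding, graphs) {
    fw <- attr(embedding, "forwardCache")
    if (is.null(fw))
        stop("embedding must come from gatEncode() (forward cache missing)")
    edges <- .as_edge_list(graphs)
    if (!identical(edges$i, fw$edges$i) || !identical(edges$j, fw$edges$j))
        stop("graphs differ from those used to encode")
    fw$hhat
}

#' Per-layer attention matrix
#'
#' Computes the softmax-normalized attention coefficients of one encoder
#' layer given that layer's input features. Row i is supported on the
#' self-inclusive neighbor set S_i and sums to one.
#'
#' @param model a \linkS4class{GATModel}.
#' @param hPrev layer input features (n x d_(layer-1)).
#' @param graph a \linkS4class{SpatialGraph} (or list of graphs).
#' @param layer layer index (1-based).
#' @return sparse n x n matrix of attention weights.
#' @export
attentionWeights <- function(model, hPrev, graph, layer = 1L) {
    edges <- .as_edge_list(graph)
    W <- model@W[[layer]]
    P <- as.matrix(hPrev) %*% t(W)
    s <- drop(P %*% model@vs[[layer]])
    r <- drop(P %*% model@vr[[layer]])
    g <- .gate(s[edges$i] + r[edges$j], model@gateActivation)
    m <- .seg_max(g, edges$splitIdx)
    ex <- exp(g - m[edges$i])
    denom <- drop(.rowsum(ex, edges$i, edges$n))
    att <- ex / denom[edges$i]
    Matrix::sparseMatrix(i = edges$i, j = edges$j, x = att,
                         dims = c(edges$n, edges$n))
}

#' Reconstruction loss
#'
#' Sum over spots of squared Euclidean distance between input and
#' reconstruction; \code{reduction = "mean_spot"} (the default used in the
#' optimized objective) divides by the number of spots so the loss scale is
#' independent of slice size.
#'
#' @param h0 input matrix (spots x genes).
#' @param h0hat reconstruction of the same shape.
#' @param reduction "mean_spot" or "sum".
#' @return nonnegative scalar.
#' @export
reconstructionLoss <- function(h0, h0hat, reduction = c("mean_spot", "sum")) {
    reduction <- match.arg(reduction)
    if (!all(dim(h0) == dim(h0hat)))
        stop("shape error: h0 and h0hat must have identical dimensions")
    s <- sum((h0 - h0hat)^2)
    if (reduction == "mean_spot") s / nrow(h0) else s
}

# joint loss and gradient: (1-gamma) * mean-spot recon + gamma * sum(C * T)
# with the plan fixed (gradient flows only through the cost). The loss uses
# the raw latent distance (max-normalization is applied only to the cost
# handed to the solver: normalizing the loss itself opens a degenerate
# descent direction where inflating the largest latent distance shrinks the
# normalized loss without aligning anything).
.gat_loss_grad <- function(model, H0, edges, nx, plan = NULL, gamma = 0,
                           costSquared = FALSE, costNormalize = FALSE,
                           wantGrads = TRUE) {
    fw <- .gat_forward(model, H0, edges)
    n <- nrow(H0)
    res <- fw$hhat - H0
    lossRecon <- sum(res^2) / n
    lossUOT <- 0
    dz <- matrix(0, n, ncol(fw$z))
    if (!is.null(plan) && gamma > 0) {
        zx <- fw$z[seq_len(nx), , drop = FALSE]
        zy <- fw$z[(nx + 1L):n, , drop = FALSE]
        cc <- .cost_and_grad(zx, zy, transportMatrix(plan),
                             squared = costSquared,
                             normalize = costNormalize)
        lossUOT <- cc$loss
        dz[seq_len(nx), ] <- gamma * cc$dzx
        dz[(nx + 1L):n, ] <- gamma * cc$dzy
    }
    loss <- (1 - gamma) * lossRecon + gamma * lossUOT
    out <- list(loss = loss, lossRecon = lossRecon, lossUOT = lossUOT,
                z = fw$z, hhat = fw$hhat)
    if (wantGrads) {
        dHhat <- (1 - gamma) * 2 * res / n
        out$grads <- .gat_backward(model, fw, dz, dHhat)
    }
    out
}

# Euclidean (or squared) latent cost with optional max-normalization, plus
# the gradient of sum(C*T) wrt both embeddings. The plan T is a constant
# (envelope scheme); the normalizer max(C) is differentiated through (its
# argmax entry carries the extra term).
.cost_and_grad <- function(zx, zy, Tm, squared = FALSE, normalize = TRUE) {
    D2 <- outer(rowSums(zx^2), rowSums(zy^2), "+") - 2 * zx %*% t(zy)
    D2[D2 < 0] <- 0
    Craw <- if (squared) D2 else sqrt(D2)
    cmax <- if (normalize) max(Craw) else 1
    if (cmax == 0) cmax <- 1
    C <- Craw / cmax
    loss <- sum(C * Tm)
    Wc <- Tm / cmax                     # dloss / dCraw
    if (normalize && max(Craw) > 0) {
        imax <- which.max(Craw)
        Wc[imax] <- Wc[imax] - sum(Craw * Tm) / cmax^2
    }
    if (squared) {
        Wg <- Wc
    } else {
        Wg <- matrix(0, nrow(Craw), ncol(Craw))
        pos <- Craw > 0
        Wg[pos] <- Wc[pos] / Craw[pos]
    }
    scale <- if (squared) 2 else 1
    dzx <- scale * (rowSums(Wg) * zx - Wg %*% zy)
    dzy <- scale * (colSums(Wg) * zy - t(Wg) %*% zx)
    list(loss = loss, C = C, dzx = dzx, dzy = dzy)
}
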