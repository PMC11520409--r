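#' Synthetic slice generation settings
#'
#' Describes the layered-tissue simulation used throughout the package's
#' tests: spots on a regular grid, annotation labels forming horizontal
#' bands (emulating cortical layering), marker genes elevated within their
#' band, a per-slice batch effect (additive shift on a random 30% gene
#' subset), Gaussian noise on the log-normalized scale, and a planted rigid
#' motion of the second slice's coordinates. Partial overlap is created by
#' vertical crops retaining a configurable fraction of spots (default 0.7,
#' so the shared middle holds 40% of spots).
#'
#' @param gridShape c(rows, cols) of the spot grid.
#' @param nLayers number of horizontal label bands (must divide into rows).
#' @param genesPerLayer marker genes per band.
#' @param gTotal total genes (markers + background filler genes).
#' @param layerEffect mean expression shift of a band's markers inside the
#'   band (log-normalized units).
#' @param batchShift per-slice additive offset applied to a random 30% gene
#'   subset (0 = no batch effect).
#' @param noiseSd Gaussian noise standard deviation.
#' @param rotationDeg,translation planted rigid motion of slice 2.
#' @param overlapFraction fraction of spots kept by each vertical crop in
#'   the partial regime, in (0.5, 1].
#' @param seed integer seed; all generators are deterministic given it.
#' @param countMode also attach Poisson counts (exp-link) so the
#'   normalization pipeline can be exercised end to end.
#' @return a validated list of class "syntheticConfig".
#' @export
syntheticConfig <- function(gridShape = c(20L, 20L), nLayers = 4L,
                            genesPerLayer = 10L, gTotal = 60L,
                            layerEffect = 1, batchShift = 1,
                            noiseSd = 0.3, rotationDeg = 0,
                            translation = c(0, 0), overlapFraction = 0.7,
                            seed = 1L, countMode = FALSE) {
    cfg <- list(gridShape = as.integer(gridShape), nLayers = as.integer(nLayers),
                genesPerLayer = as.integer(genesPerLayer),
                gTotal = as.integer(gTotal), layerEffect = layerEffect,
                batchShift = batchShift, noiseSd = noiseSd,
                rotationDeg = rotationDeg, translation = translation,
                overlapFraction = overlapFraction, seed = as.integer(seed),
                countMode = countMode)
    if (cfg$nLayers > cfg$gridShape[1L])
        stop("config error: nLayers cannot exceed the number of grid rows")
    if (cfg$nLayers < 1L || any(cfg$gridShape < 1L) || cfg$gTotal < 1L)
        stop("config error: counts must be positive")
    if (cfg$overlapFraction <= 0 || cfg$overlapFraction > 1)
        stop("config error: overlapFraction must lie in (0, 1]")
    if (cfg$noiseSd < 0 || cfg$batchShift < 0)
        stop("config error: noiseSd and batchShift must be nonnegative")
    class(cfg) <- "syntheticConfig"
    cfg
}

# band label of each grid row
.band_of_rows <- function(rows, nLayers) {
    as.integer(cut(seq_len(rows), breaks = nLayers, labels = FALSE))
}

# baseline expression of one slice layout: grid coords, band labels,
# marker structure. Layers beyond the marker budget reuse filler genes.
.base_slice <- function(cfg, nLayers = cfg$nLayers) {
    rows <- cfg$gridShape[1L]; cols <- cfg$gridShape[2L]
    xy <- as.matrix(expand.grid(x = seq_len(cols), y = seq_len(rows)))
    band <- .band_of_rows(rows, nLayers)[xy[, "y"]]
    g <- cfg$gTotal
    nMarker <- min(nLayers * cfg$genesPerLayer, g)
    expr <- matrix(1, nrow(xy), g)   # baseline level 1 (log-normalized scale)
    for (l in seq_len(nLayers)) {
        gi <- ((l - 1L) * cfg$genesPerLayer + seq_len(cfg$genesPerLayer) - 1L) %%
            g + 1L
        expr[band == l, gi] <- expr[band == l, gi] + cfg$layerEffect
    }
    genes <- sprintf("gene%03d", seq_len(g))
    list(xy = xy, band = band, expr = expr, genes = genes,
         labels = factor(paste0("layer", band),
                         levels = paste0("layer", seq_len(nLayers))))
}

.rigid2d <- function(xy, deg, trans) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(xy %*% t(R), 2L, -as.numeric(trans), "-")
}

# batch effect: additive shift on a random 30% gene subset
.batch_vector <- function(g, shift) {
    v <- numeric(g)
    if (shift > 0) {
        sub <- sample.int(g, max(1L, round(0.3 * g)))
        v[sub] <- shift
    }
    v
}

.finish_slice <- function(base, expr, xy, cfg, id) {
    lc <- t(expr)   # genes x spots
    rownames(lc) <- base$genes
    colnames(lc) <- sprintf("%s_spot%04d", id, seq_len(ncol(lc)))
    counts <- NULL
    if (cfg$countMode) counts <- matrix(stats::rpois(length(lc), exp(lc)),
                                        nrow(lc), ncol(lc),
                                        dimnames = dimnames(lc))
    STSlice(coords = xy, counts = counts, logcounts = lc,
            labels = base$labels, sliceId = id)
}

#' Generate a layered slice pair with planted ground truth
#'
#' Two slices over the same spot grid: identical band labels, expression =
#' baseline + marker effect + per-slice batch shift + Gaussian noise, and
#' slice 2 coordinates moved by the planted rigid motion. Ground truth is
#' the identity spot correspondence. Deterministic given \code{cfg$seed}.
#'
#' @param cfg a [syntheticConfig()].
#' @return list with \code{sliceX}, \code{sliceY} (\linkS4class{STSlice}s)
#'   and \code{truth}, the integer ground-truth correspondence (spot i of X
#'   corresponds to spot truth[i] of Y).
#' @export
simLayeredPair <- function(cfg = syntheticConfig()) {
    set.seed(cfg$seed)
    base <- .base_slice(cfg)
    n <- nrow(base$xy); g <- cfg$gTotal
    b1 <- .batch_vector(g, cfg$batchShift)
    b2 <- .batch_vector(g, cfg$batchShift)
    e1 <- base$expr + matrix(b1, n, g, byrow = TRUE) +
        matrix(stats::rnorm(n * g, 0, cfg$noiseSd), n, g)
    e2 <- base$expr + matrix(b2, n, g, byrow = TRUE) +
        matrix(stats::rnorm(n * g, 0, cfg$noiseSd), n, g)
    xy2 <- .rigid2d(base$xy, cfg$rotationDeg, cfg$translation)
    list(sliceX = .finish_slice(base, e1, base$xy, cfg, "sliceX"),
         sliceY = .finish_slice(base, e2, xy2, cfg, "sliceY"),
         truth = seq_len(n))
}

#' Generate a partially overlapping subslice pair
#'
#' Crops one generated slice along two vertical lines: the left crop and
#' the right crop each keep \code{overlapFraction} of the columns, so the
#' shared middle holds \code{2*overlapFraction - 1} of the spots (70%
#' crops -> 40% shared). The second crop receives its own batch shift and
#' the planted rigid motion. Ground truth is defined only on shared spots.
#'
#' @param cfg a [syntheticConfig()] with \code{overlapFraction > 0.5}.
#' @return list with \code{sliceX} (left crop), \code{sliceY} (right crop)
#'   and \code{truth}: integer vector over X's spots, index into Y's spots
#'   for shared spots and NA outside the overlap.
#' @export
simPartialPair <- function(cfg = syntheticConfig()) {
    if (cfg$overlapFraction <= 0.5)
        stop("config error: overlapFraction <= 0.5 leaves no shared region")
    set.seed(cfg$seed)
    base <- .base_slice(cfg)
    n <- nrow(base$xy); g <- cfg$gTotal
    cols <- cfg$gridShape[2L]
    expr <- base$expr + matrix(stats::rnorm(n * g, 0, cfg$noiseSd), n, g)
    nKeep <- round(cfg$overlapFraction * cols)
    leftCols <- seq_len(nKeep)
    rightCols <- seq.int(cols - nKeep + 1L, cols)
    idxL <- which(base$xy[, "x"] %in% leftCols)
    idxR <- which(base$xy[, "x"] %in% rightCols)
    b2 <- .batch_vector(g, cfg$batchShift)
    exprR <- expr[idxR, , drop = FALSE] +
        matrix(b2, length(idxR), g, byrow = TRUE)
    xyR <- .rigid2d(base$xy[idxR, , drop = FALSE], cfg$rotationDeg,
                    cfg$translation)
    subBase <- function(idx) list(genes = base$genes,
                                  labels = droplevels(base$labels[idx]))
    sliceX <- .finish_slice(c(subBase(idxL), list()),
                            expr[idxL, , drop = FALSE],
                            base$xy[idxL, , drop = FALSE], cfg, "left")
    sliceY <- .finish_slice(c(subBase(idxR), list()), exprR, xyR, cfg,
                            "right")
    truth <- match(idxL, idxR)   # NA outside the shared middle
    list(sliceX = sliceX, sliceY = sliceY, truth = truth)
}

#' Generate a stack of synthetic slices for multi-slice integration
#'
#' \code{nSlices} replicates of one layered tissue, each with an independent
#' batch shift, independent noise, and its own planted rigid motion
#' (rotation angles spaced by \code{cfg$rotationDeg}, translations scaled by
#' slice index). With \code{labelDrift = TRUE} the number of bands grows by
#' one per slice (a new annotation appears in each later slice, emulating
#' developmental series).
#'
#' @param cfg a [syntheticConfig()].
#' @param nSlices number of slices (>= 2).
#' @param labelDrift grow the label set across slices.
#' @return list with \code{slices} (list of \linkS4class{STSlice}) and
#'   \code{truth} (identity correspondence per slice, against slice 1; NA
#'   where spot counts differ).
#' @export
simMultiStack <- function(cfg = syntheticConfig(), nSlices = 3L,
                          labelDrift = FALSE) {
    if (nSlices < 2L) stop("config error: need at least two slices")
    set.seed(cfg$seed)
    out <- vector("list", nSlices)
    for (s in seq_len(nSlices)) {
        nl <- if (labelDrift) cfg$nLayers + (s - 1L) else cfg$nLayers
        if (nl > cfg$gridShape[1L])
            stop("config error: label drift exceeds grid rows")
        base <- .base_slice(cfg, nLayers = nl)
        n <- nrow(base$xy); g <- cfg$gTotal
        bv <- .batch_vector(g, cfg$batchShift)
        expr <- base$expr + matrix(bv, n, g, byrow = TRUE) +
            matrix(stats::rnorm(n * g, 0, cfg$noiseSd), n, g)
        xy <- .rigid2d(base$xy, cfg$rotationDeg * (s - 1L),
                       as.numeric(cfg$translation) * (s - 1L))
        out[[s]] <- .finish_slice(base, expr, xy, cfg,
                                  sprintf("slice%d", s))
    }
    n1 <- nSpots(out[[1L]])
    truth <- lapply(out, function(sl)
        if (nSpots(sl) == n1) seq_len(n1) else rep(NA_integer_, nSpots(sl)))
    list(slices = out, truth = truth)
}
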