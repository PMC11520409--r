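#' Build the spatial neighbor graph of a slice
#'
#' Connects two spots of the same slice whenever their Euclidean distance is
#' strictly less than \code{radius}. The adjacency is binary, symmetric, with
#' zero diagonal; message passing later adds self-inclusion so isolated spots
#' still see their own features. For large slices (> 5000 spots) neighbor
#' search uses grid bucketing so memory stays linear in the number of edges.
#'
#' @param x an \linkS4class{STSlice} or an n x 2 coordinate matrix.
#' @param radius positive neighbor radius, in coordinate units. When NULL, a
#'   radius achieving about \code{targetMeanNeighbors} mean neighbors is
#'   chosen via [suggestRadius()].
#' @param targetMeanNeighbors used only when \code{radius} is NULL (default 6,
#'   the hexagonal Visium neighborhood).
#' @return a \linkS4class{SpatialGraph}.
#' @examples
#' xy <- as.matrix(expand.grid(x = 0:2, y = 0:2))
#' g <- buildSpatialGraph(xy, radius = 1.1)
#' Matrix::rowSums(adjacency(g))   # 2 at corners, 4 in the center
#' @export
buildSpatialGraph <- function(x, radius = NULL, targetMeanNeighbors = 6) {
    coords <- if (is(x, "STSlice")) spatialCoords(x) else as.matrix(x)
    if (any(!is.finite(coords)) || ncol(coords) != 2L)
        stop("coordinates must be a finite n x 2 matrix")
    if (is.null(radius))
        radius <- suggestRadius(coords, targetMeanNeighbors)
    if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
        stop("parameter error: radius must be a single positive number")
    n <- nrow(coords)
    if (n <= 5000L) {
        d <- as.matrix(stats::dist(coords))
        hit <- which(d < radius & upper.tri(d), arr.ind = TRUE)
        ii <- hit[, 1L]; jj <- hit[, 2L]
    } else {
        pairs <- .bucket_pairs(coords, radius)
        ii <- pairs$i; jj <- pairs$j
    }
    A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii),
                              x = rep(1, 2L * length(ii)), dims = c(n, n))
    new("SpatialGraph", adjacency = methods::as(A, "dgCMatrix"),
        radius = radius)
}

# grid-bucket all-pairs-within-radius; memory linear in edges
.bucket_pairs <- function(coords, radius) {
    cell <- pmax(radius, .Machine$double.eps)
    cx <- floor(coords[, 1L] / cell); cy <- floor(coords[, 2L] / cell)
    key <- paste(cx, cy)
    buckets <- split(seq_len(nrow(coords)), key)
    ii <- integer(0); jj <- integer(0)
    keys <- do.call(rbind, strsplit(names(buckets), " "))
    kx <- as.numeric(keys[, 1L]); ky <- as.numeric(keys[, 2L])
    keyIndex <- stats::setNames(seq_along(buckets), names(buckets))
    for (b in seq_along(buckets)) {
        idx <- buckets[[b]]
        for (dx in -1:1) for (dy in -1:1) {
            nb <- keyIndex[paste(kx[b] + dx, ky[b] + dy)]
            if (is.na(nb) || nb < b) next
            jdx <- buckets[[nb]]
            dd <- outer(coords[idx, 1L], coords[jdx, 1L], "-")^2 +
                  outer(coords[idx, 2L], coords[jdx, 2L], "-")^2
            hit <- which(dd < radius^2, arr.ind = TRUE)
            a <- idx[hit[, 1L]]; bI <- jdx[hit[, 2L]]
            if (nb == b) {              # same bucket: avoid self/duplicates
                keep <- a < bI
                a <- a[keep]; bI <- bI[keep]
            }
            ii <- c(ii, pmin(a, bI)); jj <- c(jj, pmax(a, bI))
        }
    }
    list(i = ii, j = jj)
}

#' Suggest a neighbor radius from a target mean degree
#'
#' Scans candidate radii (just above the sorted unique pairwise distances,
#' subsampled for large slices) and returns the smallest one whose mean
#' neighbor count (self excluded) reaches \code{targetMeanNeighbors}. If no
#' candidate reaches the target, the largest pairwise distance plus a small
#' epsilon is returned (every pair connected). With all-identical coordinates
#' a minimal positive fallback is returned with a warning.
#'
#' @param x an \linkS4class{STSlice} or an n x 2 coordinate matrix.
#' @param targetMeanNeighbors desired mean number of neighbors (default 6).
#' @return a positive radius.
#' @export
suggestRadius <- function(x, targetMeanNeighbors = 6) {
    coords <- if (is(x, "STSlice")) spatialCoords(x) else as.matrix(x)
    n <- nrow(coords)
    if (n < 2L) stop("need at least two spots")
    if (n > 2000L) {
        set.seed(0L)  # subsample only to bound the candidate scan
        coords <- coords[sort(sample.int(n, 2000L)), , drop = FALSE]
        n <- 2000L
    }
    d <- stats::dist(coords)
    dv <- sort(unique(as.vector(d)))
    dv <- dv[dv > 0]
    if (length(dv) == 0L) {
        warning("all coordinates identical; returning a minimal radius")
        return(.Machine$double.eps * 100)
    }
    eps <- 1e-9 * dv[length(dv)]
    dm <- as.matrix(d)
    for (r in dv) {
        meanNb <- (sum(dm < r + eps) - n) / n
        if (meanNb >= targetMeanNeighbors) return(r + eps)
    }
    dv[length(dv)] + eps
}

#' @rdname SpatialGraph-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname SpatialGraph-accessors
#' @export
setGeneric("graphRadius", function(x) standardGeneric("graphRadius"))
#' @rdname SpatialGraph-accessors
#' @export
setGeneric("neighborSets", function(x) standardGeneric("neighborSets"))

#' Accessors for SpatialGraph
#'
#' \code{adjacency} returns the sparse 0/1 adjacency; \code{graphRadius} the
#' radius used; \code{neighborSets} the list of neighbor index sets S_i, each
#' including the spot itself (self-inclusion used for message passing).
#'
#' @param x a \linkS4class{SpatialGraph}.
#' @name SpatialGraph-accessors
NULL

#' @rdname SpatialGraph-accessors
#' @export
setMethod("adjacency", "SpatialGraph", function(x) x@adjacency)
#' @rdname SpatialGraph-accessors
#' @export
setMethod("graphRadius", "SpatialGraph", function(x) x@radius)
#' @rdname SpatialGraph-accessors
#' @export
setMethod("neighborSets", "SpatialGraph", function(x) {
    A <- x@adjacency
    n <- nrow(A)
    At <- Matrix::t(A)  # columns of At = rows of A; A symmetric anyway
    lapply(seq_len(n), function(i) {
        nb <- At@i[seq.int(At@p[i] + 1L, length.out = At@p[i + 1L] - At@p[i])] + 1L
        sort(unique(c(i, nb)))
    })
})

#' @export
setMethod("show", "SpatialGraph", function(object) {
    n <- nrow(object@adjacency)
    ne <- length(object@adjacency@x) / 2
    cat(sprintf("SpatialGraph: %d spots, %d edges, radius %.4g (mean degree %.2f)\n",
                n, ne, object@radius, 2 * ne / n))
})

#' Export the graph edge list as a two-column TSV (i < j, 1-based)
#' @param graph a \linkS4class{SpatialGraph}.
#' @param path output file.
#' @export
writeEdgeList <- function(graph, path) {
    A <- adjacency(graph)
    idx <- Matrix::which(A != 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    utils::write.table(data.frame(i = idx[, 1], j = idx[, 2]), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

# edge representation used by the autoencoder: for the block-diagonal union
# of per-slice graphs, with self-loops added. Edges are (i <- j) meaning
# "j is in S_i"; sorted by i.
.graph_edges <- function(graphs) {
    offs <- 0L
    ei <- integer(0); ej <- integer(0)
    for (g in graphs) {
        A <- adjacency(g)
        n <- nrow(A)
        idx <- Matrix::which(A != 0, arr.ind = TRUE)
        ei <- c(ei, offs + c(idx[, 1L], seq_len(n)))
        ej <- c(ej, offs + c(idx[, 2L], seq_len(n)))
        offs <- offs + n
    }
    o <- order(ei, ej)
    list(i = ei[o], j = ej[o], n = offs)
}
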