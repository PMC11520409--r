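#' Normalize slices and reduce them to a common highly variable gene set
#'
#' Standard spatial-transcriptomics preprocessing applied jointly to two or
#' more slices so that the downstream model sees a single ordered gene list:
#' \enumerate{
#'   \item intersect gene names across slices (error if empty);
#'   \item per-spot library-size scaling of the raw counts to
#'     \code{targetSum}, then \code{log1p};
#'   \item highly variable gene selection on the shared gene set: each slice
#'     ranks genes by dispersion (variance/mean of the scaled counts); genes
#'     are then ranked by how many slices selected them in their top
#'     \code{nHVG}, ties broken by mean dispersion across slices;
#'   \item the selected genes are ordered lexicographically, making the
#'     output independent of input format or slice order.
#' }
#' The procedure is idempotent on the gene list: re-running it on its own
#' output returns the same genes.
#'
#' @param slices list of \linkS4class{STSlice}s, each with a \code{counts}
#'   assay.
#' @param nHVG number of highly variable genes to keep (the output may have
#'   fewer if the intersection is smaller).
#' @param targetSum per-spot library size after scaling.
#' @return list of \linkS4class{STSlice}s sharing one ordered gene list, with
#'   a \code{logcounts} assay added (counts retained, subset to the same
#'   genes).
#' @export
normalizeAndIntersect <- function(slices, nHVG = 3000, targetSum = 1e4) {
    if (length(slices) < 2L)
        stop("need at least two slices")
    if (nHVG < 1L) stop("parameter error: nHVG must be >= 1")
    if (targetSum <= 0) stop("parameter error: targetSum must be positive")
    geneSets <- lapply(slices, rownames)
    if (any(vapply(geneSets, is.null, logical(1))))
        stop("all slices must have gene names (rownames)")
    shared <- Reduce(intersect, geneSets)
    if (length(shared) == 0L)
        stop("incompatibility error: empty gene intersection across slices")
    scaled <- lapply(slices, function(sl) {
        if (!"counts" %in% SummarizedExperiment::assayNames(sl))
            stop("slice '", sliceId(sl), "' has no raw counts assay")
        m <- SummarizedExperiment::assay(sl, "counts")[shared, , drop = FALSE]
        lib <- colSums(m)
        if (any(lib == 0))
            stop("validation error: spot(s) with zero total count in slice '",
                 sliceId(sl), "' (cannot scale)")
        sweep(m, 2L, lib / targetSum, "/")
    })
    # per-slice dispersion ranking
    nKeep <- min(nHVG, length(shared))
    disp <- vapply(scaled, function(m) {
        mu <- rowMeans(m)
        v <- apply(m, 1L, stats::var)
        d <- ifelse(mu > 0, v / mu, 0)
        d
    }, numeric(length(shared)))
    disp <- matrix(disp, nrow = length(shared),
                   dimnames = list(shared, NULL))
    votes <- rowSums(apply(disp, 2L, function(d)
        rank(-d, ties.method = "first") <= nKeep))
    meanDisp <- rowMeans(disp)
    ord <- order(-votes, -meanDisp, shared)
    keep <- sort(shared[ord[seq_len(nKeep)]])      # lexicographic final order
    mapply(function(sl, m) {
        lc <- log1p(m[keep, , drop = FALSE])
        counts <- SummarizedExperiment::assay(sl, "counts")[keep, ,
                                                            drop = FALSE]
        STSlice(coords = spatialCoords(sl), counts = counts, logcounts = lc,
                labels = spotLabels(sl), sliceId = sliceId(sl))
    }, slices, scaled, SIMPLIFY = FALSE)
}
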