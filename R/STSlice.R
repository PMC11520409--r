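#' Construct an STSlice
#'
#' @param coords numeric matrix/data.frame, one row per spot, two columns (x, y).
#' @param counts optional nonnegative integer-like gene x spot matrix of raw
#'   counts (genes in rows, Bioconductor orientation).
#' @param logcounts optional numeric gene x spot matrix of normalized,
#'   log-transformed expression. At least one of \code{counts}/\code{logcounts}
#'   must be given.
#' @param labels optional per-spot categorical annotation (coerced to factor).
#' @param sliceId single string naming the slice.
#'
#' @return an \linkS4class{STSlice}.
#' @examples
#' expr <- matrix(rnorm(20), nrow = 5,
#'                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' xy <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' sl <- STSlice(coords = xy, logcounts = expr, sliceId = "demo")
#' nSpots(sl)
#' @export
STSlice <- function(coords, counts = NULL, logcounts = NULL, labels = NULL,
                    sliceId = "slice") {
    if (is.null(counts) && is.null(logcounts))
        stop("provide at least one of 'counts' or 'logcounts'")
    coords <- as.matrix(coords)
    if (!is.numeric(coords))
        stop("validation error: coordinates must be numeric")
    if (ncol(coords) != 2L)
        stop("format error: coordinates must have exactly 2 columns")
    assays <- list()
    if (!is.null(counts)) assays$counts <- as.matrix(counts)
    if (!is.null(logcounts)) assays$logcounts <- as.matrix(logcounts)
    n <- ncol(assays[[1L]])
    if (nrow(coords) != n)
        stop(sprintf(
            "shape error: %d coordinate rows for %d expression columns (spots)",
            nrow(coords), n))
    cd <- S4Vectors::DataFrame(row.names = colnames(assays[[1L]]))
    if (!is.null(labels)) {
        if (length(labels) != n)
            stop("shape error: 'labels' length must equal the number of spots")
        cd$label <- factor(labels)
    }
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = assays, colData = cd)
    new("STSlice", sce, sliceId = as.character(sliceId),
        spatialCoords = unname(coords))
}

#' @rdname STSlice-accessors
#' @export
setGeneric("spatialCoords", function(x) standardGeneric("spatialCoords"))
#' @rdname STSlice-accessors
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))
#' @rdname STSlice-accessors
#' @export
setGeneric("spotLabels", function(x) standardGeneric("spotLabels"))
#' @rdname STSlice-accessors
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' Accessors for STSlice
#'
#' \code{spatialCoords} returns the n x 2 coordinate matrix; \code{sliceId}
#' the slice identifier; \code{spotLabels} the per-spot annotation factor (or
#' NULL); \code{nSpots} the number of spots.
#'
#' @param x an \linkS4class{STSlice}.
#' @name STSlice-accessors
#' @aliases spatialCoords sliceId spotLabels nSpots
NULL

#' @rdname STSlice-accessors
#' @export
setMethod("spatialCoords", "STSlice", function(x) x@spatialCoords)
#' @rdname STSlice-accessors
#' @export
setMethod("sliceId", "STSlice", function(x) x@sliceId)
#' @rdname STSlice-accessors
#' @export
setMethod("spotLabels", "STSlice", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("label" %in% colnames(cd)) cd$label else NULL
})
#' @rdname STSlice-accessors
#' @export
setMethod("nSpots", "STSlice", function(x) ncol(x))

#' @export
setMethod("show", "STSlice", function(object) {
    cat(sprintf("STSlice '%s': %d spots x %d genes\n",
                object@sliceId, ncol(object), nrow(object)))
    cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                           collapse = ", "), "\n")
    lab <- spotLabels(object)
    if (!is.null(lab))
        cat("  labels:", nlevels(lab), "levels\n")
    rng <- apply(object@spatialCoords, 2, range)
    cat(sprintf("  coords: x in [%.3g, %.3g], y in [%.3g, %.3g]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
})

# spot x gene matrix of normalized expression (model orientation)
spotExpr <- function(x) {
    if (!"logcounts" %in% SummarizedExperiment::assayNames(x))
        stop("slice has no 'logcounts' assay; run normalizeAndIntersect() ",
             "or supply logcounts")
    t(SummarizedExperiment::assay(x, "logcounts"))
}
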