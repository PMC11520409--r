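#' Read a slice from disk
#'
#' Dispatcher over the supported on-disk formats. \code{format = "h5ad"}
#' expects an AnnData file (expression in \code{X}, coordinates in a named
#' 2-column \code{obsm} field, annotations as a categorical \code{obs}
#' column). \code{format = "mtx"} expects a directory (or an .mtx path whose
#' directory) containing \code{matrix.mtx} (genes x spots), \code{genes.tsv}
#' and \code{coords.tsv} (columns: spot_id, x, y and optionally label).
#' \code{format = "csv"} expects \code{expr.csv} (spots x genes, header =
#' gene names, first column = spot ids) next to \code{coords.csv}.
#'
#' @param path file (h5ad) or directory (mtx/csv) to read.
#' @param format one of "h5ad", "mtx", "csv".
#' @param spatialKey name of the obsm field holding coordinates (h5ad only).
#' @param labelKey optional name of the annotation column.
#' @param sliceId identifier for the returned slice; defaults to the file name.
#' @return an \linkS4class{STSlice}. Raw counts are preserved when present
#'   (h5ad \code{layers/counts}, or when X itself is integer counts the matrix
#'   is stored as counts).
#' @export
loadSlice <- function(path, format = c("h5ad", "mtx", "csv"),
                      spatialKey = "spatial", labelKey = NULL,
                      sliceId = NULL) {
    format <- match.arg(format)
    if (is.null(sliceId))
        sliceId <- sub("\\.[^.]*$", "", basename(path))
    switch(format,
        h5ad = readSliceH5AD(path, spatialKey = spatialKey,
                             labelKey = labelKey, sliceId = sliceId),
        mtx = readSliceMTX(path, labelKey = labelKey, sliceId = sliceId),
        csv = readSliceCSV(path, labelKey = labelKey, sliceId = sliceId))
}

.h5_exists <- function(path, name) {
    ls <- rhdf5::h5ls(path, recursive = TRUE)
    paths <- sub("^/+", "", paste0(ls$group, "/", ls$name))
    sub("^/+", "", name) %in% paths
}

# read X-like node: dense dataset or csr/csc group -> genes x spots matrix
.h5_read_matrix <- function(path, name, nObs, nVar) {
    at <- rhdf5::h5readAttributes(path, name)
    enc <- at[["encoding-type"]]
    x <- rhdf5::h5read(path, name)
    if (!is.list(x)) {
        # dense: h5 shape (n_obs, n_var) arrives in R as (n_var, n_obs)
        storage.mode(x) <- "double"
        return(x)
    }
    shape <- as.integer(at[["shape"]])
    if (is.null(enc)) enc <- "csr_matrix"
    m <- if (identical(enc, "csr_matrix")) {
        # CSR over obs == CSC over (var x obs)
        Matrix::sparseMatrix(i = as.integer(x$indices) + 1L,
            p = as.integer(x$indptr), x = as.numeric(x$data),
            dims = c(shape[2L], shape[1L]))
    } else {
        Matrix::t(Matrix::sparseMatrix(i = as.integer(x$indices) + 1L,
            p = as.integer(x$indptr), x = as.numeric(x$data),
            dims = c(shape[1L], shape[2L])))
    }
    as.matrix(m)
}

.h5_read_column <- function(path, name) {
    obj <- rhdf5::h5read(path, name)
    if (is.list(obj)) { # categorical encoding
        factor(obj$categories[as.integer(obj$codes) + 1L],
               levels = obj$categories)
    } else as.vector(obj)
}

#' @rdname loadSlice
#' @export
readSliceH5AD <- function(path, spatialKey = "spatial", labelKey = NULL,
                          sliceId = sub("\\.h5ad$", "", basename(path))) {
    if (!file.exists(path)) stop("file not found: ", path)
    spots <- as.vector(rhdf5::h5read(path, "obs/_index"))
    genes <- as.vector(rhdf5::h5read(path, "var/_index"))
    X <- .h5_read_matrix(path, "X", length(spots), length(genes))
    dimnames(X) <- list(genes, spots)
    spName <- paste0("obsm/", spatialKey)
    if (!.h5_exists(path, spName))
        stop(sprintf("format error: spatial field 'obsm/%s' missing in %s",
                     spatialKey, path))
    sp <- rhdf5::h5read(path, spName)
    if (!is.numeric(sp))
        stop("validation error: coordinates are not numeric")
    sp <- t(sp)                       # stored (2, n) from R's view
    if (ncol(sp) != 2L)
        stop("format error: spatial field must have 2 columns")
    labels <- NULL
    if (!is.null(labelKey)) {
        lname <- paste0("obs/", labelKey)
        if (!.h5_exists(path, lname) && !.h5_exists(path, paste0(lname, "/codes")))
            stop(sprintf("format error: obs column '%s' missing", labelKey))
        labels <- .h5_read_column(path, lname)
    }
    counts <- NULL
    if (.h5_exists(path, "layers/counts")) {
        counts <- .h5_read_matrix(path, "layers/counts",
                                  length(spots), length(genes))
        dimnames(counts) <- dimnames(X)
    }
    isCounts <- is.null(counts) && all(X >= 0) && all(X == round(X))
    if (isCounts)
        STSlice(coords = sp, counts = X, labels = labels, sliceId = sliceId)
    else
        STSlice(coords = sp, counts = counts, logcounts = X, labels = labels,
                sliceId = sliceId)
}

.h5_write_attr <- function(file, name, attrs) {
    fid <- rhdf5::H5Fopen(file)
    on.exit(rhdf5::H5Fclose(fid))
    oid <- rhdf5::H5Oopen(fid, name)
    on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
    for (an in names(attrs))   # column-order must stay an array even of 1
        rhdf5::h5writeAttribute(attrs[[an]], oid, an,
                                variableLengthString = is.character(attrs[[an]]),
                                asScalar = length(attrs[[an]]) == 1L &&
                                    an != "column-order")
}

# variable-length UTF-8 string dataset (the encoding h5py decodes to str)
.h5_write_str <- function(values, file, name) {
    rhdf5::h5createDataset(file, name, dims = length(values),
                           storage.mode = "character", size = NULL,
                           encoding = "UTF-8")
    rhdf5::h5write(values, file, name)
}

.h5_write_df_index <- function(file, group, index, columns = list()) {
    rhdf5::h5createGroup(file, group)
    .h5_write_str(index, file, paste0(group, "/_index"))
    for (cn in names(columns)) {
        col <- columns[[cn]]
        cpath <- paste0(group, "/", cn)
        if (is.factor(col)) {
            rhdf5::h5createGroup(file, cpath)
            rhdf5::h5write(as.integer(col) - 1L, file,
                           paste0(cpath, "/codes"))
            .h5_write_str(levels(col), file, paste0(cpath, "/categories"))
            .h5_write_attr(file, cpath, list(
                "encoding-type" = "categorical",
                "encoding-version" = "0.2.0", ordered = 0L))
        } else if (is.character(col)) {
            .h5_write_str(col, file, cpath)
            .h5_write_attr(file, cpath, list(
                "encoding-type" = "string-array",
                "encoding-version" = "0.2.0"))
        } else {
            rhdf5::h5write(col, file, cpath)
            .h5_write_attr(file, cpath, list(
                "encoding-type" = "array", "encoding-version" = "0.2.0"))
        }
    }
    .h5_write_attr(file, group, list(
        "_index" = "_index",
        "column-order" = if (length(columns)) names(columns) else numeric(0),
        "encoding-type" = "dataframe", "encoding-version" = "0.2.0"))
}

#' Write a slice (plus optional results) as an AnnData h5ad file
#'
#' Writes normalized expression to \code{X} (or raw counts when no
#' normalized assay exists), coordinates to \code{obsm/spatial}, labels to
#' \code{obs/label}, raw counts to \code{layers/counts}, an optional
#' embedding to \code{obsm/<embeddingKey>} and optional transport metadata
#' to \code{uns}. The encoding follows the AnnData on-disk spec so scanpy
#' can read the file back.
#'
#' @param slice an \linkS4class{STSlice}.
#' @param path output .h5ad path (overwritten).
#' @param embedding optional numeric matrix with \code{nSpots(slice)} rows.
#' @param embeddingKey obsm field name for the embedding.
#' @param uns optional named list of unstructured metadata (numeric/character
#'   scalars or vectors), e.g. transport plan parameters.
#' @return \code{path}, invisibly.
#' @export
writeSliceH5AD <- function(slice, path, embedding = NULL,
                           embeddingKey = "X_sliceot", uns = list()) {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    an <- SummarizedExperiment::assayNames(slice)
    Xname <- if ("logcounts" %in% an) "logcounts" else "counts"
    X <- SummarizedExperiment::assay(slice, Xname)
    genes <- rownames(slice)
    if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(slice)))
    spots <- colnames(slice)
    if (is.null(spots)) spots <- paste0("spot", seq_len(ncol(slice)))
    rhdf5::h5write(unname(as.matrix(X)), path, "X")
    .h5_write_attr(path, "X", list("encoding-type" = "array",
                                   "encoding-version" = "0.2.0"))
    cols <- list()
    if (!is.null(spotLabels(slice))) cols$label <- spotLabels(slice)
    .h5_write_df_index(path, "obs", spots, cols)
    .h5_write_df_index(path, "var", genes)
    rhdf5::h5createGroup(path, "obsm")
    rhdf5::h5write(t(spatialCoords(slice)), path, "obsm/spatial")
    .h5_write_attr(path, "obsm/spatial",
                   list("encoding-type" = "array",
                        "encoding-version" = "0.2.0"))
    if (!is.null(embedding)) {
        stopifnot(nrow(embedding) == ncol(slice))
        rhdf5::h5write(t(unname(as.matrix(embedding))), path,
                       paste0("obsm/", embeddingKey))
        .h5_write_attr(path, paste0("obsm/", embeddingKey),
                       list("encoding-type" = "array",
                            "encoding-version" = "0.2.0"))
    }
    rhdf5::h5createGroup(path, "layers")
    if ("logcounts" %in% an && "counts" %in% an) {
        rhdf5::h5write(unname(as.matrix(
            SummarizedExperiment::assay(slice, "counts"))), path,
            "layers/counts")
        .h5_write_attr(path, "layers/counts",
                       list("encoding-type" = "array",
                            "encoding-version" = "0.2.0"))
    }
    rhdf5::h5createGroup(path, "uns")
    for (nm in names(uns)) {
        if (is.character(uns[[nm]]))
            .h5_write_str(uns[[nm]], path, paste0("uns/", nm))
        else
            rhdf5::h5write(uns[[nm]], path, paste0("uns/", nm))
    }
    for (g in c("obsp", "varm", "varp"))
        rhdf5::h5createGroup(path, g)
    .h5_write_attr(path, "/", list("encoding-type" = "anndata",
                                   "encoding-version" = "0.1.0"))
    rhdf5::h5closeAll()
    invisible(path)
}

.read_coords_table <- function(coordsPath, sep, labelKey) {
    tab <- utils::read.table(coordsPath, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("x", "y")
    if (!all(need %in% colnames(tab)))
        stop("format error: coordinate table must have columns 'x' and 'y'")
    if (!is.numeric(tab$x) || !is.numeric(tab$y))
        stop("validation error: coordinates are not numeric")
    labels <- NULL
    if (!is.null(labelKey)) {
        if (!labelKey %in% colnames(tab))
            stop(sprintf("format error: label column '%s' missing", labelKey))
        labels <- tab[[labelKey]]
    } else if ("label" %in% colnames(tab)) {
        labels <- tab$label
    }
    list(coords = cbind(x = tab$x, y = tab$y),
         ids = if ("spot_id" %in% colnames(tab)) tab$spot_id else NULL,
         labels = labels)
}

#' @rdname loadSlice
#' @param labelKey optional label column name in the coordinate table.
#' @export
readSliceMTX <- function(path, labelKey = NULL,
                         sliceId = basename(normalizePath(path,
                                                          mustWork = FALSE))) {
    dir <- if (dir.exists(path)) path else dirname(path)
    mtx <- file.path(dir, "matrix.mtx")
    if (!dir.exists(path) && grepl("\\.mtx$", path)) mtx <- path
    if (!file.exists(mtx)) stop("file not found: ", mtx)
    m <- as.matrix(Matrix::readMM(mtx))           # genes x spots
    genesPath <- file.path(dir, "genes.tsv")
    if (file.exists(genesPath))
        rownames(m) <- utils::read.table(genesPath,
                                         stringsAsFactors = FALSE)[[1L]]
    ct <- .read_coords_table(file.path(dir, "coords.tsv"), "\t", labelKey)
    if (nrow(ct$coords) != ncol(m))
        stop(sprintf("shape error: %d coordinate rows for %d matrix columns",
                     nrow(ct$coords), ncol(m)))
    if (!is.null(ct$ids)) colnames(m) <- ct$ids
    isCounts <- all(m >= 0) && all(m == round(m))
    if (isCounts)
        STSlice(coords = ct$coords, counts = m, labels = ct$labels,
                sliceId = sliceId)
    else
        STSlice(coords = ct$coords, logcounts = m, labels = ct$labels,
                sliceId = sliceId)
}

#' @rdname loadSlice
#' @export
writeSliceMTX <- function(slice, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    an <- SummarizedExperiment::assayNames(slice)
    Xname <- if ("counts" %in% an) "counts" else "logcounts"
    m <- SummarizedExperiment::assay(slice, Xname)
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(m)),
                                            "generalMatrix"), "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    genes <- rownames(slice)
    if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(slice)))
    writeLines(genes, file.path(path, "genes.tsv"))
    ids <- colnames(slice)
    if (is.null(ids)) ids <- paste0("spot", seq_len(ncol(slice)))
    tab <- data.frame(spot_id = ids, x = spatialCoords(slice)[, 1],
                      y = spatialCoords(slice)[, 2])
    lab <- spotLabels(slice)
    if (!is.null(lab)) tab$label <- as.character(lab)
    utils::write.table(tab, file.path(path, "coords.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname loadSlice
#' @export
readSliceCSV <- function(path, labelKey = NULL,
                         sliceId = basename(normalizePath(path,
                                                          mustWork = FALSE))) {
    dir <- if (dir.exists(path)) path else dirname(path)
    exprPath <- file.path(dir, "expr.csv")
    if (!file.exists(exprPath)) stop("file not found: ", exprPath)
    tab <- utils::read.csv(exprPath, row.names = 1, check.names = FALSE)
    m <- t(as.matrix(tab))                         # -> genes x spots
    ct <- .read_coords_table(file.path(dir, "coords.csv"), ",", labelKey)
    if (nrow(ct$coords) != ncol(m))
        stop(sprintf("shape error: %d coordinate rows for %d expression rows",
                     nrow(ct$coords), ncol(m)))
    isCounts <- all(m >= 0) && all(m == round(m))
    if (isCounts)
        STSlice(coords = ct$coords, counts = m, labels = ct$labels,
                sliceId = sliceId)
    else
        STSlice(coords = ct$coords, logcounts = m, labels = ct$labels,
                sliceId = sliceId)
}

#' @rdname loadSlice
#' @export
writeSliceCSV <- function(slice, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    an <- SummarizedExperiment::assayNames(slice)
    Xname <- if ("counts" %in% an) "counts" else "logcounts"
    m <- t(as.matrix(SummarizedExperiment::assay(slice, Xname)))  # spots x genes
    ids <- colnames(slice)
    if (is.null(ids)) ids <- paste0("spot", seq_len(nSpots(slice)))
    rownames(m) <- ids
    utils::write.csv(m, file.path(path, "expr.csv"), quote = FALSE)
    tab <- data.frame(spot_id = ids, x = spatialCoords(slice)[, 1],
                      y = spatialCoords(slice)[, 2])
    lab <- spotLabels(slice)
    if (!is.null(lab)) tab$label <- as.character(lab)
    utils::write.csv(tab, file.path(path, "coords.csv"), quote = FALSE,
                     row.names = FALSE)
    invisible(path)
}

#' Export a transport plan
#'
#' Dense CSV (full matrix) or sparse triplet TSV with columns i, j, mass
#' (1-based indices, entries below \code{minMass} dropped in triplet mode).
#'
#' @param plan a \linkS4class{TransportPlan}.
#' @param path output file.
#' @param format "csv" (dense) or "triplet" (TSV).
#' @param minMass triplet-mode threshold.
#' @export
writePlan <- function(plan, path, format = c("csv", "triplet"),
                      minMass = 0) {
    format <- match.arg(format)
    Tm <- transportMatrix(plan)
    if (format == "csv") {
        utils::write.csv(Tm, path, row.names = FALSE, quote = FALSE)
    } else {
        idx <- which(Tm > minMass, arr.ind = TRUE)
        tab <- data.frame(i = idx[, 1], j = idx[, 2], mass = Tm[idx])
        tab <- tab[order(tab$i, tab$j), ]
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Export a hard matching as two-column TSV (source, target; unmatched
#' spots omitted)
#' @param matching a \linkS4class{SpotMatching}.
#' @param path output file.
#' @export
writeMatching <- function(matching, path) {
    pi <- matchedPairs(matching)
    utils::write.table(pi, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
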