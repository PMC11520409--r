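#' Alignment accuracy of a hard matching
#'
#' Fraction of matched spot pairs whose annotations agree across slices.
#' Unmatched source spots are excluded from the denominator. With zero
#' matched pairs the score is undefined and NA is returned with a warning.
#'
#' @param matching a \linkS4class{SpotMatching} (source -> target).
#' @param labelsX,labelsY categorical annotations of source/target spots.
#' @return number in [0, 1], or NA.
#' @export
alignmentAccuracy <- function(matching, labelsX, labelsY) {
    pi <- matchIndices(matching)
    ok <- !is.na(pi)
    if (!any(ok)) {
        warning("no matched pairs; alignment accuracy undefined")
        return(NA_real_)
    }
    mean(as.character(labelsX)[ok] == as.character(labelsY)[pi[ok]])
}

#' Label transfer adjusted Rand index
#'
#' Builds transferred labels \eqn{\hat y_i = labels_y[\pi(i)]} over matched
#' source spots and returns the adjusted Rand index between the source
#' annotation (restricted to matched spots) and the transferred one. When
#' both restricted partitions consist of a single identical cluster the ARI
#' is returned as 1 by convention.
#'
#' @inheritParams alignmentAccuracy
#' @return number in [-1, 1], or NA when nothing is matched.
#' @export
labelTransferARI <- function(matching, labelsX, labelsY) {
    pi <- matchIndices(matching)
    ok <- !is.na(pi)
    if (!any(ok)) {
        warning("no matched pairs; LTARI undefined")
        return(NA_real_)
    }
    lx <- as.character(labelsX)[ok]
    ly <- as.character(labelsY)[pi[ok]]
    if (length(unique(lx)) == 1L && length(unique(ly)) == 1L)
        return(if (identical(unique(lx), unique(ly))) 1 else 0)
    mclust::adjustedRandIndex(lx, ly)
}

#' Batch mixing entropy of an embedding
#'
#' For every spot, the batch-composition entropy of its k nearest neighbors
#' in embedding space, averaged over spots and normalized by log(number of
#' batches) so that 1 means locally perfect mixing and 0 means pure
#' single-batch neighborhoods. (This is the standard regional kNN mixing
#' entropy of the single-cell integration benchmarking literature; k
#' defaults to 50.)
#'
#' @param emb numeric matrix (spots x dims).
#' @param batchIds per-spot batch factor (>= 2 levels).
#' @param k number of neighbors.
#' @return number in [0, 1].
#' @export
batchEntropy <- function(emb, batchIds, k = 50L) {
    emb <- as.matrix(emb)
    batchIds <- factor(batchIds)
    nb <- nlevels(batchIds)
    if (nb < 2L) stop("batch entropy requires at least two batches")
    n <- nrow(emb)
    if (k >= n) stop("k must be smaller than the number of spots")
    d2 <- outer(rowSums(emb^2), rowSums(emb^2), "+") - 2 * tcrossprod(emb)
    diag(d2) <- Inf
    codes <- as.integer(batchIds)
    ent <- vapply(seq_len(n), function(i) {
        nn <- order(d2[i, ])[seq_len(k)]
        p <- tabulate(codes[nn], nb) / k
        p <- p[p > 0]
        -sum(p * log(p))
    }, numeric(1))
    mean(ent) / log(nb)
}

#' Silhouette-based integration scores
#'
#' \code{celltypeASW}: mean silhouette width of the annotation clusters in
#' embedding space, rescaled to [0, 1] (higher = better biological
#' separation). \code{batchASW}: within each annotation group, one minus the
#' absolute mean silhouette width of the batch labels, averaged over groups
#' and clipped to [0, 1] (higher = better batch mixing; the scIB
#' convention). Groups of size 1 or with a single batch are excluded with a
#' warning.
#'
#' @param emb numeric matrix (spots x dims).
#' @param labels annotation factor (>= 2 groups for celltypeASW).
#' @param batchIds batch factor.
#' @return named list with \code{celltypeASW} and \code{batchASW}.
#' @export
silhouetteScores <- function(emb, labels, batchIds) {
    emb <- as.matrix(emb)
    labels <- factor(labels); batchIds <- factor(batchIds)
    d <- stats::dist(emb)
    if (nlevels(droplevels(labels)) < 2L)
        stop("celltype ASW requires at least two annotation groups")
    sil <- cluster::silhouette(as.integer(droplevels(labels)), d)
    celltype <- (mean(sil[, "sil_width"]) + 1) / 2
    groupScores <- c()
    for (g in levels(labels)) {
        idx <- which(labels == g)
        bg <- droplevels(batchIds[idx])
        if (length(idx) < 2L || nlevels(bg) < 2L) {
            warning("annotation group '", g,
                    "' skipped in batch ASW (too small or single batch)")
            next
        }
        if (any(table(bg) < 1L)) next
        sg <- cluster::silhouette(as.integer(bg),
                                  stats::dist(emb[idx, , drop = FALSE]))
        groupScores <- c(groupScores, 1 - abs(mean(sg[, "sil_width"])))
    }
    batch <- if (length(groupScores))
        min(max(mean(groupScores), 0), 1) else NA_real_
    list(celltypeASW = celltype, batchASW = batch)
}

#' Full evaluation report for an aligned slice pair
#'
#' Convenience wrapper computing the matching-based scores (alignment
#' accuracy, label-transfer ARI) and the embedding-based scores (batch
#' entropy, batch ASW, cell-type ASW) in one record.
#'
#' @param result an \linkS4class{IntegrationResult} for a slice pair.
#' @param labelsX,labelsY annotations of the two slices (in embedding row
#'   order).
#' @param minMass matching threshold, see [maxProbMatching()].
#' @param k neighbors for [batchEntropy()].
#' @return a one-row data.frame.
#' @export
metricsReport <- function(result, labelsX, labelsY, minMass = 0, k = 50L) {
    m <- maxProbMatching(transportPlan(result), minMass = minMass)
    emb <- embedding(result)
    batch <- sliceIds(result)
    labels <- factor(c(as.character(labelsX), as.character(labelsY)))
    sw <- silhouetteScores(emb, labels, batch)
    data.frame(
        alignmentAccuracy = alignmentAccuracy(m, labelsX, labelsY),
        ltari = labelTransferARI(m, labelsX, labelsY),
        batchEntropy = batchEntropy(emb, batch,
                                    k = min(k, nrow(emb) - 1L)),
        batchASW = sw$batchASW,
        celltypeASW = sw$celltypeASW,
        nMatched = sum(!is.na(matchIndices(m))))
}
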