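## Cellular lineage scoring: marker selection against idealized binary
## profiles, centroid correlation, and per-sample Z standardization.

#' Build a lineage marker database from a labelled compendium
#'
#' Per lineage, genes are ranked by Pearson correlation with the idealized
#' binary profile (1 on that lineage's columns, 0 elsewhere) and the top
#' `markers_per_lineage` are kept (ties broken by gene name). The centroid
#' is the mean profile over the lineage's columns restricted to the union
#' of all selected markers.
#'
#' @param compendium Numeric matrix, genes x samples.
#' @param labels Per-column lineage labels (>= 2 lineages, each with >= 1
#'   column).
#' @param markers_per_lineage Markers per lineage; values outside 50-150
#'   warn but are allowed.
#' @return A [LineageReference-class].
#' @export
buildMarkerDb <- function(compendium, labels, markers_per_lineage) {
  stopifnot(is.matrix(compendium), length(labels) == ncol(compendium))
  lineages <- sort(unique(as.character(labels)))
  if (length(lineages) < 2L) stop("need at least two lineages")
  if (markers_per_lineage > nrow(compendium))
    stop("more markers requested than genes available")
  if (markers_per_lineage < 50L || markers_per_lineage > 150L)
    warning("markers_per_lineage outside the typical 50-150 range")
  markers <- lapply(lineages, function(l) {
    ideal <- as.numeric(labels == l)
    r <- suppressWarnings(apply(compendium, 1L, cor, y = ideal))
    r[is.na(r)] <- -Inf
    ord <- order(-r, rownames(compendium))
    data.frame(lineage = l,
               gene = rownames(compendium)[ord[seq_len(markers_per_lineage)]],
               rank = seq_len(markers_per_lineage),
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, markers)
  union_genes <- sort(unique(markers$gene))
  centroids <- vapply(lineages, function(l)
    rowMeans(compendium[union_genes, labels == l, drop = FALSE]),
    numeric(length(union_genes)))
  rownames(centroids) <- union_genes
  new("LineageReference", markers = markers, centroids = centroids)
}

#' Score samples against lineage centroids by correlation Z-scores
#'
#' Per sample and lineage, the Pearson correlation between the sample and
#' the lineage centroid over the shared marker-union genes; Z-scores
#' standardize each sample's correlations across lineages (unbiased sd;
#' degenerate sd yields z = 0, so each sample's z row sums to ~0).
#'
#' @param samples Numeric matrix, genes x samples; must share at least
#'   half of the reference's marker-union genes.
#' @param ref A [LineageReference-class].
#' @return List: `r` and `z`, samples x lineages matrices.
#' @export
scoreSamples <- function(samples, ref) {
  stopifnot(is.matrix(samples), is(ref, "LineageReference"))
  cen <- centroidsOf(ref)
  shared <- intersect(rownames(cen), rownames(samples))
  if (length(shared) < 0.5 * nrow(cen))
    stop("samples share fewer than 50% of the reference marker genes")
  if (length(shared) < nrow(cen))
    ls_message(nrow(cen) - length(shared), " marker gene(s) unmatched; dropped")
  if (length(shared) < 3L)
    stop("fewer than 3 shared marker genes")
  r <- suppressWarnings(
    cor(samples[shared, , drop = FALSE], cen[shared, , drop = FALSE]))
  r[is.na(r)] <- 0
  z <- t(apply(r, 1L, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s < 1e-12) rep(0, length(v))
    else (v - mean(v)) / s
  }))
  dimnames(z) <- dimnames(r)
  list(r = r, z = z)
}

#' Hierarchically cluster lineage Z-scores
#'
#' Delegates to the city-block/average-linkage machinery of
#' [classifySamples()] on the per-sample Z matrix, returning the sample
#' ordering used for heat-map display.
#'
#' @param scores A [scoreSamples()] result (or a samples x lineages z
#'   matrix).
#' @param labels Optional known two-class sample labels for accuracy.
#' @return As [classifySamples()], plus `order` (dendrogram sample order).
#' @export
clusterLineageScores <- function(scores, labels = NULL) {
  z <- if (is.list(scores)) scores$z else scores
  stopifnot(is.matrix(z))
  if (nrow(z) == 1L) {
    return(list(hclust = NULL, clusters = setNames(1L, rownames(z)),
                accuracy = NA_real_, newick = NULL, order = 1L))
  }
  cs <- classifySamples(t(z), labels = labels)
  cs$order <- cs$hclust$order
  cs
}
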