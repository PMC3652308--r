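## Alternative-splicing detection from junction/exon probe-set matrices:
## constitutive gene summarization, reciprocal-junction regression scoring,
## exon-level splicing index, and city-block hierarchical classification.

#' Summarize gene expression from constitutive probe sets
#'
#' Per gene and sample, the arithmetic mean of the log2 intensities of the
#' gene's constitutive probe sets. Genes without constitutive probes are
#' excluded (with a message).
#'
#' @param psm A [ProbeSetMatrix-class].
#' @return Numeric matrix, genes x samples.
#' @export
summarizeGeneExpression <- function(psm) {
  stopifnot(is(psm, "ProbeSetMatrix"))
  info <- probeInfo(psm)
  x <- intensityOf(psm)
  const <- info$role == "constitutive"
  genes_all <- unique(info$gene)
  genes <- unique(info$gene[const])
  dropped <- setdiff(genes_all, genes)
  if (length(dropped))
    ls_message(length(dropped), " gene(s) without constitutive probes excluded")
  out <- matrix(NA_real_, length(genes), ncol(x),
                dimnames = list(genes, colnames(x)))
  for (g in genes) {
    rows <- which(const & info$gene == g)
    out[g, ] <- colMeans(x[rows, , drop = FALSE])
  }
  out
}

## Posterior-mean regression slope of y on x under a N(prior_mean,
## prior_sd^2) slope prior. Equals OLS as the data dominate and the prior
## mean when x carries no information (the degenerate-baseline fallback).
stabilized_slope <- function(y, x, prior_mean = 1, prior_sd = 0.5) {
  sxx <- sum((x - mean(x))^2)
  if (sxx < 1e-12) return(prior_mean)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b_ols <- sxy / sxx
  res <- y - mean(y) - b_ols * (x - mean(x))
  s2 <- sum(res^2) / max(1L, length(y) - 2L)
  if (s2 < 1e-12) return(b_ols)          # exactly linear baseline
  w_data <- sxx / s2
  w_prior <- 1 / prior_sd^2
  (b_ols * w_data + prior_mean * w_prior) / (w_data + w_prior)
}

## Welch two-sided t p-value on a per-sample score vector, with the
## degenerate zero-variance case defined deterministically: separated
## constant groups are certain (p = 0), identical constant groups carry no
## evidence (p = 1).
welch_p <- function(d, g1, g2) {
  v1 <- var(d[g1]); v2 <- var(d[g2])
  if ((is.na(v1) || v1 < 1e-24) && (is.na(v2) || v2 < 1e-24)) {
    return(if (abs(mean(d[g1]) - mean(d[g2])) > 1e-12) 0 else 1)
  }
  tryCatch(t.test(d[g2], d[g1])$p.value, error = function(e) 1)
}

#' Detect splicing events from reciprocal junction pairs
#'
#' Per reciprocal (inclusion, exclusion) pair in a gene, gene-normalized
#' values `nI = x[I,] - g[gene,]` and `nE = x[E,] - g[gene,]` are formed; a
#' linear regression of `nI` on `nE` over the baseline group (group 1)
#' defines the per-sample splicing deviation `d = nI - (a + b nE)`. The
#' slope is a posterior mean under a unit-slope prior (expression-only
#' changes move both junction measures 1:1), so a baseline `nE` with no
#' variance degenerates cleanly to `d = nI - nE`.
#' The event score is `mean(d, group2) - mean(d, group1)`. A pair is called
#' when `|score| >= log2(fc_threshold)`, the Welch t-test on `d` has
#' `p < p_threshold`, and the raw group-mean changes of the inclusion and
#' exclusion probes are opposite in sign (the reciprocity gate: genuine
#' splicing moves the two junctions in opposite directions, an expression
#' change moves them together). Direction is `inclusion` for positive
#' scores. PSR-vs-exclusion pairs run through the same scorer with the PSR
#' in the inclusion role.
#'
#' @param psm A [ProbeSetMatrix-class].
#' @param groups Two-level factor/character over samples; level 1 is the
#'   baseline.
#' @param summary Optional precomputed [summarizeGeneExpression()] matrix.
#' @param fc_threshold Fold-change threshold on the deviation scale
#'   (default 2, i.e. |score| >= 1 log2 unit).
#' @param p_threshold t-test p-value threshold (default 0.05).
#' @return data.frame, one row per reciprocal pair: `gene`,
#'   `inclusion_probe_set`, `exclusion_probe_set`, `score`, `p_value`,
#'   `direction`, `reciprocal`, `called`, `detection_method`.
#' @export
detectJunctionEvents <- function(psm, groups, summary = NULL,
                                 fc_threshold = 2, p_threshold = 0.05) {
  stopifnot(is(psm, "ProbeSetMatrix"))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  if (is.null(summary)) summary <- summarizeGeneExpression(psm)
  info <- probeInfo(psm)
  x <- intensityOf(psm)
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  pairs <- which(info$role %in% c("junction_inclusion", "exon_psr") &
                   !is.na(info$reciprocal_partner) &
                   info$reciprocal_partner %in% rownames(x))
  out <- vector("list", length(pairs))
  thr <- log2(fc_threshold)
  for (k in seq_along(pairs)) {
    i <- pairs[k]
    gene <- info$gene[i]
    if (!gene %in% rownames(summary)) next
    I <- x[i, ]; E <- x[info$reciprocal_partner[i], ]
    gexp <- summary[gene, ]
    nI <- I - gexp; nE <- E - gexp
    ## Baseline-group regression of nI on nE with a stabilized slope:
    ## under expression-only (no-splicing) changes the gene-normalized
    ## junction measures co-move 1:1, so the slope gets a N(1, 0.5^2)
    ## prior; with no baseline information (zero nE variance) the
    ## posterior collapses to the unit slope, i.e. d = nI - nE.
    b <- stabilized_slope(nI[g1], nE[g1])
    a <- mean(nI[g1]) - b * mean(nE[g1])
    d <- nI - (a + b * nE)
    score <- mean(d[g2]) - mean(d[g1])
    p <- welch_p(d, g1, g2)
    dI <- mean(I[g2]) - mean(I[g1])
    dE <- mean(E[g2]) - mean(E[g1])
    reciprocal <- dI * dE < 0
    out[[k]] <- data.frame(
      gene = gene,
      inclusion_probe_set = rownames(x)[i],
      exclusion_probe_set = info$reciprocal_partner[i],
      score = score, p_value = p,
      direction = if (score > 0) "inclusion" else "exclusion",
      reciprocal = reciprocal,
      called = abs(score) >= thr - 1e-9 & p < p_threshold & reciprocal,
      detection_method = "junction_regression",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), inclusion_probe_set = character(),
                      exclusion_probe_set = character(), score = numeric(),
                      p_value = numeric(), direction = character(),
                      reciprocal = logical(), called = logical(),
                      detection_method = character())
  rownames(res) <- NULL
  res
}

#' Detect splicing events by the exon-level splicing index
#'
#' Per exon/PSR probe set, the splicing index `SI = x[p,] - g[gene,]`
#' (probe intensity minus constitutive gene level); the event statistic is
#' `dSI = mean(SI, group2) - mean(SI, group1)`, called at
#' `|dSI| >= si_threshold` with Welch t-test `p < p_threshold`. Gene-wide
#' expression shifts cancel in SI.
#'
#' @param psm A [ProbeSetMatrix-class].
#' @param groups Two-level grouping; level 1 is the baseline.
#' @param summary Optional precomputed gene summary.
#' @param si_threshold Splicing-index change threshold in log2 units
#'   (default 1).
#' @param p_threshold t-test p threshold (default 0.05).
#' @return data.frame, one row per exon/PSR probe set: `gene`,
#'   `inclusion_probe_set` (the probe), `score` (dSI), `p_value`,
#'   `direction`, `called`, `detection_method`.
#' @export
detectSplicingIndexEvents <- function(psm, groups, summary = NULL,
                                      si_threshold = 1, p_threshold = 0.05) {
  stopifnot(is(psm, "ProbeSetMatrix"))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  if (is.null(summary)) summary <- summarizeGeneExpression(psm)
  info <- probeInfo(psm)
  x <- intensityOf(psm)
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  rows <- which(info$role == "exon_psr" & info$gene %in% rownames(summary))
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    si <- x[i, ] - summary[info$gene[i], ]
    dsi <- mean(si[g2]) - mean(si[g1])
    p <- welch_p(si, g1, g2)
    out[[k]] <- data.frame(
      gene = info$gene[i],
      inclusion_probe_set = rownames(x)[i],
      exclusion_probe_set = NA_character_,
      score = dsi, p_value = p,
      direction = if (dsi > 0) "inclusion" else "exclusion",
      called = abs(dsi) >= si_threshold - 1e-9 & p < p_threshold,
      detection_method = "splicing_index",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), inclusion_probe_set = character(),
                      exclusion_probe_set = character(), score = numeric(),
                      p_value = numeric(), direction = character(),
                      called = logical(), detection_method = character())
  rownames(res) <- NULL
  res
}

#' Classify samples by feature-restricted city-block hierarchical clustering
#'
#' Agglomerative clustering (city-block/Manhattan distance, average linkage
#' by default) of the samples restricted to the given features, cut at two
#' clusters. When known labels are supplied, accuracy is the best matched
#' fraction over the two possible cluster-to-label assignments.
#'
#' @param x Numeric matrix (features x samples), a
#'   [ProbeSetMatrix-class], or a gene summary matrix.
#' @param features Features (row names) to cluster on.
#' @param labels Optional known two-class sample labels.
#' @param linkage hclust linkage (default "average").
#' @return List: `hclust`, `clusters` (two-cluster labels), `accuracy`
#'   (or NA), `newick` (the dendrogram in Newick format).
#' @export
classifySamples <- function(x, features = NULL, labels = NULL,
                            linkage = "average") {
  if (is(x, "ProbeSetMatrix")) x <- intensityOf(x)
  stopifnot(is.matrix(x))
  if (!is.null(features)) {
    features <- intersect(features, rownames(x))
    if (!length(features)) stop("feature list disjoint from matrix")
    x <- x[features, , drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least two samples")
  d <- dist(t(x), method = "manhattan")
  hc <- hclust(d, method = linkage)
  cl <- cutree(hc, k = 2L)
  acc <- NA_real_
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(x))
    lab <- factor(labels)
    if (nlevels(lab) != 2L) stop("labels must have exactly two classes")
    tab <- table(factor(cl, levels = 1:2), lab)
    acc <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / sum(tab)
  }
  phylo <- ape::as.phylo(hc)
  list(hclust = hc, clusters = cl, accuracy = acc,
       newick = ape::write.tree(phylo))
}

#' Annotate splice events with protein-domain and miRNA-binding-site flags
#'
#' Purely relational joins of event probe sets against annotation tables.
#' Annotations referencing unknown probe sets are ignored (with a message);
#' a missing table leaves the corresponding flag FALSE with a warning.
#'
#' @param events Event data.frame from [detectJunctionEvents()] or
#'   [detectSplicingIndexEvents()].
#' @param domain_annotation Optional data.frame with column `probe_set`
#'   (and anything else) listing probes with protein-domain annotations.
#' @param mirna_site_annotation Optional data.frame with column
#'   `probe_set` listing probes overlapping predicted miRNA binding sites.
#' @return `events` with added logical columns `domain_flag`,
#'   `mirna_site_flag`.
#' @export
annotateEvents <- function(events, domain_annotation = NULL,
                           mirna_site_annotation = NULL) {
  stopifnot(is.data.frame(events))
  probes <- unique(c(events$inclusion_probe_set, events$exclusion_probe_set))
  flag_from <- function(ann, what) {
    if (is.null(ann)) {
      warning("no ", what, " annotation supplied; flags left FALSE")
      return(rep(FALSE, nrow(events)))
    }
    stopifnot("probe_set" %in% names(ann))
    unknown <- setdiff(ann$probe_set, probes)
    if (length(unknown))
      ls_message(length(unknown), " ", what,
                 " annotation row(s) reference unknown probe sets; ignored")
    events$inclusion_probe_set %in% ann$probe_set |
      (!is.na(events$exclusion_probe_set) &
         events$exclusion_probe_set %in% ann$probe_set)
  }
  events$domain_flag <- flag_from(domain_annotation, "protein-domain")
  events$mirna_site_flag <- flag_from(mirna_site_annotation, "miRNA-site")
  events
}
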