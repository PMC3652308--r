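## Over-representation analysis: hypergeometric-moment z-scores,
## permutation p-values, and the z/gene-number gated report.

#' Hypergeometric-standardized over-representation z-score
#'
#' For a universe of `N` genes, a set of `R`, a changed list of `n` and an
#' overlap of `r`, the z-score standardizes `r` by the hypergeometric mean
#' `nR/N` and variance `n (R/N)(1 - R/N)(1 - (n-1)/(N-1))`. Degenerate
#' variance yields z = 0. All arguments vectorize.
#'
#' @param N Universe size (> 0).
#' @param R Set size.
#' @param n Changed-gene count.
#' @param r Overlap count.
#' @return Numeric z-score(s).
#' @export
oraZ <- function(N, R, n, r) {
  if (any(N <= 0)) stop("universe size must be positive")
  stopifnot(all(R <= N), all(n <= N), all(r <= pmin(n, R)))
  mu <- n * R / N
  v <- n * (R / N) * (1 - R / N) * (1 - (n - 1) / (N - 1))
  z <- ifelse(v > 0, (r - mu) / sqrt(pmax(v, 0)), 0)
  as.numeric(z)
}

#' Permutation p-value for a set's over-representation z-score
#'
#' Draws `n_perm` random changed lists of the same size from the
#' background and reports the add-one tail estimate
#' `(1 + #{permuted z >= observed z}) / (n_perm + 1)`, always in (0, 1].
#'
#' @param set Character vector, the gene set.
#' @param changed Character vector of changed genes.
#' @param background Character vector, the gene universe.
#' @param n_perm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @return List: `z` (observed), `perm_p`.
#' @export
permutationP <- function(set, changed, background, n_perm = 2000L,
                         seed = 1L) {
  if (length(unique(changed)) > length(unique(background)))
    stop("more changed genes than background genes")
  set <- intersect(unique(set), background)
  changed <- intersect(unique(changed), background)
  N <- length(background); n <- length(changed); R <- length(set)
  if (n > N) stop("more changed genes than background genes")
  z_obs <- oraZ(N, R, n, length(intersect(set, changed)))
  in_set <- background %in% set
  with_seed(seed, {
    z_perm <- vapply(seq_len(n_perm), function(i) {
      r <- sum(in_set[sample.int(N, n)])
      oraZ(N, R, n, r)
    }, numeric(1L))
    list(z = z_obs, perm_p = (1 + sum(z_perm >= z_obs)) / (n_perm + 1))
  })
}

#' Over-representation analysis of a gene-set collection
#'
#' Applies [oraZ()] and [permutationP()] to every set, adds a
#' Benjamini-Hochberg column on the permutation p-values (reported
#' alongside; gating uses the z cut-off and gene number only), and marks
#' sets as reported per [rankEnrichment()]'s gates.
#'
#' @param sets Named list of character vectors (e.g. from [readGMT()]).
#' @param changed Character vector of changed genes.
#' @param background Character vector, the gene universe; sets are
#'   intersected with it.
#' @param n_perm Permutations per set (default 2000).
#' @param z_cutoff z-score gate (default 1.96).
#' @param min_genes Minimum changed genes in the set (default 3).
#' @param seed Integer seed.
#' @return data.frame: `set`, `N`, `R`, `n`, `r`, `z`, `perm_p`, `bh_q`,
#'   `reported`, sorted by (z desc, r desc, set name).
#' @export
oraTest <- function(sets, changed, background, n_perm = 2000L,
                    z_cutoff = 1.96, min_genes = 3L, seed = 1L) {
  stopifnot(is.list(sets), length(sets) > 0L)
  changed <- intersect(unique(changed), background)
  N <- length(background); n <- length(changed)
  rows <- lapply(seq_along(sets), function(k) {
    s <- intersect(unique(sets[[k]]), background)
    pp <- permutationP(s, changed, background, n_perm,
                       seed = child_seed(seed, k))
    data.frame(set = names(sets)[k], N = N, R = length(s), n = n,
               r = length(intersect(s, changed)),
               z = pp$z, perm_p = pp$perm_p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$bh_q <- stats::p.adjust(res$perm_p, method = "BH")
  res$reported <- res$z >= z_cutoff & res$r >= min_genes
  rankEnrichment(res, z_cutoff = z_cutoff, min_genes = min_genes,
                 filter = FALSE)
}

#' Rank (and optionally filter) an enrichment table
#'
#' Orders by (z descending, overlap descending, set name) and, when
#' `filter` is TRUE, keeps only sets passing both the z cut-off and the
#' minimum changed-gene count.
#'
#' @param results An [oraTest()]-shaped data.frame.
#' @param z_cutoff z gate (default 1.96).
#' @param min_genes Overlap gate (default 3).
#' @param filter Drop non-reported rows (default TRUE).
#' @return The ranked (and possibly filtered) data.frame.
#' @export
rankEnrichment <- function(results, z_cutoff = 1.96, min_genes = 3L,
                           filter = TRUE) {
  stopifnot(all(c("set", "z", "r") %in% names(results)))
  results$reported <- results$z >= z_cutoff & results$r >= min_genes
  ord <- order(-results$z, -results$r, results$set)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  if (filter) results[results$reported, , drop = FALSE] else results
}
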