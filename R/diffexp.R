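## Negative-binomial differential expression: trimmed-mean normalisation
## factors, conditional-likelihood dispersion estimation (common and
## tagwise), the conditional exact test, and empirical-Bayes posterior
## log-odds (B statistic) ranking.

## ---------------------------------------------------------------------------
## normalisation factors
## ---------------------------------------------------------------------------

#' Trimmed-mean-of-log-ratios normalisation factors
#'
#' Computes per-library scaling factors from doubly trimmed log2
#' count-proportion ratios against a reference library (the library whose
#' upper quartile of CPM is closest to the mean upper quartile), with
#' inverse-variance weights, rescaled so the factors multiply to 1. Pure
#' depth differences are absorbed by the library sizes, not the factors.
#'
#' @param cm A [CountMatrix-class] with at least two libraries.
#' @param logratio_trim,abundance_trim Two-sided trim fractions for the
#'   log-ratios (default 0.3) and mean abundances (default 0.05).
#' @return Numeric vector of factors, one per library, product 1.
#' @export
normFactors <- function(cm, logratio_trim = 0.3, abundance_trim = 0.05) {
  stopifnot(is(cm, "CountMatrix"))
  y <- countsOf(cm)
  if (ncol(y) < 2L) stop("need at least two libraries")
  N <- librarySizes(cm)
  if (any(N <= 0)) stop("a library has no counts")
  if (any(colSums(y) == 0)) stop("a library has all-zero counts")
  p <- sweep(y, 2L, N, "/")
  uq <- apply(p, 2L, function(z) quantile(z[z > 0], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(i) {
    if (i == ref) return(1)
    ok <- y[, i] > 0 & y[, ref] > 0
    if (!any(ok)) return(1)
    M <- log2(p[ok, i] / p[ok, ref])
    A <- 0.5 * (log2(p[ok, i]) + log2(p[ok, ref]))
    ## unweighted doubly trimmed mean: exactly invariant to pure depth
    keep <- M >= quantile(M, logratio_trim) &
            M <= quantile(M, 1 - logratio_trim) &
            A >= quantile(A, abundance_trim) &
            A <= quantile(A, 1 - abundance_trim)
    if (!any(keep)) return(1)
    2^mean(M[keep])
  }, numeric(1L))
  f / exp(mean(log(f)))
}

## ---------------------------------------------------------------------------
## conditioning machinery
## ---------------------------------------------------------------------------

## Scale counts to a common (geometric-mean) effective library size so the
## conditional-on-total arguments apply; returns the pseudo-count matrix and
## the common size.
equalize_counts <- function(cm) {
  Ne <- librarySizes(cm) * normFactorsOf(cm)
  Ntilde <- exp(mean(log(Ne)))
  list(pseudo = sweep(countsOf(cm), 2L, Ntilde / Ne, "*"), size = Ntilde)
}

## Conditional (on the group total) NB log-likelihood contribution of each
## feature for one group of equalized counts, as a function of phi.
## y: features x samples (one group); returns a vector over features.
cond_loglik_group <- function(y, phi) {
  n <- ncol(y)
  if (n < 2L) return(rep(0, nrow(y)))
  phi <- pmax(phi, 1e-10)
  r <- 1 / phi
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

## Summed conditional log-likelihood over features and groups.
## Accepts a scalar phi or one phi per feature.
cond_loglik <- function(pseudo, groups, phi) {
  ll <- rep(0, nrow(pseudo))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) >= 2L)
      ll <- ll + cond_loglik_group(pseudo[, idx, drop = FALSE], phi)
  }
  ll
}

## Scalar golden-section maximizer on [lo, hi].
golden_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  (lo + hi) / 2
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the conditional (on per-group totals, after equalizing
#' effective library sizes) negative-binomial log-likelihood summed over
#' features, over dispersion `phi` in `[0, 10]`, by golden-section search
#' (tolerance 1e-6). Groups with fewer than two samples carry no
#' conditional information.
#'
#' @param cm A [CountMatrix-class].
#' @param groups Factor or character of group labels, one per library.
#' @return The common dispersion estimate (scalar, >= 0).
#' @export
estimateCommonDispersion <- function(cm, groups) {
  stopifnot(is(cm, "CountMatrix"))
  groups <- droplevels(as.factor(groups))
  if (!any(table(groups) >= 2L))
    stop("need at least one group with two or more samples")
  pseudo <- equalize_counts(cm)$pseudo
  golden_max(function(phi) sum(cond_loglik(pseudo, groups, phi)), 0, 10)
}

#' Estimate tagwise NB dispersions with shrinkage toward the common value
#'
#' Per feature, maximizes the weighted conditional log-likelihood
#' `ll_g(phi) + prior_df * llbar(phi)` where `llbar` is the average
#' conditional log-likelihood over all features (evaluated through a dense
#' spline). Large `prior_df` shrinks every estimate to the common
#' dispersion's maximizer; each estimate lies between the feature's own
#' conditional MLE and the common value.
#'
#' @param cm A [CountMatrix-class].
#' @param groups Group labels, one per library.
#' @param common_phi Common dispersion (used only as a fallback centre for
#'   degenerate features).
#' @param prior_df Shrinkage weight (default 10).
#' @return Numeric vector of per-feature dispersions.
#' @export
estimateTagwiseDispersion <- function(cm, groups, common_phi,
                                      prior_df = 10) {
  stopifnot(is(cm, "CountMatrix"), prior_df > 0)
  groups <- droplevels(as.factor(groups))
  if (!any(table(groups) >= 2L))
    stop("need at least one group with two or more samples")
  pseudo <- equalize_counts(cm)$pseudo
  G <- nrow(pseudo)
  ## dense grid for the average log-likelihood, splined; while the search
  ## brackets stay in lockstep across features the exact average is used
  ## instead, so the infinite-prior limit reproduces the common estimate
  grid <- c(seq(0, 0.1, length.out = 21L), seq(0.15, 1, by = 0.05),
            seq(1.25, 10, by = 0.25))
  llbar_grid <- vapply(grid, function(phi)
    mean(cond_loglik(pseudo, groups, phi)), numeric(1L))
  llbar_spline <- stats::splinefun(grid, llbar_grid, method = "natural")
  lockstep <- TRUE
  llbar <- function(phi) {
    if (lockstep && length(unique(phi)) == 1L)
      mean(cond_loglik(pseudo, groups, phi[1L]))
    else llbar_spline(phi)
  }

  ## vectorized golden-section across features
  gr <- (sqrt(5) - 1) / 2
  lo <- rep(0, G); hi <- rep(10, G)
  obj <- function(phi) cond_loglik(pseudo, groups, phi) +
    prior_df * llbar(phi)
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- obj(x1); f2 <- obj(x2)
  while (max(hi - lo) > 1e-6) {
    move_up <- f1 < f2
    if (lockstep && length(unique(move_up)) > 1L) lockstep <- FALSE
    lo[move_up] <- x1[move_up]; x1[move_up] <- x2[move_up]
    f1[move_up] <- f2[move_up]
    x2[move_up] <- lo[move_up] + gr * (hi[move_up] - lo[move_up])
    hi[!move_up] <- x2[!move_up]; x2[!move_up] <- x1[!move_up]
    f2[!move_up] <- f1[!move_up]
    x1[!move_up] <- hi[!move_up] - gr * (hi[!move_up] - lo[!move_up])
    fx <- obj(ifelse(move_up, x2, x1))
    f2[move_up] <- fx[move_up]; f1[!move_up] <- fx[!move_up]
  }
  phi <- (lo + hi) / 2
  ## features with no conditional information (all-zero) fall back to common
  z <- rowSums(pseudo) == 0
  phi[z] <- common_phi
  phi
}

#' Bundle a dispersion model
#'
#' @param common_phi Common dispersion.
#' @param tagwise_phi Optional per-feature dispersions (default: common for
#'   every feature).
#' @param prior_df Shrinkage weight recorded with the model.
#' @return A list of class `DispersionModel`.
#' @export
dispersionModel <- function(common_phi, tagwise_phi = NULL, prior_df = 10) {
  stopifnot(common_phi >= 0, prior_df > 0)
  structure(list(common_phi = common_phi, tagwise_phi = tagwise_phi,
                 prior_df = prior_df),
            class = "DispersionModel")
}

## ---------------------------------------------------------------------------
## exact test
## ---------------------------------------------------------------------------

## Conditional two-sided exact p for one feature: group sums (s1, s2) of n1
## and n2 equal-size libraries, dispersion phi. Doubles the smaller tail,
## capped at 1. phi = 0 is the Poisson/binomial limit.
exact_test_one <- function(s1, s2, n1, n2, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  k <- 0:t
  if (phi < 1e-10) {
    logp <- dbinom(k, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r <- 1 / phi
    logp <- lgamma(k + n1 * r) - lgamma(k + 1) +
      lgamma(t - k + n2 * r) - lgamma(t - k + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p <- exp(logp - max(logp)); p <- p / sum(p)
  pl <- sum(p[k <= s1]); pu <- sum(p[k >= s1])
  min(1, 2 * min(pl, pu))
}

#' Negative-binomial conditional exact test between two groups
#'
#' Per feature, conditions on the total count across both groups at
#' equalized effective library sizes and computes the two-sided exact
#' p-value (doubled smaller tail of the conditional distribution of the
#' group-1 sum, capped at 1). Log2 fold changes (group 2 over group 1) use
#' a 0.5 small-count offset for display; testing never uses the offset.
#'
#' @param cm A [CountMatrix-class].
#' @param groups Group labels (exactly two distinct values), one per
#'   library.
#' @param dispersion A [dispersionModel()] (or a numeric dispersion used
#'   for every feature).
#' @return data.frame: `feature`, `log2_fc`, `log_cpm`, `p_value`.
#' @export
nbExactTest <- function(cm, groups, dispersion) {
  stopifnot(is(cm, "CountMatrix"))
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L)
    stop("exact test needs exactly two groups; run pairwise contrasts")
  if (is.numeric(dispersion))
    dispersion <- dispersionModel(dispersion[1L],
                                  rep(dispersion, length.out = nrow(cm)))
  phi <- dispersion$tagwise_phi
  if (is.null(phi)) phi <- rep(dispersion$common_phi, nrow(cm))
  eq <- equalize_counts(cm)
  pseudo <- eq$pseudo
  i1 <- which(groups == levels(groups)[1L])
  i2 <- which(groups == levels(groups)[2L])
  s1 <- round(rowSums(pseudo[, i1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, i2, drop = FALSE]))
  p <- vapply(seq_len(nrow(pseudo)), function(g)
    exact_test_one(s1[g], s2[g], length(i1), length(i2), phi[g]),
    numeric(1L))
  m1 <- s1 / length(i1); m2 <- s2 / length(i2)
  data.frame(
    feature = rownames(cm),
    log2_fc = log2((m2 + 0.5) / (m1 + 0.5)),
    log_cpm = log2(((s1 + s2) / (length(i1) + length(i2)) + 0.5) /
                     eq$size * 1e6),
    p_value = p,
    stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## empirical-Bayes posterior log-odds (B statistic)
## ---------------------------------------------------------------------------

## Newton solver for trigamma(x) = y, y > 0.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    x <- 0.5 + 1 / yy
    for (it in 1:50) {
      d <- trigamma(x) - yy
      if (abs(d) < 1e-12) break
      step <- d / psigamma(x, deriv = 2L)
      x <- x - step
      if (x <= 0) x <- 1e-8
    }
    x
  }, numeric(1L))
}

## Moment fit of the scaled-F hierarchical model for sample variances:
## returns prior df d0 and prior variance s0_sq (d0 may be Inf).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 1e-12
  if (sum(ok) < 2L)
    return(list(d0 = Inf, s0_sq = mean(pmax(s2, 1e-12))))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes log posterior odds of differential expression
#'
#' Computes per-feature log2-CPM values at equalized effective library
#' sizes, moderates the two-group residual variances through a scaled-F
#' prior fitted by the method of moments, and reports the log posterior
#' odds that each feature is differentially expressed under a two-component
#' mixture with prior DE proportion `1 - pi0`; the fold-change prior
#' variance ratio is itself estimated by the method of moments from the
#' moderated t statistics. Features are called at `b >= b_threshold`.
#'
#' @param cm A [CountMatrix-class].
#' @param groups Group labels (two groups, each with >= 2 samples).
#' @param pi0 Prior probability of no differential expression (default
#'   0.9).
#' @param b_threshold Posterior log-odds call threshold (default 1).
#' @param prior_count Offset added to counts for the log-CPM scale
#'   (default 0.5).
#' @return data.frame: `feature`, `b_statistic`, `t_moderated`, `called`.
#' @export
bStatistic <- function(cm, groups, pi0 = 0.9, b_threshold = 1,
                       prior_count = 0.5) {
  stopifnot(is(cm, "CountMatrix"), pi0 > 0, pi0 < 1)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stop("need exactly two groups")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) stop("need at least two samples per group")
  eq <- equalize_counts(cm)
  x <- log2((eq$pseudo + prior_count) / (eq$size + 2 * prior_count) * 1e6)
  i1 <- groups == levels(groups)[1L]
  i2 <- groups == levels(groups)[2L]
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, i2, drop = FALSE])
  beta <- m2 - m1
  df <- n1 + n2 - 2L
  rss <- rowSums((x[, i1, drop = FALSE] - m1)^2) +
         rowSums((x[, i2, drop = FALSE] - m2)^2)
  s2 <- rss / df
  vp <- fit_variance_prior(s2, df)
  d0 <- vp$d0
  s2_post <- if (is.finite(d0)) (d0 * vp$s0_sq + df * s2) / (d0 + df)
             else vp$s0_sq
  vu <- 1 / n1 + 1 / n2
  tmod <- beta / sqrt(pmax(s2_post, 1e-12) * vu)
  d_tot <- df + d0

  ## method-of-moments estimate of the DE variance ratio r = (vu+v0)/vu
  p1 <- 1 - pi0
  d_mom <- if (is.finite(d_tot)) max(d_tot, 4.5) else Inf
  expect_t2 <- if (is.finite(d_mom)) d_mom / (d_mom - 2) else 1
  r <- (mean(tmod^2) / expect_t2 - pi0) / p1
  r <- min(max(r, 1), 1e9)

  t2 <- tmod^2
  kernel <- if (is.finite(d_tot))
    ((d_tot + 1) / 2) * log((t2 + d_tot) / (t2 / r + d_tot))
  else
    (t2 - t2 / r) / 2
  b <- log(p1 / pi0) - log(r) / 2 + kernel
  data.frame(feature = rownames(cm), b_statistic = b, t_moderated = tmod,
             called = b >= b_threshold, stringsAsFactors = FALSE)
}

#' Run the full two-group differential-expression path for one contrast
#'
#' Normalisation factors, common and tagwise dispersion, the conditional
#' exact test, and B-statistic calling, assembled into one result table.
#'
#' @param cm A [CountMatrix-class] whose `condition` column covers the
#'   contrast's two groups.
#' @param contrast Contrast label (`"<g1>_vs_<g2>"`).
#' @param prior_df Tagwise shrinkage weight (default 10).
#' @param b_threshold B call threshold (default 1).
#' @param pi0 Prior non-DE proportion (default 0.9).
#' @return data.frame: `feature`, `log2_fc`, `log_cpm`, `p_value`,
#'   `b_statistic`, `called`, plus a `contrast` column.
#' @export
runDifferentialExpression <- function(cm, contrast, prior_df = 10,
                                      b_threshold = 1, pi0 = 0.9) {
  grp <- contrastGroups(contrast)
  keep <- conditionsOf(cm) %in% grp
  sub <- cm[, keep]
  groups <- factor(conditionsOf(sub), levels = grp)
  colData(sub)$norm_factor <- normFactors(sub)
  common <- estimateCommonDispersion(sub, groups)
  tagwise <- estimateTagwiseDispersion(sub, groups, common, prior_df)
  disp <- dispersionModel(common, tagwise, prior_df)
  et <- nbExactTest(sub, groups, disp)
  bs <- bStatistic(sub, groups, pi0 = pi0, b_threshold = b_threshold)
  res <- cbind(et, bs[, c("b_statistic", "called")])
  res$contrast <- contrast
  res
}
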