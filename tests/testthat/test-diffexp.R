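test_that("normalisation factors are symmetric, depth-free, and unit product", {
  set.seed(1)
  y <- matrix(rpois(400 * 4, 50), 400, 4)
  cm_same <- make_cm(cbind(y[, 1], y[, 1], y[, 1]))
  expect_equal(normFactors(cm_same), rep(1, 3))

  cm <- make_cm(y)
  f <- normFactors(cm)
  expect_equal(prod(f), 1, tolerance = 1e-12)

  ## doubling every count of library 1 is pure depth: absorbed by N, not f
  y2 <- y; y2[, 1] <- 2 * y[, 1]
  f2 <- normFactors(make_cm(y2))
  expect_equal(f, f2, tolerance = 1e-12)

  expect_error(normFactors(make_cm(cbind(y[, 1], 0 * y[, 2]))), "no counts|all-zero")
})

test_that("normalisation factors agree with an independent TMM oracle", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  y <- matrix(rnbinom(1000 * 4, mu = 100, size = 5), 1000, 4)
  y[1:50, 3] <- y[1:50, 3] * 4      # composition bias in library 3
  f <- normFactors(make_cm(y))
  f_oracle <- edgeR::calcNormFactors(y, method = "TMM")
  f_oracle <- f_oracle / exp(mean(log(f_oracle)))
  expect_equal(f, unname(f_oracle), tolerance = 0.03)
})

test_that("common dispersion recovers the generating value", {
  ## Poisson data: estimate collapses toward zero
  cm0 <- make_cm(make_nb_counts(2000, mu = 200, phi = 1e-9, seed = 3))
  est0 <- estimateCommonDispersion(cm0, two_groups())
  expect_lte(est0, 0.01)

  ## phi = 0.2: each replicate estimate inside [0.15, 0.25]
  ests <- vapply(1:10, function(k) {
    cm <- make_cm(make_nb_counts(1000, mu = 200, phi = 0.2, seed = 30 + k))
    estimateCommonDispersion(cm, two_groups())
  }, numeric(1))
  expect_true(all(ests > 0.15 & ests < 0.25))

  ## single-feature matrix still returns a finite estimate
  cm1 <- make_cm(matrix(c(10, 12, 9, 30, 28, 33), 1, 6))
  expect_true(is.finite(estimateCommonDispersion(cm1, two_groups())))

  expect_error(
    estimateCommonDispersion(cm1, factor(paste0("g", 1:6))),
    "two or more samples")
})

test_that("common dispersion tracks an independent qCML oracle", {
  skip_if_not_installed("edgeR")
  y <- make_nb_counts(1500, mu = 150, phi = 0.15, seed = 4)
  est <- estimateCommonDispersion(make_cm(y), two_groups())
  d <- edgeR::DGEList(counts = y, group = two_groups())
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(est, d$common.dispersion, tolerance = 0.03)
})

test_that("tagwise dispersion shrinks monotonically toward the common value", {
  y <- make_nb_counts(300, mu = 200, phi = 0.1, seed = 5)
  ## one feature simulated at much higher dispersion
  set.seed(6)
  y[1, ] <- rnbinom(6, mu = 200, size = 1)
  cm <- make_cm(y)
  g <- two_groups()
  common <- estimateCommonDispersion(cm, g)

  tw_inf <- estimateTagwiseDispersion(cm, g, common, prior_df = 1e9)
  ## infinite prior: every feature collapses onto one shared maximizer,
  ## which is the common-dispersion estimate
  expect_lt(diff(range(tw_inf)), 1e-6)
  expect_lt(abs(tw_inf[1] - common), 1e-4)

  tw_small <- estimateTagwiseDispersion(cm, g, common, prior_df = 0.01)
  tw_mid <- estimateTagwiseDispersion(cm, g, common, prior_df = 10)
  expect_gt(tw_small[1], common)          # the outlier feature stands out
  expect_gt(tw_mid[1], common)
  ## stronger prior pulls estimates closer to the common maximizer
  expect_true(mean(abs(tw_mid - tw_inf[1])) <
                mean(abs(tw_small - tw_inf[1])))
})

test_that("the exact test matches its closed-form and symmetry contracts", {
  ## (0 | 0): no evidence, p = 1
  cm0 <- make_cm(matrix(0, 1, 2), library_sizes = c(100, 100))
  expect_equal(nbExactTest(cm0, c("a", "b"), dispersionModel(0))$p_value, 1)

  ## (10 | 0), 1 vs 1 equal effective sizes, Poisson limit:
  ## p = 2 * 0.5^10 = 0.001953125
  cm1 <- make_cm(matrix(c(10, 0), 1, 2), library_sizes = c(100, 100))
  expect_equal(nbExactTest(cm1, c("a", "b"), dispersionModel(0))$p_value,
               0.001953125, tolerance = 1e-12)

  ## swapping groups negates log2_fc, leaves p unchanged
  y <- make_nb_counts(100, mu = 80, phi = 0.1, planted = 1:10,
                      lfc = rep(1.5, 10), seed = 7)
  cm <- make_cm(y)
  g <- two_groups()
  disp <- dispersionModel(0.1, rep(0.1, nrow(y)))
  r1 <- nbExactTest(cm, g, disp)
  r2 <- nbExactTest(cm, factor(g, levels = rev(levels(g))), disp)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$log2_fc, -r2$log2_fc, tolerance = 1e-9)

  expect_error(nbExactTest(cm, factor(rep(1:3, each = 2)), disp),
               "pairwise")
})

test_that("exact-test p-values track an independent NB oracle", {
  skip_if_not_installed("edgeR")
  y <- make_nb_counts(400, mu = 150, phi = 0.1, planted = 1:20,
                      lfc = rep(c(2, -2), 10), seed = 8)
  g <- two_groups()
  p_mine <- nbExactTest(make_cm(y), g, dispersionModel(0.1,
                                                       rep(0.1, 400)))$p_value
  d <- edgeR::DGEList(counts = y, group = g)
  d$common.dispersion <- 0.1
  p_edger <- edgeR::exactTest(d, dispersion = 0.1)$table$PValue
  expect_gt(cor(log10(p_mine), log10(p_edger)), 0.99)
  ## calls agree at p < 0.05 for the overwhelming majority of features
  expect_gt(mean((p_mine < 0.05) == (p_edger < 0.05)), 0.97)
})

test_that("posterior log-odds separate planted features from the null", {
  ## identical-expectation features: no calls, max b below threshold
  cm_null <- make_cm(make_nb_counts(1000, mu = 200, phi = 0.1, seed = 9))
  b_null <- bStatistic(cm_null, two_groups())
  expect_lt(max(b_null$b_statistic), 1)
  expect_equal(sum(b_null$called), 0L)

  ## one strongly planted feature is called in >= 90% of replicates
  hits <- vapply(1:100, function(k) {
    y <- make_nb_counts(300, mu = 500, phi = 0.1, planted = 1L, lfc = 4,
                        seed = 900 + k)
    bStatistic(make_cm(y), two_groups())$b_statistic[1] >= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ## calls at B >= 1 are a subset of calls at B >= 0
  y <- make_nb_counts(500, mu = 200, phi = 0.1, planted = 1:25,
                      lfc = rep(c(2, -2), length.out = 25), seed = 10)
  b <- bStatistic(make_cm(y), two_groups())
  expect_true(all(which(b$b_statistic >= 1) %in% which(b$b_statistic >= 0)))

  expect_error(bStatistic(make_cm(y[, c(1, 4)]), factor(c("a", "b"))),
               "two samples")
})

test_that("b and p order features identically at equal abundance", {
  ## features constructed at a common total with increasingly skewed
  ## splits: b must decrease with p (same abundance, same variance scale)
  splits <- cbind(seq(60, 95, by = 5), 120 - seq(60, 95, by = 5))
  y <- t(apply(splits, 1, function(s)
    c(rep(s[1] / 3, 3), rep(s[2] / 3, 3))))
  cm <- make_cm(round(y))
  g <- two_groups()
  p <- nbExactTest(cm, g, dispersionModel(0.05, rep(0.05, nrow(y))))$p_value
  b <- bStatistic(cm, g)$b_statistic
  expect_equal(order(b), order(-p))
})

test_that("variance moderation matches the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(11)
  s2 <- rchisq(500, df = 4) / 4 * 0.3
  fit <- leukosplice:::fit_variance_prior(s2, df = 4)
  sq <- limma::squeezeVar(s2, df = 4)
  expect_equal(fit$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(fit$s0_sq, sq$var.prior, tolerance = 0.02)
})
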