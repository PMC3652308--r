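## shared fixture: a 12-sample two-condition probe matrix with planted events
splice_design <- studyDesign(libraries_per_condition = 6L, seed = 21)
splice_groups <- function(psm, contrast = "HC_vs_PD") {
  cond <- as.character(SummarizedExperiment::colData(psm)$condition)
  grp <- contrastGroups(contrast)
  list(sub = psm[, cond %in% grp],
       groups = factor(cond[cond %in% grp], levels = grp))
}

test_that("gene summarization averages constitutive probes only", {
  x <- rbind(g1_c1 = rep(4, 4), g1_c2 = rep(6, 4), g1_incl = rep(9, 4),
             g1_excl = rep(2, 4), g1_psr = rep(5, 4))
  colnames(x) <- paste0("s", 1:4)
  info <- data.frame(gene = "g1",
                     role = c("constitutive", "constitutive",
                              "junction_inclusion", "junction_exclusion",
                              "exon_psr"),
                     reciprocal_partner = c(NA, NA, "g1_excl", "g1_incl", NA),
                     row.names = rownames(x))
  psm <- ProbeSetMatrix(x, info)
  s <- summarizeGeneExpression(psm)
  expect_equal(unname(s["g1", ]), rep(5, 4))   # mean of 4 and 6

  ## one constitutive probe: summary equals that probe's row
  psm1 <- ProbeSetMatrix(x[-2, , drop = FALSE], info[-2, ])
  expect_equal(unname(summarizeGeneExpression(psm1)["g1", ]), rep(4, 4))
})

test_that("reciprocal-junction scoring matches the noiseless closed form", {
  ps <- simulateProbeMatrix(40, splice_design, n_events = 4, effect = 1.5,
                            noise_sd = 0, seed = 22)
  sg <- splice_groups(ps$matrix)
  ev <- detectJunctionEvents(sg$sub, sg$groups)
  tr <- ps$truth
  for (k in seq_len(nrow(tr))) {
    row <- ev[ev$inclusion_probe_set == tr$inclusion_probe_set[k], ]
    s <- if (tr$direction[k] == "inclusion") 1 else -1
    ## d = nI - nE propagates +-effect on both probes into a 2x score
    expect_equal(row$score, s * 3.0, tolerance = 1e-9)
    expect_true(row$called)
    expect_equal(row$direction, tr$direction[k])
  }
  ## all non-planted pairs stay uncalled in the noiseless matrix
  expect_equal(sum(ev$called), nrow(tr))
})

test_that("co-directional changes are rejected by the reciprocity gate", {
  ps <- simulateProbeMatrix(30, splice_design, n_decoys = 6, effect = 2,
                            noise_sd = 0, seed = 23)
  sg <- splice_groups(ps$matrix)
  ev <- detectJunctionEvents(sg$sub, sg$groups)
  decoy_probes <- ps$truth$inclusion_probe_set
  hit <- ev[ev$inclusion_probe_set %in% decoy_probes, ]
  expect_true(all(!hit$called))
  expect_true(all(!hit$reciprocal))
})

test_that("junction caller recovers planted events under noise", {
  ps <- simulateProbeMatrix(200, splice_design, n_events = 25, n_decoys = 10,
                            effect = c(1, 2), noise_sd = 0.2, seed = 24)
  sg <- splice_groups(ps$matrix)
  ev <- detectJunctionEvents(sg$sub, sg$groups)
  tr_j <- ps$truth[ps$truth$type == "junction", ]
  called <- ev$inclusion_probe_set[ev$called]
  expect_gte(mean(tr_j$inclusion_probe_set %in% called), 0.9)
  null_ev <- ev[!ev$gene %in% ps$truth$gene, ]
  expect_lte(mean(null_ev$called), 0.05)
})

test_that("scores ignore per-sample intensity shifts", {
  ps <- simulateProbeMatrix(30, splice_design, n_events = 3, effect = 1.5,
                            noise_sd = 0.2, seed = 25)
  psm <- ps$matrix
  x2 <- intensityOf(psm)
  x2[, 2] <- x2[, 2] + 5      # array-level shift on one sample
  psm2 <- ProbeSetMatrix(x2, probeInfo(psm),
                         as.character(SummarizedExperiment::colData(psm)$condition))
  sg1 <- splice_groups(psm); sg2 <- splice_groups(psm2)
  e1 <- detectJunctionEvents(sg1$sub, sg1$groups)
  e2 <- detectJunctionEvents(sg2$sub, sg2$groups)
  expect_equal(e1$score, e2$score, tolerance = 1e-9)
})

test_that("group swap flips scores (exactly so in the degenerate path)", {
  ps0 <- simulateProbeMatrix(20, splice_design, n_events = 3, effect = 1.5,
                             noise_sd = 0, seed = 26)
  sg <- splice_groups(ps0$matrix)
  fwd <- detectJunctionEvents(sg$sub, sg$groups)
  rev <- detectJunctionEvents(sg$sub, factor(sg$groups,
                                             levels = rev(levels(sg$groups))))
  expect_equal(fwd$score, -rev$score, tolerance = 1e-9)
  expect_equal(fwd$called, rev$called)

  ## with noise the baseline-group regression makes the swap approximate:
  ## scores must be strongly anti-correlated and planted calls must flip
  ps <- simulateProbeMatrix(100, splice_design, n_events = 15, effect = 1.5,
                            noise_sd = 0.2, seed = 27)
  sgn <- splice_groups(ps$matrix)
  f <- detectJunctionEvents(sgn$sub, sgn$groups)
  r <- detectJunctionEvents(sgn$sub, factor(sgn$groups,
                                            levels = rev(levels(sgn$groups))))
  expect_lt(cor(f$score, r$score), -0.85)
})

test_that("splicing index is exact in the noiseless limit and cancels
           gene-wide shifts", {
  ps <- simulateProbeMatrix(30, splice_design, n_exon_events = 5, effect = 1,
                            noise_sd = 0, seed = 28)
  sg <- splice_groups(ps$matrix)
  ev <- detectSplicingIndexEvents(sg$sub, sg$groups)
  planted <- ev[match(ps$truth$inclusion_probe_set, ev$inclusion_probe_set), ]
  expect_equal(planted$score, rep(1, 5), tolerance = 1e-12)
  expect_true(all(planted$called))

  ## a pure expression shift (all probes of a gene up 2) leaves SI flat
  psm <- ps$matrix
  x <- intensityOf(psm)
  info <- probeInfo(psm)
  gshift <- setdiff(unique(info$gene), ps$truth$gene)[1]
  cond <- as.character(SummarizedExperiment::colData(psm)$condition)
  x[info$gene == gshift, cond == "PD"] <-
    x[info$gene == gshift, cond == "PD"] + 2
  psm2 <- ProbeSetMatrix(x, info, cond)
  sg2 <- splice_groups(psm2)
  ev2 <- detectSplicingIndexEvents(sg2$sub, sg2$groups)
  expect_equal(ev2$score[ev2$gene == gshift], 0, tolerance = 1e-9)
  expect_false(any(ev2$called[ev2$gene == gshift]))

  ## an infinite threshold calls nothing
  ev3 <- detectSplicingIndexEvents(sg$sub, sg$groups, si_threshold = Inf)
  expect_equal(sum(ev3$called), 0L)
})

test_that("city-block classification separates groups and respects order
           invariance", {
  lab <- simulateLabeledMatrix(n_features = 100, n1 = 12, n2 = 12,
                               effect_d = 10, seed = 29)
  cls <- classifySamples(lab$matrix, labels = lab$labels)
  expect_equal(cls$accuracy, 1)
  expect_match(cls$newick, "^\\(")

  ## permuting samples and features leaves cluster memberships intact
  set.seed(30)
  ps <- sample(ncol(lab$matrix)); fs <- sample(nrow(lab$matrix))
  cls2 <- classifySamples(lab$matrix[fs, ps], labels = lab$labels[ps])
  expect_equal(cls2$accuracy, 1)
  partition <- function(cl) sort(vapply(split(names(cl), cl), function(v)
    paste(sort(v), collapse = ","), ""))
  expect_equal(unname(partition(cls$clusters)),
               unname(partition(cls2$clusters)))

  expect_error(classifySamples(lab$matrix, features = "nope"), "disjoint")
})

test_that("label-free structure yields chance-level accuracy", {
  ## features shuffled independently across samples destroy the signal;
  ## best-matching two-cluster accuracy hovers just above 1/2
  lab <- simulateLabeledMatrix(n_features = 60, n1 = 12, n2 = 12,
                               effect_d = 2, seed = 31)
  accs <- vapply(1:50, function(k) {
    set.seed(300 + k)
    shuf <- t(apply(lab$matrix, 1, sample))
    colnames(shuf) <- colnames(lab$matrix)
    classifySamples(shuf, labels = lab$labels)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("event annotation joins are purely relational", {
  ev <- data.frame(gene = c("g1", "g2"),
                   inclusion_probe_set = c("p1", "p2"),
                   exclusion_probe_set = c("q1", NA),
                   called = TRUE)
  ann <- data.frame(probe_set = c("q1", "zz"), domain = "kinase")
  expect_message(
    out <- annotateEvents(ev, domain_annotation = ann,
                          mirna_site_annotation = data.frame(
                            probe_set = character())),
    "unknown probe sets")
  expect_equal(out$domain_flag, c(TRUE, FALSE))
  expect_equal(out$mirna_site_flag, c(FALSE, FALSE))
  expect_warning(expect_warning(annotateEvents(ev), "protein-domain"),
                 "miRNA-site")
})
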