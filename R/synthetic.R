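## Synthetic-data generators. Every downstream stage is exercised on data
## from these functions; each emits its planted ground truth alongside the
## data and is a pure function of (parameters, seed).

#' Generate a synthetic precursor/mature miRNA reference
#'
#' Emulates the structure of a mature-miRNA reference: `n_mirnas` dominant
#' mature strands, `n_star` passenger (star) strands hosted on the first
#' `n_star` precursors, and `shared_groups` additional precursors that share
#' the mature sequence of an existing record (several hairpins yielding one
#' mature product).
#'
#' @param n_mirnas Number of dominant mature miRNAs (>= 10).
#' @param n_star Number of passenger-strand records (<= n_mirnas).
#' @param seed Integer seed; the reference is byte-identical for a fixed
#'   seed.
#' @param shared_groups Number of extra precursors duplicating an existing
#'   mature sequence (default 1).
#' @return A [MiRNAReference-class] with
#'   `n_mirnas + n_star + shared_groups` records and `n_mirnas + n_star`
#'   distinct mature sequences.
#' @export
generateMiRNAReference <- function(n_mirnas, n_star = 0L, seed = 1L,
                                   shared_groups = 1L) {
  if (n_mirnas < 10L)
    stop("n_mirnas must be at least 10")
  if (n_star > n_mirnas)
    stop("n_star cannot exceed n_mirnas")
  with_seed(seed, {
    lens <- sample(18:25, n_mirnas + n_star, replace = TRUE)
    seqs <- random_seq(n_mirnas + n_star, lens, RNA_BASES)
    while (anyDuplicated(seqs)) {       # astronomically rare, but keep exact
      dup <- which(duplicated(seqs))
      seqs[dup] <- random_seq(length(dup), lens[dup], RNA_BASES)
    }
    idx <- seq_len(n_mirnas)
    rec <- data.frame(
      precursor_id = sprintf("syn-mir-%03d", idx),
      mature_id = sprintf("syn-miR-%03d", idx),
      sequence = seqs[idx],
      star_flag = FALSE,
      stringsAsFactors = FALSE
    )
    if (n_star > 0L) {
      sidx <- seq_len(n_star)
      rec <- rbind(rec, data.frame(
        precursor_id = sprintf("syn-mir-%03d", sidx),
        mature_id = sprintf("syn-miR-%03d-star", sidx),
        sequence = seqs[n_mirnas + sidx],
        star_flag = TRUE,
        stringsAsFactors = FALSE
      ))
    }
    if (shared_groups > 0L) {
      g <- seq_len(min(shared_groups, n_mirnas))
      rec <- rbind(rec, data.frame(
        precursor_id = sprintf("syn-mir-%03db", g),
        mature_id = sprintf("syn-miR-%03d", g),
        sequence = seqs[g],
        star_flag = FALSE,
        stringsAsFactors = FALSE
      ))
    }
    MiRNAReference(rec)
  })
}

## The constant 15-base terminal tag appended to every synthetic read;
## removed wholesale by the end-trim step.
READ_TAG <- "GTCGTATGCAGGCTC"

#' Simulate adapter-flanked small-RNA reads with planted fold changes
#'
#' Each read is built as: a suffix fragment (6-8 bases) of the 5' adapter,
#' the mature-derived insert, a prefix fragment of the 3' adapter filling to
#' 35 bases, and a constant 15-base terminal tag — 50 bases in all, matching
#' the layout the trimming stage expects. With probability `p_iso` the
#' insert gains or loses up to 2 terminal bases (isomiR variation); with
#' probability `p_mm` it carries 1-3 substitutions. Per-miRNA counts are
#' negative binomial with dispersion `phi` around condition means that carry
#' the design's planted log2 fold changes (applied to the contrast's second
#' group).
#'
#' @param ref A [MiRNAReference-class]; must be non-empty.
#' @param design A [StudyDesign-class]; its `planted_de` table drives the
#'   group means and its seed (offset) fixes sampling.
#' @param mean_depth Expected reads per library.
#' @param adapter_5p,adapter_3p Adapter DNA strings (defaults shared with
#'   [trimParams()]).
#' @param p_iso Probability of terminal-end variation per read (default
#'   0.15).
#' @param p_mm Probability of internal substitutions per read (default 0.1).
#' @param phi NB dispersion of the count generator (default 0.1, typical
#'   for biological replicates).
#' @param seed Optional seed; defaults to a child of the design seed.
#' @return A list of class `SmallRNASim` with elements `reads` (per-library
#'   named character vectors), `truth` (per-library data.frame of
#'   `read_id`, `mature_id`), `counts` (true per-mature count matrix),
#'   `design` and the generator parameters.
#' @export
simulateReads <- function(ref, design, mean_depth,
                          adapter_5p = trimParams()$adapter_5p,
                          adapter_3p = trimParams()$adapter_3p,
                          p_iso = 0.15, p_mm = 0.1, phi = 0.1,
                          seed = NULL) {
  stopifnot(is(ref, "MiRNAReference"), is(design, "StudyDesign"))
  if (length(ref) == 0L) stop("empty miRNA reference")
  if (is.null(seed)) seed <- child_seed(design@seed, 1L)
  mat <- matureSeqs(ref)
  mature_ids <- names(mat)
  mature_dna <- chartr("U", "T", as.character(mat))
  libs <- designLibraries(design)

  with_seed(seed, {
    base_w <- exp(rnorm(length(mature_ids), mean = 0, sd = 1.2))
    names(base_w) <- mature_ids
    ## per-condition weights with planted fold changes on the second group
    w <- matrix(base_w, nrow = length(mature_ids), ncol = length(CONDITIONS),
                dimnames = list(mature_ids, CONDITIONS))
    pd <- design@planted_de
    for (k in seq_len(nrow(pd))) {
      grp2 <- contrastGroups(pd$contrast[k])[2L]
      w[pd$mature_id[k], grp2] <- w[pd$mature_id[k], grp2] * 2^pd$log2fc[k]
    }
    mu <- sweep(w, 2L, colSums(w), "/") * mean_depth

    counts <- matrix(0L, length(mature_ids), nrow(libs),
                     dimnames = list(mature_ids, libs$library))
    reads <- vector("list", nrow(libs))
    truth <- vector("list", nrow(libs))
    names(reads) <- names(truth) <- libs$library

    for (j in seq_len(nrow(libs))) {
      m <- mu[, libs$condition[j]]
      y <- if (phi > 0) rnbinom(length(m), mu = m, size = 1 / phi)
           else rpois(length(m), m)
      counts[, j] <- y
      src <- rep(seq_along(mature_ids), y)
      n <- length(src)
      ins <- mature_dna[src]
      if (n) {
        ## isomiR end variation, 3'-biased as in real small-RNA data where
        ## 5' ends are seed-constrained: 3' ends gain/lose up to 2 bases,
        ## 5' ends at most 1.
        iso <- runif(n) < p_iso
        for (i in which(iso)) {
          end <- if (runif(1) < 0.8) "3p" else "5p"
          k <- if (end == "3p") sample(1:2, 1L) else 1L
          if (runif(1) < 0.5) {          # lose templated end bases
            ins[i] <- if (end == "5p") substr(ins[i], k + 1L, nchar(ins[i]))
                      else substr(ins[i], 1L, nchar(ins[i]) - k)
          } else {                       # gain flanking (template-like) bases
            ext <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
            ins[i] <- if (end == "5p") paste0(ext, ins[i])
                      else paste0(ins[i], ext)
          }
        }
        mm <- runif(n) < p_mm
        for (i in which(mm)) {
          k <- sample(1:3, 1L)
          pos <- sample(nchar(ins[i]), min(k, nchar(ins[i])))
          ch <- strsplit(ins[i], "")[[1L]]
          for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
          ins[i] <- paste(ch, collapse = "")
        }
        il <- nchar(ins)
        room <- 33L - il
        a5len <- ifelse(room >= 6L, 6L + floor(runif(n) * pmin(3L, room - 5L)),
                        0L)
        a3len <- 35L - a5len - il
        a5 <- substring(adapter_5p, nchar(adapter_5p) - a5len + 1L,
                        nchar(adapter_5p))
        a3 <- substring(adapter_3p, 1L, a3len)
        rd <- paste0(a5, ins, a3, READ_TAG)
        ids <- sprintf("%s_r%06d", libs$library[j], seq_len(n))
        reads[[j]] <- setNames(rd, ids)
        truth[[j]] <- data.frame(read_id = ids,
                                 mature_id = mature_ids[src],
                                 stringsAsFactors = FALSE)
      } else {
        reads[[j]] <- character()
        truth[[j]] <- data.frame(read_id = character(),
                                 mature_id = character())
      }
    }
    structure(list(reads = reads, truth = truth, counts = counts,
                   design = design,
                   params = list(mean_depth = mean_depth, p_iso = p_iso,
                                 p_mm = p_mm, phi = phi, seed = seed,
                                 adapter_5p = adapter_5p,
                                 adapter_3p = adapter_3p)),
              class = "SmallRNASim")
  })
}

#' Simulate a junction/exon probe-set intensity matrix with planted events
#'
#' Per gene the matrix carries 2 constitutive probe sets, 1 reciprocal
#' inclusion/exclusion junction pair and 1 exon/PSR probe set. Planted
#' reciprocal events add `+effect` to the inclusion probe and `-effect` to
#' the exclusion probe (direction `inclusion`; reversed for `exclusion`) in
#' the contrast's second group; planted exon events shift the PSR probe
#' only. Optional co-directional decoys shift both junction probes the same
#' way — a genuine expression change, not splicing, which the reciprocity
#' gate must reject.
#'
#' @param n_genes Number of genes.
#' @param design A [StudyDesign-class] (samples are its libraries).
#' @param n_events Planted reciprocal junction events.
#' @param n_exon_events Planted exon/PSR (splicing-index) events.
#' @param n_decoys Co-directional decoy genes.
#' @param effect Planted effect in log2 units (>= 1 for planted
#'   positives); a length-2 vector plants per-event effects drawn
#'   uniformly from that range.
#' @param contrast Contrast receiving the planted change.
#' @param noise_sd Gaussian noise sd in log2 units (>= 0).
#' @param seed Optional seed (defaults to a child of the design seed).
#' @return List with `matrix` (a [ProbeSetMatrix-class]) and `truth`
#'   (data.frame: `gene`, `inclusion_probe_set`, `exclusion_probe_set`,
#'   `contrast`, `direction`, `effect`, `type`).
#' @export
simulateProbeMatrix <- function(n_genes, design, n_events = 0L,
                                n_exon_events = 0L, n_decoys = 0L,
                                effect = 1.5, contrast = "HC_vs_PD",
                                noise_sd = 0.2, seed = NULL) {
  stopifnot(is(design, "StudyDesign"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_events + n_exon_events + n_decoys > n_genes)
    stop("more planted genes than genes")
  if (min(effect) < 1 && n_events + n_exon_events > 0)
    warning("planted effect below 1 log2 unit")
  if (is.null(seed)) seed <- child_seed(design@seed, 2L)
  libs <- designLibraries(design)
  grp2 <- contrastGroups(contrast)[2L]
  in2 <- libs$condition == grp2

  with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    roles <- c("constitutive", "constitutive", "junction_inclusion",
               "junction_exclusion", "exon_psr")
    suffix <- c("c1", "c2", "incl", "excl", "psr")
    info <- data.frame(
      probe_set = paste0(rep(genes, each = 5L), "_", suffix),
      gene = rep(genes, each = 5L),
      role = rep(roles, n_genes),
      stringsAsFactors = FALSE
    )
    info$reciprocal_partner <- NA_character_
    incl <- info$role == "junction_inclusion"
    excl <- info$role == "junction_exclusion"
    info$reciprocal_partner[incl] <- info$probe_set[excl]
    info$reciprocal_partner[excl] <- info$probe_set[incl]
    info$sequence <- random_seq(nrow(info), rep(40L, nrow(info)))
    info$event_annotation <- NA_character_

    gene_mu <- rnorm(n_genes, 8, 1)
    probe_off <- rnorm(nrow(info), 0, 0.5)
    base <- gene_mu[rep(seq_len(n_genes), each = 5L)] + probe_off
    x <- matrix(base, nrow(info), nrow(libs),
                dimnames = list(info$probe_set, libs$library))

    picked <- sample(n_genes, n_events + n_exon_events + n_decoys)
    ev_genes <- picked[seq_len(n_events)]
    ex_genes <- picked[n_events + seq_len(n_exon_events)]
    decoy_genes <- picked[n_events + n_exon_events + seq_len(n_decoys)]

    draw_effect <- function() {
      if (length(effect) == 2L) runif(1L, effect[1L], effect[2L]) else effect
    }
    truth <- data.frame(gene = character(), inclusion_probe_set = character(),
                        exclusion_probe_set = character(),
                        contrast = character(), direction = character(),
                        effect = numeric(), type = character(),
                        stringsAsFactors = FALSE)
    add_truth <- function(g, ips, eps, dir, eff, type) {
      rbind(truth, data.frame(gene = g, inclusion_probe_set = ips,
                              exclusion_probe_set = eps, contrast = contrast,
                              direction = dir, effect = eff, type = type,
                              stringsAsFactors = FALSE))
    }
    for (gi in ev_genes) {
      g <- genes[gi]
      dir <- sample(c("inclusion", "exclusion"), 1L)
      eff <- draw_effect()
      s <- if (dir == "inclusion") 1 else -1
      x[paste0(g, "_incl"), in2] <- x[paste0(g, "_incl"), in2] + s * eff
      x[paste0(g, "_excl"), in2] <- x[paste0(g, "_excl"), in2] - s * eff
      truth <- add_truth(g, paste0(g, "_incl"), paste0(g, "_excl"), dir,
                         eff, "junction")
    }
    for (gi in ex_genes) {
      g <- genes[gi]
      eff <- draw_effect()
      x[paste0(g, "_psr"), in2] <- x[paste0(g, "_psr"), in2] + eff
      truth <- add_truth(g, paste0(g, "_psr"), NA_character_, "inclusion",
                         eff, "exon")
    }
    for (gi in decoy_genes) {
      g <- genes[gi]
      eff <- draw_effect()
      x[paste0(g, "_incl"), in2] <- x[paste0(g, "_incl"), in2] + eff
      x[paste0(g, "_excl"), in2] <- x[paste0(g, "_excl"), in2] + eff
      truth <- add_truth(g, paste0(g, "_incl"), paste0(g, "_excl"),
                         "codirectional", eff, "decoy")
    }
    if (noise_sd > 0)
      x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))

    rownames(info) <- info$probe_set
    psm <- ProbeSetMatrix(x, info[, -1L], condition = libs$condition)
    list(matrix = psm, truth = truth)
  })
}

#' Simulate a miRNA target-prediction table
#'
#' Emulates the output shape of a multi-program consensus predictor: rows of
#' (miRNA, gene, region, site offset) with the binding region drawn from a
#' configurable simplex over 5'UTR / CDS / 3'UTR. The default simplex
#' (0.19, 0.38, 0.43) mirrors the observed split of a disease miRNA-target
#' network across those regions.
#'
#' @param ref A [MiRNAReference-class] supplying miRNA identifiers.
#' @param genes Character vector of target gene identifiers.
#' @param density Predicted sites per gene (> 0).
#' @param region_probs Probabilities for (5UTR, CDS, 3UTR).
#' @param exact_density If TRUE (default), emit exactly
#'   `round(density * length(genes))` rows.
#' @param seed Integer seed.
#' @return data.frame with columns `mirna_id`, `gene`, `region`,
#'   `site_offset` (0-based within region), unique per row.
#' @export
simulateTargetTable <- function(ref, genes, density,
                                region_probs = c(0.19, 0.38, 0.43),
                                exact_density = TRUE, seed = 1L) {
  stopifnot(is(ref, "MiRNAReference"), length(genes) > 0L)
  if (density <= 0) stop("density must be positive")
  stopifnot(length(region_probs) == 3L, all(region_probs >= 0),
            abs(sum(region_probs) - 1) < 1e-8)
  mirnas <- names(matureSeqs(ref))
  n_rows <- round(density * length(genes))
  with_seed(seed, {
    draw <- function(k) data.frame(
      mirna_id = sample(mirnas, k, replace = TRUE),
      gene = sample(genes, k, replace = TRUE),
      region = sample(REGIONS, k, replace = TRUE, prob = region_probs),
      site_offset = sample(0:1999, k, replace = TRUE),
      stringsAsFactors = FALSE
    )
    tab <- unique(draw(n_rows))
    while (exact_density && nrow(tab) < n_rows)
      tab <- unique(rbind(tab, draw(n_rows - nrow(tab))))
    rownames(tab) <- NULL
    tab
  })
}

#' Simulate a lineage expression compendium with planted marker blocks
#'
#' Each lineage owns `markers_per_lineage` genes elevated by `shift` log2
#' units in that lineage's columns; background genes and noise are shared.
#'
#' @param n_lineages Number of lineages (>= 2).
#' @param markers_per_lineage Markers per lineage; values outside 50-150
#'   trigger a warning (allowed).
#' @param n_samples Columns per lineage in the compendium.
#' @param shift Marker elevation in log2 units (default 3).
#' @param noise_sd Gaussian noise sd (default 0.5).
#' @param n_background_genes Non-marker genes (default 200).
#' @param seed Integer seed.
#' @return List of class `LineageSim`: `compendium` (genes x samples),
#'   `labels` (per-column lineage), `marker_truth` (data.frame `lineage`,
#'   `gene`), `baseline` (per-gene baseline), `shift`, `noise_sd`.
#' @export
simulateLineageCompendium <- function(n_lineages, markers_per_lineage,
                                      n_samples = 3L, shift = 3,
                                      noise_sd = 0.5,
                                      n_background_genes = 200L, seed = 1L) {
  stopifnot(n_lineages >= 2L, markers_per_lineage >= 1L, n_samples >= 1L)
  if (markers_per_lineage < 50L || markers_per_lineage > 150L)
    warning("markers_per_lineage outside the typical 50-150 range")
  with_seed(seed, {
    lineages <- sprintf("lineage%02d", seq_len(n_lineages))
    n_mark <- n_lineages * markers_per_lineage
    genes <- c(sprintf("MK%05d", seq_len(n_mark)),
               sprintf("BG%05d", seq_len(n_background_genes)))
    marker_truth <- data.frame(
      lineage = rep(lineages, each = markers_per_lineage),
      gene = genes[seq_len(n_mark)],
      stringsAsFactors = FALSE
    )
    baseline <- setNames(rnorm(length(genes), 5, 1), genes)
    labels <- rep(lineages, each = n_samples)
    x <- matrix(baseline, length(genes), length(labels),
                dimnames = list(genes,
                                paste0(labels, "_s", rep(seq_len(n_samples),
                                                         n_lineages))))
    for (l in lineages) {
      mk <- marker_truth$gene[marker_truth$lineage == l]
      x[mk, labels == l] <- x[mk, labels == l] + shift
    }
    if (noise_sd > 0)
      x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
    structure(list(compendium = x, labels = labels,
                   marker_truth = marker_truth, baseline = baseline,
                   shift = shift, noise_sd = noise_sd),
              class = "LineageSim")
  })
}

#' Simulate mixture samples over a lineage compendium
#'
#' Draws samples whose expression is a weighted average of noiseless lineage
#' profiles (baseline plus marker shift) with added Gaussian noise; the
#' dominant (highest-weight) lineage is recorded per sample.
#'
#' @param sim A `LineageSim` from [simulateLineageCompendium()].
#' @param n_samples Number of mixture samples.
#' @param weights Named numeric vector of lineage weights (summing to 1),
#'   e.g. `c(lineage01 = 0.9, lineage02 = 0.1)`; lineages absent from the
#'   vector get weight 0. Each sample re-draws the identity of the dominant
#'   lineage uniformly and applies the weight profile to it and a random
#'   minor lineage.
#' @param noise_sd Gaussian noise sd (default the compendium's).
#' @param seed Integer seed.
#' @return List: `samples` (genes x n_samples), `dominant` (per-sample
#'   dominant lineage label).
#' @export
simulateMixtureSamples <- function(sim, n_samples, weights,
                                   noise_sd = sim$noise_sd, seed = 1L) {
  stopifnot(inherits(sim, "LineageSim"), n_samples >= 1L)
  w <- sort(as.numeric(weights), decreasing = TRUE)
  stopifnot(abs(sum(w) - 1) < 1e-8, length(w) >= 1L)
  lineages <- unique(sim$labels)
  genes <- rownames(sim$compendium)
  profile_of <- function(l) {
    p <- sim$baseline
    mk <- sim$marker_truth$gene[sim$marker_truth$lineage == l]
    p[mk] <- p[mk] + sim$shift
    p
  }
  profiles <- vapply(lineages, profile_of, numeric(length(genes)))
  rownames(profiles) <- genes
  with_seed(seed, {
    dominant <- character(n_samples)
    x <- matrix(0, length(genes), n_samples,
                dimnames = list(genes, sprintf("mix_s%03d", seq_len(n_samples))))
    for (i in seq_len(n_samples)) {
      pick <- sample(lineages, length(w))
      dominant[i] <- pick[1L]
      x[, i] <- profiles[, pick, drop = FALSE] %*% w
    }
    if (noise_sd > 0)
      x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
    list(samples = x, dominant = dominant)
  })
}

#' Simulate an independent two-label expression matrix
#'
#' A stand-in for an external validation cohort: two sample groups whose
#' features are separated by a standardized effect size `effect_d` (Cohen's
#' d; the group shift is `effect_d * noise_sd`).
#'
#' @param n_features Number of features (rows).
#' @param n1,n2 Samples per group.
#' @param effect_d Standardized group separation per feature (default 2).
#' @param noise_sd Within-group sd (default 1).
#' @param seed Integer seed.
#' @return List: `matrix` (features x samples), `labels` (per-sample group
#'   label, `"A"`/`"B"`).
#' @export
simulateLabeledMatrix <- function(n_features = 300L, n1 = 24L, n2 = 23L,
                                  effect_d = 2, noise_sd = 1, seed = 1L) {
  stopifnot(n_features >= 1L, n1 >= 1L, n2 >= 1L, noise_sd >= 0)
  with_seed(seed, {
    labels <- c(rep("A", n1), rep("B", n2))
    base <- rnorm(n_features, 7, 1)
    dir <- sample(c(-1, 1), n_features, replace = TRUE)
    x <- matrix(base, n_features, n1 + n2,
                dimnames = list(sprintf("feat%04d", seq_len(n_features)),
                                sprintf("%s_s%02d", labels,
                                        c(seq_len(n1), seq_len(n2)))))
    x[, labels == "B"] <- x[, labels == "B"] + dir * effect_d * noise_sd
    if (noise_sd > 0)
      x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x), ncol(x))
    list(matrix = x, labels = labels)
  })
}
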