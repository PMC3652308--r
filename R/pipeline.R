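## Pipeline orchestration: configuration, the demo input bundle, and the
## end-to-end run with per-stage logging and a reproducibility manifest.

#' Build a pipeline configuration
#'
#' Paths to every input/output plus the calling thresholds; defaults are
#' the workflow's published operating points (CPM >= 1 in >= 3 libraries,
#' B >= 1, fold change 2, p < 0.05, z 1.96 with >= 3 changed genes and
#' 2000 permutations).
#'
#' @param dir Bundle directory holding the demo inputs (see [makeDemo()]);
#'   outputs go to `file.path(dir, "results")` unless `out_dir` is given.
#' @param out_dir Output directory.
#' @param min_cpm,min_libraries CPM presence filter.
#' @param b_threshold Posterior log-odds call threshold.
#' @param fc_threshold Splice fold-change threshold.
#' @param p_threshold Splice t-test p threshold.
#' @param si_threshold Splicing-index threshold (log2 units).
#' @param z_cutoff,min_genes,n_perm ORA gates and permutations.
#' @param de_contrasts Contrasts tested for miRNA differential expression.
#' @param splice_contrasts Contrasts tested for splicing.
#' @param seed Global seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(dir, out_dir = file.path(dir, "results"),
                           min_cpm = 1, min_libraries = 3L,
                           b_threshold = 1, fc_threshold = 2,
                           p_threshold = 0.05, si_threshold = 1,
                           z_cutoff = 1.96, min_genes = 3L, n_perm = 2000L,
                           de_contrasts = CONTRASTS,
                           splice_contrasts = CONTRASTS[1:2],
                           seed = 1L) {
  stopifnot(min_cpm >= 0, min_libraries >= 1L, fc_threshold > 0,
            p_threshold > 0, si_threshold > 0, z_cutoff > 0, min_genes >= 1L,
            n_perm >= 1L)
  stopifnot(all(de_contrasts %in% CONTRASTS),
            all(splice_contrasts %in% CONTRASTS))
  structure(list(dir = dir, out_dir = out_dir, min_cpm = min_cpm,
                 min_libraries = as.integer(min_libraries),
                 b_threshold = b_threshold, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, si_threshold = si_threshold,
                 z_cutoff = z_cutoff, min_genes = as.integer(min_genes),
                 n_perm = as.integer(n_perm), de_contrasts = de_contrasts,
                 splice_contrasts = splice_contrasts,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Write/read a pipeline configuration as YAML
#' @param config A [pipelineConfig()].
#' @param file Path.
#' @return `file` (write) / the config (read).
#' @export
writePipelineConfig <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(file) {
  x <- yaml::read_yaml(file)
  do.call(pipelineConfig, x[setdiff(names(x), character())])
}

#' Generate the full synthetic demo input bundle
#'
#' Calls every generator with documented defaults and writes the bundle
#' (FASTQ reads, reference FASTA + map, probe matrix + annotations, target
#' table, gene sets, lineage compendium and mixture samples, independent
#' labelled matrix) plus all planted-truth files under `dir`.
#'
#' @param dir Bundle directory (created).
#' @param seed Global seed; two seeds give differing bundles.
#' @param n_mirnas,n_star Reference size (default 120 mature + 20 star).
#' @param mean_depth Reads per library (default 5000; a desk-scale stand-in
#'   for production depths).
#' @param n_genes Genes on the probe matrix (default 300).
#' @param n_events,n_exon_events,n_decoys Planted splice events per splice
#'   contrast.
#' @param planted_mirnas Planted DE miRNAs per contrast (default 8).
#' @param planted_lfc Planted |log2 FC| (default 2).
#' @return A [pipelineConfig()] pointing at the bundle, invisibly.
#' @export
makeDemo <- function(dir, seed = 1L, n_mirnas = 120L, n_star = 20L,
                     mean_depth = 5000, n_genes = 300L, n_events = 30L,
                     n_exon_events = 15L, n_decoys = 10L,
                     planted_mirnas = 8L, planted_lfc = 2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- generateMiRNAReference(n_mirnas, n_star, seed = child_seed(seed, 10))
  mat_ids <- names(matureSeqs(ref))
  planted <- with_seed(child_seed(seed, 11), {
    picks <- lapply(seq_along(CONTRASTS), function(i)
      sample(mat_ids, planted_mirnas))
    data.frame(
      mature_id = unlist(picks),
      contrast = rep(CONTRASTS, each = planted_mirnas),
      log2fc = rep(c(planted_lfc, -planted_lfc),
                   length.out = planted_mirnas * length(CONTRASTS)),
      stringsAsFactors = FALSE)
  })
  design <- studyDesign(libraries_per_condition = 3L, planted_de = planted,
                        seed = as.integer(seed %% 2147483587))

  sim <- simulateReads(ref, design, mean_depth,
                       seed = child_seed(seed, 12))
  libs <- designLibraries(design)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  for (lib in libs$library)
    writeFastq(sim$reads[[lib]], file.path(dir, "reads",
                                           paste0(lib, ".fastq")))
  write.table(libs, file.path(dir, "libraries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeReference(ref, file.path(dir, "reference.fasta"),
                 file.path(dir, "reference_map.tsv"))
  writeMatrixTSV(sim$counts, file.path(dir, "truth_mirna_counts.tsv"))
  write.table(planted, file.path(dir, "truth_planted_de.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## probe matrices: one per splice contrast, distinct planted events
  probe_truth <- list()
  for (i in seq_len(2L)) {
    ps <- simulateProbeMatrix(n_genes, design, n_events = n_events,
                              n_exon_events = n_exon_events,
                              n_decoys = n_decoys, effect = 1.5,
                              contrast = CONTRASTS[i], noise_sd = 0.2,
                              seed = child_seed(seed, 20 + i))
    writeProbeSetMatrix(ps$matrix,
                        file.path(dir, sprintf("probes_%s.tsv", CONTRASTS[i])),
                        file.path(dir, sprintf("probes_%s_annotation.tsv",
                                               CONTRASTS[i])))
    probe_truth[[CONTRASTS[i]]] <- ps$truth
  }
  truth_all <- do.call(rbind, probe_truth)
  write.table(truth_all, file.path(dir, "truth_splice_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- sprintf("GENE%04d", seq_len(n_genes))
  ## dense consensus-style predictions (multi-program unions predict many
  ## sites per gene), so demo networks carry enough edges for stable
  ## region statistics
  targets <- simulateTargetTable(ref, genes, density = 40,
                                 seed = child_seed(seed, 30))
  writeTargetTable(targets, file.path(dir, "target_predictions.tsv"))

  ## gene sets: half loaded with planted-event genes, half random
  sets <- with_seed(child_seed(seed, 31), {
    ev_genes <- unique(truth_all$gene[truth_all$type != "decoy"])
    s <- list()
    for (k in 1:10)
      s[[sprintf("planted_set_%02d", k)]] <-
        unique(c(sample(ev_genes, min(8L, length(ev_genes))),
                 sample(genes, 7L)))
    for (k in 1:10)
      s[[sprintf("random_set_%02d", k)]] <- sample(genes, 15L)
    s
  })
  writeGMT(sets, file.path(dir, "gene_sets.gmt"))

  lin <- simulateLineageCompendium(8L, 100L, n_samples = 3L,
                                   seed = child_seed(seed, 40))
  writeMatrixTSV(lin$compendium, file.path(dir, "lineage_compendium.tsv"))
  write.table(data.frame(sample = colnames(lin$compendium),
                         lineage = lin$labels),
              file.path(dir, "lineage_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mix <- simulateMixtureSamples(lin, n_samples = 24L,
                                weights = c(0.9, 0.1),
                                seed = child_seed(seed, 41))
  writeMatrixTSV(mix$samples, file.path(dir, "lineage_samples.tsv"))
  write.table(data.frame(sample = colnames(mix$samples),
                         dominant = mix$dominant),
              file.path(dir, "truth_lineage_dominant.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  lab <- simulateLabeledMatrix(seed = child_seed(seed, 50))
  writeMatrixTSV(lab$matrix, file.path(dir, "independent_matrix.tsv"))
  write.table(data.frame(sample = colnames(lab$matrix),
                         label = lab$labels),
              file.path(dir, "independent_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cfg <- pipelineConfig(dir, seed = seed)
  writePipelineConfig(cfg, file.path(dir, "config.yaml"))
  invisible(cfg)
}

write_tsv_out <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the whole pipeline on a demo-style bundle
#'
#' Executes quantification, differential expression (three contrasts),
#' splicing detection and sample classification (two contrasts),
#' enrichment, lineage scoring and network assembly, writing every result
#' table plus a manifest recording parameters, seeds, record counts and
#' output checksums. Any stage failure aborts naming the stage.
#'
#' @param config A [pipelineConfig()] or path to its YAML.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
runAll <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  counts_rec <- list()
  stage <- function(name, expr) {
    ls_message("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  ## --- quant -------------------------------------------------------------
  res_quant <- stage("quant", {
    libs <- read.delim(file.path(config$dir, "libraries.tsv"))
    ref <- readReference(file.path(config$dir, "reference_map.tsv"))
    reads <- lapply(libs$library, function(lib)
      readFastq(file.path(config$dir, "reads", paste0(lib, ".fastq"))))
    names(reads) <- libs$library
    tp <- trimParams()
    trimmed <- lapply(reads, function(r) trimReads(r, tp)$reads)
    aligned <- alignAndCount(trimmed, ref, matchParams(),
                             condition = libs$condition)
    merged <- mergeCounts(aligned$counts)
    filtered <- cpmFilter(merged, config$min_cpm, config$min_libraries)
    outputs <- c(outputs,
                  writeCountMatrix(filtered,
                                   file.path(config$out_dir, "counts.tsv"),
                                   file.path(config$out_dir, "features.tsv"),
                                   file.path(config$out_dir,
                                             "count_libraries.tsv")),
                  write_tsv_out(aligned$stats, config$out_dir,
                                "mapping_stats.tsv"))
    counts_rec$quant <- list(n_features = nrow(filtered),
                              n_libraries = ncol(filtered))
    list(counts = filtered, stats = aligned$stats)
  })

  ## --- differential expression ------------------------------------------
  res_de <- stage("diffexp", {
    de <- lapply(config$de_contrasts, function(ct)
      runDifferentialExpression(res_quant$counts, ct,
                                b_threshold = config$b_threshold))
    names(de) <- config$de_contrasts
    for (ct in config$de_contrasts)
      outputs <- c(outputs, write_tsv_out(de[[ct]], config$out_dir,
                                           sprintf("de_%s.tsv", ct)))
    counts_rec$diffexp <- lapply(de, function(d) sum(d$called))
    de
  })

  ## --- splicing ----------------------------------------------------------
  res_splice <- stage("splicing", {
    out <- list()
    for (ct in config$splice_contrasts) {
      mf <- file.path(config$dir, sprintf("probes_%s.tsv", ct))
      af <- file.path(config$dir, sprintf("probes_%s_annotation.tsv", ct))
      if (!file.exists(mf) || !file.exists(af))
        stop("probe matrix missing for contrast ", ct)
      libs <- read.delim(file.path(config$dir, "libraries.tsv"))
      psm <- readProbeSetMatrix(mf, af, condition = libs$condition)
      grp <- contrastGroups(ct)
      keep <- conditionsOf2(psm) %in% grp
      sub <- psm[, keep]
      groups <- factor(as.character(colData(sub)$condition), levels = grp)
      summ <- summarizeGeneExpression(sub)
      jev <- detectJunctionEvents(sub, groups, summ,
                                  fc_threshold = config$fc_threshold,
                                  p_threshold = config$p_threshold)
      sev <- detectSplicingIndexEvents(sub, groups, summ,
                                       si_threshold = config$si_threshold,
                                       p_threshold = config$p_threshold)
      jev$contrast <- ct; sev$contrast <- ct
      feats <- unique(c(jev$inclusion_probe_set[jev$called],
                        jev$exclusion_probe_set[jev$called]))
      cls <- if (length(feats))
        classifySamples(intensityOf(sub), feats, labels = as.character(groups))
      else list(clusters = NULL, accuracy = NA_real_, newick = NULL)
      out[[ct]] <- list(junction = jev, splicing_index = sev,
                        classification = cls, psm = sub, groups = groups)
      outputs <- c(outputs,
                    write_tsv_out(jev, config$out_dir,
                                  sprintf("splice_junction_%s.tsv", ct)),
                    write_tsv_out(sev, config$out_dir,
                                  sprintf("splice_index_%s.tsv", ct)))
      if (!is.null(cls$newick)) {
        nf <- file.path(config$out_dir, sprintf("dendrogram_%s.nwk", ct))
        writeLines(cls$newick, nf)
        outputs <- c(outputs, nf)
      }
    }
    counts_rec$splicing <- lapply(out, function(o)
      list(junction_called = sum(o$junction$called),
           index_called = sum(o$splicing_index$called),
           classification_accuracy = o$classification$accuracy))
    out
  })

  ## --- enrichment --------------------------------------------------------
  res_enrich <- stage("enrichment", {
    sets <- readGMT(file.path(config$dir, "gene_sets.gmt"))
    first_ct <- config$splice_contrasts[1L]
    psm_ann <- probeInfo(res_splice[[first_ct]]$psm)
    background <- unique(psm_ann$gene)
    enr <- list()
    for (ct in config$splice_contrasts) {
      jev <- res_splice[[ct]]$junction
      changed <- unique(jev$gene[jev$called])
      enr[[ct]] <- oraTest(sets, changed, background,
                           n_perm = config$n_perm,
                           z_cutoff = config$z_cutoff,
                           min_genes = config$min_genes,
                           seed = child_seed(config$seed, 60))
      outputs <- c(outputs, write_tsv_out(enr[[ct]], config$out_dir,
                                           sprintf("enrichment_%s.tsv", ct)))
    }
    counts_rec$enrichment <- lapply(enr, function(e) sum(e$reported))
    enr
  })

  ## --- lineage -----------------------------------------------------------
  res_lineage <- stage("lineage", {
    comp <- readMatrixTSV(file.path(config$dir, "lineage_compendium.tsv"))
    lab <- read.delim(file.path(config$dir, "lineage_labels.tsv"))
    samples <- readMatrixTSV(file.path(config$dir, "lineage_samples.tsv"))
    ref <- buildMarkerDb(comp, lab$lineage, markers_per_lineage = 100L)
    sc <- scoreSamples(samples, ref)
    ord <- clusterLineageScores(sc)
    outputs <- c(outputs,
                  write_tsv_out(markerTable(ref), config$out_dir,
                                "lineage_markers.tsv"))
    zf <- file.path(config$out_dir, "lineage_z.tsv")
    writeMatrixTSV(sc$z, zf)
    outputs <- c(outputs, zf)
    list(reference = ref, scores = sc, clustering = ord)
  })

  ## --- network -----------------------------------------------------------
  res_net <- stage("network", {
    targets <- readTargetTable(file.path(config$dir,
                                         "target_predictions.tsv"))
    nets <- list()
    for (ct in config$splice_contrasts) {
      de <- res_de[[ct]]
      ## DE features are mature ids after merge
      de$feature <- sub("^.*:", "", de$feature)
      ev <- res_splice[[ct]]$junction
      net <- buildNetwork(de, ev, targets, ct)
      ann <- probeInfo(res_splice[[ct]]$psm)
      pseq <- setNames(ann$sequence, rownames(ann))
      ref <- readReference(file.path(config$dir, "reference_map.tsv"))
      ver <- verifyNetworkSeeds(net, ev, pseq, ref)
      nets[[ct]] <- ver
      sif <- file.path(config$out_dir, sprintf("network_%s.sif", ct))
      gml <- file.path(config$out_dir, sprintf("network_%s.graphml", ct))
      exportNetwork(ver$network, sif, "SIF")
      exportNetwork(ver$network, gml, "GraphML")
      rd <- regionDistribution(ver$network)
      js <- file.path(config$out_dir, sprintf("network_%s_summary.json", ct))
      jsonlite::write_json(
        list(contrast = ct, n_edges = rd$n_edges,
             region_fractions = as.list(rd$fractions),
             mean_sites_per_gene = rd$mean_sites_per_gene,
             incidences = rd$incidences, total_sites = rd$total_sites,
             n_seed_verified = ver$summary$n_verified,
             n_inclusion_nodes =
               sum(networkGenes(ver$network)$direction == "inclusion"),
             n_exclusion_nodes =
               sum(networkGenes(ver$network)$direction == "exclusion")),
        js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      outputs <- c(outputs, sif, gml, js)
    }
    counts_rec$network <- lapply(nets, function(v) v$summary$n_edges)
    nets
  })

  ## --- independent classification ----------------------------------------
  res_class <- stage("classification", {
    m <- readMatrixTSV(file.path(config$dir, "independent_matrix.tsv"))
    lab <- read.delim(file.path(config$dir, "independent_labels.tsv"))
    cls <- classifySamples(m, labels = lab$label)
    rep <- data.frame(sample = colnames(m), cluster = cls$clusters,
                      label = lab$label)
    outputs <- c(outputs, write_tsv_out(rep, config$out_dir,
                                         "independent_classification.tsv"))
    counts_rec$classification <- list(accuracy = cls$accuracy)
    cls
  })

  manifest <- list(
    parameters = unclass(config)[c("min_cpm", "min_libraries", "b_threshold",
                                   "fc_threshold", "p_threshold",
                                   "si_threshold", "z_cutoff", "min_genes",
                                   "n_perm", "de_contrasts",
                                   "splice_contrasts", "seed")],
    record_counts = counts_rec,
    outputs = {
      o <- sort(unique(basename(outputs)))
      md5 <- tools::md5sum(file.path(config$out_dir, o))
      setNames(as.list(unname(md5)), o)
    })
  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(quant = res_quant, de = res_de, splicing = res_splice,
                 enrichment = res_enrich, lineage = res_lineage,
                 networks = res_net, classification = res_class,
                 manifest = manifest, manifest_file = mf))
}

## condition accessor tolerant of plain SummarizedExperiment columns
conditionsOf2 <- function(x) as.character(colData(x)$condition)
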