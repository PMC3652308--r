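## miRNA -> spliced-target network assembly, binding-region attribution,
## seed-match scanning of junction probe sequences, and SIF/GraphML export.

#' Assemble a contrast-specific miRNA to spliced-target network
#'
#' Edges require all three memberships: the miRNA is DE-called in the
#' contrast, the gene has at least one called splice event in the
#' contrast, and the (miRNA, gene) pair occurs in the target-prediction
#' table. Predictions in several gene regions collapse to one edge
#' carrying the region set.
#'
#' @param de Differential-expression table ([runDifferentialExpression()]
#'   shape) with `feature`, `log2_fc`, `b_statistic`, `called`.
#' @param events Splice-event table with `gene`, `direction`, `called`.
#' @param table Target-prediction data.frame (`mirna_id`, `gene`,
#'   `region`, `site_offset`).
#' @param contrast Contrast label stored on the network.
#' @return An [InteractionNetwork-class].
#' @export
buildNetwork <- function(de, events, table, contrast) {
  stopifnot(all(c("feature", "called") %in% names(de)),
            all(c("gene", "called") %in% names(events)),
            all(c("mirna_id", "gene", "region") %in% names(table)))
  de_called <- de[de$called, , drop = FALSE]
  ev_called <- events[events$called, , drop = FALSE]
  if (nrow(de_called) == 0L || nrow(ev_called) == 0L)
    warning("no called miRNAs or no called splice events: empty network")
  mirnas <- data.frame(
    mirna_id = de_called$feature,
    log2_fc = if ("log2_fc" %in% names(de_called)) de_called$log2_fc else NA,
    b_statistic = if ("b_statistic" %in% names(de_called))
      de_called$b_statistic else NA,
    stringsAsFactors = FALSE)
  ## per gene, dominant event direction (ties -> inclusion)
  gene_dir <- vapply(split(ev_called$direction, ev_called$gene), function(d)
    if (sum(d == "inclusion") >= sum(d == "exclusion")) "inclusion"
    else "exclusion", character(1L))
  genes <- data.frame(gene = names(gene_dir), direction = unname(gene_dir),
                      stringsAsFactors = FALSE)
  hits <- table[table$mirna_id %in% mirnas$mirna_id &
                  table$gene %in% genes$gene, , drop = FALSE]
  if (nrow(hits)) {
    key <- paste(hits$mirna_id, hits$gene, sep = "\r")
    regions <- vapply(split(hits$region, key), function(rg)
      paste(REGIONS[REGIONS %in% rg], collapse = ","), character(1L))
    nsites <- vapply(split(hits$region, key), length, integer(1L))
    parts <- strsplit(names(regions), "\r", fixed = TRUE)
    edges <- data.frame(
      mirna_id = vapply(parts, `[`, character(1L), 1L),
      gene = vapply(parts, `[`, character(1L), 2L),
      regions = unname(regions),
      n_sites = unname(nsites),
      seed_verified = FALSE,
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$mirna_id, edges$gene), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(mirna_id = character(), gene = character(),
                        regions = character(), n_sites = integer(),
                        seed_verified = logical())
  }
  ## keep only nodes touching edges? The figures show connected nodes, but
  ## the node sets are the called entities; retain all called nodes.
  new("InteractionNetwork", mirnas = mirnas, genes = genes, edges = edges,
      contrast = contrast)
}

#' Binding-region distribution and sites-per-gene of a network
#'
#' Fractions over edge-region incidences (an edge carrying k regions
#' contributes k incidences, one per region) and the mean number of
#' incidences per gene node. Both the incidence tally and the raw
#' per-edge site count are reported, since "connections" can mean either.
#'
#' @param net An [InteractionNetwork-class].
#' @return List: `fractions` (named over 5UTR/CDS/3UTR, summing to 1 on
#'   non-empty networks), `incidences`, `total_sites`, `n_edges`,
#'   `mean_sites_per_gene` (incidences / gene nodes with edges).
#' @export
regionDistribution <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  ed <- networkEdges(net)
  if (nrow(ed) == 0L)
    return(list(fractions = setNames(rep(0, 3L), REGIONS), incidences = 0L,
                total_sites = 0L, n_edges = 0L, mean_sites_per_gene = 0))
  regs <- unlist(strsplit(ed$regions, ",", fixed = TRUE))
  tab <- table(factor(regs, levels = REGIONS))
  n_genes <- length(unique(ed$gene))
  list(fractions = setNames(as.numeric(tab) / sum(tab), REGIONS),
       incidences = sum(tab),
       total_sites = sum(ed$n_sites),
       n_edges = nrow(ed),
       mean_sites_per_gene = sum(tab) / n_genes)
}

#' Scan a probe sequence for miRNA seed matches
#'
#' The seed is the miRNA subsequence at positions `seed_start` to
#' `seed_start + seed_len - 1` (1-based; default 2-8, the canonical strict
#' 7-mer). Its DNA reverse complement is searched as an exact motif in the
#' probe sequence; all 0-based match offsets are returned.
#'
#' @param mirna_seq miRNA sequence (RNA or DNA string).
#' @param probe_seq Probe DNA sequence.
#' @param seed_start 1-based seed start on the miRNA (default 2).
#' @param seed_len Seed length (default 7).
#' @return data.frame: `match_offset` (0-based), `motif`; zero rows when
#'   the probe is shorter than the seed or carries no match.
#' @export
seedScan <- function(mirna_seq, probe_seq, seed_start = 2L, seed_len = 7L) {
  stopifnot(nchar(mirna_seq) >= seed_start - 1L + seed_len)
  seed <- substr(chartr("U", "T", mirna_seq), seed_start,
                 seed_start + seed_len - 1L)
  motif <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seed)))
  if (nchar(probe_seq) < seed_len)
    return(data.frame(match_offset = integer(), motif = character()))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(probe_seq))
  data.frame(match_offset = Biostrings::start(hits) - 1L,
             motif = rep(motif, length(hits)),
             stringsAsFactors = FALSE)
}

#' Verify network edges by seed matches in called junction sequences
#'
#' For each edge, `seed_verified` becomes TRUE iff the miRNA's seed motif
#' occurs in at least one *called* junction probe sequence of the target
#' gene (probes of non-called events do not count).
#'
#' @param net An [InteractionNetwork-class].
#' @param events The contrast's splice-event table (for the called probe
#'   sets per gene).
#' @param probe_seqs Named character vector of probe DNA sequences
#'   (names = probe-set ids), e.g. from `probeInfo(psm)$sequence`.
#' @param ref A [MiRNAReference-class] supplying miRNA sequences.
#' @param seed_start,seed_len Seed definition as in [seedScan()].
#' @return List: `network` (flags set), `summary` (data.frame with
#'   `n_edges`, `n_verified`, `n_events_verified`).
#' @export
verifyNetworkSeeds <- function(net, events, probe_seqs, ref,
                               seed_start = 2L, seed_len = 7L) {
  stopifnot(is(net, "InteractionNetwork"), is(ref, "MiRNAReference"))
  ed <- networkEdges(net)
  mat <- matureSeqs(ref)
  if (is.null(probe_seqs) || !length(probe_seqs)) {
    warning("no probe sequences supplied; seed flags left FALSE")
    return(list(network = net,
                summary = data.frame(n_edges = nrow(ed), n_verified = 0L,
                                     n_events_verified = 0L)))
  }
  called <- events[events$called, , drop = FALSE]
  probes_of_gene <- function(g) {
    p <- c(called$inclusion_probe_set[called$gene == g],
           called$exclusion_probe_set[called$gene == g])
    p <- p[!is.na(p)]
    p[p %in% names(probe_seqs)]
  }
  n_events_verified <- 0L
  if (nrow(ed)) {
    for (k in seq_len(nrow(ed))) {
      mseq <- as.character(mat[[ed$mirna_id[k]]])
      hits <- 0L
      for (p in probes_of_gene(ed$gene[k])) {
        nh <- nrow(seedScan(mseq, probe_seqs[[p]], seed_start, seed_len))
        hits <- hits + nh
      }
      ed$seed_verified[k] <- hits > 0L
      n_events_verified <- n_events_verified + (hits > 0L)
    }
  }
  net@edges <- ed
  list(network = net,
       summary = data.frame(n_edges = nrow(ed),
                            n_verified = sum(ed$seed_verified),
                            n_events_verified = n_events_verified))
}

## canonical XML escaping for the GraphML writer
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Export an interaction network as SIF or GraphML
#'
#' SIF emits one `mirna targets gene` line per edge. GraphML carries node
#' attributes (type, direction, log2 fold change, B statistic) and edge
#' attributes (regions, n_sites, seed_verified) in a canonical attribute
#' order, so export -> [importNetwork()] -> export round-trips
#' byte-identically.
#'
#' @param net An [InteractionNetwork-class].
#' @param file Output path.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `file`, invisibly.
#' @export
exportNetwork <- function(net, file, format = c("SIF", "GraphML")) {
  stopifnot(is(net, "InteractionNetwork"))
  format <- match.arg(format)
  ed <- networkEdges(net)
  if (format == "SIF") {
    lines <- if (nrow(ed))
      paste(ed$mirna_id, "targets", ed$gene) else character()
    writeLines(lines, file)
    return(invisible(file))
  }
  mi <- networkMirnas(net); ge <- networkGenes(net)
  num <- function(x) sprintf("%.10g", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="ntype" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="dir" for="node" attr.name="direction" attr.type="string"/>',
    '  <key id="lfc" for="node" attr.name="log2_fc" attr.type="double"/>',
    '  <key id="b" for="node" attr.name="b_statistic" attr.type="double"/>',
    '  <key id="reg" for="edge" attr.name="regions" attr.type="string"/>',
    '  <key id="ns" for="edge" attr.name="n_sites" attr.type="int"/>',
    '  <key id="sv" for="edge" attr.name="seed_verified" attr.type="boolean"/>',
    sprintf('  <graph id="%s" edgedefault="directed">',
            xml_escape(net@contrast)))
  for (k in seq_len(nrow(mi)))
    lines <- c(lines, sprintf(
      '    <node id="%s"><data key="ntype">mirna</data><data key="lfc">%s</data><data key="b">%s</data></node>',
      xml_escape(mi$mirna_id[k]), num(mi$log2_fc[k]), num(mi$b_statistic[k])))
  for (k in seq_len(nrow(ge)))
    lines <- c(lines, sprintf(
      '    <node id="%s"><data key="ntype">gene</data><data key="dir">%s</data></node>',
      xml_escape(ge$gene[k]), xml_escape(ge$direction[k])))
  for (k in seq_len(nrow(ed)))
    lines <- c(lines, sprintf(
      '    <edge source="%s" target="%s"><data key="reg">%s</data><data key="ns">%d</data><data key="sv">%s</data></edge>',
      xml_escape(ed$mirna_id[k]), xml_escape(ed$gene[k]),
      xml_escape(ed$regions[k]), ed$n_sites[k],
      tolower(as.character(ed$seed_verified[k]))))
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, file)
  invisible(file)
}

#' Import a GraphML network written by [exportNetwork()]
#'
#' @param file GraphML path.
#' @return An [InteractionNetwork-class].
#' @export
importNetwork <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  contrast <- xml2::xml_attr(graph, "id")
  get_data <- function(node, key) {
    d <- xml2::xml_find_first(node, sprintf(".//g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nodes <- xml2::xml_find_all(graph, ".//g:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  types <- vapply(nodes, get_data, character(1L), key = "ntype")
  is_mi <- types == "mirna"
  mirnas <- data.frame(
    mirna_id = ids[is_mi],
    log2_fc = as.numeric(vapply(nodes[is_mi], get_data, character(1L), "lfc")),
    b_statistic = as.numeric(vapply(nodes[is_mi], get_data, character(1L),
                                    "b")),
    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene = ids[!is_mi],
    direction = vapply(nodes[!is_mi], get_data, character(1L), "dir"),
    stringsAsFactors = FALSE)
  enodes <- xml2::xml_find_all(graph, ".//g:edge", ns)
  edges <- data.frame(
    mirna_id = xml2::xml_attr(enodes, "source"),
    gene = xml2::xml_attr(enodes, "target"),
    regions = vapply(enodes, get_data, character(1L), "reg"),
    n_sites = as.integer(vapply(enodes, get_data, character(1L), "ns")),
    seed_verified = vapply(enodes, get_data, character(1L), "sv") == "true",
    stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(mirna_id = character(), gene = character(),
                        regions = character(), n_sites = integer(),
                        seed_verified = logical())
  new("InteractionNetwork", mirnas = mirnas, genes = genes, edges = edges,
      contrast = contrast)
}
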