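make_de <- function(ids, called = TRUE) {
  data.frame(feature = ids, log2_fc = seq_along(ids) / 2,
             b_statistic = 2, called = called)
}
make_events <- function(genes, called = TRUE, direction = "inclusion") {
  data.frame(gene = genes, inclusion_probe_set = paste0(genes, "_incl"),
             exclusion_probe_set = paste0(genes, "_excl"),
             direction = direction, called = called)
}
full_table <- function(mirnas, genes, region = "3UTR") {
  expand.grid(mirna_id = mirnas, gene = genes,
              stringsAsFactors = FALSE) |>
    transform(region = region, site_offset = 0)
}

test_that("edges require DE call, splice call, and a prediction", {
  de <- make_de(c("m1", "m2"))
  ev <- make_events(c("gA", "gB", "gC"))
  tab <- full_table(c("m1", "m2"), c("gA", "gB", "gC"))
  net <- buildNetwork(de, ev, tab, "HC_vs_PD")
  expect_equal(nrow(networkEdges(net)), 6L)

  ## empty prediction table: no edges regardless of calls
  net0 <- buildNetwork(de, ev, tab[0, ], "HC_vs_PD")
  expect_equal(nrow(networkEdges(net0)), 0L)

  ## a non-called miRNA contributes no edges even if predicted
  de2 <- make_de(c("m1", "m2")); de2$called[2] <- FALSE
  net2 <- buildNetwork(de2, ev, tab, "HC_vs_PD")
  expect_true(all(networkEdges(net2)$mirna_id == "m1"))

  expect_warning(buildNetwork(de2[0, ], ev, tab, "HC_vs_PD"), "empty")

  ## edge-gate soundness: recount every edge against the inputs
  ed <- networkEdges(net2)
  for (k in seq_len(nrow(ed))) {
    expect_true(ed$mirna_id[k] %in% de2$feature[de2$called])
    expect_true(ed$gene[k] %in% ev$gene[ev$called])
    expect_true(any(tab$mirna_id == ed$mirna_id[k] &
                      tab$gene == ed$gene[k]))
  }
})

test_that("multi-region predictions collapse to one edge with a region set", {
  de <- make_de("m1")
  ev <- make_events("gA")
  tab <- data.frame(mirna_id = "m1", gene = "gA",
                    region = c("3UTR", "CDS"), site_offset = c(0, 10))
  net <- buildNetwork(de, ev, tab, "HC_vs_PD")
  ed <- networkEdges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$regions, "CDS,3UTR")
  expect_equal(ed$n_sites, 2L)
})

test_that("region distributions count incidences and sites per gene", {
  de <- make_de(c("m1", "m2"))
  ev <- make_events(c("gA", "gB"))
  tab <- data.frame(mirna_id = c("m1", "m1", "m2", "m2"),
                    gene = c("gA", "gA", "gA", "gB"),
                    region = c("3UTR", "3UTR", "CDS", "5UTR"),
                    site_offset = c(0, 5, 0, 0))
  net <- buildNetwork(de, ev, tab, "HC_vs_PD")
  rd <- regionDistribution(net)
  ## incidences: m1-gA {3UTR}, m2-gA {CDS}, m2-gB {5UTR} -> 1/3 each
  expect_equal(unname(rd$fractions), c(1, 1, 1) / 3)
  expect_equal(sum(rd$fractions), 1, tolerance = 1e-12)
  expect_equal(rd$total_sites, 4L)
  expect_equal(rd$n_edges, 3L)

  ## an average of 2.58 sites per gene prints as the familiar 2.6
  expect_equal(round(560 / 217, 1), 2.6)

  rd0 <- regionDistribution(buildNetwork(de, ev, tab[0, ], "x_vs_y"))
  expect_equal(rd0$n_edges, 0L)
  expect_equal(unname(rd0$fractions), c(0, 0, 0))
})

test_that("seed scanning matches its definition and a brute-force oracle", {
  ## positions 2-8 of UAGCAGCACGUA are AGCAGCA; motif TGCTGCT at offset 3
  hits <- seedScan("UAGCAGCACGUA", "AAATGCTGCTAAA")
  expect_equal(hits$match_offset, 3L)
  expect_equal(hits$motif[1], "TGCTGCT")

  expect_equal(nrow(seedScan("UAGCAGCACGUA", "AAACCCGGGTTT")), 0L)
  two <- seedScan("UAGCAGCACGUA", strrep("TGCTGCT", 2))
  expect_equal(two$match_offset, c(0L, 7L))
  expect_equal(nrow(seedScan("UAGCAGCACGUA", "TGCTG")), 0L)

  ## brute-force cross-check on random pairs
  set.seed(1)
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  for (i in 1:300) {
    mi <- rand_rna(1, sample(18:24, 1))
    probe <- rand_dna(1, sample(10:60, 1))
    got <- seedScan(mi, probe)$match_offset
    seed <- substr(mi, 2, 8)
    motif <- paste(rev(comp[strsplit(seed, "")[[1]]]), collapse = "")
    want <- integer()
    if (nchar(probe) >= 7)
      for (o in 0:(nchar(probe) - 7))
        if (substr(probe, o + 1, o + 7) == motif) want <- c(want, o)
    expect_identical(got, want)
  }
})

test_that("seed verification only counts called junction probes", {
  ref <- MiRNAReference(data.frame(
    precursor_id = "p1", mature_id = "m1",
    sequence = "UAGCAGCACGUAAUCGAUCGAU", star_flag = FALSE))
  de <- make_de("m1")
  ev <- rbind(make_events("gA"), make_events("gB"))
  ev$called <- c(TRUE, FALSE)
  tab <- full_table("m1", c("gA", "gB"))
  net <- buildNetwork(de, ev[ev$called | TRUE, ], tab, "HC_vs_PD")
  ## motif TGCTGCT present in gA's called probe and gB's non-called probe
  pseq <- c(gA_incl = "AATGCTGCTAA", gA_excl = "CCCCCCCCCC",
            gB_incl = "AATGCTGCTAA", gB_excl = "CCCCCCCCCC")
  ver <- verifyNetworkSeeds(net, ev, pseq, ref)
  ed <- networkEdges(ver$network)
  expect_true(ed$seed_verified[ed$gene == "gA"])
  ## gB's motif sits in a probe whose event was not called: not verified
  if (any(ed$gene == "gB"))
    expect_false(ed$seed_verified[ed$gene == "gB"])
  ## summary equals an independent recount
  expect_equal(ver$summary$n_verified, sum(ed$seed_verified))
})

test_that("SIF and GraphML exports round-trip and stay canonical", {
  de <- make_de(c("m1", "m2"))
  ev <- make_events(c("gA", "gB", "gC"))
  tab <- full_table(c("m1", "m2"), c("gA", "gB", "gC"))
  net <- buildNetwork(de, ev, tab, "HC_vs_PD")

  sif <- tempfile(fileext = ".sif")
  exportNetwork(net, sif, "SIF")
  expect_equal(length(readLines(sif)), 6L)

  gml <- tempfile(fileext = ".graphml")
  exportNetwork(net, gml, "GraphML")
  back <- importNetwork(gml)
  gml2 <- tempfile(fileext = ".graphml")
  exportNetwork(back, gml2, "GraphML")
  expect_identical(readLines(gml), readLines(gml2))
  expect_equal(networkEdges(back), networkEdges(net))

  ## an empty network still yields a valid, importable document
  empty <- suppressWarnings(buildNetwork(de[0, ], ev, tab, "HC_vs_PD"))
  gml0 <- tempfile(fileext = ".graphml")
  exportNetwork(empty, gml0, "GraphML")
  back0 <- importNetwork(gml0)
  expect_equal(nrow(networkEdges(back0)), 0L)

  expect_error(exportNetwork(net, tempfile(), "DOT"))
})

test_that("the GraphML writer is readable by an independent parser", {
  skip_if_not_installed("igraph")
  de <- make_de(c("m1", "m2"))
  ev <- make_events(c("gA", "gB"))
  tab <- full_table(c("m1", "m2"), c("gA", "gB"))
  net <- buildNetwork(de, ev, tab, "HC_vs_PD")
  gml <- tempfile(fileext = ".graphml")
  exportNetwork(net, gml, "GraphML")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 4L)
  expect_equal(igraph::gsize(g), nrow(networkEdges(net)))
  expect_setequal(igraph::vertex_attr(g, "type"),
                  c("mirna", "mirna", "gene", "gene"))
})
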