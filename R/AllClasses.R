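#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData `colData<-`
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

## ---------------------------------------------------------------------------
## MiRNAReference
## ---------------------------------------------------------------------------

#' MiRNAReference: precursor/mature miRNA reference
#'
#' Holds one row per (precursor, mature) record. Several precursors may share
#' one mature sequence (e.g. two hairpins yielding the same mature product);
#' passenger (star) strands are flagged and carry a "-star" style suffix in
#' their mature identifier.
#'
#' @slot records data.frame with columns `precursor_id`, `mature_id`,
#'   `sequence` (RNA, 18-25 nt over ACGU) and `star_flag` (logical).
#' @export
setClass("MiRNAReference", representation(records = "data.frame"))

setValidity("MiRNAReference", function(object) {
  rec <- object@records
  need <- c("precursor_id", "mature_id", "sequence", "star_flag")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(paste(rec$precursor_id, rec$mature_id)))
    return("duplicated (precursor_id, mature_id) pairs")
  if (any(!grepl("^[ACGU]+$", rec$sequence)))
    return("sequences must be RNA over {A,C,G,U}")
  len <- nchar(rec$sequence)
  if (any(len < 18L | len > 25L))
    return("mature sequences must be 18-25 nt")
  TRUE
})

#' Construct a MiRNAReference from a record table
#' @param records data.frame with columns `precursor_id`, `mature_id`,
#'   `sequence`, `star_flag`.
#' @return A [MiRNAReference-class] object.
#' @export
MiRNAReference <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  new("MiRNAReference", records = records)
}

#' @describeIn MiRNAReference-class number of (precursor, mature) records
#' @param x,object A `MiRNAReference`.
#' @export
setMethod("length", "MiRNAReference", function(x) nrow(x@records))

#' Access the record table of a miRNA reference
#' @param x A [MiRNAReference-class].
#' @return data.frame of records.
#' @export
referenceRecords <- function(x) {
  stopifnot(is(x, "MiRNAReference"))
  x@records
}

#' Mature sequences of a miRNA reference
#'
#' One entry per distinct (mature_id, sequence) pair, named by mature_id.
#'
#' @param x A [MiRNAReference-class].
#' @return A named [Biostrings::RNAStringSet].
#' @export
matureSeqs <- function(x) {
  stopifnot(is(x, "MiRNAReference"))
  rec <- unique(x@records[, c("mature_id", "sequence")])
  Biostrings::RNAStringSet(setNames(rec$sequence, rec$mature_id))
}

setMethod("show", "MiRNAReference", function(object) {
  rec <- object@records
  cat("MiRNAReference with", nrow(rec), "records;",
      length(unique(rec$sequence)), "distinct mature sequences;",
      sum(rec$star_flag), "passenger-strand records\n")
})

## ---------------------------------------------------------------------------
## StudyDesign
## ---------------------------------------------------------------------------

#' StudyDesign: the four-state leukocyte study layout
#'
#' Fixed ordered conditions HC, PD, DBS_ON, DBS_OFF with a common number of
#' libraries per condition, a table of planted differentially expressed
#' matures, and the seed that fixes all sampling.
#'
#' @slot conditions character, always `c("HC","PD","DBS_ON","DBS_OFF")`.
#' @slot libraries_per_condition integer, libraries per state.
#' @slot planted_de data.frame with columns `mature_id`, `contrast`,
#'   `log2fc`.
#' @slot seed integer seed.
#' @export
setClass("StudyDesign", representation(
  conditions = "character",
  libraries_per_condition = "integer",
  planted_de = "data.frame",
  seed = "integer"
))

setValidity("StudyDesign", function(object) {
  if (!identical(object@conditions, CONDITIONS))
    return("conditions must be HC, PD, DBS_ON, DBS_OFF (in order)")
  if (object@libraries_per_condition < 1L)
    return("libraries_per_condition must be positive")
  pd <- object@planted_de
  if (nrow(pd) && !all(pd$contrast %in% CONTRASTS))
    return(paste("planted contrasts must be one of:",
                 paste(CONTRASTS, collapse = ", ")))
  TRUE
})

#' Construct a StudyDesign
#'
#' @param libraries_per_condition Libraries per state (default 3, the
#'   sequencing arm's three subjects per state).
#' @param planted_de Optional data.frame (`mature_id`, `contrast`, `log2fc`)
#'   of planted fold changes; the change is applied to the contrast's second
#'   group.
#' @param seed Integer seed fixing all sampling downstream.
#' @return A [StudyDesign-class] object.
#' @export
studyDesign <- function(libraries_per_condition = 3L,
                        planted_de = NULL,
                        seed = 1L) {
  if (is.null(planted_de))
    planted_de <- data.frame(mature_id = character(), contrast = character(),
                             log2fc = numeric())
  new("StudyDesign",
      conditions = CONDITIONS,
      libraries_per_condition = as.integer(libraries_per_condition),
      planted_de = as.data.frame(planted_de),
      seed = as.integer(seed))
}

#' Library labels and conditions of a design
#' @param design A [StudyDesign-class].
#' @return data.frame with columns `library` and `condition`.
#' @export
designLibraries <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  n <- design@libraries_per_condition
  data.frame(
    library = paste0(rep(design@conditions, each = n), "_", seq_len(n)),
    condition = rep(design@conditions, each = n),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@conditions), "conditions x",
      object@libraries_per_condition, "libraries;",
      nrow(object@planted_de), "planted DE features; seed",
      object@seed, "\n")
})

## ---------------------------------------------------------------------------
## CountMatrix
## ---------------------------------------------------------------------------

#' CountMatrix: miRNA read counts per library
#'
#' Extends SummarizedExperiment. The `counts` assay holds non-negative
#' integer counts; `colData` carries `library_size` (defined as the column
#' sum of mapped counts), `norm_factor` (positive, default 1) and
#' `condition`; `rowData` carries `precursor_id`, `mature_id` and
#' `star_flag`.
#'
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  y <- assay(object, "counts")
  if (any(y < 0)) return("counts must be non-negative")
  cd <- colData(object)
  if (!all(c("library_size", "norm_factor") %in% names(cd)))
    return("colData must have library_size and norm_factor")
  if (any(cd$norm_factor <= 0)) return("norm factors must be positive")
  TRUE
})

#' Construct a CountMatrix
#'
#' @param counts Integer matrix, features x libraries.
#' @param feature_info data.frame with `precursor_id`, `mature_id`,
#'   `star_flag` (one row per count row).
#' @param condition Optional per-library condition labels.
#' @param norm_factors Optional positive normalisation factors (default 1).
#' @param library_sizes Optional explicit library sizes; by default the
#'   column sums of `counts` (total mapped reads).
#' @return A [CountMatrix-class].
#' @export
CountMatrix <- function(counts, feature_info, condition = NULL,
                        norm_factors = NULL, library_sizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (is.null(condition)) condition <- rep(NA_character_, ncol(counts))
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  cd <- DataFrame(library_size = unname(library_sizes),
                  norm_factor = norm_factors,
                  condition = condition,
                  row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = DataFrame(feature_info),
                             colData = cd)
  new("CountMatrix", se)
}

#' Library sizes (total mapped reads) of a CountMatrix
#' @param x A [CountMatrix-class].
#' @return Numeric vector of per-library totals.
#' @export
librarySizes <- function(x) colData(x)$library_size

#' Normalisation factors of a CountMatrix
#' @param x A [CountMatrix-class].
#' @return Numeric vector of factors (product scaled to 1 by [normFactors()]).
#' @export
normFactorsOf <- function(x) colData(x)$norm_factor

#' Per-library condition labels of a CountMatrix
#' @param x A [CountMatrix-class].
#' @return Character vector of condition labels.
#' @export
conditionsOf <- function(x) as.character(colData(x)$condition)

#' Read counts of a CountMatrix
#' @param x A [CountMatrix-class].
#' @return Numeric matrix of counts.
#' @export
countsOf <- function(x) assay(x, "counts")

setMethod("show", "CountMatrix", function(object) {
  cat("CountMatrix:", nrow(object), "features x", ncol(object),
      "libraries; median library size",
      round(median(librarySizes(object))), "\n")
})

## ---------------------------------------------------------------------------
## ProbeSetMatrix
## ---------------------------------------------------------------------------

PROBE_ROLES <- c("constitutive", "junction_inclusion", "junction_exclusion",
                 "exon_psr")

#' ProbeSetMatrix: log2 probe-set intensities with splicing annotations
#'
#' Extends SummarizedExperiment. The `log2intensity` assay holds log2
#' intensities (probe sets x samples); `rowData` carries `gene`, `role`
#' (constitutive / junction_inclusion / junction_exclusion / exon_psr),
#' `reciprocal_partner` (for junctions), `sequence` (DNA, for seed
#' scanning) and `event_annotation`; `colData` carries `condition`.
#'
#' @export
setClass("ProbeSetMatrix", contains = "SummarizedExperiment")

setValidity("ProbeSetMatrix", function(object) {
  if (!"log2intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'log2intensity' is required")
  x <- assay(object, "log2intensity")
  if (any(!is.finite(x))) return("intensities must be finite")
  rd <- rowData(object)
  if (!all(c("gene", "role") %in% names(rd)))
    return("rowData must have gene and role")
  if (!all(rd$role %in% PROBE_ROLES))
    return(paste("roles must be one of:", paste(PROBE_ROLES, collapse = ", ")))
  inc <- rd$role == "junction_inclusion"
  if (any(inc)) {
    partner <- rd$reciprocal_partner[inc]
    ok <- partner %in% rownames(object)[rd$role == "junction_exclusion"]
    if (!all(ok))
      return("every junction_inclusion needs a junction_exclusion partner")
  }
  TRUE
})

#' Construct a ProbeSetMatrix
#'
#' @param intensity Numeric matrix of log2 intensities, probe sets x samples.
#' @param probe_info data.frame with at least `gene` and `role`; optionally
#'   `reciprocal_partner`, `sequence`, `event_annotation`.
#' @param condition Optional per-sample condition labels.
#' @return A [ProbeSetMatrix-class].
#' @export
ProbeSetMatrix <- function(intensity, probe_info, condition = NULL) {
  intensity <- as.matrix(intensity)
  pi <- as.data.frame(probe_info)
  if (is.null(pi$reciprocal_partner)) pi$reciprocal_partner <- NA_character_
  if (is.null(pi$sequence)) pi$sequence <- NA_character_
  if (is.null(pi$event_annotation)) pi$event_annotation <- NA_character_
  if (is.null(condition)) condition <- rep(NA_character_, ncol(intensity))
  se <- SummarizedExperiment(
    assays = list(log2intensity = intensity),
    rowData = DataFrame(pi),
    colData = DataFrame(condition = condition, row.names = colnames(intensity))
  )
  new("ProbeSetMatrix", se)
}

#' Log2 intensities of a ProbeSetMatrix
#' @param x A [ProbeSetMatrix-class].
#' @return Numeric matrix.
#' @export
intensityOf <- function(x) assay(x, "log2intensity")

#' Probe-set annotations of a ProbeSetMatrix
#' @param x A [ProbeSetMatrix-class].
#' @return data.frame of per-probe-set annotations.
#' @export
probeInfo <- function(x) as.data.frame(rowData(x))

setMethod("show", "ProbeSetMatrix", function(object) {
  rd <- rowData(object)
  cat("ProbeSetMatrix:", nrow(object), "probe sets x", ncol(object),
      "samples;", length(unique(rd$gene)), "genes;",
      sum(rd$role == "junction_inclusion"), "reciprocal junction pairs\n")
})

## ---------------------------------------------------------------------------
## LineageReference
## ---------------------------------------------------------------------------

#' LineageReference: marker genes and centroid profiles per lineage
#'
#' @slot markers data.frame with columns `lineage`, `gene`, `rank`.
#' @slot centroids numeric matrix, marker-union genes x lineages.
#' @export
setClass("LineageReference", representation(
  markers = "data.frame",
  centroids = "matrix"
))

setValidity("LineageReference", function(object) {
  if (!all(c("lineage", "gene", "rank") %in% names(object@markers)))
    return("markers must have lineage, gene, rank")
  if (any(!is.finite(object@centroids)))
    return("centroids must be finite")
  if (!all(unique(object@markers$lineage) %in% colnames(object@centroids)))
    return("every marker lineage needs a centroid column")
  TRUE
})

setMethod("show", "LineageReference", function(object) {
  tab <- table(object@markers$lineage)
  cat("LineageReference:", ncol(object@centroids), "lineages;",
      "markers per lineage", min(tab), "-", max(tab), ";",
      nrow(object@centroids), "genes in marker union\n")
})

#' Marker table of a LineageReference
#' @param x A [LineageReference-class].
#' @return data.frame (`lineage`, `gene`, `rank`).
#' @export
markerTable <- function(x) x@markers

#' Centroid profiles of a LineageReference
#' @param x A [LineageReference-class].
#' @return Matrix, marker-union genes x lineages.
#' @export
centroidsOf <- function(x) x@centroids

## ---------------------------------------------------------------------------
## InteractionNetwork
## ---------------------------------------------------------------------------

REGIONS <- c("5UTR", "CDS", "3UTR")

#' InteractionNetwork: contrast-specific miRNA to spliced-target network
#'
#' Nodes are differentially expressed miRNAs (with direction and B statistic)
#' and alternatively spliced genes (with event direction); an edge exists iff
#' the miRNA is DE-called, the gene has a called splice event, and the pair
#' occurs in the target-prediction table. Multi-region predictions collapse
#' to one edge carrying a region set.
#'
#' @slot mirnas data.frame (`mirna_id`, `log2_fc`, `b_statistic`).
#' @slot genes data.frame (`gene`, `direction`).
#' @slot edges data.frame (`mirna_id`, `gene`, `regions` as
#'   comma-separated labels, `n_sites`, `seed_verified`).
#' @slot contrast character contrast label.
#' @export
setClass("InteractionNetwork", representation(
  mirnas = "data.frame",
  genes = "data.frame",
  edges = "data.frame",
  contrast = "character"
))

setValidity("InteractionNetwork", function(object) {
  ed <- object@edges
  if (nrow(ed)) {
    if (!all(ed$mirna_id %in% object@mirnas$mirna_id))
      return("edge miRNA not among miRNA nodes")
    if (!all(ed$gene %in% object@genes$gene))
      return("edge gene not among gene nodes")
    regs <- unlist(strsplit(ed$regions, ",", fixed = TRUE))
    if (!all(regs %in% REGIONS))
      return("edge regions must be 5UTR/CDS/3UTR")
  }
  TRUE
})

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork [", object@contrast, "]: ",
      nrow(object@mirnas), " miRNAs, ", nrow(object@genes), " genes, ",
      nrow(object@edges), " edges\n", sep = "")
})

#' Edge table of an InteractionNetwork
#' @param x An [InteractionNetwork-class].
#' @return data.frame of edges.
#' @export
networkEdges <- function(x) x@edges

#' miRNA node table of an InteractionNetwork
#' @param x An [InteractionNetwork-class].
#' @return data.frame of miRNA nodes.
#' @export
networkMirnas <- function(x) x@mirnas

#' Gene node table of an InteractionNetwork
#' @param x An [InteractionNetwork-class].
#' @return data.frame of gene nodes.
#' @export
networkGenes <- function(x) x@genes

## ---------------------------------------------------------------------------
## Parameter holders
## ---------------------------------------------------------------------------

#' Trimming parameters for small-RNA reads
#'
#' @param end_trim Terminal tag bases removed first (default 15).
#' @param adapter_5p,adapter_3p Adapter DNA strings; the 5' adapter occurs as
#'   a suffix fragment at the read start, the 3' adapter as a prefix fragment
#'   before the terminal tag.
#' @param sw_match,sw_mismatch,sw_gap Local-alignment scores (match +1,
#'   mismatch -1, gap -2 by default). The scorer evaluates ungapped
#'   end-anchored configurations, so `sw_gap` is kept for interface
#'   completeness.
#' @param min_adapter_overlap Minimum anchored overlap score to excise
#'   (default 6); shorter 3' overlaps are excised only when exact.
#' @param drop_5p_terminal Remove the first remaining base after adapter
#'   excision (default TRUE).
#' @param min_length Minimum surviving read length (default 16, i.e. reads
#'   longer than 15 bases are kept).
#' @return A list of class `TrimParams`.
#' @export
trimParams <- function(end_trim = 15L,
                       adapter_5p = "CCACTACGCCTCCGC",
                       adapter_3p = "CTGACGTGCAATCGAGGCT",
                       sw_match = 1, sw_mismatch = -1, sw_gap = -2,
                       min_adapter_overlap = 6L,
                       drop_5p_terminal = TRUE,
                       min_length = 16L) {
  stopifnot(end_trim >= 0L, min_length >= 1L)
  structure(list(end_trim = as.integer(end_trim),
                 adapter_5p = adapter_5p, adapter_3p = adapter_3p,
                 sw_match = sw_match, sw_mismatch = sw_mismatch,
                 sw_gap = sw_gap,
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 drop_5p_terminal = drop_5p_terminal,
                 min_length = as.integer(min_length)),
            class = "TrimParams")
}

#' Matching parameters for isomiR-tolerant alignment
#'
#' @param max_mismatches Maximum substitutions within the mature overlap
#'   (default 3).
#' @param iso_extend Maximum extra (non-mature) bases tolerated at either
#'   read end (default 2).
#' @param iso_trim Maximum missing mature bases tolerated at either read end
#'   (default 2).
#' @return A list of class `MatchParams`.
#' @export
matchParams <- function(max_mismatches = 3L, iso_extend = 2L, iso_trim = 2L) {
  stopifnot(max_mismatches >= 0L, iso_extend >= 0L, iso_trim >= 0L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 iso_extend = as.integer(iso_extend),
                 iso_trim = as.integer(iso_trim)),
            class = "MatchParams")
}
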