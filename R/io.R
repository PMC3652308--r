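## Shared I/O: FASTQ/FASTA via Biostrings, GMT via fgsea, and the plain
## TSV formats the pipeline exchanges between stages.

#' Write reads as FASTQ with constant Q30 qualities
#'
#' @param reads Named character vector of base-space reads.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeFastq <- function(reads, file) {
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(
    vapply(nchar(reads), function(n) strrep("?", n), character(1L)))
  qdna <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(qdna, file)
  invisible(file)
}

#' Read a FASTQ file into a named character vector
#' @param file FASTQ path.
#' @return Named character vector of reads.
#' @export
readFastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write a miRNA reference as FASTA plus precursor-map TSV
#'
#' @param ref A [MiRNAReference-class].
#' @param fasta_file Mature-sequence FASTA path (one entry per record,
#'   named `precursor_id|mature_id`).
#' @param map_file Precursor-map TSV path.
#' @return `map_file`, invisibly.
#' @export
writeReference <- function(ref, fasta_file, map_file) {
  rec <- referenceRecords(ref)
  seqs <- Biostrings::RNAStringSet(
    setNames(rec$sequence, paste(rec$precursor_id, rec$mature_id, sep = "|")))
  Biostrings::writeXStringSet(seqs, fasta_file)
  write.table(rec, map_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map_file)
}

#' Read a miRNA reference from its precursor-map TSV
#' @param map_file Path written by [writeReference()].
#' @return A [MiRNAReference-class].
#' @export
readReference <- function(map_file) {
  MiRNAReference(read.delim(map_file, stringsAsFactors = FALSE))
}

#' Write a CountMatrix as counts TSV plus feature/library annotation TSVs
#' @param cm A [CountMatrix-class].
#' @param counts_file,features_file,libraries_file Output paths.
#' @return `counts_file`, invisibly.
#' @export
writeCountMatrix <- function(cm, counts_file, features_file,
                             libraries_file) {
  y <- countsOf(cm)
  write.table(data.frame(feature = rownames(y), y, check.names = FALSE),
              counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(feature = rownames(y), as.data.frame(rowData(cm))),
              features_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(library = colnames(y), as.data.frame(colData(cm))),
              libraries_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(counts_file)
}

#' Read a CountMatrix written by [writeCountMatrix()]
#' @param counts_file,features_file,libraries_file Input paths.
#' @return A [CountMatrix-class].
#' @export
readCountMatrix <- function(counts_file, features_file, libraries_file) {
  y <- read.delim(counts_file, check.names = FALSE)
  rownames(y) <- y$feature
  y$feature <- NULL
  feats <- read.delim(features_file, stringsAsFactors = FALSE)
  libs <- read.delim(libraries_file, stringsAsFactors = FALSE)
  cm <- CountMatrix(as.matrix(y), feats[, setdiff(names(feats), "feature")],
                    condition = libs$condition,
                    norm_factors = libs$norm_factor)
  colData(cm)$library_size <- libs$library_size
  cm
}

#' Write a ProbeSetMatrix as intensity TSV plus annotation TSV
#' @param psm A [ProbeSetMatrix-class].
#' @param matrix_file,annotation_file Output paths.
#' @return `matrix_file`, invisibly.
#' @export
writeProbeSetMatrix <- function(psm, matrix_file, annotation_file) {
  x <- intensityOf(psm)
  write.table(data.frame(probe_set = rownames(x), x, check.names = FALSE),
              matrix_file, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- cbind(probe_set = rownames(x), probeInfo(psm))
  write.table(ann, annotation_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrix_file)
}

#' Read a ProbeSetMatrix written by [writeProbeSetMatrix()]
#' @param matrix_file,annotation_file Input paths.
#' @param condition Optional per-sample condition labels.
#' @return A [ProbeSetMatrix-class].
#' @export
readProbeSetMatrix <- function(matrix_file, annotation_file,
                               condition = NULL) {
  x <- read.delim(matrix_file, check.names = FALSE)
  rownames(x) <- x$probe_set
  x$probe_set <- NULL
  ann <- read.delim(annotation_file, stringsAsFactors = FALSE)
  rownames(ann) <- ann$probe_set
  ProbeSetMatrix(as.matrix(x), ann[rownames(x),
                                   setdiff(names(ann), "probe_set")],
                 condition = condition)
}

#' Read gene sets from a GMT file
#' @param file GMT path.
#' @return Named list of character vectors.
#' @export
readGMT <- function(file) {
  fgsea::gmtPathways(file)
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param file Output path.
#' @param description Second-column description (recycled).
#' @return `file`, invisibly.
#' @export
writeGMT <- function(sets, file, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, file)
  invisible(file)
}

#' Write/read a target-prediction table as TSV
#' @param table Prediction data.frame.
#' @param file Path.
#' @return `file` (write) / the data.frame (read).
#' @export
writeTargetTable <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTargetTable
#' @export
readTargetTable <- function(file) {
  read.delim(file, stringsAsFactors = FALSE)
}

#' Write/read a plain numeric matrix as TSV (rows labelled `id`)
#' @param m Numeric matrix.
#' @param file Path.
#' @return `file` (write) / the matrix (read).
#' @export
writeMatrixTSV <- function(m, file) {
  write.table(data.frame(id = rownames(m), m, check.names = FALSE),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(file) {
  x <- read.delim(file, check.names = FALSE)
  rownames(x) <- x$id
  as.matrix(x[, setdiff(names(x), "id"), drop = FALSE])
}
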