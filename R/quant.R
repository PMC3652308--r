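## Small-RNA quantification: adapter trimming, isomiR-tolerant alignment
## against the mature miRNA reference, count merging and CPM filtering.

## Best end-anchored ungapped local-alignment overlap of `adapter` against
## one end of each sequence. Adapters ligate at read termini, so the scorer
## evaluates exactly the anchored configurations of a local alignment:
## for side "3p", read suffixes vs adapter prefixes; for side "5p", read
## prefixes vs adapter suffixes. Score = match*sw_match + mismatch*
## sw_mismatch; overlaps scoring >= min_overlap are excised. For the 3'
## side, shorter overlaps are also excised when they match exactly
## (a partial adapter can end flush with the read). Returns the per-read
## overlap length (0 = none).
anchored_adapter_overlap <- function(seqs, adapter, side = c("3p", "5p"),
                                     min_overlap = 6L, sw_match = 1,
                                     sw_mismatch = -1,
                                     allow_short_exact = FALSE,
                                     max_error = 0.1) {
  side <- match.arg(side)
  n <- length(seqs)
  if (n == 0L) return(integer(0))
  la <- nchar(adapter)
  lens <- nchar(seqs)
  best_k <- integer(n)
  best_score <- rep(-Inf, n)
  a_chars <- strsplit(adapter, "")[[1L]]
  for (k in seq_len(la)) {
    idx <- which(lens >= k)
    if (!length(idx)) next
    if (side == "3p") {
      frag <- substring(seqs[idx], lens[idx] - k + 1L, lens[idx])
      ref <- a_chars[seq_len(k)]
    } else {
      frag <- substring(seqs[idx], 1L, k)
      ref <- a_chars[(la - k + 1L):la]
    }
    mm <- integer(length(idx))
    for (p in seq_len(k))
      mm <- mm + (substring(frag, p, p) != ref[p])
    score <- (k - mm) * sw_match + mm * sw_mismatch
    ## adapter copies must also clear a per-base identity bar, so a long
    ## low-identity overlap cannot tie with (and displace) a clean one
    eligible <- (score >= min_overlap & mm <= floor(k * max_error)) |
      (allow_short_exact & k < min_overlap & mm == 0L)
    better <- eligible & (score > best_score[idx] |
                            (score == best_score[idx] & k > best_k[idx]))
    best_score[idx[better]] <- score[better]
    best_k[idx[better]] <- k
  }
  best_k
}

#' Trim small-RNA reads: terminal tag, adapters, 5' base, length filter
#'
#' Pipeline order: (1) remove the last `end_trim` bases (the sequencing tag
#' end, 50 to 35); (2) locate and excise 5'/3' adapter fragments by
#' end-anchored local alignment scoring at least `min_adapter_overlap`
#' (short exact 3' overlaps are also excised); (3) remove the first
#' remaining base when `drop_5p_terminal`; (4) discard reads shorter than
#' `min_length`. Reads with characters outside ACGTN are rejected and
#' logged.
#'
#' @param reads Character vector of base-space reads (named or not) or a
#'   [Biostrings::DNAStringSet].
#' @param params A [trimParams()] list.
#' @return List: `reads` (surviving trimmed reads, names preserved),
#'   `log` (per-read data.frame: `read_id`, `k5`, `k3`, `status` one of
#'   kept/too_short/invalid_characters), `stats` (list with `n_input`,
#'   `n_kept`, `n_adapter` = reads with any adapter excised,
#'   `adapter_fraction`).
#' @export
trimReads <- function(reads, params = trimParams()) {
  if (is(reads, "XStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads))
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(reads))
  n <- length(reads)
  status <- rep("kept", n)
  valid <- grepl("^[ACGTN]*$", reads)
  status[!valid] <- "invalid_characters"

  ## stage 1: terminal tag-end removal
  body <- reads
  body[valid] <- substr(reads[valid], 1L,
                        pmax(0L, nchar(reads[valid]) - params$end_trim))

  ## stage 2: adapter excision, computed on unique sequences
  k5 <- k3 <- integer(n)
  vidx <- which(valid)
  if (length(vidx)) {
    uniq <- unique(body[vidx])
    u3 <- anchored_adapter_overlap(uniq, params$adapter_3p, "3p",
                                   params$min_adapter_overlap,
                                   params$sw_match, params$sw_mismatch,
                                   allow_short_exact = TRUE)
    u5 <- anchored_adapter_overlap(uniq, params$adapter_5p, "5p",
                                   params$min_adapter_overlap,
                                   params$sw_match, params$sw_mismatch)
    m <- match(body[vidx], uniq)
    k3[vidx] <- u3[m]
    k5[vidx] <- u5[m]
    keep_len <- nchar(body[vidx]) - k3[vidx] - k5[vidx]
    body[vidx] <- ifelse(keep_len > 0L,
                         substr(body[vidx], k5[vidx] + 1L,
                                nchar(body[vidx]) - k3[vidx]),
                         "")
  }

  ## stage 3: 5' terminal nucleotide removal
  if (params$drop_5p_terminal)
    body[valid] <- substr(body[valid], 2L, nchar(body[valid]))

  ## stage 4: length filter
  too_short <- valid & nchar(body) < params$min_length
  status[too_short] <- "too_short"

  keep <- status == "kept"
  log <- data.frame(read_id = ids, k5 = k5, k3 = k3, status = status,
                    stringsAsFactors = FALSE)
  n_adapter <- sum(valid & (k5 > 0L | k3 > 0L))
  list(reads = setNames(body[keep], ids[keep]),
       log = log,
       stats = list(n_input = n, n_kept = sum(keep), n_adapter = n_adapter,
                    adapter_fraction = if (n) n_adapter / n else 0))
}

## Match one read against every mature record, returning the best assignment
## under (fewest mismatches, smallest end shift, lexicographic mature then
## precursor id) or NULL. `mat` is the internal mature table.
match_read <- function(read, mat, params) {
  lr <- nchar(read)
  best <- NULL
  for (i in seq_len(nrow(mat))) {
    lm <- mat$len[i]
    ## s: read-start offset in mature coords (negative = extension);
    ## t: read-end offset past mature end (positive = extension).
    ## lr = lm - s + t  =>  t = s + lr - lm.
    for (s in (-params$iso_extend):params$iso_trim) {
      t <- s + lr - lm
      if (t < -params$iso_trim || t > params$iso_extend) next
      ov_m_start <- max(s, 0L) + 1L
      ov_m_end <- lm + min(t, 0L)
      if (ov_m_end < ov_m_start) next
      ov_r_start <- ov_m_start - s
      ov_r_end <- ov_m_end - s
      mm <- hamming(substr(read, ov_r_start, ov_r_end),
                    substr(mat$seq_dna[i], ov_m_start, ov_m_end))
      if (mm > params$max_mismatches) next
      shift <- abs(s) + abs(t)
      cand <- list(row = i, mm = mm, shift = shift)
      if (is.null(best) || mm < best$mm ||
          (mm == best$mm && shift < best$shift) ||
          (mm == best$mm && shift == best$shift &&
             (mat$mature_id[i] < mat$mature_id[best$row] ||
                (mat$mature_id[i] == mat$mature_id[best$row] &&
                   mat$precursor_id[i] < mat$precursor_id[best$row]))))
        best <- cand
    }
  }
  best
}

## Internal mature table with DNA sequences and a trim-variant dictionary
## for the exact (0-mismatch, no-extension) fast path.
build_matcher <- function(ref, params) {
  rec <- referenceRecords(ref)
  mat <- data.frame(precursor_id = rec$precursor_id,
                    mature_id = rec$mature_id,
                    seq_dna = chartr("U", "T", rec$sequence),
                    stringsAsFactors = FALSE)
  mat$len <- nchar(mat$seq_dna)
  ord <- order(mat$mature_id, mat$precursor_id)
  mat <- mat[ord, , drop = FALSE]
  keys <- list()
  for (i in seq_len(nrow(mat))) {
    for (s in 0:params$iso_trim) {
      for (t in 0:params$iso_trim) {
        if (mat$len[i] - s - t < 1L) next
        key <- substr(mat$seq_dna[i], s + 1L, mat$len[i] - t)
        hit <- data.frame(row = i, mm = 0L, shift = s + t)
        keys[[key]] <- if (is.null(keys[[key]])) hit
                       else rbind(keys[[key]], hit)
      }
    }
  }
  ## resolve each dictionary key to its best candidate up front
  dict <- lapply(keys, function(h) {
    h <- h[order(h$shift, mat$mature_id[h$row], mat$precursor_id[h$row]), ,
           drop = FALSE]
    h[1L, , drop = FALSE]
  })
  list(mat = mat, dict = dict)
}

#' Align trimmed reads to a miRNA reference with isomiR tolerance
#'
#' A read is assigned to a mature record when it matches the mature
#' sequence allowing up to `iso_extend` extra and `iso_trim` missing bases
#' at either end and at most `max_mismatches` substitutions in the
#' overlapping region (extended, non-mature bases are not compared). Each
#' read gets one best assignment, ties broken by (fewest mismatches,
#' smallest end shift, lexicographic mature then precursor id).
#'
#' @param trimmed Per-library trimmed reads: a named list of character
#'   vectors (as in `SmallRNASim$reads` after [trimReads()]) or a single
#'   character vector (treated as one library).
#' @param ref A [MiRNAReference-class].
#' @param params A [matchParams()] list.
#' @param condition Optional per-library condition labels.
#' @return List: `counts` (per-precursor [CountMatrix-class], one row per
#'   (precursor, mature) record), `unmapped` (per-library character vectors
#'   for secondary alignment), `assignments` (per-library data.frame
#'   `read_id`, `precursor_id`, `mature_id`, `mismatches`, `end_shift`),
#'   `stats` (per-library data.frame with mapped counts, perfect-match
#'   fraction and mismatch histogram columns `mm0`..`mm<max>`).
#' @export
alignAndCount <- function(trimmed, ref, params = matchParams(),
                          condition = NULL) {
  stopifnot(is(ref, "MiRNAReference"))
  if (length(ref) == 0L) stop("empty miRNA reference")
  if (!is.list(trimmed)) trimmed <- list(library1 = trimmed)
  if (is.null(names(trimmed)))
    names(trimmed) <- sprintf("library%d", seq_along(trimmed))
  if (all(lengths(trimmed) == 0L))
    warning("empty read set: returning an all-zero count matrix")

  mt <- build_matcher(ref, params)
  mat <- mt$mat

  ## resolve unique read sequences across all libraries once
  all_seqs <- unique(unlist(trimmed, use.names = FALSE))
  res_row <- integer(length(all_seqs)); res_mm <- integer(length(all_seqs))
  res_shift <- integer(length(all_seqs))
  for (u in seq_along(all_seqs)) {
    rd <- all_seqs[u]
    hit <- mt$dict[[rd]]
    if (is.null(hit)) {
      b <- match_read(rd, mat, params)
      if (is.null(b)) { res_row[u] <- 0L; next }
      res_row[u] <- b$row; res_mm[u] <- b$mm; res_shift[u] <- b$shift
    } else {
      res_row[u] <- hit$row; res_mm[u] <- 0L; res_shift[u] <- hit$shift
    }
  }

  feat <- paste(mat$precursor_id, mat$mature_id, sep = ":")
  counts <- matrix(0, nrow(mat), length(trimmed),
                   dimnames = list(feat, names(trimmed)))
  unmapped <- vector("list", length(trimmed))
  names(unmapped) <- names(trimmed)
  assignments <- vector("list", length(trimmed))
  names(assignments) <- names(trimmed)
  stats <- data.frame(library = names(trimmed), n_reads = 0L, n_mapped = 0L,
                      perfect_fraction = NA_real_)
  mmh <- matrix(0L, length(trimmed), params$max_mismatches + 1L,
                dimnames = list(names(trimmed),
                                paste0("mm", 0:params$max_mismatches)))

  for (j in seq_along(trimmed)) {
    rds <- trimmed[[j]]
    idx <- match(rds, all_seqs)
    row <- res_row[idx]
    mapped <- row > 0L
    if (any(mapped))
      counts[, j] <- tabulate(row[mapped], nbins = nrow(mat))
    unmapped[[j]] <- rds[!mapped]
    ids <- names(rds)
    if (is.null(ids)) ids <- sprintf("read%06d", seq_along(rds))
    assignments[[j]] <- data.frame(
      read_id = ids[mapped],
      precursor_id = mat$precursor_id[row[mapped]],
      mature_id = mat$mature_id[row[mapped]],
      mismatches = res_mm[idx][mapped],
      end_shift = res_shift[idx][mapped],
      stringsAsFactors = FALSE)
    stats$n_reads[j] <- length(rds)
    stats$n_mapped[j] <- sum(mapped)
    if (any(mapped)) {
      mmv <- res_mm[idx][mapped]
      stats$perfect_fraction[j] <- mean(mmv == 0L)
      mmh[j, ] <- tabulate(mmv + 1L, nbins = params$max_mismatches + 1L)
    }
  }
  stats <- cbind(stats, as.data.frame(mmh))

  feature_info <- data.frame(precursor_id = mat$precursor_id,
                             mature_id = mat$mature_id,
                             sequence = mat$seq_dna,
                             star_flag = grepl("-star$", mat$mature_id),
                             stringsAsFactors = FALSE)
  cm <- CountMatrix(counts, feature_info, condition = condition)
  list(counts = cm, unmapped = unmapped, assignments = assignments,
       stats = stats)
}

#' Align leftover reads against a filter (non-miRNA) reference
#'
#' Runs the same isomiR-tolerant matcher against a secondary reference of
#' other non-coding RNA sequences (snoRNA/tRNA/SINE-ALU style filter
#' databases) and reports the per-library mapped percentage and mismatch
#' histogram.
#'
#' @param unmapped Per-library character vectors of reads left unmapped by
#'   [alignAndCount()].
#' @param filter_ref A [MiRNAReference-class]-shaped reference of filter
#'   sequences (or any object accepted by [alignAndCount()]).
#' @param params A [matchParams()] list.
#' @return As [alignAndCount()], with `stats` additionally carrying
#'   `mapped_percent`.
#' @export
alignFilterDb <- function(unmapped, filter_ref, params = matchParams()) {
  res <- alignAndCount(unmapped, filter_ref, params)
  res$stats$mapped_percent <-
    ifelse(res$stats$n_reads > 0, 100 * res$stats$n_mapped / res$stats$n_reads,
           0)
  res
}

#' Merge per-precursor counts into per-mature counts
#'
#' Records sharing a mature sequence (several precursors yielding one
#' mature product) are summed into a single mature row; the per-precursor
#' grouping remains available in the input.
#'
#' @param cm A per-precursor [CountMatrix-class] from [alignAndCount()].
#' @return A per-mature [CountMatrix-class]; column sums are conserved.
#' @export
mergeCounts <- function(cm) {
  stopifnot(is(cm, "CountMatrix"))
  rd <- as.data.frame(rowData(cm))
  if (!all(c("mature_id", "sequence") %in% names(rd)))
    stop("inconsistent annotations: need mature_id and sequence in rowData")
  one_seq <- tapply(rd$sequence, rd$mature_id, function(s) length(unique(s)))
  if (any(one_seq != 1L))
    stop("inconsistent annotations: a mature_id maps to several sequences")
  key <- rd$mature_id
  y <- countsOf(cm)
  groups <- sort(unique(key))
  merged <- matrix(0, length(groups), ncol(y),
                   dimnames = list(groups, colnames(y)))
  for (g in groups)
    merged[g, ] <- colSums(y[key == g, , drop = FALSE])
  info <- data.frame(
    precursor_id = vapply(groups, function(g)
      paste(sort(rd$precursor_id[key == g]), collapse = ";"), character(1L)),
    mature_id = groups,
    sequence = vapply(groups, function(g) rd$sequence[key == g][1L],
                      character(1L)),
    star_flag = vapply(groups, function(g) rd$star_flag[key == g][1L],
                       logical(1L)),
    stringsAsFactors = FALSE)
  CountMatrix(merged, info, condition = conditionsOf(cm),
              norm_factors = normFactorsOf(cm))
}

#' Filter features by counts-per-million presence
#'
#' Keeps feature g iff its CPM (`y[g,i] / N[i] * 1e6`) reaches `min_cpm` in
#' at least `min_libraries` libraries. Row order is preserved.
#'
#' @param cm A [CountMatrix-class] with positive library sizes.
#' @param min_cpm CPM threshold (default 1).
#' @param min_libraries Minimum libraries at or above the threshold
#'   (default 3).
#' @return The filtered [CountMatrix-class] (library sizes retained from
#'   the unfiltered totals).
#' @export
cpmFilter <- function(cm, min_cpm = 1, min_libraries = 3L) {
  stopifnot(is(cm, "CountMatrix"))
  N <- librarySizes(cm)
  if (any(N <= 0)) stop("library sizes must be positive")
  if (min_libraries > ncol(cm))
    stop("min_libraries exceeds the number of libraries")
  cpm <- sweep(countsOf(cm), 2L, N, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_libraries
  out <- cm[keep, ]
  colData(out)$library_size <- N   # totals refer to all mapped reads
  out
}
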