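tp <- trimParams()

test_that("trimming follows the tag / adapter / 5'-base / length pipeline", {
  ## 50-base read without adapter content: 50 - 15 (tag) - 1 (5' base) = 34.
  ## Built so neither end collides with an adapter terminus by chance.
  set.seed(1)
  a3_first <- substr(tp$adapter_3p, 1, 1)
  body35 <- paste(c(sample(c("A", "C", "G", "T"), 34, TRUE),
                    setdiff(c("A", "C", "G", "T"), a3_first)[1]),
                  collapse = "")
  read <- paste0(body35, strrep("T", 15))
  out <- trimReads(setNames(read, "r1"), tp)
  expect_equal(unname(nchar(out$reads)), 34L)

  ## post-trim length 15 is discarded ("longer than 15 bases" survive)
  short <- paste0(substr(body35, 1, 16), strrep("T", 15))  # 16 -> 15 kept bases
  out2 <- trimReads(setNames(short, "r1"), tp)
  expect_equal(length(out2$reads), 0L)
  expect_equal(out2$log$status, "too_short")

  ## non-ACGTN characters are rejected per read and logged
  out3 <- trimReads(c(a = "ACXT", b = read), tp)
  expect_equal(out3$log$status[1], "invalid_characters")
  expect_equal(length(out3$reads), 1L)
})

test_that("adapter-flanked inserts are excised down to insert minus 5' base", {
  set.seed(2)
  insert <- rand_dna(1, 22)
  a5 <- substr(tp$adapter_5p, nchar(tp$adapter_5p) - 7, nchar(tp$adapter_5p))
  a3 <- substr(tp$adapter_3p, 1, 35 - 8 - 22)
  read <- paste0(a5, insert, a3, strrep("G", 15))
  expect_equal(nchar(read), 50L)
  out <- trimReads(setNames(read, "r1"), tp)
  ## brute-force oracle: the adapters flank the insert exactly, so the
  ## surviving read is the insert minus its 5' terminal base
  expect_equal(unname(out$reads), substr(insert, 2, nchar(insert)))
  expect_equal(out$stats$n_adapter, 1L)

  ## trimming never increases length; output reads <= input reads
  set.seed(3)
  reads <- vapply(1:50, function(i) paste0(rand_dna(1, 35), strrep("A", 15)),
                  "")
  outs <- trimReads(reads, tp)
  expect_true(all(nchar(outs$reads) <= 35))
  expect_lte(length(outs$reads), length(reads))
})

test_that("isomiR-tolerant matching counts end variants and caps mismatches", {
  ref <- generateMiRNAReference(12, 0, seed = 5)
  rec <- referenceRecords(ref)
  mat <- chartr("U", "T", rec$sequence[1])
  id1 <- paste(rec$precursor_id[1], rec$mature_id[1], sep = ":")

  ## mature + 2 template 3' bases -> counted to that mature
  r_ext <- paste0(mat, "AG")
  res <- alignAndCount(list(L = c(x = r_ext)), ref)
  expect_equal(unname(countsOf(res$counts)[id1, ]), 1)

  ## 4 substitutions -> unmapped (3 allowed at most)
  ch <- strsplit(mat, "")[[1]]
  for (p in c(3, 7, 11, 15)) ch[p] <- setdiff(c("A","C","G","T"), ch[p])[1]
  res4 <- alignAndCount(list(L = c(x = paste(ch, collapse = ""))), ref)
  expect_equal(sum(countsOf(res4$counts)), 0)
  expect_equal(lengths(res4$unmapped)[["L"]], 1L)

  ## exact mature -> counted, perfect-match fraction = 1
  res0 <- alignAndCount(list(L = c(x = mat)), ref)
  expect_equal(unname(countsOf(res0$counts)[id1, ]), 1)
  expect_equal(res0$stats$perfect_fraction, 1)

  ## 3 substitutions still map, and land in the mm3 histogram bin
  ch3 <- strsplit(mat, "")[[1]]
  for (p in c(3, 7, 11)) ch3[p] <- setdiff(c("A","C","G","T"), ch3[p])[1]
  res3 <- alignAndCount(list(L = c(x = paste(ch3, collapse = ""))), ref)
  expect_equal(unname(countsOf(res3$counts)[id1, ]), 1)
  expect_equal(res3$stats$mm3, 1L)
})

test_that("read accounting conserves totals across mapped/filter/unmapped", {
  ref <- generateMiRNAReference(15, 3, seed = 6)
  des <- studyDesign(seed = 7)
  sim <- simulateReads(ref, des, 400, p_iso = 0.2, p_mm = 0.15)
  trimmed <- lapply(sim$reads, function(r) trimReads(r, tp)$reads)
  res <- alignAndCount(trimmed, ref)
  for (lib in names(trimmed)) {
    n_mapped <- sum(countsOf(res$counts)[, lib])
    expect_equal(n_mapped + length(res$unmapped[[lib]]),
                 length(trimmed[[lib]]))
  }
})

test_that("filter-database alignment reuses the matcher faithfully", {
  ref <- generateMiRNAReference(12, 0, seed = 8)
  set.seed(9)
  ## a filter reference of tRNA-fragment-like sequences, distinct from ref
  filt <- MiRNAReference(data.frame(
    precursor_id = sprintf("trf-%02d", 1:8),
    mature_id = sprintf("tRF-%02d", 1:8),
    sequence = rand_rna(8, 21), star_flag = FALSE))

  ## reads drawn from the filter sequences map to the filter db, none to ref
  frag_reads <- chartr("U", "T", referenceRecords(filt)$sequence[1:5])
  names(frag_reads) <- paste0("t", 1:5)
  r_mi <- alignAndCount(list(L = frag_reads), ref)
  expect_equal(sum(countsOf(r_mi$counts)), 0)
  r_f <- alignFilterDb(r_mi$unmapped, filt)
  expect_equal(r_f$stats$mapped_percent, 100)

  ## disjoint read set -> 0% mapped
  set.seed(10)
  rand_reads <- setNames(rand_dna(4, 20), paste0("x", 1:4))
  r0 <- alignFilterDb(list(L = rand_reads), filt)
  expect_equal(r0$stats$mapped_percent, 0)

  ## using the miRNA reference as "filter" reproduces alignAndCount
  mi_reads <- chartr("U", "T", referenceRecords(ref)$sequence[1:6])
  names(mi_reads) <- paste0("m", 1:6)
  a <- alignAndCount(list(L = mi_reads), ref)
  b <- alignFilterDb(list(L = mi_reads), ref)
  expect_identical(countsOf(a$counts), countsOf(b$counts))
})

test_that("merging sums shared-mature precursors and conserves columns", {
  y <- matrix(c(5, 7, 3, 2, 1, 4), 3, 2,
              dimnames = list(c("P1:M", "P2:M", "P3:Q"), c("a", "b")))
  fi <- data.frame(precursor_id = c("P1", "P2", "P3"),
                   mature_id = c("M", "M", "Q"),
                   sequence = c("ACGUACGUACGUACGUAA", "ACGUACGUACGUACGUAA",
                                "UUGCAUGCAUGCAUGCAA"),
                   star_flag = FALSE)
  cm <- CountMatrix(y, fi)
  m <- mergeCounts(cm)
  expect_equal(unname(countsOf(m)["M", ]), c(5 + 7, 2 + 1))
  expect_equal(colSums(countsOf(m)), colSums(y))

  ## no shared matures: merge is the identity on counts
  fi2 <- fi; fi2$mature_id <- c("M1", "M2", "Q")
  fi2$sequence[2] <- "ACGUACGUACGUACGUCC"
  m2 <- mergeCounts(CountMatrix(y, fi2))
  expect_equal(sort(unname(rowSums(countsOf(m2)))), sort(unname(rowSums(y))))

  ## inconsistent annotation (one mature id, two sequences) errors
  fi3 <- fi; fi3$sequence[2] <- "ACGUACGUACGUACGUGG"
  expect_error(mergeCounts(CountMatrix(y, fi3)), "inconsistent")
})

test_that("CPM presence filter applies its boundary and is monotone", {
  y <- rbind(a = c(1, 1, 1, 0), b = c(2, 0, 0, 0), c = c(5, 5, 5, 5))
  colnames(y) <- paste0("s", 1:4)
  cm <- make_cm(y, library_sizes = rep(1e6, 4))
  kept <- rownames(cpmFilter(cm, min_cpm = 1, min_libraries = 3))
  expect_true("a" %in% kept)     # CPM exactly 1 in 3 libraries: retained
  expect_false("b" %in% kept)
  expect_true("c" %in% kept)

  ## min_cpm = 0 is the identity filter
  expect_equal(rownames(cpmFilter(cm, 0, 1)), rownames(y))
  expect_error(cpmFilter(cm, 1, 5), "exceeds")

  ## monotone: raising either threshold never adds features
  set.seed(11)
  y2 <- matrix(rpois(200, 3), 50, 4)
  cm2 <- make_cm(y2, library_sizes = rep(1e6, 4) * c(1, 2, 1, 2))
  for (cpm in c(0.5, 1, 2)) {
    k1 <- rownames(cpmFilter(cm2, cpm, 2))
    k2 <- rownames(cpmFilter(cm2, cpm * 2, 2))
    k3 <- rownames(cpmFilter(cm2, cpm, 3))
    expect_true(all(k2 %in% k1))
    expect_true(all(k3 %in% k1))
  }
})

test_that("noise-free simulated libraries are recovered exactly end to end", {
  ref <- generateMiRNAReference(20, 4, seed = 12)
  des <- studyDesign(seed = 13)
  sim <- simulateReads(ref, des, 800, p_iso = 0, p_mm = 0)
  trimmed <- lapply(sim$reads, function(r) trimReads(r, tp)$reads)
  res <- alignAndCount(trimmed, ref)
  merged <- mergeCounts(res$counts)
  expect_equal(unname(countsOf(merged)[rownames(sim$counts), ]),
               unname(sim$counts * 1.0))
  expect_equal(sum(lengths(res$unmapped)), 0L)
})
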