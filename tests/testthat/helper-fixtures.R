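## Shared fixture builders; everything is generated in code at test time.

## Minimal CountMatrix from a bare matrix.
make_cm <- function(y, condition = NULL, library_sizes = NULL) {
  if (is.null(rownames(y))) rownames(y) <- sprintf("f%04d", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- sprintf("s%02d", seq_len(ncol(y)))
  fi <- data.frame(precursor_id = rownames(y), mature_id = rownames(y),
                   star_flag = FALSE)
  CountMatrix(y, fi, condition = condition, library_sizes = library_sizes)
}

## NB count matrix, G features x (n1 + n2) libraries, planted log2 fold
## changes `lfc` (vector over planted rows) applied to group 2.
make_nb_counts <- function(G, n1 = 3L, n2 = 3L, mu = 200, phi = 0.1,
                           planted = integer(), lfc = numeric(),
                           seed = 1L) {
  set.seed(seed)
  y <- matrix(rnbinom(G * (n1 + n2), mu = mu, size = 1 / phi), G, n1 + n2)
  if (length(planted)) {
    mu2 <- mu * 2^lfc
    y[planted, n1 + seq_len(n2)] <-
      rnbinom(length(planted) * n2, mu = rep(mu2, n2), size = 1 / phi)
  }
  rownames(y) <- sprintf("f%04d", seq_len(G))
  colnames(y) <- sprintf("s%02d", seq_len(n1 + n2))
  y
}

two_groups <- function(n1 = 3L, n2 = 3L)
  factor(rep(c("g1", "g2"), c(n1, n2)), levels = c("g1", "g2"))

## Random DNA/RNA strings.
rand_dna <- function(n, len) vapply(seq_len(n), function(i)
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
rand_rna <- function(n, len) vapply(seq_len(n), function(i)
  paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = ""), "")

## Independent brute-force two-sided conditional binomial exact p
## (doubled smaller tail, capped at 1), by full enumeration.
binom_exact_p <- function(s1, t, prob) {
  if (t == 0) return(1)
  k <- 0:t
  pk <- dbinom(k, t, prob)
  min(1, 2 * min(sum(pk[k <= s1]), sum(pk[k >= s1])))
}

## One demo bundle shared across test files (built once).
demo_env <- new.env()
demo_bundle <- function() {
  if (is.null(demo_env$cfg)) {
    dir <- file.path(tempdir(), "leukosplice-demo")
    demo_env$cfg <- makeDemo(dir, seed = 42L, n_mirnas = 60L, n_star = 10L,
                             mean_depth = 1500, n_genes = 150L,
                             n_events = 20L, n_exon_events = 10L,
                             n_decoys = 5L)
  }
  demo_env$cfg
}
demo_result <- function() {
  if (is.null(demo_env$res))
    demo_env$res <- suppressMessages(runAll(demo_bundle()))
  demo_env$res
}
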