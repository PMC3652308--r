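#' @importFrom methods new validObject is setValidity show slot
#' @importFrom stats rnbinom rpois rnorm runif rbinom cor sd var dist hclust
#'   cutree
#'   lm coef pnorm pt qt dbinom pbinom t.test setNames quantile median
#'   complete.cases optimize digamma trigamma psigamma
#' @importFrom utils head tail write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

CONDITIONS <- c("HC", "PD", "DBS_ON", "DBS_OFF")
CONTRASTS <- c("HC_vs_PD", "PD_vs_DBS_ON", "DBS_ON_vs_DBS_OFF")

#' Split a contrast label into its two condition groups
#'
#' Contrasts are written `"<group1>_vs_<group2>"`; group 1 is the baseline
#' and signed quantities (log2 fold changes, splicing scores) are
#' group 2 over/minus group 1.
#'
#' @param contrast A contrast string such as `"HC_vs_PD"`.
#' @return Character vector of length 2: `c(group1, group2)`.
#' @export
contrastGroups <- function(contrast) {
  stopifnot(is.character(contrast), length(contrast) == 1L)
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("malformed contrast: ", contrast)
  parts
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All generators route through this so they are pure functions of
## (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a reproducible child seed from a base seed and a stream index,
## kept strictly below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + as.numeric(stream) * 12347) %% 2147483587
}

random_seq <- function(n, len, alphabet = DNA_BASES) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len[min(i, length(len))], replace = TRUE),
          collapse = "")
  }, character(1L))
}

## Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

ls_message <- function(...) {
  message("[leukosplice] ", ...)
}
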