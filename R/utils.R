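#' @importFrom stats anova coef cor.test lm pf predict pt rnorm rpois runif
#'   sd setNames t.test aggregate as.formula fitted rbinom
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_cfg <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Check that a numeric scalar lies in a range
#' @noRd
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_cfg("'%s' must be a single number in [0, 1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_cfg("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# DNA helpers on plain character strings (Biostrings objects are used at the
# I/O boundary; the generators work on character vectors for simplicity).
DNA_BASES_CHR <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES_CHR, n, replace = TRUE, prob = p), collapse = "")
}

#' Canonical rotation of a repeat motif: the lexicographically smallest
#' rotation considering both strands, so "TA" and "AT" phasings (and their
#' reverse complements) report the same motif.
#' @noRd
canonical_motif <- function(unit) {
  rots <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n), function(i)
      paste0(substr(s, i, n), substr(s, 1, i - 1L)), character(1))
  }
  min(c(rots(unit), rots(revcomp_chr(unit))))
}
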