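# Low-level sequence string helpers shared across the package.
# Genomes are represented as named character vectors of uppercase
# A/C/G/T/N strings; all coordinates are 0-based half-open internally.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement over the alphabet A/C/G/T/N.
#' Vectorised over its input.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTAA"))
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nzchar(s)) return("")
    chartr("ACGTN", "TGCAN", rawToChar(rev(charToRaw(s))))
  }, character(1), USE.NAMES = FALSE)
}

# Longest common prefix length of two strings, optionally capped.
lcp_len <- function(a, b, max_len = Inf) {
  m <- min(nchar(a), nchar(b), max_len)
  if (m <= 0) return(0L)
  ra <- charToRaw(substr(a, 1L, m))
  rb <- charToRaw(substr(b, 1L, m))
  neq <- which(ra != rb)
  if (length(neq) == 0L) as.integer(m) else neq[1L] - 1L
}

# 0-based half-open substring of a 1-based R string.
substr0 <- function(s, start0, end0) {
  if (end0 <= start0) return("")
  substr(s, start0 + 1L, end0)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(utils::head(names(x)[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-stream seeds so that, e.g., adding sRNA reads does
# not perturb the genome draw. Kept below 2^31 - 1.
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1000 + offset) %% 2147483647)
}
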