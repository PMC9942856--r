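# Terminal direct repeats (pointers), terminal inverted repeats, and
# the geometric null model for repeat-length enrichment.

#' Detect terminal direct repeats (TDRs) at IES boundaries
#'
#' A TDR is a sequence of any length exactly repeated on both ends of
#' the IES, one copy inside the IES and one in the MAC-destined
#' sequence. On a left-normalized context this is the longest common
#' prefix of the IES sequence and the right flank. An IES is
#' "TA-bound" when its TDR (of length at least `min_tdr`) contains
#' the dinucleotide TA anywhere, even if the TDR is longer than 2 bp.
#'
#' @param context left-normalized context ([normalize_left()]).
#' @param min_tdr minimum repeat length for a TDR call (default 2).
#' @param max_tdr maximum repeat length searched (default: flank
#'   length).
#' @return data.frame with `ies_id`, `k` (TDR length), `tdr_seq`,
#'   `klass` in {TA_TDR, OTHER_TDR, NONE}, `ta_offset` (0-based
#'   left-most index of "TA" within the TDR, NA unless TA_TDR).
#' @export
find_tdr <- function(context, min_tdr = 2L, max_tdr = NULL) {
  max_tdr <- max_tdr %||% context$flank_len
  n <- nrow(context)
  k <- integer(n)
  for (i in seq_len(n)) {
    k[i] <- lcp_len(context$seq[i], context$right_flank[i],
                    max_len = min(nchar(context$seq[i]), max_tdr[
                      if (length(max_tdr) > 1L) i else 1L]))
  }
  tdr_seq <- substr(context$seq, 1L, k)
  ta_pos <- regexpr("TA", tdr_seq, fixed = TRUE)
  klass <- ifelse(k < min_tdr, "NONE",
                  ifelse(ta_pos > 0L, "TA_TDR", "OTHER_TDR"))
  data.frame(ies_id = context$id, k = k, tdr_seq = tdr_seq, klass = klass,
             ta_offset = ifelse(klass == "TA_TDR",
                                as.integer(ta_pos) - 1L, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Detect an exact ungapped terminal inverted repeat (TIR)
#'
#' Starting from the ends of the element, each base is compared to
#' the complement of the corresponding base on the opposite end,
#' extending the TIR until the first mismatch, up to a maximum of
#' `cap` bp (default 25; `cap = NULL` disables the cap, as used when
#' curating repeat-family boundaries). The scan never crosses the
#' element midpoint. By default the element starts immediately after
#' the single in-IES TDR copy of a left-normalized record
#' (`tdr_len` bases are stripped from the left end only).
#'
#' @param ies_seq IES sequence (character scalar).
#' @param tdr_len length of the TDR prefix to strip.
#' @param cap maximum TIR length, or NULL for no cap.
#' @param strip which end(s) to strip `tdr_len` bases from:
#'   "left" (default, the in-IES TDR copy), "none", or "both".
#' @return list with `tir_len`, `arm_seq`, `capped`, `cap`,
#'   `element_len`.
#' @export
find_tir <- function(ies_seq, tdr_len = 0L, cap = 25L, strip = c("left", "none", "both")) {
  strip <- match.arg(strip)
  L <- nchar(ies_seq)
  if (tdr_len > L) stop("tdr_len exceeds IES length", call. = FALSE)
  from <- switch(strip, none = 0L, left = tdr_len, both = tdr_len)
  to <- switch(strip, none = L, left = L, both = L - tdr_len)
  element <- substr0(ies_seq, from, to)
  n <- nchar(element)
  if (n <= 0L) {
    return(list(tir_len = 0L, arm_seq = "", capped = FALSE, cap = cap,
                element_len = 0L))
  }
  m <- min(n %/% 2L, if (is.null(cap)) n else cap)
  if (m <= 0L) {
    return(list(tir_len = 0L, arm_seq = "", capped = FALSE, cap = cap,
                element_len = n))
  }
  a <- substr(element, 1L, m)
  b <- revcomp(substr(element, n - m + 1L, n))
  k <- lcp_len(a, b)
  list(tir_len = k, arm_seq = substr(element, 1L, k),
       capped = !is.null(cap) && k == cap, cap = cap, element_len = n)
}

#' TIR detection across a set of IES records
#'
#' @param context left-normalized context.
#' @param tdr TDR results from [find_tdr()].
#' @param cap maximum TIR length (NULL disables).
#' @param strip see [find_tir()].
#' @return data.frame with `ies_id`, `tir_len`, `arm_seq`, `capped`.
#' @export
find_tir_all <- function(context, tdr, cap = 25L, strip = "left") {
  stopifnot(identical(context$id, tdr$ies_id))
  res <- lapply(seq_len(nrow(context)), function(i) {
    find_tir(context$seq[i], tdr_len = tdr$k[i], cap = cap, strip = strip)
  })
  data.frame(ies_id = context$id,
             tir_len = vapply(res, `[[`, integer(1), "tir_len"),
             arm_seq = vapply(res, `[[`, character(1), "arm_seq"),
             capped = vapply(res, `[[`, logical(1), "capped"),
             stringsAsFactors = FALSE)
}

#' Empirical base-frequency null model for terminal repeats
#'
#' Estimates base frequencies p over {A,C,G,T} from a set of
#' sequences (by convention the concatenation of all IES sequences
#' and both flanks) and derives the per-position match probabilities
#' for direct repeats (`m_direct` = sum of p^2) and inverted repeats
#' (`m_inverted` = sum of p * p(complement)). N bases are ignored.
#'
#' @param seqs character vector of sequences, or NULL when `p` given.
#' @param p optional user-supplied frequency vector (named A,C,G,T),
#'   overriding estimation.
#' @return list with `p`, `m_direct`, `m_inverted`, `n_bases`.
#' @export
null_model <- function(seqs = NULL, p = NULL) {
  if (is.null(p)) {
    if (is.null(seqs)) stop("either seqs or p required", call. = FALSE)
    tab <- Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(seqs), as.prob = FALSE)
    counts <- colSums(tab)[DNA_BASES]
    if (sum(counts) == 0) stop("no A/C/G/T bases in input", call. = FALSE)
    p <- counts / sum(counts)
  } else {
    p <- p[DNA_BASES]
    if (anyNA(p) || abs(sum(p) - 1) > 1e-8) {
      stop("p must be named frequencies over A,C,G,T summing to 1",
           call. = FALSE)
    }
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m_direct <- sum(p^2)
  m_inverted <- sum(p * p[comp[DNA_BASES]])
  list(p = p, m_direct = m_direct, m_inverted = m_inverted,
       n_bases = if (is.null(seqs)) NA_real_ else
         sum(nchar(seqs)))
}

#' Expected vs observed counts of terminal repeat lengths
#'
#' Under an i.i.d. base model, the probability that two independent
#' sequences agree on exactly L leading positions (direct mode: base
#' vs base; inverted mode: base vs complement) is geometric:
#' P(L) = m^L * (1 - m). Expected counts are n_ies * P(L). This
#' closed form is the package's explicit stand-in null; it is
#' validated against Monte-Carlo simulation in the test suite.
#'
#' @param observed named integer vector: count of IESs with repeat
#'   length exactly L, names are L values.
#' @param null a [null_model()].
#' @param n_ies total number of IESs scanned.
#' @param mode "direct" (TDR) or "inverted" (TIR).
#' @return data.frame with `L`, `observed`, `expected`, `ratio`
#'   (observed/expected, NA where expected is 0).
#' @export
expected_observed <- function(observed, null, n_ies,
                              mode = c("direct", "inverted")) {
  mode <- match.arg(mode)
  m <- if (mode == "direct") null$m_direct else null$m_inverted
  if (m >= 1) stop("degenerate composition: match probability is 1",
                   call. = FALSE)
  if (n_ies <= 0) stop("n_ies must be positive", call. = FALSE)
  L <- sort(unique(as.integer(names(observed))))
  obs <- as.numeric(observed[as.character(L)])
  expected <- n_ies * m^L * (1 - m)
  ratio <- ifelse(expected > 0, obs / expected, NA_real_)
  data.frame(L = L, observed = obs, expected = expected, ratio = ratio)
}
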