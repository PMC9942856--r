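# Repeat-family downstream analysis: divergence/full-length
# profiling, mobile-IES (MITIES) and nested-copy calling against
# family TIR/TSD signatures, microsatellite unit detection, and
# catalytic-triad motif formatting.

#' Define a repeat-family signature
#'
#' @param name family name.
#' @param tir_consensus TIR consensus sequence (5' arm).
#' @param tsd_motifs character vector of target-site-duplication
#'   motifs; closed under reverse complement automatically.
#' @param consensus_len full-length consensus in bp.
#' @param classification free-text classification label.
#' @param microsat_unit optional microsatellite repeat unit.
#' @return list of class `repeat_family`.
#' @export
repeat_family <- function(name, tir_consensus, tsd_motifs, consensus_len,
                          classification = NA_character_,
                          microsat_unit = NA_character_) {
  if (length(tsd_motifs) == 0L || any(!nzchar(tsd_motifs))) {
    stop("tsd_motifs must be nonempty", call. = FALSE)
  }
  if (!nzchar(tir_consensus)) stop("tir_consensus must be nonempty",
                                   call. = FALSE)
  tsd <- unique(c(toupper(tsd_motifs), revcomp(toupper(tsd_motifs))))
  structure(list(name = name, tir_consensus = toupper(tir_consensus),
                 tsd_motifs = tsd, consensus_len = as.integer(consensus_len),
                 classification = classification,
                 microsat_unit = microsat_unit),
            class = "repeat_family")
}

#' Load repeat-family signatures from TSV
#'
#' Tab-separated with header columns `name`, `tir`, `tsd_list`
#' (comma-separated), `consensus_len`, optional `classification` and
#' `microsat_unit`. The packaged preset
#' `system.file("extdata/families/bstoltei.tsv", package = "ieskit")`
#' carries the published Blepharisma stoltei Bogo/BogoMITE and
#' BstTc1 signatures.
#'
#' @param path TSV file; defaults to the packaged B. stoltei preset.
#' @return named list of [repeat_family()] objects.
#' @export
load_families <- function(path = NULL) {
  path <- path %||% system.file("extdata", "families", "bstoltei.tsv",
                                package = "ieskit", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  fams <- lapply(seq_len(nrow(tab)), function(i) {
    repeat_family(tab$name[i], tab$tir[i],
                  strsplit(tab$tsd_list[i], ",", fixed = TRUE)[[1]],
                  tab$consensus_len[i],
                  classification = if ("classification" %in% names(tab))
                    tab$classification[i] else NA_character_,
                  microsat_unit = if ("microsat_unit" %in% names(tab))
                    tab$microsat_unit[i] else NA_character_)
  })
  stats::setNames(fams, tab$name)
}

#' Divergence and full-length profile of repeat copies
#'
#' A copy is full-length when its length is at least `f_min` times
#' the family consensus length. Returns a percent-divergence
#' histogram and per-subset medians (full-length vs partial).
#'
#' @param copies repeat-copy data.frame ([read_repeat_tsv()]).
#' @param family a [repeat_family()].
#' @param f_min full-length fraction threshold (default 0.95).
#' @param bin histogram bin width in percent (default 1).
#' @return list with `copies` (input plus `full_length` flag),
#'   `histogram` (data.frame `bin_lo`, `count`),
#'   `median_divergence_full`, `median_divergence_partial`,
#'   `n_full`, `n_partial`.
#' @export
divergence_profile <- function(copies, family, f_min = 0.95, bin = 1.0) {
  fam_copies <- copies[copies$family == family$name, , drop = FALSE]
  if (nrow(fam_copies) == 0L) {
    return(list(copies = fam_copies,
                histogram = data.frame(bin_lo = numeric(0), count = integer(0)),
                median_divergence_full = NA_real_,
                median_divergence_partial = NA_real_,
                n_full = 0L, n_partial = 0L))
  }
  fam_copies$full_length <-
    fam_copies$copy_len >= f_min * family$consensus_len
  b <- floor(fam_copies$divergence_pct / bin) * bin
  tab <- table(b)
  hist <- data.frame(bin_lo = as.numeric(names(tab)),
                     count = as.integer(tab))
  list(copies = fam_copies, histogram = hist,
       median_divergence_full =
         stats::median(fam_copies$divergence_pct[fam_copies$full_length]),
       median_divergence_partial =
         stats::median(fam_copies$divergence_pct[!fam_copies$full_length]),
       n_full = sum(fam_copies$full_length),
       n_partial = sum(!fam_copies$full_length))
}

# Collapse homopolymer runs of >= 4 to exactly 4 (option for matching
# TIRs whose poly-C run length is variable, e.g. from assembly error).
collapse_homopolymers <- function(x) {
  gsub("(.)\\1{4,}", "\\1\\1\\1\\1", x)
}

hamming_frac <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    # Length mismatch (possible after homopolymer collapsing):
    # count the length difference as mismatches over the longer.
    n <- max(nchar(a), nchar(b))
    m <- min(nchar(a), nchar(b))
    extra <- n - m
    a <- substr(a, 1L, m); b <- substr(b, 1L, m)
    return((sum(charToRaw(a) != charToRaw(b)) + extra) / n)
  }
  if (nchar(a) == 0L) return(0)
  sum(charToRaw(a) != charToRaw(b)) / nchar(a)
}

#' Call mobile IESs (MITIES) and nested copies against a family
#'
#' An IES is a MOBILE_IES of a family when (i) its TDR equals one of
#' the family's TSD motifs exactly, and (ii) after stripping that TDR
#' prefix, the element begins with the family TIR and ends with its
#' reverse complement, each arm matching with a mismatch fraction at
#' most `max_tir_mismatch_frac`. An IES that is not mobile but
#' contains a provided repeat copy of the family strictly inside its
#' hybrid span (at least `margin` bp from either end) is NESTED;
#' otherwise NONE.
#'
#' @param context left-normalized context with hybrid spans filled
#'   (run [insert_ies()] first when nested calling is wanted).
#' @param tdr TDR results from [find_tdr()].
#' @param family a [repeat_family()].
#' @param max_tir_mismatch_frac per-arm mismatch tolerance
#'   (default 0.1).
#' @param nested_copies optional repeat-copy data.frame on the hybrid
#'   assembly for NESTED calls.
#' @param margin minimum interior distance in bp for a nested copy.
#' @param collapse collapse homopolymer runs >= 4 before TIR
#'   comparison (default FALSE).
#' @return data.frame with `ies_id`, `family`, `status` in
#'   {MOBILE_IES, NESTED, NONE}, `tir_mismatch_frac` (max over the
#'   two arms; NA when not evaluated), `tsd_matched`.
#' @export
detect_mities <- function(context, tdr, family, max_tir_mismatch_frac = 0.1,
                          nested_copies = NULL, margin = 5L,
                          collapse = FALSE) {
  if (!inherits(family, "repeat_family")) {
    stop("family must be a repeat_family", call. = FALSE)
  }
  stopifnot(identical(context$id, tdr$ies_id))
  tl <- nchar(family$tir_consensus)
  cons <- if (collapse) collapse_homopolymers(family$tir_consensus)
          else family$tir_consensus
  n <- nrow(context)
  status <- rep("NONE", n)
  mism <- rep(NA_real_, n)
  tsd_ok <- tdr$tdr_seq %in% family$tsd_motifs & tdr$k > 0L
  for (i in seq_len(n)) {
    el <- substr0(context$seq[i], tdr$k[i], nchar(context$seq[i]))
    if (collapse) el <- collapse_homopolymers(el)
    ne <- nchar(el)
    tlc <- nchar(cons)
    if (tsd_ok[i] && ne >= 2L * tlc) {
      a5 <- substr(el, 1L, tlc)
      a3 <- revcomp(substr(el, ne - tlc + 1L, ne))
      f <- max(hamming_frac(a5, cons), hamming_frac(a3, cons))
      mism[i] <- f
      if (f <= max_tir_mismatch_frac) status[i] <- "MOBILE_IES"
    }
  }
  if (!is.null(nested_copies)) {
    fc <- nested_copies[nested_copies$family == family$name, , drop = FALSE]
    if (nrow(fc) > 0L) {
      hs <- context$hybrid_start
      he <- context$hybrid_end
      for (i in seq_len(n)) {
        if (status[i] != "NONE" || is.na(hs[i])) next
        inside <- fc$start >= hs[i] + margin & fc$end <= he[i] - margin &
          fc$contig == context$contig[i]
        if (any(inside)) status[i] <- "NESTED"
      }
    }
  }
  data.frame(ies_id = context$id, family = family$name, status = status,
             tir_mismatch_frac = mism, tsd_matched = tsd_ok,
             stringsAsFactors = FALSE)
}

#' Smallest tandem-repeat unit of a sequence
#'
#' The smallest string period p such that seq\[i\] == seq\[i + p\]
#' for every valid i, computed with the Knuth-Morris-Pratt border
#' (failure) function: p = n - border(n). The copy number n / p may
#' be fractional when the last repeat unit is partial.
#'
#' @param seq nonempty character scalar.
#' @return list with `unit_len`, `unit`, `copies`.
#' @export
smallest_repeat_unit <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence", call. = FALSE)
  if (n == 1L) return(list(unit_len = 1L, unit = seq, copies = 1))
  s <- charToRaw(seq)
  border <- integer(n)
  k <- 0L
  for (i in 2:n) {
    while (k > 0L && s[k + 1L] != s[i]) k <- border[k]
    if (s[k + 1L] == s[i]) k <- k + 1L
    border[i] <- k
  }
  p <- n - border[n]
  list(unit_len = as.integer(p), unit = substr(seq, 1L, p), copies = n / p)
}

#' Format a transposase catalytic-triad motif string
#'
#' DDE/D-superfamily transposases carry three conserved acidic
#' residues; the conventional shorthand gives the three residue
#' letters with the number of residues between the second and third
#' (e.g. DD35D, DD34E).
#'
#' @param residues three single-letter amino-acid codes.
#' @param positions three strictly increasing integer positions.
#' @return motif string.
#' @export
triad_motif <- function(residues, positions) {
  if (length(residues) != 3L || length(positions) != 3L) {
    stop("need exactly three residues and positions", call. = FALSE)
  }
  if (!all(diff(positions) > 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(!grepl("^[A-Z]$", residues))) {
    stop("residues must be single uppercase letters", call. = FALSE)
  }
  paste0(residues[1], residues[2], positions[3] - positions[2] - 1L,
         residues[3])
}
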