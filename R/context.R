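# IES filtering, flank extraction and left-most normalization of
# floating excision junctions.

#' Filter IES predictions by length and retention score
#'
#' Removes predictions that are more likely to be spurious or too
#' poorly covered for accurate assembly: a record is removed if its
#' length is below `min_len` OR its retention score is present and
#' below `min_score`. Records without a score are never removed on
#' the score criterion.
#'
#' @param ies IES data.frame (see [read_ies_gff()]).
#' @param min_len minimum IES length in bp (default 50).
#' @param min_score minimum retention score (default 0.075).
#' @return list with elements `kept` and `removed`; `removed` gains a
#'   `reason` column ("length", "score" or "length+score").
#' @export
filter_ies <- function(ies, min_len = 50, min_score = 0.075) {
  short <- ies$length < min_len
  low <- !is.na(ies$retention_score) & ies$retention_score < min_score
  drop <- short | low
  reason <- ifelse(short & low, "length+score",
                   ifelse(short, "length", "score"))
  removed <- ies[drop, , drop = FALSE]
  if (nrow(removed) > 0L) removed$reason <- reason[drop]
  else removed$reason <- character(0)
  list(kept = ies[!drop, , drop = FALSE], removed = removed)
}

#' Extract MAC-destined flanks around IES insertion points
#'
#' For each IES, takes up to `flank_len` bp of MAC sequence on either
#' side of the insertion point. Flanks are clipped at contig ends and
#' flagged as truncated. The IES sequence itself comes from the
#' record, not from the genome (it is absent from the MAC product).
#'
#' @param genome named character vector of MAC contigs.
#' @param ies IES data.frame.
#' @param flank_len flank length F in bp (default 50).
#' @return the IES data.frame with added columns `left_flank`,
#'   `right_flank`, `left_truncated`, `right_truncated`, `flank_len`,
#'   `shift` (0 until [normalize_left()]).
#' @export
extract_context <- function(genome, ies, flank_len = 50L) {
  unknown <- setdiff(unique(ies$contig), names(genome))
  if (length(unknown) > 0L) {
    stop("unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ctg <- genome[ies$contig]
  clen <- nchar(ctg)
  if (any(ies$mac_point > clen | ies$mac_point < 0L)) {
    stop("mac_point outside contig for ID(s): ",
         paste(utils::head(ies$id[ies$mac_point > clen | ies$mac_point < 0L], 5),
               collapse = ", "), call. = FALSE)
  }
  ls <- pmax(ies$mac_point - flank_len, 0L)
  out <- ies
  out$left_flank <- substr(ctg, ls + 1L, ies$mac_point)
  out$right_flank <- substr(ctg, ies$mac_point + 1L,
                            pmin(ies$mac_point + flank_len, clen))
  out$left_truncated <- nchar(out$left_flank) < flank_len
  out$right_truncated <- nchar(out$right_flank) < flank_len
  out$flank_len <- as.integer(flank_len)
  out$shift <- 0L
  rownames(out) <- NULL
  out
}

#' Left-normalize floating IES windows
#'
#' When a terminal direct repeat bounds an IES, the exact excision
#' window is ambiguous ("floating"): shifting the window by one
#' within the repeat yields the same MAC product. Calls are therefore
#' reported from the left-most coordinate. While the last base of the
#' left flank equals the last base of the IES, the window is rotated
#' one position left: the IES becomes (that base + IES minus its last
#' base), the insertion point moves left by one, and the displaced
#' base joins the right flank. The MAC product (left flank + right
#' flank) is unchanged, and the operation is idempotent.
#'
#' @param context output of [extract_context()].
#' @return the context with rotated `seq`/flanks/`mac_point` and the
#'   per-record `shift` applied.
#' @export
normalize_left <- function(context) {
  for (i in seq_len(nrow(context))) {
    left <- context$left_flank[i]
    right <- context$right_flank[i]
    s <- context$seq[i]
    L <- nchar(s)
    sh <- 0L
    while (nchar(left) > 0L && L > 0L &&
           substr(left, nchar(left), nchar(left)) == substr(s, L, L)) {
      b <- substr(s, L, L)
      s <- paste0(b, substr(s, 1L, L - 1L))
      left <- substr(left, 1L, nchar(left) - 1L)
      right <- paste0(b, right)
      sh <- sh + 1L
    }
    if (sh > 0L) {
      context$seq[i] <- s
      context$left_flank[i] <- left
      context$right_flank[i] <- right
      context$mac_point[i] <- context$mac_point[i] - sh
      context$shift[i] <- context$shift[i] + sh
    }
  }
  context
}
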