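# MDS-IES junction base-count matrices for TA-bound IESs.

#' Junction base-count matrix for TA-bound IESs
#'
#' For each TA-bound IES, two junction strings are extracted in the
#' orientation 5'-(MDS segment)-TA-(IES segment)-3', anchored on the
#' left-most TA of each TDR copy: the left junction around the TA in
#' the in-IES copy (read in sense), and the right junction around the
#' TA in the right-flank copy (reverse-complemented into the same
#' orientation). Each junction contributes 10 MDS bp ending just
#' before the TA and 14 IES bp starting just after it; the TA itself
#' is excluded, giving 24 positions. Junctions with insufficient
#' sequence on either side are skipped and counted.
#'
#' @param context left-normalized context.
#' @param tdr TDR results from [find_tdr()]; only TA_TDR rows are
#'   accepted.
#' @param mds_len MDS bases per junction (default 10).
#' @param ies_len IES bases per junction (default 14).
#' @return 24 x 4 integer matrix of base counts (rows: positions
#'   MDS-10..MDS-1 then IES+1..IES+14; columns A,C,G,T), with
#'   attributes `n_junctions` (counted) and `n_skipped`.
#' @export
junction_matrix <- function(context, tdr, mds_len = 10L, ies_len = 14L) {
  stopifnot(identical(context$id, tdr$ies_id))
  if (any(tdr$klass != "TA_TDR")) {
    stop("junction_matrix accepts TA-bound IESs only", call. = FALSE)
  }
  w <- mds_len + 2L + ies_len
  junctions <- character(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(context))) {
    t <- tdr$ta_offset[i]
    ies <- context$seq[i]
    # Left junction: TA at 0-based offset t of the in-IES TDR copy,
    # context = left_flank ++ ies.
    hl <- paste0(context$left_flank[i], ies)
    a <- nchar(context$left_flank[i]) + t  # 0-based TA start in hl
    if (a - mds_len >= 0L && a + 2L + ies_len <= nchar(hl)) {
      j <- substr0(hl, a - mds_len, a + 2L + ies_len)
      junctions <- c(junctions, paste0(substr(j, 1L, mds_len),
                                       substr(j, mds_len + 3L, w)))
    } else n_skipped <- n_skipped + 1L
    # Right junction: TA at offset t of the right-flank TDR copy,
    # context = ies ++ right_flank; reverse-complemented so MDS
    # (right flank downstream of the TA) comes first.
    hr <- paste0(ies, context$right_flank[i])
    b <- nchar(ies) + t
    if (b - ies_len >= 0L && b + 2L + mds_len <= nchar(hr)) {
      j <- revcomp(substr0(hr, b - ies_len, b + 2L + mds_len))
      junctions <- c(junctions, paste0(substr(j, 1L, mds_len),
                                       substr(j, mds_len + 3L, w)))
    } else n_skipped <- n_skipped + 1L
  }
  counts <- if (length(junctions) > 0L) {
    t(Biostrings::consensusMatrix(
      Biostrings::DNAStringSet(junctions))[DNA_BASES, , drop = FALSE])
  } else {
    matrix(0L, nrow = mds_len + ies_len, ncol = 4L)
  }
  dimnames(counts) <- list(
    c(paste0("MDS", -(mds_len:1)), paste0("IES+", seq_len(ies_len))),
    DNA_BASES)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  attr(counts, "n_junctions") <- length(junctions)
  attr(counts, "n_skipped") <- n_skipped
  counts
}
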