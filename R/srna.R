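# Developmental small-RNA quantification: length spectra,
# feature-priority read assignment, RPKM, and positional base-bias
# matrices with the 5'-U fraction.

#' Read-length histogram
#'
#' @param reads read-placement data.frame ([read_read_placements()]).
#' @return data.frame with `length`, `count`, `fraction` (fractions
#'   are NA on empty input).
#' @export
length_histogram <- function(reads) {
  tab <- table(reads$length)
  n <- sum(tab)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab),
             fraction = if (n > 0) as.integer(tab) / n else NA_real_)
}

#' Assign reads to feature classes with fixed priority
#'
#' Each read is counted exactly once: reads overlapping any excluded
#' interval (tRNA/rRNA) by at least 1 bp are excluded; otherwise a
#' read is IES if it overlaps any IES interval by at least 1 bp, else
#' CDS by the same rule, else NON. All intervals must be on the same
#' (hybrid MAC + IES) assembly as the placements.
#'
#' @param reads read-placement data.frame.
#' @param ies_intervals,cds_intervals,exclude_intervals data.frames
#'   with `contig`, `start`, `end` (0-based half-open).
#' @param contig_lengths optional named lengths of known contigs, for
#'   validation.
#' @return list with `assignment` (per-read factor of IES/CDS/NON/
#'   EXCLUDED), `counts` (data.frame `read_length` x `feature` with
#'   `count`), `excluded_count`, `total_mapped`.
#' @export
assign_features <- function(reads, ies_intervals, cds_intervals,
                            exclude_intervals = NULL,
                            contig_lengths = NULL) {
  if (!is.null(contig_lengths)) {
    unknown <- setdiff(unique(reads$contig), names(contig_lengths))
    if (length(unknown) > 0L) {
      stop("read placements on unknown contig(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  rg <- GenomicRanges::GRanges(reads$contig,
                               IRanges::IRanges(reads$start + 1L, reads$end))
  as_gr <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(iv$contig, IRanges::IRanges(iv$start + 1L, iv$end))
  }
  in_excl <- suppressWarnings(IRanges::overlapsAny(rg, as_gr(exclude_intervals)))
  in_ies <- suppressWarnings(IRanges::overlapsAny(rg, as_gr(ies_intervals)))
  in_cds <- suppressWarnings(IRanges::overlapsAny(rg, as_gr(cds_intervals)))
  assignment <- ifelse(in_excl, "EXCLUDED",
                       ifelse(in_ies, "IES", ifelse(in_cds, "CDS", "NON")))
  keep <- assignment != "EXCLUDED"
  counts <- as.data.frame(table(read_length = reads$length[keep],
                                feature = factor(assignment[keep],
                                                 levels = c("IES", "CDS", "NON"))),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "count"
  counts$read_length <- as.integer(counts$read_length)
  list(assignment = assignment, counts = counts,
       excluded_count = sum(in_excl), total_mapped = nrow(reads))
}

#' RPKM with feature-type total length
#'
#' Reads per kbp of feature per million reads mapped, computed with
#' the total genomic length of the feature TYPE in place of the
#' transcript length: 1e9 * count / (total_mapped * feature_length).
#'
#' @param count reads assigned to the feature type.
#' @param total_mapped total mapped reads in the library.
#' @param feature_total_length_bp total length of the feature type.
#' @return RPKM (real, >= 0).
#' @export
rpkm <- function(count, total_mapped, feature_total_length_bp) {
  if (any(total_mapped <= 0) || any(feature_total_length_bp <= 0)) {
    stop("total_mapped and feature_total_length_bp must be positive",
         call. = FALSE)
  }
  1e9 * count / (total_mapped * feature_total_length_bp)
}

#' Positional base-bias matrix and 5'-U fraction
#'
#' Frequencies are computed from the read sequences as sequenced
#' (position 1 is the 5' end of the read regardless of genomic
#' strand), so no strand complementing is needed. The 5'-U fraction
#' is the position-1 frequency of T.
#'
#' @param reads read-placement data.frame; all reads must share one
#'   length.
#' @return list with `freq` (length x 4 matrix, rows positions,
#'   columns A,C,G,T), `five_prime_u_fraction`, `n_reads`.
#' @export
base_bias <- function(reads) {
  if (nrow(reads) == 0L) stop("no reads", call. = FALSE)
  if (length(unique(reads$length)) != 1L) {
    stop("mixed read lengths; subset to one length first", call. = FALSE)
  }
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(reads$seq),
                                    as.prob = FALSE)[DNA_BASES, , drop = FALSE]
  tot <- colSums(cm)
  freq <- t(cm) / tot
  dimnames(freq) <- list(paste0("pos", seq_len(nrow(freq))), DNA_BASES)
  list(freq = freq, five_prime_u_fraction = unname(freq[1, "T"]),
       n_reads = nrow(reads))
}

#' Quantify an sRNA time course into one tidy table
#'
#' Runs [assign_features()] and [rpkm()] per time point and
#' concatenates the results, together with per-(length, feature)
#' 5'-U fractions.
#'
#' @param reads_by_time named list of read-placement data.frames
#'   (names are time-point labels).
#' @param ies_intervals,cds_intervals,exclude_intervals interval
#'   data.frames on the hybrid assembly.
#' @param feature_lengths named vector of total feature-type lengths
#'   (IES, CDS, NON) in bp.
#' @param lengths read lengths to report (default c(22, 24)).
#' @return data.frame with `timepoint`, `read_length`, `feature`,
#'   `count`, `rpkm`, `five_prime_u_fraction`.
#' @export
srna_series <- function(reads_by_time, ies_intervals, cds_intervals,
                        exclude_intervals = NULL, feature_lengths,
                        lengths = c(22L, 24L)) {
  rows <- list()
  for (tp in names(reads_by_time)) {
    reads <- reads_by_time[[tp]]
    asg <- assign_features(reads, ies_intervals, cds_intervals,
                           exclude_intervals)
    for (len in lengths) {
      for (feat in c("IES", "CDS", "NON")) {
        cnt <- asg$counts$count[asg$counts$read_length == len &
                                asg$counts$feature == feat]
        cnt <- if (length(cnt) == 0L) 0L else cnt
        sub <- reads[asg$assignment == feat & reads$length == len, ,
                     drop = FALSE]
        u5 <- if (nrow(sub) > 0L) base_bias(sub)$five_prime_u_fraction
              else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          timepoint = tp, read_length = len, feature = feat, count = cnt,
          rpkm = rpkm(cnt, asg$total_mapped, feature_lengths[[feat]]),
          five_prime_u_fraction = u5, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
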