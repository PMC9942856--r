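# Intragenic depletion test.

#' One-sided exact binomial test for intragenic IES depletion
#'
#' If IES insertion points were placed uniformly, the number falling
#' inside genes would be Binomial(n_total, genic_fraction). The
#' depletion p-value is the exact lower-tail probability
#' P(X <= n_intragenic), evaluated in log space so that p-values far
#' below the smallest representable double (p << 1e-300) are still
#' reported meaningfully via their log10.
#'
#' @param n_intragenic observed number of intragenic IESs.
#' @param n_total total number of IESs.
#' @param genic_fraction fraction of the assembly covered by genes.
#' @return list with `p_value` (may underflow to 0), `log10_p`,
#'   `expected` count, and `observed_fraction`.
#' @export
intragenic_depletion_test <- function(n_intragenic, n_total, genic_fraction) {
  if (genic_fraction < 0 || genic_fraction > 1) {
    stop("genic_fraction must be in [0,1]", call. = FALSE)
  }
  if (n_intragenic < 0 || n_intragenic > n_total) {
    stop("n_intragenic must be in [0, n_total]", call. = FALSE)
  }
  logp <- stats::pbinom(n_intragenic, n_total, genic_fraction,
                        lower.tail = TRUE, log.p = TRUE)
  list(p_value = exp(logp),
       log10_p = logp / log(10),
       expected = n_total * genic_fraction,
       observed_fraction = if (n_total > 0) n_intragenic / n_total else NA_real_)
}

#' Count IES insertion points inside genic intervals
#'
#' An insertion point p is intragenic when some genic interval
#' \[start, end) satisfies start < p < end: the IES interrupts the
#' gene body (a point exactly at an interval boundary does not).
#'
#' @param ies IES data.frame.
#' @param genic data.frame of genic intervals (`contig`, `start`,
#'   `end`, 0-based half-open, on the MAC assembly).
#' @return integer count.
#' @export
count_intragenic <- function(ies, genic) {
  if (nrow(genic) == 0L || nrow(ies) == 0L) return(0L)
  # Encode the 0-based point p as integer position p on both sides;
  # the interior of [start, end) is then positions start+1 .. end-1.
  pts <- GenomicRanges::GRanges(ies$contig,
                                IRanges::IRanges(ies$mac_point,
                                                 ies$mac_point))
  keep <- genic$end - genic$start >= 2L
  g <- genic[keep, , drop = FALSE]
  if (nrow(g) == 0L) return(0L)
  gr <- GenomicRanges::GRanges(g$contig,
                               IRanges::IRanges(g$start + 1L, g$end - 1L))
  sum(IRanges::overlapsAny(pts, gr))
}
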