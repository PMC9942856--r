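# One-call driver for the core IES characterization: filtering,
# context extraction, left-normalization, TDR/TIR detection,
# null-model enrichment, length peaks and size classes, junction
# matrix, and the intragenic depletion test.

#' Characterize an IES landscape
#'
#' Runs the full downstream characterization over a MAC genome and a
#' set of IES records. Records whose terminal 25 bp contain N are
#' flagged and excluded from the TDR/TIR statistics.
#'
#' @param genome named character vector of MAC contigs.
#' @param ies IES data.frame ([read_ies_gff()] or the synthetic
#'   generator).
#' @param flank_len MAC-destined flank length in bp.
#' @param min_len,min_score filtering thresholds ([filter_ies()]).
#' @param min_tdr minimum repeat length for a TDR call.
#' @param tir_cap TIR extension cap in bp (NULL disables).
#' @param peak_cutoff length-peak height cutoff.
#' @param periodic_range inclusive periodic length range in bp.
#' @param genic optional data.frame of genic intervals on the MAC
#'   assembly for the intragenic depletion test.
#' @param genic_fraction fraction of the assembly covered by genes;
#'   computed from `genic` when omitted.
#' @return list with components `ies` (kept records), `removed`,
#'   `context`, `tdr`, `tir`, `null`, `expected_observed_direct`,
#'   `expected_observed_inverted`, `peaks`, `period` (NA when fewer
#'   than two periodic peaks), `size_classes`, `junctions`,
#'   `intragenic` (NULL without `genic`), `n_flagged_n`, `summary`.
#' @export
characterize <- function(genome, ies, flank_len = 50L, min_len = 50,
                         min_score = 0.075, min_tdr = 2L, tir_cap = 25L,
                         peak_cutoff = 100L, periodic_range = c(65, 115),
                         genic = NULL, genic_fraction = NULL) {
  flt <- filter_ies(ies, min_len = min_len, min_score = min_score)
  kept <- flt$kept
  ctx <- extract_context(genome, kept, flank_len = flank_len)
  ctx <- normalize_left(ctx)
  # Records with N in their terminal 25 bp are unusable for exact
  # terminal-repeat matching.
  term <- paste0(substr(ctx$seq, 1L, 25L),
                 substr(ctx$seq, pmax(nchar(ctx$seq) - 24L, 1L),
                        nchar(ctx$seq)))
  has_n <- grepl("N", term, fixed = TRUE) |
    grepl("N", ctx$right_flank, fixed = TRUE) |
    grepl("N", ctx$left_flank, fixed = TRUE)
  ctx_ok <- ctx[!has_n, , drop = FALSE]
  tdr <- find_tdr(ctx_ok, min_tdr = min_tdr, max_tdr = flank_len)
  tir <- find_tir_all(ctx_ok, tdr, cap = tir_cap)
  nm <- null_model(c(ctx_ok$seq, ctx_ok$left_flank, ctx_ok$right_flank))
  eo_dir <- expected_observed(table(tdr$k), nm, nrow(tdr), mode = "direct")
  eo_inv <- expected_observed(table(tir$tir_len), nm, nrow(tir),
                              mode = "inverted")
  ta <- tdr$klass == "TA_TDR"
  ta_ids <- tdr$ies_id[ta]
  peaks <- call_length_peaks(ctx_ok$length[ctx_ok$id %in% ta_ids],
                             height_cutoff = peak_cutoff)
  period <- tryCatch(estimate_period(peaks$center, window = periodic_range),
                     error = function(e) NA_real_)
  classes <- assign_size_classes(kept, peaks, periodic_range = periodic_range)
  jm <- junction_matrix(ctx_ok[ta, , drop = FALSE],
                        tdr[ta, , drop = FALSE])
  intragenic <- NULL
  if (!is.null(genic)) {
    gf <- genic_fraction %||%
      (sum(genic$end - genic$start) / sum(nchar(genome)))
    intragenic <- c(intragenic_depletion_test(
      count_intragenic(kept, genic), nrow(kept), gf),
      genic_fraction = gf)
  }
  gc_genome <- {
    cnt <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(genome)))[DNA_BASES]
    unname((cnt["G"] + cnt["C"]) / sum(cnt))
  }
  list(ies = kept, removed = flt$removed, context = ctx, tdr = tdr,
       tir = tir, null = nm, expected_observed_direct = eo_dir,
       expected_observed_inverted = eo_inv, peaks = peaks, period = period,
       size_classes = classes, junctions = jm, intragenic = intragenic,
       n_flagged_n = sum(has_n),
       summary = list(
         n_input = nrow(ies), n_kept = nrow(kept),
         n_removed = nrow(flt$removed), n_flagged_n = sum(has_n),
         genome_gc = gc_genome,
         ta_bound_fraction = mean(ta),
         other_tdr_fraction = mean(tdr$klass == "OTHER_TDR"),
         median_length = stats::median(kept$length),
         n_peaks = nrow(peaks), period = period))
}
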