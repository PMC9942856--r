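# IES length histogram peak calling, periodicity estimation, and
# per-IES size-class assignment.

#' Call peaks on a 1 bp-binned IES length histogram
#'
#' A peak is a histogram bin whose count is strictly greater than
#' both neighbours and at least `height_cutoff`; a maximal plateau of
#' equal counts flanked by strictly smaller counts resolves to its
#' left-most bin. Each peak's size-class range \[lo, hi\] is the width
#' at half peak height: the outermost contiguous run of bins with
#' count >= height/2 around the center.
#'
#' @param lengths integer vector of IES lengths in bp (the histogram
#'   is built internally at 1 bp bins), or a pre-binned named count
#'   vector when `is_histogram = TRUE` (names = bin lengths).
#' @param height_cutoff minimum peak height (default 100).
#' @param is_histogram interpret `lengths` as a named count vector.
#' @return data.frame with `center`, `height`, `lo`, `hi`, `label`
#'   (one row per peak, ascending center), zero rows when none.
#' @export
call_length_peaks <- function(lengths, height_cutoff = 100L,
                              is_histogram = FALSE) {
  empty <- data.frame(center = integer(0), height = numeric(0),
                      lo = integer(0), hi = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (is_histogram) {
    bins <- as.integer(names(lengths))
    cnt <- as.numeric(lengths)
    if (length(bins) == 0L) return(empty)
    lo_bin <- min(bins)
    counts <- numeric(max(bins) - lo_bin + 1L)
    counts[bins - lo_bin + 1L] <- cnt
  } else {
    if (length(lengths) == 0L) return(empty)
    lo_bin <- min(lengths)
    counts <- as.numeric(tabulate(lengths - lo_bin + 1L,
                                  nbins = max(lengths) - lo_bin + 1L))
  }
  # Pad with zero bins so runs at the histogram edges behave like
  # interior runs over an implicitly zero-extended support.
  padded <- c(0, counts, 0)
  r <- rle(padded)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- list()
  for (j in seq_along(r$values)) {
    v <- r$values[j]
    if (v < height_cutoff) next
    left_ok <- j > 1L && r$values[j - 1L] < v
    right_ok <- j < length(r$values) && r$values[j + 1L] < v
    if (!(left_ok && right_ok)) next
    ci <- starts[j] - 1L            # unpadded index of leftmost plateau bin
    center <- lo_bin + ci - 1L
    half <- v / 2
    lo_i <- ci
    while (lo_i > 1L && counts[lo_i - 1L] >= half) lo_i <- lo_i - 1L
    hi_i <- ends[j] - 1L
    if (hi_i > length(counts)) hi_i <- length(counts)
    while (hi_i < length(counts) && counts[hi_i + 1L] >= half) hi_i <- hi_i + 1L
    peaks[[length(peaks) + 1L]] <-
      data.frame(center = center, height = v,
                 lo = lo_bin + lo_i - 1L, hi = lo_bin + hi_i - 1L,
                 label = paste0("peak_", center), stringsAsFactors = FALSE)
  }
  if (length(peaks) == 0L) return(empty)
  out <- do.call(rbind, peaks)
  out[order(out$center), , drop = FALSE]
}

#' Estimate the period of the short-IES length peaks
#'
#' The median of consecutive differences between peak centers that
#' fall inside the periodic window (default 65-115 bp, where the
#' peaks recur every ~10-11 bp).
#'
#' @param peak_centers integer vector of peak centers in bp.
#' @param window inclusive \[lo, hi\] periodic range in bp.
#' @return period in bp (real).
#' @export
estimate_period <- function(peak_centers, window = c(65, 115)) {
  inw <- sort(peak_centers[peak_centers >= window[1] &
                           peak_centers <= window[2]])
  if (length(inw) < 2L) {
    stop("insufficient peaks in periodic window", call. = FALSE)
  }
  stats::median(diff(inw))
}

#' Assign each IES to a length size class
#'
#' An IES is labelled with the peak whose half-height range
#' \[lo, hi\] contains its length; when several peak ranges cover it,
#' the peak with the nearest center wins (ties to the smaller
#' center). IESs covered by no peak are "periodic-offpeak" when their
#' length falls in the periodic range, else "nonperiodic-offpeak".
#'
#' @param ies IES data.frame (uses the `length` column).
#' @param peaks peak table from [call_length_peaks()].
#' @param periodic_range inclusive \[lo, hi\] in bp (default 65-115).
#' @return list with `labels` (character, one per IES, named by id)
#'   and `peaks` (the input peak table).
#' @export
assign_size_classes <- function(ies, peaks, periodic_range = c(65, 115)) {
  labels <- vapply(ies$length, function(len) {
    if (nrow(peaks) > 0L) {
      cover <- which(peaks$lo <= len & len <= peaks$hi)
      if (length(cover) > 0L) {
        d <- abs(len - peaks$center[cover])
        best <- cover[order(d, peaks$center[cover])][1L]
        return(peaks$label[best])
      }
    }
    if (len >= periodic_range[1] && len <= periodic_range[2]) {
      "periodic-offpeak"
    } else {
      "nonperiodic-offpeak"
    }
  }, character(1))
  names(labels) <- ies$id
  list(labels = labels, peaks = peaks, periodic_range = periodic_range)
}
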