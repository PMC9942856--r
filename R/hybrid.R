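# Construction of the hybrid (MAC + IES) assembly, coordinate
# liftover, and the inverse excision operation.

#' Insert IES sequences into the MAC assembly
#'
#' Produces the hybrid MAC + IES assembly: for each contig, every IES
#' sequence is inserted before its `mac_point`, with cumulative
#' offsets. Each record's `hybrid_start`/`hybrid_end` span (0-based
#' half-open on the hybrid) is filled in, and a liftover table maps
#' MAC coordinates to hybrid coordinates. Excising all hybrid spans
#' reproduces the input genome exactly.
#'
#' @param genome named character vector of MAC contigs.
#' @param ies IES data.frame.
#' @return list with `hybrid` (named character vector), `ies` (input
#'   with hybrid spans filled), `liftover` (data.frame `contig`,
#'   `mac_point`, `ies_len`, `cum_offset`).
#' @export
insert_ies <- function(genome, ies) {
  unknown <- setdiff(unique(ies$contig), names(genome))
  if (length(unknown) > 0L) {
    stop("unknown contig(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(ies[, c("contig", "mac_point")])
  if (any(dup)) {
    key <- paste(ies$contig, ies$mac_point)[dup]
    ids <- ies$id[paste(ies$contig, ies$mac_point) %in% key]
    stop("multiple IESs at one insertion point: ",
         paste(utils::head(ids, 10), collapse = ", "), call. = FALSE)
  }
  over <- ies$mac_point > nchar(genome[ies$contig]) | ies$mac_point < 0L
  if (any(over)) {
    stop("mac_point outside contig for: ",
         paste(utils::head(ies$id[over], 5), collapse = ", "), call. = FALSE)
  }
  hybrid <- genome
  out <- ies[order(match(ies$contig, names(genome)), ies$mac_point), ,
             drop = FALSE]
  lift <- list()
  for (ctg in unique(out$contig)) {
    idx <- which(out$contig == ctg)
    pts <- out$mac_point[idx]
    seqs <- out$seq[idx]
    lens <- nchar(seqs)
    offs <- c(0L, cumsum(lens))[seq_along(lens)]
    # Split the MAC contig at the insertion points and interleave.
    bounds <- c(0L, pts, nchar(genome[[ctg]]))
    pieces <- substring(genome[[ctg]], utils::head(bounds, -1) + 1L,
                        utils::tail(bounds, -1))
    interleaved <- character(2L * length(seqs) + 1L)
    interleaved[seq(1L, by = 2L, length.out = length(pieces))] <- pieces
    interleaved[seq(2L, by = 2L, length.out = length(seqs))] <- seqs
    hybrid[[ctg]] <- paste(interleaved, collapse = "")
    out$hybrid_start[idx] <- pts + offs
    out$hybrid_end[idx] <- pts + offs + lens
    lift[[ctg]] <- data.frame(contig = ctg, mac_point = pts, ies_len = lens,
                              cum_offset = offs + lens,
                              stringsAsFactors = FALSE)
  }
  liftover <- if (length(lift) > 0L) do.call(rbind, lift) else
    data.frame(contig = character(0), mac_point = integer(0),
               ies_len = integer(0), cum_offset = integer(0))
  rownames(liftover) <- NULL
  rownames(out) <- NULL
  list(hybrid = hybrid, ies = out, liftover = liftover)
}

#' Lift MAC coordinates to hybrid coordinates
#'
#' A MAC coordinate c maps to c plus the total length of IESs whose
#' insertion point is at or before c.
#'
#' @param liftover liftover table from [insert_ies()].
#' @param contig contig name (scalar or vector).
#' @param pos 0-based MAC coordinate(s).
#' @return 0-based hybrid coordinate(s).
#' @export
lift_coord <- function(liftover, contig, pos) {
  mapply(function(ctg, p) {
    lt <- liftover[liftover$contig == ctg, , drop = FALSE]
    if (nrow(lt) == 0L) return(p)
    i <- findInterval(p, lt$mac_point)
    p + if (i == 0L) 0L else lt$cum_offset[i]
  }, contig, pos, USE.NAMES = FALSE)
}

#' Lift MAC intervals to hybrid intervals
#'
#' Both endpoints are lifted; an interval spanning insertion points
#' therefore widens to include the inserted IES sequence.
#'
#' @param liftover liftover table from [insert_ies()].
#' @param intervals data.frame with `contig`, `start`, `end`.
#' @return the intervals with lifted `start`/`end`.
#' @export
lift_intervals <- function(liftover, intervals) {
  intervals$start <- lift_coord(liftover, intervals$contig, intervals$start)
  intervals$end <- lift_coord(liftover, intervals$contig, intervals$end)
  intervals
}

#' Excise spans from a hybrid genome
#'
#' Removes the given (non-overlapping) 0-based half-open spans from
#' each contig; the inverse of [insert_ies()] when applied to the
#' hybrid spans it reports.
#'
#' @param hybrid named character vector.
#' @param spans data.frame with `contig`, `hybrid_start`,
#'   `hybrid_end` (or `start`/`end`).
#' @return named character vector with spans removed.
#' @export
excise_spans <- function(hybrid, spans) {
  s0 <- spans$hybrid_start %||% spans$start
  e0 <- spans$hybrid_end %||% spans$end
  if (is.null(s0)) s0 <- spans$start
  if (is.null(e0)) e0 <- spans$end
  out <- hybrid
  for (ctg in unique(spans$contig)) {
    idx <- which(spans$contig == ctg)
    ss <- sort(s0[idx])
    ee <- sort(e0[idx])
    if (any(utils::head(ee, -1) > utils::tail(ss, -1))) {
      stop("overlapping spans on contig ", ctg, call. = FALSE)
    }
    bounds_s <- c(0L, ee)
    bounds_e <- c(ss, nchar(hybrid[[ctg]]))
    keep <- substring(hybrid[[ctg]], bounds_s + 1L, bounds_e)
    out[[ctg]] <- paste(keep, collapse = "")
  }
  out
}
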