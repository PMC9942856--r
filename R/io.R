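# Readers and writers for the formats the pipeline touches: FASTA
# genomes, IES annotations in a MILRAA-like GFF3 dialect, BED read
# placements, and the simplified repeat-copy TSV. Everything is
# converted at the boundary to the single internal convention:
# 0-based half-open coordinates.

#' Read a genome FASTA file
#'
#' Sequences are uppercased on read (soft-masking is not used
#' semantically anywhere in the pipeline) and validated against the
#' alphabet A/C/G/T/N.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return named character vector of contig sequences, in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(dss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(dss))
  names(seqs) <- ids
  check_dna(seqs, "genome FASTA")
  seqs
}

#' Write a genome FASTA file
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  dss <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Read IES annotations from a MILRAA-like GFF3 dialect
#'
#' The dialect encodes each IES as a feature on the somatic (MAC)
#' genome whose GFF3 coordinates satisfy `start == end`: the IES is a
#' point insertion, absent from the MAC product, inserted before
#' 0-based MAC position `start`. Column 9 must carry `ID=`; the
#' optional attributes `retention_score=` (fraction of reads
#' supporting the unexcised form, in \[0,1\]) and `seq=` (the IES
#' sequence) are parsed when present. IES sequences missing from the
#' GFF can be supplied through a companion FASTA keyed by ID.
#'
#' @param path GFF3 file.
#' @param genome named character vector (for coordinate validation).
#' @param seq_fasta optional FASTA of IES sequences keyed by ID.
#' @param feature_types feature types (column 3) to keep.
#' @return data.frame with columns `id`, `contig`, `mac_point`
#'   (0-based insertion point), `seq`, `length`, `retention_score`
#'   (NA when absent), `hybrid_start`, `hybrid_end` (NA until
#'   [insert_ies()] fills them).
#' @export
read_ies_gff <- function(path, genome, seq_fasta = NULL,
                         feature_types = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_types)) {
    gr <- gr[as.character(gr$type) %in% feature_types]
  }
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$ID) || anyNA(mc$ID)) {
    stop("GFF3 record(s) without an ID attribute in ", path, call. = FALSE)
  }
  ids <- as.character(mc$ID)
  contig <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(contig), names(genome))
  if (length(unknown) > 0L) {
    stop("GFF3 contig(s) not in genome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  start1 <- GenomicRanges::start(gr)
  end1 <- GenomicRanges::end(gr)
  if (any(start1 != end1)) {
    stop("IES features must be point insertions (GFF start == end); ",
         "offending ID(s): ",
         paste(utils::head(ids[start1 != end1], 5), collapse = ", "),
         call. = FALSE)
  }
  mac_point <- as.integer(start1)  # 1-based start == 0-based insertion point
  too_far <- mac_point > nchar(genome[contig])
  if (any(too_far)) {
    stop("mac_point beyond contig end for ID(s): ",
         paste(utils::head(ids[too_far], 5), collapse = ", "), call. = FALSE)
  }
  score <- if (!is.null(mc$retention_score)) {
    suppressWarnings(as.numeric(as.character(mc$retention_score)))
  } else {
    rep(NA_real_, length(gr))
  }
  bad_score <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad_score)) {
    stop("retention score out of range [0,1] for ID(s): ",
         paste(utils::head(ids[bad_score], 5), collapse = ", "),
         call. = FALSE)
  }
  seqs <- if (!is.null(mc$seq)) toupper(as.character(mc$seq))
          else rep(NA_character_, length(gr))
  if (!is.null(seq_fasta)) {
    fa <- read_genome(seq_fasta)
    hit <- is.na(seqs) & ids %in% names(fa)
    seqs[hit] <- fa[ids[hit]]
  }
  if (anyNA(seqs)) {
    stop("no sequence for IES ID(s): ",
         paste(utils::head(ids[is.na(seqs)], 10), collapse = ", "),
         call. = FALSE)
  }
  names(seqs) <- ids
  check_dna(seqs, "IES sequence")
  data.frame(id = ids, contig = contig, mac_point = mac_point,
             seq = unname(seqs), length = nchar(seqs),
             retention_score = score,
             hybrid_start = NA_integer_, hybrid_end = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Write IES records to the MILRAA-like GFF3 dialect
#'
#' @param ies IES data.frame (see [read_ies_gff()]).
#' @param path output path.
#' @param source value for GFF column 2.
#' @param with_seq embed the sequence in a `seq=` attribute.
#' @return `path`, invisibly.
#' @export
write_ies_gff <- function(ies, path, source = "ieskit", with_seq = TRUE) {
  attrs <- paste0("ID=", ies$id,
                  ifelse(is.na(ies$retention_score), "",
                         paste0(";retention_score=", ies$retention_score)),
                  if (with_seq) paste0(";seq=", ies$seq) else "")
  lines <- paste(ies$contig, source, "internal_eliminated_sequence",
                 ies$mac_point, ies$mac_point, ".", ".", ".", attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read BED3/BED6 intervals
#'
#' BED coordinates are already 0-based half-open and are preserved
#' unchanged. Strand "." is allowed (returned as ".").
#'
#' @param path BED file.
#' @param feature_type label attached to every interval.
#' @return data.frame with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`, `type`.
#' @export
read_bed <- function(path, feature_type = "region") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path,
                           call. = FALSE)
  start <- as.integer(raw[[2]])
  end <- as.integer(raw[[3]])
  bad <- which(!(start < end) | start < 0L)
  if (length(bad) > 0L) {
    stop(sprintf("invalid BED interval (start >= end) at line %d of %s",
                 bad[1], path), call. = FALSE)
  }
  data.frame(
    contig = raw[[1]], start = start, end = end,
    name = if (ncol(raw) >= 4L) raw[[4]] else NA_character_,
    score = if (ncol(raw) >= 5L) suppressWarnings(as.numeric(raw[[5]]))
            else NA_real_,
    strand = if (ncol(raw) >= 6L) ifelse(is.na(raw[[6]]) | raw[[6]] == "",
                                         ".", raw[[6]]) else ".",
    type = feature_type, stringsAsFactors = FALSE)
}

#' Read sRNA read placements from BED6 plus a read FASTA
#'
#' Each BED6 line is one (primary) ungapped placement; the name column
#' is the read id and must key into `seq_fasta`, which holds the read
#' sequences as sequenced (5'->3' regardless of genomic strand).
#'
#' @param bed_path BED6 file of placements.
#' @param seq_fasta FASTA of read sequences keyed by read id.
#' @return data.frame with columns `read_id`, `contig`, `start`,
#'   `end`, `strand`, `length`, `seq`.
#' @export
read_read_placements <- function(bed_path, seq_fasta) {
  bed <- read_bed(bed_path, feature_type = "read")
  if (anyNA(bed$name)) stop("BED6 with read ids required", call. = FALSE)
  fa <- read_genome(seq_fasta)
  missing <- setdiff(bed$name, names(fa))
  if (length(missing) > 0L) {
    stop("no sequence for read id(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  seq <- unname(fa[bed$name])
  len <- bed$end - bed$start
  if (any(nchar(seq) != len)) {
    stop("read sequence length disagrees with BED interval for: ",
         paste(utils::head(bed$name[nchar(seq) != len], 5), collapse = ", "),
         call. = FALSE)
  }
  data.frame(read_id = bed$name, contig = bed$contig, start = bed$start,
             end = bed$end, strand = bed$strand, length = len, seq = seq,
             stringsAsFactors = FALSE)
}

#' Convert feature GFF3 to internal intervals
#'
#' Ordinary (nonzero-length) features: GFF3 1-based inclusive
#' coordinates become 0-based half-open.
#'
#' @param path GFF3 file.
#' @param feature_types optional filter on column 3.
#' @return data.frame with `contig`, `start`, `end`, `strand`, `type`.
#' @export
read_feature_gff <- function(path, feature_types = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_types)) {
    gr <- gr[as.character(gr$type) %in% feature_types]
  }
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(gr$type), stringsAsFactors = FALSE)
}

#' Read repeat copies from the simplified annotation TSV
#'
#' Tab-separated with a header row and '#' comments; required columns
#' `family`, `contig`, `start`, `end` (1-based inclusive, as in
#' RepeatMasker-style outputs) and `divergence_pct` (percent
#' divergence from the family consensus). Converted to the internal
#' 0-based half-open convention.
#'
#' @param path TSV file.
#' @return data.frame with `family`, `contig`, `start`, `end`,
#'   `divergence_pct`, `copy_len`.
#' @export
read_repeat_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("family", "contig", "start", "end", "divergence_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("repeat TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(tab$end < tab$start)
  if (length(bad) > 0L) {
    stop(sprintf("repeat TSV end < start at data line %d", bad[1]),
         call. = FALSE)
  }
  bad_div <- which(tab$divergence_pct < 0)
  if (length(bad_div) > 0L) {
    stop(sprintf("negative divergence at data line %d", bad_div[1]),
         call. = FALSE)
  }
  data.frame(family = tab$family, contig = tab$contig,
             start = as.integer(tab$start) - 1L, end = as.integer(tab$end),
             divergence_pct = as.numeric(tab$divergence_pct),
             copy_len = as.integer(tab$end) - as.integer(tab$start) + 1L,
             stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Records the resolved parameters, seed, package version and input
#' checksums of an analysis run next to its outputs, so that a rerun
#' with identical inputs and seed is identifiable from the manifest
#' alone (timestamps aside).
#'
#' @param out_dir output directory (created if needed).
#' @param step name of the analysis step.
#' @param params named list of resolved parameters.
#' @param inputs character vector of input file paths (checksummed).
#' @param seed integer seed used, or NULL.
#' @return path of the manifest, invisibly.
#' @export
run_manifest <- function(out_dir, step, params = list(), inputs = character(),
                         seed = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sums <- if (length(inputs) > 0L) {
    stats::setNames(as.character(tools::md5sum(inputs)), basename(inputs))
  } else NULL
  manifest <- list(step = step,
                   package_version = as.character(utils::packageVersion("ieskit")),
                   seed = seed, parameters = params, input_md5 = sums,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write sRNA read placements as BED6 plus a read FASTA
#'
#' @param reads read-placement data.frame.
#' @param bed_path,fasta_path output paths.
#' @return `bed_path`, invisibly.
#' @export
write_read_placements <- function(reads, bed_path, fasta_path) {
  lines <- paste(reads$contig, reads$start, reads$end, reads$read_id,
                 0L, reads$strand, sep = "\t")
  writeLines(lines, bed_path)
  write_genome(stats::setNames(reads$seq, reads$read_id), fasta_path)
  invisible(bed_path)
}

#' Write repeat copies to the annotation TSV dialect
#'
#' Internal 0-based half-open coordinates are converted back to the
#' dialect's 1-based inclusive columns.
#'
#' @param copies repeat-copy data.frame (internal convention).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeat_tsv <- function(copies, path) {
  out <- data.frame(family = copies$family, contig = copies$contig,
                    start = copies$start + 1L, end = copies$end,
                    divergence_pct = copies$divergence_pct)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# repeat copies: 1-based inclusive coordinates", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
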