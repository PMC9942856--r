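# Ground-truth synthetic data: an AT-rich somatic genome with genes,
# IESs with periodic and family length structure, planted TDR/TIR/TSD
# signatures, degenerate and nested repeat copies, and time-course
# sRNA reads. Every planted structure is recorded in a truth table so
# each pipeline stage can be tested against known parameters.

#' Default simulation configuration
#'
#' Composition defaults follow the Blepharisma stoltei study system:
#' somatic GC 33.5%, genes covering 77% of the assembly, ~76% of IESs
#' TA-bound, a periodic short-IES range (65-115 bp, ~10 bp period)
#' and nonperiodic family peaks (153/174/228/389 bp), BogoMITE
#' (TSD TAA/TTA, 30 bp TIR) and BstTc1 (TSD TATA, 38 bp TIR, 10 bp
#' microsatellite unit) family signatures, and 22/24 nt dominated
#' sRNA libraries with a 5'-U biased 24 nt class whose IES coverage
#' rises after a mid-development switch. The periodic peak-center
#' preset interpolates between the anchor peaks at 65, 72 and 110 bp
#' and must not be read as a reproduction of the study's full peak
#' table.
#'
#' @param seed integer master seed; sub-streams for genome, IES and
#'   sRNA draws are derived from it.
#' @param ... named overrides of any top-level default.
#' @return nested configuration list.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    contigs = list(n = 4L, length = 500000L),
    gc = 0.335,
    gene_fraction = 0.77,
    gene_len_mean = 2000, gene_len_sd = 400,
    n_trna = 12L, trna_len = 80L,
    ies = list(
      n = 8000L,
      flank_guard = 100L, min_spacing = 60L,
      intragenic_prob = 0.70,
      class_probs = c(ta = 0.759, other = 0.165, none = 0.076),
      ta_motifs = c(TA = 0.70, TAT = 0.10, ATA = 0.10, TATA = 0.10),
      other_k_range = c(2L, 6L),
      periodic_centers = c(65L, 72L, 83L, 93L, 104L, 110L),
      nonperiodic_centers = c(153L, 174L, 228L, 389L),
      peak_sd = 1,
      mix = c(periodic = 0.45, nonperiodic = 0.35, offpeak = 0.20),
      offpeak_range = c(50L, 600L),
      retention_range = c(0.1, 0.9)),
    families = list(
      BogoMITE = list(n_mobile = 30L, n_nested = 8L, n_degenerate = 10L,
                      divergence_pct = 0.5),
      BstTc1 = list(n_mobile = 22L, n_nested = 5L, n_degenerate = 8L,
                    divergence_pct = 0.5)),
    srna = list(
      timepoints = c(2, 6, 10, 14, 22, 30, 38),
      switch_time = 14,
      n_reads = 20000L,
      length_probs = local({
        p <- stats::setNames(rep(0.38 / 11, 13), 18:30)
        p["22"] <- 0.32; p["24"] <- 0.30; p / sum(p)
      }),
      p5u_24_ies = 0.90, p5u_other = 0.25,
      ies24_start = 0.15, ies24_end = 0.60,
      cds24_start = 0.55, cds24_end = 0.25,
      ies22 = 0.05, cds22_start = 0.65, cds22_end = 0.35,
      origin_other = c(IES = 0.10, CDS = 0.50, NON = 0.40))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  stopifnot(cfg$gc > 0, cfg$gc < 1,
            abs(sum(cfg$ies$class_probs) - 1) < 1e-8,
            abs(sum(cfg$ies$mix) - 1) < 1e-8)
  cfg
}

rnd_dna <- function(n, p_base) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p_base), collapse = "")
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Force a mismatch between a core's first base and the complement of
# its last base, so a planted TIR never extends into the core and the
# truth TIR length stays exact.
block_tir_extension <- function(core) {
  n <- nchar(core)
  if (n < 2L) return(core)
  last <- substr(core, n, n)
  comp <- chartr("ACGTN", "TGCAN", last)
  if (substr(core, 1L, 1L) == comp) {
    substr(core, 1L, 1L) <- sample(setdiff(DNA_BASES, comp), 1L)
  }
  core
}

# Mutate a sequence with uniform random point substitutions at the
# given per-base rate (percent).
mutate_seq <- function(seq, divergence_pct) {
  if (divergence_pct <= 0 || nchar(seq) == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < divergence_pct / 100)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate the somatic (MAC) genome with gene and tRNA annotations
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2. Non-overlapping gene
#' intervals are tiled to cover approximately `gene_fraction` of each
#' contig; a few tRNA intervals are placed in intergenic gaps.
#' Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector) and `features`
#'   (data.frame `contig`, `start`, `end`, `strand`, `type` in
#'   {gene, tRNA}, 0-based half-open).
#' @export
simulate_genome <- function(config) {
  set.seed(substream_seed(config$seed, 1L))
  p <- base_probs(config$gc)
  n_ctg <- config$contigs$n
  clen <- rep_len(config$contigs$length, n_ctg)
  genome <- stats::setNames(vapply(seq_len(n_ctg), function(i)
    rnd_dna(clen[i], p), character(1)), paste0("contig_", seq_len(n_ctg)))
  feats <- list()
  f <- config$gene_fraction
  for (i in seq_len(n_ctg)) {
    if (f <= 0) next
    pos <- 0L
    gap_mean <- config$gene_len_mean * (1 - f) / f
    while (pos < clen[i]) {
      gap <- max(0L, round(stats::rnorm(1, gap_mean, gap_mean / 3)))
      glen <- max(200L, round(stats::rnorm(1, config$gene_len_mean,
                                           config$gene_len_sd)))
      gstart <- pos + gap
      gend <- min(gstart + glen, clen[i])
      if (gend - gstart >= 200L) {
        feats[[length(feats) + 1L]] <- data.frame(
          contig = names(genome)[i], start = gstart, end = gend,
          strand = sample(c("+", "-"), 1L), type = "gene",
          stringsAsFactors = FALSE)
      }
      pos <- gend
    }
  }
  features <- if (length(feats) > 0L) do.call(rbind, feats) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), type = character(0))
  # tRNAs into intergenic gaps, clear of gene bodies.
  trna <- list()
  tries <- 0L
  while (length(trna) < config$n_trna && tries < 500L) {
    tries <- tries + 1L
    ci <- sample(n_ctg, 1L)
    s <- sample(clen[ci] - config$trna_len, 1L)
    cand <- c(s, s + config$trna_len)
    g <- features[features$contig == names(genome)[ci] &
                    features$type == "gene", , drop = FALSE]
    if (!any(g$start < cand[2] & cand[1] < g$end)) {
      trna[[length(trna) + 1L]] <- data.frame(
        contig = names(genome)[ci], start = s, end = s + config$trna_len,
        strand = "+", type = "tRNA", stringsAsFactors = FALSE)
    }
  }
  if (length(trna) > 0L) features <- rbind(features, do.call(rbind, trna))
  rownames(features) <- NULL
  list(genome = genome, features = features)
}

# Candidate insertion sites where the genome carries `motif` starting
# at the site (0-based), split into intragenic/intergenic pools.
motif_sites <- function(genome, motif, guard) {
  out <- list()
  for (ctg in names(genome)) {
    if (nzchar(motif)) {
      m <- gregexpr(motif, genome[[ctg]], fixed = TRUE)[[1]]
      pos <- if (m[1] == -1L) integer(0) else as.integer(m) - 1L
    } else {
      pos <- seq.int(guard, nchar(genome[[ctg]]) - guard, by = 7L)
    }
    pos <- pos[pos >= guard & pos <= nchar(genome[[ctg]]) - guard]
    out[[ctg]] <- pos
  }
  out
}

point_in_intervals <- function(contig, pos, intervals, interior = TRUE) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  pad <- if (interior) 1L else 0L
  pts <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, pos))
  iv <- GenomicRanges::GRanges(intervals$contig,
                               IRanges::IRanges(intervals$start + pad,
                                                intervals$end - pad))
  suppressWarnings(IRanges::overlapsAny(pts, iv))
}

#' Simulate IESs and repeat copies, and build the hybrid assembly
#'
#' Generic IESs draw a length from the configured periodic /
#' nonperiodic / offpeak mixture and a TDR class (TA motif, other
#' exact repeat, or none); sites are chosen so that the planted TDR
#' is exact: the motif is present in the MAC-destined right flank,
#' the repeat terminates immediately after it, and the record is
#' already left-normalized (no accidental terminal extension).
#' Mobile-family IESs are built as TSD + TIR + core +
#' revcomp(TIR) inserted where the genome carries the TSD, so the
#' planted TDR equals the TSD; family divergence is applied as
#' uniform random point mutations of the TIR arms. Nested and
#' degenerate family copies are planted strictly inside long host
#' IESs. Excising all planted hybrid spans reproduces the MAC genome
#' byte-for-byte.
#'
#' @param sim_gen output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return list with `ies` (records with hybrid spans), `hybrid`
#'   (named character vector), `liftover`, `copies` (repeat-copy
#'   table on the hybrid assembly), `truth` (per-IES planted
#'   parameters), `features` (MAC features passed through).
#' @export
simulate_ies_repeats <- function(sim_gen, config) {
  set.seed(substream_seed(config$seed, 2L))
  genome <- sim_gen$genome
  genes <- sim_gen$features[sim_gen$features$type == "gene", , drop = FALSE]
  trna <- sim_gen$features[sim_gen$features$type == "tRNA", , drop = FALSE]
  p_base <- base_probs(config$gc)
  guard <- config$ies$flank_guard
  spacing <- config$ies$min_spacing
  fams <- load_families()

  # Occupancy at block granularity to keep insertion points apart.
  blocks <- lapply(genome, function(s)
    logical(nchar(s) %/% spacing + 2L))
  take_site <- function(ctg, p) {
    b <- p %/% spacing + 1L
    idx <- c(b - 1L, b, b + 1L)
    idx <- idx[idx >= 1L & idx <= length(blocks[[ctg]])]
    if (any(blocks[[ctg]][idx])) return(FALSE)
    blocks[[ctg]][b] <<- TRUE
    TRUE
  }

  # Pre-computed site pools per motif, split genic/intergenic. The
  # empty motif (arbitrary point) is keyed as ".point".
  mkey <- function(m) if (nzchar(m)) m else ".point"
  motifs_needed <- unique(c(names(config$ies$ta_motifs), "TAA", "TTA",
                            "TATA", ".point"))
  pools <- list()
  for (m in motifs_needed) {
    sites <- motif_sites(genome, if (m == ".point") "" else m, guard)
    for (ctg in names(sites)) {
      pos <- sites[[ctg]]
      if (length(pos) == 0L) next
      # Exclude sites inside tRNA features (keeps sRNA truth exact).
      in_trna <- point_in_intervals(ctg, pos,
                                    trna[trna$contig == ctg, , drop = FALSE],
                                    interior = FALSE)
      pos <- pos[!in_trna]
      genic <- point_in_intervals(ctg, pos,
                                  genes[genes$contig == ctg, , drop = FALSE],
                                  interior = TRUE)
      pools[[m]][[ctg]] <- list(genic = pos[genic], inter = pos[!genic])
    }
  }
  ctg_weights <- nchar(genome) / sum(nchar(genome))

  # Draw an unoccupied insertion site carrying `motif`. Candidate
  # sites are validated BEFORE claiming occupancy so rejected draws
  # do not consume space; when the requested genic/intergenic pool is
  # effectively exhausted the other pool is used (slightly diluting
  # the intragenic fraction rather than failing).
  draw_site <- function(motif, want_genic, validate = NULL) {
    for (attempt in 1:600) {
      genic_now <- if (attempt <= 400) want_genic else !want_genic
      ctg <- sample(names(genome), 1L, prob = ctg_weights)
      pool <- pools[[mkey(motif)]][[ctg]][[if (genic_now) "genic" else "inter"]]
      if (length(pool) == 0L) next
      p <- pool[sample.int(length(pool), 1L)]
      if (!is.null(validate) && !validate(ctg, p)) next
      if (take_site(ctg, p)) return(list(contig = ctg, p = p))
    }
    stop(sprintf(paste0("insufficient genome space for planted IESs ",
                        "(motif '%s', pools exhausted after %d records)"),
                 motif, length(recs)), call. = FALSE)
  }

  base_at <- function(ctg, pos0) substr(genome[[ctg]], pos0 + 1L, pos0 + 1L)

  recs <- list()
  truths <- list()
  pending_copies <- list()  # element offsets within IES, resolved after insert

  add_record <- function(seq, site, truth_row, copy = NULL) {
    id <- sprintf("IES%05d", length(recs) + 1L)
    recs[[length(recs) + 1L]] <<- data.frame(
      id = id, contig = site$contig, mac_point = site$p, seq = seq,
      length = nchar(seq),
      retention_score = stats::runif(1, config$ies$retention_range[1],
                                     config$ies$retention_range[2]),
      hybrid_start = NA_integer_, hybrid_end = NA_integer_,
      stringsAsFactors = FALSE)
    truth_row$id <- id
    truth_row$length <- nchar(seq)
    truths[[length(truths) + 1L]] <<- as.data.frame(truth_row,
                                                    stringsAsFactors = FALSE)
    if (!is.null(copy)) {
      copy$id <- id
      pending_copies[[length(pending_copies) + 1L]] <<-
        as.data.frame(copy, stringsAsFactors = FALSE)
    }
    id
  }

  # Compose a generic IES of target length with an exact planted TDR.
  make_generic <- function(len, tdr_class, size_class) {
    repeat {
      if (tdr_class == "ta") {
        motif <- sample(names(config$ies$ta_motifs), 1L,
                        prob = config$ies$ta_motifs)
      } else if (tdr_class == "other") {
        motif <- NA
      } else motif <- ""
      want_genic <- stats::runif(1) < config$ies$intragenic_prob
      if (is.na(motif)) {
        # Exact repeat without TA: read a k-mer off a random site,
        # validated before the site is claimed.
        k <- sample(seq(config$ies$other_k_range[1],
                        config$ies$other_k_range[2]), 1L)
        site <- draw_site("", want_genic, validate = function(ctg, p) {
          mot <- substr(genome[[ctg]], p + 1L, p + k)
          !grepl("TA", mot, fixed = TRUE) && !grepl("N", mot, fixed = TRUE)
        })
        motif <- substr(genome[[site$contig]], site$p + 1L, site$p + k)
      } else {
        site <- draw_site(motif, want_genic)
      }
      k <- nchar(motif)
      core_len <- len - k
      if (core_len < 5L) next
      core <- rnd_dna(core_len, p_base)
      # Terminate the TDR exactly at k, and forbid a left shift.
      stop_base <- base_at(site$contig, site$p + k)
      first <- substr(core, 1L, 1L)
      if (first == stop_base) {
        substr(core, 1L, 1L) <- sample(setdiff(DNA_BASES, stop_base), 1L)
      }
      left_last <- base_at(site$contig, site$p - 1L)
      if (substr(core, core_len, core_len) == left_last) {
        substr(core, core_len, core_len) <-
          sample(setdiff(DNA_BASES, left_last), 1L)
      }
      seq <- paste0(motif, core)
      if (tdr_class == "none" && substr(seq, 1L, 1L) ==
            base_at(site$contig, site$p)) {
        substr(seq, 1L, 1L) <- sample(setdiff(
          DNA_BASES, c(base_at(site$contig, site$p), left_last)), 1L)
      }
      return(list(seq = seq, site = site, motif = motif,
                  want_genic = want_genic, size_class = size_class))
    }
  }

  draw_generic_length <- function() {
    bucket <- sample(names(config$ies$mix), 1L, prob = config$ies$mix)
    if (bucket == "periodic") {
      c0 <- sample(config$ies$periodic_centers, 1L)
      list(len = max(50L, round(stats::rnorm(1, c0, config$ies$peak_sd))),
           class = paste0("peak_", c0))
    } else if (bucket == "nonperiodic") {
      c0 <- sample(config$ies$nonperiodic_centers, 1L)
      list(len = max(50L, round(stats::rnorm(1, c0, config$ies$peak_sd))),
           class = paste0("peak_", c0))
    } else {
      list(len = sample(seq(config$ies$offpeak_range[1],
                            config$ies$offpeak_range[2]), 1L),
           class = "offpeak")
    }
  }

  # --- Mobile family IESs -------------------------------------------------
  for (fam_name in names(config$families)) {
    fam_cfg <- config$families[[fam_name]]
    fam <- fams[[fam_name]]
    tir <- fam$tir_consensus
    tl <- nchar(tir)
    core_len <- max(fam$consensus_len - 2L * tl, 60L)
    for (j in seq_len(fam_cfg$n_mobile)) {
      tsd <- sample(fam$tsd_motifs, 1L)
      arm5 <- mutate_seq(tir, fam_cfg$divergence_pct)
      arm3 <- revcomp(mutate_seq(tir, fam_cfg$divergence_pct))
      core <- if (fam_name == "BstTc1" && !is.na(fam$microsat_unit)) {
        ncop <- sample(5:42, 1L)
        micro <- strrep(fam$microsat_unit, ncop)
        rest <- core_len - nchar(micro)
        if (rest < 10L) { micro <- strrep(fam$microsat_unit, 5L)
                          rest <- core_len - nchar(micro) }
        pre <- rnd_dna(rest %/% 2L, p_base)
        paste0(pre, micro, rnd_dna(rest - nchar(pre), p_base))
      } else rnd_dna(core_len, p_base)
      core <- block_tir_extension(core)
      site <- draw_site(tsd, stats::runif(1) < config$ies$intragenic_prob,
                        validate = function(ctg, p) {
        base_at(ctg, p + nchar(tsd)) != substr(arm5, 1L, 1L) &&
          base_at(ctg, p - 1L) != substr(arm3, nchar(arm3), nchar(arm3))
      })
      seq <- paste0(tsd, arm5, core, arm3)
      add_record(seq, site,
                 list(class = "mobile", size_class = fam_name,
                      tdr_motif = tsd, tdr_klass = "TA_TDR",
                      family = fam_name, status = "MOBILE_IES",
                      planted_tir_len = tl),
                 copy = list(family = fam_name, offset = nchar(tsd),
                             copy_len = nchar(seq) - nchar(tsd),
                             divergence_pct = fam_cfg$divergence_pct))
    }
    # Nested full-length copies inside long host IESs.
    for (j in seq_len(fam_cfg$n_nested)) {
      g <- make_generic(sample(700:1200, 1L), "ta", "nested_host")
      elem <- paste0(mutate_seq(tir, fam_cfg$divergence_pct), rnd_dna(
        core_len, p_base), revcomp(mutate_seq(tir, fam_cfg$divergence_pct)))
      off <- sample(seq(50L, max(51L, nchar(g$seq) - 50L)), 1L)
      seq <- paste0(substr(g$seq, 1L, off), elem,
                    substr(g$seq, off + 1L, nchar(g$seq)))
      add_record(seq, g$site,
                 list(class = "nested_host", size_class = "offpeak",
                      tdr_motif = g$motif, tdr_klass = "TA_TDR",
                      family = fam_name, status = "NESTED",
                      planted_tir_len = NA_integer_),
                 copy = list(family = fam_name, offset = off,
                             copy_len = nchar(elem),
                             divergence_pct = fam_cfg$divergence_pct))
    }
    # Degenerate partial copies inside offpeak hosts.
    for (j in seq_len(fam_cfg$n_degenerate)) {
      g <- make_generic(sample(500:900, 1L), "ta", "degenerate_host")
      frac <- stats::runif(1, 0.3, 0.7)
      div <- stats::runif(1, 5, 15)
      elem <- mutate_seq(substr(paste0(tir, rnd_dna(core_len, p_base)),
                                1L, round(frac * fam$consensus_len)), div)
      off <- sample(seq(50L, max(51L, nchar(g$seq) - 50L)), 1L)
      seq <- paste0(substr(g$seq, 1L, off), elem,
                    substr(g$seq, off + 1L, nchar(g$seq)))
      add_record(seq, g$site,
                 list(class = "degenerate_host", size_class = "offpeak",
                      tdr_motif = g$motif, tdr_klass = "TA_TDR",
                      family = fam_name, status = "NESTED",
                      planted_tir_len = NA_integer_),
                 copy = list(family = fam_name, offset = off,
                             copy_len = nchar(elem), divergence_pct = div))
    }
  }

  # --- Generic IESs -------------------------------------------------------
  n_family <- length(recs)
  n_generic <- max(0L, config$ies$n - n_family)
  classes <- sample(names(config$ies$class_probs), n_generic, replace = TRUE,
                    prob = config$ies$class_probs)
  for (i in seq_len(n_generic)) {
    dl <- draw_generic_length()
    g <- make_generic(dl$len, classes[i], dl$class)
    klass <- switch(classes[i], ta = "TA_TDR", other = "OTHER_TDR",
                    none = "NONE")
    add_record(g$seq, g$site,
               list(class = "generic", size_class = dl$class,
                    tdr_motif = g$motif, tdr_klass = klass,
                    family = NA_character_, status = "NONE",
                    planted_tir_len = NA_integer_))
  }

  ies <- do.call(rbind, recs)
  truth <- do.call(rbind, truths)
  ins <- insert_ies(genome, ies)
  ord <- match(ins$ies$id, truth$id)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL

  copies <- if (length(pending_copies) > 0L) {
    pc <- do.call(rbind, pending_copies)
    idx <- match(pc$id, ins$ies$id)
    data.frame(family = pc$family, contig = ins$ies$contig[idx],
               start = ins$ies$hybrid_start[idx] + pc$offset,
               end = ins$ies$hybrid_start[idx] + pc$offset + pc$copy_len,
               divergence_pct = pc$divergence_pct, copy_len = pc$copy_len,
               ies_id = pc$id, stringsAsFactors = FALSE)
  } else data.frame()

  list(ies = ins$ies, hybrid = ins$hybrid, liftover = ins$liftover,
       copies = copies, truth = truth, features = sim_gen$features,
       mac = genome)
}

#' Feature compartments of the hybrid assembly
#'
#' Interval arithmetic on the hybrid MAC + IES assembly: IES spans,
#' lifted gene intervals minus IES spans (CDS), lifted tRNA intervals
#' (EXCL), and the residual NON compartment.
#'
#' @param sim a list with `liftover`, `ies` (hybrid spans filled),
#'   `hybrid` and `features` (MAC-coordinate gene/tRNA intervals), as
#'   returned by [simulate_ies_repeats()] or assembled from
#'   [insert_ies()] output.
#' @return list of interval data.frames `IES`, `CDS`, `EXCL`, `NON`
#'   (0-based half-open, on the hybrid assembly).
#' @export
hybrid_feature_intervals <- function(sim) {
  lifted <- lift_intervals(sim$liftover,
                           sim$features[, c("contig", "start", "end", "type")])
  as_gr <- function(df) GenomicRanges::GRanges(
    df$contig, IRanges::IRanges(df$start + 1L, df$end))
  ies_gr <- GenomicRanges::GRanges(
    sim$ies$contig, IRanges::IRanges(sim$ies$hybrid_start + 1L,
                                     sim$ies$hybrid_end))
  gene_gr <- suppressWarnings(
    GenomicRanges::setdiff(as_gr(lifted[lifted$type == "gene", , drop = FALSE]),
                           ies_gr))
  trna_df <- lifted[lifted$type == "tRNA", , drop = FALSE]
  trna_gr <- as_gr(trna_df)
  all_gr <- GenomicRanges::GRanges(
    names(sim$hybrid), IRanges::IRanges(1L, nchar(sim$hybrid)))
  non_gr <- suppressWarnings(GenomicRanges::setdiff(
    GenomicRanges::setdiff(GenomicRanges::setdiff(all_gr, ies_gr), gene_gr),
    trna_gr))
  to_df <- function(gr, type) {
    if (length(gr) == 0L) return(data.frame(contig = character(0),
                                            start = integer(0),
                                            end = integer(0),
                                            type = character(0)))
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), type = type,
               stringsAsFactors = FALSE)
  }
  list(IES = to_df(ies_gr, "IES"), CDS = to_df(gene_gr, "CDS"),
       EXCL = to_df(trna_gr, "tRNA"), NON = to_df(non_gr, "NON"))
}

#' Simulate a developmental sRNA time course on the hybrid assembly
#'
#' Per time point, reads draw a length from the configured mixture
#' and an origin compartment (IES / CDS / NON); the 24 nt IES weight
#' rises after the switch time while the CDS weight falls, emulating
#' an scnRNA-like schedule. Reads are placed uniformly within a
#' random interval of their origin compartment, on a random strand;
#' the first sequenced base is forced to T with the configured
#' probability. Deterministic given the config seed.
#'
#' @param sim output of [simulate_ies_repeats()].
#' @param config a [sim_config()].
#' @return list with `reads_by_time` (named list of read-placement
#'   data.frames), `truth` (per-read origin), `intervals` (the
#'   hybrid compartment intervals), `feature_lengths` (total bp per
#'   compartment).
#' @export
simulate_srna_timecourse <- function(sim, config) {
  set.seed(substream_seed(config$seed, 3L))
  sc <- config$srna
  iv <- hybrid_feature_intervals(sim)
  feature_lengths <- vapply(iv[c("IES", "CDS", "NON")],
                            function(d) sum(d$end - d$start), numeric(1))
  names(feature_lengths) <- c("IES", "CDS", "NON")
  if (any(feature_lengths <= 0)) {
    stop("origin compartment with zero total length", call. = FALSE)
  }
  ramp <- function(t, a, b) {
    if (t <= sc$switch_time) a
    else a + (b - a) * (t - sc$switch_time) /
      (max(sc$timepoints) - sc$switch_time)
  }
  origin_probs <- function(t, len) {
    if (len == 24L) {
      i <- ramp(t, sc$ies24_start, sc$ies24_end)
      c0 <- ramp(t, sc$cds24_start, sc$cds24_end)
      c(IES = i, CDS = c0, NON = 1 - i - c0)
    } else if (len == 22L) {
      c0 <- ramp(t, sc$cds22_start, sc$cds22_end)
      c(IES = sc$ies22, CDS = c0, NON = 1 - sc$ies22 - c0)
    } else sc$origin_other
  }
  lens_all <- as.integer(names(sc$length_probs))
  reads_by_time <- list()
  truth <- list()
  for (t in sc$timepoints) {
    lens <- sample(lens_all, sc$n_reads, replace = TRUE,
                   prob = sc$length_probs)
    origin <- character(sc$n_reads)
    for (lc in unique(lens)) {
      sel <- lens == lc
      origin[sel] <- sample(c("IES", "CDS", "NON"), sum(sel), replace = TRUE,
                            prob = origin_probs(t, lc))
    }
    contig <- character(sc$n_reads); start <- integer(sc$n_reads)
    strand <- sample(c("+", "-"), sc$n_reads, replace = TRUE)
    for (feat in c("IES", "CDS", "NON")) {
      sel <- which(origin == feat)
      if (length(sel) == 0L) next
      tab <- iv[[feat]]
      w <- pmax(tab$end - tab$start - max(lens_all) + 1L, 0L)
      ok <- w > 0L
      pick <- sample.int(sum(ok), length(sel), replace = TRUE,
                         prob = w[ok])
      rows <- which(ok)[pick]
      contig[sel] <- tab$contig[rows]
      offs <- floor(stats::runif(length(sel)) *
                      (tab$end[rows] - tab$start[rows] - lens[sel] + 1L))
      start[sel] <- tab$start[rows] + as.integer(offs)
    }
    end <- start + lens
    seq <- substr(sim$hybrid[contig], start + 1L, end)
    neg <- strand == "-"
    seq[neg] <- revcomp(seq[neg])
    p5 <- ifelse(lens == 24L & origin == "IES", sc$p5u_24_ies, sc$p5u_other)
    force_u <- stats::runif(sc$n_reads) < p5
    substr(seq[force_u], 1L, 1L) <- "T"
    label <- paste0("t", t)
    ids <- sprintf("%s_r%06d", label, seq_len(sc$n_reads))
    reads_by_time[[label]] <- data.frame(
      read_id = ids, contig = contig, start = start, end = end,
      strand = strand, length = lens, seq = seq, stringsAsFactors = FALSE)
    truth[[label]] <- data.frame(read_id = ids, timepoint = t,
                                 origin = origin, forced_u = force_u,
                                 stringsAsFactors = FALSE)
  }
  list(reads_by_time = reads_by_time, truth = do.call(rbind, truth),
       intervals = iv, feature_lengths = feature_lengths)
}

#' Run the full synthetic pipeline for one seed
#'
#' Convenience wrapper: genome, IESs/repeats/hybrid, and optionally
#' the sRNA time course.
#'
#' @param config a [sim_config()].
#' @param srna also simulate the sRNA time course.
#' @return list combining the outputs of [simulate_genome()],
#'   [simulate_ies_repeats()] and (optionally)
#'   [simulate_srna_timecourse()].
#' @export
simulate_all <- function(config = sim_config(), srna = FALSE) {
  gen <- simulate_genome(config)
  sim <- simulate_ies_repeats(gen, config)
  if (srna) sim$srna <- simulate_srna_timecourse(sim, config)
  sim$config <- config
  sim
}
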