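jm_fixture <- function(left, ies_seq, right) {
  ctx <- data.frame(id = "i1", contig = "c1", mac_point = nchar(left),
                    seq = ies_seq, length = nchar(ies_seq),
                    retention_score = NA_real_,
                    hybrid_start = NA_integer_, hybrid_end = NA_integer_,
                    left_flank = left, right_flank = right,
                    left_truncated = FALSE, right_truncated = FALSE,
                    flank_len = nchar(left), shift = 0L,
                    stringsAsFactors = FALSE)
  list(ctx = ctx, tdr = find_tdr(ctx))
}

test_that("each TA-bound IES contributes two junctions and columns sum to them", {
  set.seed(3)
  core <- rand_dna(30)
  left <- rand_dna(20)
  right <- paste0("TA", rand_dna(20))
  fx <- jm_fixture(left, paste0("TA", core), right)
  expect_identical(fx$tdr$klass, "TA_TDR")
  jm <- junction_matrix(fx$ctx, fx$tdr)
  expect_identical(attr(jm, "n_junctions"), 2L)
  expect_identical(attr(jm, "n_skipped"), 0L)
  expect_identical(dim(jm), c(24L, 4L))
  expect_true(all(rowSums(jm) == 2L))
  expect_error(junction_matrix(fx$ctx,
                               transform(fx$tdr, klass = "NONE")),
               "TA-bound")
})

test_that("identical planted junction sequences give frequency-1 columns", {
  # both junction strings identical by construction: the right flank
  # carries revcomp(MDS) after its TA and the IES ends with
  # revcomp(IES segment), so the reverse-complemented right junction
  # reproduces the left one exactly
  mds <- "GGGGGCCCCC"
  iesfill <- "CCCCCGGGGGCCCC"
  left <- paste0("AAAA", mds)
  ies_seq <- paste0("TA", iesfill, revcomp(iesfill))
  right <- paste0("TA", revcomp(mds), "TTTT")
  fx <- jm_fixture(left, ies_seq, right)
  expect_identical(fx$tdr$tdr_seq, "TA")
  jm <- junction_matrix(fx$ctx, fx$tdr)
  expect_identical(attr(jm, "n_junctions"), 2L)
  expect_true(all(apply(jm, 1, max) == 2L))  # one base per position
  expect_identical(paste(colnames(jm)[apply(jm, 1, which.max)],
                         collapse = ""),
                   paste0(mds, iesfill))
})

test_that("junctions with insufficient flanks are skipped and counted", {
  fx <- jm_fixture("GGG", paste0("TA", rand_dna(30)),
                   paste0("TA", rand_dna(30)))
  jm <- junction_matrix(fx$ctx, fx$tdr)
  expect_identical(attr(jm, "n_skipped"), 1L)  # left MDS too short
  expect_identical(attr(jm, "n_junctions"), 1L)
})

test_that("mirroring the locus (reverse complement) leaves the matrix unchanged", {
  # Anchoring on the left-most TA is mirror-symmetric for TDRs with a
  # single TA occurrence (TA, TAT/ATA, TAA/TTA); the fixture avoids
  # TATA-pointer records, where the two TA copies pick different
  # physical anchors under mirroring.
  set.seed(9)
  cfg <- sim_config(seed = 31,
                    contigs = list(n = 1L, length = 20000L),
                    ies = list(n = 30L, ta_motifs = c(TA = 0.6, TAT = 0.2,
                                                      ATA = 0.2)),
                    families = list(
                      BogoMITE = list(n_mobile = 3L, n_nested = 0L,
                                      n_degenerate = 0L, divergence_pct = 0),
                      BstTc1 = list(n_mobile = 0L, n_nested = 0L,
                                    n_degenerate = 0L, divergence_pct = 0)))
  sim <- simulate_all(cfg)
  ctx <- normalize_left(extract_context(sim$mac, sim$ies, flank_len = 30L))
  tdr <- find_tdr(ctx)
  ta <- tdr$klass == "TA_TDR"
  jm1 <- junction_matrix(ctx[ta, , drop = FALSE], tdr[ta, , drop = FALSE])
  # mirror the genome and records
  clen <- nchar(sim$mac)
  mgen <- revcomp(sim$mac)
  names(mgen) <- names(sim$mac)
  mies <- sim$ies
  mies$mac_point <- clen[mies$contig] - mies$mac_point
  mies$seq <- revcomp(mies$seq)
  mctx <- normalize_left(extract_context(mgen, mies, flank_len = 30L))
  mtdr <- find_tdr(mctx)
  mta <- mtdr$klass == "TA_TDR"
  jm2 <- junction_matrix(mctx[mta, , drop = FALSE], mtdr[mta, , drop = FALSE])
  expect_identical(sum(ta), sum(mta))
  expect_identical(jm1, jm2)
})
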