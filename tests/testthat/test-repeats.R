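test_that("family presets carry reverse-complement-closed TSD sets", {
  fams <- load_families()
  expect_setequal(names(fams), c("Bogo", "BogoMITE", "BstTc1"))
  expect_setequal(fams$BogoMITE$tsd_motifs, c("TAA", "TTA"))
  expect_identical(nchar(fams$BogoMITE$tir_consensus), 30L)
  expect_identical(nchar(fams$BstTc1$tir_consensus), 38L)
  expect_true("TATA" %in% fams$BstTc1$tsd_motifs)  # palindromic TSD
  expect_error(repeat_family("x", "", "TAA", 100), "tir_consensus")
  expect_error(repeat_family("x", "ACGT", character(0), 100), "tsd_motifs")
})

test_that("divergence profile flags full-length copies and is monotone in f_min", {
  fam <- repeat_family("fam1", "ACGTACGT", "TAA", 389L)
  copies <- data.frame(family = "fam1", contig = "c1",
                       start = c(0L, 500L), end = c(388L, 700L),
                       divergence_pct = c(0.5, 8), copy_len = c(388L, 200L),
                       stringsAsFactors = FALSE)
  dp <- divergence_profile(copies, fam, f_min = 0.95)
  expect_identical(dp$copies$full_length, c(TRUE, FALSE))
  expect_equal(dp$median_divergence_full, 0.5)
  expect_equal(dp$median_divergence_partial, 8)
  # the >80% criterion admits a 320/389 copy
  copies2 <- rbind(copies, data.frame(family = "fam1", contig = "c1",
                                      start = 900L, end = 1220L,
                                      divergence_pct = 1, copy_len = 320L))
  expect_false(divergence_profile(copies2, fam, f_min = 0.95)$copies$full_length[3])
  expect_true(divergence_profile(copies2, fam, f_min = 0.80)$copies$full_length[3])
  # monotonicity: lowering f_min never unflags
  set.seed(2)
  lens <- sample(50:400, 50, replace = TRUE)
  cp <- data.frame(family = "fam1", contig = "c1", start = 0L, end = lens,
                   divergence_pct = runif(50, 0, 20), copy_len = lens)
  f_hi <- divergence_profile(cp, fam, f_min = 0.9)$copies$full_length
  f_lo <- divergence_profile(cp, fam, f_min = 0.6)$copies$full_length
  expect_true(all(f_lo[f_hi]))
  # identical copies: one histogram bin
  cp3 <- data.frame(family = "fam1", contig = "c1", start = 0L, end = 388L,
                    divergence_pct = rep(0.4, 5), copy_len = 388L)
  expect_identical(nrow(divergence_profile(cp3, fam)$histogram), 1L)
})

mities_ctx <- function(ies_seq, left, right, hybrid_start = NA_integer_,
                       hybrid_end = NA_integer_) {
  ctx <- data.frame(id = "i1", contig = "c1", mac_point = nchar(left),
                    seq = ies_seq, length = nchar(ies_seq),
                    retention_score = NA_real_,
                    hybrid_start = hybrid_start, hybrid_end = hybrid_end,
                    left_flank = left, right_flank = right,
                    left_truncated = FALSE, right_truncated = FALSE,
                    flank_len = nchar(left), shift = 0L,
                    stringsAsFactors = FALSE)
  list(ctx = ctx, tdr = find_tdr(ctx))
}

test_that("mobile IESs are called from exact TSD pointers and matching TIR arms", {
  set.seed(4)
  fams <- load_families()
  for (fn in c("BogoMITE", "BstTc1")) {
    fam <- fams[[fn]]
    tsd <- fam$tsd_motifs[1]
    core <- rand_dna(300)
    ies_seq <- paste0(tsd, fam$tir_consensus, core,
                      revcomp(fam$tir_consensus))
    # right-flank filler must not extend the pointer into the TIR's
    # first base, so it starts with a base no family TIR starts with
    fx <- mities_ctx(ies_seq, left = rand_dna(20),
                     right = paste0(tsd, "AACC", rand_dna(16)))
    expect_identical(fx$tdr$tdr_seq, tsd)
    call <- detect_mities(fx$ctx, fx$tdr, fam)
    expect_identical(call$status, "MOBILE_IES")
    expect_equal(call$tir_mismatch_frac, 0)
    expect_true(call$tsd_matched)
  }
})

test_that("TIR arm mutations are tolerated up to the mismatch fraction", {
  set.seed(6)
  fam <- load_families()$BogoMITE
  tl <- nchar(fam$tir_consensus)
  mut_arm <- function(arm, k) {
    ch <- strsplit(arm, "")[[1]]
    idx <- sample(2:length(ch), k)  # keep base 1 so the pointer stays TAA
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  build <- function(k) {
    ies <- paste0("TAA", mut_arm(fam$tir_consensus, k), rand_dna(200),
                  revcomp(fam$tir_consensus))
    mities_ctx(ies, rand_dna(15), paste0("TAA", "GGCC", rand_dna(10)))
  }
  fx_ok <- build(3)   # 3/30 = 0.1, at tolerance
  expect_identical(detect_mities(fx_ok$ctx, fx_ok$tdr, fam)$status,
                   "MOBILE_IES")
  fx_bad <- build(4)  # 4/30 > 0.1
  expect_identical(detect_mities(fx_bad$ctx, fx_bad$tdr, fam)$status, "NONE")
})

test_that("random TA-pointer IESs are not called mobile; planted copies nest", {
  set.seed(8)
  fam <- load_families()$BogoMITE
  # plain TA pointer, random content
  fx <- mities_ctx(paste0("TA", rand_dna(300)), rand_dna(15),
                   paste0("TA", "GGCC", rand_dna(10)))
  expect_identical(detect_mities(fx$ctx, fx$tdr, fam)$status, "NONE")
  # family copy strictly inside the hybrid span -> NESTED
  fx2 <- mities_ctx(paste0("TA", rand_dna(900)), rand_dna(15),
                    paste0("TA", "GGCC", rand_dna(10)),
                    hybrid_start = 1000L, hybrid_end = 1902L)
  copies <- data.frame(family = "BogoMITE", contig = "c1",
                       start = 1200L, end = 1589L, divergence_pct = 0.5,
                       copy_len = 389L, stringsAsFactors = FALSE)
  expect_identical(detect_mities(fx2$ctx, fx2$tdr, fam,
                                 nested_copies = copies)$status, "NESTED")
  # a copy at the IES edge (inside the margin) does not nest
  copies_edge <- transform(copies, start = 1001L, end = 1390L)
  expect_identical(detect_mities(fx2$ctx, fx2$tdr, fam,
                                 nested_copies = copies_edge)$status, "NONE")
})

test_that("homopolymer collapsing tolerates variable poly-C run lengths", {
  fam <- load_families()$BogoMITE  # TIR starts CTCCCCCCCCCCC...
  long_c <- sub("CCCCCCCCCCC", "CCCCCCCCCCCCCC", fam$tir_consensus)
  ies <- paste0("TAA", long_c, rand_dna(200), revcomp(fam$tir_consensus))
  fx <- mities_ctx(ies, rand_dna(15), paste0("TAA", "GGCC", rand_dna(10)))
  expect_identical(detect_mities(fx$ctx, fx$tdr, fam,
                                 collapse = TRUE)$status, "MOBILE_IES")
})

test_that("smallest repeat unit equals the string period", {
  r <- smallest_repeat_unit(strrep("GGGAAGGACT", 8))
  expect_identical(r$unit_len, 10L)
  expect_identical(r$unit, "GGGAAGGACT")
  expect_equal(r$copies, 8)
  expect_identical(smallest_repeat_unit("AAAAA")$unit_len, 1L)
  expect_equal(smallest_repeat_unit("AAAAA")$copies, 5)
  r2 <- smallest_repeat_unit("ACGTAC")
  expect_identical(r2$unit_len, 4L)
  expect_equal(r2$copies, 1.5)
  expect_error(smallest_repeat_unit(""), "empty")
  # brute-force oracle on random strings (small alphabet provokes periods)
  set.seed(13)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "T"), sample(1:24, 1), replace = TRUE),
               collapse = "")
    expect_identical(smallest_repeat_unit(s)$unit_len, as.integer(brute_period(s)))
  }
})

test_that("catalytic-triad motifs are formatted from residue spacing", {
  expect_identical(triad_motif(c("D", "D", "D"), c(10, 100, 136)), "DD35D")
  expect_identical(triad_motif(c("D", "D", "E"), c(10, 100, 135)), "DD34E")
  expect_identical(triad_motif(c("D", "D", "D"), c(0, 1, 2)), "DD0D")
  expect_error(triad_motif(c("D", "D", "D"), c(5, 5, 9)), "increasing")
  expect_error(triad_motif(c("D", "d", "D"), c(1, 2, 9)), "uppercase")
})
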