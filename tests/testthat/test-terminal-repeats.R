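ctx_row <- function(ies_seq, right, left = strrep("G", 10), flank_len = 50L) {
  data.frame(id = "i1", contig = "c1", mac_point = 10L, seq = ies_seq,
             length = nchar(ies_seq), retention_score = NA_real_,
             hybrid_start = NA_integer_, hybrid_end = NA_integer_,
             left_flank = left, right_flank = right,
             left_truncated = FALSE, right_truncated = FALSE,
             flank_len = flank_len, shift = 0L, stringsAsFactors = FALSE)
}

test_that("TDR detection classifies TA, other and absent repeats", {
  r <- find_tdr(ctx_row("TACGGCC", "TAGCCAA"))
  expect_identical(r$k, 2L)
  expect_identical(r$tdr_seq, "TA")
  expect_identical(r$klass, "TA_TDR")
  expect_identical(r$ta_offset, 0L)
  r2 <- find_tdr(ctx_row("GGGCTTT", "GGGATTT"))
  expect_identical(r2$k, 3L)
  expect_identical(r2$klass, "OTHER_TDR")
  expect_true(is.na(r2$ta_offset))
  r3 <- find_tdr(ctx_row("CATTGGG", "GATTGGG"))
  expect_identical(r3$k, 0L)
  expect_identical(r3$klass, "NONE")
  # 1 bp repeats fall below the default minimum
  r4 <- find_tdr(ctx_row("CATTGGG", "CTTTGGG"))
  expect_identical(r4$k, 1L)
  expect_identical(r4$klass, "NONE")
  # TA within a longer TDR still marks the IES TA-bound
  r5 <- find_tdr(ctx_row("GTACTTTT", "GTACAAAA"))
  expect_identical(r5$tdr_seq, "GTAC")
  expect_identical(r5$klass, "TA_TDR")
  expect_identical(r5$ta_offset, 1L)
})

test_that("TIR extension stops at mismatch, midpoint and cap", {
  r <- find_tir("TACCGAAACGG", tdr_len = 2L)
  expect_identical(r$tir_len, 3L)
  expect_identical(r$arm_seq, "CCG")
  expect_false(r$capped)
  # A vs complement(A)=T mismatches immediately
  expect_identical(find_tir("AAAAAAAA", tdr_len = 0L)$tir_len, 0L)
  # perfect palindrome hits the cap
  half <- rand_dna(30)
  pal <- paste0(half, revcomp(half))
  r2 <- find_tir(pal, tdr_len = 0L, cap = 25L)
  expect_identical(r2$tir_len, 25L)
  expect_true(r2$capped)
  # cap disabled: runs to the midpoint
  r3 <- find_tir(pal, tdr_len = 0L, cap = NULL)
  expect_identical(r3$tir_len, 30L)
  expect_false(r3$capped)
  # empty element
  expect_identical(find_tir("TA", tdr_len = 2L)$tir_len, 0L)
  # stripping both ends shortens the element
  r4 <- find_tir(paste0("TA", half, revcomp(half), "TA"), tdr_len = 2L,
                 cap = NULL, strip = "both")
  expect_identical(r4$tir_len, 30L)
})

test_that("TDR and TIR scans match brute-force oracles on random cases", {
  set.seed(11)
  for (i in 1:1000) {
    # biased draws so repeats of useful length actually occur
    ies_seq <- rand_dna(sample(6:40, 1), p = c(A = .4, C = .1, G = .1, T = .4))
    right <- paste0(substr(ies_seq, 1, sample(0:6, 1)),
                    rand_dna(20, p = c(A = .4, C = .1, G = .1, T = .4)))
    ctx <- ctx_row(ies_seq, right)
    expect_identical(find_tdr(ctx)$k, brute_tdr(ies_seq, right, 50L))
    cap <- sample(list(25L, NULL), 1)[[1]]
    expect_identical(find_tir(ies_seq, 0L, cap = cap)$tir_len,
                     brute_tir(ies_seq, cap))
  }
})

test_that("geometric null model matches the closed form and conserves mass", {
  nm <- null_model(p = c(A = .25, C = .25, G = .25, T = .25))
  expect_equal(nm$m_direct, 0.25)
  expect_equal(nm$m_inverted, 0.25)
  eo <- expected_observed(c(`2` = 40), nm, n_ies = 1000, mode = "direct")
  expect_equal(eo$expected, 1000 * 0.0625 * 0.75)  # 46.875
  # expected counts over all L sum to n_ies
  all_l <- stats::setNames(rep(0, 101), 0:100)
  eo_all <- expected_observed(all_l, nm, n_ies = 1000, mode = "direct")
  expect_equal(sum(eo_all$expected), 1000 * (1 - 0.25^101), tolerance = 1e-12)
  # m_direct - m_inverted = (pA-pT)^2 + (pC-pG)^2: equal only for
  # strand-symmetric compositions
  nm2 <- null_model(p = c(A = .5, C = .2, G = .1, T = .2))
  expect_equal(nm2$m_inverted, 2 * (.5 * .2 + .2 * .1))
  expect_lt(nm2$m_inverted, nm2$m_direct)
  nm3 <- null_model(p = c(A = .4, C = .1, G = .1, T = .4))
  expect_equal(nm3$m_inverted, nm3$m_direct)
  expect_error(expected_observed(c(`0` = 1), null_model(p = c(A = 1, C = 0, G = 0, T = 0)),
                                 10, "direct"),
               "degenerate")
})

test_that("null model estimates frequencies from sequences", {
  nm <- null_model(c("AAAT", "GCGC"))
  expect_equal(unname(nm$p["A"]), 3 / 8)
  expect_equal(sum(nm$p), 1)
})
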