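test_that("IES filtering removes on either criterion and keeps unscored records", {
  ies <- data.frame(id = c("a", "b", "c", "d"), contig = "c1",
                    mac_point = 0L,
                    seq = c(strrep("A", 40), strrep("A", 200),
                            strrep("A", 200), strrep("A", 40)),
                    length = c(40L, 200L, 200L, 40L),
                    retention_score = c(0.5, 0.05, NA, 0.01),
                    hybrid_start = NA_integer_, hybrid_end = NA_integer_,
                    stringsAsFactors = FALSE)
  flt <- filter_ies(ies)
  expect_identical(flt$kept$id, "c")
  expect_identical(flt$removed$reason[flt$removed$id == "a"], "length")
  expect_identical(flt$removed$reason[flt$removed$id == "b"], "score")
  expect_identical(flt$removed$reason[flt$removed$id == "d"], "length+score")
  empty <- filter_ies(ies[0, , drop = FALSE])
  expect_identical(nrow(empty$kept), 0L)
})

make_rec <- function(genome_seq, mac_point, seq, id = "i1") {
  list(genome = c(c1 = genome_seq),
       ies = data.frame(id = id, contig = "c1", mac_point = mac_point,
                        seq = seq, length = nchar(seq),
                        retention_score = NA_real_,
                        hybrid_start = NA_integer_, hybrid_end = NA_integer_,
                        stringsAsFactors = FALSE))
}

test_that("flank extraction clips at contig ends and flags truncation", {
  g <- strrep("ACGTG", 20)  # 100 bp
  fx <- make_rec(g, 10L, "TTTT")
  ctx <- extract_context(fx$genome, fx$ies, flank_len = 5L)
  expect_identical(ctx$left_flank, substr(g, 6, 10))
  expect_identical(ctx$right_flank, substr(g, 11, 15))
  expect_false(ctx$left_truncated); expect_false(ctx$right_truncated)
  ctx2 <- extract_context(fx$genome,
                          transform(fx$ies, mac_point = 2L), flank_len = 5L)
  expect_identical(nchar(ctx2$left_flank), 2L)
  expect_true(ctx2$left_truncated)
  ctx3 <- extract_context(fx$genome,
                          transform(fx$ies, mac_point = 100L), flank_len = 5L)
  expect_identical(ctx3$right_flank, "")
  expect_true(ctx3$right_truncated)
  expect_error(extract_context(fx$genome,
                               transform(fx$ies, contig = "nope")),
               "unknown contig")
})

test_that("left-normalization rotates floating windows to the left-most coordinate", {
  # left GGA | ies CGTA | right CGTT: one rotation.
  g <- paste0("GGA", "CGTT")
  fx <- make_rec(g, 3L, "CGTA")
  ctx <- normalize_left(extract_context(fx$genome, fx$ies, flank_len = 4L))
  expect_identical(ctx$shift, 1L)
  expect_identical(ctx$seq, "ACGT")
  expect_identical(ctx$left_flank, "GG")
  expect_identical(ctx$right_flank, "ACGTT")
  expect_identical(ctx$mac_point, 2L)
  # no trailing match: no rotation
  fx2 <- make_rec(paste0("GGC", "CGTT"), 3L, "CGTA")
  ctx2 <- normalize_left(extract_context(fx2$genome, fx2$ies, flank_len = 4L))
  expect_identical(ctx2$shift, 0L)
  # idempotence
  expect_identical(normalize_left(ctx), ctx)
})

test_that("normalization never changes the MAC product (random floating windows)", {
  set.seed(5)
  for (i in 1:200) {
    g <- rand_dna(60)
    p <- sample(20:40, 1)
    ies_seq <- rand_dna(sample(5:15, 1))
    fx <- make_rec(g, p, ies_seq)
    ctx0 <- extract_context(fx$genome, fx$ies, flank_len = 15L)
    ctx1 <- normalize_left(ctx0)
    # MAC product around the insertion: flanks concatenated.
    expect_identical(paste0(ctx1$left_flank, ctx1$right_flank),
                     paste0(ctx0$left_flank, ctx0$right_flank))
    # hybrid local sequence also unchanged
    expect_identical(paste0(ctx1$left_flank, ctx1$seq, ctx1$right_flank),
                     paste0(ctx0$left_flank, ctx0$seq, ctx0$right_flank))
    # idempotent
    expect_identical(normalize_left(ctx1), ctx1)
  }
})
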