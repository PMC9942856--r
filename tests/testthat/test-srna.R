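mk_reads <- function(contig, start, len, seq = NULL, strand = "+") {
  n <- length(start)
  if (is.null(seq)) seq <- vapply(len, rand_dna, character(1))
  data.frame(read_id = sprintf("r%d", seq_len(n)), contig = contig,
             start = start, end = start + len, strand = strand,
             length = len, seq = seq, stringsAsFactors = FALSE)
}

test_that("length histogram fractions sum to one", {
  reads <- mk_reads("c1", c(0L, 10L, 20L, 30L), c(22L, 22L, 24L, 25L))
  h <- length_histogram(reads)
  expect_equal(h$fraction[h$length == 22], 0.5)
  expect_equal(h$fraction[h$length == 24], 0.25)
  expect_equal(sum(h$fraction), 1)
  one <- length_histogram(mk_reads("c1", 0L, 24L))
  expect_equal(one$fraction, 1)
})

test_that("feature assignment follows exclusion-first IES > CDS > NON priority", {
  ies <- data.frame(contig = "c1", start = 100L, end = 200L)
  cds <- data.frame(contig = "c1", start = 150L, end = 400L)
  excl <- data.frame(contig = "c1", start = 500L, end = 600L)
  reads <- mk_reads("c1", c(180L, 300L, 450L, 580L, 199L), rep(22L, 5))
  asg <- assign_features(reads, ies, cds, excl)
  expect_identical(asg$assignment,
                   c("IES", "CDS", "NON", "EXCLUDED", "IES"))
  expect_identical(asg$excluded_count, 1L)
  expect_identical(asg$total_mapped, 5L)
  # conservation: assigned + excluded == total
  expect_identical(sum(asg$counts$count) + asg$excluded_count,
                   asg$total_mapped)
  # a single-bp overlap suffices (read at 199 overlaps [100,200) by 1)
  expect_identical(asg$assignment[5], "IES")
  expect_error(assign_features(reads, ies, cds, excl,
                               contig_lengths = c(cX = 1000L)),
               "unknown contig")
})

test_that("count conservation holds on random fixtures", {
  set.seed(19)
  for (i in 1:20) {
    reads <- mk_reads("c1", sample(0:900, 50, TRUE), sample(18:30, 50, TRUE))
    ies <- data.frame(contig = "c1", start = c(50L, 700L), end = c(120L, 800L))
    cds <- data.frame(contig = "c1", start = 100L, end = 600L)
    excl <- data.frame(contig = "c1", start = 850L, end = 880L)
    asg <- assign_features(reads, ies, cds, excl)
    expect_identical(sum(asg$counts$count) + asg$excluded_count, 50L)
  }
})

test_that("RPKM implements the feature-length substitution and its invariances", {
  expect_equal(rpkm(100, 1e6, 1e4), 10)
  expect_equal(rpkm(0, 1e6, 1e4), 0)
  # linearity in count
  expect_equal(rpkm(200, 1e6, 1e4), 2 * rpkm(100, 1e6, 1e4))
  # scaling counts and library size together changes nothing
  expect_equal(rpkm(100, 1e6, 1e4), rpkm(700, 7e6, 1e4))
  expect_error(rpkm(1, 0, 10), "positive")
})

test_that("base bias reads the sequenced strand and reports the 5'-U fraction", {
  reads <- mk_reads("c1", c(0L, 10L, 20L), 4L,
                    seq = c("TAAA", "TCCC", "GAAA"))
  bb <- base_bias(reads)
  expect_equal(bb$five_prime_u_fraction, 2 / 3)
  expect_equal(rowSums(bb$freq), rep(1, 4), ignore_attr = TRUE)
  reads2 <- mk_reads("c1", c(0L, 10L), 4L, seq = c("TAAA", "TGGG"))
  expect_equal(base_bias(reads2)$five_prime_u_fraction, 1)
  expect_error(base_bias(mk_reads("c1", c(0L, 10L), c(22L, 24L))), "mixed")
})

test_that("an scnRNA-like schedule yields rising 24 nt IES RPKM after the switch", {
  cfg <- sim_config(seed = 23, contigs = list(n = 1L, length = 40000L),
                    ies = list(n = 60L),
                    families = list(
                      BogoMITE = list(n_mobile = 2L, n_nested = 1L,
                                      n_degenerate = 1L, divergence_pct = 0),
                      BstTc1 = list(n_mobile = 2L, n_nested = 1L,
                                    n_degenerate = 1L, divergence_pct = 0)),
                    srna = list(n_reads = 5000L,
                                timepoints = c(6, 14, 22, 30, 38)))
  sim <- simulate_all(cfg, srna = TRUE)
  s <- sim$srna
  ser <- srna_series(s$reads_by_time, s$intervals$IES, s$intervals$CDS,
                     s$intervals$EXCL, s$feature_lengths)
  i24 <- ser[ser$read_length == 24 & ser$feature == "IES", ]
  i24 <- i24[match(paste0("t", c(14, 22, 30, 38)), i24$timepoint), ]
  expect_true(all(diff(i24$rpkm) > 0))
  c24 <- ser[ser$read_length == 24 & ser$feature == "CDS", ]
  c24 <- c24[match(paste0("t", c(14, 22, 30, 38)), c24$timepoint), ]
  expect_true(all(diff(c24$count) <= 0))
  # strong 5'-U bias on the 24 nt IES class
  expect_gt(min(i24$five_prime_u_fraction), 0.8)
  # assignments agree with the generator's truth
  asg <- assign_features(s$reads_by_time[["t38"]], s$intervals$IES,
                         s$intervals$CDS, s$intervals$EXCL)
  tr <- s$truth[s$truth$timepoint == 38, ]
  expect_equal(mean(asg$assignment == tr$origin), 1)
})
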