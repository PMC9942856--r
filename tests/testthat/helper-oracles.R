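# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use naive character-by-character scans so they stay
# independent of the implementations they check.

rand_dna <- function(n, p = c(A = 0.3325, C = 0.1675, G = 0.1675, T = 0.3325)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Naive TDR: largest j with ies[0:j] == right_flank[0:j].
brute_tdr <- function(ies_seq, right_flank, max_tdr = Inf) {
  m <- min(nchar(ies_seq), nchar(right_flank), max_tdr)
  k <- 0L
  a <- strsplit(ies_seq, "")[[1]]
  b <- strsplit(right_flank, "")[[1]]
  while (k < m && a[k + 1L] == b[k + 1L]) k <- k + 1L
  k
}

# Naive TIR on an element: compare element[i] to the complement of
# element[n - 1 - i], stopping at mismatch, midpoint, or cap.
brute_tir <- function(element, cap = 25L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- strsplit(element, "")[[1]]
  n <- length(ch)
  lim <- min(n %/% 2L, if (is.null(cap)) n else cap)
  k <- 0L
  while (k < lim && ch[k + 1L] == comp[[ch[n - k]]]) k <- k + 1L
  k
}

# Naive smallest string period: try every p from 1 up.
brute_period <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  for (p in 1:n) {
    if (p == n) return(n)
    if (all(ch[seq_len(n - p)] == ch[seq_len(n - p) + p])) return(p)
  }
}

# A tiny deterministic genome + IES set with planted TDRs, used by
# several suites. Each IES is inserted at a point where the MAC
# carries its pointer motif.
tiny_fixture <- function(seed = 42, n = 40, contig_len = 20000) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, contigs = list(n = 1L, length = contig_len),
                    ies = list(n = n, flank_guard = 60L, min_spacing = 60L,
                               mix = c(periodic = 0.5, nonperiodic = 0.3,
                                       offpeak = 0.2)),
                    families = list(
                      BogoMITE = list(n_mobile = 2L, n_nested = 1L,
                                      n_degenerate = 1L, divergence_pct = 0),
                      BstTc1 = list(n_mobile = 2L, n_nested = 1L,
                                    n_degenerate = 1L, divergence_pct = 0)))
  simulate_all(cfg)
}
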