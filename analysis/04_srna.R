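#!/usr/bin/env Rscript
# Step 4 — developmental sRNA quantification on the hybrid assembly:
# read-length spectrum, feature-priority counting (excluding
# tRNA-overlapping reads), RPKM per feature type per time point, and
# positional base bias with the 5'-U fraction for the 22/24 nt
# classes.

suppressPackageStartupMessages(library(ieskit))

sim_dir <- "scratch/sim"
out_dir <- "results/04_srna"
if (!file.exists(file.path(sim_dir, "hybrid.fasta"))) {
  stop("run analysis/01_simulate.R first", call. = FALSE)
}
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome(file.path(sim_dir, "mac.fasta"))
ies <- read_ies_gff(file.path(sim_dir, "ies.gff3"), genome)
feat <- utils::read.table(file.path(sim_dir, "features.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)

# Rebuild hybrid-assembly feature compartments from the MAC features
# and the IES spans: IES priority, genes minus IESs, tRNAs excluded.
ins <- insert_ies(genome, ies)
sim_like <- list(liftover = ins$liftover, ies = ins$ies,
                 hybrid = ins$hybrid, features = feat)
iv <- hybrid_feature_intervals(sim_like)
feature_lengths <- vapply(iv[c("IES", "CDS", "NON")],
                          function(d) sum(d$end - d$start), numeric(1))

beds <- sort(list.files(sim_dir, pattern = "^reads_t\\d+\\.bed$"))
tps <- sub("^reads_(t\\d+)\\.bed$", "\\1", beds)
reads_by_time <- stats::setNames(lapply(tps, function(tp)
  read_read_placements(file.path(sim_dir, paste0("reads_", tp, ".bed")),
                       file.path(sim_dir, paste0("reads_", tp, ".fasta")))),
  tps)
ord <- order(as.integer(sub("^t", "", tps)))
reads_by_time <- reads_by_time[ord]

wt <- function(x, f) utils::write.table(
  x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

# Pooled length spectrum.
all_reads <- do.call(rbind, reads_by_time)
wt(length_histogram(all_reads), "length_hist.tsv")

# Per-time-point counts, RPKM and 5'-U fraction for 22/24 nt.
series <- srna_series(reads_by_time, iv$IES, iv$CDS, iv$EXCL,
                      feature_lengths)
wt(series, "rpkm_series.tsv")

# Positional base bias for the 24 nt IES class at the last time point.
last <- reads_by_time[[length(reads_by_time)]]
asg <- assign_features(last, iv$IES, iv$CDS, iv$EXCL)
sub <- last[asg$assignment == "IES" & last$length == 24L, , drop = FALSE]
bb <- base_bias(sub)
bb_df <- as.data.frame(bb$freq)
bb_df$position <- seq_len(nrow(bb_df))
wt(bb_df[, c("position", "A", "C", "G", "T")], "base_bias_24_IES.tsv")
run_manifest(out_dir, "srna",
             params = list(lengths = "22,24", priority = "EXCL>IES>CDS>NON"),
             inputs = file.path(sim_dir, beds))

h <- length_histogram(all_reads)
i24 <- series[series$read_length == 24 & series$feature == "IES", ]
cat(sprintf("22 nt: %.0f%% of reads; 24 nt: %.0f%%.\n",
            100 * h$fraction[h$length == 22], 100 * h$fraction[h$length == 24]))
cat(sprintf("24 nt IES RPKM rises from %.0f (%s) to %.0f (%s); 5'-U fraction %.2f at the last time point.\n",
            i24$rpkm[1], i24$timepoint[1], i24$rpkm[nrow(i24)],
            i24$timepoint[nrow(i24)], bb$five_prime_u_fraction))
cat("Tables in", out_dir, "\n")
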