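#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study system with known ground
# truth: an AT-rich somatic genome (33.5% GC, 77% genic), 8,000 IESs
# with periodic (65-115 bp, ~10 bp period) and nonperiodic
# (153/174/228/389 bp) length structure, TA/other/no pointer classes,
# planted BogoMITE and BstTc1 mobile/nested/degenerate copies, and a
# seven-point developmental sRNA time course with an scnRNA-like
# schedule.
#
# Sequence-heavy outputs (FASTA/GFF/BED, regenerable from the seed)
# go to scratch/sim/; summary tables go to results/01_simulate/.

suppressPackageStartupMessages(library(ieskit))

seed <- 1234L
sim_dir <- "scratch/sim"
out_dir <- "results/01_simulate"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
sim <- simulate_all(cfg, srna = TRUE)

# Full file set in the pipeline's external formats.
write_genome(sim$mac, file.path(sim_dir, "mac.fasta"))
write_genome(sim$hybrid, file.path(sim_dir, "hybrid.fasta"))
write_ies_gff(sim$ies, file.path(sim_dir, "ies.gff3"))
write_genome(stats::setNames(sim$ies$seq, sim$ies$id),
             file.path(sim_dir, "ies.fasta"))
write_repeat_tsv(sim$copies, file.path(sim_dir, "repeats.tsv"))
feat <- sim$features
utils::write.table(feat, file.path(sim_dir, "features.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (tp in names(sim$srna$reads_by_time)) {
  write_read_placements(sim$srna$reads_by_time[[tp]],
                        file.path(sim_dir, paste0("reads_", tp, ".bed")),
                        file.path(sim_dir, paste0("reads_", tp, ".fasta")))
}
utils::write.table(sim$truth, file.path(sim_dir, "truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$srna$truth, file.path(sim_dir, "srna_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# Summary of what was planted.
cls <- table(sim$truth$tdr_klass)
summary <- data.frame(
  quantity = c("genome_bp", "n_contigs", "n_ies", "n_ta_bound",
               "n_other_tdr", "n_no_tdr", "n_mobile", "n_nested_hosts",
               "n_repeat_copies", "n_srna_timepoints", "reads_per_timepoint"),
  value = c(sum(nchar(sim$mac)), length(sim$mac), nrow(sim$ies),
            cls[["TA_TDR"]], cls[["OTHER_TDR"]], cls[["NONE"]],
            sum(sim$truth$status == "MOBILE_IES"),
            sum(sim$truth$status == "NESTED"),
            nrow(sim$copies), length(sim$srna$reads_by_time),
            cfg$srna$n_reads))
utils::write.table(summary, file.path(out_dir, "planted_summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
run_manifest(out_dir, "simulate", params = list(
  seed = seed, genome_bp = sum(nchar(sim$mac)), n_ies = cfg$ies$n),
  seed = seed)

cat("Planted", nrow(sim$ies), "IESs on a",
    round(sum(nchar(sim$mac)) / 1e6, 1), "Mbp somatic genome;",
    sum(sim$truth$status == "MOBILE_IES"), "mobile IESs,",
    nrow(sim$copies), "repeat copies,",
    length(sim$srna$reads_by_time), "sRNA time points.\n")
cat("Files in", sim_dir, "; summary in", out_dir, "\n")
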