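#!/usr/bin/env Rscript
# Simulate the synthetic DPC-seq study: a 50 Mb genome in 1-kb bins with
# ~1,200 genes, a nascent-RNA expression track, and 0 h / 4 h DPC-seq bin
# counts for WT and transcription-blocked (THZ1) conditions, plus FRAP
# cohorts and a DPC-qPCR Ct table. Writes plain-text fixtures and ground
# truth under results/sim/.

suppressPackageStartupMessages(library(dpcrepair))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1)
wt <- simulate_dpc_experiment(cfg, "WT")
thz <- simulate_dpc_counts(cfg, wt$expression, "THZ1")

cat(sprintf("genome: %d chromosome(s), %d bins of %d b\n",
            nrow(wt$chrom_sizes), n_bins(wt$bins), cfg$bin_size))
cat(sprintf("genes: %d (%d expressed), expressed bins: %d\n",
            nrow(wt$genes), sum(wt$genes$tpm > 0), sum(wt$expression$true_tpm > 0)))
cat(sprintf("true expressed-bin repair fraction (WT): %.2f; THZ1: %.2f\n",
            max(wt$truth$true_repair), max(thz$truth$true_repair)))

frap_treated <- simulate_frap_traces(0.6, 0.5, n_cells = 30, n_frames = 30,
                                     noise_sd = 0.05, seed = 11)
frap_untreated <- simulate_frap_traces(0, 0.5, n_cells = 30, n_frames = 30,
                                       noise_sd = 0.05, seed = 12)
ct <- simulate_ct_table(c(NT = 1, FA_0h = 12, FA_4h = 5),
                        amplicons = c("ampA", "ampB"), noise_sd = 0.1, seed = 13)

paths <- write_fixtures(wt, frap_treated, ct, out)
write_bedgraph(thz$t0[[1]]$counts, wt$bins, file.path(out, "dpc_0h_rep1_thz1.counts.bedGraph"))
write_bedgraph(thz$t4[[1]]$counts, wt$bins, file.path(out, "dpc_4h_rep1_thz1.counts.bedGraph"))
write_frap_csv(frap_untreated, file.path(out, "frap_traces_untreated.csv"))
write_bedgraph(wt$truth$true_repair, wt$bins, file.path(out, "truth.repair_fraction.bedGraph"))

# bin-level count tables for the downstream drivers (all replicates)
for (k in seq_len(cfg$n_replicates)) {
  for (cond in c("wt", "thz1")) {
    src <- if (cond == "wt") wt else thz
    write_bedgraph(src$t0[[k]]$counts, wt$bins,
                   file.path(out, sprintf("dpc_0h_rep%d_%s.bedGraph", k, cond)))
    write_bedgraph(src$t4[[k]]$counts, wt$bins,
                   file.path(out, sprintf("dpc_4h_rep%d_%s.bedGraph", k, cond)))
  }
}
utils::write.table(wt$genes, file.path(out, "genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("fixtures written under", out, "\n")
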