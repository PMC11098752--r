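#!/usr/bin/env Rscript
# qPCR quantification: the DPC-qPCR 2^-ddCt chain (DPC-associated DNA vs
# free DNA, vs untreated, vs FA 0 h) on the simulated Ct table, and a
# worked 2^-dCt nascent-transcription time course.

suppressPackageStartupMessages(library(dpcrepair))

ct <- read_ct_csv("results/sim/ct_table.csv")
dpc <- ddct_dpc_levels(ct)
cat("relative DPC levels (FA 0 h = 1):\n")
print(dpc)

trans <- dct_transcription(data.frame(
  amplicon = "GAPDH_pre",
  treatment = rep(c("FA", "mock"), each = 3),
  sample = rep(c("0min", "30min", "60min"), 2),
  fraction = "cdna", replicate = 1L,
  ct = c(21, 23.2, 22.1, 21.4, 21.3, 21.5)
))
cat("relative nascent transcription (0 min = 1):\n")
print(trans)

dir.create("results/qpcr", showWarnings = FALSE, recursive = TRUE)
utils::write.table(dpc, "results/qpcr/dpc_levels.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(trans, "results/qpcr/transcription_timecourse.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
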