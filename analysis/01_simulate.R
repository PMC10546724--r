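#!/usr/bin/env Rscript
# Generate the synthetic parallel snRNA/snATAC study (24 donors, 12 case
# / 12 control, 3 clusters, planted DEGs/DAPs, co-accessibility blocks,
# motifs and affinity-changing SNPs) and emit it in standard formats.
source("analysis/00_common.R")

sim <- generate_dataset(config)
dir <- file.path("scratch", "synthetic")
write_synthetic_dataset(sim, dir)
message("dataset written to ", dir)

write_result(data.frame(
  what = c("donors", "nuclei", "genes", "peaks", "planted_degs",
           "planted_daps", "coaccess_blocks", "snps"),
  n = c(config$n_donors, nrow(sim$counts$nuclei), config$n_genes,
        config$n_peaks, nrow(sim$truth$deg), nrow(sim$truth$dap),
        length(sim$truth$ccan_blocks), nrow(sim$sequences$snps))),
  "01_dataset_summary.tsv")
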