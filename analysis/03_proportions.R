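#!/usr/bin/env Rscript
# Case-control cell-proportion testing with the bootstrapped Wilcoxon
# procedure (20% of nuclei per iteration, 30 iterations, BH tiers).
source("analysis/00_common.R")

pl <- pipeline()
write_result(pl$proportions, "03_proportion_tests.tsv")
shift <- pl$sim$truth$prop_shift
message("planted shift: cluster ", shift$cluster, " x", shift$fold,
        "; its FDR tier: ",
        pl$proportions$tier[pl$proportions$unit == shift$cluster])
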