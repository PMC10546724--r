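#!/usr/bin/env Rscript
# Per-cluster hurdle differential expression (donor random intercept)
# and binomial-LRT differential accessibility; recovery of the planted
# effects.
source("analysis/00_common.R")

pl <- pipeline()
de <- do.call(rbind, pl$de)
da <- do.call(rbind, pl$da)
write_result(de, "05_differential_expression.tsv")
write_result(da, "05_differential_accessibility.tsv")
truth <- pl$sim$truth
for (cl in unique(truth$deg$cluster)) {
  planted <- truth$deg$feature[truth$deg$cluster == cl]
  found <- de$feature[de$cluster == cl & !is.na(de$fdr) & de$fdr <= 0.05]
  message(cl, ": ", sum(planted %in% found), "/", length(planted),
          " planted DEGs recovered at FDR 0.05 (",
          sum(!found %in% planted), " extra calls)")
}
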