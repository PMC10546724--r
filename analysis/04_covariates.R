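#!/usr/bin/env Rscript
# Iterative PC-regression covariate selection on donor pseudobulk.
source("analysis/00_common.R")

pl <- pipeline()
sel <- pl$covariates$selection
message("selected covariates: ",
        if (length(sel$selected)) paste(sel$selected, collapse = ", ")
        else "(none - no donor-level driver planted in expression)")
write_result(sel$log, "04_covariate_rounds.tsv")
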