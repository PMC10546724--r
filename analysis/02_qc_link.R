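#!/usr/bin/env Rscript
# Per-nucleus QC filtering with removal reasons, and cross-modality
# cluster linking validated by barcode Jaccard.
source("analysis/00_common.R")

pl <- pipeline()
reasons <- table(unlist(strsplit(pl$qc$rna$removed$reason, ",")))
message("RNA nuclei kept: ", length(pl$qc$rna$kept),
        "; ATAC kept: ", length(pl$qc$atac$kept))
write_result(data.frame(rule = names(reasons),
                        n_failed = as.integer(reasons)),
             "02_qc_removal_reasons.tsv")
links <- pl$link$links
links$jaccard <- pl$link$jaccard$per_cluster$jaccard
write_result(links, "02_cluster_links.tsv")
message("mean link Jaccard: ", round(pl$link$jaccard$mean, 3))
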