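#!/usr/bin/env Rscript
# Cis-co-accessibility networks from the disease-group aggregated
# accessibility, directionality classification, cCRE-target links, GWAS
# windows, and gene-set enrichment of linked targets.
source("analysis/00_common.R")

pl <- pipeline()
ccs <- pl$ccan$ccans
summ <- data.frame(
  ccan = vapply(ccs, `[[`, "", "id"),
  n_peaks = vapply(ccs, function(c) length(c$peaks), 1L),
  klass = vapply(ccs, `[[`, "", "klass"),
  n_daps = vapply(ccs, function(c) nrow(c$daps), 1L),
  gwas_window = pl$ccan$gwas_flag)
write_result(summ, "07_ccan_summary.tsv")
write_result(pl$ccan$ccre_links, "07_ccre_links.tsv")

# gene-set enrichment of cCRE-linked targets: block-derived set vs a
# size-matched random set, against the expressed background
targets <- unique(pl$ccan$ccre_links$target)
background <- rownames(pl$sim$counts$rna_counts)
sets <- list(
  planted_block_targets = unique(pl$sim$plan$block_info$gene),
  random_set = background[seq(10, 40)])
go <- go_enrichment(targets, background, sets, p_cutoff = 1,
                    min_genes = 1L)
write_result(go, "07_target_geneset_enrichment.tsv")
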