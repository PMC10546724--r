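#!/usr/bin/env Rscript
# Dynamic-lambda Poisson peak calling per sample and Fisher-method
# consensus, on fragment midpoints simulated over the annotation's peaks.
source("analysis/00_common.R")

set.seed(config$seed)
ann <- generate_annotation(config)
cl <- config$chrom_lengths
samples <- lapply(1:4, function(s) {
  bg <- data.frame(
    chrom = sample(names(cl), 4000, TRUE, prob = cl / sum(cl)),
    pos = NA_integer_)
  bg$pos <- vapply(bg$chrom, function(ch) sample.int(cl[[ch]], 1L),
                   integer(1))
  enriched <- ann$peaks[seq(1, nrow(ann$peaks), by = 6), ]
  fg <- data.frame(
    chrom = rep(enriched$chrom, each = 25),
    pos = rep((enriched$start + enriched$end) %/% 2L, each = 25))
  call_peaks(rbind(bg, fg), cl)
})
names(samples) <- sprintf("s%d", seq_along(samples))
cons <- consensus_peaks(samples)
message("per-sample calls: ",
        paste(vapply(samples, nrow, 1L), collapse = ", "),
        "; consensus peaks: ", nrow(cons))
write_result(cons, "06_consensus_peaks.tsv")
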