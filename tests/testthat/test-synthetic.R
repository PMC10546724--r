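# Synthetic-data generator: determinism, planted-truth checkability,
# coordinate conventions.

test_that("promoter windows follow the strand-oriented 2000/200 rule", {
  expect_equal(promoter_window(10000L, "+"),
               cbind(start = 8000L, end = 10200L))
  expect_equal(promoter_window(10000L, "-"),
               cbind(start = 9800L, end = 12000L))
})

test_that("annotation has promoters, first introns and in-bounds peaks", {
  sim <- small_dataset()
  ann <- sim$annotation
  g <- ann$genes
  pw <- promoter_window(g$tss, g$strand)
  expect_equal(ann$promoters$start, pw[, "start"])
  expect_equal(ann$promoters$end, pw[, "end"])
  expect_true(all(ann$intron1$end > ann$intron1$start))
  cl <- sim$config$chrom_lengths
  expect_true(all(ann$peaks$end <= cl[ann$peaks$chrom]))
  # non-overlapping within each chromosome
  for (ch in names(cl)) {
    p <- ann$peaks[ann$peaks$chrom == ch, ]
    p <- p[order(p$start), ]
    expect_true(all(diff(p$start) >= (p$end - p$start)[-nrow(p)]))
  }
  # exactly two exons per gene, intron 1 is their genomic gap
  tab <- table(ann$exons$gene_id)
  expect_true(all(tab == 2))
})

test_that("a chromosome too short for its genes raises a sizing error", {
  expect_error(generate_annotation(
    small_config(chrom_lengths = c(tiny = 5e4))), "tiny")
})

test_that("generation is deterministic down to written bytes", {
  cfg <- small_config()
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_synthetic_dataset(generate_dataset(cfg), d1)
  write_synthetic_dataset(generate_dataset(cfg), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- file.path(d2, basename(f1))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the data
  d3 <- file.path(tempdir(), "det3")
  write_synthetic_dataset(generate_dataset(small_config(seed = 2L)), d3)
  mtx3 <- tools::md5sum(file.path(d3, "rna.mtx"))
  expect_false(identical(unname(tools::md5sum(file.path(d1, "rna.mtx"))),
                         unname(mtx3)))
})

test_that("planted DEG shifts have the configured sign at generation", {
  sim <- small_dataset()
  cnt <- sim$counts
  lg <- log2(cnt$rna_counts + 1)
  for (i in seq_len(nrow(sim$truth$deg))) {
    row <- sim$truth$deg[i, ]
    sel <- cnt$nuclei$cluster == row$cluster
    load <- sel & cnt$nuclei$diagnosis == "LOAD"
    norm <- sel & cnt$nuclei$diagnosis == "Normal"
    diff <- mean(lg[row$feature, load]) - mean(lg[row$feature, norm])
    expect_equal(sign(diff), sign(row$log2fc))
  }
})

test_that("hybrid fraction matches the planted count within binomial
           tolerance", {
  sim <- small_dataset()
  sc <- sim$counts$scores
  x1 <- apply(sc, 1, max)
  x2 <- apply(sc, 1, function(v) sort(v, decreasing = TRUE)[2])
  observed <- sum((x1 - x2) / x1 < 0.2)
  n <- nrow(sc)
  expected <- round(sim$config$hybrid_frac * n)
  # all planted hybrids qualify by construction; background nuclei add a
  # few borderline cases at most
  expect_gte(observed, expected)
  expect_lte(observed, expected + ceiling(3 * sqrt(n * 0.05)))
  planted <- sim$truth$hybrid_barcodes
  expect_true(all(((x1 - x2) / x1)[planted] < 0.2))
})

test_that("SNP ledger marks decoys as filter-excluded and loss SNPs
           lower the score", {
  sim <- small_dataset()
  tr <- sim$truth$snps
  expect_true(all(tr$filter_excluded[tr$effect == "decoy"]))
  snps <- sim$sequences$snps
  expect_true(all(snps$maf[match(tr$snp[tr$effect == "decoy"],
                                 snps$snp)] < 0.01))
  expect_true(all(tr$score_ref_minus_alt[tr$effect == "loss"] > 0))
  expect_true(all(tr$score_ref_minus_alt[tr$effect == "gain"] < 0))
})

test_that("planted motif instances clear the exact threshold", {
  sim <- small_dataset()
  for (i in seq_len(nrow(sim$sequences$motif_plants))) {
    pl <- sim$sequences$motif_plants[i, ]
    pw <- sim$sequences$pwms[[pl$pwm]]
    et <- exact_threshold(pw)
    expect_gte(pl$score, et$threshold)
  }
})

test_that("tag-window ledger flags agree with a direct distance check", {
  sim <- small_dataset()
  flags <- sim$truth$peaks_in_gwas_window
  pk <- sim$annotation$peaks
  tags <- sim$sequences$tag_snps
  for (i in seq_len(nrow(pk))) {
    near <- any(tags$chrom == pk$chrom[i] &
                  tags$pos >= pk$start[i] - 5e5 &
                  tags$pos <= pk$end[i] - 1 + 5e5)
    expect_identical(unname(flags[pk$name[i]]), near)
  }
})

test_that("VCF output round-trips through an independent reader", {
  skip_if_not_installed("vcfR")
  sim <- small_dataset()
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$sequences$snps, f)
  v <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_equal(nrow(v@fix), nrow(sim$sequences$snps))
  expect_identical(unname(v@fix[, "ID"]), sim$sequences$snps$snp)
  expect_equal(as.integer(v@fix[, "POS"]), sim$sequences$snps$pos + 1L)
})

test_that("GTF round-trip preserves genes, exons and derived regions", {
  sim <- small_dataset()
  f <- tempfile(fileext = ".gtf")
  write_gtf(sim$annotation, f)
  back <- read_gtf_annotation(f)
  expect_equal(back$genes$tss, sim$annotation$genes$tss)
  expect_equal(back$promoters$start, sim$annotation$promoters$start)
  i1 <- back$intron1[match(sim$annotation$intron1$gene_id,
                           back$intron1$gene_id), ]
  expect_equal(i1$start, sim$annotation$intron1$start)
  expect_equal(i1$end, sim$annotation$intron1$end)
})
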