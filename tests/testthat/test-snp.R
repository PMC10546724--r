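# Importance-sampling affinity-change test and candidate criteria.

# exhaustive oracle for L = 3: enumerate all flank configurations of the
# 2L-1 context under the uniform background, reference allele at centre
exact_affinity_p <- function(pw, ref, alt) {
  ref_c <- match(ref, c("A", "C", "G", "T"))
  alt_c <- match(alt, c("A", "C", "G", "T"))
  d_of <- function(x) {
    xr <- replace(x, 3, ref_c); xa <- replace(x, 3, alt_c)
    best <- function(v) max(snregnet:::window_scores(v, pw),
                            snregnet:::window_scores(
                              snregnet:::revcomp_codes(v), pw))
    best(xr) - best(xa)
  }
  g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  ds <- apply(g, 1, function(f) d_of(c(f[1], f[2], 1L, f[3], f[4])))
  list(d = ds, p_of = function(d_obs) {
    if (d_obs >= 0) mean(ds >= d_obs) else mean(ds <= d_obs)
  })
}

test_that("identical alleles give p = 1 and no effect", {
  pw <- build_pwm(toy_pfm(3), tf = "T")
  r <- affinity_test(pw, "AACGT", "C", "C", n_runs = 3)
  expect_equal(r$p_mean, 1)
  expect_identical(r$effect, "none")
})

test_that("run summaries respect min <= mean <= max", {
  pw <- build_pwm(toy_pfm(3, seed = 4), tf = "T")
  r <- affinity_test(pw, "ACGTA", "G", "T", n_runs = 50, seed = 2)
  expect_lte(r$p_min, r$p_mean)
  expect_lte(r$p_mean, r$p_max)
})

test_that("importance-sampled p matches the L = 3 enumeration oracle for
           loss and gain", {
  pfm <- toy_pfm(3, consensus = c(1, 3, 2), strength = 85)
  pw <- build_pwm(pfm, tf = "T")
  oracle <- exact_affinity_p(pw, "A", "T")
  ctx <- "AAGCT"  # consensus AGC planted at the centre window
  r <- affinity_test(pw, ctx, "A", "T", n_runs = 300, seed = 5)
  p_ex <- oracle$p_of(r$statistic)
  se <- sqrt(r$p_var / r$n_runs)
  expect_lt(abs(r$p_mean - p_ex), 3 * se)
  expect_identical(r$effect, "loss")
  # gain: reference is a weak base, alternate restores the consensus
  oracle_g <- exact_affinity_p(pw, "T", "G")
  rg <- affinity_test(pw, "AAGCT", "T", "G", n_runs = 300, seed = 6)
  pg <- oracle_g$p_of(rg$statistic)
  seg <- sqrt(rg$p_var / rg$n_runs)
  expect_lt(abs(rg$p_mean - pg), 3 * seg)
  expect_identical(rg$effect, "gain")
})

test_that("Monte-Carlo variance shrinks roughly as 1/N", {
  pw <- build_pwm(toy_pfm(3, seed = 7), tf = "T")
  r1 <- affinity_test(pw, "ACGTA", "G", "A", n_mc = 100, n_runs = 120,
                      seed = 3)
  r4 <- affinity_test(pw, "ACGTA", "G", "A", n_mc = 400, n_runs = 120,
                      seed = 4)
  ratio <- r1$p_var / r4$p_var
  expect_gt(ratio, 2)   # ~4 expected; allow Monte-Carlo slack
  expect_lt(ratio, 8)
})

test_that("non-central SNP contexts are rejected", {
  pw <- build_pwm(toy_pfm(3), tf = "T")
  expect_error(affinity_test(pw, "ACGT", "C", "A"), "2L-1")
})

test_that("candidate criteria exclude low MAF and missing tag windows", {
  sim <- small_dataset()
  pl_dir <- file.path(tempdir(), "snp-cand")
  # build the upstream tables directly from generator outputs
  edges <- coaccessibility(sim$coaccess$matrix, sim$annotation$peaks)
  ccs <- extract_ccans(edges)
  dap <- sim$truth$dap[sim$truth$dap$cluster == "C1",
                       c("feature", "log2fc")]
  deg <- sim$truth$deg[sim$truth$deg$cluster == "C1",
                       c("feature", "log2fc")]
  ccs <- lapply(ccs, function(cc)
    c(cc, classify_ccan(cc, dap, deg, sim$annotation$peaks,
                        sim$annotation)))
  seqs <- sim$sequences$sequences
  hits <- do.call(rbind, lapply(sim$sequences$pwms, function(pw) {
    h <- scan_motifs(seqs, pw)
    if (nrow(h) == 0) return(NULL)
    data.frame(peak = h$seq,
               chrom = sim$annotation$peaks$chrom[
                 match(h$seq, sim$annotation$peaks$name)],
               start = attr(seqs, "peak_start")[h$seq] + h$start,
               end = attr(seqs, "peak_start")[h$seq] + h$end,
               strand = h$strand, tf = h$tf, score = h$score, p = h$p)
  }))
  cand <- candidate_pairs(hits, sim$sequences$snps, dap, ccs,
                          sim$annotation$peaks, sim$sequences$tag_snps,
                          seqs, sim$sequences$pwms)
  # decoy SNPs (MAF < 1%) never appear
  decoys <- sim$truth$snps$snp[sim$truth$snps$effect == "decoy"]
  expect_false(any(cand$snp %in% decoys))
  # removing all tag SNPs empties the candidate list (criterion c)
  no_tag <- candidate_pairs(hits, sim$sequences$snps, dap, ccs,
                            sim$annotation$peaks,
                            data.frame(chrom = "chrZ", pos = 1),
                            seqs, sim$sequences$pwms)
  expect_equal(nrow(no_tag), 0)
})
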