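# Shared fixtures: a small, fast synthetic configuration and a cached
# dataset generated from it (built once per test run).

small_config <- function(...) {
  args <- list(n_genes = 60L, n_peaks = 80L, nuclei_per_donor = 40L,
               chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
               n_deg_per_cluster = 6L, n_dap_per_cluster = 8L,
               n_ccan_blocks = 2L, n_motifs = 2L, n_motif_plants = 2L,
               n_decoy_snps = 2L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

.fixture_env <- new.env()

small_dataset <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- generate_dataset(small_config())
  .fixture_env$sim
}

# simple PWM fixture: one dominant base per column
toy_pfm <- function(L, consensus = NULL, strength = 85, seed = 1) {
  set.seed(seed)
  if (is.null(consensus)) consensus <- sample(1:4, L, replace = TRUE)
  m <- matrix((100 - strength) / 3, 4, L)
  m[cbind(consensus, seq_len(L))] <- strength
  rownames(m) <- c("A", "C", "G", "T")
  m
}
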