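# Per-nucleus QC metrics, filtering rules, and cross-modality linking.

make_fragments <- function(barcode, n, len, chrom = "chr1", at = 5000L) {
  start <- seq(at, by = 10L, length.out = n)
  data.frame(chrom = chrom, start = start, end = start + len,
             barcode = barcode)
}

test_that("ATAC QC metrics follow their definitions", {
  peaks <- genomic_intervals("chr1", 4000, 20000, "pk1")
  bl <- genomic_intervals("chr1", 5000, 5025, "bl1")
  tss <- data.frame(chrom = "chr1", tss = 500000L)
  fr <- rbind(make_fragments("bc1", 100, 100L),   # nucleosome-free
              make_fragments("bc1", 500, 200L, at = 7000L))  # mono
  qc <- compute_atac_qc(fr, peaks, tss, bl)
  expect_equal(qc$nucleosome_signal, 5.0)  # 500/100, fails the <= 4 rule
  expect_equal(qc$pct_reads_in_peaks, 1.0) # all inside pk1
  # 3 of 600 fragments start on the blacklist interval
  expect_equal(sum(fr$start < 5025 & fr$end > 5000), 3)
  expect_equal(qc$blacklist_ratio, 3 / 600)
})

test_that("zero nucleosome-free fragments give infinite signal", {
  fr <- make_fragments("bc1", 10, 200L)
  qc <- compute_atac_qc(fr, genomic_intervals("chr1", 0, 1e6, "p"),
                        data.frame(chrom = "chr1", tss = 1000L))
  expect_identical(qc$nucleosome_signal, Inf)
})

test_that("RNA filter rules and hybrid formula fire with reasons", {
  qc <- data.frame(barcode = c("a", "b", "c", "d"),
                   n_features = c(150L, 5000L, 5000L, 5000L),
                   pct_mito = c(0.01, 0.30, 0.05, 0.05))
  sc <- data.frame(barcode = c("a", "b", "c"),
                   x1 = c(0.9, 0.9, 0.9), x2 = c(0.1, 0.8, 0.45))
  r <- filter_nuclei(qc, sc, "rna")
  expect_setequal(r$kept, "c")  # (0.9-0.45)/0.9 = 0.5 >= 0.2
  reasons <- setNames(r$removed$reason, r$removed$barcode)
  expect_match(reasons[["a"]], "n_features")
  expect_match(reasons[["b"]], "pct_mito")
  expect_match(reasons[["b"]], "hybrid")   # (0.9-0.8)/0.9 = 0.111 < 0.2
  expect_match(reasons[["d"]], "unscored")
  expect_equal(length(r$kept) + nrow(r$removed), nrow(qc))
})

test_that("ATAC filter applies the per-sample 99th percentile cap", {
  n <- 200
  qc <- data.frame(barcode = sprintf("b%03d", 1:n),
                   donor = rep(c("d1", "d2"), each = n / 2),
                   nucleosome_signal = 1, tss_enrichment = 5,
                   pct_reads_in_peaks = 0.5,
                   peak_region_fragments = rep(2000L, n),
                   blacklist_ratio = 0.01)
  qc$peak_region_fragments[1] <- 90000L   # d1's extreme outlier
  sc <- data.frame(barcode = qc$barcode, x1 = 0.9, x2 = 0.2)
  r <- filter_nuclei(qc, sc, "atac")
  expect_true("b001" %in% r$removed$barcode)
  expect_match(r$removed$reason[r$removed$barcode == "b001"],
               "peak_region_fragments")
})

test_that("filtering is idempotent and row-order invariant", {
  sim <- small_dataset()
  sc <- data.frame(barcode = rownames(sim$counts$scores),
                   x1 = apply(sim$counts$scores, 1, max),
                   x2 = apply(sim$counts$scores, 1, function(v)
                     sort(v, decreasing = TRUE)[2]))
  r1 <- filter_nuclei(sim$counts$qc, sc, "rna")
  qc2 <- sim$counts$qc[sim$counts$qc$barcode %in% r1$kept, ]
  r2 <- filter_nuclei(qc2, sc, "rna")
  expect_setequal(r2$kept, r1$kept)
  shuffled <- sim$counts$qc[rev(seq_len(nrow(sim$counts$qc))), ]
  r3 <- filter_nuclei(shuffled, sc, "rna")
  expect_setequal(r3$kept, r1$kept)
})

test_that("cluster links use summed-score argmax with hybrid score", {
  sc <- rbind(c(6, 3), c(4, 2))          # cluster a: sums {A:10, B:5}
  colnames(sc) <- c("A", "B")
  r <- link_clusters(sc, c("a", "a"))
  expect_identical(r$linked_rna_cluster, "A")
  expect_equal(r$cluster_hybrid_score, 0.5)
  expect_false(r$tie)
  # tie -> lowest id, flagged
  sc2 <- rbind(c(7, 7)); colnames(sc2) <- c("B", "A")
  r2 <- link_clusters(sc2, "a")
  expect_identical(r2$linked_rna_cluster, "A")
  expect_true(r2$tie)
})

test_that("links are invariant to permuting nuclei within clusters", {
  set.seed(8)
  sc <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  cl <- rep(c("x", "y"), each = 10)
  perm <- sample(20)
  r1 <- link_clusters(sc, cl)
  r2 <- link_clusters(sc[perm, ], cl[perm])
  expect_equal(r1, r2, ignore_attr = TRUE)
})

test_that("linked synthetic clusters are cell-type concordant", {
  sim <- small_dataset()
  cl <- paste0("C", seq_len(sim$config$n_clusters))
  ct <- setNames(cl, cl)
  r <- link_clusters(sim$counts$scores, sim$counts$nuclei$cluster,
                     atac_celltype = ct, rna_celltype = ct)
  expect_identical(r$linked_rna_cluster, r$atac_cluster)
  expect_true(all(r$celltype_concordant))
})

test_that("Jaccard validation matches a direct set computation", {
  links <- data.frame(atac_cluster = c("a", "b"),
                      linked_rna_cluster = c("r1", "r2"))
  atac <- setNames(rep(c("a", "b"), each = 100), sprintf("bc%03d", 1:200))
  rna <- atac
  names(rna) <- names(atac)
  rna[] <- ifelse(atac == "a", "r1", "r2")
  r <- jaccard_validate(links, atac, rna)
  expect_equal(r$per_cluster$jaccard, c(1, 1))
  expect_equal(r$mean, 1)
  # partial overlap: a = {1..100}, r1 = {51..150} -> J = 50/150
  rna2 <- setNames(c(rep("r2", 50), rep("r1", 100), rep("r2", 50)),
                   names(atac))
  r2 <- jaccard_validate(links[1, ], atac, rna2)
  expect_equal(r2$per_cluster$jaccard, 1 / 3)
  # 10% shuffled labels: recompute independently from the sets
  set.seed(11)
  rna3 <- rna
  flip <- sample(200, 20)
  rna3[flip] <- ifelse(rna3[flip] == "r1", "r2", "r1")
  r3 <- jaccard_validate(links, atac, rna3)
  for (i in 1:2) {
    A <- names(atac)[atac == links$atac_cluster[i]]
    B <- names(rna3)[rna3 == links$linked_rna_cluster[i]]
    expect_equal(r3$per_cluster$jaccard[i],
                 length(intersect(A, B)) / length(union(A, B)))
  }
})
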