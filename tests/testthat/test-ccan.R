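# Distance-penalized sparse inverse covariance, CCAN extraction,
# directionality classification, cCRE linking, GWAS windows, GO
# enrichment.

test_that("with vanishing penalty the estimate matches direct inversion", {
  set.seed(1)
  S <- cov(MASS::mvrnorm(2000, rep(0, 4),
                         Sigma = solve(diag(4) - 0.15 * (1 - diag(4)))))
  fit <- glasso_penalized(S, rho = 1e-8)
  direct <- solve(S)
  d <- sqrt(diag(direct))
  pc_direct <- -direct / tcrossprod(d); diag(pc_direct) <- 1
  expect_equal(fit$partial_cor, pc_direct, tolerance = 1e-3)
})

test_that("large penalties zero the off-diagonal support", {
  set.seed(2)
  S <- cov(matrix(rnorm(400), 100, 4))
  rho <- matrix(10, 4, 4); diag(rho) <- 0
  fit <- glasso_penalized(S, rho)
  off <- fit$precision[upper.tri(fit$precision)]
  expect_true(all(abs(off) < 1e-10))
})

test_that("identity-precision data produce no edges at the 0.2 cutoff", {
  sim <- small_dataset()
  peaks <- sim$annotation$peaks
  edge_counts <- vapply(1:5, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(200 * nrow(peaks)), 200)
    colnames(X) <- peaks$name
    e <- coaccessibility(X, peaks)
    sum(abs(e$score) >= 0.2)
  }, numeric(1))
  expect_equal(sum(edge_counts), 0)
})

test_that("planted blocks rank above background and beyond-limit pairs
           are never emitted", {
  cfg <- small_config(n_ccan_blocks = 1L)
  ann <- generate_annotation(cfg)
  plan <- truth_plan(cfg, ann)
  coa <- generate_coaccessible_counts(cfg, ann, n_samples = 500L,
                                      plan = plan)
  edges <- coaccessibility(coa$matrix, ann$peaks)
  expect_true(all(edges$distance <= 5e5))
  bl <- coa$blocks[[1]]
  ib <- edges$peak_a %in% bl & edges$peak_b %in% bl
  expect_equal(sum(ib), choose(length(bl), 2))
  expect_gt(min(abs(edges$score[ib])), max(abs(edges$score[!ib])))
})

test_that("ledger check: empirical inverse covariance separates the
           planted block", {
  cfg <- small_config(n_ccan_blocks = 1L)
  ann <- generate_annotation(cfg)
  plan <- truth_plan(cfg, ann)
  coa <- generate_coaccessible_counts(cfg, ann, n_samples = 200L,
                                      plan = plan)
  idx <- match(coa$blocks[[1]], colnames(coa$matrix))
  P <- solve(cov(coa$matrix))  # direct inversion, independent of glasso
  d <- sqrt(diag(P)); pc <- -P / tcrossprod(d)
  ib <- as.matrix(expand.grid(idx, idx))
  ib <- ib[ib[, 1] < ib[, 2], , drop = FALSE]
  out_pairs <- cbind(idx[1], setdiff(seq_len(ncol(pc)), idx)[1:20])
  expect_gt(mean(pc[ib]), mean(abs(pc[out_pairs])))
})

test_that("CCAN extraction respects threshold, size and components", {
  clique <- function(peaks, score) {
    g <- t(combn(peaks, 2))
    data.frame(peak_a = g[, 1], peak_b = g[, 2], score = score,
               distance = 1000)
  }
  e <- rbind(clique(sprintf("a%d", 1:5), 0.5),
             clique(sprintf("b%d", 1:5), 0.5))
  ccs <- extract_ccans(e)
  expect_length(ccs, 2)
  expect_setequal(unlist(lapply(ccs, `[[`, "peaks")),
                  c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)))
  expect_length(extract_ccans(clique(sprintf("c%d", 1:5), 0.19)), 0)
  # a 2-peak community is below the minimum size
  expect_length(extract_ccans(clique(sprintf("d%d", 1:2), 0.9)), 0)
})

test_that("directionality classification follows the sign taxonomy", {
  sim <- small_dataset()
  ann <- sim$annotation
  # build a CCAN over one planted block (anchor + cCRE present)
  info <- sim$plan$block_info[1, ]
  bl <- sim$truth$ccan_blocks[[1]]
  cc <- list(id = "cc1", peaks = bl,
             edges = data.frame(peak_a = bl[1], peak_b = bl[2],
                                score = 0.5, distance = 100))
  dap <- data.frame(feature = c(info$anchor_peak, info$ccre_peak),
                    log2fc = c(0.5, 0.5))
  deg <- data.frame(feature = info$gene, log2fc = 0.4)
  r <- classify_ccan(cc, dap, deg, ann$peaks, ann)
  expect_identical(r$klass, "unidirectional")
  dap2 <- dap; dap2$log2fc <- c(0.5, -0.5)
  expect_identical(classify_ccan(cc, dap2, deg, ann$peaks, ann)$klass,
                   "mixed")
  dap3 <- dap; dap3$log2fc <- c(-0.5, -0.5)
  expect_identical(classify_ccan(cc, dap3, deg, ann$peaks, ann)$klass,
                   "bidirectional")
  expect_identical(classify_ccan(cc, dap[0, ], deg, ann$peaks,
                                 ann)$klass, "unclassified")
  expect_identical(
    classify_ccan(cc, dap, deg[0, ], ann$peaks, ann)$klass,
    "unclassified")
})

test_that("cCRE links require all four criteria", {
  sim <- small_dataset()
  ann <- sim$annotation
  info <- sim$plan$block_info[1, ]
  bl <- sim$truth$ccan_blocks[[1]]
  edges <- data.frame(peak_a = info$ccre_peak, peak_b = info$anchor_peak,
                      score = 0.5, distance = 1000)
  base_cc <- list(id = "cc1", peaks = bl, edges = edges)
  dap <- data.frame(feature = c(info$anchor_peak, info$ccre_peak),
                    log2fc = c(0.5, 0.5))
  deg <- data.frame(feature = info$gene, log2fc = 0.4)
  cls <- classify_ccan(base_cc, dap, deg, ann$peaks, ann)
  cc <- c(base_cc, cls)
  links <- link_ccres(list(cc), dap, deg, ann$peaks, ann)
  expect_equal(nrow(links), 1)
  expect_identical(links$ccre, info$ccre_peak)
  expect_identical(links$target, info$gene)

  # (1) low co-accessibility
  cc1 <- cc; cc1$edges$score <- 0.1
  expect_equal(nrow(link_ccres(list(cc1), dap, deg, ann$peaks, ann)), 0)
  # (2) anchor not a DAP
  dap2 <- dap[dap$feature != info$anchor_peak, ]
  cls2 <- classify_ccan(base_cc, dap2, deg, ann$peaks, ann)
  expect_equal(nrow(link_ccres(list(c(base_cc, cls2)), dap2, deg,
                               ann$peaks, ann)), 0)
  # (3) sign discordance
  deg3 <- deg; deg3$log2fc <- -0.4
  cls3 <- classify_ccan(base_cc, dap, deg3, ann$peaks, ann)
  expect_equal(nrow(link_ccres(list(c(base_cc, cls3)), dap, deg3,
                               ann$peaks, ann)), 0)
  # (4) effect size below 0.15
  deg4 <- deg; deg4$log2fc <- 0.10
  cls4 <- classify_ccan(base_cc, dap, deg4, ann$peaks, ann)
  expect_equal(nrow(link_ccres(list(c(base_cc, cls4)), dap, deg4,
                               ann$peaks, ann)), 0)
  # bidirectional CCANs are never considered
  dap5 <- dap; dap5$log2fc <- c(-0.5, -0.5)
  cls5 <- classify_ccan(base_cc, dap5, deg, ann$peaks, ann)
  expect_equal(nrow(link_ccres(list(c(base_cc, cls5)), dap5, deg,
                               ann$peaks, ann)), 0)
})

test_that("GWAS window flags use the inclusive 500 kb boundary", {
  tags <- data.frame(chrom = "chr1", pos = 1e6)
  iv <- genomic_intervals(rep("chr1", 3),
                          c(1400000, 1500001, 1500000),
                          c(1400200, 1500101, 1500001))
  f <- gwas_window_overlap(iv, tags)
  expect_identical(f, c(TRUE, FALSE, TRUE))
  # chromosome mismatch is never flagged
  expect_false(gwas_window_overlap(
    genomic_intervals("chr2", 1e6, 1e6 + 100), tags))
})

test_that("GO enrichment matches the hypergeometric tail", {
  bg <- sprintf("g%03d", 1:1000)
  term <- bg[1:10]
  sets <- list(hit = term, other = bg[900:920])
  r <- go_enrichment(term, bg, sets)
  # oracle: direct tail sum of the hypergeometric pmf
  pmf <- function(k) choose(10, k) * choose(990, 10 - k) /
    choose(1000, 10)
  expect_equal(r$p[r$term == "hit"], pmf(10), tolerance = 1e-12)
  expect_false("other" %in% r$term)  # 0 test genes in that term
  # a term with only 2 test genes is excluded even if enriched
  sets2 <- list(small = bg[1:2])
  expect_equal(nrow(go_enrichment(bg[1:2], bg, sets2)), 0)
  # disjoint test set: p = 1, filtered by the cutoff
  expect_equal(nrow(go_enrichment(bg[500:520], bg, list(t = term))), 0)
})

test_that("kNN aggregation normalizes depth and groups by state", {
  set.seed(31)
  counts <- matrix(rpois(20 * 100, 2), nrow = 20,
                   dimnames = list(sprintf("p%d", 1:20), NULL))
  emb <- matrix(rnorm(200), 100, 2)
  # k = 1: identity up to depth normalization
  a1 <- aggregate_knn(counts, emb, k = 1L)
  expect_equal(a1$matrix[5, ],
               counts[, 5] / sum(counts[, 5]) * 1e4,
               ignore_attr = TRUE)
  # identical nuclei: every group vector equal
  cc <- matrix(rep(counts[, 1], 60), nrow = 20)
  ai <- aggregate_knn(cc, matrix(0, 60, 2), k = 10L)
  expect_true(all(apply(ai$matrix, 2, function(x) diff(range(x)) == 0)))
  # a cluster smaller than k errors with advice
  expect_error(aggregate_knn(counts[, 1:5], emb[1:5, ], k = 50L),
               "merge")
  # two separated states: groups stay state-pure
  emb2 <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
                matrix(rnorm(100, 10, 0.3), 50, 2))
  state <- rep(1:2, each = 50)
  a2 <- aggregate_knn(counts, emb2, k = 10L)
  purity <- vapply(a2$members, function(m)
    max(table(state[m])) / length(m), numeric(1))
  expect_gte(mean(purity == 1), 0.9)
})
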