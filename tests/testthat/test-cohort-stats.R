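# Donor-level demographic statistics and bootstrapped proportion tests.

test_that("pooled t test reproduces the cohort table statistics", {
  # male age: 77.67 +/- 7.09 (n=6) vs 75.83 +/- 12.16 (n=6)
  r <- summary_t_test(group_summary(77.67, 7.09, 6),
                      group_summary(75.83, 12.16, 6))
  expect_equal(r$df, 10)
  expect_equal(round(r$t, 2), 0.32)
  expect_equal(round(r$p, 2), 0.76)
  # female PMI: 10.59 +/- 4.73 vs 9.36 +/- 5.83
  r2 <- summary_t_test(group_summary(10.59, 4.73, 6),
                       group_summary(9.36, 5.83, 6))
  expect_equal(round(r2$t, 2), 0.40)
  expect_equal(round(r2$p, 2), 0.70)
})

test_that("summary t test is antisymmetric and handles degenerate groups", {
  g1 <- group_summary(5, 1, 8); g2 <- group_summary(3.2, 2, 10)
  a <- summary_t_test(g1, g2); b <- summary_t_test(g2, g1)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  same <- summary_t_test(g1, g1)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_warning(z <- summary_t_test(group_summary(1, 0, 5),
                                     group_summary(2, 0, 5)), "zero")
  expect_equal(z$p, 0)
  expect_error(summary_t_test(group_summary(1, 0, 5),
                              group_summary(1, 0, 5)), "degenerate")
})

test_that("demographic comparison picks the branch Shapiro-Wilk dictates", {
  set.seed(42)
  x <- rnorm(6); y <- rnorm(6)
  # fixture chosen normal: verify with Shapiro-Wilk directly
  stopifnot(shapiro.test(x)$p.value > 0.05, shapiro.test(y)$p.value > 0.05)
  r <- demographic_compare(x, y)
  expect_identical(r$test, "t")
  skew <- c(0.1, 0.12, 0.13, 0.15, 0.2, 60)  # heavy right tail
  stopifnot(shapiro.test(skew)$p.value <= 0.05)
  r2 <- demographic_compare(skew, y)
  expect_identical(r2$test, "wilcoxon")
  r3 <- demographic_compare(x, x)
  expect_equal(r3$p, 1)
  expect_warning(r4 <- demographic_compare(c(1, 2), c(3, 4)), "small")
  expect_identical(r4$test, "wilcoxon")
})

test_that("per-donor proportions sum to one", {
  nt <- data.frame(donor = rep(c("d1", "d2"), each = 6),
                   diagnosis = rep(c("LOAD", "Normal"), each = 6),
                   unit = c(rep("A", 4), rep("B", 2),
                            rep("A", 1), rep("B", 5)))
  pr <- donor_proportions(nt)
  sums <- tapply(pr$proportion, pr$donor, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(pr$proportion[pr$donor == "d1" & pr$unit == "A"], 4 / 6)
})

test_that("bootstrap Wilcoxon degenerates to the plain test and is
           row-order invariant", {
  set.seed(3)
  nt <- do.call(rbind, lapply(1:8, function(d) {
    n <- 40
    data.frame(donor = sprintf("d%d", d),
               diagnosis = if (d <= 4) "LOAD" else "Normal",
               unit = sample(c("A", "B"), n, TRUE,
                             prob = if (d <= 4) c(0.7, 0.3)
                             else c(0.4, 0.6)))
  }))
  r1 <- bootstrap_wilcoxon_proportions(nt, frac = 1, iters = 1L, seed = 9)
  pr <- donor_proportions(nt)
  direct <- sapply(c("A", "B"), function(u)
    suppressWarnings(wilcox.test(
      pr$proportion[pr$unit == u & pr$diagnosis == "LOAD"],
      pr$proportion[pr$unit == u & pr$diagnosis == "Normal"])$p.value))
  expect_equal(r1$p, unname(direct[r1$unit]), tolerance = 1e-12)

  shuf <- nt[sample(nrow(nt)), ]
  r2 <- bootstrap_wilcoxon_proportions(nt, seed = 5)
  r3 <- bootstrap_wilcoxon_proportions(shuf, seed = 5)
  expect_equal(r2, r3, ignore_attr = TRUE)
})

test_that("identical per-donor proportions give FDR 1", {
  nt <- expand.grid(donor = sprintf("d%d", 1:8), unit = c("A", "B"))
  nt <- nt[rep(seq_len(nrow(nt)), each = 10), ]
  nt$diagnosis <- ifelse(as.integer(sub("d", "", nt$donor)) <= 4,
                         "LOAD", "Normal")
  # full-data iterations: no rank separation anywhere
  r <- bootstrap_wilcoxon_proportions(nt, frac = 1, iters = 3L, seed = 2)
  expect_true(all(r$fdr == 1))
  expect_true(all(r$tier == ""))
})

test_that("BH ordering of raw p is preserved in FDR", {
  p <- c(0.001, 0.2, 0.04, 0.9, 0.04)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q >= p))
})
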