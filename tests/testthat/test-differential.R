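# Hurdle differential expression and binomial-LRT differential
# accessibility.

sim_gene <- function(seed, lfc = 0.5, donor_sd = 0.2, n_donors = 12,
                     per_donor = 60, base = 1.5) {
  set.seed(seed)
  donors <- sprintf("D%02d", seq_len(2 * n_donors))
  dx <- rep(c("LOAD", "Normal"), each = n_donors)
  donor <- rep(donors, each = per_donor)
  dxv <- rep(dx, each = per_donor)
  u <- rnorm(2 * n_donors, 0, donor_sd)[rep(seq_len(2 * n_donors),
                                            each = per_donor)]
  mu <- pmax(2^(base + lfc * (dxv == "LOAD") + u) - 1, 0.05)
  list(y = rnbinom(length(mu), mu = mu, size = 2), dx = dxv,
       donor = donor, cdr = runif(length(mu), 0.3, 0.6))
}

test_that("hurdle detects a planted positive shift with the right sign", {
  d <- sim_gene(1, lfc = 0.5)
  r <- de_hurdle(d$y, d$dx, d$donor, cdr = d$cdr, nagq = 1L)
  expect_gt(r$log2fc, 0)
  expect_lt(r$p, 0.01)
  expect_gte(r$lrt, 0)
})

test_that("relabelling the groups flips the fold change, not the p", {
  d <- sim_gene(2, lfc = 0.4)
  r1 <- de_hurdle(d$y, d$dx, d$donor, cdr = d$cdr, control_level = "Normal",
                  nagq = 1L)
  swapped <- ifelse(d$dx == "LOAD", "Normal", "LOAD")
  r2 <- de_hurdle(d$y, swapped, d$donor, cdr = d$cdr,
                  control_level = "Normal", nagq = 1L)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("without donor effects the mixed fit matches the fixed fit", {
  d <- sim_gene(3, lfc = 0, donor_sd = 0)
  rm_ <- de_hurdle(d$y, d$dx, d$donor, cdr = d$cdr, method = "mixed",
                   nagq = 1L)
  rf <- de_hurdle(d$y, d$dx, d$donor, cdr = d$cdr, method = "fixed")
  # the random-intercept variance sits at the boundary; log-likelihoods of
  # the two fits coincide up to optimizer tolerance
  ll <- function(r) r$fit$discrete$ll_full + r$fit$continuous$ll_full
  expect_equal(ll(rm_), ll(rf), tolerance = 1e-4)
})

test_that("the table wrapper filters by detection and adjusts within the
           table", {
  set.seed(4)
  counts <- rbind(expressed = rpois(200, 3),
                  rare = c(rpois(6, 2), rep(0, 194)))
  colnames(counts) <- sprintf("n%03d", 1:200)
  dx <- rep(c("LOAD", "Normal"), each = 100)
  donor <- rep(sprintf("D%d", 1:8), each = 25)
  tab <- de_hurdle_table(counts, dx, donor, method = "fixed")
  expect_false("rare" %in% tab$feature)  # 3% < 10% in both groups
  expect_identical(attr(tab, "filtered")$feature, "rare")
  expect_true(all(tab$fdr >= tab$p))
})

test_that("a constant peak yields p = 1 in the accessibility LRT", {
  set.seed(5)
  covs <- data.frame(a = rnorm(100))
  r <- da_binomial_lr(rep(2L, 100), rep(c("LOAD", "Normal"), 50), covs)
  expect_equal(r$p, 1)
  expect_equal(r$lrt, 0)
})

test_that("a planted accessible-in-LOAD peak is detected with + log2fc", {
  set.seed(6)
  n <- 400
  dx <- rep(c("LOAD", "Normal"), each = n / 2)
  y <- rpois(n, lambda = ifelse(dx == "LOAD", 3, 1.2))
  covs <- data.frame(depth = rnorm(n))
  r <- da_binomial_lr(y, dx, covs)
  expect_gt(r$log2fc, 0)
  expect_lt(r$p, 1e-6)
})

test_that("null accessibility p-values are roughly uniform", {
  set.seed(7)
  ps <- replicate(200, {
    n <- 120
    dx <- rep(c("LOAD", "Normal"), each = n / 2)
    y <- rpois(n, 1.5)
    da_binomial_lr(y, dx)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("perfect separation is ridge-stabilized and flagged", {
  n <- 60
  dx <- rep(c("LOAD", "Normal"), each = n / 2)
  y <- ifelse(dx == "LOAD", 5L, 0L) + 0L
  r <- da_binomial_lr(y, dx)
  expect_identical(r$flag, "separation")
  expect_true(is.finite(r$p))
  expect_lt(r$p, 0.01)
})

test_that("BH step-up matches the hand computation", {
  # p = (0.01, 0.02, 0.03), m = 3: q_i = min over j >= i of p_(j) * m / j
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
  expect_equal(bh_fdr(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))
})
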