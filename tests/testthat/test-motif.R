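# PWM construction, exact score distributions, scanning, enrichment.

test_that("PWM entries follow the log2 probability-ratio definition", {
  pfm <- matrix(c(10, 0, 0, 0), 4, 1, dimnames = list(c("A", "C", "G",
                                                        "T"), NULL))
  pw0 <- build_pwm(cbind(pfm, pfm), pseudocount = 0)
  expect_equal(unname(pw0$mat["A", 1]), log2(4))
  expect_identical(unname(pw0$mat["C", 1]), -Inf)
  # uniform column, uniform background: all zeros
  uf <- matrix(5, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_true(all(abs(build_pwm(uf)$mat) < 1e-12))
  # halving one base's background probability adds exactly one bit
  bg <- markov_background(initial = c(0.125, 0.25, 0.25, 0.375),
                          transition = matrix(rep(c(0.125, 0.25, 0.25,
                                                    0.375), each = 4),
                                              4, 4, byrow = FALSE))
  pw_u <- build_pwm(cbind(pfm, pfm), pseudocount = 0.8)
  pw_b <- build_pwm(cbind(pfm, pfm), background = bg, pseudocount = 0.8)
  expect_equal(unname(pw_b$mat["A", 1] - pw_u$mat["A", 1]), 1)
  expect_error(build_pwm(matrix(0, 4, 2)), "zero-total")
})

test_that("exact tail for a two-column PWM matches hand enumeration", {
  # only "AA" reaches the top score; uniform iid background
  pfm <- matrix(1, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  pfm["A", ] <- 97
  pw <- build_pwm(pfm)
  et <- exact_threshold(pw, alpha = 1)
  top <- sum(apply(pw$mat, 2, max))
  expect_equal(et$pvalue(top), 1 / 16, tolerance = 1e-9)
  # alpha = 1: the threshold is the minimum achievable score
  expect_equal(et$threshold, sum(apply(pw$mat, 2, min)),
               tolerance = 1e-3)
})

test_that("DP tail equals brute-force enumeration for small motifs", {
  for (s in 1:3) {
    L <- c(3, 4, 5)[s]
    pw <- build_pwm(toy_pfm(L, seed = s), tf = "t")
    et <- exact_threshold(pw, alpha = 1)
    # oracle: enumerate all 4^L windows under the iid uniform background
    grids <- do.call(expand.grid, rep(list(1:4), L))
    sc <- apply(grids, 1, function(v)
      sum(pw$mat[cbind(v, seq_len(L))]))
    for (q in quantile(sc, c(0.5, 0.9, 0.99))) {
      brute <- mean(sc >= q - 1e-9)
      expect_equal(et$pvalue(q), brute, tolerance = 2e-3)
    }
  }
})

test_that("degenerate PWMs cannot reach the scan threshold", {
  uf <- matrix(25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(exact_threshold(build_pwm(uf)), "degenerate|threshold")
})

test_that("scanning recovers planted instances on both strands", {
  pw <- build_pwm(toy_pfm(8, consensus = c(1, 2, 3, 4, 1, 2, 1, 3)),
                  tf = "T1")
  cons <- "ACGTACAG"
  rc <- "CTGTACGT"
  set.seed(9)
  left <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  seqs <- c(fwd = paste0(left, cons),
            rev = paste0(rc, left))
  h <- scan_motifs(seqs, pw)
  fw <- h[h$seq == "fwd", ]
  expect_true(any(fw$start == 20 & fw$strand == "+"))
  rv <- h[h$seq == "rev", ]
  expect_true(any(rv$start == 0 & rv$strand == "-"))
  expect_equal(max(fw$score), max(rv$score))  # strand symmetry
})

test_that("overlapping same-TF hits keep only the best score", {
  pw <- build_pwm(toy_pfm(4, consensus = c(1, 1, 1, 1)), tf = "T1")
  et <- exact_threshold(pw, alpha = 1 / 64)  # L = 4 cannot reach 5e-5
  # AAAAA contains two overlapping top windows; the dedup keeps one
  h <- scan_motifs(c(s = "AAAAA"), pw, et)
  expect_equal(nrow(h), 1)
  h2 <- scan_motifs(c(s = "AAAAA"), pw, et, dedup = FALSE)
  expect_gt(nrow(h2), 1)
  expect_equal(h$score, max(h2$score))
})

test_that("sequences shorter than the motif yield no hits", {
  pw <- build_pwm(toy_pfm(8), tf = "T1")
  expect_equal(nrow(scan_motifs(c(s = "ACG"), pw)), 0)
})

test_that("enrichment fold, floor and expression rule behave", {
  set.seed(4)
  pw <- build_pwm(toy_pfm(8, consensus = rep(1, 8)), tf = "T1")
  rand_seq <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1))
  target <- rand_seq(30, 60)
  # plant the consensus into 40% of targets
  idx <- 1:12
  target[idx] <- paste0(substr(target[idx], 1, 20), "AAAAAAAA",
                        substr(target[idx], 29, 60))
  bg <- rand_seq(120, 60)
  names(target) <- paste0("t", seq_along(target))
  names(bg) <- paste0("b", seq_along(bg))
  r <- motif_enrichment(target, bg, list(pw), c(T1 = 0.5))
  expect_gte(r$fold, 1.2)
  expect_true(r$retained)
  # same signal but TF expressed in 8% of cells: excluded
  r2 <- motif_enrichment(target, bg, list(pw), c(T1 = 0.08))
  expect_false(r2$retained)
})

test_that("JASPAR PFM text round-trips", {
  pfms <- list(M1 = toy_pfm(5, seed = 2), M2 = toy_pfm(7, seed = 3))
  f <- tempfile(fileext = ".pfm")
  write_jaspar_pfm(pfms, f)
  back <- read_jaspar_pfm(f)
  expect_equal(back, pfms, ignore_attr = TRUE)
})
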