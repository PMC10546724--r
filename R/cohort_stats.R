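# Donor-level demographic comparisons and case-control cell-proportion
# testing.

#' Group summary for a summary-statistic t test
#'
#' @param mean,sd,n Group mean, standard deviation and size.
#' @return A `group_summary` list.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Recomputes the classical equal-variance two-sample t test from printed
#' group means, SDs and sizes, as used for cohort demographic tables:
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2) / (n_1+n_2-2)} and
#' \eqn{t = (m_1-m_2) / (s_p \sqrt{1/n_1 + 1/n_2})} on
#' \eqn{n_1+n_2-2} degrees of freedom, two-sided.
#'
#' @param g1,g2 Objects from [group_summary()].
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' summary_t_test(group_summary(77.67, 7.09, 6), group_summary(75.83, 12.16, 6))
summary_t_test <- function(g1, g2) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  df <- g1$n + g2$n - 2L
  sp2 <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  if (sp2 == 0) {
    if (g1$mean == g2$mean) stop("both groups degenerate with equal means")
    warning("pooled variance is zero with unequal means; p = 0")
    return(list(t = sign(g1$mean - g2$mean) * Inf, df = df, p = 0))
  }
  t <- (g1$mean - g2$mean) / (sqrt(sp2) * sqrt(1 / g1$n + 1 / g2$n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df = df))
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality check on each group; if both pass (p > 0.05) an
#' equal-variance check (Bartlett) gates into the pooled two-sample t test,
#' otherwise a two-sided Mann-Whitney U test is used. The fired branch is
#' reported so the choice can be audited.
#'
#' @param values1,values2 Numeric vectors of raw per-donor values.
#' @param normality_alpha Shapiro-Wilk significance cutoff (default 0.05).
#' @return List with `test` ("t" or "wilcoxon"), `statistic`, `p`,
#'   `shapiro_p` (length-2), `bartlett_p` (or `NA`).
#' @export
demographic_compare <- function(values1, values2, normality_alpha = 0.05) {
  stopifnot(is.numeric(values1), is.numeric(values2))
  if (length(values1) < 3L || length(values2) < 3L) {
    warning("group too small for a normality test; using Mann-Whitney U")
    w <- stats::wilcox.test(values1, values2, exact = FALSE)
    return(list(test = "wilcoxon", statistic = unname(w$statistic),
                p = w$p.value, shapiro_p = c(NA_real_, NA_real_),
                bartlett_p = NA_real_))
  }
  sw <- c(stats::shapiro.test(values1)$p.value,
          stats::shapiro.test(values2)$p.value)
  if (all(sw > normality_alpha)) {
    bt <- stats::bartlett.test(list(values1, values2))$p.value
    tt <- stats::t.test(values1, values2, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         shapiro_p = sw, bartlett_p = bt)
  } else {
    w <- suppressWarnings(stats::wilcox.test(values1, values2))
    list(test = "wilcoxon", statistic = unname(w$statistic), p = w$p.value,
         shapiro_p = sw, bartlett_p = NA_real_)
  }
}

#' Per-donor proportions of nuclei across units
#'
#' @param nucleus_table Data frame with columns `donor`, `diagnosis`, `unit`
#'   (cell type or subtype label per nucleus).
#' @return Data frame donor/diagnosis/unit/proportion; proportions sum to 1
#'   within donor.
#' @export
donor_proportions <- function(nucleus_table) {
  stopifnot(all(c("donor", "diagnosis", "unit") %in% names(nucleus_table)))
  units <- sort(unique(nucleus_table$unit))
  donors <- unique(nucleus_table[, c("donor", "diagnosis")])
  tab <- table(factor(nucleus_table$donor, levels = donors$donor),
               factor(nucleus_table$unit, levels = units))
  prop <- sweep(tab, 1, pmax(1L, rowSums(tab)), "/")
  out <- data.frame(
    donor = rep(donors$donor, times = length(units)),
    diagnosis = rep(donors$diagnosis, times = length(units)),
    unit = rep(units, each = nrow(donors)),
    proportion = as.vector(prop),
    stringsAsFactors = FALSE)
  out
}

#' Bootstrapped Wilcoxon test of case-control proportion differences
#'
#' In each of `iters` iterations a fraction `frac` of all nuclei is sampled
#' without replacement, per-donor per-unit proportions are recomputed, and a
#' two-sided Wilcoxon rank-sum test compares case vs control donors per
#' unit. The per-unit p-values over iterations are combined (mean by
#' default) and BH-adjusted across units.
#'
#' @param nucleus_table Data frame with `donor`, `diagnosis`, `unit`;
#'   `diagnosis` must have exactly two levels, the case level sorting last
#'   or supplied via `case`.
#' @param frac Fraction of nuclei sampled per iteration (default 0.2).
#' @param iters Number of bootstrap iterations (default 30).
#' @param seed Integer seed for the subsampling RNG.
#' @param combine How to combine per-iteration p-values: "mean" (default),
#'   "median" or "fisher".
#' @param case Diagnosis level treated as the case group (default "LOAD"
#'   when present, else the second sorted level).
#' @return Data frame with unit, combined p, `fdr`, significance `tier`
#'   (`""`, `"*"`, `"**"`, `"***"` at FDR 0.05/0.01/0.001) and the raw
#'   per-iteration p-value matrix as attribute `"iteration_p"`.
#' @export
bootstrap_wilcoxon_proportions <- function(nucleus_table, frac = 0.2,
                                           iters = 30L, seed = 1L,
                                           combine = c("mean", "median",
                                                       "fisher"),
                                           case = NULL) {
  combine <- match.arg(combine)
  stopifnot(frac > 0, frac <= 1, iters >= 1)
  dx <- unique(nucleus_table[, c("donor", "diagnosis")])
  lv <- sort(unique(dx$diagnosis))
  if (length(lv) != 2L) stop("diagnosis must have exactly two levels")
  if (is.null(case)) case <- if ("LOAD" %in% lv) "LOAD" else lv[2]
  if (min(table(dx$diagnosis)) < 2L) stop("need >= 2 donors per group")
  units <- sort(unique(nucleus_table$unit))
  # canonical row order so results are invariant to input row order
  o <- order(nucleus_table$donor, nucleus_table$unit)
  nucleus_table <- nucleus_table[o, , drop = FALSE]
  n <- nrow(nucleus_table)
  pm <- matrix(NA_real_, nrow = iters, ncol = length(units),
               dimnames = list(NULL, units))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (it in seq_len(iters)) {
    idx <- sample.int(n, size = max(1L, round(frac * n)))
    sub <- nucleus_table[idx, , drop = FALSE]
    # donors absent from the draw contribute all-zero proportions
    missing <- setdiff(dx$donor, unique(sub$donor))
    pr <- donor_proportions(sub)
    if (length(missing)) {
      extra <- expand.grid(donor = missing, unit = units,
                           stringsAsFactors = FALSE)
      extra$diagnosis <- dx$diagnosis[match(extra$donor, dx$donor)]
      extra$proportion <- 0
      pr <- rbind(pr, extra[, names(pr)])
    }
    # units absent from the draw: proportion 0 for every donor
    for (u in units) {
      x <- pr$proportion[pr$unit == u & pr$diagnosis == case]
      y <- pr$proportion[pr$unit == u & pr$diagnosis != case]
      if (length(x) == 0) x <- rep(0, sum(dx$diagnosis == case))
      if (length(y) == 0) y <- rep(0, sum(dx$diagnosis != case))
      pv <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      # complete ties: no rank separation, no evidence against the null
      pm[it, u] <- if (is.na(pv)) 1 else pv
    }
  }
  p <- switch(combine,
    mean = colMeans(pm),
    median = apply(pm, 2, stats::median),
    fisher = {
      x2 <- -2 * colSums(log(pmax(pm, .Machine$double.xmin)))
      stats::pchisq(x2, df = 2 * nrow(pm), lower.tail = FALSE)
    })
  fdr <- bh_fdr(p)
  tier <- cut(fdr, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
              labels = c("***", "**", "*", ""))
  out <- data.frame(unit = units, p = unname(p), fdr = unname(fdr),
                    tier = as.character(tier), stringsAsFactors = FALSE)
  attr(out, "iteration_p") <- pm
  out
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
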