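# Differential expression (two-part hurdle with donor random effect) and
# differential accessibility (binomial-regression likelihood-ratio test).

#' Two-part hurdle differential expression test for one gene
#'
#' Expression is modelled on the log2(x + 1) scale. The discrete part is a
#' mixed logistic regression of detection (y > 0) on diagnosis, the
#' supplied covariates, the centred/scaled cellular detection rate and a
#' donor random intercept; the continuous part is a linear mixed model of
#' log2(x + 1) among detected nuclei with the same fixed and random
#' effects. The test is a 2-df likelihood-ratio test dropping diagnosis
#' simultaneously from both parts. The reported log2 fold change is the
#' empirical difference of mean log2(x + 1), case minus control; the
#' continuous-part diagnosis coefficient is returned as a model-based
#' secondary effect size.
#'
#' @param y Non-negative integer counts, one per nucleus.
#' @param diagnosis Factor/character; `control_level` is the reference so a
#'   positive log2FC means up in the case group.
#' @param donor Donor id per nucleus (random-intercept grouping).
#' @param covariates Optional data frame of per-nucleus covariates (numeric
#'   columns; donor-level values repeated per nucleus).
#' @param cdr Optional cellular detection rate per nucleus (fraction of
#'   genes detected); centred and scaled internally. Omit to exclude.
#' @param control_level Reference diagnosis level (default "Normal").
#' @param method `"mixed"` (donor random intercept, default) or `"fixed"`
#'   (plain two-part GLM, also the documented fallback when a mixed fit
#'   fails).
#' @param nagq Number of adaptive Gauss-Hermite quadrature nodes for the
#'   logistic part (default 9; 0 uses the faster PIRLS approximation).
#' @return List with `log2fc`, `model_log2fc`, `lrt`, `df`, `p`,
#'   `pct_case`, `pct_control`, `converged`, `fallback` (NA or a string),
#'   and `fit` (coefficients and log-likelihoods of both parts).
#' @export
de_hurdle <- function(y, diagnosis, donor, covariates = NULL, cdr = NULL,
                      control_level = "Normal",
                      method = c("mixed", "fixed"), nagq = 9L) {
  method <- match.arg(method)
  stopifnot(length(y) == length(diagnosis), length(y) == length(donor))
  dx <- stats::relevel(factor(diagnosis), ref = control_level)
  case_level <- levels(dx)[2]
  expr <- log2(y + 1)
  det <- y > 0
  pct_case <- mean(det[dx == case_level])
  pct_control <- mean(det[dx == control_level])
  log2fc <- mean(expr[dx == case_level]) - mean(expr[dx == control_level])

  dat <- data.frame(expr = expr, det = det, dx = dx,
                    donor = factor(donor))
  if (!is.null(cdr)) dat$cdr <- as.numeric(scale(cdr))
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, covariates)
  }
  covnames <- c(if (!is.null(covariates)) names(covariates),
                if (!is.null(cdr)) "cdr")
  # drop constant covariates (e.g. a donor-level variable within one donor)
  covnames <- covnames[vapply(covnames, function(v)
    stats::sd(as.numeric(dat[[v]])) > 0, logical(1))]
  rhs <- paste(c("dx", covnames), collapse = " + ")
  rhs0 <- if (length(covnames)) paste(covnames, collapse = " + ") else "1"

  fallback <- NA_character_
  fit_part <- function(formula_full, formula_red, family) {
    mixed_ok <- method == "mixed"
    if (mixed_ok) {
      res <- tryCatch({
        if (identical(family, "binomial")) {
          ff <- lme4::glmer(formula_full, data = dat, family = stats::binomial(),
                            nAGQ = nagq,
                            control = lme4::glmerControl(
                              check.conv.singular = "ignore",
                              calc.derivs = FALSE))
          fr <- lme4::glmer(formula_red, data = dat, family = stats::binomial(),
                            nAGQ = nagq,
                            control = lme4::glmerControl(
                              check.conv.singular = "ignore",
                              calc.derivs = FALSE))
        } else {
          ff <- lme4::lmer(formula_full, data = dat, REML = FALSE,
                           control = lme4::lmerControl(
                             check.conv.singular = "ignore",
                             calc.derivs = FALSE))
          fr <- lme4::lmer(formula_red, data = dat, REML = FALSE,
                           control = lme4::lmerControl(
                             check.conv.singular = "ignore",
                             calc.derivs = FALSE))
        }
        list(ll_full = as.numeric(stats::logLik(ff)),
             ll_red = as.numeric(stats::logLik(fr)),
             coef = lme4::fixef(ff),
             re_var = as.data.frame(lme4::VarCorr(ff))$vcov[1])
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(res)) return(res)
      fallback <<- "fixed_effects"
    }
    f_full <- stats::update(stats::as.formula(formula_full), . ~ . - (1 | donor))
    f_red <- stats::update(stats::as.formula(formula_red), . ~ . - (1 | donor))
    if (identical(family, "binomial")) {
      ff <- suppressWarnings(stats::glm(f_full, data = dat,
                                        family = stats::binomial()))
      fr <- suppressWarnings(stats::glm(f_red, data = dat,
                                        family = stats::binomial()))
      if (any(ff$fitted.values < 1e-8 | ff$fitted.values > 1 - 1e-8))
        fallback <<- paste(stats::na.omit(c(fallback, "separation")),
                           collapse = ",")
    } else {
      ff <- stats::glm(f_full, data = dat, family = stats::gaussian())
      fr <- stats::glm(f_red, data = dat, family = stats::gaussian())
    }
    list(ll_full = as.numeric(stats::logLik(ff)),
         ll_red = as.numeric(stats::logLik(fr)),
         coef = stats::coef(ff), re_var = 0)
  }

  # discrete part: skip when detection is constant (no information)
  if (length(unique(det)) > 1L) {
    disc <- fit_part(stats::as.formula(paste("det ~", rhs, "+ (1 | donor)")),
                     stats::as.formula(paste("det ~", rhs0, "+ (1 | donor)")),
                     "binomial")
  } else disc <- list(ll_full = 0, ll_red = 0, coef = NULL, re_var = 0)

  sub_ok <- sum(det) >= 3L && length(unique(dx[det])) == 2L
  if (sub_ok) {
    datd <- dat[det, , drop = FALSE]
    covd <- covnames[vapply(covnames, function(v)
      stats::sd(as.numeric(datd[[v]])) > 0, logical(1))]
    rhsd <- paste(c("dx", covd), collapse = " + ")
    rhsd0 <- if (length(covd)) paste(covd, collapse = " + ") else "1"
    dat_all <- dat; dat <- datd
    cont <- fit_part(stats::as.formula(paste("expr ~", rhsd, "+ (1 | donor)")),
                     stats::as.formula(paste("expr ~", rhsd0, "+ (1 | donor)")),
                     "gaussian")
    dat <- dat_all
  } else cont <- list(ll_full = 0, ll_red = 0, coef = NULL, re_var = 0)

  lrt <- max(0, 2 * ((disc$ll_full + cont$ll_full) -
                       (disc$ll_red + cont$ll_red)))
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  dx_coef_name <- paste0("dx", case_level)
  model_log2fc <- if (!is.null(cont$coef) && dx_coef_name %in% names(cont$coef))
    unname(cont$coef[dx_coef_name]) else NA_real_
  list(log2fc = log2fc, model_log2fc = model_log2fc, lrt = lrt, df = 2L,
       p = p, pct_case = pct_case, pct_control = pct_control,
       converged = is.na(fallback) || method == "fixed",
       fallback = fallback,
       fit = list(discrete = disc, continuous = cont))
}

#' Hurdle differential expression over a gene x nucleus matrix
#'
#' Applies the 10% detection filter (a gene must be detected in at least
#' `min_pct` of nuclei in at least one diagnosis group), computes the
#' cellular detection rate from the full matrix, runs [de_hurdle()] per
#' gene, and BH-adjusts within the table.
#'
#' @param counts Gene x nucleus count matrix.
#' @param diagnosis,donor Per-nucleus labels (columns of `counts`).
#' @param covariates Optional per-nucleus covariate data frame.
#' @param min_pct Detection filter (default 0.10).
#' @param ... Passed to [de_hurdle()].
#' @return Data frame: feature, log2fc, model_log2fc, p, fdr, pct_case,
#'   pct_control, fallback, test = "hurdle". Filtered genes are absent;
#'   attribute `"filtered"` lists them with reasons.
#' @export
de_hurdle_table <- function(counts, diagnosis, donor, covariates = NULL,
                            min_pct = 0.10, ...) {
  counts <- as.matrix(counts)
  dx <- factor(diagnosis)
  cdr <- colMeans(counts > 0)
  keep <- rowSums(vapply(levels(dx), function(l)
    rowMeans(counts[, dx == l, drop = FALSE] > 0) >= min_pct,
    logical(nrow(counts)))) > 0
  filtered <- data.frame(feature = rownames(counts)[!keep],
                         reason = rep("min_pct", sum(!keep)),
                         stringsAsFactors = FALSE)
  rows <- lapply(rownames(counts)[keep], function(g) {
    r <- de_hurdle(counts[g, ], diagnosis, donor, covariates = covariates,
                   cdr = cdr, ...)
    data.frame(feature = g, log2fc = r$log2fc,
               model_log2fc = r$model_log2fc, p = r$p,
               pct_case = r$pct_case, pct_control = r$pct_control,
               fallback = ifelse(is.na(r$fallback), "", r$fallback),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(feature = character(),
                                      log2fc = numeric(),
                                      model_log2fc = numeric(),
                                      p = numeric(), pct_case = numeric(),
                                      pct_control = numeric(),
                                      fallback = character())
  out$fdr <- bh_fdr(out$p)
  out$test <- "hurdle"
  attr(out, "filtered") <- filtered
  out
}

# Ridge-stabilized logistic fit by penalized IRLS; used when the plain GLM
# separates. Returns coefficients and the *unpenalized* log-likelihood.
ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100L) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0   # no penalty on intercept
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- drop(new); break }
    beta <- drop(new)
  }
  mu <- stats::plogis(drop(X %*% beta))
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coef = beta, loglik = ll)
}

#' Binomial-regression likelihood-ratio differential accessibility test
#'
#' Logistic regression of diagnosis on the nuisance covariates with and
#' without the peak's per-nucleus fragment count; the 1-df LRT p-value is
#' the peak's test. The log2 fold change is the empirical difference of
#' mean log2(x + 1) accessibility, case minus control. Perfect separation
#' triggers a ridge-stabilized fit, flagged in the result.
#'
#' @param y Per-nucleus fragment counts in the peak.
#' @param diagnosis Factor/character diagnosis per nucleus.
#' @param covariates Data frame of per-nucleus covariates (e.g. peak-region
#'   fragments, fraction of fragments in targeted regions, nuclei
#'   proportion, age, sex, PMI).
#' @param control_level Reference diagnosis level (default "Normal").
#' @param log1p_counts Use log2(x + 1)-transformed fragment counts as the
#'   predictor instead of raw counts (default FALSE).
#' @return List with `log2fc`, `lrt`, `df`, `p`, `flag` (NA or
#'   "separation"), `skipped` (reason or NA).
#' @export
da_binomial_lr <- function(y, diagnosis, covariates = NULL,
                           control_level = "Normal", log1p_counts = FALSE) {
  dx <- stats::relevel(factor(diagnosis), ref = control_level)
  case_level <- levels(dx)[2]
  expr <- log2(y + 1)
  log2fc <- mean(expr[dx == case_level]) - mean(expr[dx == control_level])
  yy <- as.integer(dx == case_level)
  pred <- if (log1p_counts) expr else as.numeric(y)
  X0 <- if (is.null(covariates) || ncol(covariates) == 0L)
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  else stats::model.matrix(~., data = covariates)
  if (stats::sd(pred) == 0)  # constant peak: full model equals reduced
    return(list(log2fc = log2fc, lrt = 0, df = 1L, p = 1,
                flag = NA_character_, skipped = NA_character_))
  X1 <- cbind(X0, peak = pred)
  f0 <- suppressWarnings(stats::glm.fit(X0, yy, family = stats::binomial()))
  f1 <- suppressWarnings(stats::glm.fit(X1, yy, family = stats::binomial()))
  flag <- NA_character_
  sep <- any(f1$fitted.values < 1e-8 | f1$fitted.values > 1 - 1e-8)
  ll <- function(f) -f$deviance / 2
  ll0 <- ll(f0); ll1 <- ll(f1)
  if (sep || !f1$converged || !is.finite(ll1)) {
    flag <- "separation"
    r0 <- ridge_logistic(X0, yy); r1 <- ridge_logistic(X1, yy)
    ll0 <- r0$loglik; ll1 <- r1$loglik
  }
  if (!is.finite(ll0) || !is.finite(ll1))
    return(list(log2fc = log2fc, lrt = NA_real_, df = 1L, p = NA_real_,
                flag = flag, skipped = "nonfinite_deviance"))
  lrt <- max(0, 2 * (ll1 - ll0))
  list(log2fc = log2fc, lrt = lrt, df = 1L,
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       flag = flag, skipped = NA_character_)
}

#' Differential accessibility over a peak x nucleus matrix
#'
#' Applies the detection filter (default: peak detected in at least 2.5% of
#' nuclei), runs [da_binomial_lr()] per peak and BH-adjusts within the
#' table.
#'
#' @inheritParams da_binomial_lr
#' @param counts Peak x nucleus fragment count matrix.
#' @param min_pct Detection filter (default 0.025).
#' @return Data frame: feature, log2fc, p, fdr, pct_case, pct_control,
#'   flag, test = "binomLR"; attribute `"filtered"` lists dropped peaks.
#' @export
da_binomial_lr_table <- function(counts, diagnosis, covariates = NULL,
                                 min_pct = 0.025,
                                 control_level = "Normal", ...) {
  counts <- as.matrix(counts)
  dx <- stats::relevel(factor(diagnosis), ref = control_level)
  case_level <- levels(dx)[2]
  keep <- rowMeans(counts > 0) >= min_pct
  filtered <- data.frame(feature = rownames(counts)[!keep],
                         reason = rep("min_pct", sum(!keep)),
                         stringsAsFactors = FALSE)
  rows <- lapply(rownames(counts)[keep], function(pk) {
    r <- da_binomial_lr(counts[pk, ], diagnosis, covariates = covariates,
                        control_level = control_level, ...)
    data.frame(feature = pk, log2fc = r$log2fc, p = r$p,
               pct_case = mean(counts[pk, dx == case_level] > 0),
               pct_control = mean(counts[pk, dx == control_level] > 0),
               flag = ifelse(is.na(r$flag), "", r$flag),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(feature = character(),
                                      log2fc = numeric(), p = numeric(),
                                      pct_case = numeric(),
                                      pct_control = numeric(),
                                      flag = character())
  out$fdr <- bh_fdr(out$p)
  out$test <- "binomLR"
  attr(out, "filtered") <- filtered
  out
}
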