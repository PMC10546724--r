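# Iterative principal-component covariate selection for the differential
# models.

#' Donor pseudobulk matrix
#'
#' Sums counts over all nuclei per donor, removes features with zero values
#' in more than `max_zero_frac` of donors, and centres/scales the rest.
#'
#' @param counts Feature x nucleus matrix (dense or `Matrix` sparse).
#' @param nucleus_donor Character vector, donor of each nucleus (column).
#' @param max_zero_frac Zero-fraction cutoff for feature removal
#'   (default 0.2; features with zeros in > 20% of donors are dropped).
#' @return List with `matrix` (donors x features, scaled), `raw` (donors x
#'   features pseudobulk sums), `dropped_features`.
#' @export
donor_pseudobulk <- function(counts, nucleus_donor, max_zero_frac = 0.2) {
  stopifnot(ncol(counts) == length(nucleus_donor))
  donors <- sort(unique(nucleus_donor))
  ind <- Matrix::sparseMatrix(
    i = seq_along(nucleus_donor),
    j = match(nucleus_donor, donors),
    x = 1, dims = c(length(nucleus_donor), length(donors)))
  pb <- t(as.matrix(counts %*% ind))          # donors x features
  rownames(pb) <- donors
  colnames(pb) <- rownames(counts)
  zero_frac <- colMeans(pb == 0)
  drop <- zero_frac > max_zero_frac
  keep <- pb[, !drop, drop = FALSE]
  # constant features cannot be scaled
  const <- apply(keep, 2, stats::sd) == 0
  drop_names <- c(colnames(pb)[drop], colnames(keep)[const])
  keep <- keep[, !const, drop = FALSE]
  list(matrix = scale(keep), raw = pb, dropped_features = drop_names)
}

#' Iterative PC-regression covariate selection
#'
#' Repeatedly: PCA on the (residualized) donor matrix; among PCs explaining
#' more than `var_threshold` of variance, regress each PC on each metadata
#' variable one at a time (numeric: slope t test; categorical: one-way F
#' test); if any variable survives Bonferroni (family = #PCs x #variables
#' tested this round) at `alpha`, take the most-associated variable on the
#' top-variance PC that has any significant variable, residualize every
#' feature on it, and iterate; stop when no variable is significant.
#'
#' @param mat Donors x features matrix, centred/scaled
#'   (see [donor_pseudobulk()]).
#' @param metadata Data frame of donor-level variables, rows aligned to
#'   `mat` rows; numeric or factor/character columns.
#' @param var_threshold Minimum PC variance fraction to test (default 0.10).
#' @param alpha Bonferroni-corrected significance level (default 0.05).
#' @param max_rounds Hard cap on rounds (default: number of variables).
#' @return List with `selected` (ordered character vector) and `log`
#'   (data frame: round, pc, variable, p, p_bonf, selected).
#' @export
iterative_pc_selection <- function(mat, metadata, var_threshold = 0.10,
                                   alpha = 0.05, max_rounds = NULL) {
  stopifnot(nrow(mat) == nrow(metadata), nrow(mat) >= 3,
            ncol(metadata) >= 1)
  vars <- names(metadata)
  usable <- vapply(vars, function(v) {
    x <- metadata[[v]]
    if (is.numeric(x)) stats::sd(x) > 0 else length(unique(x)) > 1
  }, logical(1))
  if (any(!usable))
    warning("constant metadata variable(s) excluded: ",
            paste(vars[!usable], collapse = ", "))
  vars <- vars[usable]
  if (is.null(max_rounds)) max_rounds <- length(vars)
  selected <- character(0)
  logs <- list()
  cur <- mat
  for (round in seq_len(max_rounds)) {
    pca <- stats::prcomp(cur, center = FALSE, scale. = FALSE)
    vfrac <- pca$sdev^2 / sum(pca$sdev^2)
    test_pcs <- which(vfrac > var_threshold)
    if (length(test_pcs) == 0L) break
    cand <- setdiff(vars, selected)
    if (length(cand) == 0L) break
    fam <- length(test_pcs) * length(cand)
    rows <- list()
    for (pc in test_pcs) {
      y <- pca$x[, pc]
      for (v in cand) {
        x <- metadata[[v]]
        p <- if (is.numeric(x)) {
          summary(stats::lm(y ~ x))$coefficients[2, 4]
        } else {
          a <- stats::anova(stats::lm(y ~ factor(x)))
          a[["Pr(>F)"]][1]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          round = round, pc = pc, pc_var = vfrac[pc], variable = v,
          p = p, p_bonf = min(1, p * fam), selected = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    rl <- do.call(rbind, rows)
    sig <- rl[rl$p_bonf < alpha, , drop = FALSE]
    if (nrow(sig) == 0L) { logs[[round]] <- rl; break }
    # anchor on the highest-variance tested PC that has any significant
    # variable; take its most-associated variable
    anchor_pc <- min(sig$pc)
    pick <- sig[sig$pc == anchor_pc, , drop = FALSE]
    pick <- pick$variable[which.min(pick$p)]
    rl$selected <- rl$variable == pick & rl$pc == anchor_pc &
      rl$p == min(sig$p[sig$pc == anchor_pc])
    logs[[round]] <- rl
    selected <- c(selected, pick)
    x <- metadata[[pick]]
    mm <- if (is.numeric(x)) stats::model.matrix(~x) else
      stats::model.matrix(~factor(x))
    cur <- stats::resid(stats::lm.fit(mm, cur))
  }
  list(selected = selected,
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(round = integer(), pc = integer(), pc_var = numeric(),
                    variable = character(), p = numeric(),
                    p_bonf = numeric(), selected = logical()))
}
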