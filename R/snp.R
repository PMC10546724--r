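# Candidate regulatory SNP selection (criteria a-h) and the
# importance-sampling test of allele-driven binding-affinity change.

#' Best window score over all L windows covering the centre of a context
#'
#' The context has length 2L-1 with the variant position at its centre;
#' both strands are scored.
#'
#' @param codes Integer base codes of the 2L-1 context.
#' @param pwm A [build_pwm()] object.
#' @return Maximum window score.
#' @keywords internal
best_center_score <- function(codes, pwm) {
  max(window_scores(codes, pwm), window_scores(revcomp_codes(codes), pwm))
}

#' DAPs co-accessible with a DEG anchor peak, with sign concordance
#'
#' For each classified CCAN, returns the member DAPs that have a
#' co-accessibility edge (score >= `min_coacc`) to a peak overlapping a
#' DEG's promoter or first intron, together with the sign-concordance
#' flag. This realizes the open-chromatin candidate criteria that tie a
#' DAP to a target DEG without the full cCRE rules.
#'
#' @param ccans Classified CCAN list (see [link_ccres()] input).
#' @param min_coacc Minimum edge score (default 0.2).
#' @return Data frame: ccan, dap, gene, score, same_sign.
#' @export
dap_deg_coaccessible <- function(ccans, min_coacc = 0.2) {
  out <- list()
  for (cc in ccans) {
    if (nrow(cc$daps) == 0L || nrow(cc$deg_anchors) == 0L) next
    for (i in seq_len(nrow(cc$daps))) for (j in seq_len(nrow(cc$deg_anchors))) {
      d <- cc$daps$feature[i]; a <- cc$deg_anchors$peak[j]
      if (d == a) next
      e <- cc$edges
      hit <- (e$peak_a == d & e$peak_b == a) | (e$peak_a == a & e$peak_b == d)
      if (!any(hit) || max(e$score[hit]) < min_coacc) next
      out[[length(out) + 1L]] <- data.frame(
        ccan = cc$id, dap = d, gene = cc$deg_anchors$gene[j],
        score = max(e$score[hit]),
        same_sign = sign(cc$daps$log2fc[i]) ==
          sign(cc$deg_anchors$gene_log2fc[j]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(ccan = character(), dap = character(),
                      gene = character(), score = numeric(),
                      same_sign = logical()))
  unique(do.call(rbind, out))
}

#' Candidate SNP-TFBS pairs (open-chromatin, TFBS and SNP criteria)
#'
#' Emits pairs satisfying all of: (a) the TFBS and SNP lie within a DAP;
#' (b) that peak belongs to a unidirectional or mixed CCAN; (c) the CCAN
#' has at least one peak within `gwas_window` of a GWAS tag SNP; (d) the
#' DAP is co-accessible (>= `min_coacc`) with a peak overlapping the
#' promoter or first intron of a DEG; (e) that DAP and DEG share the sign
#' of their fold changes; (f) the motif p-value at the TFBS is <= `max_p`
#' for the major or the minor allele sequence; (g) the TFBS overlaps the
#' SNP; (h) SNP minor allele frequency >= `min_maf`.
#'
#' @param hits Motif hits with absolute coordinates: columns `peak`,
#'   `chrom`, `start`, `end`, `strand`, `tf`, `score`, `p` (reference
#'   genome scan, from [scan_motifs()] hits lifted to genome coordinates).
#' @param snps Data frame: `snp`, `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `maf`.
#' @param dap_table DAP table (`feature`, `log2fc`).
#' @param ccans Classified CCAN list.
#' @param peaks Interval data frame for all peaks.
#' @param tag_snps Data frame `chrom`, `pos` of GWAS tag SNPs.
#' @param sequences Named character vector of peak sequences (names match
#'   peak names) used to evaluate the minor-allele score for criterion (f).
#' @param pwms Named list of PWMs (names match `hits$tf`).
#' @param max_p Motif p-value threshold (default 5e-5).
#' @param min_coacc Minimum DAP-DEG co-accessibility (default 0.2).
#' @param gwas_window GWAS tag window half-width (default 500,000).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return Data frame of candidates: snp, tf, peak, ccan, gene (linked
#'   DEG), hit_start, hit_end, strand, p_ref, p_alt, maf.
#' @export
candidate_pairs <- function(hits, snps, dap_table, ccans, peaks, tag_snps,
                            sequences, pwms, max_p = 5e-5, min_coacc = 0.2,
                            gwas_window = 5e5, min_maf = 0.01) {
  if (nrow(hits) == 0L || nrow(snps) == 0L) return(empty_candidates())
  # CCANs passing (b)+(c)
  keep_ccan <- Filter(function(cc) {
    cc$klass %in% c("unidirectional", "mixed") &&
      any(gwas_window_overlap(peaks[peaks$name %in% cc$peaks, ,
                                    drop = FALSE],
                              tag_snps, window = gwas_window))
  }, ccans)
  if (length(keep_ccan) == 0L) return(empty_candidates())
  links <- dap_deg_coaccessible(keep_ccan, min_coacc = min_coacc)
  links <- links[links$same_sign, , drop = FALSE]           # (d)+(e)
  if (nrow(links) == 0L) return(empty_candidates())
  out <- list()
  for (r in seq_len(nrow(hits))) {
    pk <- hits$peak[r]
    li <- links[links$dap == pk, , drop = FALSE]
    if (nrow(li) == 0L) next                                 # (a,b,c,d,e)
    ov <- snps$chrom == hits$chrom[r] & snps$pos >= hits$start[r] &
      snps$pos < hits$end[r]                                 # (g)
    for (s in which(ov)) {
      if (snps$maf[s] < min_maf) next                        # (h)
      # (f): p for ref already from the scan; evaluate the alt allele
      pw <- pwms[[hits$tf[r]]]
      p_alt <- alt_allele_p(hits[r, ], snps[s, ], sequences, pk, pw)
      if (!(hits$p[r] <= max_p || (!is.na(p_alt) && p_alt <= max_p))) next
      out[[length(out) + 1L]] <- data.frame(
        snp = snps$snp[s], tf = hits$tf[r], peak = pk,
        ccan = li$ccan[1], gene = li$gene[1],
        hit_start = hits$start[r], hit_end = hits$end[r],
        strand = hits$strand[r], p_ref = hits$p[r], p_alt = p_alt,
        maf = snps$maf[s], stringsAsFactors = FALSE)
    }
  }
  # minor-allele-driven candidates: a TFBS may exist only on the alternate
  # allele sequence (criterion on major *or* minor allele), so windows
  # covering each qualifying SNP are rescored with the alternate base
  peak_start <- attr(sequences, "peak_start")
  for (pk in unique(links$dap)) {
    li <- links[links$dap == pk, , drop = FALSE]
    pk_row <- match(pk, peaks$name)
    ov <- which(snps$chrom == peaks$chrom[pk_row] &
                  snps$pos >= peaks$start[pk_row] &
                  snps$pos < peaks$end[pk_row] & snps$maf >= min_maf)
    for (s in ov) {
      codes <- seq_to_codes(sequences[[pk]])
      off <- snps$pos[s] - peak_start[pk]
      codes[off + 1L] <- match(snps$alt[s], BASES)
      for (tf in names(pwms)) {
        if (length(out) && any(vapply(out, function(r)
          r$snp == snps$snp[s] && r$tf == tf, logical(1)))) next
        pw <- pwms[[tf]]
        bw <- best_window_over_pos(codes, pw, off)
        if (is.null(bw)) next
        p_alt <- exact_threshold(pw, alpha = 1)$pvalue(bw$score)
        if (p_alt > max_p) next
        out[[length(out) + 1L]] <- data.frame(
          snp = snps$snp[s], tf = tf, peak = pk, ccan = li$ccan[1],
          gene = li$gene[1],
          hit_start = peak_start[pk] + bw$start,
          hit_end = peak_start[pk] + bw$start + pw$L,
          strand = bw$strand, p_ref = NA_real_, p_alt = p_alt,
          maf = snps$maf[s], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_candidates())
  unique(do.call(rbind, out))
}

# best-scoring L-window covering 0-based in-peak position `off`, both
# strands; returns NULL when no window fits
best_window_over_pos <- function(codes, pwm, off) {
  Lm <- pwm$L
  starts <- max(0L, off - Lm + 1L):min(length(codes) - Lm, off)
  if (length(starts) == 0L || starts[1] > off) return(NULL)
  best <- NULL
  for (st in starts) {
    win <- codes[(st + 1L):(st + Lm)]
    for (strand in c("+", "-")) {
      sc <- if (strand == "+") sum(pwm$mat[cbind(win, seq_len(Lm))])
      else sum(pwm$mat[cbind(revcomp_codes(win), seq_len(Lm))])
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, start = st, strand = strand)
    }
  }
  best
}

empty_candidates <- function() {
  data.frame(snp = character(), tf = character(), peak = character(),
             ccan = character(), gene = character(), hit_start = integer(),
             hit_end = integer(), strand = character(), p_ref = numeric(),
             p_alt = numeric(), maf = numeric())
}

# p-value of the TFBS window with the alternate allele substituted;
# needs the peak sequence and the peak's genomic start to locate the SNP.
alt_allele_p <- function(hit, snp, sequences, pk, pwm) {
  if (is.null(sequences) || !pk %in% names(sequences) || is.null(pwm))
    return(NA_real_)
  seq <- sequences[[pk]]
  peak_start <- attr(sequences, "peak_start")[pk]
  if (is.null(peak_start) || is.na(peak_start)) return(NA_real_)
  off <- snp$pos - peak_start                 # 0-based offset in peak
  codes <- seq_to_codes(seq)
  if (off < 0 || off >= length(codes)) return(NA_real_)
  codes[off + 1L] <- match(snp$alt, BASES)
  ws <- hit$start - peak_start                # hit offset in peak
  win <- codes[(ws + 1L):(ws + pwm$L)]
  sc <- if (hit$strand == "+") sum(pwm$mat[cbind(win, seq_len(pwm$L))])
  else sum(pwm$mat[cbind(revcomp_codes(win), seq_len(pwm$L))])
  exact_threshold(pwm, alpha = 1)$pvalue(sc)
}

#' Importance-sampling test of SNP-driven binding-affinity change
#'
#' The observed statistic is the best-window score of the 2L-1 context
#' carrying the reference allele minus the best-window score with the
#' alternate allele (windows covering the centre, both strands). Under the
#' null the context is drawn from the first-order Markov background with
#' the reference allele at the centre; the Monte-Carlo p-value is the
#' probability of an affinity change at least as large as observed in the
#' observed direction. Sampling uses a motif-planted proposal (motif
#' offset uniform over the L windows covering the centre) with exact
#' density, so the weighted indicator mean is unbiased. The procedure is
#' repeated `n_runs` times; the mean, variance, minimum and maximum of the
#' per-run estimates are reported.
#'
#' @param pwm A [build_pwm()] object.
#' @param context Character DNA string of length 2L-1 with the SNP at the
#'   centre (carrying either allele).
#' @param ref,alt Reference and alternate alleles (single bases).
#' @param n_mc Monte-Carlo draws per run (default 100 * L).
#' @param n_runs Number of independent runs (default 1000).
#' @param seed Integer RNG seed.
#' @return List with `best_score_ref`, `best_score_alt`, `statistic`,
#'   `effect` ("gain", "loss" or "none"), `p_mean`, `p_var`, `p_min`,
#'   `p_max`, `n_mc`, `n_runs`.
#' @export
affinity_test <- function(pwm, context, ref, alt, n_mc = NULL,
                          n_runs = 1000L, seed = 1L) {
  Lm <- pwm$L
  codes <- seq_to_codes(context)
  if (length(codes) != 2L * Lm - 1L)
    stop("context must have length 2L-1 with the SNP at position L")
  if (is.null(n_mc)) n_mc <- 100L * Lm
  centre <- Lm
  ref_c <- match(toupper(ref), BASES); alt_c <- match(toupper(alt), BASES)
  stopifnot(!is.na(ref_c), !is.na(alt_c))
  x_ref <- codes; x_ref[centre] <- ref_c
  x_alt <- codes; x_alt[centre] <- alt_c
  s_ref <- best_center_score(x_ref, pwm)
  s_alt <- best_center_score(x_alt, pwm)
  d_obs <- s_ref - s_alt
  if (ref_c == alt_c)
    return(list(best_score_ref = s_ref, best_score_alt = s_alt,
                statistic = 0, effect = "none", p_mean = 1, p_var = 0,
                p_min = 1, p_max = 1, n_mc = n_mc, n_runs = n_runs))
  effect <- if (s_alt > s_ref) "gain" else "loss"
  bg <- pwm$background
  log_stat <- log(bg$stationary)
  log_T <- log(bg$transition)
  log_m <- log(pwm$prob)
  n_ctx <- 2L * Lm - 1L
  exceeds <- function(x) {
    d <- best_center_score(x, pwm) -
      best_center_score(replace(x, centre, alt_c), pwm)
    if (d_obs >= 0) d >= d_obs else d <= d_obs
  }
  # log background (Markov, stationary start) of a full context with the
  # centre conditioned to ref: subtract log P(centre base) = log stationary
  log_null <- function(x) {
    log_stat[x[1]] + sum(log_T[cbind(x[-n_ctx], x[-1])]) - log_stat[ref_c]
  }
  # proposal: defensive mixture of (i) pure background flanks and (ii) a
  # motif-weighted subsequence at a uniform offset among the L windows
  # covering the centre, flanks iid stationary. The background component
  # bounds the importance weights; the motif component covers the
  # large-change event region.
  log_q <- function(x) {
    comps <- vapply(seq_len(Lm), function(o) {
      win <- o:(o + Lm - 1L)
      lp <- 0
      for (i in seq_len(Lm)) {
        pos <- win[i]
        if (pos == centre) next
        lp <- lp + log_m[x[pos], i]
      }
      lp + sum(log_stat[x[setdiff(seq_len(n_ctx), win)]])
    }, numeric(1))
    comps <- c(comps - log(Lm), sum(log_stat[x[-centre]]))
    m <- max(comps)
    m + log(sum(exp(comps - m))) - log(2)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p_hat <- numeric(n_runs)
  for (run in seq_len(n_runs)) {
    w_ind <- numeric(n_mc)
    for (s in seq_len(n_mc)) {
      x <- integer(n_ctx)
      if (stats::runif(1) < 0.5) {
        x[-centre] <- sample.int(4L, n_ctx - 1L, replace = TRUE,
                                 prob = bg$stationary)
      } else {
        o <- sample.int(Lm, 1L)
        win <- o:(o + Lm - 1L)
        for (i in seq_len(Lm))
          x[win[i]] <- sample.int(4L, 1L, prob = pwm$prob[, i])
        flank <- setdiff(seq_len(n_ctx), win)
        if (length(flank))
          x[flank] <- sample.int(4L, length(flank), replace = TRUE,
                                 prob = bg$stationary)
      }
      x[centre] <- ref_c
      if (exceeds(x))
        w_ind[s] <- exp(log_null(x) - log_q(x))
    }
    p_hat[run] <- min(1, mean(w_ind))
  }
  list(best_score_ref = s_ref, best_score_alt = s_alt, statistic = d_obs,
       effect = effect, p_mean = mean(p_hat), p_var = stats::var(p_hat),
       p_min = min(p_hat), p_max = max(p_hat), n_mc = n_mc,
       n_runs = n_runs)
}

#' Run affinity tests over a candidate table and apply flagship filters
#'
#' @param candidates Output of [candidate_pairs()].
#' @param snps SNP table (`snp`, `chrom`, `pos`, `ref`, `alt`, `maf`).
#' @param sequences Named peak sequences with `peak_start` attribute.
#' @param pwms Named list of PWMs.
#' @param tf_pct Named vector of per-TF expressed-cell fractions.
#' @param deg_table DEG table (`feature`, `log2fc`).
#' @param n_runs,n_mc,seed Passed to [affinity_test()].
#' @param flag_fdr Flagship FDR cutoff (default 0.01).
#' @param flag_lfc Flagship |target DEG log2FC| cutoff (default 0.15).
#' @param flag_tf_pct Flagship TF expression cutoff (default 0.10).
#' @return Candidate table augmented with affinity-test columns, `fdr`
#'   and `flagship`.
#' @export
affinity_test_table <- function(candidates, snps, sequences, pwms, tf_pct,
                                deg_table, n_runs = 1000L, n_mc = NULL,
                                seed = 1L, flag_fdr = 0.01,
                                flag_lfc = 0.15, flag_tf_pct = 0.10) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$p_mean <- out$fdr <- numeric(0)
    out$flagship <- logical(0)
    return(out)
  }
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    cd <- candidates[i, ]
    sn <- snps[snps$snp == cd$snp, ][1, ]
    pw <- pwms[[cd$tf]]
    seq <- sequences[[cd$peak]]
    pk_start <- attr(sequences, "peak_start")[cd$peak]
    off <- sn$pos - pk_start
    codes <- seq_to_codes(seq)
    Lm <- pw$L
    span <- (off - Lm + 2L):(off + Lm)    # 2L-1 window centred on the SNP
    ctx <- codes[pmin(pmax(span, 1L), length(codes))]
    if (any(span < 1L | span > length(codes)))
      ctx[span < 1L | span > length(codes)] <-
        sample.int(4L, sum(span < 1L | span > length(codes)), replace = TRUE)
    ctx[Lm] <- match(sn$ref, BASES)
    at <- affinity_test(pw, codes_to_seq(ctx), sn$ref, sn$alt,
                        n_mc = n_mc, n_runs = n_runs,
                        seed = seed + i)
    data.frame(cd, effect = at$effect, best_score_ref = at$best_score_ref,
               best_score_alt = at$best_score_alt,
               statistic = at$statistic, p_mean = at$p_mean,
               p_var = at$p_var, p_min = at$p_min, p_max = at$p_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$p_mean)
  lfc <- deg_table$log2fc[match(out$gene, deg_table$feature)]
  tfp <- ifelse(out$tf %in% names(tf_pct), tf_pct[out$tf], 0)
  out$flagship <- out$fdr <= flag_fdr & abs(lfc) >= flag_lfc &
    tfp >= flag_tf_pct
  out
}
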