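# PWM construction, exact score-threshold computation by dynamic
# programming, motif scanning with best-overlap deduplication, and
# GC-matched motif enrichment.

BASES <- c("A", "C", "G", "T")

#' First-order Markov background model
#'
#' @param initial Length-4 initial/stationary base distribution
#'   (default uniform). Names A,C,G,T.
#' @param transition 4 x 4 transition matrix, rows summing to 1
#'   (default uniform).
#' @return A `markov_background` list with `initial`, `transition` and the
#'   `stationary` distribution of the chain.
#' @export
markov_background <- function(initial = rep(0.25, 4),
                              transition = matrix(0.25, 4, 4)) {
  stopifnot(length(initial) == 4, all(dim(transition) == c(4, 4)),
            abs(sum(initial) - 1) < 1e-9,
            all(abs(rowSums(transition) - 1) < 1e-9))
  names(initial) <- BASES
  dimnames(transition) <- list(BASES, BASES)
  ev <- eigen(t(transition))
  i <- which.min(abs(ev$values - 1))
  stat <- Re(ev$vectors[, i]); stat <- stat / sum(stat)
  names(stat) <- BASES
  structure(list(initial = initial, transition = transition,
                 stationary = stat), class = "markov_background")
}

#' Estimate a first-order Markov background from sequences
#'
#' Empirical base and transition frequencies over a character vector of
#' sequences (the regions tested), with add-one smoothing on transitions.
#'
#' @param sequences Character vector of DNA strings.
#' @return A [markov_background()] object.
#' @export
background_from_sequences <- function(sequences) {
  codes <- lapply(sequences, seq_to_codes)
  all <- unlist(codes)
  init <- tabulate(all, 4) + 1
  trans <- matrix(1, 4, 4)
  for (cv in codes) {
    if (length(cv) < 2) next
    for (i in seq_len(length(cv) - 1))
      trans[cv[i], cv[i + 1]] <- trans[cv[i], cv[i + 1]] + 1
  }
  markov_background(initial = init / sum(init),
                    transition = trans / rowSums(trans))
}

#' @keywords internal
seq_to_codes <- function(s) {
  match(strsplit(toupper(s), "")[[1]], BASES)
}

#' @keywords internal
codes_to_seq <- function(v) paste(BASES[v], collapse = "")

#' @keywords internal
revcomp_codes <- function(v) rev(5L - v)

#' Build a log2 probability-ratio PWM from a count matrix
#'
#' Column probabilities are `(count + pseudocount) / (total + 4 *
#' pseudocount)`; matrix entries are log2 of the column probability over
#' the background stationary probability of the base.
#'
#' @param pfm 4 x L non-negative count matrix (rows A,C,G,T).
#' @param background A [markov_background()] object.
#' @param pseudocount Per-cell pseudocount (default 0.8).
#' @param tf Transcription-factor id attached to the PWM.
#' @return A `pwm` list with `tf`, `mat` (4 x L log2 ratios), `prob`
#'   (4 x L probabilities), `L`, `background`.
#' @export
build_pwm <- function(pfm, background = markov_background(),
                      pseudocount = 0.8, tf = "TF") {
  pfm <- as.matrix(pfm)
  stopifnot(nrow(pfm) == 4, all(pfm >= 0))
  if (any(colSums(pfm) == 0)) stop("zero-total PWM column")
  prob <- sweep(pfm + pseudocount, 2, colSums(pfm) + 4 * pseudocount, "/")
  mat <- log2(prob / background$stationary)
  rownames(mat) <- rownames(prob) <- BASES
  structure(list(tf = tf, mat = mat, prob = prob, L = ncol(pfm),
                 background = background), class = "pwm")
}

#' Exact score distribution and threshold for a PWM
#'
#' Dynamic programming over (position, previous base, discretized score)
#' computes the exact distribution of the length-L window score under the
#' first-order Markov background (window start at stationarity). Returns
#' the smallest score whose upper-tail probability is at or below `alpha`,
#' plus a p-value function for arbitrary scores.
#'
#' @param pwm A [build_pwm()] object.
#' @param alpha Tail probability threshold (default 5e-5).
#' @param bin Score discretization width in bits (default 1e-3).
#' @return List with `threshold` (score s*), `alpha_attained` (tail at
#'   s*), `pvalue` (function(score) -> exact tail probability), `support`
#'   (achievable score range).
#' @export
exact_threshold <- function(pwm, alpha = 5e-5, bin = 1e-3) {
  stopifnot(inherits(pwm, "pwm"), all(is.finite(pwm$mat)))
  Lm <- pwm$L
  E <- round(pwm$mat / bin)  # integer bin offsets per base/column
  bg <- pwm$background
  # P[base, bin]: prob the window so far ends in `base` with binned score;
  # bin index is the partial score offset by the running minimum
  part_lo <- cumsum(apply(E, 2, min)); part_hi <- cumsum(apply(E, 2, max))
  P <- matrix(0, 4, part_hi[1] - part_lo[1] + 1L)
  for (b in 1:4) P[b, E[b, 1] - part_lo[1] + 1L] <-
    P[b, E[b, 1] - part_lo[1] + 1L] + bg$stationary[b]
  if (Lm >= 2) for (i in 2:Lm) {
    width_prev <- part_hi[i - 1] - part_lo[i - 1] + 1L
    width_new <- part_hi[i] - part_lo[i] + 1L
    Q <- matrix(0, 4, width_new)
    for (b2 in 1:4) {
      shift <- E[b2, i] - (part_lo[i] - part_lo[i - 1])
      col_idx <- seq_len(width_prev) + shift
      contrib <- colSums(P[, seq_len(width_prev), drop = FALSE] *
                           bg$transition[, b2])
      Q[b2, col_idx] <- Q[b2, col_idx] + contrib
    }
    P <- Q
  }
  dist <- colSums(P[, seq_len(part_hi[Lm] - part_lo[Lm] + 1L),
                    drop = FALSE])
  scores <- (part_lo[Lm]:part_hi[Lm]) * bin
  tail <- rev(cumsum(rev(dist)))
  pvalue <- function(s) {
    # tail probability of binned score >= s (s in bits); per-column
    # rounding can shift a real score by up to L/2 bins off the grid
    target <- round(s / bin)
    if (target > part_hi[Lm] + ceiling(Lm / 2)) return(0)
    target <- min(target, part_hi[Lm])
    if (target <= part_lo[Lm]) return(1)
    unname(tail[target - part_lo[Lm] + 1L])
  }
  ok <- which(tail <= alpha & dist >= 0)
  achievable <- which(dist > 0)
  if (length(ok) == 0L || min(ok) > max(achievable))
    stop("no achievable score reaches tail probability <= ", alpha,
         "; motif too degenerate to scan at this threshold")
  thr <- scores[min(ok)]
  list(threshold = thr, alpha_attained = tail[min(ok)], pvalue = pvalue,
       support = range(scores[achievable]))
}

#' Score all windows of a coded sequence against a PWM (one strand)
#' @keywords internal
window_scores <- function(codes, pwm) {
  Lm <- pwm$L
  n <- length(codes) - Lm + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(Lm))
    s <- s + pwm$mat[cbind(codes[i:(i + n - 1L)], i)]
  s
}

#' Scan sequences for motif hits above an exact threshold
#'
#' Scores every length-L window on both strands; windows at or above the
#' threshold become hits with exact p-values. Overlapping hits of the same
#' transcription factor are collapsed to the best-scoring one (ties:
#' leftmost, then + strand).
#'
#' @param sequences Named character vector of DNA sequences (names become
#'   the `seq` column).
#' @param pwm A [build_pwm()] object.
#' @param et Output of [exact_threshold()] for this PWM (computed if
#'   omitted).
#' @param dedup Collapse overlapping same-TF hits (default TRUE).
#' @return Data frame of hits: seq, start (0-based, in-sequence), end,
#'   strand, tf, score, p.
#' @export
scan_motifs <- function(sequences, pwm, et = NULL, dedup = TRUE) {
  if (is.null(et)) et <- exact_threshold(pwm)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  Lm <- pwm$L
  out <- list()
  for (nm in names(sequences)) {
    codes <- seq_to_codes(sequences[[nm]])
    if (length(codes) < Lm) next
    sp <- window_scores(codes, pwm)
    sm <- rev(window_scores(revcomp_codes(codes), pwm))
    hit <- function(s, strand) {
      i <- which(s >= et$threshold)
      if (length(i) == 0L) return(NULL)
      data.frame(seq = nm, start = i - 1L, end = i - 1L + Lm,
                 strand = strand, tf = pwm$tf, score = s[i],
                 p = vapply(s[i], et$pvalue, numeric(1)),
                 stringsAsFactors = FALSE)
    }
    h <- rbind(hit(sp, "+"), hit(sm, "-"))
    if (is.null(h) || nrow(h) == 0L) next
    if (dedup && nrow(h) > 1L) {
      # union-find over overlapping windows, keep best per component
      h <- h[order(-h$score, h$start, h$strand != "+"), , drop = FALSE]
      keep <- logical(nrow(h))
      taken <- IRanges::IRanges()
      for (i in seq_len(nrow(h))) {
        iv <- IRanges::IRanges(h$start[i] + 1L, h$end[i])
        if (!any(IRanges::overlapsAny(iv, taken))) {
          keep[i] <- TRUE
          taken <- c(taken, iv)
        }
      }
      h <- h[keep, , drop = FALSE]
    }
    out[[nm]] <- h
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(seq = character(), start = integer(),
                      end = integer(), strand = character(),
                      tf = character(), score = numeric(), p = numeric()))
  res <- res[order(res$seq, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @keywords internal
gc_fraction <- function(sequences) {
  vapply(sequences, function(s) {
    v <- seq_to_codes(s)
    mean(v == 2L | v == 3L)
  }, numeric(1))
}

#' Motif enrichment in target vs GC-matched background peaks
#'
#' The background peak set is resampled (with replacement) to match the
#' target GC distribution in 5% bins. Per motif, the number of target
#' peaks with at least one hit is tested against the background hit
#' fraction with a one-sided binomial upper-tail test; fold enrichment is
#' the ratio of hit fractions. Motifs are retained at `fold >= min_fold`,
#' BH FDR <= `max_fdr`, and TF detected in at least `min_tf_pct` of the
#' cluster's cells.
#'
#' @param target_seqs,background_seqs Named character vectors of peak
#'   sequences.
#' @param pwms List of [build_pwm()] objects.
#' @param tf_pct Named numeric vector: fraction of cluster cells
#'   expressing each TF (names match `pwm$tf`); missing TFs count as 0.
#' @param min_fold,max_fdr,min_tf_pct Retention rules (defaults 1.2,
#'   0.05, 0.10).
#' @param gc_bin GC-stratification bin width (default 0.05).
#' @param seed RNG seed for the GC resampling.
#' @return Data frame: tf, n_target_hits, target_frac, bg_frac, fold, p,
#'   fdr, expressed_pct, retained.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms, tf_pct,
                             min_fold = 1.2, max_fdr = 0.05,
                             min_tf_pct = 0.10, gc_bin = 0.05, seed = 1L) {
  n_t <- length(target_seqs)
  stopifnot(n_t > 0, length(background_seqs) > 0)
  gt <- gc_fraction(target_seqs)
  gb <- gc_fraction(background_seqs)
  breaks <- seq(0, 1, by = gc_bin)
  bt <- cut(gt, breaks, include.lowest = TRUE)
  bb <- cut(gb, breaks, include.lowest = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # resample the background to the target GC bin profile
  idx <- unlist(lapply(levels(bt), function(lv) {
    need <- sum(bt == lv)
    if (need == 0L) return(integer(0))
    pool <- which(bb == lv)
    if (length(pool) == 0L) pool <- seq_along(background_seqs)
    sample(pool, size = need * ceiling(length(background_seqs) / n_t),
           replace = TRUE)
  }))
  bg <- background_seqs[idx]
  rows <- lapply(pwms, function(pw) {
    et <- exact_threshold(pw)
    h_t <- scan_motifs(target_seqs, pw, et, dedup = FALSE)
    h_b <- scan_motifs(bg, pw, et, dedup = FALSE)
    k <- length(unique(h_t$seq))
    p_bg <- length(unique(h_b$seq)) / length(bg)
    if (p_bg == 0 && k > 0) {
      message("background hit fraction floored for ", pw$tf)
      p_bg <- 0.5 / length(bg)
    }
    p <- if (p_bg == 0) 1 else
      stats::pbinom(k - 1, n_t, p_bg, lower.tail = FALSE)
    data.frame(tf = pw$tf, n_target_hits = k, target_frac = k / n_t,
               bg_frac = p_bg,
               fold = if (p_bg > 0) (k / n_t) / p_bg else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- bh_fdr(res$p)
  res$expressed_pct <- ifelse(res$tf %in% names(tf_pct),
                              tf_pct[res$tf], 0)
  res$retained <- !is.na(res$fold) & res$fold >= min_fold &
    res$fdr <= max_fdr & res$expressed_pct >= min_tf_pct
  rownames(res) <- NULL
  res
}

#' Read JASPAR-format PFM text
#'
#' Parses the simple JASPAR text layout: a `>ID NAME` header line followed
#' by four rows `A [ counts ]` ... `T [ counts ]`.
#'
#' @param path File path.
#' @return Named list of 4 x L count matrices.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      id <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]][1]
      rows <- lines[(i + 1):(i + 4)]
      mat <- t(vapply(rows, function(r) {
        v <- gsub("^[ACGT]\\s*\\[|\\]\\s*$", "", r)
        as.numeric(strsplit(trimws(v), "\\s+")[[1]])
      }, FUN.VALUE = numeric(
        length(strsplit(trimws(gsub("^[ACGT]\\s*\\[|\\]\\s*$", "",
                                    rows[1])), "\\s+")[[1]]))))
      rownames(mat) <- BASES
      out[[id]] <- mat
      i <- i + 5L
    } else i <- i + 1L
  }
  out
}

#' Write PFMs in JASPAR text format
#'
#' @param pfms Named list of 4 x L count matrices.
#' @param path Output file.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pfms)) {
    writeLines(paste0(">", id, " ", id), con)
    m <- pfms[[id]]
    for (b in 1:4)
      writeLines(sprintf("%s  [ %s ]", BASES[b],
                         paste(format(m[b, ], trim = TRUE),
                               collapse = " ")), con)
  }
}
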