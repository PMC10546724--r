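# Sliding-window Poisson peak calling with a dynamic local background and
# Fisher-method multi-sample consensus.

#' Call peaks from fragment midpoints with a dynamic Poisson background
#'
#' Slides a `window`-bp window (step `step`) along each chromosome and
#' tests the midpoint count against a local Poisson rate
#' \eqn{\lambda_{local}} taken as the maximum of the genome-wide rate and
#' the rates in surrounding windows at each scale in `lambda_scales`, each
#' rescaled to the window size. Windows with upper-tail
#' \eqn{P(X \ge k)} at or below `p_cutoff` are merged when adjacent or
#' overlapping; a merged peak's p-value is the minimum member p.
#'
#' @param midpoints Data frame with `chrom` and `pos` (0-based fragment
#'   midpoints), or a numeric vector of positions for a single chromosome.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window Window width in bp (default 200).
#' @param step Step between window starts (default 100).
#' @param lambda_scales Local background scales in bp
#'   (default 1000, 5000, 10000).
#' @param p_cutoff Window significance cutoff (default 1e-5).
#' @return Data frame of peaks: chrom, start, end, p (min member window p),
#'   summit_count (max member window count).
#' @export
call_peaks <- function(midpoints, chrom_lengths, window = 200L, step = 100L,
                       lambda_scales = c(1000L, 5000L, 10000L),
                       p_cutoff = 1e-5) {
  if (is.numeric(midpoints))
    midpoints <- data.frame(
      chrom = rep(names(chrom_lengths)[1], length(midpoints)),
      pos = midpoints)
  stopifnot(all(c("chrom", "pos") %in% names(midpoints)))
  genome_bp <- sum(as.numeric(chrom_lengths))
  n_total <- nrow(midpoints)
  if (n_total == 0L || genome_bp == 0) return(empty_peaks())
  rate_bp <- n_total / genome_bp  # genome-wide fragments per bp
  out <- list()
  for (ch in names(chrom_lengths)) {
    pos <- sort(midpoints$pos[midpoints$chrom == ch])
    if (length(pos) == 0L) next
    L <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, L - window), by = step)
    # cumulative count of midpoints < x, for O(1) window counts
    count_in <- function(lo, hi) {  # [lo, hi)
      findInterval(hi - 1e-9, pos) - findInterval(lo - 1e-9, pos)
    }
    k <- count_in(starts, starts + window)
    lam <- rep(rate_bp * window, length(starts))
    centre <- starts + window / 2
    for (sc in lambda_scales) {
      cs <- count_in(pmax(0, centre - sc / 2), pmin(L, centre + sc / 2))
      width <- pmin(L, centre + sc / 2) - pmax(0, centre - sc / 2)
      lam <- pmax(lam, cs / width * window)
    }
    p <- stats::ppois(k - 1, lam, lower.tail = FALSE)
    sig <- which(p <= p_cutoff)
    if (length(sig) == 0L) next
    # merge adjacent/overlapping significant windows
    iv <- IRanges::reduce(IRanges::IRanges(starts[sig] + 1L,
                                           starts[sig] + window))
    hit <- IRanges::findOverlaps(IRanges::IRanges(starts[sig] + 1L,
                                                  starts[sig] + window), iv)
    gp <- S4Vectors::subjectHits(hit)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(iv) - 1L,
      end = IRanges::end(iv),
      p = as.numeric(tapply(p[sig], gp, min)),
      summit_count = as.integer(tapply(k[sig], gp, max)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_peaks())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             p = numeric(), summit_count = integer())
}

#' Fisher's combined probability
#'
#' \eqn{X^2 = -2\sum \ln p_i} referred to a chi-square with 2k df.
#'
#' @param p Vector of p-values (zeros are clamped to the smallest positive
#'   double, with a message).
#' @return List with `statistic`, `df`, `p`.
#' @export
fisher_combine <- function(p) {
  if (any(p == 0)) {
    message("p = 0 input clamped to .Machine$double.xmin")
    p <- pmax(p, .Machine$double.xmin)
  }
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = x2, df = df,
       p = stats::pchisq(x2, df = df, lower.tail = FALSE))
}

#' Multi-sample consensus peaks by Fisher's method
#'
#' Groups overlapping per-sample peaks by single-linkage interval overlap,
#' combines member p-values with Fisher's method, and keeps groups backed
#' by at least `min_samples` distinct samples with BH FDR at or below
#' `fdr`. Consensus coordinates are the union span of the group.
#'
#' @param peak_list Named list of per-sample peak data frames (columns
#'   chrom, start, end, p), names = sample ids.
#' @param min_samples Minimum distinct samples per group (default 2).
#' @param fdr BH FDR cutoff on the combined p (default 0.05).
#' @return Data frame: chrom, start, end, n_samples, statistic, p, fdr.
#' @export
consensus_peaks <- function(peak_list, min_samples = 2L, fdr = 0.05) {
  stopifnot(length(peak_list) >= 2L)
  if (is.null(names(peak_list)))
    names(peak_list) <- paste0("s", seq_along(peak_list))
  all <- do.call(rbind, lapply(sort(names(peak_list)), function(s) {
    d <- peak_list[[s]]
    if (nrow(d) == 0L) return(NULL)
    cbind(d[, c("chrom", "start", "end", "p")], sample = s)
  }))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_samples = integer(),
                      statistic = numeric(), p = numeric(),
                      fdr = numeric()))
  gr <- intervals_to_granges(all)
  # single-linkage overlap groups = connected components of the overlap
  # graph = reduced ranges
  red <- GenomicRanges::reduce(gr)
  grp <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, red))
  rows <- lapply(split(seq_len(nrow(all)), grp), function(idx) {
    sub <- all[idx, , drop = FALSE]
    fc <- suppressMessages(fisher_combine(sub$p))
    data.frame(chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end),
               n_samples = length(unique(sub$sample)),
               statistic = fc$statistic, p = fc$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$n_samples >= min_samples, , drop = FALSE]
  res$fdr <- bh_fdr(res$p)
  res <- res[!is.na(res$fdr) & res$fdr <= fdr, , drop = FALSE]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
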