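#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment with monotonicity enforcement, delegating to
#' [stats::p.adjust()]. Missing p-values propagate as `NA` and do not count
#' towards the family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Hybrid score of a score vector
#'
#' The relative separation (x1 - x2) / x1 between the top two prediction
#' scores; low values indicate ambiguous (hybrid) identity.
#'
#' @param scores Numeric vector of non-negative prediction scores.
#' @return Single numeric value in `[0, 1]` (NaN when the maximum is 0).
#' @export
hybrid_score <- function(scores) {
  s <- sort(scores, decreasing = TRUE)
  (s[1] - s[2]) / s[1]
}

# Interval helpers -- all coordinates 0-based, half-open [start, end).

#' Construct a 0-based half-open genomic interval table
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param name Optional feature names (defaults to `iv1..ivn`).
#' @param strand Optional strand (`"+"`, `"-"`, or `"."`).
#' @return A `data.frame` with columns chrom/start/end/name/strand.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- paste0("iv", seq_len(n))
  if (is.null(strand)) strand <- rep(".", n)
  stopifnot(length(start) == n, length(end) == n, all(end > start))
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), name = as.character(name),
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' @keywords internal
intervals_to_granges <- function(iv) {
  GenomicRanges::GRanges(
    seqnames = iv$chrom,
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    strand = if ("strand" %in% names(iv)) {
      ifelse(iv$strand %in% c("+", "-"), iv$strand, "*")
    } else "*")
}

#' Promoter interval for a TSS
#'
#' Strand-oriented promoter window: 2000 bp upstream through 200 bp
#' downstream of the transcription start site, 0-based half-open.
#'
#' @param tss Integer vector of TSS coordinates (0-based).
#' @param strand `"+"` or `"-"` per gene.
#' @param upstream,downstream Window extents in bp.
#' @return A two-column matrix (`start`, `end`).
#' @export
promoter_window <- function(tss, strand, upstream = 2000L, downstream = 200L) {
  stopifnot(all(strand %in% c("+", "-")))
  start <- ifelse(strand == "+", tss - upstream, tss - downstream)
  end <- ifelse(strand == "+", tss + downstream, tss + upstream)
  cbind(start = pmax(0L, as.integer(start)), end = as.integer(end))
}

#' @keywords internal
stable_file_hash <- function(path) {
  unname(tools::md5sum(path))
}

#' @keywords internal
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # deparse to canonical text so the hash is stable across sessions
  writeLines(deparse(x, control = c("exact")), f)
  stable_file_hash(f)
}
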