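# Per-nucleus QC, hybrid-score multiplet removal, and cross-modality
# cluster linking.

#' Default QC thresholds
#'
#' RNA: 200-10,000 detected features, <= 17.4% mitochondrial reads.
#' ATAC: nucleosome signal <= 4, TSS enrichment >= 2, >= 15% reads in
#' peaks, 1000 <= peak-region fragments <= per-sample 99th percentile,
#' blacklist ratio <= 5%. Both modalities: top prediction score >= 0.5 and
#' hybrid score (x1 - x2)/x1 >= 0.2.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(rna_min_features = 200L, rna_max_features = 10000L,
       rna_max_pct_mito = 0.174,
       atac_max_nucleosome_signal = 4, atac_min_tss_enrichment = 2,
       atac_min_pct_reads_in_peaks = 0.15,
       atac_min_peak_fragments = 1000L, atac_fragment_quantile = 0.99,
       atac_max_blacklist_ratio = 0.05,
       min_prediction_score = 0.5, min_hybrid_score = 0.2)
}

#' Per-nucleus ATAC QC metrics from fragments
#'
#' Computes, per barcode: nucleosome signal (ratio of mononucleosome
#' fragments of 147-294 bp to nucleosome-free fragments < 147 bp), TSS
#' enrichment (mean fragment signal in a +/- `tss_window` bp window around
#' TSSs over the mean in two `tss_window`-bp flanks ending at
#' +/- `tss_flank_at` bp), fraction of fragments in peaks, peak-region
#' fragment count, and blacklist overlap ratio.
#'
#' @param fragments Data frame with `chrom`, `start`, `end`, `barcode`
#'   (0-based half-open fragment intervals).
#' @param peaks,blacklist Interval data frames ([genomic_intervals()]).
#' @param tss Data frame with `chrom`, `tss` (0-based TSS positions).
#' @param tss_window Half-width of the central TSS window (default 100 bp).
#' @param tss_flank_at Outer edge of the flanking windows (default 2000 bp).
#' @return Data frame, one row per barcode: `barcode`, `n_fragments`,
#'   `nucleosome_signal`, `tss_enrichment`, `pct_reads_in_peaks`,
#'   `peak_region_fragments`, `blacklist_ratio`. Zero nucleosome-free
#'   fragments give `Inf` signal; zero fragments give `NaN` ratios.
#' @export
compute_atac_qc <- function(fragments, peaks, tss, blacklist = NULL,
                            tss_window = 100L, tss_flank_at = 2000L) {
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(fragments)))
  bc <- sort(unique(fragments$barcode))
  fb <- factor(fragments$barcode, levels = bc)
  len <- fragments$end - fragments$start
  total <- as.integer(table(fb))
  mono <- tapply(len >= 147 & len <= 294, fb, sum, default = 0L)
  free <- tapply(len < 147, fb, sum, default = 0L)
  ns <- ifelse(free > 0, mono / free, ifelse(mono > 0, Inf, NaN))

  fr_gr <- intervals_to_granges(
    data.frame(chrom = fragments$chrom, start = fragments$start,
               end = fragments$end))
  in_set <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, nrow(fragments)))
    suppressWarnings(IRanges::overlapsAny(fr_gr, intervals_to_granges(iv)))
  }
  in_peak <- in_set(peaks)
  in_bl <- in_set(blacklist)
  peak_frag <- tapply(in_peak, fb, sum, default = 0L)
  bl_frag <- tapply(in_bl, fb, sum, default = 0L)

  # TSS enrichment via fragment midpoints: per-bp signal density in the
  # centre window vs the mean of the two outer flanks
  mid <- (fragments$start + fragments$end) %/% 2L
  win_count <- function(lo_off, hi_off) {
    w <- genomic_intervals(
      chrom = rep(tss$chrom, 2L),
      start = pmax(0L, c(tss$tss + lo_off, tss$tss - hi_off)),
      end = pmax(1L, c(tss$tss + hi_off, tss$tss - lo_off)))
    mg <- GenomicRanges::GRanges(fragments$chrom,
                                 IRanges::IRanges(mid + 1L, mid + 1L))
    suppressWarnings(IRanges::overlapsAny(mg, intervals_to_granges(w)))
  }
  centre <- win_count(-tss_window, tss_window)
  flank <- win_count(tss_flank_at - tss_window, tss_flank_at)
  c_ct <- tapply(centre, fb, sum, default = 0L)
  f_ct <- tapply(flank, fb, sum, default = 0L)
  # equal total widths (2*window centre vs 2*window flank) -> plain ratio;
  # +1 pseudocount on the flank keeps the score finite in sparse nuclei
  tsse <- c_ct / pmax(f_ct, 1L)

  data.frame(barcode = bc, n_fragments = total,
             nucleosome_signal = as.numeric(ns),
             tss_enrichment = as.numeric(tsse),
             pct_reads_in_peaks = as.numeric(peak_frag) / total,
             peak_region_fragments = as.integer(peak_frag),
             blacklist_ratio = as.numeric(bl_frag) / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter nuclei on QC metrics and prediction scores
#'
#' Applies the modality-specific QC rules plus the score rules (top
#' prediction score >= 0.5, hybrid score >= 0.2). Every removed nucleus
#' carries a machine-readable comma-separated list of failed rules. The
#' ATAC upper fragment cap is the per-sample (donor) 99th percentile.
#'
#' @param qc_table Data frame keyed by `barcode`; RNA needs `n_features`,
#'   `pct_mito`; ATAC needs `nucleosome_signal`, `tss_enrichment`,
#'   `pct_reads_in_peaks`, `peak_region_fragments`, `blacklist_ratio`, and
#'   `donor` (for the percentile cap).
#' @param score_table Data frame with `barcode`, `x1`, `x2` (top-two
#'   prediction scores); nuclei missing from it are removed as "unscored".
#' @param modality `"rna"` or `"atac"`.
#' @param thresholds Threshold list, see [qc_thresholds()].
#' @return List with `kept` (character barcodes) and `removed` (data frame
#'   `barcode`, `reason`).
#' @export
filter_nuclei <- function(qc_table, score_table, modality = c("rna", "atac"),
                          thresholds = qc_thresholds()) {
  modality <- match.arg(modality)
  th <- thresholds
  qc_table <- qc_table[order(qc_table$barcode), , drop = FALSE]
  reasons <- vector("list", nrow(qc_table))
  add <- function(fail, tag) {
    fail[is.na(fail)] <- TRUE  # undefined metric fails the rule
    for (i in which(fail)) reasons[[i]] <<- c(reasons[[i]], tag)
  }
  if (modality == "rna") {
    add(qc_table$n_features < th$rna_min_features |
          qc_table$n_features > th$rna_max_features, "n_features")
    add(qc_table$pct_mito > th$rna_max_pct_mito, "pct_mito")
  } else {
    add(!(qc_table$nucleosome_signal <= th$atac_max_nucleosome_signal),
        "nucleosome_signal")
    add(!(qc_table$tss_enrichment >= th$atac_min_tss_enrichment),
        "tss_enrichment")
    add(!(qc_table$pct_reads_in_peaks >= th$atac_min_pct_reads_in_peaks),
        "pct_reads_in_peaks")
    cap <- stats::ave(qc_table$peak_region_fragments, qc_table$donor,
                      FUN = function(x)
                        stats::quantile(x, th$atac_fragment_quantile,
                                        names = FALSE))
    add(!(qc_table$peak_region_fragments >= th$atac_min_peak_fragments &
            qc_table$peak_region_fragments <= cap), "peak_region_fragments")
    add(!(qc_table$blacklist_ratio <= th$atac_max_blacklist_ratio),
        "blacklist_ratio")
  }
  m <- match(qc_table$barcode, score_table$barcode)
  add(is.na(m), "unscored")
  x1 <- score_table$x1[m]; x2 <- score_table$x2[m]
  add(!is.na(m) & !(x1 >= th$min_prediction_score), "prediction_score")
  add(!is.na(m) & !((x1 - x2) / x1 >= th$min_hybrid_score), "hybrid")
  removed <- lengths(reasons) > 0L
  list(kept = qc_table$barcode[!removed],
       removed = data.frame(
         barcode = qc_table$barcode[removed],
         reason = vapply(reasons[removed], paste, "", collapse = ","),
         stringsAsFactors = FALSE))
}

#' Link ATAC clusters to RNA clusters by summed prediction scores
#'
#' Per-ATAC-cluster column sums of the per-nucleus RNA-cluster prediction
#' scores; the argmax designates the linked RNA cluster; the cluster hybrid
#' score is (s1 - s2)/s1 on the summed scores. Ties are broken towards the
#' lowest cluster id and flagged.
#'
#' @param score_matrix Numeric matrix, nuclei x RNA clusters (colnames are
#'   RNA cluster ids); rownames are barcodes.
#' @param atac_clusters Character/factor vector of ATAC cluster ids, one
#'   per row of `score_matrix`.
#' @param atac_celltype,rna_celltype Optional named vectors mapping cluster
#'   id to cell-type label for the concordance flag.
#' @return Data frame, one row per ATAC cluster: `atac_cluster`,
#'   `linked_rna_cluster`, `cluster_hybrid_score`, `tie`,
#'   `celltype_concordant` (NA when no maps are given); the summed score
#'   matrix is attached as attribute `"summed_scores"`.
#' @export
link_clusters <- function(score_matrix, atac_clusters,
                          atac_celltype = NULL, rna_celltype = NULL) {
  stopifnot(nrow(score_matrix) == length(atac_clusters))
  cl <- sort(unique(as.character(atac_clusters)))
  if (any(!table(atac_clusters) > 0)) stop("empty ATAC cluster")
  sums <- t(vapply(cl, function(a)
    colSums(score_matrix[atac_clusters == a, , drop = FALSE]),
    numeric(ncol(score_matrix))))
  rownames(sums) <- cl
  rna_ids <- colnames(score_matrix)
  link <- character(length(cl)); hyb <- numeric(length(cl))
  tie <- logical(length(cl))
  for (i in seq_along(cl)) {
    s <- sums[i, ]
    top <- max(s)
    winners <- rna_ids[s == top]
    tie[i] <- length(winners) > 1L
    link[i] <- sort(winners)[1]          # lowest-id tie rule
    s2 <- max(s[rna_ids != link[i]], -Inf)
    hyb[i] <- if (top > 0) (top - s2) / top else NaN
  }
  conc <- rep(NA, length(cl))
  if (!is.null(atac_celltype) && !is.null(rna_celltype))
    conc <- unname(atac_celltype[cl] == rna_celltype[link])
  out <- data.frame(atac_cluster = cl, linked_rna_cluster = link,
                    cluster_hybrid_score = hyb, tie = tie,
                    celltype_concordant = conc, stringsAsFactors = FALSE)
  attr(out, "summed_scores") <- sums
  out
}

#' Jaccard validation of cluster links on shared barcodes
#'
#' For each link a -> r, the Jaccard index of the barcode sets assigned to
#' ATAC cluster a and RNA cluster r in a multiome-style fixture where every
#' barcode carries both assignments.
#'
#' @param links Data frame from [link_clusters()] (`atac_cluster`,
#'   `linked_rna_cluster`).
#' @param atac_assign,rna_assign Named character vectors barcode -> cluster.
#' @return List with `per_cluster` (data frame `atac_cluster`,
#'   `linked_rna_cluster`, `jaccard`) and `mean` (unweighted mean J).
#' @export
jaccard_validate <- function(links, atac_assign, rna_assign) {
  j <- mapply(function(a, r) {
    A <- names(atac_assign)[atac_assign == a]
    B <- names(rna_assign)[rna_assign == r]
    if (length(A) == 0L) stop("empty ATAC cluster: ", a)
    length(intersect(A, B)) / length(union(A, B))
  }, links$atac_cluster, links$linked_rna_cluster)
  per <- data.frame(atac_cluster = links$atac_cluster,
                    linked_rna_cluster = links$linked_rna_cluster,
                    jaccard = unname(j), stringsAsFactors = FALSE)
  list(per_cluster = per, mean = mean(per$jaccard))
}
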