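# Cross-study consensus calling for differential genes (identity, cell
# type, direction) and differential peaks (interval overlap + Jaccard +
# direction).

#' Consensus differentially expressed genes across studies
#'
#' Per cell type, a gene is in the 2-study tier when it passes
#' |log2FC| > `min_abs_lfc` with the same sign in at least two studies,
#' and in the all-study tier when it does so in every study. Genes
#' perturbed in opposite directions are never consensus.
#'
#' @param tables Named list of per-study data frames with columns `gene`,
#'   `celltype`, `log2fc`.
#' @param min_abs_lfc Effect-size cutoff (default 0.2).
#' @return List with `consensus` (data frame gene/celltype/direction/
#'   n_studies/studies/tier) and `per_study` (passing-gene counts).
#' @export
consensus_degs <- function(tables, min_abs_lfc = 0.2) {
  stopifnot(length(tables) >= 2L, !is.null(names(tables)))
  n_studies <- length(tables)
  pass <- lapply(names(tables), function(s) {
    d <- tables[[s]]
    stopifnot(all(c("gene", "celltype", "log2fc") %in% names(d)))
    d <- d[abs(d$log2fc) > min_abs_lfc, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    data.frame(study = s, gene = d$gene, celltype = d$celltype,
               sign = sign(d$log2fc), stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pass)
  per_study <- vapply(names(tables), function(s)
    sum(all$study == s), integer(1))
  if (is.null(all) || nrow(all) == 0L)
    return(list(consensus = data.frame(gene = character(),
                                       celltype = character(),
                                       direction = character(),
                                       n_studies = integer(),
                                       studies = character(),
                                       tier = character()),
                per_study = per_study))
  key <- paste(all$gene, all$celltype, sep = "\r")
  rows <- lapply(split(seq_len(nrow(all)), key), function(idx) {
    sub <- all[idx, , drop = FALSE]
    sub <- sub[!duplicated(sub$study), , drop = FALSE]
    if (nrow(sub) < 2L) return(NULL)
    if (length(unique(sub$sign)) > 1L) return(NULL)  # opposite directions
    data.frame(gene = sub$gene[1], celltype = sub$celltype[1],
               direction = if (sub$sign[1] > 0) "+" else "-",
               n_studies = nrow(sub),
               studies = paste(sort(sub$study), collapse = ","),
               tier = if (nrow(sub) == n_studies) "all_studies"
               else "two_studies",
               stringsAsFactors = FALSE)
  })
  cons <- do.call(rbind, rows)
  if (is.null(cons)) cons <- data.frame(gene = character(),
                                        celltype = character(),
                                        direction = character(),
                                        n_studies = integer(),
                                        studies = character(),
                                        tier = character())
  rownames(cons) <- NULL
  list(consensus = cons[order(cons$celltype, cons$gene), , drop = FALSE],
       per_study = per_study)
}

#' Match differentially accessible peaks across two studies
#'
#' For every overlapping pair of peaks, the overlap width and the interval
#' Jaccard index (intersection width over union width) are computed; pairs
#' with overlap >= `min_overlap` bp, Jaccard >= `min_jaccard` and the same
#' log2FC sign are kept. A peak is consensus when it has at least one kept
#' pair.
#'
#' @param peaks_a,peaks_b Data frames with `chrom`, `start`, `end`,
#'   `name`, `log2fc` (0-based half-open intervals).
#' @param min_overlap Minimum overlap in bp (default 200).
#' @param min_jaccard Minimum interval Jaccard (default 0.25).
#' @return List with `matches` (data frame peak_a/peak_b/overlap_bp/
#'   jaccard/direction) and `consensus_a`, `consensus_b` (character
#'   vectors of consensus peak names). Pairs overlapping with conflicting
#'   signs are reported in `conflicting`.
#' @export
match_daps <- function(peaks_a, peaks_b, min_overlap = 200L,
                       min_jaccard = 0.25) {
  stopifnot(all(peaks_a$end > peaks_a$start),
            all(peaks_b$end > peaks_b$start))
  ga <- intervals_to_granges(peaks_a)
  gb <- intervals_to_granges(peaks_b)
  ov <- GenomicRanges::findOverlaps(ga, gb)
  if (length(ov) == 0L)
    return(list(matches = empty_matches(), consensus_a = character(),
                consensus_b = character(), conflicting = empty_matches()))
  i <- S4Vectors::queryHits(ov); j <- S4Vectors::subjectHits(ov)
  inter <- pmin(peaks_a$end[i], peaks_b$end[j]) -
    pmax(peaks_a$start[i], peaks_b$start[j])
  uni <- pmax(peaks_a$end[i], peaks_b$end[j]) -
    pmin(peaks_a$start[i], peaks_b$start[j])
  jac <- inter / uni
  same <- sign(peaks_a$log2fc[i]) == sign(peaks_b$log2fc[j])
  m <- data.frame(peak_a = peaks_a$name[i], peak_b = peaks_b$name[j],
                  overlap_bp = as.integer(inter), jaccard = jac,
                  direction = ifelse(peaks_a$log2fc[i] > 0, "+", "-"),
                  same_sign = same, stringsAsFactors = FALSE)
  size_ok <- m$overlap_bp >= min_overlap & m$jaccard >= min_jaccard
  kept <- m[size_ok & m$same_sign, , drop = FALSE]
  conflicting <- m[size_ok & !m$same_sign, , drop = FALSE]
  rownames(kept) <- rownames(conflicting) <- NULL
  list(matches = kept[, setdiff(names(kept), "same_sign")],
       consensus_a = sort(unique(kept$peak_a)),
       consensus_b = sort(unique(kept$peak_b)),
       conflicting = conflicting[, setdiff(names(conflicting), "same_sign")])
}

empty_matches <- function() {
  data.frame(peak_a = character(), peak_b = character(),
             overlap_bp = integer(), jaccard = numeric(),
             direction = character())
}
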