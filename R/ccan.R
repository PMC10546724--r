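# Cis-co-accessibility networks: kNN aggregation, distance-penalized
# sparse inverse covariance, Louvain community extraction, directionality
# classification, cCRE-target linking, GWAS-window flags, GO enrichment.

#' Aggregate nuclei into k-nearest-neighbour groups
#'
#' Sums raw counts over groups of `k` nearest neighbours in the embedding
#' and depth-normalizes each group (counts / group total x 1e4). Seed
#' nuclei are accepted greedily (in input order) while the shared-member
#' fraction with every accepted group stays at or below `max_overlap`.
#'
#' @param counts Peak x nucleus count matrix (one cluster's nuclei).
#' @param embedding Nuclei x dims numeric matrix.
#' @param k Group size (default 50).
#' @param max_overlap Maximum shared-member fraction between accepted
#'   groups (default 0.8).
#' @return List with `matrix` (groups x peaks, depth-normalized) and
#'   `members` (list of member column indices per group).
#' @export
aggregate_knn <- function(counts, embedding, k = 50L, max_overlap = 0.8) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  stopifnot(nrow(embedding) == n)
  if (n < k) stop("cluster has ", n, " nuclei < k = ", k,
                  "; merge clusters or skip")
  d2 <- as.matrix(stats::dist(embedding))
  members <- list()
  for (i in seq_len(n)) {
    grp <- order(d2[i, ])[seq_len(k)]
    ok <- all(vapply(members, function(m)
      length(intersect(m, grp)) / k <= max_overlap, logical(1)))
    if (ok) members[[length(members) + 1L]] <- sort(grp)
  }
  agg <- t(vapply(members, function(m)
    rowSums(counts[, m, drop = FALSE]), numeric(nrow(counts))))
  tot <- pmax(rowSums(agg), 1)
  list(matrix = sweep(agg, 1, tot, "/") * 1e4, members = members)
}

#' Distance-penalized co-accessibility scores
#'
#' Estimates, per chromosome and per overlapping genomic window, a sparse
#' inverse covariance of the aggregated peak accessibility with pairwise
#' penalty \eqn{\rho_{ij} = \rho_0 (d_{ij}/d_{max})^{\gamma}} for peak
#' pairs within `max_dist` and an effectively infinite penalty beyond.
#' The precision matrix is converted to partial correlations ("scores");
#' duplicate pairs from window overlap are averaged. Edges beyond
#' `max_dist` are never emitted.
#'
#' @param agg Groups x peaks matrix ([aggregate_knn()]).
#' @param peaks Interval data frame aligned to the columns of `agg`.
#' @param max_dist Maximum pair distance in bp (default 500,000).
#' @param rho0 Penalty scale (default 0.1).
#' @param gamma Distance-penalty exponent (default 0.5).
#' @param window_bp,window_overlap Estimation window size and fractional
#'   overlap (defaults 1 Mb, 0.5).
#' @return Data frame of edges: peak_a, peak_b (canonical order by column
#'   index), score, distance.
#' @export
coaccessibility <- function(agg, peaks, max_dist = 5e5, rho0 = 0.1,
                            gamma = 0.5, window_bp = 1e6,
                            window_overlap = 0.5) {
  stopifnot(ncol(agg) == nrow(peaks))
  pk_mid <- (peaks$start + peaks$end) / 2
  pk_name <- peaks$name
  acc <- new.env()  # "i:j" -> c(sum, n)
  step <- window_bp * (1 - window_overlap)
  for (ch in unique(peaks$chrom)) {
    on_ch <- which(peaks$chrom == ch)
    if (length(on_ch) < 2L) next
    mids <- pk_mid[on_ch]
    w0 <- seq(floor(min(mids) / step) * step, max(mids), by = step)
    for (ws in w0) {
      idx <- on_ch[mids >= ws & mids < ws + window_bp]
      if (length(idx) < 2L) next
      X <- agg[, idx, drop = FALSE]
      sds <- apply(X, 2, stats::sd)
      live <- sds > 0
      idx <- idx[live]
      if (length(idx) < 2L) next
      X <- scale(X[, live, drop = FALSE])
      S <- stats::cov(X)
      d <- abs(outer(pk_mid[idx], pk_mid[idx], "-"))
      rho <- rho0 * (d / max_dist)^gamma
      rho[d > max_dist] <- 1e6
      diag(rho) <- 0
      fit <- suppressMessages(glasso_penalized(S, rho))
      pc <- fit$partial_cor
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (a >= b || d[a, b] > max_dist) next
        key <- paste(idx[a], idx[b], sep = ":")
        prev <- if (!is.null(acc[[key]])) acc[[key]] else c(0, 0)
        acc[[key]] <- prev + c(pc[a, b], 1)
      }
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L)
    return(data.frame(peak_a = character(), peak_b = character(),
                      score = numeric(), distance = numeric()))
  ij <- do.call(rbind, strsplit(keys, ":"))
  i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
  vals <- t(vapply(keys, function(k) acc[[k]], numeric(2)))
  out <- data.frame(peak_a = pk_name[i], peak_b = pk_name[j],
                    score = vals[, 1] / vals[, 2],
                    distance = abs(pk_mid[i] - pk_mid[j]),
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$peak_a, pk_name), match(out$peak_b, pk_name)), ]
  rownames(out) <- NULL
  out
}

#' Extract CCANs by Louvain community detection
#'
#' Builds a graph on peaks from edges with score at or above `min_score`,
#' runs weighted Louvain community detection (fixed seed for determinism)
#' and emits communities with at least `min_size` peaks as CCANs.
#'
#' @param edges Edge data frame from [coaccessibility()].
#' @param min_score Minimum co-accessibility score (default 0.2).
#' @param min_size Minimum community size in peaks (default 3).
#' @param seed RNG seed for Louvain (default 1).
#' @param resolution Louvain resolution (default 1).
#' @return List of CCANs, each a list with `id`, `peaks` (character),
#'   `edges` (data frame subset).
#' @export
extract_ccans <- function(edges, min_score = 0.2, min_size = 3L, seed = 1L,
                          resolution = 1) {
  e <- edges[!is.na(edges$score) & edges$score >= min_score, , drop = FALSE]
  if (nrow(e) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$peak_a, to = e$peak_b, weight = e$score),
    directed = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  mem <- igraph::membership(comm)
  out <- list()
  for (cid in sort(unique(mem))) {
    pk <- sort(names(mem)[mem == cid])
    if (length(pk) < min_size) next
    out[[length(out) + 1L]] <- list(
      id = paste0("ccan", length(out) + 1L), peaks = pk,
      edges = e[e$peak_a %in% pk & e$peak_b %in% pk, , drop = FALSE])
  }
  out
}

#' Peaks overlapping a DEG's promoter or first intron
#'
#' @keywords internal
deg_anchor_peaks <- function(peak_iv, deg_ids, annotation) {
  pr <- annotation$promoters
  in1 <- annotation$intron1
  rows <- list()
  pk_gr <- intervals_to_granges(peak_iv)
  for (g in deg_ids) {
    regs <- rbind(
      cbind(pr[pr$gene_id == g, c("chrom", "start", "end")],
            kind = "promoter"),
      if (!is.null(in1) && any(in1$gene_id == g))
        cbind(in1[in1$gene_id == g, c("chrom", "start", "end")],
              kind = "intron1"))
    if (is.null(regs) || nrow(regs) == 0L) next
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
      pk_gr, intervals_to_granges(regs)))
    if (length(ov) == 0L) next
    rows[[g]] <- data.frame(
      gene = g, peak = peak_iv$name[S4Vectors::queryHits(ov)],
      kind = regs$kind[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(), peak = character(),
                      kind = character()))
  unique(do.call(rbind, rows))
}

#' Classify a CCAN by DAP/DEG directionality
#'
#' Forms all (member DAP, DEG-anchor) pairs. All pairs same sign:
#' unidirectional; no pair same sign: bidirectional; otherwise mixed. A
#' CCAN with no member DAP or no DEG anchor is "unclassified".
#'
#' @param ccan CCAN list element ([extract_ccans()]).
#' @param dap_table Data frame `feature`, `log2fc` of DAPs (peak names).
#' @param deg_table Data frame `feature`, `log2fc` of DEGs (gene ids).
#' @param peaks Interval data frame covering the CCAN's peaks.
#' @param annotation Annotation list with `promoters` and `intron1`
#'   (single-exon genes may be absent from `intron1`; they anchor via the
#'   promoter only).
#' @return List with `klass`, `daps` (data frame), `deg_anchors`
#'   (data frame gene/peak/kind with gene log2fc).
#' @export
classify_ccan <- function(ccan, dap_table, deg_table, peaks, annotation) {
  member_iv <- peaks[peaks$name %in% ccan$peaks, , drop = FALSE]
  daps <- dap_table[dap_table$feature %in% ccan$peaks, , drop = FALSE]
  anchors <- deg_anchor_peaks(member_iv, deg_table$feature, annotation)
  anchors$gene_log2fc <- deg_table$log2fc[match(anchors$gene,
                                                deg_table$feature)]
  if (nrow(daps) == 0L || nrow(anchors) == 0L)
    return(list(klass = "unclassified", daps = daps, deg_anchors = anchors))
  same <- outer(sign(daps$log2fc),
                sign(anchors$gene_log2fc[!duplicated(anchors$gene)]), "==")
  klass <- if (all(same)) "unidirectional"
  else if (!any(same)) "bidirectional" else "mixed"
  list(klass = klass, daps = daps, deg_anchors = anchors)
}

#' Noncoding flag for candidate cis-regulatory peaks
#'
#' A peak is noncoding when it overlaps no annotated exon and no promoter
#' of any gene.
#'
#' @keywords internal
is_noncoding_peak <- function(peak_iv, annotation) {
  pk <- intervals_to_granges(peak_iv)
  ex <- intervals_to_granges(annotation$exons)
  pr <- intervals_to_granges(annotation$promoters)
  suppressWarnings(!(IRanges::overlapsAny(pk, ex) |
                       IRanges::overlapsAny(pk, pr)))
}

#' Link candidate cis-regulatory elements to target DEGs
#'
#' Within unidirectional and mixed CCANs only, emits (cCRE, DEG) links
#' where (1) the cCRE DAP is co-accessible with a DEG promoter/intron-1
#' anchor peak at score >= `min_coacc`, (2) the anchor peak is itself a
#' DAP, (3) the cCRE DAP, the anchor DAP and the DEG share the same sign,
#' and (4) |DEG log2FC| >= `min_abs_lfc`; the cCRE must be noncoding
#' (overlapping no exon and no promoter).
#'
#' @param ccans List of CCANs with classifications: each element needs
#'   `peaks`, `edges`, `klass`, `daps`, `deg_anchors` (merge the outputs of
#'   [extract_ccans()] and [classify_ccan()]).
#' @param dap_table,deg_table As in [classify_ccan()].
#' @param peaks Interval data frame for all peaks.
#' @param annotation Annotation list.
#' @param min_coacc Minimum co-accessibility (default 0.2).
#' @param min_abs_lfc Minimum |DEG log2FC| (default 0.15).
#' @return Data frame of links: ccan, ccre, target, anchor, anchor_kind,
#'   coaccessibility, ccre_log2fc, anchor_log2fc, target_log2fc.
#' @export
link_ccres <- function(ccans, dap_table, deg_table, peaks, annotation,
                       min_coacc = 0.2, min_abs_lfc = 0.15) {
  out <- list()
  for (cc in ccans) {
    if (!cc$klass %in% c("unidirectional", "mixed")) next
    daps <- cc$daps
    anchors <- cc$deg_anchors
    if (nrow(daps) == 0L || nrow(anchors) == 0L) next
    nc <- is_noncoding_peak(peaks[match(daps$feature, peaks$name), ,
                                  drop = FALSE], annotation)
    edge_score <- function(a, b) {
      e <- cc$edges
      hit <- (e$peak_a == a & e$peak_b == b) |
        (e$peak_a == b & e$peak_b == a)
      if (any(hit)) max(e$score[hit]) else NA_real_
    }
    for (i in which(nc)) {
      ccre <- daps$feature[i]
      for (j in seq_len(nrow(anchors))) {
        anchor <- anchors$peak[j]
        if (anchor == ccre) next
        sc <- edge_score(ccre, anchor)
        if (is.na(sc) || sc < min_coacc) next                    # (1)
        k <- match(anchor, dap_table$feature)
        if (is.na(k)) next                                       # (2)
        g_lfc <- anchors$gene_log2fc[j]
        if (!(sign(daps$log2fc[i]) == sign(dap_table$log2fc[k]) &&
                sign(daps$log2fc[i]) == sign(g_lfc))) next       # (3)
        if (abs(g_lfc) < min_abs_lfc) next                       # (4)
        out[[length(out) + 1L]] <- data.frame(
          ccan = cc$id, ccre = ccre, target = anchors$gene[j],
          anchor = anchor, anchor_kind = anchors$kind[j],
          coaccessibility = sc, ccre_log2fc = daps$log2fc[i],
          anchor_log2fc = dap_table$log2fc[k], target_log2fc = g_lfc,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(ccan = character(), ccre = character(),
                      target = character(), anchor = character(),
                      anchor_kind = character(), coaccessibility = numeric(),
                      ccre_log2fc = numeric(), anchor_log2fc = numeric(),
                      target_log2fc = numeric()))
  res <- unique(do.call(rbind, out))
  # an anchor peak may overlap both the promoter and intron 1 of the same
  # gene; that is one link (promoter kind listed first wins)
  res <- res[!duplicated(res[, c("ccan", "ccre", "target", "anchor")]), ]
  rownames(res) <- NULL
  res
}

#' Flag entities within a window of any GWAS tag SNP
#'
#' An interval (or a CCAN, via any member peak) is flagged when any of its
#' coordinates lies within +/- `window` bp (inclusive) of a tag SNP on the
#' same chromosome.
#'
#' @param intervals Interval data frame ([genomic_intervals()]).
#' @param tag_snps Data frame with `chrom`, `pos` (0-based positions).
#' @param window Window half-width in bp (default 500,000).
#' @return Logical vector, one flag per interval row.
#' @export
gwas_window_overlap <- function(intervals, tag_snps, window = 5e5) {
  vapply(seq_len(nrow(intervals)), function(i) {
    ts <- tag_snps[tag_snps$chrom == intervals$chrom[i], , drop = FALSE]
    if (nrow(ts) == 0L) return(FALSE)
    # inclusive distance from any point of [start, end) to the SNP
    any(ts$pos >= intervals$start[i] - window &
          ts$pos <= (intervals$end[i] - 1L) + window)
  }, logical(1))
}

#' Hypergeometric GO-style gene-set enrichment
#'
#' One-sided hypergeometric test for overrepresentation of each gene set
#' among the test genes, against the supplied background (genes expressed
#' in at least 10% of the cluster's cells, by convention). Terms need at
#' least `min_genes` test-set genes and p at or below `p_cutoff`.
#'
#' @param test_genes Character vector of target genes.
#' @param background Character vector of background genes.
#' @param gene_sets Named list of character vectors (e.g. from a GMT).
#' @param p_cutoff Report cutoff (default 0.05).
#' @param min_genes Minimum test-set genes mapped to the term (default 3).
#' @return Data frame: term, n_test, n_term, p; sorted by p.
#' @export
go_enrichment <- function(test_genes, background, gene_sets,
                          p_cutoff = 0.05, min_genes = 3L) {
  test_genes <- intersect(unique(test_genes), background)
  N <- length(unique(background))
  n <- length(test_genes)
  rows <- lapply(names(gene_sets), function(tm) {
    term_bg <- intersect(gene_sets[[tm]], background)
    K <- length(term_bg)
    if (K == 0L) return(NULL)
    k <- length(intersect(test_genes, term_bg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, n_test = k, n_term = K, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(), n_test = integer(),
                      n_term = integer(), p = numeric()))
  res <- res[res$n_test >= min_genes & res$p <= p_cutoff, , drop = FALSE]
  res[order(res$p), , drop = FALSE]
}
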