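# Synthetic parallel snRNA/snATAC data with a machine-readable truth
# ledger: cluster structure, donor-level diagnosis effects on genes and
# peaks, block-structured peak co-accessibility, motif instances in peak
# sequences, and affinity-changing SNP alleles.

#' Synthetic study configuration
#'
#' Defaults describe a desk-scale version of a 12-vs-12 donor parallel
#' single-nucleus case-control study: 24 donors split evenly, 3 cell
#' clusters, two 10-Mb chromosomes, planted differential genes/peaks at
#' |log2FC| 0.5, donor random-intercept SD 0.2 on the log2 scale, 5%
#' hybrid nuclei and 2% QC failures per rule, co-accessibility blocks of
#' 5 peaks at partial correlation 0.2, and a doubled case proportion in
#' cluster 1.
#'
#' @param n_donors Total donors, split evenly case/control (default 24).
#' @param n_clusters Clusters per modality (default 3).
#' @param n_genes,n_peaks Feature counts (defaults 300, 360).
#' @param nuclei_per_donor Nuclei per donor per modality (default 150).
#' @param chrom_lengths Named vector of chromosome lengths (default two
#'   10-Mb chromosomes).
#' @param n_deg_per_cluster,deg_log2fc Planted DEGs per cluster and their
#'   |log2FC| (defaults 12, 0.5; alternating signs).
#' @param n_dap_per_cluster,dap_log2fc Planted DAPs per cluster and their
#'   |log2FC| (defaults 16, 0.5).
#' @param max_abs_log2fc Bound on planted effects (default 2).
#' @param donor_sd Donor random-intercept SD, log2 scale (default 0.2).
#' @param hybrid_frac Fraction of nuclei given ambiguous top-two
#'   prediction scores (default 0.05).
#' @param qc_fail_frac Fraction of nuclei violating each QC rule
#'   (default 0.02).
#' @param prop_shift_cluster,prop_shift_fold Cluster whose case-group
#'   proportion is multiplied by the fold (defaults 1, 2).
#' @param promoter_peak_frac Fraction of peaks placed over promoters or
#'   first introns (default 0.3).
#' @param n_ccan_blocks,ccan_block_size,ccan_partial_cor Planted
#'   co-accessibility blocks (defaults 4 blocks of 5 peaks at 0.2).
#' @param motif_length,n_motifs Planted PWMs (defaults length 8, 3 PWMs).
#' @param n_motif_plants Motif instances planted per PWM (default 4).
#' @param n_decoy_snps Low-frequency decoy SNPs (default 5).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_donors = 24L, n_clusters = 3L, n_genes = 300L,
                         n_peaks = 360L, nuclei_per_donor = 150L,
                         chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                         n_deg_per_cluster = 12L, deg_log2fc = 0.5,
                         n_dap_per_cluster = 16L, dap_log2fc = 0.5,
                         max_abs_log2fc = 2, donor_sd = 0.2,
                         hybrid_frac = 0.05, qc_fail_frac = 0.02,
                         prop_shift_cluster = 1L, prop_shift_fold = 2,
                         promoter_peak_frac = 0.3, n_ccan_blocks = 4L,
                         ccan_block_size = 5L, ccan_partial_cor = 0.2,
                         motif_length = 8L, n_motifs = 3L,
                         n_motif_plants = 4L, n_decoy_snps = 5L,
                         seed = 1L) {
  stopifnot(n_donors %% 2 == 0, n_genes > 0, n_peaks > 0,
            length(chrom_lengths) >= 1,
            abs(deg_log2fc) <= max_abs_log2fc,
            abs(dap_log2fc) <= max_abs_log2fc,
            ccan_partial_cor < 1 / (ccan_block_size - 1))
  structure(as.list(environment()), class = "synth_config")
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Generate gene annotation and peak set
#'
#' Genes get a TSS, strand, two exons (defining intron 1) and a derived
#' strand-oriented promoter \[TSS-2000, TSS+200). Peaks are
#' non-overlapping; a configured fraction overlap promoters or first
#' introns, the rest are distal.
#'
#' @param config A [synth_config()].
#' @return List with `genes`, `exons`, `promoters`, `intron1`, `peaks`
#'   (interval data frames).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cl <- config$chrom_lengths
  per_chrom <- round(config$n_genes * cl / sum(cl))
  per_chrom[1] <- config$n_genes - sum(per_chrom[-1])
  with_seed(config$seed, {
    genes <- exons <- intr <- list()
    gi <- 0L
    for (ch in names(cl)) {
      ng <- per_chrom[[ch]]
      slot <- floor(cl[[ch]] / ng)
      if (slot < 12000)
        stop("chromosome ", ch, " too short to host ", ng, " genes")
      for (s in seq_len(ng)) {
        gi <- gi + 1L
        id <- sprintf("gene%03d", gi)
        strand <- sample(c("+", "-"), 1L)
        e1 <- 200L
        i1 <- sample(500:2000, 1L)
        e2 <- 300L
        body <- e1 + i1 + e2
        lo <- (s - 1L) * slot + 3000L
        hi <- s * slot - 3000L - body
        tss <- sample(lo:hi, 1L)
        if (strand == "+") {
          ex <- data.frame(gene_id = id, chrom = ch,
                           start = c(tss, tss + e1 + i1),
                           end = c(tss + e1, tss + e1 + i1 + e2),
                           exon_number = 1:2)
          ii <- data.frame(gene_id = id, chrom = ch, start = tss + e1,
                           end = tss + e1 + i1)
          g <- data.frame(gene_id = id, chrom = ch, strand = strand,
                          tss = tss, start = tss, end = tss + body)
        } else {
          # transcribed right-to-left: TSS at the high end
          tss_m <- tss + body - 1L
          ex <- data.frame(gene_id = id, chrom = ch,
                           start = c(tss_m - e1 + 1L,
                                     tss_m - e1 - i1 - e2 + 1L),
                           end = c(tss_m + 1L, tss_m - e1 - i1 + 1L),
                           exon_number = 1:2)
          ii <- data.frame(gene_id = id, chrom = ch,
                           start = tss_m - e1 - i1 + 1L,
                           end = tss_m - e1 + 1L)
          g <- data.frame(gene_id = id, chrom = ch, strand = strand,
                          tss = tss_m, start = tss, end = tss + body)
        }
        genes[[gi]] <- g; exons[[gi]] <- ex; intr[[gi]] <- ii
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    intron1 <- do.call(rbind, intr)
    pw <- promoter_window(genes$tss, genes$strand)
    promoters <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                            start = pw[, "start"], end = pw[, "end"],
                            stringsAsFactors = FALSE)
    # peaks: a fraction over promoters / first introns, rest distal
    n_pk <- config$n_peaks
    n_prox <- round(config$promoter_peak_frac * n_pk)
    prox_genes <- sample(seq_len(nrow(genes)), n_prox, replace = n_prox >
                           nrow(genes))
    pk <- list()
    for (k in seq_len(n_prox)) {
      g <- prox_genes[k]
      width <- sample(300:600, 1L)
      anchor <- if (k %% 3 == 0 && !is.na(intron1$start[g]))
        (intron1$start[g] + intron1$end[g]) %/% 2L else genes$tss[g]
      pk[[k]] <- data.frame(chrom = genes$chrom[g],
                            start = anchor - width %/% 2L,
                            end = anchor + width %/% 2L)
    }
    # distal peaks placed on a jittered grid to stay non-overlapping
    n_dist <- n_pk - n_prox
    dist_per_chrom <- round(n_dist * cl / sum(cl))
    dist_per_chrom[1] <- n_dist - sum(dist_per_chrom[-1])
    for (ch in names(cl)) {
      nd <- dist_per_chrom[[ch]]
      if (nd <= 0) next
      grid <- floor(cl[[ch]] / nd)
      for (s in seq_len(nd)) {
        width <- sample(300:600, 1L)
        lo <- (s - 1L) * grid + 1000L
        start <- lo + sample.int(max(1L, grid - 2000L - width), 1L)
        pk[[length(pk) + 1L]] <- data.frame(chrom = ch, start = start,
                                            end = start + width)
      }
    }
    peaks <- do.call(rbind, pk)
    peaks <- peaks[order(peaks$chrom, peaks$start), ]
    # enforce non-overlap: shift overlapping peaks right of predecessor
    for (ch in unique(peaks$chrom)) {
      idx <- which(peaks$chrom == ch)
      for (t in idx[-1]) {
        prev <- idx[which(idx == t) - 1L]
        if (peaks$start[t] < peaks$end[prev]) {
          w <- peaks$end[t] - peaks$start[t]
          peaks$start[t] <- peaks$end[prev] + 50L
          peaks$end[t] <- peaks$start[t] + w
        }
      }
    }
    stopifnot(all(peaks$end <= cl[peaks$chrom]))
    peaks <- genomic_intervals(peaks$chrom, peaks$start, peaks$end,
                               name = sprintf("peak%03d",
                                              seq_len(nrow(peaks))))
    list(genes = genes, exons = exons, promoters = promoters,
         intron1 = intron1, peaks = peaks)
  })
}

#' Plan the planted truth over an annotation
#'
#' Chooses, deterministically from the configuration, the co-accessibility
#' blocks (consecutive same-chromosome peak runs within the 500-kb pair
#' limit), and coordinates the planted effects so each block carries a
#' complete cis-regulatory story: one peak overlapping the promoter or
#' first intron of a gene (the anchor), and one noncoding peak (the
#' candidate cCRE); both become DAPs and the anchored gene becomes a DEG,
#' all with the same sign. Motif instances and affinity-changing SNPs are
#' hosted by the cCRE peaks. GWAS tag SNPs are placed within 500 kb of
#' every block except the last, which exercises the tag-window exclusion.
#' Remaining DEG/DAP quota is filled with unlinked features.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @return List with `deg`, `dap` (planted tables), `blocks` (peak-index
#'   list), `block_info` (per-block anchor peak, cCRE peak, gene, sign,
#'   gwas_tagged), `tag_snps`, `motif_hosts`.
#' @export
truth_plan <- function(config, annotation) {
  peaks <- annotation$peaks
  p <- nrow(peaks)
  bs <- config$ccan_block_size
  mids <- (peaks$start + peaks$end) / 2
  anchors <- deg_anchor_peaks(peaks, annotation$genes$gene_id, annotation)
  noncoding <- peaks$name[is_noncoding_peak(peaks, annotation)]
  blocks <- list(); info <- list(); used <- integer(0)
  for (b in seq_len(config$n_ccan_blocks)) {
    placed <- FALSE
    for (s in seq_len(p - bs + 1L)) {
      idx <- s:(s + bs - 1L)
      if (any(idx %in% used)) next
      if (length(unique(peaks$chrom[idx])) > 1L) next
      if (max(mids[idx]) - min(mids[idx]) > 5e5) next
      nm <- peaks$name[idx]
      a <- anchors[anchors$peak %in% nm, , drop = FALSE]
      nc <- intersect(nm, noncoding)
      nc <- setdiff(nc, a$peak)
      if (nrow(a) == 0L || length(nc) == 0L) next
      wide_enough <- (peaks$end - peaks$start)[match(nc, peaks$name)] >
        4L * config$motif_length
      if (!any(wide_enough)) next
      blocks[[b]] <- idx
      info[[b]] <- data.frame(
        block = b, anchor_peak = a$peak[1], gene = a$gene[1],
        ccre_peak = nc[wide_enough][1],
        sign = if (b %% 2L == 0L) -1 else 1,
        gwas_tagged = b < config$n_ccan_blocks,
        stringsAsFactors = FALSE)
      used <- c(used, idx)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place co-accessibility block ", b,
                      " with an anchor and a noncoding cCRE peak")
  }
  info <- do.call(rbind, info)
  # planted DEG/DAP tables: block-linked features in cluster C1, the rest
  # filled per cluster with unlinked features, alternating signs
  clusters <- paste0("C", seq_len(config$n_clusters))
  deg <- data.frame(feature = info$gene, cluster = clusters[1],
                    log2fc = config$deg_log2fc * info$sign,
                    stringsAsFactors = FALSE)
  dap <- data.frame(
    feature = c(info$anchor_peak, info$ccre_peak),
    cluster = clusters[1],
    log2fc = config$dap_log2fc * c(info$sign, info$sign),
    stringsAsFactors = FALSE)
  genes_all <- annotation$genes$gene_id
  free_genes <- setdiff(genes_all, deg$feature)
  free_peaks <- setdiff(peaks$name, dap$feature)
  for (k in seq_along(clusters)) {
    need_g <- config$n_deg_per_cluster - sum(deg$cluster == clusters[k])
    if (need_g > 0) {
      gs <- free_genes[seq_len(need_g)]
      free_genes <- free_genes[-seq_len(need_g)]
      deg <- rbind(deg, data.frame(
        feature = gs, cluster = clusters[k],
        log2fc = config$deg_log2fc * rep_len(c(1, -1), need_g)))
    }
    need_p <- config$n_dap_per_cluster - sum(dap$cluster == clusters[k])
    if (need_p > 0) {
      ps <- free_peaks[seq_len(need_p)]
      free_peaks <- free_peaks[-seq_len(need_p)]
      dap <- rbind(dap, data.frame(
        feature = ps, cluster = clusters[k],
        log2fc = config$dap_log2fc * rep_len(c(1, -1), need_p)))
    }
  }
  tag <- do.call(rbind, lapply(which(info$gwas_tagged), function(b) {
    idx <- blocks[[b]]
    data.frame(snp = sprintf("tag_block%d", b),
               chrom = peaks$chrom[idx[1]],
               pos = as.integer(max(0, peaks$start[idx[1]] - 1e5)),
               stringsAsFactors = FALSE)
  }))
  list(deg = deg, dap = dap, blocks = blocks, block_info = info,
       tag_snps = tag, motif_hosts = info$ccre_peak)
}

#' Generate count matrices, nucleus metadata and an embedding
#'
#' Gene counts are negative binomial with cluster-specific baselines,
#' planted case-control log2 fold changes, and per-donor-per-gene random
#' intercepts; peak fragment counts are Bernoulli-thinned Poisson with
#' planted accessibility shifts. A configured fraction of nuclei violate
#' each QC rule, a configured fraction get hybrid prediction scores, and
#' a 2-d embedding separates the clusters.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()] for the same
#'   config.
#' @param plan Optional [truth_plan()]; computed from the annotation when
#'   omitted.
#' @return List with `rna_counts`, `atac_counts` (feature x nucleus
#'   matrices), `nuclei` (metadata data frame), `scores` (nucleus x
#'   cluster prediction scores), `embedding`, and `truth` (planted DEG /
#'   DAP tables, hybrid barcodes, QC-violation barcodes, donor table).
#' @export
generate_counts <- function(config, annotation, plan = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(annotation$peaks) != config$n_peaks)
    stop("annotation/config mismatch: peak count differs")
  if (is.null(plan)) plan <- truth_plan(config, annotation)
  with_seed(config$seed + 1L, {
    nd <- config$n_donors
    donors <- sprintf("D%02d", seq_len(nd))
    diagnosis <- rep(c("LOAD", "Normal"), each = nd / 2L)
    names(diagnosis) <- donors
    K <- config$n_clusters
    clusters <- paste0("C", seq_len(K))
    genes <- sprintf("gene%03d", seq_len(config$n_genes))
    peaks <- annotation$peaks$name

    deg <- plan$deg
    dap <- plan$dap

    # per-donor cluster proportions with the planted case shift
    base_prop <- rep(1 / K, K)
    shift <- base_prop
    shift[config$prop_shift_cluster] <-
      shift[config$prop_shift_cluster] * config$prop_shift_fold
    shift <- shift / sum(shift)
    donor_tab <- data.frame(
      donor = donors, diagnosis = unname(diagnosis),
      age = round(stats::rnorm(nd, 78, 8), 1),
      sex = rep_len(c("F", "M"), nd),
      pmi = round(stats::runif(nd, 2, 20), 1),
      seq_saturation = round(stats::runif(nd, 0.5, 0.9), 3),
      stringsAsFactors = FALSE)

    n_per <- config$nuclei_per_donor
    nuc <- list()
    for (d in donors) {
      pr <- if (diagnosis[[d]] == "LOAD") shift else base_prop
      cl_draw <- sample(clusters, n_per, replace = TRUE, prob = pr)
      nuc[[d]] <- data.frame(
        barcode = sprintf("%s_N%04d", d, seq_len(n_per)), donor = d,
        diagnosis = diagnosis[[d]], cluster = cl_draw,
        stringsAsFactors = FALSE)
    }
    nuclei <- do.call(rbind, nuc)
    rownames(nuclei) <- NULL
    n_nuc <- nrow(nuclei)

    # gene baselines (log2 scale), cluster wobble, donor x gene intercepts
    base_log2 <- stats::runif(config$n_genes, 0.5, 3.5)
    clust_eff <- matrix(stats::rnorm(config$n_genes * K, 0, 0.3),
                        config$n_genes, K,
                        dimnames = list(genes, clusters))
    donor_eff <- matrix(stats::rnorm(config$n_genes * nd, 0,
                                     config$donor_sd),
                        config$n_genes, nd,
                        dimnames = list(genes, donors))
    deg_eff <- matrix(0, config$n_genes, K,
                      dimnames = list(genes, clusters))
    deg_eff[cbind(deg$feature, deg$cluster)] <- deg$log2fc
    is_load <- nuclei$diagnosis == "LOAD"
    log2mu <- base_log2 + clust_eff[, nuclei$cluster] +
      donor_eff[, nuclei$donor] +
      deg_eff[, nuclei$cluster] * rep(is_load, each = config$n_genes)
    mu <- 2^log2mu - 1
    mu[mu < 0.05] <- 0.05
    rna <- matrix(stats::rnbinom(length(mu), mu = mu, size = 2),
                  config$n_genes, n_nuc,
                  dimnames = list(genes, nuclei$barcode))

    # peak fragments: thinned Poisson with planted accessibility shifts
    base_lam <- stats::runif(config$n_peaks, 0.3, 2)
    dap_eff <- matrix(0, config$n_peaks, K,
                      dimnames = list(peaks, clusters))
    dap_eff[cbind(dap$feature, dap$cluster)] <- dap$log2fc
    donor_eff_a <- matrix(stats::rnorm(config$n_peaks * nd, 0,
                                       config$donor_sd),
                          config$n_peaks, nd,
                          dimnames = list(peaks, donors))
    lam <- base_lam * 2^(dap_eff[, nuclei$cluster] *
                           rep(is_load, each = config$n_peaks) +
                           donor_eff_a[, nuclei$donor])
    open <- matrix(stats::rbinom(length(lam), 1, 0.7),
                   config$n_peaks, n_nuc)
    atac <- matrix(stats::rpois(length(lam), lam), config$n_peaks,
                   n_nuc, dimnames = list(peaks, nuclei$barcode)) * open

    # prediction scores: concentrated on the true cluster except hybrids
    x1 <- stats::runif(n_nuc, 0.75, 0.95)
    scores <- matrix(0, n_nuc, K, dimnames = list(nuclei$barcode,
                                                  clusters))
    for (i in seq_len(n_nuc)) {
      rest <- stats::runif(K - 1L)
      rest <- rest / sum(rest) * (1 - x1[i])
      scores[i, setdiff(clusters, nuclei$cluster[i])] <- rest
      scores[i, nuclei$cluster[i]] <- x1[i]
    }
    n_hyb <- round(config$hybrid_frac * n_nuc)
    hyb_idx <- sample.int(n_nuc, n_hyb)
    for (i in hyb_idx) {
      other <- sample(setdiff(clusters, nuclei$cluster[i]), 1L)
      # second score within 20% of the first -> hybrid by definition
      scores[i, other] <- scores[i, nuclei$cluster[i]] *
        stats::runif(1, 0.85, 0.999)
    }

    # QC metrics: draw passing values, then push a fraction over each line
    qc <- data.frame(
      barcode = nuclei$barcode, donor = nuclei$donor,
      n_features = pmax(201L, stats::rpois(n_nuc, 2500)),
      pct_mito = stats::runif(n_nuc, 0, 0.15),
      nucleosome_signal = stats::runif(n_nuc, 0.2, 3.5),
      tss_enrichment = stats::runif(n_nuc, 2.5, 8),
      pct_reads_in_peaks = stats::runif(n_nuc, 0.2, 0.7),
      peak_region_fragments = as.integer(
        stats::runif(n_nuc, 1100, 20000)),
      blacklist_ratio = stats::runif(n_nuc, 0, 0.04),
      stringsAsFactors = FALSE)
    fail <- list()
    push <- function(col, bad_values) {
      idx <- sample.int(n_nuc, round(config$qc_fail_frac * n_nuc))
      qc[[col]][idx] <<- bad_values(length(idx))
      fail[[col]] <<- nuclei$barcode[idx]
    }
    push("n_features", function(n) sample(c(50L, 15000L), n, TRUE))
    push("pct_mito", function(n) stats::runif(n, 0.2, 0.6))
    push("nucleosome_signal", function(n) stats::runif(n, 4.5, 8))
    push("tss_enrichment", function(n) stats::runif(n, 0.2, 1.8))
    push("pct_reads_in_peaks", function(n) stats::runif(n, 0.01, 0.12))
    push("peak_region_fragments", function(n)
      sample(100:900, n, TRUE))
    push("blacklist_ratio", function(n) stats::runif(n, 0.06, 0.2))

    # embedding: cluster centroids on a circle + isotropic noise
    centroids <- cbind(6 * cos(2 * pi * seq_len(K) / K),
                       6 * sin(2 * pi * seq_len(K) / K))
    emb <- centroids[match(nuclei$cluster, clusters), , drop = FALSE] +
      matrix(stats::rnorm(2 * n_nuc, 0, 0.7), n_nuc, 2)
    rownames(emb) <- nuclei$barcode

    list(rna_counts = rna, atac_counts = atac, nuclei = nuclei,
         scores = scores, qc = qc, embedding = emb,
         truth = list(deg = deg, dap = dap,
                      hybrid_barcodes = sort(nuclei$barcode[hyb_idx]),
                      qc_violations = fail, donors = donor_tab,
                      prop_shift = list(
                        cluster = clusters[config$prop_shift_cluster],
                        fold = config$prop_shift_fold)))
  })
}

#' Generate aggregated-cell peak accessibility with block precision
#'
#' Samples from a multivariate normal whose precision matrix has nonzero
#' off-diagonal entries exactly on the planted within-block peak pairs
#' (target partial correlation on those pairs), and records the true
#' precision matrix.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @param n_samples Number of aggregated samples (default 200).
#' @param plan Optional [truth_plan()] providing the blocks; computed
#'   when omitted.
#' @return List with `matrix` (samples x peaks), `precision` (true
#'   precision), `blocks` (list of member peak names), `peaks` (intervals
#'   used).
#' @export
generate_coaccessible_counts <- function(config, annotation,
                                         n_samples = 200L, plan = NULL) {
  stopifnot(inherits(config, "synth_config"))
  peaks <- annotation$peaks
  p <- nrow(peaks)
  mids <- (peaks$start + peaks$end) / 2
  if (is.null(plan)) plan <- truth_plan(config, annotation)
  blocks <- plan$blocks
  for (idx in blocks)
    if (max(mids[idx]) - min(mids[idx]) > 5e5)
      stop("block spans more than the maximum pair distance")
  Theta <- diag(p)
  for (idx in blocks) {
    for (a in idx) for (b2 in idx) if (a != b2)
      Theta[a, b2] <- -config$ccan_partial_cor
  }
  stopifnot(min(eigen(Theta, symmetric = TRUE,
                      only.values = TRUE)$values) > 0)
  Sigma <- solve(Theta)
  X <- with_seed(config$seed + 2L,
                 MASS::mvrnorm(n_samples, mu = rep(0, p), Sigma = Sigma))
  colnames(X) <- peaks$name
  list(matrix = X, precision = Theta,
       blocks = lapply(blocks, function(i) peaks$name[i]),
       peaks = peaks)
}

#' Generate peak sequences, PFMs, SNPs and GWAS tag SNPs
#'
#' Peak sequences are drawn from the first-order Markov background;
#' motif consensus instances are planted at recorded offsets and verified
#' against each PWM's exact 5e-5 threshold; "gain" SNPs raise and "loss"
#' SNPs lower the best-window score; low-frequency decoy SNPs and GWAS
#' tag SNPs (placing a configured subset of peaks in-window) complete the
#' set.
#'
#' @param config A [synth_config()].
#' @param annotation Output of [generate_annotation()].
#' @param plan Optional [truth_plan()]; planted motifs and
#'   affinity-changing SNPs are hosted by the plan's candidate cCRE
#'   peaks first, then by other wide-enough peaks.
#' @param background A [markov_background()] (default uniform).
#' @return List with `sequences` (named character vector with
#'   `peak_start` attribute), `pfms`, `pwms`, `snps` (data frame),
#'   `tag_snps`, `motif_plants`, `truth` (planted SNP effects and
#'   in-window flags).
#' @export
generate_sequences_snps_motifs <- function(config, annotation,
                                           plan = NULL,
                                           background =
                                             markov_background()) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(plan)) plan <- truth_plan(config, annotation)
  peaks <- annotation$peaks
  with_seed(config$seed + 3L, {
    widths <- peaks$end - peaks$start
    seqs <- vapply(widths, function(w) {
      v <- integer(w)
      v[1] <- sample.int(4L, 1L, prob = background$initial)
      for (i in seq_len(w - 1L))
        v[i + 1L] <- sample.int(4L, 1L,
                                prob = background$transition[v[i], ])
      codes_to_seq(v)
    }, character(1))
    names(seqs) <- peaks$name
    attr(seqs, "peak_start") <- stats::setNames(peaks$start, peaks$name)

    # informative PFMs: 85% consensus-base columns
    pfms <- list()
    for (m in seq_len(config$n_motifs)) {
      cons <- sample.int(4L, config$motif_length, replace = TRUE)
      mat <- matrix(5, 4, config$motif_length)
      mat[cbind(cons, seq_len(config$motif_length))] <- 85
      rownames(mat) <- BASES
      pfms[[sprintf("MOTIF%d", m)]] <- mat
    }
    pwms <- lapply(names(pfms), function(id)
      build_pwm(pfms[[id]], background = background, tf = id))
    names(pwms) <- names(pfms)
    thresholds <- lapply(pwms, exact_threshold)

    # plant consensus instances in the planned cCRE peaks first, then in
    # other wide-enough peaks (decoy hosts)
    host_pool <- c(plan$motif_hosts,
                   setdiff(peaks$name, plan$motif_hosts))
    host_pool <- host_pool[widths[match(host_pool, peaks$name)] >
                             4L * config$motif_length]
    plants <- list()
    snp_rows <- list()
    truth_snps <- list()
    si <- 0L
    for (id in names(pwms)) {
      pw <- pwms[[id]]
      cons <- apply(pw$prob, 2, which.max)
      hosts <- host_pool[(match(id, names(pwms)) - 1L) *
                           config$n_motif_plants +
                           seq_len(config$n_motif_plants)]
      hosts <- hosts[!is.na(hosts)]
      for (h in hosts) {
        w <- widths[match(h, peaks$name)]
        off <- sample.int(w - 3L * pw$L, 1L) + pw$L  # keep 2L-1 context
        v <- seq_to_codes(seqs[[h]])
        v[off:(off + pw$L - 1L)] <- cons
        sc <- sum(pw$mat[cbind(cons, seq_len(pw$L))])
        if (sc < thresholds[[id]]$threshold)
          stop("planted instance for ", id, " fails its own threshold")
        seqs[h] <- codes_to_seq(v)
        plants[[length(plants) + 1L]] <- data.frame(
          pwm = id, peak = h, offset = off - 1L, strand = "+",
          score = sc, stringsAsFactors = FALSE)
        # one affinity-changing SNP per planted instance, at the
        # most-informative column: ref = consensus (loss) or alternate
        # base (gain)
        si <- si + 1L
        col <- which.max(apply(pw$mat, 2, max) - apply(pw$mat, 2, min))
        worst <- which.min(pw$mat[, col])
        eff <- if (si %% 2L == 0L) "gain" else "loss"
        if (eff == "loss") { ref <- cons[col]; alt <- worst }
        else { ref <- worst; alt <- cons[col]
               v[off + col - 1L] <- ref; seqs[h] <- codes_to_seq(v) }
        pos0 <- peaks$start[match(h, peaks$name)] + off - 1L + col - 1L
        maf <- stats::runif(1, 0.05, 0.4)
        snp_rows[[si]] <- data.frame(
          snp = sprintf("rs%04d", si),
          chrom = peaks$chrom[match(h, peaks$name)], pos = pos0,
          ref = BASES[ref], alt = BASES[alt], maf = maf,
          stringsAsFactors = FALSE)
        delta <- pw$mat[ref, col] - pw$mat[alt, col]
        truth_snps[[si]] <- data.frame(
          snp = sprintf("rs%04d", si), pwm = id, peak = h,
          effect = eff, score_ref_minus_alt = delta,
          filter_excluded = FALSE, stringsAsFactors = FALSE)
      }
    }
    # decoy SNPs with MAF < 1% (filter-excluded by the >= 1% rule)
    for (k in seq_len(config$n_decoy_snps)) {
      si <- si + 1L
      pk <- sample(peaks$name, 1L)
      w <- widths[match(pk, peaks$name)]
      off <- sample.int(w, 1L)
      v <- seq_to_codes(seqs[[pk]])
      ref <- v[off]
      alt <- sample(setdiff(1:4, ref), 1L)
      snp_rows[[si]] <- data.frame(
        snp = sprintf("rs%04d", si),
        chrom = peaks$chrom[match(pk, peaks$name)],
        pos = peaks$start[match(pk, peaks$name)] + off - 1L,
        ref = BASES[ref], alt = BASES[alt],
        maf = stats::runif(1, 0.001, 0.009), stringsAsFactors = FALSE)
      truth_snps[[si]] <- data.frame(
        snp = sprintf("rs%04d", si), pwm = NA_character_, peak = pk,
        effect = "decoy", score_ref_minus_alt = NA_real_,
        filter_excluded = TRUE, stringsAsFactors = FALSE)
    }
    snps <- do.call(rbind, snp_rows)
    motif_plants <- do.call(rbind, plants)

    # GWAS tag SNPs from the plan: near every block but the last, so a
    # known subset of peaks falls in the +/- 500 kb window
    tag <- plan$tag_snps
    in_window <- gwas_window_overlap(peaks, tag)
    list(sequences = seqs, pfms = pfms, pwms = pwms, snps = snps,
         tag_snps = tag, motif_plants = motif_plants,
         truth = list(snps = do.call(rbind, truth_snps),
                      peaks_in_gwas_window =
                        stats::setNames(in_window, peaks$name)))
  })
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper running [generate_annotation()],
#' [generate_counts()], [generate_coaccessible_counts()] and
#' [generate_sequences_snps_motifs()] with a shared configuration, and
#' assembling the combined truth ledger.
#'
#' @param config A [synth_config()].
#' @param n_agg_samples Samples for the co-accessibility matrix.
#' @return List with all component outputs plus `truth`.
#' @export
generate_dataset <- function(config = synth_config(),
                             n_agg_samples = 200L) {
  ann <- generate_annotation(config)
  plan <- truth_plan(config, ann)
  cnt <- generate_counts(config, ann, plan = plan)
  coa <- generate_coaccessible_counts(config, ann,
                                      n_samples = n_agg_samples,
                                      plan = plan)
  sq <- generate_sequences_snps_motifs(config, ann, plan = plan)
  truth <- c(cnt$truth, sq$truth,
             list(ccan_blocks = coa$blocks,
                  block_info = plan$block_info,
                  precision = coa$precision))
  list(config = config, annotation = ann, plan = plan, counts = cnt,
       coaccess = coa, sequences = sq, truth = truth)
}
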