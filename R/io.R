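# Plain-text emitters and readers for the standard formats the workflow
# exchanges: MTX + TSV matrices, GTF, BED, FASTA, VCF, JASPAR PFM text,
# GMT, JSON truth ledger.

#' Write a count matrix as MatrixMarket + row/column TSVs
#'
#' @param mat Feature x sample matrix.
#' @param prefix Path prefix; writes `<prefix>.mtx`,
#'   `<prefix>.features.tsv`, `<prefix>.barcodes.tsv`.
#' @export
write_mtx <- function(mat, prefix) {
  sp <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, paste0(prefix, ".mtx"))
  writeLines(rownames(mat), paste0(prefix, ".features.tsv"))
  writeLines(colnames(mat), paste0(prefix, ".barcodes.tsv"))
  invisible(prefix)
}

#' Read a MatrixMarket matrix with row/column TSVs
#' @param prefix Path prefix used by [write_mtx()].
#' @return A sparse `Matrix` with dimnames.
#' @export
read_mtx <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  dimnames(m) <- list(readLines(paste0(prefix, ".features.tsv")),
                      readLines(paste0(prefix, ".barcodes.tsv")))
  m
}

#' Write gene annotation as GTF
#'
#' Emits gene and exon records (1-based inclusive coordinates, as the
#' format requires).
#'
#' @param annotation Output of [generate_annotation()].
#' @param path Output file.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  lines <- c(
    sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
    sprintf(paste0("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; exon_number \"%d\";"),
            e$chrom, e$start + 1L, e$end,
            g$strand[match(e$gene_id, g$gene_id)], e$gene_id,
            e$exon_number))
  writeLines(lines, path)
}

#' Read the synthetic GTF back into an annotation list
#'
#' Reconstructs genes, exons, first introns and promoters from the gene
#' and exon records.
#'
#' @param path GTF file written by [write_gtf()].
#' @return Annotation list (`genes`, `exons`, `promoters`, `intron1`).
#' @export
read_gtf_annotation <- function(path) {
  raw <- utils::read.table(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  names(raw) <- c("chrom", "source", "feature", "start", "end", "score",
                  "strand", "frame", "attr")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", raw$attr)
  g <- raw[raw$feature == "gene", ]
  genes <- data.frame(gene_id = gid[raw$feature == "gene"],
                      chrom = g$chrom, strand = g$strand,
                      start = g$start - 1L, end = g$end,
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  ex <- raw[raw$feature == "exon", ]
  exons <- data.frame(gene_id = gid[raw$feature == "exon"],
                      chrom = ex$chrom, start = ex$start - 1L,
                      end = ex$end,
                      exon_number = as.integer(
                        sub('.*exon_number "([0-9]+)".*', "\\1",
                            ex$attr)),
                      stringsAsFactors = FALSE)
  intron1 <- do.call(rbind, lapply(split(exons, exons$gene_id),
                                   function(e2) {
    if (nrow(e2) < 2L) return(NULL)
    e2 <- e2[order(e2$exon_number)[1:2], ]
    left <- which.min(e2$start); right <- 3L - left
    # intron 1 = genomic gap between exon 1 and exon 2
    data.frame(gene_id = e2$gene_id[1], chrom = e2$chrom[1],
               start = e2$end[left], end = e2$start[right],
               stringsAsFactors = FALSE)
  }))
  rownames(intron1) <- NULL
  pw <- promoter_window(genes$tss, genes$strand)
  promoters <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                          start = pw[, "start"], end = pw[, "end"],
                          stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, promoters = promoters,
       intron1 = intron1)
}

#' Write intervals as BED (0-based half-open, matching the format)
#'
#' @param iv Interval data frame ([genomic_intervals()]); an optional
#'   `score` column becomes column 5.
#' @param path Output file.
#' @export
write_bed <- function(iv, path) {
  score <- if ("score" %in% names(iv)) iv$score else 0
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", iv$chrom, iv$start,
                     iv$end, iv$name, format(score, trim = TRUE),
                     if ("strand" %in% names(iv)) iv$strand else "."),
             path)
}

#' Read a BED file into an interval data frame
#' @param path BED file.
#' @return Interval data frame.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  genomic_intervals(raw[[1]], raw[[2]], raw[[3]],
                    name = if (ncol(raw) >= 4) raw[[4]] else NULL,
                    strand = if (ncol(raw) >= 6) raw[[6]] else NULL)
}

#' Write peak sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(sequences)), path)
}

#' Write SNPs as a minimal VCFv4.2 file
#'
#' Positions convert from the internal 0-based convention to the format's
#' 1-based POS; allele frequency goes to the INFO AF field.
#'
#' @param snps Data frame `snp`, `chrom`, `pos`, `ref`, `alt`, `maf`.
#' @param path Output file.
#' @export
write_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%s", snps$chrom,
                  snps$pos + 1L, snps$snp, snps$ref, snps$alt,
                  format(snps$maf, trim = TRUE, digits = 6))
  writeLines(c(hdr, body), path)
}

#' Read a gene-set GMT file
#' @param path GMT file (term, description, genes... per tab-separated
#'   line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[`, "", 1L))
}

#' Write the full synthetic dataset to a directory
#'
#' Emits MTX + TSV count matrices, nucleus metadata and prediction
#' scores, QC table, embedding, GTF annotation, peak BED, FASTA
#' sequences, VCF SNPs, JASPAR PFM text, GWAS tag TSV, and the truth
#' ledger as JSON. Output bytes are a deterministic function of the
#' dataset.
#'
#' @param sim Output of [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_mtx(sim$counts$rna_counts, fp("rna"))
  write_mtx(sim$counts$atac_counts, fp("atac"))
  wt <- function(d, f) utils::write.table(
    d, fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$counts$nuclei, "nuclei.tsv")
  wt(sim$counts$qc, "qc.tsv")
  wt(data.frame(barcode = rownames(sim$counts$scores),
                sim$counts$scores, check.names = FALSE), "scores.tsv")
  wt(data.frame(barcode = rownames(sim$counts$embedding),
                dim1 = sim$counts$embedding[, 1],
                dim2 = sim$counts$embedding[, 2]), "embedding.tsv")
  wt(sim$sequences$tag_snps, "gwas_tags.tsv")
  wt(sim$counts$truth$donors, "donors.tsv")
  write_gtf(sim$annotation, fp("genes.gtf"))
  write_bed(sim$annotation$peaks, fp("peaks.bed"))
  write_fasta(sim$sequences$sequences, fp("peaks.fa"))
  write_vcf(sim$sequences$snps, fp("snps.vcf"))
  write_jaspar_pfm(sim$sequences$pfms, fp("motifs.pfm"))
  truth <- sim$truth
  truth$precision <- NULL  # dense matrix; keep the ledger light
  jsonlite::write_json(truth, fp("truth.json"), digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
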