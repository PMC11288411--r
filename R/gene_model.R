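#' Gene models
#'
#' A gene model is a `data.frame` with one row per gene and columns
#' `gene_id`, `chrom`, `strand` ("+" or "-"), `start`, `end` (0-based
#' half-open gene body) and list-columns `exon_starts` / `exon_ends`
#' (parallel integer vectors, 0-based half-open).  The transcription start
#' site (TSS) is `start` for "+" genes and `end` for "-" genes; all
#' distance computations in the package are anchored on it.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome name per gene.
#' @param strand "+" or "-" per gene.
#' @param start,end 0-based half-open gene body coordinates.
#' @param exon_starts,exon_ends lists of integer vectors, one per gene.
#' @return a `gene_model` data.frame with a `tss` column.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       exon_starts = NULL, exon_ends = NULL) {
  stopifnot(!anyDuplicated(gene_id), all(strand %in% c("+", "-")),
            all(end > start))
  n <- length(gene_id)
  if (is.null(exon_starts)) exon_starts <- as.list(start)
  if (is.null(exon_ends)) exon_ends <- as.list(end)
  stopifnot(length(exon_starts) == n, length(exon_ends) == n)
  gm <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  gm$exon_starts <- lapply(exon_starts, as.numeric)
  gm$exon_ends <- lapply(exon_ends, as.numeric)
  gm$tss <- ifelse(gm$strand == "+", gm$start, gm$end)
  class(gm) <- c("gene_model", "data.frame")
  gm
}

#' Total exon length of each gene in a gene model
#' @param genes a `gene_model`.
#' @return numeric vector of summed exon widths (bp), named by gene_id.
#' @export
exon_length <- function(genes) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    sum(genes$exon_ends[[i]] - genes$exon_starts[[i]])
  }, numeric(1))
  names(out) <- genes$gene_id
  out
}

#' Read a gene model from a 6-column TSV
#'
#' Columns: gene_id, chrom, strand, tss, exon_starts, exon_ends where the
#' exon columns are comma-separated 0-based half-open coordinates.  The gene
#' body is taken as the exon span.
#'
#' @param path TSV file path.
#' @return a `gene_model`.
#' @export
read_gene_model_tsv <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  es <- lapply(strsplit(as.character(tb$exon_starts), ","), as.numeric)
  ee <- lapply(strsplit(as.character(tb$exon_ends), ","), as.numeric)
  body_start <- vapply(es, min, numeric(1))
  body_end <- vapply(ee, max, numeric(1))
  gene_model(tb$gene_id, tb$chrom, tb$strand, body_start, body_end, es, ee)
}

#' Write a gene model to the 6-column TSV format
#' @param genes a `gene_model`.
#' @param path output path.
#' @export
write_gene_model_tsv <- function(genes, path) {
  tb <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss,
    exon_starts = vapply(genes$exon_starts, paste, "", collapse = ","),
    exon_ends = vapply(genes$exon_ends, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene and exon features from a GTF file
#'
#' Uses `gene` rows for gene bodies and `exon` rows (grouped by gene_id) for
#' exons; GTF coordinates (1-based closed) are converted to 0-based
#' half-open.
#'
#' @param path GTF file path.
#' @return a `gene_model`.
#' @export
read_gene_model_gtf <- function(path) {
  gr <- rtracklayer_import_gtf(path)
  is_gene <- gr$type == "gene"
  ids <- gr$gene_id[is_gene]
  ex <- gr[gr$type == "exon"]
  es <- split(GenomicRanges::start(ex) - 1, ex$gene_id)[ids]
  ee <- split(GenomicRanges::end(ex), ex$gene_id)[ids]
  no_ex <- vapply(es, is.null, logical(1))
  es[no_ex] <- as.list(GenomicRanges::start(gr[is_gene][no_ex]) - 1)
  ee[no_ex] <- as.list(GenomicRanges::end(gr[is_gene][no_ex]))
  gene_model(ids,
             as.character(GenomicRanges::seqnames(gr[is_gene])),
             as.character(GenomicRanges::strand(gr[is_gene])),
             GenomicRanges::start(gr[is_gene]) - 1,
             GenomicRanges::end(gr[is_gene]),
             es, ee)
}

# thin seam so tests can exercise the GTF path without network
rtracklayer_import_gtf <- function(path) {
  requireNamespace("rtracklayer", quietly = TRUE) ||
    stop("rtracklayer required to read GTF")
  rtracklayer::import(path, format = "gtf")
}
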