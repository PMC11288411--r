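#' Regulatory-potential (RP) model
#'
#' The RP of a TR cistrome on a gene g sums exponentially decayed
#' contributions of nearby binding sites,
#' \deqn{S_g = \sum_{i=1}^{n} 2^{-d_i / d_0},}
#' where d_i is the distance from the i-th peak centre to the TSS of g and
#' d_0 the half-decay distance.  d_0 is 1 kb for promoter-centric TRs (>20%
#' of peak centres in promoter regions) and 10 kb for enhancer-centric TRs.
#' Peaks beyond 15 d_0 are skipped: their contribution is below
#' 2^-15 < 0.0005.
#'
#' @name rp_model
NULL

#' Classify a cistrome as promoter- or enhancer-centric
#'
#' @param cis a [cistrome].
#' @param genes a [gene_model].
#' @param promoter_window half-width of the promoter window around each TSS
#'   (bp); default 2000.
#' @return list(centricity = "promoter"|"enhancer", d0 = 1000|10000,
#'   promoter_fraction).
#' @export
classify_centricity <- function(cis, genes, promoter_window = 2000) {
  if (nrow(cis$intervals) == 0) stop("empty cistrome")
  centers <- peak_centers(cis)
  in_prom <- vapply(seq_along(centers), function(i) {
    same <- genes$chrom == cis$intervals$chrom[i]
    any(abs(genes$tss[same] - centers[i]) <= promoter_window)
  }, logical(1))
  frac <- mean(in_prom)
  if (frac > 0.20) list(centricity = "promoter", d0 = 1000,
                        promoter_fraction = frac)
  else list(centricity = "enhancer", d0 = 10000, promoter_fraction = frac)
}

#' Basic RP of one cistrome on one gene
#'
#' @param cis a [cistrome].
#' @param gene one-row [gene_model] (or a row index into `genes`).
#' @param d0 half-decay distance (bp).
#' @param range_factor peaks farther than `range_factor * d0` from the TSS
#'   contribute 0; default 15.
#' @return non-negative scalar RP.
#' @export
compute_rp <- function(cis, gene, d0, range_factor = 15) {
  stopifnot(d0 > 0)
  centers <- peak_centers(cis)
  on_chrom <- cis$intervals$chrom == gene$chrom
  d <- abs(centers[on_chrom] - gene$tss)
  d <- d[d <= range_factor * d0]
  sum(2^(-d / d0))
}

#' Enhanced RP with exon and neighbour-gene rules
#'
#' As [compute_rp], but a peak whose centre lies inside an exon of the gene
#' contributes 1 normalized by the gene's total exon length (bp), and a peak
#' inside the promoter window or an exon of any neighbouring gene
#' contributes 0.  All remaining peaks contribute the decay term.
#'
#' @inheritParams compute_rp
#' @param neighbors a [gene_model] of other genes (the gene itself is
#'   ignored if present).
#' @param promoter_window promoter half-width for the neighbour rule (bp).
#' @return non-negative scalar RP.
#' @export
compute_rp_enhanced <- function(cis, gene, neighbors, d0,
                                range_factor = 15, promoter_window = 2000) {
  stopifnot(d0 > 0)
  exlen <- sum(gene$exon_ends[[1]] - gene$exon_starts[[1]])
  if (exlen <= 0) stop("zero total exon length")
  neighbors <- neighbors[neighbors$gene_id != gene$gene_id, , drop = FALSE]
  centers <- peak_centers(cis)
  keep <- cis$intervals$chrom == gene$chrom &
    abs(centers - gene$tss) <= range_factor * d0
  centers <- centers[keep]
  if (!length(centers)) return(0)

  in_own_exon <- vapply(centers, function(ctr) {
    any(ctr >= gene$exon_starts[[1]] & ctr < gene$exon_ends[[1]])
  }, logical(1))
  nb <- neighbors[neighbors$chrom == gene$chrom, , drop = FALSE]
  in_neighbor <- vapply(centers, function(ctr) {
    if (nrow(nb) == 0) return(FALSE)
    prom <- any(abs(nb$tss - ctr) <= promoter_window)
    exo <- any(vapply(seq_len(nrow(nb)), function(j) {
      any(ctr >= nb$exon_starts[[j]] & ctr < nb$exon_ends[[j]])
    }, logical(1)))
    prom || exo
  }, logical(1))

  contrib <- 2^(-abs(centers - gene$tss) / d0)
  contrib[in_own_exon] <- 1 / exlen
  contrib[in_neighbor & !in_own_exon] <- 0
  sum(contrib)
}

#' RP matrix of a cistrome collection over a gene model
#'
#' Classifies each cistrome's centricity (fixing its d_0) and computes its
#' RP on every gene, by the enhanced model by default.
#'
#' @param cistromes list of [cistrome] objects (or a `tr_reference`).
#' @param genes a [gene_model].
#' @param enhanced use the exon/neighbour-aware model (default TRUE).
#' @param promoter_window promoter half-width (bp).
#' @return matrix dataset x gene with attributes `d0` and `centricity`
#'   (named vectors per dataset).
#' @export
rp_matrix <- function(cistromes, genes, enhanced = TRUE,
                      promoter_window = 2000) {
  if (inherits(cistromes, "tr_reference")) cistromes <- cistromes$cistromes
  ids <- vapply(cistromes, `[[`, "", "dataset_id")
  cents <- lapply(cistromes, classify_centricity, genes = genes,
                  promoter_window = promoter_window)
  d0 <- vapply(cents, `[[`, numeric(1), "d0")
  vals <- t(vapply(seq_along(cistromes), function(k) {
    cis <- cistromes[[k]]
    vapply(seq_len(nrow(genes)), function(g) {
      gene <- genes[g, , drop = FALSE]
      if (enhanced)
        compute_rp_enhanced(cis, gene, genes, d0[k],
                            promoter_window = promoter_window)
      else compute_rp(cis, gene, d0[k])
    }, numeric(1))
  }, numeric(nrow(genes))))
  dimnames(vals) <- list(ids, genes$gene_id)
  attr(vals, "d0") <- stats::setNames(d0, ids)
  attr(vals, "centricity") <-
    stats::setNames(vapply(cents, `[[`, "", "centricity"), ids)
  vals
}

#' Select TR target genes from an RP row
#'
#' Genes with RP above `threshold` are targets; if fewer than `fallback_n`
#' qualify, the top `fallback_n` genes by RP are used instead.  Output is
#' sorted by descending RP, ties broken by gene id.
#'
#' @param rp_row named numeric vector (gene -> RP).
#' @param threshold RP cut-off (strict >); default 5.
#' @param fallback_n fallback target count; default 300.
#' @return list(genes, rp) parallel vectors, descending RP.
#' @export
select_targets <- function(rp_row, threshold = 5, fallback_n = 300) {
  stopifnot(length(rp_row) > 0, !is.null(names(rp_row)))
  ord <- order(-rp_row, names(rp_row))
  rp_sorted <- rp_row[ord]
  n_above <- sum(rp_row > threshold)
  if (n_above >= fallback_n) {
    keep <- rp_sorted > threshold
  } else {
    if (length(rp_row) < fallback_n)
      warning("fewer genes than fallback_n; returning all")
    keep <- seq_along(rp_sorted) <= min(fallback_n, length(rp_sorted))
  }
  list(genes = names(rp_sorted)[keep],
       rp = unname(rp_sorted[keep]))
}
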