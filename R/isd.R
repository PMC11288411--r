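#' Chromatin landscapes and in-silico deletion (ISD)
#'
#' A chromatin profile is a genome-wide signal on a fixed 1-kb bin grid
#' (DNase, H3K27ac, or aggregated ATAC per SuperCell).  The chrom-RP of a
#' gene sums decay-weighted signal within +/-L of its TSS,
#' \deqn{RP_k = \sum_{|i - t_k| \le L} w_i s_{ji},\quad
#'       w_i = 2^{-|i - t_k|/10\,000},\ L = 100\,000,}
#' evaluated at bin centres.  ISD zeroes the signal in every 1-kb bin
#' overlapping at least one peak of a TR cistrome and records the per-gene
#' drop (deltaRP).  Per TR, one-sided Wilcoxon rank-sum tests compare
#' query-gene vs background-gene statistics across evidence channels
#' (peak-RP plus deltaRP per selected landscape sample), and channel
#' P-values are combined by the Cauchy combination test.
#'
#' @name isd_engine
NULL

#' Construct a binned chromatin profile
#'
#' @param sample_id profile identifier.
#' @param assay one of "dnase", "h3k27ac", "atac_supercell".
#' @param signal named list: chromosome -> numeric per-bin signal (bin i
#'   covers [ (i-1)*bin_size, i*bin_size )).
#' @param bin_size bin width in bp; default 1000.
#' @return a `chromatin_profile`.
#' @export
chromatin_profile <- function(sample_id, assay, signal, bin_size = 1000) {
  assay <- match.arg(assay, c("dnase", "h3k27ac", "atac_supercell"))
  stopifnot(is.list(signal), all(vapply(signal, function(s) all(s >= 0),
                                        logical(1))))
  structure(list(sample_id = sample_id, assay = assay, signal = signal,
                 bin_size = bin_size),
            class = "chromatin_profile")
}

#' Read a 4-column bedGraph onto the 1-kb bin grid
#'
#' Interval values are projected as coverage-weighted means per bin.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @inheritParams chromatin_profile
#' @return a `chromatin_profile`.
#' @export
read_bedgraph_profile <- function(path, chrom_lengths, sample_id,
                                  assay = "dnase", bin_size = 1000) {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  signal <- lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    v <- numeric(nb)
    sub <- tb[tb$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      b0 <- floor(sub$start[i] / bin_size) + 1
      b1 <- min(nb, ceiling(sub$end[i] / bin_size))
      for (b in b0:b1) {
        ov <- min(sub$end[i], b * bin_size) - max(sub$start[i],
                                                  (b - 1) * bin_size)
        v[b] <- v[b] + sub$value[i] * ov / bin_size
      }
    }
    v
  })
  names(signal) <- names(chrom_lengths)
  chromatin_profile(sample_id, assay, signal, bin_size)
}

#' Write a chromatin profile as bedGraph
#' @param profile a `chromatin_profile`.
#' @param path output path.
#' @export
write_bedgraph_profile <- function(profile, path) {
  rows <- lapply(names(profile$signal), function(ch) {
    v <- profile$signal[[ch]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.frame(chrom = ch, start = (nz - 1) * profile$bin_size,
               end = nz * profile$bin_size, value = v[nz])
  })
  tb <- do.call(rbind, rows)
  if (is.null(tb)) tb <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric(), value = numeric())
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Chromatin regulatory potential of one gene
#'
#' @param profile a `chromatin_profile`.
#' @param gene one-row [gene_model].
#' @param L half-window around the TSS (bp); default 1e5.
#' @param decay half-decay distance of the bin weight (bp); default 1e4.
#' @return non-negative scalar chrom-RP.
#' @export
chrom_rp <- function(profile, gene, L = 1e5, decay = 1e4) {
  v <- profile$signal[[gene$chrom]]
  if (is.null(v)) return(0)
  centers <- (seq_along(v) - 0.5) * profile$bin_size
  d <- abs(centers - gene$tss)
  sel <- d <= L
  sum(v[sel] * 2^(-d[sel] / decay))
}

#' Chrom-RP matrix over a gene model
#' @param profiles list of `chromatin_profile`s.
#' @param genes a [gene_model].
#' @inheritParams chrom_rp
#' @return gene x sample matrix.
#' @export
chrom_rp_matrix <- function(profiles, genes, L = 1e5, decay = 1e4) {
  m <- vapply(profiles, function(p) {
    vapply(seq_len(nrow(genes)), function(g)
      chrom_rp(p, genes[g, , drop = FALSE], L, decay), numeric(1))
  }, numeric(nrow(genes)))
  m <- matrix(m, nrow = nrow(genes))
  dimnames(m) <- list(genes$gene_id,
                      vapply(profiles, `[[`, "", "sample_id"))
  m
}

#' Select an optimal landscape sample set by L1-logistic regression
#'
#' Standardized per-sample chrom-RP columns are the features; query genes
#' are labelled 1, background genes 0.  The lasso path is descended until
#' `k_samples` coefficients are nonzero (taking the largest-magnitude
#' coefficients if the path jumps past k); if the path is exhausted, all
#' samples with nonzero coefficients are returned.
#'
#' @param chromrp gene x sample chrom-RP matrix.
#' @param query_genes,background_genes disjoint gene-id sets present in
#'   `chromrp` rows.
#' @param k_samples target number of samples; default 10.
#' @param seed RNG seed (glmnet internal folds are unused, kept for
#'   contract determinism).
#' @return character vector of selected sample ids (sorted).
#' @export
select_landscape <- function(chromrp, query_genes, background_genes,
                             k_samples = 10, seed = 0) {
  stopifnot(!length(intersect(query_genes, background_genes)))
  if (ncol(chromrp) < 2 || ncol(chromrp) <= k_samples) {
    if (ncol(chromrp) < 2) warning("fewer than 2 samples; returning all")
    return(sort(colnames(chromrp)))
  }
  genes <- c(query_genes, background_genes)
  x <- chromrp[genes, , drop = FALSE]
  x <- scale(x)
  x[!is.finite(x)] <- 0
  y <- c(rep(1, length(query_genes)), rep(0, length(background_genes)))
  set.seed(seed)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        nlambda = 100, standardize = FALSE)
  nz <- fit$df
  i <- which(nz >= k_samples)[1]
  if (is.na(i)) i <- length(nz)  # path exhausted: take the densest fit
  beta <- abs(fit$beta[, i])
  sel <- names(sort(beta, decreasing = TRUE))[seq_len(min(k_samples,
                                                          sum(beta > 0)))]
  sort(sel)
}

#' Aggregate per-cell fragments into per-SuperCell chromatin profiles
#'
#' Fragments of each SuperCell's member cells are sorted and merged;
#' merged intervals are split so that none exceeds `merge_limit` bp, then
#' binned (bp coverage / bin size) onto the 1-kb grid.
#'
#' @param fragments data.frame(chrom, start, end, barcode).
#' @param partition a `supercell_partition`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param merge_limit maximum merged-interval length; default 1000.
#' @param bin_size bin width; default 1000.
#' @return named list supercell_id -> `chromatin_profile`
#'   (assay "atac_supercell"); unknown barcodes are skipped and counted in
#'   attribute `n_skipped`.
#' @export
build_paired_landscape <- function(fragments, partition, chrom_lengths,
                                   merge_limit = 1000, bin_size = 1000) {
  known <- fragments$barcode %in% names(partition$assignment)
  n_skipped <- sum(!known)
  fragments <- fragments[known, , drop = FALSE]
  sc_of <- partition$assignment[fragments$barcode]
  out <- lapply(names(partition$sizes), function(sc) {
    fr <- fragments[sc_of == sc, , drop = FALSE]
    signal <- lapply(names(chrom_lengths), function(ch) {
      nb <- ceiling(chrom_lengths[[ch]] / bin_size)
      v <- numeric(nb)
      sub <- fr[fr$chrom == ch, , drop = FALSE]
      if (!nrow(sub)) return(v)
      merged <- merge_capped(sub$start, sub$end, merge_limit)
      for (i in seq_len(nrow(merged))) {
        b0 <- floor(merged$start[i] / bin_size) + 1
        b1 <- min(nb, ceiling(merged$end[i] / bin_size))
        for (b in b0:b1) {
          ov <- min(merged$end[i], b * bin_size) -
            max(merged$start[i], (b - 1) * bin_size)
          v[b] <- v[b] + ov / bin_size
        }
      }
      v
    })
    names(signal) <- names(chrom_lengths)
    chromatin_profile(sc, "atac_supercell", signal, bin_size)
  })
  names(out) <- names(partition$sizes)
  attr(out, "n_skipped") <- n_skipped
  out
}

# merge overlapping intervals, then split pieces longer than `limit`
merge_capped <- function(start, end, limit) {
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  ms <- numeric(0); me <- numeric(0)
  cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] < ce) ce <- max(ce, end[i])
    else { ms <- c(ms, cs); me <- c(me, ce); cs <- start[i]; ce <- end[i] }
  }
  ms <- c(ms, cs); me <- c(me, ce)
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(ms)) {
    s <- ms[i]
    while (me[i] - s > limit) {
      out_s <- c(out_s, s); out_e <- c(out_e, s + limit)
      s <- s + limit
    }
    out_s <- c(out_s, s); out_e <- c(out_e, me[i])
  }
  data.frame(start = out_s, end = out_e)
}

#' In-silico deletion of a cistrome from a chromatin profile
#'
#' Every 1-kb bin overlapping at least one peak is zeroed; deltaRP per gene
#' is the chrom-RP lost to the deletion.
#'
#' @param profile a `chromatin_profile`.
#' @param cis a [cistrome].
#' @param genes a [gene_model].
#' @inheritParams chrom_rp
#' @return named numeric vector gene -> deltaRP (>= 0).
#' @export
in_silico_delete <- function(profile, cis, genes, L = 1e5, decay = 1e4) {
  erased <- profile
  for (ch in names(profile$signal)) {
    pk <- cis$intervals[cis$intervals$chrom == ch, , drop = FALSE]
    if (!nrow(pk)) next
    v <- erased$signal[[ch]]
    bs <- profile$bin_size
    hit <- logical(length(v))
    for (i in seq_len(nrow(pk))) {
      b0 <- max(1, floor(pk$start[i] / bs) + 1)
      b1 <- min(length(v), ceiling(pk$end[i] / bs))
      if (b1 >= b0) hit[b0:b1] <- TRUE
    }
    v[hit] <- 0
    erased$signal[[ch]] <- v
  }
  before <- vapply(seq_len(nrow(genes)), function(g)
    chrom_rp(profile, genes[g, , drop = FALSE], L, decay), numeric(1))
  after <- vapply(seq_len(nrow(genes)), function(g)
    chrom_rp(erased, genes[g, , drop = FALSE], L, decay), numeric(1))
  stats::setNames(before - after, genes$gene_id)
}

#' One-sided Wilcoxon rank-sum P-value (query greater)
#'
#' Exact enumeration for small tie-free samples (via stats::wilcox.test),
#' normal approximation with tie correction otherwise; identical constant
#' values in both groups give p = 1 (no evidence).
#'
#' @param query,background numeric vectors.
#' @return P-value in (0, 1].
#' @export
wilcox_greater_p <- function(query, background) {
  if (length(unique(c(query, background))) == 1) return(1)
  suppressWarnings(
    stats::wilcox.test(query, background, alternative = "greater")$p.value)
}

#' Cauchy combination of P-values (Liu-Xie)
#'
#' T = (1/c) sum tan((0.5 - p_i) pi); combined p = 0.5 - atan(T)/pi,
#' clipped into (1e-300, 1].
#'
#' @param p vector of P-values in (0, 1].
#' @param weights optional weights summing to 1; default equal.
#' @return combined P-value.
#' @export
cauchy_combine <- function(p, weights = NULL) {
  p <- p[is.finite(p)]
  if (!length(p)) return(1)
  p <- pmin(pmax(p, 1e-300), 1)
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  t_stat <- sum(weights * tan((0.5 - p) * pi))
  out <- 0.5 - atan(t_stat) / pi
  min(max(out, 1e-300), 1)
}

#' Per-TR evidence combination for one SuperCell
#'
#' @param peak_rp_row named gene -> peak-RP vector for the TR dataset.
#' @param delta_rows list of named gene -> deltaRP vectors, one per selected
#'   landscape sample (may be empty).
#' @param query_genes,background_genes disjoint gene sets (>= 5 each).
#' @return list(p_channels, p_summary).
#' @export
rank_tr <- function(peak_rp_row, delta_rows, query_genes,
                    background_genes) {
  stopifnot(!length(intersect(query_genes, background_genes)),
            length(query_genes) >= 5, length(background_genes) >= 5)
  channels <- c(list(peak = peak_rp_row), delta_rows)
  ps <- vapply(channels, function(v) {
    wilcox_greater_p(v[query_genes], v[background_genes])
  }, numeric(1))
  list(p_channels = ps, p_summary = cauchy_combine(ps))
}

#' ISD scoring of all TR datasets across SuperCells
#'
#' For each SuperCell, landscape samples are selected against its marker
#' genes, per-channel statistics (peak-RP and per-sample deltaRP) are
#' compared query-vs-background by one-sided Wilcoxon tests, and channel
#' P-values are combined per TR dataset.  SuperCells are processed in
#' `chunks` independent chunks; chunking does not change results.
#'
#' @param peak_rp dataset x gene peak-RP matrix ([rp_matrix]).
#' @param cistromes list of [cistrome]s matching `rownames(peak_rp)`.
#' @param profiles list of `chromatin_profile`s (reference landscapes), or a
#'   named list supercell_id -> profile when `paired = TRUE`.
#' @param markers named list supercell_id -> marker gene vector.
#' @param genes a [gene_model].
#' @param background_genes background gene ids (see [sample_background]).
#' @param k_samples landscape samples per channel; default 10.
#' @param chunks number of SuperCell chunks; default 8.
#' @param paired if TRUE, `profiles[[sc]]` is that SuperCell's own ATAC
#'   landscape (single channel, no sample selection).
#' @param seed RNG seed for landscape selection.
#' @return list(p_summary = supercell x dataset matrix, channels = nested
#'   list of per-channel P-values).
#' @export
isd_score <- function(peak_rp, cistromes, profiles, markers, genes,
                      background_genes, k_samples = 10, chunks = 8,
                      paired = FALSE, seed = 0) {
  datasets <- rownames(peak_rp)
  names(cistromes) <- vapply(cistromes, `[[`, "", "dataset_id")
  stopifnot(all(datasets %in% names(cistromes)))
  scs <- names(markers)
  if (!paired) {
    chromrp <- chrom_rp_matrix(profiles, genes)
    delta_all <- lapply(datasets, function(ds) {
      lapply(profiles, function(p)
        in_silico_delete(p, cistromes[[ds]], genes))
    })
    names(delta_all) <- datasets
    for (ds in datasets)
      names(delta_all[[ds]]) <- vapply(profiles, `[[`, "", "sample_id")
  }
  chunk_id <- rep(seq_len(max(1, chunks)), length.out = length(scs))
  res <- vector("list", length(scs)); names(res) <- scs
  for (ck in sort(unique(chunk_id))) {
    for (s in scs[chunk_id == ck]) {
      query <- intersect(markers[[s]], genes$gene_id)
      bg <- setdiff(background_genes, query)
      if (paired) {
        delta <- list(atac = in_silico_delete_all(profiles[[s]], cistromes,
                                                  datasets, genes))
        res[[s]] <- lapply(datasets, function(ds)
          rank_tr(peak_rp[ds, ], list(atac = delta$atac[[ds]]), query, bg))
      } else {
        sel <- select_landscape(chromrp, query, bg, k_samples, seed)
        res[[s]] <- lapply(datasets, function(ds)
          rank_tr(peak_rp[ds, ], delta_all[[ds]][sel], query, bg))
      }
      names(res[[s]]) <- datasets
    }
  }
  p_summary <- t(vapply(res, function(r)
    vapply(r, `[[`, numeric(1), "p_summary"), numeric(length(datasets))))
  dimnames(p_summary) <- list(scs, datasets)
  list(p_summary = p_summary, channels = res)
}

in_silico_delete_all <- function(profile, cistromes, datasets, genes) {
  out <- lapply(datasets, function(ds)
    in_silico_delete(profile, cistromes[[ds]], genes))
  names(out) <- datasets
  out
}

#' Draw a shared background gene set
#' @param genes a [gene_model].
#' @param exclude gene ids never sampled (e.g. the union of markers).
#' @param n background size; default 3000 (capped at available genes).
#' @param seed RNG seed.
#' @return character vector of gene ids.
#' @export
sample_background <- function(genes, exclude = character(), n = 3000,
                              seed = 0) {
  pool <- setdiff(genes$gene_id, exclude)
  set.seed(seed)
  sort(sample(pool, min(n, length(pool))))
}
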