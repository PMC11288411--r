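# shared helpers for the suite; everything is generated in code

adjusted_rand <- function(a, b) {
  t <- table(a, b); n <- sum(t)
  sij <- sum(choose(t, 2))
  si <- sum(choose(rowSums(t), 2)); sj <- sum(choose(colSums(t), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# one-row gene with TSS at `tss` on "+" strand and a single exon
toy_gene <- function(tss, id = "g1", chrom = "chr1", width = 2000) {
  gene_model(id, chrom, "+", tss, tss + width)
}

# cistrome of peaks centred at `centers` (width 200, fold 10)
toy_cistrome <- function(centers, chrom = "chr1", tr = "TF1", ds = "ds1",
                         fold = 10) {
  cistrome(tr, ds, data.frame(chrom = rep_len(chrom, length(centers)),
                              start = centers - 100,
                              end = centers + 100,
                              fold = rep_len(fold, length(centers))))
}

# QC record with every field passing by a margin; override via ...
passing_qc <- function(dataset_id = "d1", ...) {
  rec <- data.frame(dataset_id = dataset_id, median_quality = 30,
                    unique_map_rate = 0.9, pbc = 0.95,
                    n_peaks_10fold = 5000, frip = 0.2,
                    dhs_overlap_top5000 = 0.9, n_peaks = 20000,
                    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# small expression fixture reused by several files (built once per run)
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fixture_preset(seed = 11, n_genes = 120, n_cells = 240,
                               n_groups = 2, n_trs = 2, regulon_size = 20)
    cache
  }
})

# exhaustive-vertex LP oracle for small transportation problems: try every
# basis of m+n-1 cells, solve the tree system, keep feasible minima
ot_oracle <- function(L, R, D) {
  L <- L / sum(L); R <- R / sum(R)
  m <- length(L); n <- length(R)
  cells <- expand.grid(i = seq_len(m), j = seq_len(n))
  best <- Inf
  for (sel in utils::combn(nrow(cells), m + n - 1, simplify = FALSE)) {
    A <- matrix(0, m + n, length(sel))
    for (k in seq_along(sel)) {
      A[cells$i[sel[k]], k] <- 1
      A[m + cells$j[sel[k]], k] <- 1
    }
    x <- tryCatch(qr.solve(A[-1, , drop = FALSE], c(L, R)[-1]),
                  error = function(e) NULL)
    if (is.null(x)) next
    if (any(x < -1e-9)) next
    if (max(abs(A %*% x - c(L, R))) > 1e-9) next
    cost <- sum(x * D[cbind(cells$i[sel], cells$j[sel])])
    best <- min(best, cost)
  }
  best
}
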