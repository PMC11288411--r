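#' Expression-corrected TR activity score
#'
#' The ISD summary P-value of TR m in SuperCell i gives
#' N = -log10(P_summary).  Expression enters through clipped z-scores
#' computed across SuperCells: M_TR is the TR gene's z-score, M_Target the
#' mean z-score of its k target genes, both clipped into [-4, 4];
#' M_exp = M_TR + M_Target, and the activity score is
#' \deqn{S = N \times \frac{M_{exp} - \min M_{exp}}
#'                        {\max M_{exp} - \min M_{exp}},}
#' with the min/max taken over the whole M_exp matrix so scores remain
#' comparable across SuperCells.
#'
#' @name tr_scoring
NULL

#' Negative log10 of a summary P-value
#' @param p P-values in (0, 1]; values <= 0 are clipped to 1e-300 with a
#'   warning.
#' @return -log10(p).
#' @export
neglog <- function(p) {
  if (any(p <= 0)) {
    warning("non-positive p clipped to 1e-300")
    p <- pmax(p, 1e-300)
  }
  -log10(pmin(p, 1))
}

#' Across-SuperCell z-score, clipped to [-4, 4]
#' @param values numeric vector (one gene across >= 2 SuperCells).
#' @param clip clip bound; default 4.
#' @return clipped z-scores (0 everywhere if the gene is constant).
#' @export
zscore_clip <- function(values, clip = 4) {
  if (length(values) < 2) stop("need >= 2 SuperCells")
  s <- stats::sd(values)
  z <- if (s == 0) rep(0, length(values)) else (values - mean(values)) / s
  pmin(pmax(z, -clip), clip)
}

#' Mean clipped z-score of a TR's target genes
#' @param E SuperCell x gene expression matrix (normalized aggregated).
#' @param target_genes character vector of target gene ids.
#' @param clip clip bound; default 4.
#' @return per-SuperCell M_Target (clipped mean of per-gene z-scores).
#' @export
target_component <- function(E, target_genes, clip = 4) {
  present <- intersect(target_genes, colnames(E))
  if (!length(present)) stop("targets missing")
  z <- vapply(present, function(g) zscore_clip(E[, g], clip),
              numeric(nrow(E)))
  z <- matrix(z, nrow = nrow(E))
  stats::setNames(pmin(pmax(rowMeans(z), -clip), clip), rownames(E))
}

#' Combine N and expression components into the activity score
#'
#' @param N SuperCell x TR matrix of -log10 summary P-values.
#' @param M_TR,M_Target matching matrices of clipped z components.
#' @param scope "global" (min/max over the whole M_exp matrix, default) or
#'   "per_supercell" (row-wise min/max).
#' @return list(S, M_exp).
#' @export
activity_score <- function(N, M_TR, M_Target,
                           scope = c("global", "per_supercell")) {
  scope <- match.arg(scope)
  stopifnot(length(N) > 0, all(dim(N) == dim(M_TR)),
            all(dim(N) == dim(M_Target)))
  M_exp <- M_TR + M_Target
  if (scope == "global") {
    rng <- range(M_exp)
    norm <- if (diff(rng) == 0) matrix(0.5, nrow(N), ncol(N))
            else (M_exp - rng[1]) / diff(rng)
  } else {
    norm <- t(apply(M_exp, 1, function(r) {
      if (max(r) == min(r)) rep(0.5, length(r))
      else (r - min(r)) / (max(r) - min(r))
    }))
  }
  S <- N * norm
  dimnames(S) <- dimnames(N)
  list(S = S, M_exp = M_exp)
}

#' Full TR activity scoring from ISD output and expression
#'
#' Computes N from the summary P-value matrix, M_TR from each TR gene's
#' expression (0 when the TR gene is absent from the matrix), M_Target from
#' the dataset's target genes, and S; when a TR has several reference
#' datasets, per-dataset scores are combined by taking the maximum
#' (best-matched cistrome).
#'
#' @param p_summary SuperCell x dataset matrix from [isd_score].
#' @param E SuperCell x gene normalized aggregated expression.
#' @param targets named list dataset_id -> [select_targets] output.
#' @param tr_of named map dataset_id -> TR symbol.
#' @param scope min/max scope for [activity_score].
#' @return list(S (SuperCell x TR), S_dataset, N, M_TR, M_Target, M_exp,
#'   p_summary).
#' @export
tr_activity <- function(p_summary, E, targets, tr_of,
                        scope = "global") {
  datasets <- colnames(p_summary)
  stopifnot(all(datasets %in% names(targets)),
            all(datasets %in% names(tr_of)),
            identical(rownames(p_summary), rownames(E)))
  N <- neglog(p_summary)
  M_TR <- vapply(datasets, function(ds) {
    g <- tr_of[[ds]]
    if (g %in% colnames(E)) zscore_clip(E[, g]) else rep(0, nrow(E))
  }, numeric(nrow(p_summary)))
  M_Target <- vapply(datasets, function(ds) {
    target_component(E, targets[[ds]]$genes)
  }, numeric(nrow(p_summary)))
  dimnames(M_TR) <- dimnames(M_Target) <- dimnames(p_summary)
  sc <- activity_score(N, M_TR, M_Target, scope)
  trs <- unname(tr_of[datasets])
  S_tr <- vapply(unique(trs), function(tr) {
    cols <- datasets[trs == tr]
    apply(sc$S[, cols, drop = FALSE], 1, max)
  }, numeric(nrow(p_summary)))
  S_tr <- matrix(S_tr, nrow = nrow(p_summary),
                 dimnames = list(rownames(p_summary), unique(trs)))
  list(S = S_tr, S_dataset = sc$S, N = N, M_TR = M_TR,
       M_Target = M_Target, M_exp = sc$M_exp, p_summary = p_summary)
}

#' Write TR activity outputs as TSV
#' @param activity a [tr_activity] result.
#' @param dir output directory.
#' @return dir, invisibly.  Writes `tf_score.tsv` (S),
#'   `P_value_matrix.tsv` (summary P-values) and `components.tsv`.
#' @export
write_activity <- function(activity, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) utils::write.table(
    data.frame(supercell = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(activity$S, "tf_score.tsv")
  wr(activity$p_summary, "P_value_matrix.tsv")
  comp <- do.call(rbind, lapply(c("N", "M_TR", "M_Target"), function(nm) {
    data.frame(component = nm, supercell = rownames(activity[[nm]]),
               activity[[nm]], check.names = FALSE)
  }))
  utils::write.table(comp, file.path(dir, "components.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
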