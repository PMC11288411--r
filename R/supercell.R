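#' SuperCell construction
#'
#' Cells are aggregated into SuperCells -- pooled pseudo-bulk profiles of at
#' least 30 transcriptionally similar cells -- by two-level Leiden
#' clustering: a primary pass at a fixed resolution delineates coarse
#' populations, then within each primary cluster a secondary resolution is
#' binary-searched until the mean sub-cluster size approaches a target
#' (default 30 cells).  Undersized sub-clusters are merged into the nearest
#' sub-cluster (centroid distance in PCA space) of the same primary
#' cluster.  Each SuperCell is treated downstream as an independent
#' high-coverage RNA-seq sample.
#'
#' @name supercell
NULL

#' Basic cell/gene filtering
#' @param counts cell x gene count matrix.
#' @param min_genes drop cells expressing fewer genes; default 200.
#' @param min_cells drop genes expressed in fewer cells; default 3.
#' @return filtered count matrix.
#' @export
filter_counts <- function(counts, min_genes = 200, min_cells = 3) {
  counts <- as.matrix(counts)
  counts <- counts[rowSums(counts > 0) >= min_genes, , drop = FALSE]
  counts[, colSums(counts > 0) >= min_cells, drop = FALSE]
}

#' Normalize counts (counts-per-10k, log1p)
#' @param counts cell x gene counts.
#' @return dense matrix of log1p(1e4 * count / cell_total).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  tot <- rowSums(counts)
  tot[tot == 0] <- 1
  log1p(counts / tot * 1e4)
}

#' Preprocess expression: normalize, embed, cluster
#'
#' Total-count normalization (counts-per-10k) and log1p, PCA to `n_pcs`
#' principal components, a Jaccard-weighted shared-nearest-neighbour graph
#' on `n_neighbors` neighbours, and Leiden clustering (modularity
#' objective) at `resolution`.
#'
#' @param counts cell x gene non-negative count matrix with dimnames.
#' @param n_neighbors KNN graph size; default 10.
#' @param n_pcs principal components; default 40 (reduced with a warning if
#'   there are fewer cells).
#' @param resolution primary Leiden resolution; default 0.8.
#' @param seed RNG seed for PCA sign conventions and Leiden.
#' @return list(normalized, embedding, labels, graph).
#' @export
preprocess <- function(counts, n_neighbors = 10, n_pcs = 40,
                       resolution = 0.8, seed = 0) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  normalized <- normalize_counts(counts)
  if (nrow(normalized) <= n_pcs) {
    n_pcs <- max(2, nrow(normalized) - 1)
    warning("fewer cells than n_pcs; reduced to ", n_pcs)
  }
  embedding <- pca_embed(normalized, n_pcs, seed)
  graph <- snn_graph(embedding, n_neighbors)
  labels <- leiden_cluster(graph, resolution, seed)
  list(normalized = normalized, embedding = embedding, labels = labels,
       graph = graph)
}

pca_embed <- function(x, n_pcs, seed = 0) {
  set.seed(seed)
  n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x))
  ctr <- sweep(x, 2, colMeans(x))
  sv <- svd(ctr, nu = n_pcs, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  # fix signs for reproducibility across BLAS implementations
  flip <- apply(emb, 2, function(col) sign(col[which.max(abs(col))]))
  emb <- sweep(emb, 2, flip, "*")
  rownames(emb) <- rownames(x)
  emb
}

#' Jaccard-weighted shared-nearest-neighbour graph
#' @param embedding cell x PC matrix.
#' @param k neighbours per cell.
#' @param prune drop edges with Jaccard weight below this; default 1/15.
#' @return an undirected weighted [igraph::graph].
#' @export
snn_graph <- function(embedding, k, prune = 1 / 15) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(embedding))
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k + 1)]))  # incl self
  adj <- lapply(seq_len(n), function(i) nn[i, ])
  pairs <- unique(t(apply(
    cbind(rep(seq_len(n), each = k), as.vector(t(nn[, -1, drop = FALSE]))),
    1, sort)))
  w <- vapply(seq_len(nrow(pairs)), function(e) {
    a <- adj[[pairs[e, 1]]]; b <- adj[[pairs[e, 2]]]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
  keep <- w >= prune
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  igraph::V(g)$name <- rownames(embedding)
  g
}

#' Leiden clustering (modularity objective) on a weighted graph
#' @param graph an [igraph::graph] with edge weights.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed.
#' @param n_iterations Leiden refinement iterations; default 5.
#' @return integer labels (0-based) named by vertex.
#' @export
leiden_cluster <- function(graph, resolution, seed, n_iterations = 5) {
  if (igraph::vcount(graph) == 1) return(stats::setNames(0L, igraph::V(graph)$name))
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               resolution = resolution,
                               weights = igraph::E(graph)$weight,
                               n_iterations = n_iterations)
  stats::setNames(as.integer(igraph::membership(cl)) - 1L,
                  igraph::V(graph)$name)
}

#' Build SuperCells from a primary clustering
#'
#' @param counts raw cell x gene counts (rows named by barcode).
#' @param embedding PCA embedding from [preprocess].
#' @param labels primary Leiden labels (named by barcode).
#' @param target_n desired mean SuperCell size; default 30.
#' @param min_size minimum SuperCell size after merging; default 30.
#' @param seed RNG seed for the secondary Leiden runs.
#' @param n_neighbors KNN size for the per-cluster subgraphs; default 10.
#' @param max_iter binary-search iteration cap; default 25.
#' @param band relative tolerance on the mean sub-cluster size; default 0.1.
#' @return a `supercell_partition`: list(assignment, sizes, parent_cluster,
#'   centroid, aggregated, normalized_aggregated).
#' @export
build_supercells <- function(counts, embedding, labels, target_n = 30,
                             min_size = 30, seed = 0, n_neighbors = 10,
                             max_iter = 25, band = 0.1) {
  counts <- as.matrix(counts)
  stopifnot(identical(rownames(counts), rownames(embedding)),
            identical(rownames(counts), names(labels)))
  assignment <- character(nrow(counts))
  names(assignment) <- rownames(counts)
  for (cl in sort(unique(labels))) {
    cells <- names(labels)[labels == cl]
    emb <- embedding[cells, , drop = FALSE]
    sub <- subcluster_to_target(emb, target_n, min_size, seed,
                                n_neighbors, max_iter, band)
    assignment[cells] <- paste0("c", cl, "_s", sub)
  }
  finalize_partition(counts, embedding, labels, assignment)
}

subcluster_to_target <- function(emb, target_n, min_size, seed,
                                 n_neighbors, max_iter, band) {
  n <- nrow(emb)
  if (n < min_size || n <= target_n) return(rep(0L, n))
  g <- snn_graph(emb, n_neighbors)
  lo <- 0.01; hi <- 50
  best <- rep(0L, n); best_gap <- abs(n - target_n)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    lab <- leiden_cluster(g, mid, seed + it)
    mean_size <- n / length(unique(lab))
    gap <- abs(mean_size - target_n)
    if (gap < best_gap) { best <- lab; best_gap <- gap }
    if (gap <= band * target_n) break
    if (mean_size > target_n) lo <- mid else hi <- mid
  }
  merge_undersized(unname(best), emb, min_size)
}

merge_undersized <- function(lab, emb, min_size) {
  lab <- as.integer(factor(lab)) - 1L
  repeat {
    sizes <- table(lab)
    if (length(sizes) <= 1) break
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    victim <- small[which.min(sizes[small])]
    cent <- centroids_by(emb, lab)
    others <- setdiff(rownames(cent), victim)
    d <- sqrt(colSums((t(cent[others, , drop = FALSE]) -
                         cent[victim, ])^2))
    target <- others[which.min(d)]
    lab[lab == as.integer(victim)] <- as.integer(target)
    lab <- as.integer(factor(lab)) - 1L
  }
  lab
}

centroids_by <- function(emb, lab) {
  agg <- rowsum(emb, group = lab)
  sweep(agg, 1, as.vector(table(lab)), "/")
}

finalize_partition <- function(counts, embedding, labels, assignment) {
  ids <- sort(unique(assignment))
  sizes <- stats::setNames(as.vector(table(assignment)[ids]), ids)
  parent <- stats::setNames(
    vapply(ids, function(id) unname(labels[assignment == id][1]),
           labels[1]), ids)
  aggregated <- rowsum(counts, group = assignment)[ids, , drop = FALSE]
  centroid <- centroids_by(embedding, assignment)[ids, , drop = FALSE]
  structure(list(assignment = assignment, sizes = sizes,
                 parent_cluster = parent, centroid = centroid,
                 aggregated = aggregated,
                 normalized_aggregated = normalize_counts(aggregated)),
            class = "supercell_partition")
}

#' @export
print.supercell_partition <- function(x, ...) {
  cat(sprintf("<supercell_partition> %d cells -> %d SuperCells (sizes %d-%d)\n",
              length(x$assignment), length(x$sizes), min(x$sizes),
              max(x$sizes)))
  invisible(x)
}

#' Per-SuperCell marker genes (small-dataset strategy)
#'
#' Each SuperCell's aggregated profile is contrasted one-vs-rest across
#' SuperCells by an exact Wilcoxon rank-sum on the normalized aggregated
#' expression (single observation vs the rest); genes must be expressed in
#' the SuperCell.  The `top_k` best-ranked genes become markers; SuperCells
#' ending with fewer than `min_markers` markers are excluded.
#'
#' @param partition a `supercell_partition`.
#' @param top_k markers per SuperCell; default 500.
#' @param min_markers exclusion floor; default 35.
#' @return list(markers = named list supercell -> character vector,
#'   excluded = character vector of supercell ids).
#' @export
select_markers_small <- function(partition, top_k = 500, min_markers = 35) {
  expr <- partition$normalized_aggregated
  K <- nrow(expr)
  if (K < 2) stop("no contrast")
  markers <- list(); excluded <- character()
  for (s in rownames(expr)) {
    x <- expr[s, ]
    rest <- expr[setdiff(rownames(expr), s), , drop = FALSE]
    # exact one-sided rank-sum with a single "query" observation:
    # p = (1 + #{other SuperCells with value >= x}) / K
    p <- (1 + colSums(sweep(rest, 2, x, ">="))) / K
    lfc <- x - colMeans(rest)
    cand <- names(x)[x > 0 & lfc > 0]  # expressed and positively enriched
    ord <- cand[order(p[cand], -lfc[cand], cand)]
    genes <- utils::head(ord, top_k)
    if (length(genes) < min_markers) excluded <- c(excluded, s)
    else markers[[s]] <- genes
  }
  list(markers = markers, excluded = excluded)
}

#' Per-SuperCell marker genes (large-dataset strategy)
#'
#' The top `per_cluster_top` genes per primary cluster (mean normalized
#' aggregated expression over the cluster's SuperCells) form a candidate
#' pool; within each SuperCell, candidates expressed strictly above the
#' SuperCell's `percentile`-th percentile (over candidate genes,
#' linear-interpolation quantile) are markers.
#'
#' @inheritParams select_markers_small
#' @param per_cluster_top candidate genes per primary cluster; default 1500.
#' @param percentile marker threshold percentile; default 60.
#' @return as [select_markers_small].
#' @export
select_markers_large <- function(partition, per_cluster_top = 1500,
                                 percentile = 60, min_markers = 35) {
  expr <- partition$normalized_aggregated
  markers <- list(); excluded <- character()
  for (cl in unique(partition$parent_cluster)) {
    scs <- names(partition$parent_cluster)[partition$parent_cluster == cl]
    prof <- colMeans(expr[scs, , drop = FALSE])
    cand <- names(sort(prof, decreasing = TRUE))[
      seq_len(min(per_cluster_top, ncol(expr)))]
    for (s in scs) {
      v <- expr[s, cand]
      thr <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
      genes <- sort(cand[v > thr])
      if (length(genes) < min_markers) excluded <- c(excluded, s)
      else markers[[s]] <- genes
    }
  }
  list(markers = markers, excluded = excluded)
}
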