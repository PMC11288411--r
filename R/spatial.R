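#' Spatial neighbour networks and graph-attention auto-encoder
#'
#' Spatial data are embedded by (i) building an undirected spatial
#' neighbour network (SNN) linking spots within a radius r, (ii) optionally
#' pruning it with a cell-type-aware pass that keeps only edges whose
#' endpoints share a pre-cluster label, (iii) learning a graph-attention
#' auto-encoder whose per-node attention over neighbours is computed
#' separately on the spatial and aware graphs and combined as
#' \deqn{att = (1-\alpha)\,att^{spatial} + \alpha\,att^{aware}.}
#' The decoder output is the reconstructed normalized expression.
#'
#' @name spatial_embedding
NULL

#' Build the radius-based spatial neighbour network
#'
#' @param coords matrix/data.frame of spot coordinates (columns x, y; rows
#'   named by barcode).
#' @param r neighbour radius (same units as coords); edge iff
#'   0 < Euclidean distance <= r.
#' @return a `spatial_graph`: list(coords, radius, edges (2-column index
#'   matrix, i < j), aware_edges = NULL).
#' @export
build_snn <- function(coords, r) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2)
  if (r <= 0) stop("radius must be positive")
  d <- as.matrix(stats::dist(coords))
  idx <- which(upper.tri(d) & d > 0 & d <= r, arr.ind = TRUE)
  structure(list(coords = coords, radius = r,
                 edges = unname(idx), aware_edges = NULL),
            class = "spatial_graph")
}

#' Default neighbour radius: 1.5 x median nearest-neighbour spacing
#' @param coords spot coordinates.
#' @return a radius.
#' @export
auto_radius <- function(coords) {
  d <- as.matrix(stats::dist(as.matrix(coords)))
  diag(d) <- Inf
  1.5 * stats::median(apply(d, 1, min))
}

#' Cell-type-aware pruning of the SNN
#'
#' @param graph a `spatial_graph`.
#' @param pre_clusters vector of pre-cluster labels covering all spots
#'   (named by barcode or positional).
#' @return the graph with `aware_edges` set to the edges whose endpoints
#'   share a label.
#' @export
prune_aware <- function(graph, pre_clusters) {
  stopifnot(length(pre_clusters) == nrow(graph$coords))
  if (!is.null(names(pre_clusters)))
    pre_clusters <- pre_clusters[rownames(graph$coords)]
  e <- graph$edges
  same <- pre_clusters[e[, 1]] == pre_clusters[e[, 2]]
  graph$aware_edges <- e[same, , drop = FALSE]
  graph
}

# row-stochastic attention over neighbours (+ self) from scaled dot
# products of PCA features; nodes with no neighbours attend to themselves
attention_matrix <- function(feats, n, edges) {
  A <- matrix(-Inf, n, n)
  sc <- tcrossprod(feats) / sqrt(ncol(feats))
  if (nrow(edges)) {
    A[edges] <- sc[edges]
    A[edges[, c(2, 1), drop = FALSE]] <- sc[edges[, c(2, 1), drop = FALSE]]
  }
  diag(A) <- diag(sc)
  A <- exp(A - apply(A, 1, max))
  A[!is.finite(A)] <- 0
  sweep(A, 1, rowSums(A), "/")
}

#' Fit the graph-attention auto-encoder
#'
#' A two-layer tied-weight auto-encoder on the attention-propagated
#' expression: H = AXW1, Z = AHW2 (the embedding), and the symmetric
#' decoder reconstructs X through the transposed weights.  A is the
#' combined attention matrix of Eq.-style linear combination
#' (1-alpha) spatial + alpha aware; attention is the softmax over each
#' node's neighbours (plus self) of scaled dot products of expression PCA
#' features.  Full-batch gradient descent with backtracking keeps the
#' recorded loss non-increasing.
#'
#' @param expr normalized spot x gene matrix.
#' @param graph a `spatial_graph` (run [prune_aware] first for a
#'   non-trivial aware channel; otherwise aware = spatial).
#' @param alpha weight of the cell-type-aware attention in [0, 1];
#'   default 0.5.
#' @param epochs gradient steps; default 200.
#' @param seed RNG seed for weight initialization.
#' @param hidden,latent layer widths; defaults 64 and 16.
#' @param lr initial learning rate; default 1e-3.
#' @return list(embedding, reconstructed, graph (with att_spatial,
#'   att_aware, att matrices), loss (checkpoint trace)).
#' @export
fit_gat_autoencoder <- function(expr, graph, alpha = 0.5, epochs = 200,
                                seed = 0, hidden = 64, latent = 16,
                                lr = 1e-3) {
  expr <- as.matrix(expr)
  if (!all(is.finite(expr))) stop("non-finite expression")
  n <- nrow(expr)
  stopifnot(n == nrow(graph$coords), alpha >= 0, alpha <= 1)
  feats <- pca_embed(expr, min(20, n - 1, ncol(expr)), seed)
  att_sp <- attention_matrix(feats, n, graph$edges)
  aware <- if (is.null(graph$aware_edges)) graph$edges else graph$aware_edges
  att_aw <- attention_matrix(feats, n, aware)
  A <- (1 - alpha) * att_sp + alpha * att_aw

  p <- ncol(expr)
  hidden <- min(hidden, p, n - 1); latent <- min(latent, hidden)
  set.seed(seed)
  # PCA-informed initialization: the encoder starts as the projection onto
  # the leading principal axes, so early embeddings are already meaningful
  ctr <- sweep(expr, 2, colMeans(expr))
  sv <- svd(ctr, nu = 0, nv = hidden)
  W1 <- sv$v + matrix(stats::rnorm(p * hidden, sd = 1e-3), p, hidden)
  W2 <- diag(1, hidden, latent) +
    matrix(stats::rnorm(hidden * latent, sd = 1e-3), hidden, latent)
  forward <- function(W1, W2) {
    H1 <- A %*% (expr %*% W1)
    Z <- A %*% (H1 %*% W2)
    H2 <- A %*% (Z %*% t(W2))
    Xh <- A %*% (H2 %*% t(W1))
    list(H1 = H1, Z = Z, H2 = H2, Xh = Xh,
         loss = mean((expr - Xh)^2))
  }
  fw <- forward(W1, W2)
  trace <- fw$loss
  for (ep in seq_len(epochs)) {
    g_Xh <- 2 * (fw$Xh - expr) / length(expr)
    dW1 <- t(g_Xh) %*% (A %*% fw$H2)                     # decoder W1^T
    dH2 <- t(A) %*% g_Xh %*% W1
    dW2 <- t(dH2) %*% (A %*% fw$Z)                       # decoder W2^T
    dZ <- t(A) %*% dH2 %*% W2
    dW2 <- dW2 + t(A %*% fw$H1) %*% dZ                   # encoder W2
    dH1 <- t(A) %*% dZ %*% t(W2)
    dW1 <- dW1 + t(A %*% expr) %*% dH1                   # encoder W1
    repeat {
      cand <- forward(W1 - lr * dW1, W2 - lr * dW2)
      if (cand$loss <= fw$loss || lr < 1e-14) break
      lr <- lr / 2
    }
    if (cand$loss <= fw$loss) {
      W1 <- W1 - lr * dW1; W2 <- W2 - lr * dW2; fw <- cand
      lr <- lr * 1.5   # adaptive growth; backtracking keeps loss monotone
    }
    if (ep %% 10 == 0) trace <- c(trace, fw$loss)
  }
  graph$att_spatial <- att_sp; graph$att_aware <- att_aw; graph$att <- A
  graph$alpha <- alpha
  emb <- fw$Z
  rownames(emb) <- rownames(expr)
  recon <- fw$Xh
  dimnames(recon) <- dimnames(expr)
  list(embedding = emb, reconstructed = recon, graph = graph, loss = trace)
}
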