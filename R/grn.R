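#' TR-centred gene regulatory networks and spatial ligand-receptor analysis
#'
#' GRN edges connect a TR to its RP-selected target genes and are pruned by
#' TR-target co-expression (Pearson correlation over SuperCells).  Module
#' structure is summarized by degree centrality on the TR-TR projection
#' (two TRs linked iff they share at least one target).  Spatial crosstalk
#' is quantified by the exact Wasserstein (earth-mover's) distance between
#' the ligand and receptor expression distributions over spots,
#' \deqn{W(L, R) = \min_{\gamma \in \tau(L,R)} \langle \gamma, D \rangle,}
#' with D the Euclidean spot-distance matrix, solved by the transportation
#' simplex.
#'
#' @name grn_cci
NULL

#' Build a co-expression-pruned TR-target network
#'
#' @param targets named list TR -> [select_targets] output.
#' @param expr SuperCell x gene expression (normalized aggregated).
#' @param min_coexpr minimum Pearson correlation between TR and target
#'   expression for an edge to be kept; default 0.3.  Set <= -1 to keep all
#'   edges (e.g. to retain repressor-negative correlations).
#' @return a `grn`: data.frame(tr, target, rp_weight, coexpr).
#' @export
build_grn <- function(targets, expr, min_coexpr = 0.3) {
  rows <- lapply(names(targets), function(tr) {
    ts <- targets[[tr]]
    tg <- intersect(ts$genes, colnames(expr))
    if (!length(tg)) return(NULL)
    tr_expr <- if (tr %in% colnames(expr)) expr[, tr] else
      rep(0, nrow(expr))
    co <- vapply(tg, function(g) {
      if (stats::sd(tr_expr) == 0 || stats::sd(expr[, g]) == 0) return(0)
      stats::cor(tr_expr, expr[, g])
    }, numeric(1))
    data.frame(tr = tr, target = tg,
               rp_weight = ts$rp[match(tg, ts$genes)],
               coexpr = unname(co), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(tr = character(), target = character(),
                                      rp_weight = numeric(),
                                      coexpr = numeric())
  out <- out[out$coexpr >= min_coexpr, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("grn", "data.frame")
  out
}

#' Degree centrality of TRs on the shared-target projection
#'
#' @param grn a [build_grn] result.
#' @param module_members TR symbols forming the module.
#' @return named numeric TR -> degree / (n_nodes - 1) (0 for a single
#'   node).
#' @export
degree_centrality <- function(grn, module_members) {
  stopifnot(length(module_members) >= 1)
  n <- length(module_members)
  if (n == 1) return(stats::setNames(0, module_members))
  tg <- lapply(module_members, function(tr) grn$target[grn$tr == tr])
  names(tg) <- module_members
  deg <- vapply(module_members, function(a) {
    sum(vapply(setdiff(module_members, a), function(b)
      length(intersect(tg[[a]], tg[[b]])) >= 1, logical(1)))
  }, numeric(1))
  deg / (n - 1)
}

#' Exact discrete optimal transport (transportation simplex)
#'
#' @param L source masses (sum > 0).
#' @param R sink masses (sum > 0).
#' @param D m x n cost matrix.
#' @param normalize rescale both marginals to unit mass (default TRUE);
#'   the transport polytope requires equal totals.
#' @return list(gamma, cost).
#' @export
solve_ot <- function(L, R, D, normalize = TRUE) {
  m <- length(L); n <- length(R)
  stopifnot(nrow(D) == m, ncol(D) == n, sum(L) > 0, sum(R) > 0)
  if (normalize) { L <- L / sum(L); R <- R / sum(R) }
  stopifnot(abs(sum(L) - sum(R)) < 1e-9)
  if (m == 1) return(list(gamma = matrix(R, 1), cost = sum(R * D)))
  if (n == 1) return(list(gamma = matrix(L, ncol = 1), cost = sum(L * D)))
  eps <- 1e-11
  a <- L + eps; b <- R; b[n] <- b[n] + m * eps
  gamma <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  i <- 1; j <- 1
  repeat {                                       # north-west corner start
    q <- min(a[i], b[j])
    gamma[i, j] <- q; basis[i, j] <- TRUE
    a[i] <- a[i] - q; b[j] <- b[j] - q
    if (i == m && j == n) break
    if (a[i] == 0 && i < m) i <- i + 1 else j <- j + 1
  }
  for (iter in seq_len(100 * (m + n) * max(m, n))) {
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1] <- 0
    repeat {                                     # duals on the basis tree
      changed <- FALSE
      for (bi in seq_len(m)) for (bj in seq_len(n)) if (basis[bi, bj]) {
        if (!is.na(u[bi]) && is.na(v[bj])) {
          v[bj] <- D[bi, bj] - u[bi]; changed <- TRUE
        } else if (is.na(u[bi]) && !is.na(v[bj])) {
          u[bi] <- D[bi, bj] - v[bj]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    red <- D - outer(u, v, "+")
    red[basis] <- 0
    best <- which.min(red)
    if (red[best] >= -1e-12) break
    ei <- (best - 1) %% m + 1; ej <- (best - 1) %/% m + 1
    path <- basis_path(basis, ei, ej)            # row ei ... col ej
    cells <- rbind(c(ei, ej), path)
    sgn <- rep_len(c(1, -1), nrow(cells))
    minus <- which(sgn == -1)
    g_minus <- gamma[cells[minus, , drop = FALSE]]
    theta <- min(g_minus)
    leave <- minus[which.min(g_minus)]
    gamma[cells] <- gamma[cells] + sgn * theta
    basis[ei, ej] <- TRUE
    basis[cells[leave, 1], cells[leave, 2]] <- FALSE
    gamma[cells[leave, 1], cells[leave, 2]] <- 0
  }
  # re-solve the basic flows on the optimal tree with unperturbed masses
  gamma <- basis_flows(basis, L, R)
  list(gamma = gamma, cost = sum(gamma * D))
}

# flows of the basic cells for given marginals, by leaf elimination on the
# basis spanning tree; degenerate flows are clamped at 0
basis_flows <- function(basis, L, R) {
  m <- length(L); n <- length(R)
  gamma <- matrix(0, m, n)
  B <- basis
  a <- L; b <- R
  active_r <- rep(TRUE, m); active_c <- rep(TRUE, n)
  for (step in seq_len(m + n - 1)) {
    deg_r <- rowSums(B); deg_c <- colSums(B)
    lr <- which(active_r & deg_r == 1)
    if (length(lr)) {
      i <- lr[1]; j <- which(B[i, ])[1]
      gamma[i, j] <- a[i]; b[j] <- b[j] - a[i]
      B[i, j] <- FALSE; active_r[i] <- FALSE
    } else {
      lc <- which(active_c & deg_c == 1)
      if (!length(lc)) break
      j <- lc[1]; i <- which(B[, j])[1]
      gamma[i, j] <- b[j]; a[i] <- a[i] - b[j]
      B[i, j] <- FALSE; active_c[j] <- FALSE
    }
  }
  pmax(gamma, 0)
}

# unique alternating path of basic cells from row node `ri` to col node
# `cj` in the basis spanning tree (excluding the entering cell)
basis_path <- function(basis, ri, cj) {
  m <- nrow(basis); n <- ncol(basis)
  # nodes: rows 1..m, cols m+1..m+n
  parent <- rep(NA_integer_, m + n)
  seen <- rep(FALSE, m + n)
  queue <- ri; seen[ri] <- TRUE
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    if (node == m + cj) break
    if (node <= m) {
      for (j in which(basis[node, ])) if (!seen[m + j]) {
        seen[m + j] <- TRUE; parent[m + j] <- node
        queue <- c(queue, m + j)
      }
    } else {
      jj <- node - m
      for (i in which(basis[, jj])) if (!seen[i]) {
        seen[i] <- TRUE; parent[i] <- node
        queue <- c(queue, i)
      }
    }
  }
  nodes <- m + cj
  while (nodes[1] != ri) nodes <- c(parent[nodes[1]], nodes)
  cells <- matrix(0L, length(nodes) - 1, 2)
  for (k in seq_len(length(nodes) - 1)) {
    a <- nodes[k]; b <- nodes[k + 1]
    if (a <= m) cells[k, ] <- c(a, b - m) else cells[k, ] <- c(b, a - m)
  }
  cells  # ordered from the entering row towards the entering column
}

#' Wasserstein distance between ligand and receptor expression
#'
#' Spot expression values are treated as masses (normalized to unit total
#' on each side); ground cost is the Euclidean distance between spot
#' coordinates.
#'
#' @param ligand_expr,receptor_expr named spot -> expression vectors
#'   (non-negative; zero-expression spots are dropped).
#' @param coords spot coordinate matrix (rows named by barcode).
#' @return list(L, R, D, gamma, W).
#' @export
wasserstein_lr <- function(ligand_expr, receptor_expr, coords) {
  coords <- as.matrix(coords)
  ls <- ligand_expr[ligand_expr > 0]
  rs <- receptor_expr[receptor_expr > 0]
  if (!length(ls) || !length(rs)) stop("zero total mass")
  cl <- coords[names(ls), , drop = FALSE]
  cr <- coords[names(rs), , drop = FALSE]
  D <- sqrt(outer(cl[, 1], cr[, 1], "-")^2 +
              outer(cl[, 2], cr[, 2], "-")^2)
  sol <- solve_ot(as.numeric(ls), as.numeric(rs), D)
  list(L = ls / sum(ls), R = rs / sum(rs), D = D, gamma = sol$gamma,
       W = sol$cost)
}

#' Screen ligand-receptor pairs against the GRN and spatial graph
#'
#' A pair is retained when some ligand-expressing spot has a spatial
#' neighbour that expresses the receptor together with a downstream TR
#' signature: a GRN TR whose target set contains the receptor and at least
#' one of whose targets is expressed in that neighbour.  Retained pairs are
#' ranked by ascending Wasserstein distance between the ligand and receptor
#' expression distributions (per region if labels are given).
#'
#' @param grn a [build_grn] result.
#' @param lr_catalog data.frame(ligand, receptor).
#' @param expr spot x gene expression matrix.
#' @param graph a `spatial_graph` over the same spots.
#' @param regions optional named spot -> region labels; W is then computed
#'   within each region.
#' @return data.frame(ligand, receptor, region, W) sorted by ascending W
#'   (possibly empty).
#' @export
screen_lr_pairs <- function(grn, lr_catalog, expr, graph, regions = NULL) {
  empty <- data.frame(ligand = character(), receptor = character(),
                      region = character(), W = numeric())
  if (!nrow(lr_catalog)) return(empty)
  spots <- rownames(expr)
  e <- graph$edges
  adj <- lapply(seq_along(spots), function(i)
    c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))
  rows <- list()
  for (k in seq_len(nrow(lr_catalog))) {
    lig <- lr_catalog$ligand[k]; rec <- lr_catalog$receptor[k]
    if (!(lig %in% colnames(expr)) || !(rec %in% colnames(expr))) next
    trs <- unique(grn$tr[grn$target == rec])
    if (!length(trs)) next
    lig_spots <- which(expr[, lig] > 0)
    hit <- FALSE
    for (u in lig_spots) {
      for (v in adj[[u]]) {
        if (expr[v, rec] <= 0) next
        for (tr in trs) {
          tg <- intersect(grn$target[grn$tr == tr], colnames(expr))
          if (length(tg) && any(expr[v, tg] > 0)) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) break
    }
    if (!hit) next
    reg_of <- if (is.null(regions)) stats::setNames(rep("all", length(spots)),
                                                    spots) else regions
    for (reg in unique(reg_of)) {
      sp <- spots[reg_of[spots] == reg]
      lv <- expr[sp, lig]; rv <- expr[sp, rec]
      if (sum(lv) == 0 || sum(rv) == 0) next
      w <- wasserstein_lr(stats::setNames(lv, sp), stats::setNames(rv, sp),
                          graph$coords)$W
      rows[[length(rows) + 1]] <- data.frame(ligand = lig, receptor = rec,
                                             region = reg, W = w)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$W), , drop = FALSE]
}

#' Export a GRN as edge-list TSV
#' @param grn a [build_grn] result.
#' @param path output path.
#' @export
write_grn <- function(grn, path) {
  utils::write.table(grn, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
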