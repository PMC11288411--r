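# two well-separated expression programs as count blobs
blob_counts <- function(n_per = 200, n_genes = 100, seed = 3) {
  set.seed(seed)
  mu <- matrix(2, 2, n_genes)
  mu[1, 1:30] <- 20; mu[2, 31:60] <- 20
  counts <- rbind(
    matrix(rpois(n_per * n_genes, rep(mu[1, ], each = n_per)), n_per),
    matrix(rpois(n_per * n_genes, rep(mu[2, ], each = n_per)), n_per))
  dimnames(counts) <- list(paste0("c", seq_len(2 * n_per)),
                           paste0("g", seq_len(n_genes)))
  counts
}

test_that("preprocess separates two well-separated blobs at resolution 0.8", {
  counts <- blob_counts()
  pp <- preprocess(counts, seed = 1)
  truth <- rep(1:2, each = 200)
  expect_equal(length(unique(pp$labels)), 2)
  expect_equal(adjusted_rand(pp$labels, truth), 1)
})

test_that("preprocess drops all-zero genes and reduces n_pcs when needed", {
  counts <- blob_counts(n_per = 30)
  counts[, "g5"] <- 0
  expect_warning(pp <- preprocess(counts, n_pcs = 100, seed = 1),
                 "fewer cells")
  expect_false("g5" %in% colnames(pp$normalized))
})

test_that("identical cells collapse to one cluster", {
  counts <- matrix(rep(c(5, 0, 3, 1), each = 40), nrow = 40,
                   dimnames = list(paste0("c", 1:40), paste0("g", 1:4)))
  pp <- suppressWarnings(preprocess(counts, seed = 1))
  expect_equal(length(unique(pp$labels)), 1)
})

test_that("build_supercells respects target size, floor and conservation", {
  fx <- small_fixture()
  pp <- preprocess(fx$counts, seed = 1)
  part <- build_supercells(fx$counts, pp$embedding, pp$labels,
                           target_n = 30, seed = 2)
  expect_true(all(part$sizes >= 30))
  expect_equal(sum(part$sizes), nrow(fx$counts))
  expect_setequal(names(part$assignment), rownames(fx$counts))
  # aggregation conserves counts exactly
  expect_equal(colSums(part$aggregated), colSums(fx$counts))
  for (sc in sample(names(part$sizes), 3)) {
    cells <- names(part$assignment)[part$assignment == sc]
    expect_equal(part$aggregated[sc, ],
                 colSums(fx$counts[cells, , drop = FALSE]))
  }
})

test_that("three tight sub-blobs of 30 in one cluster yield 3 SuperCells", {
  set.seed(4)
  emb <- rbind(matrix(rnorm(30 * 2, 0), 30),
               matrix(rnorm(30 * 2, 20), 30),
               matrix(rnorm(30 * 2, -20), 30))
  rownames(emb) <- paste0("c", 1:90)
  counts <- matrix(rpois(90 * 50, 3), 90,
                   dimnames = list(rownames(emb), paste0("g", 1:50)))
  labels <- setNames(rep(0L, 90), rownames(emb))
  part <- build_supercells(counts, emb, labels, target_n = 30, seed = 1)
  expect_equal(length(part$sizes), 3)
  expect_true(all(part$sizes >= 30))
})

test_that("an undersized primary cluster becomes a single SuperCell", {
  set.seed(5)
  emb <- matrix(rnorm(25 * 2), 25)
  rownames(emb) <- paste0("c", 1:25)
  counts <- matrix(rpois(25 * 30, 2), 25,
                   dimnames = list(rownames(emb), paste0("g", 1:30)))
  labels <- setNames(rep(0L, 25), rownames(emb))
  part <- build_supercells(counts, emb, labels, target_n = 30, seed = 1)
  expect_equal(unname(part$sizes), 25)
  # target >= cluster size: one SuperCell too
  part2 <- build_supercells(counts, emb, labels, target_n = 100, seed = 1)
  expect_equal(length(part2$sizes), 1)
})

test_that("partitioning is deterministic and monotone in target_n", {
  fx <- small_fixture()
  pp <- preprocess(fx$counts, seed = 1)
  p1 <- build_supercells(fx$counts, pp$embedding, pp$labels, seed = 7)
  p2 <- build_supercells(fx$counts, pp$embedding, pp$labels, seed = 7)
  expect_identical(p1$assignment, p2$assignment)
  p_big <- build_supercells(fx$counts, pp$embedding, pp$labels,
                            target_n = 60, seed = 7)
  expect_lte(length(p_big$sizes), length(p1$sizes))
})

test_that("small-strategy markers are capped, enriched and floored", {
  fx <- small_fixture()
  pp <- preprocess(fx$counts, seed = 1)
  part <- build_supercells(fx$counts, pp$embedding, pp$labels, seed = 2)
  ms <- select_markers_small(part, top_k = 20, min_markers = 10)
  expect_true(all(lengths(ms$markers) <= 20))
  expect_true(all(lengths(ms$markers) >= 10))
  # a SuperCell whose profile has almost no expressed genes is excluded
  agg <- rbind(part$aggregated, poor = 0)
  agg["poor", 1:30] <- 5
  part2 <- part
  part2$aggregated <- agg
  part2$normalized_aggregated <- normalize_counts(agg)
  part2$sizes <- c(part$sizes, poor = 30)
  part2$parent_cluster <- c(part$parent_cluster, poor = 0)
  ms2 <- select_markers_small(part2)
  expect_true("poor" %in% ms2$excluded)
  expect_false("poor" %in% names(ms2$markers))
})

test_that("single SuperCell gives no contrast", {
  fx <- small_fixture()
  part <- list(normalized_aggregated =
                 fx$counts[1, , drop = FALSE])
  expect_error(select_markers_small(part), "no contrast")
})

test_that("large-strategy markers use a strict 60th-percentile rule", {
  # 2 SuperCells, 100 candidate genes with distinct values
  expr <- rbind(a = 1:100, b = c(2:101))
  colnames(expr) <- sprintf("g%03d", 1:100)
  part <- list(normalized_aggregated = log1p(expr),
               parent_cluster = c(a = 0, b = 0))
  ms <- select_markers_large(part, per_cluster_top = 100, min_markers = 10)
  # strictly above the 60th percentile of 100 distinct values -> 40 genes
  expect_equal(lengths(ms$markers)[["a"]], 40)
  # 34 passing genes -> excluded
  ms2 <- select_markers_large(part, per_cluster_top = 100,
                              min_markers = 41)
  expect_true("a" %in% ms2$excluded)
})
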