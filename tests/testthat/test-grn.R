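test_that("GRN pruning equals a brute-force correlation filter", {
  set.seed(31)
  scs <- paste0("s", 1:12)
  genes <- c("TF1", paste0("g", 1:20))
  E <- matrix(rnorm(12 * 21), 12, dimnames = list(scs, genes))
  E[, "g1"] <- E[, "TF1"] * 2 + 0.01 * rnorm(12)      # r ~ 1
  E[, "g2"] <- -E[, "TF1"] + 0.01 * rnorm(12)         # r ~ -1
  targets <- list(TF1 = list(genes = paste0("g", 1:20), rp = 20:1))
  g <- build_grn(targets, E, min_coexpr = 0.3)
  expect_true("g1" %in% g$target)
  expect_false("g2" %in% g$target)
  manual <- sapply(paste0("g", 1:20), function(x) cor(E[, "TF1"], E[, x]))
  expect_setequal(g$target, names(manual)[manual >= 0.3])
  expect_equal(g$coexpr, unname(manual[g$target]), tolerance = 1e-12)
  expect_equal(g$rp_weight, (20:1)[match(g$target, paste0("g", 1:20))])
  # monotone in the threshold; escape hatch keeps everything
  g_low <- build_grn(targets, E, min_coexpr = -1)
  expect_true(all(g$target %in% g_low$target))
  expect_equal(nrow(g_low), 20)
  # constant expression -> coexpr 0
  E2 <- E; E2[, "g3"] <- 5
  g2 <- build_grn(targets, E2, min_coexpr = 0.3)
  expect_false("g3" %in% g2$target)
})

test_that("degree centrality on the shared-target projection", {
  grn <- data.frame(
    tr = c("hub", "hub", "hub", "a", "b", "c", "d"),
    target = c("x", "y", "z", "x", "y", "z", "w"),
    rp_weight = 1, coexpr = 1)
  cent <- degree_centrality(grn, c("hub", "a", "b", "c"))
  expect_equal(cent[["hub"]], 1)
  expect_equal(cent[["a"]], 1 / 3)
  # edgeless module
  expect_equal(unname(degree_centrality(grn, c("a", "d"))), c(0, 0))
  expect_equal(unname(degree_centrality(grn, "a")), 0)
  # random module equals an independent recount
  set.seed(32)
  trs <- paste0("t", 1:6)
  rnd <- data.frame(tr = sample(trs, 40, TRUE),
                    target = sample(paste0("g", 1:8), 40, TRUE),
                    rp_weight = 1, coexpr = 1)
  cent2 <- degree_centrality(rnd, trs)
  for (a in trs) {
    deg <- sum(sapply(setdiff(trs, a), function(b)
      length(intersect(rnd$target[rnd$tr == a],
                       rnd$target[rnd$tr == b])) > 0))
    expect_equal(cent2[[a]], deg / 5)
  }
})

test_that("Wasserstein distance reproduces closed-form cases", {
  co <- rbind(a = c(0, 0), b = c(3, 4), c = c(6, 8))
  expect_equal(wasserstein_lr(c(a = 1, b = 2), c(a = 1, b = 2), co)$W, 0)
  expect_equal(wasserstein_lr(c(a = 1), c(b = 1), co)$W, 5)
  # marginal constraints hold
  w <- wasserstein_lr(c(a = 2, b = 1), c(b = 1, c = 3), co)
  expect_equal(rowSums(w$gamma), unname(w$L), tolerance = 1e-12)
  expect_equal(colSums(w$gamma), unname(w$R), tolerance = 1e-12)
  expect_equal(w$W, sum(w$gamma * w$D), tolerance = 1e-12)
  expect_error(wasserstein_lr(c(a = 0), c(b = 1), co), "zero total mass")
})

test_that("exact OT agrees with the LP vertex-enumeration oracle", {
  set.seed(33)
  for (rep in 1:15) {
    m <- sample(2:3, 1); n <- sample(2:4, 1)
    L <- runif(m, 0.1, 1); R <- runif(n, 0.1, 1)
    D <- matrix(runif(m * n), m, n)
    sol <- solve_ot(L, R, D)
    expect_equal(sol$cost, ot_oracle(L, R, D), tolerance = 1e-9)
    expect_true(all(sol$gamma >= 0))
  }
})

test_that("W satisfies metric axioms and scales with coordinates", {
  set.seed(34)
  n <- 6
  co <- matrix(runif(2 * n, 0, 10), n,
               dimnames = list(paste0("s", 1:n), c("x", "y")))
  masses <- replicate(3, {
    v <- runif(n); v[sample(n, 2)] <- 0
    setNames(v, rownames(co))
  }, simplify = FALSE)
  W <- function(a, b) wasserstein_lr(a, b, co)$W
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(W(masses[[pair[1]]], masses[[pair[2]]]),
                 W(masses[[pair[2]]], masses[[pair[1]]]),
                 tolerance = 1e-9)
  }
  expect_lte(W(masses[[1]], masses[[3]]),
             W(masses[[1]], masses[[2]]) + W(masses[[2]], masses[[3]]) +
               1e-9)
  co2 <- co * 3.5
  W2 <- wasserstein_lr(masses[[1]], masses[[2]],
                       co2)$W
  expect_equal(W2, 3.5 * W(masses[[1]], masses[[2]]), tolerance = 1e-9)
})

test_that("ligand-receptor screening requires adjacency and GRN support", {
  # 1-D chain of 6 spots; ligand on the left, receptor adjacent
  co <- cbind(x = 0:5, y = 0)
  rownames(co) <- paste0("s", 1:6)
  g <- build_snn(co, 1.1)
  genes <- c("LIG", "REC", "TF1", "tg1")
  E <- matrix(0, 6, 4, dimnames = list(rownames(co), genes))
  E[1:2, "LIG"] <- 5
  E[3, c("REC", "TF1", "tg1")] <- 4
  grn <- data.frame(tr = "TF1", target = c("REC", "tg1"),
                    rp_weight = c(8, 7), coexpr = c(0.9, 0.8))
  cat_ok <- data.frame(ligand = "LIG", receptor = "REC")
  out <- screen_lr_pairs(grn, cat_ok, E, g)
  expect_equal(nrow(out), 1)
  expect_equal(out$ligand, "LIG")
  # receptor too far away (no adjacent expressing spot): dropped
  E2 <- E; E2[3, ] <- 0; E2[6, c("REC", "TF1", "tg1")] <- 4
  expect_equal(nrow(screen_lr_pairs(grn, cat_ok, E2, g)), 0)
  # empty catalog
  expect_equal(nrow(screen_lr_pairs(grn, cat_ok[0, ], E, g)), 0)
  # planted adjacent pair ranks first among two candidates
  E3 <- cbind(E, LIG2 = c(0, 0, 0, 0, 3, 0), REC2 = c(0, 0, 0, 0, 0, 3))
  grn3 <- rbind(grn, data.frame(tr = "TF1", target = "REC2",
                                rp_weight = 5, coexpr = 0.5))
  E3[6, "tg1"] <- 1
  cat2 <- data.frame(ligand = c("LIG", "LIG2"),
                     receptor = c("REC", "REC2"))
  out2 <- screen_lr_pairs(grn3, cat2, E3, g)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$ligand[1], out2$ligand[order(out2$W)][1])
})
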