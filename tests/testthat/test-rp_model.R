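test_that("centricity classification uses a strict 20% promoter rule", {
  genes <- gene_model(paste0("g", 1:3), "chr1", "+",
                      c(1e5, 2e5, 3e5), c(1e5, 2e5, 3e5) + 2000)
  near <- function(n) genes$tss[1] + seq_len(n) * 100      # in promoter
  far <- function(n) 5e5 + seq_len(n) * 50000              # nowhere near
  expect_equal(
    classify_centricity(toy_cistrome(c(near(3), far(7))), genes),
    list(centricity = "promoter", d0 = 1000, promoter_fraction = 0.3))
  cls20 <- classify_centricity(toy_cistrome(c(near(2), far(8))), genes)
  expect_equal(cls20$centricity, "enhancer")
  expect_equal(cls20$d0, 10000)
  expect_equal(
    classify_centricity(toy_cistrome(far(5)), genes)$centricity,
    "enhancer")
  expect_error(
    classify_centricity(toy_cistrome(numeric(0)), genes), "empty")
})

test_that("compute_rp reproduces the decay closed forms", {
  g <- toy_gene(1e6)
  for (d0 in c(1000, 10000)) {
    expect_equal(compute_rp(toy_cistrome(1e6), g, d0), 1)
    expect_equal(compute_rp(toy_cistrome(1e6 + d0), g, d0), 0.5)
    expect_equal(compute_rp(toy_cistrome(1e6 + c(0, d0, 2 * d0)), g, d0),
                 1.75)
    rp15 <- compute_rp(toy_cistrome(1e6 + 15 * d0), g, d0)
    expect_equal(rp15, 2^-15)
    expect_lt(rp15, 0.0005)
    # just beyond the range: contributes 0
    expect_equal(compute_rp(toy_cistrome(1e6 + 15 * d0 + 1), g, d0), 0)
  }
})

test_that("compute_rp matches a no-cutoff brute-force oracle within bound", {
  set.seed(5)
  g <- toy_gene(5e5)
  for (rep in 1:20) {
    centers <- round(runif(50, 0, 1e6))
    d0 <- sample(c(1000, 10000), 1)
    cis <- toy_cistrome(centers)
    oracle <- sum(2^(-abs(centers - g$tss) / d0))
    n_out <- sum(abs(centers - g$tss) > 15 * d0)
    expect_lte(abs(compute_rp(cis, g, d0) - oracle), n_out * 2^-15 + 1e-12)
  }
})

test_that("compute_rp is translation invariant and decays monotonically", {
  g <- toy_gene(2e5)
  centers <- 2e5 + c(-3000, 500, 9000)
  base <- compute_rp(toy_cistrome(centers), g, 1e4)
  shift <- 123456
  expect_equal(
    compute_rp(toy_cistrome(centers + shift), toy_gene(2e5 + shift), 1e4),
    base)
  ds <- seq(0, 15000, by = 1000)
  rps <- vapply(ds, function(d)
    compute_rp(toy_cistrome(2e5 + d), g, 1e4), numeric(1))
  expect_true(all(diff(rps) < 0))
})

test_that("enhanced RP applies exon and neighbour-promoter rules", {
  # gene with one 2000-bp exon starting at its TSS
  g <- gene_model("g1", "chr1", "+", 1e5, 1e5 + 2000)
  nb <- gene_model("g2", "chr1", "+", 1e5 + 30000, 1e5 + 32000)
  both <- rbind(g, nb); class(both) <- class(g)

  in_exon <- toy_cistrome(1e5 + 1000)
  expect_equal(compute_rp_enhanced(in_exon, g[1, ], both, 1e4), 1 / 2000)
  in_nb_prom <- toy_cistrome(1e5 + 30000 - 500)
  expect_equal(compute_rp_enhanced(in_nb_prom, g[1, ], both, 1e4), 0)
  in_nb_exon <- toy_cistrome(1e5 + 31000)
  expect_equal(compute_rp_enhanced(in_nb_exon, g[1, ], both, 1e4), 0)
  intergenic <- toy_cistrome(1e5 - 1e4)   # d0 away, outside everything
  expect_equal(compute_rp_enhanced(intergenic, g[1, ], both, 1e4), 0.5)

  g0 <- g; g0$exon_starts[[1]] <- g0$exon_ends[[1]] <- 1e5
  expect_error(compute_rp_enhanced(in_exon, g0[1, ], both, 1e4),
               "exon length")
})

test_that("select_targets follows the >5 threshold with the 300 fallback", {
  set.seed(8)
  rp <- setNames(runif(1000, 6, 50), sprintf("g%04d", 1:1000))
  out <- select_targets(rp)
  expect_equal(length(out$genes), 1000)       # all above threshold
  expect_true(all(diff(out$rp) <= 0))

  rp2 <- setNames(c(runif(50, 6, 50), runif(9950, 0, 4)),
                  sprintf("g%05d", 1:10000))
  out2 <- select_targets(rp2)
  expect_equal(length(out2$genes), 300)
  expect_true(all(names(rp2)[1:50] %in% out2$genes))

  rp3 <- setNames(rep(0, 500), sprintf("g%03d", 500:1))
  expect_warning(out3 <- select_targets(rp3), NA)
  expect_equal(length(out3$genes), 300)
  expect_equal(out3$genes, sort(names(rp3))[1:300])  # lexicographic ties

  expect_warning(out4 <- select_targets(setNames(runif(100), 1:100)),
                 "fewer genes")
  expect_equal(length(out4$genes), 100)
})

test_that("select_targets output size matches the stated formula", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(50:800, 1)
    rp <- setNames(runif(n, 0, 10), paste0("g", seq_len(n)))
    res <- suppressWarnings(select_targets(rp))
    expect_equal(length(res$genes),
                 max(sum(rp > 5), min(300, n)))
  }
})

test_that("rp_matrix fixes d0 per cistrome and matches per-gene calls", {
  fx <- small_fixture()
  cis <- fx$cistromes[[1]]
  m <- rp_matrix(list(cis), fx$genes, enhanced = FALSE)
  d0 <- attr(m, "d0")[[1]]
  gi <- sample(nrow(fx$genes), 5)
  for (g in gi)
    expect_equal(m[1, g], compute_rp(cis, fx$genes[g, ], d0))
})
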