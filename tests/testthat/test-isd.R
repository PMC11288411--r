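# one-chromosome profile with unit signal in chosen bins
unit_profile <- function(bins, n_bins = 400, id = "p1", assay = "dnase") {
  v <- numeric(n_bins)
  v[bins] <- 1
  chromatin_profile(id, assay, list(chr1 = v))
}

# gene whose TSS sits exactly at the centre of bin `b` (1-based)
gene_at_bin <- function(b) toy_gene((b - 1) * 1000 + 500)

test_that("chrom_rp reproduces the decay-weighted window sums", {
  g <- gene_at_bin(200)
  expect_equal(chrom_rp(unit_profile(integer(0)), g), 0)
  expect_equal(chrom_rp(unit_profile(200), g), 1)           # w0 = 1
  expect_equal(chrom_rp(unit_profile(c(190, 210)), g), 1)   # 2 x 2^-1
  # 100 kb + 1 bin away: outside L
  expect_equal(chrom_rp(unit_profile(200 + 101), g), 0)
  # boundary bin at exactly 100 kb contributes 2^-10
  expect_equal(chrom_rp(unit_profile(300), g), 2^-10)
})

test_that("in_silico_delete erases peak bins and bounds deltaRP", {
  g <- gene_at_bin(200)
  genes <- g
  prof <- unit_profile(190:210)
  # no peaks near the gene
  far <- toy_cistrome(350 * 1000)
  expect_equal(unname(in_silico_delete(prof, far, genes)), 0)
  # a peak in the TSS bin of a unit-signal profile: deltaRP = 1
  tss_peak <- toy_cistrome(199 * 1000 + 500)
  expect_equal(unname(in_silico_delete(unit_profile(200), tss_peak, genes)),
               1)
  # peaks covering every signal bin: deltaRP = full chrom-RP
  wide <- cistrome("T", "d", data.frame(chrom = "chr1", start = 0,
                                        end = 400000, fold = 10))
  expect_equal(unname(in_silico_delete(prof, wide, genes)),
               chrom_rp(prof, g))
  # monotone in added peaks; bounded by chrom-RP
  set.seed(6)
  for (rep in 1:10) {
    c1 <- toy_cistrome(sort(sample(1:400, 5)) * 1000 - 500)
    extra <- rbind(c1$intervals,
                   toy_cistrome(sample(1:400, 3) * 1000 - 500)$intervals)
    c2 <- cistrome("T", "d2", extra)
    d1 <- in_silico_delete(prof, c1, genes)
    d2 <- in_silico_delete(prof, c2, genes)
    expect_gte(d2, d1 - 1e-12)
    expect_lte(d1, chrom_rp(prof, g) + 1e-12)
    expect_gte(d1, 0)
  }
})

test_that("fragment merging respects the 1000-bp cap", {
  m <- trforge:::merge_capped(c(100, 300), c(500, 700), 1000)
  expect_equal(nrow(m), 1)
  expect_lte(max(m$end - m$start), 1000)
  # chain spanning 2500 bp -> >= 3 pieces, each <= 1000
  m2 <- trforge:::merge_capped(c(0, 800, 1600), c(900, 1700, 2500), 1000)
  expect_gte(nrow(m2), 3)
  expect_true(all(m2$end - m2$start <= 1000))
  expect_equal(m2$start[1], 0)
  expect_equal(max(m2$end), 2500)
})

test_that("paired landscapes bin per-SuperCell coverage and skip unknowns", {
  part <- list(assignment = c(cellA = "sc1", cellB = "sc1", cellC = "sc2"),
               sizes = c(sc1 = 2, sc2 = 1))
  frags <- data.frame(
    chrom = "chr1",
    start = c(100, 300, 5000, 99999),
    end = c(500, 700, 5400, 100399),
    barcode = c("cellA", "cellB", "cellC", "ghost"))
  lands <- build_paired_landscape(frags, part, c(chr1 = 400000))
  expect_equal(attr(lands, "n_skipped"), 1)
  expect_equal(lands$sc1$signal$chr1[1], 0.6)   # merged [100,700) in bin 1
  expect_equal(sum(lands$sc2$signal$chr1), 0.4)
  empty_part <- list(assignment = c(cellA = "sc1"), sizes = c(sc1 = 1))
  lands2 <- build_paired_landscape(frags[0, ], empty_part,
                                   c(chr1 = 400000))
  expect_equal(sum(lands2$sc1$signal$chr1), 0)
})

test_that("landscape selection finds a planted separating sample", {
  set.seed(10)
  genes <- paste0("g", 1:200)
  query <- genes[1:40]; bg <- genes[101:200]
  n_samp <- 8
  chromrp <- matrix(runif(200 * n_samp), 200, n_samp,
                    dimnames = list(genes, paste0("samp", 1:n_samp)))
  chromrp[query, "samp3"] <- chromrp[query, "samp3"] + 3  # separator
  sel <- select_landscape(chromrp, query, bg, k_samples = 2)
  expect_true("samp3" %in% sel)
  expect_lte(length(sel), 2)
  # k >= total samples: everything comes back
  expect_equal(select_landscape(chromrp, query, bg, k_samples = 20),
               sort(colnames(chromrp)))
  expect_warning(
    one <- select_landscape(chromrp[, 1, drop = FALSE], query, bg),
    "fewer than 2")
  expect_equal(one, "samp1")
})

test_that("one-sided Wilcoxon matches exact enumeration and calibrates", {
  # complete separation, n = m = 10: exact p = 1 / choose(20, 10)
  p <- wilcox_greater_p(11:20, 1:10)
  expect_equal(p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(wilcox_greater_p(rep(3, 8), rep(3, 9)), 1)
  # type-I error calibration under the null
  set.seed(13)
  rej <- mean(replicate(1000, {
    wilcox_greater_p(rnorm(20), rnorm(20)) < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("Cauchy combination equals the distribution-function oracle", {
  # independent oracle via R's Cauchy quantile/CDF
  oracle <- function(p) {
    stats::pcauchy(mean(stats::qcauchy(1 - p)), lower.tail = FALSE)
  }
  set.seed(14)
  for (rep in 1:50) {
    p <- runif(sample(2:8, 1), 1e-6, 1)
    expect_equal(cauchy_combine(p), oracle(p), tolerance = 1e-12)
  }
  expect_equal(cauchy_combine(rep(0.031, 3)), 0.031, tolerance = 1e-12)
  expect_equal(cauchy_combine(numeric(0)), 1)
  expect_gte(cauchy_combine(c(1e-320, 0.5)), 1e-300)
})

test_that("rank_tr favours a planted regulator over a decoy", {
  fx <- small_fixture()
  genes <- fx$genes
  tr_a <- names(fx$regulons)[1]
  query <- fx$regulons[[tr_a]]
  background <- setdiff(genes$gene_id, unlist(fx$regulons))[1:50]
  prof <- fx$profiles[[1]]  # group 1: TR A active
  peak_rp <- rp_matrix(fx$cistromes, genes, enhanced = FALSE)
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    dstart <- sort(sample.int(fx$chrom_lengths[[1]] - 400, 60))
    decoy <- cistrome("decoy", "decoy_ds", data.frame(
      chrom = "chrS", start = dstart, end = dstart + 300, fold = 10))
    decoy_rp <- rp_matrix(list(decoy), genes, enhanced = FALSE)
    pa <- rank_tr(peak_rp[1, ],
                  list(d1 = in_silico_delete(prof, fx$cistromes[[1]], genes)),
                  query, background)
    pb <- rank_tr(decoy_rp[1, ],
                  list(d1 = in_silico_delete(prof, decoy, genes)),
                  query, background)
    pa$p_summary < pb$p_summary
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("chunked ISD equals unchunked ISD exactly", {
  fx <- small_fixture()
  pp <- preprocess(fx$counts, seed = 1)
  part <- build_supercells(fx$counts, pp$embedding, pp$labels, seed = 2)
  markers <- select_markers_small(part)$markers
  peak_rp <- rp_matrix(fx$cistromes, fx$genes, enhanced = FALSE)
  bg <- sample_background(fx$genes, n = 80, seed = 3)
  run <- function(chunks) isd_score(peak_rp, fx$cistromes,
                                    unname(fx$profiles), markers,
                                    fx$genes, bg, k_samples = 2,
                                    chunks = chunks, seed = 4)
  expect_identical(run(1)$p_summary, run(8)$p_summary)
})
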