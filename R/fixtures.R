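#' Synthetic fixtures with planted regulatory programs
#'
#' Generates every input the pipeline consumes, without downloads: a toy
#' one-chromosome genome annotation (optionally with sequence), TR
#' cistromes whose peaks concentrate near their regulon genes' TSSs,
#' negative-binomial expression counts in which each group up-regulates
#' the targets of its active TRs, and chromatin profiles / fragments whose
#' signal is enriched over active TRs' peaks.  All generators are
#' deterministic given their seed.
#'
#' @name synthetic_fixtures
NULL

#' Generate a toy genome annotation
#'
#' Genes are laid out on one chromosome with TSS spacing >= 30 kb and 2-8
#' exons each.
#'
#' @param n_genes number of genes.
#' @param chrom_length chromosome length (bp); must be >= 50 kb per gene.
#' @param seed RNG seed.
#' @param fasta also generate a random sequence (a
#'   [Biostrings::DNAStringSet]); default FALSE.
#' @return list(genes = [gene_model], chrom_lengths, fasta or NULL).
#' @export
make_genome <- function(n_genes, chrom_length = n_genes * 52000,
                        seed = 0, fasta = FALSE) {
  if (n_genes * 50000 > chrom_length) stop("overcrowded genome")
  set.seed(seed)
  spacing <- floor((chrom_length - 60000) / n_genes)
  anchors <- 30000 + (seq_len(n_genes) - 1) * spacing +
    sample(0:2000, n_genes, replace = TRUE)
  widths <- sample(2000:8000, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  exon_starts <- vector("list", n_genes)
  exon_ends <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    k <- sample(2:8, 1)
    cuts <- sort(sample(seq(100, widths[i] - 100, by = 50), 2 * k - 2))
    bounds <- c(0, cuts, widths[i])
    es <- bounds[seq(1, 2 * k - 1, by = 2)]
    ee <- bounds[seq(2, 2 * k, by = 2)]
    exon_starts[[i]] <- anchors[i] + es
    exon_ends[[i]] <- anchors[i] + ee
  }
  genes <- gene_model(sprintf("g%04d", seq_len(n_genes)),
                      rep("chrS", n_genes), strand,
                      anchors, anchors + widths, exon_starts, exon_ends)
  fa <- NULL
  if (fasta) {
    fa <- Biostrings::DNAStringSet(paste(
      sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
      collapse = ""))
    names(fa) <- "chrS"
  }
  list(genes = genes, chrom_lengths = c(chrS = chrom_length), fasta = fa)
}

#' Plant TR cistromes around regulon genes
#'
#' @param genes a [gene_model].
#' @param regulons named list TR symbol -> target gene ids (TR symbols
#'   should themselves be gene ids so TR expression exists downstream).
#' @param peaks_per_target peaks placed within `max_dist` of each target
#'   TSS; default 3.
#' @param max_dist TSS neighbourhood for planted peaks (bp); default 5000.
#' @param decoy_frac uniform decoy peaks as a fraction of planted peaks;
#'   default 0.3.
#' @param chrom_lengths named chromosome lengths.
#' @param seed RNG seed.
#' @return list of [cistrome]s (all folds >= 5).
#' @export
make_cistromes <- function(genes, regulons, peaks_per_target = 3,
                           max_dist = 5000, decoy_frac = 0.3,
                           chrom_lengths, seed = 0) {
  set.seed(seed)
  lapply(names(regulons), function(tr) {
    tg <- regulons[[tr]]
    tss <- genes$tss[match(tg, genes$gene_id)]
    chrom <- genes$chrom[match(tg, genes$gene_id)]
    ctr <- rep(tss, each = peaks_per_target) +
      sample(-max_dist:max_dist, length(tss) * peaks_per_target,
             replace = TRUE)
    chrom <- rep(chrom, each = peaks_per_target)
    n_dec <- ceiling(length(ctr) * decoy_frac)
    if (n_dec > 0) {
      dchrom <- sample(names(chrom_lengths), n_dec, replace = TRUE)
      dctr <- vapply(dchrom, function(ch)
        sample.int(chrom_lengths[[ch]] - 1000, 1) + 500, numeric(1))
      ctr <- c(ctr, dctr); chrom <- c(chrom, dchrom)
    }
    hw <- sample(100:200, length(ctr), replace = TRUE)
    cistrome(tr, paste0(tr, "_ds"),
             data.frame(chrom = chrom,
                        start = pmax(0, ctr - hw), end = ctr + hw,
                        fold = stats::runif(length(ctr), 5, 20)))
  })
}

#' Simulate grouped expression counts with planted regulon activity
#'
#' Baseline negative-binomial counts per gene; in each group, the targets
#' of its active TRs (and the TR genes themselves) are shifted up by
#' `effect_size` in log2 space.  In spatial mode cells are laid on a grid
#' and groups occupy contiguous bands.
#'
#' @param genes a [gene_model].
#' @param regulons named list TR -> target gene ids.
#' @param active named list group -> active TR symbols; groups are
#'   "grp1".."grpG".
#' @param n_cells total cells; default 900.
#' @param effect_size log2 fold-change of active targets; default 2.
#' @param dispersion NB dispersion (1/size); default 0.3.
#' @param base_mean mean of the baseline log-normal expression; default 1.
#' @param spatial lay groups out as contiguous grid bands; default FALSE.
#' @param seed RNG seed.
#' @return list(counts (cell x gene), labels, coords or NULL).
#' @export
make_expression <- function(genes, regulons, active, n_cells = 900,
                            effect_size = 2, dispersion = 0.3,
                            base_mean = 1, spatial = FALSE, seed = 0) {
  groups <- names(active)
  stopifnot(length(groups) >= 2)
  set.seed(seed)
  n_genes <- nrow(genes)
  gmu <- base_mean * stats::rlnorm(n_genes, sdlog = 0.5)
  names(gmu) <- genes$gene_id
  per_group <- rep(floor(n_cells / length(groups)), length(groups))
  per_group[1] <- per_group[1] + n_cells - sum(per_group)
  labels <- rep(groups, per_group)
  counts <- matrix(0L, n_cells, n_genes,
                   dimnames = list(sprintf("cell%04d", seq_len(n_cells)),
                                   genes$gene_id))
  for (g in seq_along(groups)) {
    mu <- gmu
    up <- unique(c(unlist(regulons[active[[groups[g]]]]),
                   active[[groups[g]]]))
    mu[up] <- mu[up] * 2^effect_size
    rows <- which(labels == groups[g])
    counts[rows, ] <- matrix(
      stats::rnbinom(length(rows) * n_genes,
                     mu = rep(mu, each = length(rows)),
                     size = 1 / dispersion),
      nrow = length(rows))
  }
  names(labels) <- rownames(counts)
  coords <- NULL
  if (spatial) {
    side <- ceiling(sqrt(n_cells))
    xy <- cbind(x = (seq_len(n_cells) - 1) %% side,
                y = (seq_len(n_cells) - 1) %/% side)
    # contiguous bands: order cells by group, then fill the grid row-wise
    ord <- order(match(labels, groups))
    coords <- matrix(NA_real_, n_cells, 2,
                     dimnames = list(rownames(counts), c("x", "y")))
    coords[rownames(counts)[ord], ] <- xy
  }
  list(counts = counts, labels = labels, coords = coords)
}

# bp coverage of [start,end) intervals on a bin grid, in units of bins
bin_coverage <- function(start, end, n_bins, bin_size) {
  v <- numeric(n_bins)
  for (i in seq_along(start)) {
    b0 <- max(1, floor(start[i] / bin_size) + 1)
    b1 <- min(n_bins, ceiling(end[i] / bin_size))
    if (b1 < b0) next
    for (b in b0:b1) {
      ov <- min(end[i], b * bin_size) - max(start[i], (b - 1) * bin_size)
      v[b] <- v[b] + ov / bin_size
    }
  }
  v
}

#' Bin raw fragments into a chromatin profile (no merging)
#'
#' Conserves mass: sum(signal) = sum(fragment lengths) / bin_size.
#'
#' @param fragments data.frame(chrom, start, end).
#' @param chrom_lengths named chromosome lengths.
#' @param sample_id,assay profile metadata.
#' @param bin_size bin width; default 1000.
#' @return a `chromatin_profile`.
#' @export
fragments_to_profile <- function(fragments, chrom_lengths,
                                 sample_id = "frag", assay = "atac_supercell",
                                 bin_size = 1000) {
  signal <- lapply(names(chrom_lengths), function(ch) {
    sub <- fragments[fragments$chrom == ch, , drop = FALSE]
    bin_coverage(sub$start, sub$end, ceiling(chrom_lengths[[ch]] / bin_size),
                 bin_size)
  })
  names(signal) <- names(chrom_lengths)
  chromatin_profile(sample_id, assay, signal, bin_size)
}

#' Simulate per-group chromatin profiles and per-cell fragments
#'
#' Each group's profile has Poisson background noise plus enrichment in
#' the 1-kb bins overlapping the peaks of that group's active TRs;
#' fragments are sampled per cell proportional to the group signal.
#'
#' @param cistromes list of [cistrome]s (named by TR symbol or with
#'   tr_name set).
#' @param active named list group -> active TR symbols.
#' @param labels named cell -> group vector (for fragment generation).
#' @param chrom_lengths named chromosome lengths.
#' @param noise_rate Poisson background mean per bin; default 0.2.
#' @param enrich added signal on active peak bins; default 5.
#' @param frags_per_cell fragments sampled per cell; default 100.
#' @param frag_len fragment length (bp); default 300.
#' @param assay assay tag for the group profiles; default "dnase".
#' @param bin_size bin width; default 1000.
#' @param seed RNG seed.
#' @return list(profiles = named list group -> `chromatin_profile`,
#'   fragments = data.frame(chrom, start, end, barcode)).
#' @export
make_profiles <- function(cistromes, active, labels, chrom_lengths,
                          noise_rate = 0.2, enrich = 5,
                          frags_per_cell = 100, frag_len = 300,
                          assay = "dnase", bin_size = 1000, seed = 0) {
  set.seed(seed)
  trs <- vapply(cistromes, `[[`, "", "tr_name")
  profiles <- lapply(names(active), function(grp) {
    signal <- lapply(names(chrom_lengths), function(ch) {
      nb <- ceiling(chrom_lengths[[ch]] / bin_size)
      v <- stats::rpois(nb, noise_rate)
      for (tr in active[[grp]]) {
        cis <- cistromes[[which(trs == tr)[1]]]
        pk <- cis$intervals[cis$intervals$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(pk))) {
          b0 <- max(1, floor(pk$start[i] / bin_size) + 1)
          b1 <- min(nb, ceiling(pk$end[i] / bin_size))
          if (b1 >= b0) v[b0:b1] <- v[b0:b1] + enrich
        }
      }
      as.numeric(v)
    })
    names(signal) <- names(chrom_lengths)
    chromatin_profile(paste0("prof_", grp), assay, signal, bin_size)
  })
  names(profiles) <- names(active)
  frags <- list()
  for (cell in names(labels)) {
    prof <- profiles[[labels[[cell]]]]
    ch <- names(chrom_lengths)[1]
    w <- prof$signal[[ch]] + 1e-6
    bins <- sample.int(length(w), frags_per_cell, replace = TRUE,
                       prob = w / sum(w))
    start <- (bins - 1) * bin_size +
      sample.int(bin_size, frags_per_cell, replace = TRUE) - 1
    frags[[cell]] <- data.frame(chrom = ch, start = start,
                                end = pmin(start + frag_len,
                                           chrom_lengths[[ch]]),
                                barcode = cell)
  }
  list(profiles = profiles, fragments = do.call(rbind, frags))
}

#' Default end-to-end fixture
#'
#' The stated world of the validation suite: 300 genes, 900 cells, 3
#' groups, 3 TRs with 50-gene regulons, log2 effect size 2, NB dispersion
#' 0.3.  TR symbols are the first gene of each regulon's complement so
#' that TR expression is observable.
#'
#' @param seed RNG seed.
#' @param n_genes,n_cells,n_groups,n_trs,regulon_size,effect_size
#'   fixture-scale parameters (defaults as above).
#' @param spatial generate grid coordinates; default FALSE.
#' @return list(genes, chrom_lengths, regulons, active, cistromes, counts,
#'   labels, coords, profiles, fragments).
#' @export
fixture_preset <- function(seed = 0, n_genes = 300, n_cells = 900,
                           n_groups = 3, n_trs = 3, regulon_size = 50,
                           effect_size = 2, spatial = FALSE) {
  gen <- make_genome(n_genes, seed = seed)
  set.seed(seed + 1)
  ids <- gen$genes$gene_id
  tr_genes <- ids[seq_len(n_trs)]
  pool <- setdiff(ids, tr_genes)
  regulons <- list()
  for (t in seq_len(n_trs)) {
    regulons[[tr_genes[t]]] <- sort(sample(pool, regulon_size))
    pool <- setdiff(pool, regulons[[tr_genes[t]]])
  }
  active <- stats::setNames(
    lapply(seq_len(n_groups), function(g)
      tr_genes[((g - 1) %% n_trs) + 1]),
    paste0("grp", seq_len(n_groups)))
  cistromes <- make_cistromes(gen$genes, regulons,
                              chrom_lengths = gen$chrom_lengths,
                              seed = seed + 2)
  expr <- make_expression(gen$genes, regulons, active, n_cells = n_cells,
                          effect_size = effect_size, spatial = spatial,
                          seed = seed + 3)
  prof <- make_profiles(cistromes, active, expr$labels, gen$chrom_lengths,
                        seed = seed + 4)
  c(gen[c("genes", "chrom_lengths")],
    list(regulons = regulons, active = active, cistromes = cistromes,
         counts = expr$counts, labels = expr$labels, coords = expr$coords,
         profiles = prof$profiles, fragments = prof$fragments))
}
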