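#' End-to-end runs
#'
#' [run_pipeline] chains preprocessing, (optionally) the spatial
#' auto-encoder, SuperCell construction, marker selection, chromatin
#' landscape construction, in-silico deletion, TR activity scoring and GRN
#' assembly, with one global seed fanned out to per-stage seeds.
#'
#' @name pipeline_cli
NULL

#' Pipeline configuration with the published defaults
#'
#' @param mode "rna_only", "multiome" or "spatial".
#' @param seed global RNG seed.
#' @param n_neighbors,n_pcs,resolution preprocessing defaults (10, 40,
#'   0.8).
#' @param target_n,min_size SuperCell sizing (30, 30).
#' @param top_k,min_markers marker selection (500, 35).
#' @param large_markers use the large-dataset marker strategy; default
#'   FALSE (recommended above 150 000 cells).
#' @param alpha spatial attention weight (0.5).
#' @param radius spatial neighbour radius; NULL = 1.5 x median spacing.
#' @param rp_threshold,fallback_n target selection (5, 300).
#' @param k_samples,chunks ISD (10, 8).
#' @param n_background background gene count (3000, capped at the
#'   annotation size).
#' @param min_coexpr GRN pruning threshold (0.3).
#' @param enhanced_rp use the exon/neighbour-aware RP model (TRUE).
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("rna_only", "multiome", "spatial"),
                       seed = 0, n_neighbors = 10, n_pcs = 40,
                       resolution = 0.8, target_n = 30, min_size = 30,
                       top_k = 500, min_markers = 35, large_markers = FALSE,
                       alpha = 0.5, radius = NULL, rp_threshold = 5,
                       fallback_n = 300, k_samples = 10, chunks = 8,
                       n_background = 3000, min_coexpr = 0.3,
                       enhanced_rp = TRUE) {
  structure(list(mode = match.arg(mode), seed = seed,
                 n_neighbors = n_neighbors, n_pcs = n_pcs,
                 resolution = resolution, target_n = target_n,
                 min_size = min_size, top_k = top_k,
                 min_markers = min_markers, large_markers = large_markers,
                 alpha = alpha, radius = radius,
                 rp_threshold = rp_threshold, fallback_n = fallback_n,
                 k_samples = k_samples, chunks = chunks,
                 n_background = n_background, min_coexpr = min_coexpr,
                 enhanced_rp = enhanced_rp),
            class = "run_config")
}

#' Run the full pipeline
#'
#' @param config a [run_config].
#' @param inputs list with elements `counts` (cell x gene), `genes`
#'   ([gene_model]), `cistromes` (list of [cistrome]), and per mode:
#'   `profiles` (reference landscapes; rna_only/spatial), `fragments` +
#'   `chrom_lengths` (multiome), `coords` (spatial).
#' @param out_dir optional output directory for TSV artifacts and a JSON
#'   manifest; reruns with the same config and inputs are byte-identical.
#' @return list(partition, markers, targets, isd, activity, grn, config).
#' @export
run_pipeline <- function(config, inputs, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  need <- c("counts", "genes", "cistromes",
            switch(config$mode,
                   rna_only = "profiles",
                   multiome = c("fragments", "chrom_lengths"),
                   spatial = c("coords", "profiles")))
  missing <- setdiff(need, names(inputs))
  if (length(missing))
    stop("missing required input for mode ", config$mode, ": ",
         paste(missing, collapse = ", "))
  seed <- config$seed
  counts <- as.matrix(inputs$counts)

  pp <- preprocess(counts, config$n_neighbors, config$n_pcs,
                   config$resolution, seed = seed + 1)
  embedding <- pp$embedding; labels <- pp$labels
  if (config$mode == "spatial") {
    r <- if (is.null(config$radius)) auto_radius(inputs$coords) else
      config$radius
    sg <- build_snn(inputs$coords[rownames(counts), , drop = FALSE], r)
    sg <- prune_aware(sg, pp$labels)
    gat <- fit_gat_autoencoder(pp$normalized, sg, alpha = config$alpha,
                               seed = seed + 2)
    embedding <- gat$embedding
    graph <- snn_graph(embedding, config$n_neighbors)
    labels <- leiden_cluster(graph, config$resolution, seed + 3)
  }

  partition <- build_supercells(counts, embedding, labels,
                                target_n = config$target_n,
                                min_size = config$min_size,
                                seed = seed + 4,
                                n_neighbors = config$n_neighbors)
  markers <- if (config$large_markers)
    select_markers_large(partition, min_markers = config$min_markers)
  else select_markers_small(partition, top_k = config$top_k,
                            min_markers = config$min_markers)

  peak_rp <- rp_matrix(inputs$cistromes, inputs$genes,
                       enhanced = config$enhanced_rp)
  targets <- lapply(rownames(peak_rp), function(ds)
    select_targets(peak_rp[ds, ], config$rp_threshold, config$fallback_n))
  names(targets) <- rownames(peak_rp)

  background <- sample_background(
    inputs$genes, exclude = character(),
    n = config$n_background, seed = seed + 5)

  if (config$mode == "multiome") {
    landscapes <- build_paired_landscape(inputs$fragments, partition,
                                         inputs$chrom_lengths)
    isd <- isd_score(peak_rp, inputs$cistromes, landscapes,
                     markers$markers, inputs$genes, background,
                     k_samples = config$k_samples, chunks = config$chunks,
                     paired = TRUE, seed = seed + 6)
  } else {
    isd <- isd_score(peak_rp, inputs$cistromes, inputs$profiles,
                     markers$markers, inputs$genes, background,
                     k_samples = config$k_samples, chunks = config$chunks,
                     paired = FALSE, seed = seed + 6)
  }

  E <- partition$normalized_aggregated[rownames(isd$p_summary), ,
                                       drop = FALSE]
  tr_of <- vapply(inputs$cistromes, `[[`, "", "tr_name")
  names(tr_of) <- vapply(inputs$cistromes, `[[`, "", "dataset_id")
  activity <- tr_activity(isd$p_summary, E, targets, tr_of)

  tr_targets <- lapply(split(names(tr_of), unname(tr_of)), function(dss) {
    targets[[dss[1]]]
  })
  grn <- build_grn(tr_targets, E, min_coexpr = config$min_coexpr)

  result <- list(partition = partition, markers = markers,
                 targets = targets, isd = isd, activity = activity,
                 grn = grn, config = config)
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_activity(result$activity, out_dir)
  write_grn(result$grn, file.path(out_dir, "grn.tsv"))
  utils::write.table(
    data.frame(barcode = names(result$partition$assignment),
               supercell = unname(result$partition$assignment)),
    file.path(out_dir, "supercells.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  files <- c("tf_score.tsv", "P_value_matrix.tsv", "grn.tsv",
             "supercells.tsv")
  manifest <- list(
    package = "trforge",
    version = as.character(utils::packageVersion("trforge")),
    mode = result$config$mode, seed = result$config$seed,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
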