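#' TR cistromes and the reference container
#'
#' A cistrome is one TR binding-interval set (ChIP-seq peaks or motif
#' pseudo-peaks) with its provenance.  Intervals are 0-based half-open and
#' kept sorted by (chrom, start).
#'
#' @param tr_name TR (transcription factor / chromatin regulator) symbol.
#' @param dataset_id unique dataset identifier.
#' @param intervals data.frame with columns chrom, start, end, fold
#'   (fold enrichment over background, >= 0).
#' @param species species tag, e.g. "synthetic".
#' @param source "chipseq" or "motif".
#' @return a `cistrome` object.
#' @export
cistrome <- function(tr_name, dataset_id, intervals, species = "synthetic",
                     source = c("chipseq", "motif")) {
  source <- match.arg(source)
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "fold") %in% names(intervals)))
  if (nrow(intervals)) {
    stopifnot(all(intervals$end > intervals$start),
              all(intervals$fold >= 0))
    intervals <- intervals[order(intervals$chrom, intervals$start), ,
                           drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(list(tr_name = tr_name, dataset_id = dataset_id,
                 species = species, intervals = intervals, source = source),
            class = "cistrome")
}

#' @export
print.cistrome <- function(x, ...) {
  cat(sprintf("<cistrome> %s (%s, %s): %d intervals\n",
              x$dataset_id, x$tr_name, x$source, nrow(x$intervals)))
  invisible(x)
}

peak_centers <- function(cis) {
  (cis$intervals$start + cis$intervals$end) / 2
}

#' Quality-control filter for ChIP-seq-style datasets
#'
#' Retains datasets meeting all sequencing / peak-quality thresholds:
#' median base quality > 25, uniquely mapped read fraction > 0.5, PCR
#' bottleneck coefficient > 0.8, more than 100 peaks at 10-fold enrichment,
#' fraction of reads in peaks > 0.01, top-5000-peak DHS overlap > 0.7, and
#' at least 1000 peaks (datasets with fewer than 1000 peaks are excluded).
#'
#' @param records data.frame with columns dataset_id, median_quality,
#'   unique_map_rate, pbc, n_peaks_10fold, frip, dhs_overlap_top5000,
#'   n_peaks.
#' @return character vector of retained dataset_ids, input order preserved.
#' @export
qc_filter <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no datasets")
  keep <- records$median_quality > 25 &
    records$unique_map_rate > 0.5 &
    records$pbc > 0.8 &
    records$n_peaks_10fold > 100 &
    records$frip > 0.01 &
    records$dhs_overlap_top5000 > 0.7 &
    records$n_peaks >= 1000
  as.character(records$dataset_id[keep])
}

#' Drop peaks below a fold-enrichment floor
#'
#' @param cis a `cistrome`.
#' @param min_fold minimum fold enrichment (inclusive); default 5.
#' @return the filtered `cistrome` (possibly with zero intervals).
#' @export
filter_peaks <- function(cis, min_fold = 5) {
  stopifnot(inherits(cis, "cistrome"), nrow(cis$intervals) >= 1)
  cis$intervals <- cis$intervals[cis$intervals$fold >= min_fold, ,
                                 drop = FALSE]
  rownames(cis$intervals) <- NULL
  cis
}

#' Assemble a TR reference from filtered cistromes
#'
#' @param cistromes list of `cistrome` objects (post QC and peak filtering).
#' @param qc optional QC data.frame (as for [qc_filter]), kept as metadata.
#' @param rp optional precomputed regulatory-potential matrix
#'   (dataset x gene) stored alongside the cistromes.
#' @return a `tr_reference`: list(cistromes, qc, tr_index, species, rp).
#' @export
build_reference <- function(cistromes, qc = NULL, rp = NULL) {
  if (length(cistromes) == 0) stop("no cistromes")
  ids <- vapply(cistromes, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset_id")
  names(cistromes) <- ids
  trs <- vapply(cistromes, `[[`, "", "tr_name")
  tr_index <- split(ids, trs)
  structure(list(cistromes = cistromes, qc = qc, tr_index = tr_index,
                 species = cistromes[[1]]$species, rp = rp),
            class = "tr_reference")
}

#' @export
print.tr_reference <- function(x, ...) {
  cat(sprintf("<tr_reference> %d datasets, %d TRs (%s)\n",
              length(x$cistromes), length(x$tr_index), x$species))
  invisible(x)
}

#' Serialize / load a TR reference
#'
#' The container is a plain-text directory: one intervals table
#' (`cistromes.tsv`), a dataset metadata table (`datasets.tsv`), optional QC
#' (`qc.tsv`) and precomputed RP (`rp.tsv`), plus a JSON index
#' (`index.json`).  `load_reference(save_reference(x)) == x` up to numeric
#' formatting.
#'
#' @param ref a `tr_reference`.
#' @param path directory to create/overwrite.
#' @return `save_reference` the path, invisibly; `load_reference` a
#'   `tr_reference`.
#' @export
save_reference <- function(ref, path) {
  stopifnot(inherits(ref, "tr_reference"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  iv <- do.call(rbind, lapply(ref$cistromes, function(cs) {
    if (nrow(cs$intervals) == 0) return(NULL)
    cbind(dataset_id = cs$dataset_id, cs$intervals)
  }))
  if (is.null(iv)) iv <- data.frame(dataset_id = character(),
                                    chrom = character(), start = numeric(),
                                    end = numeric(), fold = numeric())
  utils::write.table(iv, file.path(path, "cistromes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(
    dataset_id = names(ref$cistromes),
    tr_name = vapply(ref$cistromes, `[[`, "", "tr_name"),
    species = vapply(ref$cistromes, `[[`, "", "species"),
    source = vapply(ref$cistromes, `[[`, "", "source"),
    n_peaks = vapply(ref$cistromes, function(cs) nrow(cs$intervals), 0L),
    stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(path, "datasets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(ref$qc))
    utils::write.table(ref$qc, file.path(path, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(ref$rp)) {
    rp <- data.frame(dataset_id = rownames(ref$rp), ref$rp,
                     check.names = FALSE)
    utils::write.table(rp, file.path(path, "rp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(format = "trforge-reference", version = 1L,
                            species = ref$species, tr_index = ref$tr_index),
                       file.path(path, "index.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_reference
#' @export
load_reference <- function(path) {
  idx <- jsonlite::read_json(file.path(path, "index.json"),
                             simplifyVector = TRUE)
  stopifnot(identical(idx$format, "trforge-reference"))
  iv <- utils::read.table(file.path(path, "cistromes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  meta <- utils::read.table(file.path(path, "datasets.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  cistromes <- lapply(seq_len(nrow(meta)), function(i) {
    sub <- iv[iv$dataset_id == meta$dataset_id[i],
              c("chrom", "start", "end", "fold"), drop = FALSE]
    rownames(sub) <- NULL
    cistrome(meta$tr_name[i], meta$dataset_id[i], sub,
             species = meta$species[i], source = meta$source[i])
  })
  qc <- NULL
  if (file.exists(file.path(path, "qc.tsv")))
    qc <- utils::read.table(file.path(path, "qc.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  rp <- NULL
  if (file.exists(file.path(path, "rp.tsv"))) {
    tb <- utils::read.table(file.path(path, "rp.tsv"), header = TRUE,
                            sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
    rp <- as.matrix(tb[, -1, drop = FALSE])
    rownames(rp) <- tb$dataset_id
  }
  ref <- build_reference(cistromes, qc = qc, rp = rp)
  ref$species <- idx$species
  ref
}

#' Read / write cistrome intervals as BED6+
#'
#' Columns: chrom, start, end, name (dataset_id), score (fold enrichment),
#' strand (".").  0-based half-open, as in BED.
#'
#' @param cis a `cistrome`.
#' @param path BED path.
#' @export
write_cistrome_bed <- function(cis, path) {
  iv <- cis$intervals
  utils::write.table(
    data.frame(iv$chrom, as.integer(iv$start), as.integer(iv$end),
               cis$dataset_id, iv$fold, "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_cistrome_bed
#' @param tr_name,species,source metadata for the loaded cistrome.
#' @export
read_cistrome_bed <- function(path, tr_name, species = "synthetic",
                              source = "chipseq") {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  cistrome(tr_name, dataset_id = as.character(tb[[4]][1]),
           data.frame(chrom = tb[[1]], start = tb[[2]], end = tb[[3]],
                      fold = tb[[5]]),
           species = species, source = source)
}
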