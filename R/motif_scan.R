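#' Motif models and genome scanning
#'
#' A motif model is a position weight matrix (PWM) of base probabilities
#' (rows A, C, G, T; columns sum to 1) plus a background base composition.
#' Scanning scores every genomic position on both strands by the
#' log-likelihood ratio of PWM vs background, converts scores to P-values
#' from the exact null score distribution (dynamic programming over a
#' quantized score grid), keeps hits that fall in open chromatin (DHS) and
#' outside blacklisted regions, extends each hit symmetrically to a fixed
#' width, and retains the best-scoring sites.
#'
#' @name motif_scan
NULL

BASES <- c("A", "C", "G", "T")

#' Construct a motif model
#' @param tr_name TR symbol the motif represents.
#' @param pwm 4 x width matrix of probabilities, rows A/C/G/T.
#' @param background length-4 base frequencies (default uniform).
#' @return a `motif_model`.
#' @export
motif_model <- function(tr_name, pwm, background = rep(0.25, 4)) {
  pwm <- as.matrix(pwm)
  stopifnot(nrow(pwm) == 4, ncol(pwm) >= 4,
            all(abs(colSums(pwm) - 1) < 1e-6),
            length(background) == 4, abs(sum(background) - 1) < 1e-6)
  rownames(pwm) <- BASES
  structure(list(tr_name = tr_name, pwm = pwm,
                 background = as.numeric(background)),
            class = "motif_model")
}

#' Read motifs from a JASPAR plain-text matrix file
#'
#' Count matrices are converted to probabilities with a 0.5 pseudocount
#' per base.
#'
#' @param path JASPAR-format file (">id name" header, 4 A/C/G/T rows).
#' @param background base frequencies for all motifs.
#' @return named list of `motif_model`s.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  stopifnot(length(heads) > 0)
  out <- lapply(heads, function(h) {
    fields <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    name <- if (length(fields) >= 2) fields[2] else fields[1]
    rows <- sub("^\\s*[ACGTacgt]", "", lines[h + 1:4])
    nums <- lapply(rows, function(r)
      as.numeric(regmatches(r, gregexpr("[0-9.]+", r))[[1]]))
    stopifnot(length(unique(lengths(nums))) == 1)
    counts <- do.call(rbind, nums)
    counts <- counts + 0.5
    motif_model(name, sweep(counts, 2, colSums(counts), "/"), background)
  })
  names(out) <- vapply(out, `[[`, "", "tr_name")
  out
}

#' Exact PWM score P-value function under the background model
#'
#' Enumerates the null distribution of the log2 likelihood-ratio score by
#' convolving per-column score distributions on a quantized grid.
#'
#' @param motif a `motif_model`.
#' @param bin score quantization bin width; default 0.01.
#' @return function(score) -> P(null score >= score) (vectorized).
#' @export
pwm_score_pvalue <- function(motif, bin = 0.01) {
  llr <- log2(pmax(motif$pwm, 1e-12) / motif$background)
  q <- round(llr / bin)  # integer score per base/column
  cur_lo <- 0; cur_vec <- 1  # DP state: P(partial score = cur_lo + i - 1)
  for (j in seq_len(ncol(q))) {
    col_lo <- min(q[, j]); col_hi <- max(q[, j])
    new_lo <- cur_lo + col_lo
    new_vec <- rep(0, length(cur_vec) + (col_hi - col_lo))
    for (b in 1:4) {
      off <- q[b, j] - col_lo
      idx <- seq_along(cur_vec) + off
      new_vec[idx] <- new_vec[idx] + cur_vec * motif$background[b]
    }
    cur_vec <- new_vec; cur_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(cur_vec)))  # P(score_idx >= i)
  function(score) {
    i <- round(score / bin) - cur_lo + 1
    i <- pmin(pmax(i, 1), length(tail_p) + 1)
    ifelse(i > length(tail_p), 0, tail_p[i])
  }
}

score_sequence <- function(seq_codes, llr) {
  w <- ncol(llr)
  L <- length(seq_codes)
  if (w > L) stop("PWM wider than sequence")
  n <- L - w + 1
  sc <- numeric(n)
  for (j in seq_len(w)) {
    v <- llr[, j][seq_codes[j:(j + n - 1)]]
    v[is.na(v)] <- -Inf  # N bases kill the window
    sc <- sc + v
  }
  sc
}

#' Scan a genome for motif pseudo-peaks
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @param motif a `motif_model`.
#' @param dhs data.frame(chrom, start, end): open-chromatin intervals a hit
#'   must overlap (1-bp overlap suffices); NULL disables the filter.
#' @param blacklist data.frame(chrom, start, end): intervals a hit must not
#'   overlap; NULL disables.
#' @param top_n retain the best `top_n` sites by P-value; default 25000.
#' @param final_width each hit is extended symmetrically about its centre to
#'   this width (clipped at chromosome bounds); default 340.
#' @param dataset_id id for the resulting cistrome.
#' @return a [cistrome] with `source = "motif"`; `fold` holds the log2
#'   likelihood-ratio score (floored at 0).
#' @export
scan_motif <- function(genome, motif, dhs = NULL, blacklist = NULL,
                       top_n = 25000, final_width = 340,
                       dataset_id = paste0(motif$tr_name, "_motif")) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  llr <- log2(pmax(motif$pwm, 1e-12) / motif$background)
  w <- ncol(llr)
  pval <- pwm_score_pvalue(motif)
  hits <- list()
  for (chrom in names(genome)) {
    s <- as.character(genome[[chrom]])
    L <- nchar(s)
    codes <- match(strsplit(s, "")[[1]], BASES)
    fwd <- score_sequence(codes, llr)
    rc <- as.character(Biostrings::reverseComplement(genome[[chrom]]))
    rev_codes <- match(strsplit(rc, "")[[1]], BASES)
    rev <- score_sequence(rev_codes, llr)
    # hit centres (0-based): forward window at 1-based pos p covers
    # [p-1, p-1+w); reverse pos p maps to forward [L-p-w+1, L-p+1)
    ctr_f <- (seq_along(fwd) - 1) + w / 2
    ctr_r <- (L - seq_along(rev) - w + 1) + w / 2
    df <- data.frame(chrom = chrom,
                     center = c(ctr_f, ctr_r),
                     score = c(fwd, rev),
                     strand = rep(c("+", "-"), c(length(fwd), length(rev))))
    df <- df[is.finite(df$score) & df$score > 0, , drop = FALSE]
    df$L <- L
    hits[[chrom]] <- df
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0)
    return(cistrome(motif$tr_name, dataset_id,
                    data.frame(chrom = character(), start = numeric(),
                               end = numeric(), fold = numeric()),
                    source = "motif"))
  hit_start <- floor(hits$center - w / 2)
  hit_end <- hit_start + w
  keep <- rep(TRUE, nrow(hits))
  if (!is.null(dhs))
    keep <- keep & overlaps_any(hits$chrom, hit_start, hit_end, dhs)
  if (!is.null(blacklist))
    keep <- keep & !overlaps_any(hits$chrom, hit_start, hit_end, blacklist)
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0)
    return(cistrome(motif$tr_name, dataset_id,
                    data.frame(chrom = character(), start = numeric(),
                               end = numeric(), fold = numeric()),
                    source = "motif"))
  hits$p <- pval(hits$score)
  ord <- order(hits$p, hits$chrom, floor(hits$center - final_width / 2))
  hits <- hits[ord, , drop = FALSE][seq_len(min(top_n, nrow(hits))), ,
                                    drop = FALSE]
  start <- pmax(0, floor(hits$center - final_width / 2))
  end <- pmin(hits$L, floor(hits$center - final_width / 2) + final_width)
  cistrome(motif$tr_name, dataset_id,
           data.frame(chrom = hits$chrom, start = start, end = end,
                      fold = pmax(hits$score, 0)),
           source = "motif")
}

overlaps_any <- function(chrom, start, end, iv) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  s <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1, iv$end))
  IRanges::overlapsAny(q, s)
}
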