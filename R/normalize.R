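#' CPM-normalise a raw peak count matrix
#'
#' Scales each sample (column) so its counts sum to one million, then adds a
#' log2(CPM + 1) layer. Columns with a zero total are left all-zero with a
#' warning.
#'
#' @param raw non-negative numeric matrix, peaks x samples. Row and column
#'   names are carried through as peak and sample ids.
#' @return list of class `count_matrix` with elements `raw`, `cpm`,
#'   `logcpm`, `peak_ids`, `sample_ids`.
#' @export
cpm_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("raw counts must be non-negative")
  totals <- colSums(raw)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " column(s) with zero total counts; CPM left at zero")
    totals[zero] <- 1
  }
  cpm <- sweep(raw, 2, totals, "/") * 1e6
  out <- list(raw = raw, cpm = cpm, logcpm = log2(cpm + 1),
              peak_ids = rownames(raw), sample_ids = colnames(raw))
  class(out) <- "count_matrix"
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$raw), "peaks x", ncol(x$raw), "samples\n")
  invisible(x)
}

#' Technical-replicate QC by Pearson correlation
#'
#' Computes the Pearson correlation of log2(CPM+1) profiles for each
#' replicate pair and flags pairs below a threshold. Pairs involving a
#' constant profile have an undefined correlation and are reported as `NA`.
#'
#' @param logcpm numeric matrix, peaks x samples.
#' @param replicate_pairs data.frame with columns `sample_a`, `sample_b`.
#' @param threshold flag pairs with `r < threshold` (default 0.8).
#' @return data.frame `sample_a, sample_b, r, below_threshold`.
#' @export
replicate_qc <- function(logcpm, replicate_pairs, threshold = 0.8) {
  stopifnot(all(c("sample_a", "sample_b") %in% names(replicate_pairs)))
  miss <- setdiff(unique(c(replicate_pairs$sample_a, replicate_pairs$sample_b)),
                  colnames(logcpm))
  if (length(miss)) stop("unknown samples in replicate pairs: ",
                         paste(miss, collapse = ", "))
  r <- mapply(function(a, b) {
    x <- logcpm[, a]; y <- logcpm[, b]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, replicate_pairs$sample_a, replicate_pairs$sample_b)
  data.frame(sample_a = replicate_pairs$sample_a,
             sample_b = replicate_pairs$sample_b,
             r = as.numeric(r),
             below_threshold = !is.na(r) & r < threshold,
             stringsAsFactors = FALSE)
}

#' Peak presence from a count matrix
#'
#' Stand-in presence rule when per-sample peak calls are unavailable: a peak
#' is present in a sample when its (rounded) count reaches `threshold`.
#'
#' @param raw counts matrix, peaks x samples.
#' @param threshold minimum rounded count (default 1).
#' @return binary integer matrix of the same shape.
#' @export
presence_from_counts <- function(raw, threshold = 1) {
  p <- (round(raw) >= threshold) * 1L
  dimnames(p) <- dimnames(raw)
  p
}

#' Histogram of peak sharing across samples
#'
#' Counts how many peaks are present in exactly n samples, n = 1..N.
#'
#' @param presence binary matrix, peaks x samples.
#' @return data.frame `n_samples` (1..N), `n_peaks`.
#' @export
presence_histogram <- function(presence) {
  stopifnot(all(presence %in% c(0, 1)))
  n <- ncol(presence)
  counts <- tabulate(rowSums(presence), nbins = n)
  data.frame(n_samples = seq_len(n), n_peaks = counts)
}
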