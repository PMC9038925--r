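# Shared fixtures, built once per test run. Small cohorts keep the unit
# tests fast; the acceptance tests build their own full-size cohorts.

small_config <- function(...) {
  args <- list(n_clusters = 3, samples_per_cluster = c(8, 8, 8),
               n_peaks = 3000, n_genes = 400, frac_cluster_specific = 0.02,
               n_motifs = 40, motif_program_size = 5, seed = 101)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

.fixture_env <- new.env()

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(small_config())
  }
  .fixture_env$small
}

# brute-force O(n^2) interval union (bedtools-merge semantics: overlap or
# bookended) used as the independent merge oracle
oracle_merge <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] <= cur_e) {        # overlap or bookended
        cur_e <- max(cur_e, sub$end[i])
      } else {
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s, end = cur_e)
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = cur_s, end = cur_e)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

# brute-force overlap test between one interval set and another
oracle_overlaps <- function(a_start, a_end, b_start, b_end) {
  outer(a_start, b_end, "<") & outer(a_end, b_start, ">")
}

random_peak_calls <- function(n_samples, n_intervals, chrom_len = 10000,
                              seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_samples), function(j) {
    s <- sample.int(chrom_len - 60, n_intervals, replace = TRUE)
    data.frame(chrom = "chr1", start = s, end = s + sample(10:50, n_intervals,
                                                           replace = TRUE))
  })
}
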