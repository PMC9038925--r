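#' chromVAR-style motif accessibility deviations
#'
#' For each motif and sample, the raw deviation is the relative excess of
#' counts in the motif's member peaks over the expectation under the
#' sample's composition: `Y[m, j] = (obs[m, j] - E[m, j]) / E[m, j]` with
#' `E[m, j] = (sum_i M[i, m] f_i) * T_j`, where `T_j` is the sample total
#' and `f_i` is the peak's expected count fraction. `f_i` is taken as the
#' mean over samples of the per-sample count fractions `X[i, j] / T_j`, a
#' composition-based expectation that makes the deviations exactly
#' invariant to rescaling any sample's column (library-size closure) and
#' exactly zero for a motif covering all peaks.
#'
#' Bias correction follows the chromVAR scheme: `n_background` random peak
#' sets per motif, matched per member peak within `n_bins` quantile bins of
#' mean accessibility, give a background deviation distribution; the z
#' score is the observed deviation standardised by the background mean and
#' SD. A motif's variability is the SD of its z scores across samples.
#' (Synthetic peaks carry no sequence, so GC matching is not applicable;
#' matching is on mean accessibility only.)
#'
#' @param raw_counts non-negative matrix, peaks x samples.
#' @param motif_membership binary matrix, peaks x motifs.
#' @param n_background background sets per motif.
#' @param n_bins accessibility-matching quantile bins.
#' @param seed integer seed for background sampling.
#' @return list of class `motif_deviations`: `Y` (raw), `Z`
#'   (bias-corrected), `variability` (named per motif), `n_background`,
#'   `seed`, `dropped` (motifs without counts).
#' @export
compute_deviations <- function(raw_counts, motif_membership,
                               n_background = 50, n_bins = 10, seed = 1) {
  X <- as.matrix(raw_counts)
  M <- as.matrix(motif_membership)
  if (nrow(M) != nrow(X)) stop("membership rows must align to peaks")
  if (any(colSums(M) == 0)) stop("every motif needs at least one member peak")
  set.seed(seed)
  Tj <- colSums(X)
  if (any(Tj == 0)) stop("sample with zero total counts")
  f <- rowMeans(sweep(X, 2, Tj, "/"))

  Ms <- Matrix::Matrix(M, sparse = TRUE)
  obs <- as.matrix(Matrix::crossprod(Ms, X))          # motifs x samples
  e_frac <- as.numeric(Matrix::crossprod(Ms, f))
  keep <- e_frac > 0
  dropped <- colnames(M)[!keep]
  if (length(dropped))
    warning(length(dropped), " motif(s) with zero expected counts dropped")
  obs <- obs[keep, , drop = FALSE]
  e_frac <- e_frac[keep]
  Ms <- Ms[, keep, drop = FALSE]
  E <- outer(e_frac, Tj)
  Y <- (obs - E) / E

  # accessibility-matched background: each peak is swapped for a random
  # peak from its mean-accessibility quantile bin
  bin <- ceiling(rank(f, ties.method = "first") / (length(f) / n_bins))
  bin <- pmin(pmax(bin, 1), n_bins)
  by_bin <- split(seq_along(f), bin)
  bin_of <- bin
  sum_bg <- matrix(0, nrow(Y), ncol(Y))
  sumsq_bg <- matrix(0, nrow(Y), ncol(Y))
  for (b in seq_len(n_background)) {
    swap <- integer(length(f))
    for (bb in seq_along(by_bin)) {
      members <- by_bin[[bb]]
      swap[members] <- members[sample.int(length(members),
                                          length(members), replace = TRUE)]
    }
    obs_b <- as.matrix(Matrix::crossprod(Ms, X[swap, , drop = FALSE]))
    e_b <- as.numeric(Matrix::crossprod(Ms, f[swap]))
    E_b <- outer(pmax(e_b, 1e-300), Tj)
    Yb <- (obs_b - E_b) / E_b
    sum_bg <- sum_bg + Yb
    sumsq_bg <- sumsq_bg + Yb^2
  }
  mean_bg <- sum_bg / n_background
  var_bg <- pmax(sumsq_bg / n_background - mean_bg^2, 0) *
    n_background / (n_background - 1)
  sd_bg <- sqrt(var_bg)
  sd_bg[sd_bg == 0] <- NA_real_
  Z <- (Y - mean_bg) / sd_bg
  Z[is.na(Z)] <- 0
  dimnames(Y) <- dimnames(Z) <- list(colnames(M)[keep], colnames(X))
  v <- apply(Z, 1, stats::sd)
  structure(list(Y = Y, Z = Z, variability = v,
                 n_background = n_background, seed = seed,
                 dropped = dropped), class = "motif_deviations")
}

#' Cluster-enriched motif selection
#'
#' Selects motifs whose deviation z scores correlate positively with a
#' cluster's one-vs-rest indicator, at BH-corrected q below `q_threshold`
#' and variability above `v_threshold`.
#'
#' @param Z motifs x samples deviation z-score matrix.
#' @param v per-motif variability (named, aligned to Z rows).
#' @param labels cluster labels per sample.
#' @param cluster the cluster tested.
#' @param v_threshold,q_threshold selection cut-offs.
#' @return data.frame of class `motif_selection`: `motif_id, r, p, q,
#'   variability, selected`, with attribute `cluster`.
#' @export
cluster_enriched_motifs <- function(Z, v, labels, cluster,
                                    v_threshold = 1.5, q_threshold = 0.05) {
  if (length(unique(labels)) < 2) stop("need at least two clusters in labels")
  if (!is.null(names(labels)) && !is.null(colnames(Z)))
    labels <- labels[colnames(Z)]
  ind <- as.numeric(labels == cluster)
  n <- ncol(Z)
  zi <- (ind - mean(ind)) / stats::sd(ind)
  zZ <- (Z - rowMeans(Z)) / sqrt(rowVars(Z))
  r <- as.numeric(zZ %*% zi) / (n - 1)
  r[!is.finite(r)] <- 0
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- stats::p.adjust(p, method = "BH")
  vv <- if (!is.null(names(v))) v[rownames(Z)] else v
  out <- data.frame(motif_id = rownames(Z), r = r, p = p, q = q,
                    variability = as.numeric(vv),
                    selected = r > 0 & q < q_threshold &
                      as.numeric(vv) > v_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cluster") <- cluster
  class(out) <- c("motif_selection", "data.frame")
  out
}

#' Correlate motif deviations with their TF's expression
#'
#' Pearson correlation between each motif's deviation z scores and the
#' expression of the motif's transcription factor gene across shared
#' samples; motifs with a positive correlation at p below the threshold
#' are retained. Unmapped motifs and constant expression profiles are
#' skipped and reported.
#'
#' @param Z motifs x samples deviation z scores.
#' @param tf_expression genes x samples expression matrix.
#' @param motif_gene_map data.frame `motif_id, gene_id`.
#' @param p_threshold retention threshold (default 0.05).
#' @return list: `results` (data.frame `motif_id, gene_id, r, p,
#'   retained`), `skipped` (motif ids).
#' @export
motif_expression_correlation <- function(Z, tf_expression, motif_gene_map,
                                         p_threshold = 0.05) {
  shared <- intersect(colnames(Z), colnames(tf_expression))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  map <- motif_gene_map[motif_gene_map$motif_id %in% rownames(Z), , drop = FALSE]
  skipped <- setdiff(rownames(Z), map$motif_id)
  rows <- list()
  for (i in seq_len(nrow(map))) {
    m <- map$motif_id[i]; g <- map$gene_id[i]
    if (!g %in% rownames(tf_expression)) { skipped <- c(skipped, m); next }
    zm <- Z[m, shared]; eg <- tf_expression[g, shared]
    if (stats::sd(zm) == 0 || stats::sd(eg) == 0) { skipped <- c(skipped, m); next }
    ct <- stats::cor.test(zm, eg)
    rows[[length(rows) + 1]] <- data.frame(
      motif_id = m, gene_id = g, r = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), gene_id = character(0),
               r = numeric(0), p = numeric(0))
  res$retained <- res$r > 0 & res$p < p_threshold
  list(results = res, skipped = unique(skipped))
}

#' Top-k overlap of two motif rankings
#'
#' @param ranking_a,ranking_b ordered motif id vectors (no duplicates).
#' @param k list depth (default 10).
#' @return list: `overlap` (count), `fraction`.
#' @export
top_k_overlap <- function(ranking_a, ranking_b, k = 10) {
  if (anyDuplicated(ranking_a) || anyDuplicated(ranking_b))
    stop("rankings must not contain duplicates")
  if (k > length(ranking_a) || k > length(ranking_b))
    stop("k exceeds ranking length")
  ov <- length(intersect(ranking_a[seq_len(k)], ranking_b[seq_len(k)]))
  list(overlap = ov, fraction = ov / k)
}

#' Rank motifs by hypergeometric enrichment in a peak set
#'
#' Surrogate for sequence-based motif enrichment: tests each motif's
#' membership count inside the peak set against the universe with a
#' one-sided hypergeometric test, BH-corrects across motifs, and ranks by
#' p value (ties broken by descending in-set count, then motif id).
#'
#' @param peak_ids the peak set of interest.
#' @param motif_membership binary matrix, universe peaks x motifs, with
#'   peak-id rownames.
#' @return data.frame ordered by rank: `motif_id, in_set, in_universe, p,
#'   q`.
#' @export
motif_enrichment_ranking <- function(peak_ids, motif_membership) {
  M <- as.matrix(motif_membership)
  universe <- rownames(M)
  sel <- universe %in% peak_ids
  n_set <- sum(sel)
  if (n_set == 0) stop("peak set does not intersect the universe")
  in_set <- colSums(M[sel, , drop = FALSE])
  in_universe <- colSums(M)
  p <- stats::phyper(in_set - 1, in_universe, nrow(M) - in_universe,
                     n_set, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(motif_id = colnames(M), in_set = in_set,
                    in_universe = in_universe, p = p, q = q,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$in_set, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
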