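#' Convert mouse cluster-unique peaks to human peaks
#'
#' The homolog-mediated conversion chain: mouse peaks are annotated to
#' their nearest genes, the deduplicated genes are mapped to human
#' homologs, the homologs are intersected with the significant
#' peak-to-gene links, and the union of their linked human peaks is
#' returned. Every step's retention count is recorded. An empty set at any
#' step yields an empty result with diagnostics rather than an error.
#'
#' @param mouse_unique_peaks character vector of mouse peak ids.
#' @param mouse_annotation data.frame `peak_id, nearest_gene_id` (from
#'   [annotate_peaks()]).
#' @param homologs data.frame `mouse_gene_id, human_gene_id`.
#' @param human_links a `peak_gene_links` table for the human cohort.
#' @param significant_only use only FDR-significant links (default TRUE).
#' @return list of class `crossmap_result`: `human_peak_ids`,
#'   `step_counts` (mouse_peaks, mouse_genes, homolog_genes, linked_genes,
#'   human_peaks), and the intermediate gene sets.
#' @export
map_unique_peaks_cross_species <- function(mouse_unique_peaks,
                                           mouse_annotation, homologs,
                                           human_links,
                                           significant_only = TRUE) {
  ann <- mouse_annotation[match(mouse_unique_peaks, mouse_annotation$peak_id), ]
  mouse_genes <- unique(stats::na.omit(ann$nearest_gene_id))
  homolog_genes <- unique(
    homologs$human_gene_id[homologs$mouse_gene_id %in% mouse_genes])
  g2p <- if (length(homolog_genes)) {
    genes_to_peaks(homolog_genes, human_links, significant_only)
  } else {
    list(peak_ids = character(0), genes_without_links = character(0))
  }
  linked_genes <- setdiff(homolog_genes, g2p$genes_without_links)
  structure(list(
    human_peak_ids = g2p$peak_ids,
    mouse_genes = mouse_genes,
    homolog_genes = homolog_genes,
    linked_genes = linked_genes,
    step_counts = c(mouse_peaks = length(mouse_unique_peaks),
                    mouse_genes = length(mouse_genes),
                    homolog_genes = length(homolog_genes),
                    linked_genes = length(linked_genes),
                    human_peaks = length(g2p$peak_ids))),
    class = "crossmap_result")
}

#' @export
print.crossmap_result <- function(x, ...) {
  cat("crossmap_result:",
      paste(names(x$step_counts), x$step_counts, sep = "=", collapse = " -> "),
      "\n")
  invisible(x)
}

#' Cluster human samples on a guided peak set and score the agreement
#'
#' Restricts the human accessibility matrix to a given peak set, runs
#' consensus nsNMF at a fixed rank, and scores the resulting labels
#' against reference labels by matched agreement and adjusted Rand index.
#'
#' @param human_logcpm peaks x samples matrix with peak-id rownames.
#' @param mapped_peaks peak ids to cluster on (at least `k`).
#' @param reference_labels named reference labels.
#' @param k clustering rank.
#' @param n_runs consensus restarts.
#' @param theta nsNMF smoothing.
#' @param seed integer seed.
#' @param max_iter,tol per-run stopping rule.
#' @return list: `labels`, `matched_agreement`, `ari`, `n_peaks`.
#' @export
guided_clustering_agreement <- function(human_logcpm, mapped_peaks,
                                        reference_labels, k, n_runs = 10,
                                        theta = 0.5, seed = 1,
                                        max_iter = 300, tol = 1e-6) {
  peaks <- intersect(mapped_peaks, rownames(human_logcpm))
  if (length(peaks) < k)
    stop("need at least ", k, " mapped peaks; got ", length(peaks))
  V <- human_logcpm[peaks, , drop = FALSE]
  res <- consensus_cophenetic(V, k_range = k, n_runs = n_runs, theta = theta,
                              seed = seed, max_iter = max_iter, tol = tol)
  agr <- cluster_agreement(res$labels, reference_labels)
  list(labels = res$labels, matched_agreement = agr$matched_agreement,
       ari = agr$ari, n_peaks = length(peaks))
}

#' Random-peak null for guided clustering agreement
#'
#' Repeats the guided clustering on random peak sets of the same size,
#' drawn without replacement from a candidate universe (by default the
#' peaks entering the peak-to-gene linkage), to form the null distribution
#' of agreement that an uninformative peak set would produce.
#'
#' @param human_logcpm peaks x samples matrix.
#' @param candidate_peak_universe peak ids to draw from.
#' @param set_size peaks per draw.
#' @param reference_labels named reference labels.
#' @param k clustering rank.
#' @param n_iter number of random draws.
#' @param seed integer seed.
#' @param observed optional observed agreement; its empirical percentile
#'   in the null is then reported.
#' @param n_runs,theta,max_iter,tol forwarded to the clustering.
#' @return list: `values` (null agreements), `mean`, `sd`, `se`,
#'   `observed`, `percentile` (of `observed`, in 0..100).
#' @export
random_peak_control <- function(human_logcpm, candidate_peak_universe,
                                set_size, reference_labels, k,
                                n_iter = 1000, seed = 1, observed = NULL,
                                n_runs = 4, theta = 0.5, max_iter = 300,
                                tol = 1e-6) {
  universe <- intersect(candidate_peak_universe, rownames(human_logcpm))
  if (set_size > length(universe))
    stop("set_size exceeds the candidate universe")
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  values <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    set.seed(draw_seeds[i])
    ids <- sample(universe, set_size)
    values[i] <- guided_clustering_agreement(
      human_logcpm, ids, reference_labels, k, n_runs = n_runs,
      theta = theta, seed = draw_seeds[i], max_iter = max_iter,
      tol = tol)$matched_agreement
  }
  out <- list(values = values, mean = mean(values), sd = stats::sd(values),
              se = stats::sd(values) / sqrt(max(n_iter, 1)),
              observed = observed, percentile = NA_real_)
  if (!is.null(observed) && n_iter > 0)
    out$percentile <- 100 * mean(values < observed)
  out
}

#' Top-k motif overlap with a random-peak control
#'
#' Ranks motifs by hypergeometric enrichment within the mouse unique peak
#' set and within its chained human peak set, and reports the top-k
#' overlap of the two rankings. The control repeats the comparison
#' `n_iter` times with size-matched random mouse peak sets and their own
#' chained human mappings.
#'
#' @param mouse_unique_peaks mouse peak ids.
#' @param mouse_annotation,homologs,human_links the conversion-chain inputs
#'   (see [map_unique_peaks_cross_species()]).
#' @param mouse_membership,human_membership binary peak x motif matrices on
#'   a shared motif namespace.
#' @param mouse_universe mouse peak ids the random sets are drawn from
#'   (default: all membership rows).
#' @param k top-list depth (default 10).
#' @param n_iter control iterations (0 = observed only).
#' @param seed integer seed.
#' @return list: `observed` (overlap count), `observed_fraction`,
#'   `null_values`, `null_mean`, `null_sd`.
#' @export
motif_overlap_control <- function(mouse_unique_peaks, mouse_annotation,
                                  homologs, human_links,
                                  mouse_membership, human_membership,
                                  mouse_universe = NULL, k = 10,
                                  n_iter = 1000, seed = 1) {
  shared_motifs <- intersect(colnames(mouse_membership),
                             colnames(human_membership))
  if (!length(shared_motifs)) stop("shared motif namespace is empty")
  mouse_membership <- mouse_membership[, shared_motifs, drop = FALSE]
  human_membership <- human_membership[, shared_motifs, drop = FALSE]
  if (is.null(mouse_universe)) mouse_universe <- rownames(mouse_membership)

  overlap_for <- function(mouse_set) {
    mapped <- map_unique_peaks_cross_species(mouse_set, mouse_annotation,
                                             homologs, human_links)
    if (!length(mapped$human_peak_ids)) return(NA_real_)
    rank_m <- motif_enrichment_ranking(mouse_set, mouse_membership)$motif_id
    rank_h <- motif_enrichment_ranking(mapped$human_peak_ids,
                                       human_membership)$motif_id
    top_k_overlap(rank_m, rank_h, k)$overlap
  }
  observed <- overlap_for(mouse_unique_peaks)
  null_values <- numeric(0)
  if (n_iter > 0) {
    set.seed(seed)
    null_values <- vapply(seq_len(n_iter), function(i)
      overlap_for(sample(mouse_universe, length(mouse_unique_peaks))),
      numeric(1))
    null_values <- null_values[!is.na(null_values)]
  }
  list(observed = observed, observed_fraction = observed / k,
       null_values = null_values,
       null_mean = if (length(null_values)) mean(null_values) else NA_real_,
       null_sd = if (length(null_values)) stats::sd(null_values) else NA_real_)
}
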