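#' Configuration for a synthetic ATAC-seq cohort
#'
#' The generator emulates a patient-derived GSC culture cohort: a master
#' peak set on a toy genome, negative-binomial read counts with planted
#' cluster-specific open-peak programs concentrated in distal regulatory
#' elements (DREs), gene expression correlated with the accessibility of
#' linked DRE peaks, and motif programs marking cluster-specific peaks.
#'
#' The toy genome places genes on a grid (one TSS every 2 Mb, 200 genes per
#' chromosome, alternating strand) so that promoter/DRE windows never
#' overlap between neighbouring genes. Each gene's first DRE peak is its
#' "linked" peak: the gene's expression equals the standardised log2(CPM+1)
#' accessibility of that peak plus Gaussian noise with SD `link_noise_sd`,
#' so the population accessibility-expression correlation is exactly
#' `1/sqrt(1 + link_noise_sd^2)`.
#'
#' @param n_clusters number of planted sample clusters.
#' @param samples_per_cluster integer vector of length `n_clusters`.
#' @param n_peaks total peaks in the master set.
#' @param frac_cluster_specific fraction of peaks made specifically open in
#'   each cluster (scalar recycled, or one value per cluster). The default
#'   keeps each cluster's program a ~1% minority of the distal peak
#'   universe: cluster structure is then recoverable from the full
#'   top-variance selection and from program-enriched peak sets, but not
#'   from size-matched random draws — the regime the random-peak null
#'   controls of the cross-species stage are meaningful in.
#' @param frac_dre fraction of peaks placed at DRE coordinates; the rest is
#'   split evenly between promoter and distant "other" positions.
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson).
#' @param library_size_range sampled uniform per-sample depth; only the
#'   relative depth (size / cohort mean) scales the expected counts.
#' @param open_mean,closed_mean expected counts (at average depth) of open
#'   and closed peaks; `open_mean > closed_mean > 0`.
#' @param link_noise_sd SD of the Gaussian noise on linked-gene expression.
#' @param n_genes genes on the toy genome.
#' @param n_extra_linked_genes linked genes beyond the cluster-program
#'   genes (the program genes are always linked). Keeping the planted
#'   links a small fraction of the candidate pairs mirrors real cohorts,
#'   where most peak-gene candidates are nonspecific — the empirical null
#'   of the linkage stage is only meaningful in that regime.
#' @param n_motifs motifs in the (shared) motif namespace.
#' @param motif_program_size motifs per cluster program.
#' @param motif_program_rate,motif_base_rate membership probability of a
#'   program motif in its cluster's specific peaks, and of any motif in any
#'   other peak.
#' @param replicate_noise_sd SD used by [make_technical_replicates()].
#' @param prefix species/sample-id prefix (e.g. `"hs"`, `"mm"`).
#' @param seed integer; fixes all randomness in [generate_cohort()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_clusters = 3,
                          samples_per_cluster = c(20, 20, 20),
                          n_peaks = 20000,
                          frac_cluster_specific = 0.0025,
                          frac_dre = 0.7,
                          nb_dispersion = 0.1,
                          library_size_range = c(7e6, 13e6),
                          open_mean = 50,
                          closed_mean = 5,
                          link_noise_sd = 0.75,
                          n_genes = 2000,
                          n_extra_linked_genes = 200,
                          n_motifs = 100,
                          motif_program_size = 10,
                          motif_program_rate = 0.9,
                          motif_base_rate = 0.05,
                          replicate_noise_sd = 0.3,
                          prefix = "hs",
                          seed = 1) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  fr <- c(cfg$frac_cluster_specific, cfg$frac_dre,
          cfg$motif_program_rate, cfg$motif_base_rate)
  if (any(fr < 0 | fr > 1)) stop("configuration error: fractions must lie in [0, 1]")
  if (length(cfg$samples_per_cluster) != cfg$n_clusters)
    stop("configuration error: samples_per_cluster must have one entry per cluster")
  if (sum(cfg$samples_per_cluster) < cfg$n_clusters)
    stop("configuration error: need at least one sample per cluster")
  if (!(cfg$open_mean > cfg$closed_mean && cfg$closed_mean > 0))
    stop("configuration error: need open_mean > closed_mean > 0")
  k <- length(cfg$frac_cluster_specific)
  if (!k %in% c(1L, cfg$n_clusters))
    stop("configuration error: frac_cluster_specific length must be 1 or n_clusters")
  n_spec <- round(cfg$n_peaks * rep_len(cfg$frac_cluster_specific, cfg$n_clusters))
  n_linkable <- min(round(cfg$n_peaks * cfg$frac_dre), cfg$n_genes)
  if (sum(n_spec) + cfg$n_extra_linked_genes > n_linkable)
    stop("configuration error: program plus extra linked genes (",
         sum(n_spec) + cfg$n_extra_linked_genes,
         ") exceed linkable DRE peaks (", n_linkable, ")")
  invisible(cfg)
}

# Gene grid: 200 genes per chromosome, TSS every 2 Mb, alternating strand.
toy_gene_grid <- function(n_genes, prefix) {
  per_chrom <- 200L
  idx <- seq_len(n_genes)
  chrom <- paste0("chr", (idx - 1L) %/% per_chrom + 1L)
  pos_in_chrom <- (idx - 1L) %% per_chrom
  tss <- 1e6 + pos_in_chrom * 2e6
  strand <- ifelse(idx %% 2 == 1, "+", "-")
  tts <- tss + ifelse(strand == "+", 5e4, -5e4)
  gene_annotation(sprintf("%sG%04d", prefix, idx), chrom, strand, tss, tts = tts)
}

#' Generate a synthetic cohort with planted structure
#'
#' See [cohort_config()] for the generative model. The returned cohort
#' carries full ground truth: sample labels, peak-gene links, and
#' cluster-specific motif programs.
#'
#' @param config a `cohort_config`.
#' @return list of class `synthetic_cohort` with elements `peaks`, `counts`
#'   (a `count_matrix`), `presence`, `genes`, `expression`, `true_labels`,
#'   `true_links`, `true_motif_programs`, `motif_membership`,
#'   `motif_gene_map`, `annotation` fields (`peak_class`, `linked_gene`),
#'   and the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  K <- config$n_clusters
  n_samples <- sum(config$samples_per_cluster)
  labels <- rep(seq_len(K), config$samples_per_cluster)
  genes <- toy_gene_grid(config$n_genes, config$prefix)

  n_dre <- round(config$n_peaks * config$frac_dre)
  n_prom <- round(config$n_peaks * (1 - config$frac_dre) / 2)
  n_other <- config$n_peaks - n_dre - n_prom

  place <- function(n, offsets_for_rung) {
    # round-robin over genes; "rung" = how many peaks of this class the gene
    # already has. Returns gene index and genomic midpoint.
    g <- (seq_len(n) - 1L) %% config$n_genes + 1L
    rung <- (seq_len(n) - 1L) %/% config$n_genes
    off <- offsets_for_rung(rung, g)
    mid <- genes$tss[g] + off
    list(gene = g, mid = mid, rung = rung)
  }
  dre_rungs <- max(ceiling(n_dre / config$n_genes), 1)
  dre_off <- function(rung, g) {
    base <- seq(10000, 480000, length.out = max(dre_rungs, 2))[rung + 1]
    side <- ifelse((g + rung) %% 2 == 0, 1, -1)
    side * base
  }
  prom_off <- function(rung, g) {
    base <- seq(-800, 0, length.out = max(ceiling(n_prom / config$n_genes), 2))[rung + 1]
    ifelse(genes$strand[g] == "+", base, -base)
  }
  other_off <- function(rung, g) {
    base <- 600000 + rung * 150000
    side <- ifelse(g %% 2 == 0, 1, -1)
    side[genes$tss[g] - base < 1000] <- 1
    side * base
  }
  dre <- place(n_dre, dre_off)
  prom <- place(n_prom, prom_off)
  oth <- place(n_other, other_off)

  gene_idx <- c(dre$gene, prom$gene, oth$gene)
  mid <- c(dre$mid, prom$mid, oth$mid)
  peak_class <- rep(c("DRE", "promoter", "other"), c(n_dre, n_prom, n_other))
  chrom <- genes$chrom[gene_idx]
  ord <- order(chrom, mid)
  peaks <- peak_set(chrom[ord], mid[ord] - 250, mid[ord] + 250)
  gene_idx <- gene_idx[ord]; peak_class <- peak_class[ord]
  rung <- c(dre$rung, prom$rung, oth$rung)[ord]

  # each gene's rung-0 DRE peak is its linked peak
  linked_row <- which(peak_class == "DRE" & rung == 0)
  linked_gene <- gene_idx[linked_row]               # one row per linked gene
  linked_row <- linked_row[order(linked_gene)]
  linked_gene <- sort(linked_gene)

  # cluster-specific peaks: the linked DRE peaks of disjoint gene blocks
  # (n_spec may be zero: a structureless cohort is a valid null condition)
  n_spec <- round(config$n_peaks * rep_len(config$frac_cluster_specific, K))
  offsets <- cumsum(c(0, n_spec))
  spec_gene <- lapply(seq_len(K), function(c)
    seq_len(n_spec[c]) + offsets[c])
  spec_row <- lapply(spec_gene, function(g)
    linked_row[match(g, linked_gene)])

  # expected counts
  lib <- stats::runif(n_samples, config$library_size_range[1],
                      config$library_size_range[2])
  s_j <- lib / mean(lib)
  base_mean <- 2^stats::runif(nrow(peaks), log2(config$closed_mean),
                              log2(config$open_mean))
  mu <- outer(base_mean, s_j)
  for (c in seq_len(K)) {
    rows <- spec_row[[c]]
    mu[rows, ] <- outer(rep(config$closed_mean, length(rows)), s_j)
    mu[rows, labels == c] <- outer(rep(config$open_mean, length(rows)),
                                   s_j[labels == c])
  }
  raw <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(length(mu), size = 1 / config$nb_dispersion, mu = mu),
           nrow = nrow(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
  }
  dimnames(raw) <- list(peaks$peak_id,
                        sprintf("%s_S%02d", config$prefix, seq_len(n_samples)))
  counts <- cpm_normalize(raw)
  presence <- presence_from_counts(raw)

  # expression: linked genes (program genes plus an extra pool) follow
  # their peak's standardised log-accessibility; all other genes are noise
  n_linked <- min(sum(n_spec) + config$n_extra_linked_genes,
                  length(linked_gene))
  linked_row <- linked_row[seq_len(n_linked)]
  linked_gene <- linked_gene[seq_len(n_linked)]
  expression <- matrix(stats::rnorm(config$n_genes * n_samples),
                       nrow = config$n_genes,
                       dimnames = list(genes$gene_id, colnames(raw)))
  acc <- counts$logcpm[linked_row, , drop = FALSE]
  acc_sd <- apply(acc, 1, stats::sd)
  ok <- acc_sd > 0
  zacc <- (acc[ok, , drop = FALSE] - rowMeans(acc[ok, , drop = FALSE])) / acc_sd[ok]
  noise <- matrix(stats::rnorm(sum(ok) * n_samples, sd = config$link_noise_sd),
                  nrow = sum(ok))
  expression[linked_gene[ok], ] <- zacc + noise
  true_links <- data.frame(peak_id = peaks$peak_id[linked_row[ok]],
                           gene_id = genes$gene_id[linked_gene[ok]],
                           stringsAsFactors = FALSE)

  # motif membership: base rate everywhere, program motifs enriched in their
  # cluster's specific peaks
  if (config$n_motifs < K * config$motif_program_size)
    stop("configuration error: n_motifs < n_clusters * motif_program_size")
  motif_ids <- sprintf("motif_%03d", seq_len(config$n_motifs))
  membership <- matrix(
    stats::rbinom(nrow(peaks) * config$n_motifs, 1, config$motif_base_rate),
    nrow = nrow(peaks), dimnames = list(peaks$peak_id, motif_ids))
  programs <- lapply(seq_len(K), function(c)
    motif_ids[(c - 1) * config$motif_program_size +
                seq_len(config$motif_program_size)])
  names(programs) <- paste0("cluster_", seq_len(K))
  for (c in seq_len(K)) {
    rows <- spec_row[[c]]
    for (m in programs[[c]])
      membership[rows, m] <- stats::rbinom(length(rows), 1,
                                           config$motif_program_rate)
  }
  motif_gene_map <- data.frame(
    motif_id = motif_ids,
    gene_id = genes$gene_id[(seq_len(config$n_motifs) - 1) %% config$n_genes + 1],
    stringsAsFactors = FALSE)

  structure(list(
    peaks = peaks,
    counts = counts,
    presence = presence,
    genes = genes,
    expression = expression,
    true_labels = stats::setNames(labels, colnames(raw)),
    true_links = true_links,
    true_motif_programs = programs,
    motif_membership = membership,
    motif_gene_map = motif_gene_map,
    peak_class = stats::setNames(peak_class, peaks$peak_id),
    linked_gene = stats::setNames(genes$gene_id[gene_idx], peaks$peak_id),
    cluster_specific_peaks = lapply(spec_row, function(r) peaks$peak_id[r]),
    program_genes = lapply(spec_gene, function(g) genes$gene_id[g]),
    config = config), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$peaks), "peaks,",
      length(x$true_labels), "samples,", x$config$n_clusters, "clusters\n")
  invisible(x)
}

#' Generate paired mouse/human cohorts with a shared regulatory program
#'
#' Generates two cohorts independently and then constructs a one-to-one
#' homolog map so that a fraction `shared_program_frac` of each mouse
#' cluster's program genes (the genes whose linked DRE peaks are that
#' cluster's specific peaks) is paired with program genes of the
#' corresponding human cluster. The remaining mouse program genes map to
#' random non-program human genes, and all other genes are paired at
#' random, so the mouse-to-human peak conversion recovers the human
#' cluster-specific program exactly in proportion to `shared_program_frac`.
#'
#' @param config_mouse,config_human `cohort_config`s with equal `n_clusters`.
#' @param shared_program_frac fraction in `[0, 1]`.
#' @param seed master seed; the per-cohort seeds are derived from it.
#' @return list with `mouse`, `human` (both `synthetic_cohort`), `homologs`
#'   (data.frame `mouse_gene_id, human_gene_id`), and `shared_program_frac`.
#' @export
generate_paired_species <- function(config_mouse, config_human,
                                    shared_program_frac, seed = 1) {
  if (shared_program_frac < 0 || shared_program_frac > 1)
    stop("shared_program_frac must lie in [0, 1]")
  if (config_mouse$n_clusters != config_human$n_clusters)
    stop("both species must use the same number of clusters")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3)
  config_mouse$seed <- seeds[1]; config_human$seed <- seeds[2]
  mouse <- generate_cohort(config_mouse)
  human <- generate_cohort(config_human)

  set.seed(seeds[3])
  K <- config_mouse$n_clusters
  pairs <- list()
  used_h <- character(0)
  h_program_all <- unlist(human$program_genes, use.names = FALSE)
  h_linked_nonprog <- setdiff(human$true_links$gene_id, h_program_all)
  for (c in seq_len(K)) {
    gm <- mouse$program_genes[[c]]
    gh <- human$program_genes[[c]]
    n_share <- round(shared_program_frac * length(gm))
    n_share <- min(n_share, length(gh))
    if (n_share > 0)
      pairs[[length(pairs) + 1]] <- data.frame(
        mouse_gene_id = gm[seq_len(n_share)],
        human_gene_id = gh[seq_len(n_share)], stringsAsFactors = FALSE)
    rest <- gm[setdiff(seq_along(gm), seq_len(n_share))]
    if (length(rest)) {
      pool <- setdiff(h_linked_nonprog, used_h)
      if (length(rest) > length(pool))
        stop("not enough non-program linked human genes for the homolog map")
      pick <- sample(pool, length(rest))
      used_h <- c(used_h, pick)
      pairs[[length(pairs) + 1]] <- data.frame(
        mouse_gene_id = rest, human_gene_id = pick, stringsAsFactors = FALSE)
    }
  }
  homologs <- do.call(rbind, pairs)
  m_rest <- setdiff(mouse$genes$gene_id, homologs$mouse_gene_id)
  h_rest <- setdiff(human$genes$gene_id, homologs$human_gene_id)
  n_extra <- min(length(m_rest), length(h_rest))
  if (n_extra > 0)
    homologs <- rbind(homologs, data.frame(
      mouse_gene_id = m_rest[seq_len(n_extra)],
      human_gene_id = sample(h_rest, n_extra), stringsAsFactors = FALSE))
  rownames(homologs) <- NULL
  list(mouse = mouse, human = human, homologs = homologs,
       shared_program_frac = shared_program_frac, seed = seed)
}

#' Mouse-sized default configuration
#'
#' Convenience wrapper over [cohort_config()] with desk-scale defaults for
#' the 9-sample, 3-group mouse cohort.
#' @param ... overrides passed to [cohort_config()].
#' @export
mouse_cohort_config <- function(...) {
  args <- list(n_clusters = 3, samples_per_cluster = c(3, 3, 3),
               n_peaks = 6000, n_genes = 1000, frac_cluster_specific = 0.008,
               prefix = "mm")
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

#' Generate a presence matrix with power-law peak sharing
#'
#' Each peak is present in `m` samples with `P(m)` proportional to
#' `m^(-sharing_exponent)`; the samples carrying it are chosen uniformly.
#' This emulates the heavy-tailed sharing profile of cohort ATAC peaks,
#' where most peaks are private to few samples.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_total_peaks number of peaks.
#' @param sharing_exponent positive power-law exponent.
#' @param seed integer seed.
#' @return binary integer matrix, peaks x samples.
#' @export
generate_saturation_presence <- function(n_samples, n_total_peaks,
                                         sharing_exponent, seed = 1) {
  if (n_samples < 2) stop("need at least 2 samples")
  if (sharing_exponent <= 0) stop("sharing_exponent must be positive")
  set.seed(seed)
  prob <- seq_len(n_samples)^(-sharing_exponent)
  m <- sample.int(n_samples, n_total_peaks, replace = TRUE,
                  prob = prob / sum(prob))
  cols <- lapply(m, function(k) sample.int(n_samples, k))
  presence <- matrix(0L, n_total_peaks, n_samples,
                     dimnames = list(sprintf("peak_%05d", seq_len(n_total_peaks)),
                                     sprintf("S%02d", seq_len(n_samples))))
  presence[cbind(rep(seq_len(n_total_peaks), m), unlist(cols))] <- 1L
  presence
}

#' Add technical replicates to a cohort's log-CPM matrix
#'
#' Duplicates selected samples with additive Gaussian noise on the
#' log2(CPM+1) scale, returning the augmented matrix and the replicate
#' pairing for [replicate_qc()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param samples sample ids to replicate (default: first of each cluster).
#' @param noise_sd noise SD (default from the cohort's config).
#' @param seed integer seed.
#' @export
make_technical_replicates <- function(cohort, samples = NULL, noise_sd = NULL,
                                      seed = 1) {
  set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- cohort$config$replicate_noise_sd
  if (is.null(samples))
    samples <- names(cohort$true_labels)[!duplicated(cohort$true_labels)]
  logcpm <- cohort$counts$logcpm
  reps <- logcpm[, samples, drop = FALSE] +
    matrix(stats::rnorm(nrow(logcpm) * length(samples), sd = noise_sd),
           nrow = nrow(logcpm))
  colnames(reps) <- paste0(samples, "_rep")
  list(logcpm = cbind(logcpm, reps),
       pairs = data.frame(sample_a = samples, sample_b = colnames(reps),
                          stringsAsFactors = FALSE))
}
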