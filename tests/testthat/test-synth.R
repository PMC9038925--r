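test_that("cohort generation is bitwise deterministic under seed", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$counts$raw, b$counts$raw)
  expect_identical(a$expression, b$expression)
  expect_identical(a$motif_membership, b$motif_membership)
  c <- generate_cohort(small_config(seed = 102))
  expect_false(identical(a$counts$raw, c$counts$raw))
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(frac_dre = 1.2), "configuration error")
  expect_error(small_config(open_mean = 3, closed_mean = 5), "configuration error")
  expect_error(small_config(samples_per_cluster = c(5, 5)), "configuration error")
  expect_error(small_config(frac_cluster_specific = 0.5), "configuration error")
})

test_that("noiseless links give exact accessibility-expression correlation", {
  co <- generate_cohort(small_config(link_noise_sd = 0, seed = 7))
  idx <- sample(nrow(co$true_links), 25)
  for (i in idx) {
    r <- cor(co$counts$logcpm[co$true_links$peak_id[i], ],
             co$expression[co$true_links$gene_id[i], ])
    expect_equal(r, 1, tolerance = 1e-12)
  }
})

test_that("cluster-specific peak counts match the NB analytic mean within 3 SE", {
  cfg <- cohort_config(n_clusters = 3, samples_per_cluster = c(20, 20, 20),
                       n_peaks = 20000, seed = 31)
  co <- generate_cohort(cfg)
  spec1 <- co$cluster_specific_peaks[[1]]
  in1 <- names(co$true_labels)[co$true_labels == 1]
  counts <- co$counts$raw[spec1, in1]
  # expected NB mean with library scaling factor ~1 on average; variance per
  # count is mu + disp*mu^2
  mu <- cfg$open_mean
  v <- mu + cfg$nb_dispersion * mu^2
  n <- length(counts)
  se <- sqrt(v / n) * 1.2     # library-size factor widens the spread slightly
  expect_lt(abs(mean(counts) - mu), 3 * se + 0.05 * mu)
  # closed outside the cluster
  out1 <- setdiff(colnames(co$counts$raw), in1)
  expect_lt(mean(co$counts$raw[spec1, out1]), cfg$closed_mean * 1.2)
})

test_that("every cluster-specific peak is open exactly in its own cluster", {
  co <- small_cohort()
  for (c in 1:3) {
    rows <- co$cluster_specific_peaks[[c]]
    inc <- names(co$true_labels)[co$true_labels == c]
    outc <- setdiff(names(co$true_labels), inc)
    m_in <- rowMeans(co$counts$raw[rows, inc])
    m_out <- rowMeans(co$counts$raw[rows, outc])
    expect_true(all(m_in > m_out))
  }
})

test_that("paired cohorts share the configured fraction of the program (set oracle)", {
  pr <- generate_paired_species(mouse_cohort_config(seed = 1),
                                cohort_config(seed = 1),
                                shared_program_frac = 0.8, seed = 5)
  ann <- annotate_peaks(pr$mouse$peaks, pr$mouse$genes)
  prs <- candidate_peak_gene_pairs(pr$human$peaks, pr$human$genes)
  links <- link_peaks_to_genes(pr$human$counts$logcpm, pr$human$expression, prs)
  m_unique <- unlist(pr$mouse$cluster_specific_peaks, use.names = FALSE)
  res <- map_unique_peaks_cross_species(m_unique, ann, pr$homologs, links)
  truth <- unlist(pr$human$cluster_specific_peaks, use.names = FALSE)
  frac <- mean(res$human_peak_ids %in% truth)
  # brute-force chained-join oracle for the step counts
  genes_o <- unique(ann$nearest_gene_id[match(m_unique, ann$peak_id)])
  hom_o <- unique(pr$homologs$human_gene_id[pr$homologs$mouse_gene_id %in% genes_o])
  sig <- links[links$significant, ]
  peaks_o <- unique(sig$peak_id[sig$gene_id %in% hom_o])
  expect_equal(sort(res$human_peak_ids), sort(peaks_o))
  expect_equal(unname(res$step_counts["mouse_genes"]), length(genes_o))
  expect_equal(unname(res$step_counts["homolog_genes"]), length(hom_o))
  # planted share: 0.8 of mapped peaks should be truly cluster-specific
  # (up to linkage false negatives/positives)
  expect_gt(frac, 0.7)
  expect_lt(frac, 0.9)
})

test_that("fully shared noiseless program maps exactly onto the human program", {
  pr <- generate_paired_species(
    mouse_cohort_config(link_noise_sd = 0, seed = 2),
    cohort_config(link_noise_sd = 0,
                  frac_cluster_specific = 0.0024, seed = 2),
    shared_program_frac = 1, seed = 9)
  # mouse program sizes equal human program sizes (48 genes each) so the
  # chain covers the full human program
  ann <- annotate_peaks(pr$mouse$peaks, pr$mouse$genes)
  prs <- candidate_peak_gene_pairs(pr$human$peaks, pr$human$genes)
  links <- link_peaks_to_genes(pr$human$counts$logcpm, pr$human$expression, prs)
  m_unique <- unlist(pr$mouse$cluster_specific_peaks, use.names = FALSE)
  res <- map_unique_peaks_cross_species(m_unique, ann, pr$homologs, links)
  truth <- unlist(pr$human$cluster_specific_peaks, use.names = FALSE)
  expect_setequal(res$human_peak_ids, truth)
})

test_that("shared_program_frac outside [0,1] errors", {
  expect_error(generate_paired_species(mouse_cohort_config(),
                                       cohort_config(), 1.4), "\\[0, 1\\]")
})

test_that("saturation presence marginals follow the configured power law", {
  expect_error(generate_saturation_presence(1, 10, 1), "at least 2")
  expect_error(generate_saturation_presence(10, 10, 0), "positive")

  # large exponent: nearly all peaks private to one sample
  p <- generate_saturation_presence(20, 2000, sharing_exponent = 12, seed = 3)
  expect_gt(mean(rowSums(p) == 1), 0.999)

  # chi-square goodness of fit against the sampled power law
  n <- 60; gamma <- 1.5
  p2 <- generate_saturation_presence(n, 50000, gamma, seed = 7)
  m <- rowSums(p2)
  prob <- (1:n)^(-gamma); prob <- prob / sum(prob)
  cs <- suppressWarnings(chisq.test(tabulate(m, n), p = prob))
  expect_gt(cs$p.value, 0.001)
})

test_that("power-law goodness of fit holds across seeds", {
  n <- 30; gamma <- 1.5
  prob <- (1:n)^(-gamma); prob <- prob / sum(prob)
  pvals <- vapply(1:20, function(s) {
    m <- rowSums(generate_saturation_presence(n, 20000, gamma, seed = s))
    suppressWarnings(chisq.test(tabulate(m, n), p = prob))$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("technical replicates pair with their source samples", {
  co <- small_cohort()
  tr <- make_technical_replicates(co, noise_sd = 0.2, seed = 4)
  qc <- replicate_qc(tr$logcpm, tr$pairs)
  expect_true(all(qc$r > 0.9))
})
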