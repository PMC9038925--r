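make_motif_fixture <- function(seed = 1, n_peaks = 800, n_samples = 24,
                               n_motifs = 30) {
  set.seed(seed)
  mu <- 2^runif(n_peaks, 2, 6)
  raw <- matrix(rnbinom(n_peaks * n_samples, size = 10, mu = rep(mu, n_samples)),
                nrow = n_peaks,
                dimnames = list(sprintf("p%04d", 1:n_peaks),
                                sprintf("s%02d", 1:n_samples)))
  M <- matrix(rbinom(n_peaks * n_motifs, 1, 0.1), n_peaks,
              dimnames = list(rownames(raw), sprintf("m%02d", 1:n_motifs)))
  M[cbind(sample(n_peaks, n_motifs), 1:n_motifs)] <- 1  # no empty motifs
  list(raw = raw, M = M)
}

test_that("a motif covering all peaks has exactly zero deviation", {
  fx <- make_motif_fixture(2)
  M <- fx$M; M[, 1] <- 1
  dev <- compute_deviations(fx$raw, M, n_background = 10, seed = 3)
  expect_equal(unname(dev$Y["m01", ]), rep(0, ncol(fx$raw)), tolerance = 1e-12)
})

test_that("deviations are exactly invariant to library-size rescaling", {
  fx <- make_motif_fixture(4)
  d1 <- compute_deviations(fx$raw, fx$M, n_background = 15, seed = 5)
  scaled <- fx$raw
  scaled[, 3] <- scaled[, 3] * 7.5
  scaled[, 10] <- scaled[, 10] * 0.2
  d2 <- compute_deviations(scaled, fx$M, n_background = 15, seed = 5)
  expect_equal(d1$Y, d2$Y, tolerance = 1e-12)
  expect_equal(d1$Z, d2$Z, tolerance = 1e-9)
})

test_that("samples with proportional columns share identical raw deviations", {
  fx <- make_motif_fixture(6)
  raw <- fx$raw
  raw[, 2] <- raw[, 1] * 3   # same composition, different depth
  dev <- compute_deviations(raw, fx$M, n_background = 10, seed = 1)
  expect_equal(unname(dev$Y[, 1]), unname(dev$Y[, 2]), tolerance = 1e-12)
})

test_that("a motif marking only cluster-1-specific peaks is detected", {
  # single planted motif against a base-rate background of motifs; the
  # planted motif must correlate positively with its cluster and rank in
  # the top 5% of variability
  detected <- vapply(1:15, function(s) {
    co <- generate_cohort(small_config(seed = 400 + s))
    set.seed(s)
    M <- matrix(rbinom(nrow(co$peaks) * 99, 1, 0.05), nrow(co$peaks),
                dimnames = list(co$peaks$peak_id, sprintf("null_%02d", 1:99)))
    M[cbind(sample(nrow(co$peaks), 99), 1:99)] <- 1
    M <- cbind(mu = as.integer(co$peaks$peak_id %in%
                                 co$cluster_specific_peaks[[1]]), M)
    dev <- compute_deviations(co$counts$raw, M, n_background = 25, seed = s)
    ind <- as.numeric(co$true_labels == 1)
    cor(dev$Z["mu", ], ind) > 0 &&
      dev$variability["mu"] >= quantile(dev$variability, 0.95, type = 1)
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("cluster-enriched selection follows sign, q and variability rules", {
  set.seed(44)
  n <- 30
  labels <- rep(1:3, each = 10)
  Z <- matrix(rnorm(50 * n), 50,
              dimnames = list(sprintf("m%02d", 1:50), paste0("s", 1:n)))
  ind <- as.numeric(labels == 1)
  Z["m01", ] <- ind * 4 + rnorm(n, 0, 0.1)       # strong positive
  Z["m02", ] <- -ind * 4 + rnorm(n, 0, 0.1)      # strong negative
  v <- setNames(rep(2, 50), rownames(Z))
  sel <- cluster_enriched_motifs(Z, v, labels, 1)
  expect_true(sel$selected[sel$motif_id == "m01"])
  expect_false(sel$selected[sel$motif_id == "m02"])  # excluded by sign
  # variability gate
  v2 <- v; v2["m01"] <- 1.0
  sel2 <- cluster_enriched_motifs(Z, v2, labels, 1)
  expect_false(sel2$selected[sel2$motif_id == "m01"])
  expect_error(cluster_enriched_motifs(Z, v, rep(1, n), 1), "two clusters")
  # monotone: raising the variability threshold never adds motifs
  s_low <- cluster_enriched_motifs(Z, v, labels, 1, v_threshold = 1)
  s_high <- cluster_enriched_motifs(Z, v, labels, 1, v_threshold = 3)
  expect_true(all(s_high$selected <= s_low$selected))
})

test_that("null deviation rows stay within the expected selection rate", {
  set.seed(91)
  labels <- rep(1:2, each = 15)
  hits <- replicate(20, {
    Z <- matrix(rnorm(400 * 30), 400,
                dimnames = list(sprintf("m%03d", 1:400), paste0("s", 1:30)))
    v <- setNames(rep(2, 400), rownames(Z))   # all pass the v gate
    sum(cluster_enriched_motifs(Z, v, labels, 1)$selected)
  })
  # BH at q < 0.05 under a full null rejects rarely
  expect_lt(mean(hits), 0.05 * 400 * 0.5 + 3 * sd(hits) / sqrt(20) + 1)
})

test_that("motif-TF expression correlation keeps positive significant pairs", {
  set.seed(10)
  n <- 50
  Z <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("m", 1:5),
                                               paste0("s", 1:n)))
  expr <- matrix(rnorm(5 * n), 5, dimnames = list(paste0("g", 1:5),
                                                  paste0("s", 1:n)))
  expr["g1", ] <- Z["m1", ]               # exact match
  expr["g2", ] <- 3                        # constant -> skipped
  map <- data.frame(motif_id = paste0("m", 1:4),
                    gene_id = paste0("g", 1:4))
  res <- motif_expression_correlation(Z, expr, map)
  r1 <- res$results[res$results$motif_id == "m1", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_true(r1$retained)
  expect_true("m2" %in% res$skipped)   # constant expression
  expect_true("m5" %in% res$skipped)   # unmapped

  # power: population r = 0.7 at n = 50 retained in >= 95% of simulations
  kept <- replicate(200, {
    z <- rnorm(50)
    e <- z + rnorm(50, 0, sqrt(1 / 0.7^2 - 1))
    ct <- cor.test(z, e)
    ct$estimate > 0 && ct$p.value < 0.05
  })
  expect_gte(mean(kept), 0.95)
})

test_that("top-k overlap counts and its random baseline match the hypergeometric law", {
  r1 <- sprintf("m%03d", 1:50)
  expect_equal(top_k_overlap(r1, r1, 10)$overlap, 10)
  expect_equal(top_k_overlap(r1, rev(r1), 10)$overlap, 0)
  expect_error(top_k_overlap(c("a", "a", "b"), r1[1:3], 2), "duplicates")
  expect_error(top_k_overlap(r1[1:5], r1[1:5], 10), "exceeds")

  # random rankings over 414 motifs: E[overlap] = k^2 / 414
  set.seed(27)
  motifs <- sprintf("m%03d", 1:414)
  ov <- replicate(10000, {
    length(intersect(sample(motifs, 10), sample(motifs, 10)))
  })
  expected <- 100 / 414
  v_hyper <- sum((0:10)^2 * dhyper(0:10, 10, 404, 10)) - expected^2
  expect_lt(abs(mean(ov) - expected), 3 * sqrt(v_hyper / 10000))
})

test_that("hypergeometric enrichment ranking surfaces planted programs", {
  set.seed(50)
  n_peaks <- 1000
  M <- matrix(rbinom(n_peaks * 20, 1, 0.08), n_peaks,
              dimnames = list(sprintf("p%04d", 1:n_peaks),
                              sprintf("m%02d", 1:20)))
  target <- sprintf("p%04d", 1:100)
  M[1:100, "m07"] <- 1    # m07 saturates the target set
  rk <- motif_enrichment_ranking(target, M)
  expect_equal(rk$motif_id[1], "m07")
  expect_true(all(diff(rk$p) >= 0))
  expect_error(motif_enrichment_ranking("absent_peak", M), "intersect")
})
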