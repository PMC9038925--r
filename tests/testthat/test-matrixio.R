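test_that("merging overlapping and disjoint peak calls follows bedtools semantics", {
  a <- data.frame(chrom = "chr1", start = 100, end = 200)
  b <- data.frame(chrom = "chr1", start = 150, end = 250)
  m <- merge_peak_calls(list(s1 = a, s2 = b))
  expect_equal(nrow(m$peaks), 1)
  expect_equal(m$peaks$start, 100)
  expect_equal(m$peaks$end, 250)
  expect_equal(unname(m$presence[1, ]), c(1L, 1L))

  d <- merge_peak_calls(list(s1 = a, s2 = data.frame(chrom = "chr1",
                                                     start = 300, end = 400)))
  expect_equal(nrow(d$peaks), 2)
  expect_equal(unname(d$presence), rbind(c(1L, 0L), c(0L, 1L)))

  # bookended intervals merge
  bk <- merge_peak_calls(list(s1 = data.frame(chrom = "chr1", start = 0, end = 10),
                              s2 = data.frame(chrom = "chr1", start = 10, end = 20)))
  expect_equal(nrow(bk$peaks), 1)
})

test_that("merge equals the O(n^2) interval oracle and is idempotent", {
  for (seed in 1:20) {
    calls <- random_peak_calls(3, 50, seed = seed)
    m <- merge_peak_calls(calls)
    all_iv <- do.call(rbind, calls)
    expected <- oracle_merge(all_iv)
    expect_equal(m$peaks$start, expected$start)
    expect_equal(m$peaks$end, expected$end)
    expect_lte(nrow(m$peaks), nrow(all_iv))
    # presence equals brute-force overlap
    for (j in seq_along(calls)) {
      ov <- oracle_overlaps(m$peaks$start, m$peaks$end,
                            calls[[j]]$start, calls[[j]]$end)
      expect_equal(unname(m$presence[, j]), as.integer(rowSums(ov) > 0))
    }
    # idempotence
    m2 <- merge_peak_calls(list(again = m$peaks))
    expect_equal(m2$peaks$start, m$peaks$start)
    expect_equal(m2$peaks$end, m$peaks$end)
  }
})

test_that("malformed intervals are rejected with their id", {
  expect_error(peak_set("chr1", 200, 100, "bad_peak"), "bad_peak")
})

test_that("CPM normalisation is exact arithmetic and preserves rank order", {
  raw <- matrix(c(200, rep(1999800 / 3, 3)), ncol = 1)
  expect_equal(cpm_normalize(raw)$cpm[1, 1], 100)

  flat <- matrix(5, nrow = 8, ncol = 2)
  expect_equal(unique(as.vector(cpm_normalize(flat)$cpm)), 1e6 / 8)

  set.seed(3)
  r <- matrix(rpois(600, 40), nrow = 100, ncol = 6)
  cm <- cpm_normalize(r)
  expect_equal(unname(colSums(cm$cpm)), rep(1e6, 6), tolerance = 1e-9)
  for (j in 1:6) expect_equal(order(cm$cpm[, j]), order(r[, j] + seq_len(100) * 1e-9))
  expect_true(all(cm$logcpm >= 0))
  # cross-check against the field-standard implementation
  skip_if_not_installed("edgeR")
  expect_equal(unname(cm$cpm), unname(edgeR::cpm(r, lib.size = colSums(r))),
               tolerance = 1e-9)
})

test_that("zero-total columns warn and stay zero", {
  raw <- cbind(c(5, 5), c(0, 0))
  expect_warning(cm <- cpm_normalize(raw), "zero total")
  expect_equal(unname(cm$cpm[, 2]), c(0, 0))
  expect_error(cpm_normalize(matrix(c(-1, 2), 2)), "non-negative")
})

test_that("replicate QC recovers exact and noisy correlations", {
  set.seed(11)
  x <- rnorm(500, 5, 2)
  logcpm <- cbind(a = x, b = x, c = -x + 10, d = rep(1, 500))
  qc <- replicate_qc(logcpm, data.frame(sample_a = c("a", "a", "a"),
                                        sample_b = c("b", "c", "d")))
  expect_equal(qc$r[1], 1)
  expect_equal(qc$r[2], -1)
  expect_true(is.na(qc$r[3]))
  expect_true(qc$below_threshold[2])

  # population r = 0.9 via noise SD; Fisher-z oracle for the sampling band
  rho <- 0.9
  noise_sd <- sqrt(1 / rho^2 - 1) * 1   # signal SD 1
  rs <- replicate(200, {
    s <- rnorm(120)
    cor(s, s + rnorm(120, sd = noise_sd))
  })
  z <- atanh(rs)
  se_fisher <- 1 / sqrt(120 - 3)
  expect_lt(abs(mean(z) - atanh(rho)), 3 * se_fisher / sqrt(200))
})

test_that("presence histogram equals brute-force row-sum tally", {
  p <- matrix(1L, 50, 4)
  h <- presence_histogram(p)
  expect_equal(h$n_peaks, c(0, 0, 0, 50))

  eye <- diag(1L, 6)
  expect_equal(presence_histogram(eye)$n_peaks, c(6, 0, 0, 0, 0, 0))

  set.seed(9)
  b <- matrix(rbinom(1000 * 10, 1, 0.3), 1000, 10)
  h2 <- presence_histogram(b)
  expect_equal(h2$n_peaks, as.integer(table(factor(rowSums(b), levels = 1:10))))
  expect_equal(sum(h2$n_peaks), sum(rowSums(b) >= 1))
})

test_that("peak annotation distance, class and nearest gene match the all-pairs oracle", {
  genes <- gene_annotation(c("gA", "gB"), "chr1", c("+", "-"),
                           c(50000, 200000))
  # midpoint exactly at the TSS of a + strand gene
  pk <- peak_set("chr1", 49750, 50250)
  ann <- annotate_peaks(pk, genes)
  expect_equal(ann$tss_distance, 0)
  expect_equal(ann$region_class, "promoter")

  # midpoint 10 kb downstream -> DRE
  pk2 <- peak_set("chr1", 59750, 60250)
  ann2 <- annotate_peaks(pk2, genes)
  expect_equal(ann2$tss_distance, 10000)
  expect_equal(ann2$region_class, "DRE")

  # random peaks vs random TSSs: exhaustive oracle
  set.seed(21)
  tss <- sort(sample.int(2e6, 20))
  g <- gene_annotation(sprintf("g%02d", 1:20), "chr1",
                       sample(c("+", "-"), 20, TRUE), tss)
  starts <- sample.int(2e6, 200)
  pks <- peak_set("chr1", starts, starts + 500)
  ann3 <- annotate_peaks(pks, g)
  mid <- floor((pks$start + pks$end) / 2)
  for (i in seq_len(200)) {
    d_abs <- abs(mid[i] - g$tss)
    best <- which(d_abs == min(d_abs))
    best <- best[order(g$gene_id[best])][1]
    expect_equal(ann3$nearest_gene_id[i], g$gene_id[best])
    d_signed <- if (g$strand[best] == "+") mid[i] - g$tss[best] else
      g$tss[best] - mid[i]
    expect_equal(ann3$tss_distance[i], d_signed)
    cls <- if (d_signed >= -1000 && d_signed <= 100) "promoter" else
      if (abs(d_signed) > 3000 && abs(d_signed) <= 500000) "DRE" else "other"
    expect_equal(ann3$region_class[i], cls)
  }
})

test_that("annotation region classes partition the peak set", {
  co <- small_cohort()
  ann <- annotate_peaks(co$peaks, co$genes)
  expect_equal(sum(table(ann$region_class)), nrow(co$peaks))
  expect_warning(annotate_peaks(co$peaks[1:5, ],
                                co$genes[0, , drop = FALSE]), "empty gene set")
})

test_that("seven-feature classification matches a hand-enumerated tiling oracle", {
  # one + strand gene: TSS 1000, TTS 3000, exons [1000,1400) and [2600,3000),
  # utr5 [1000,1100), utr3 [2900,3000)
  genes <- gene_annotation("g1", "chr1", "+", 1000, tts = 3000)
  exons <- data.frame(gene_id = "g1", start = c(1000, 2600), end = c(1400, 3000))
  utr5 <- data.frame(gene_id = "g1", start = 1000, end = 1100)
  utr3 <- data.frame(gene_id = "g1", start = 2900, end = 3000)
  pos <- seq(0, 4000, by = 50)
  tile <- peak_set("chr1", pos, pos + 1)
  cls <- classify_genomic_features(tile, genes, exons = exons,
                                   utr5 = utr5, utr3 = utr3)
  oracle <- vapply(pos, function(s) {
    if (s >= 0 && s <= 1100) return("TSS")          # promoter window -1000..+100
    if (s >= 2900 && s <= 3100) return("TTS")       # +/-100 around TTS
    if (s >= 1000 && s < 1100) return("5'UTR")
    if (s >= 2900 && s < 3000) return("3'UTR")
    if ((s >= 1000 && s < 1400) || (s >= 2600 && s < 3000)) return("exon")
    if (s >= 1000 && s < 3000) return("intron")
    "intergenic"
  }, character(1))
  expect_equal(cls, oracle)

  # peak overlapping an exon only (outside TSS/TTS windows)
  expect_equal(classify_genomic_features(peak_set("chr1", 1200, 1300),
                                         genes, exons = exons), "exon")
  # gene-free chromosome
  expect_equal(classify_genomic_features(peak_set("chr9", 100, 200), genes),
               "intergenic")
})
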