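#' Candidate peak-gene pairs within the linkage window
#'
#' Pairs every peak with every gene whose TSS lies within +/-0.5 Mbp of the
#' peak midpoint but outside the +/-3 kbp proximal exclusion zone. A peak
#' may pair with several genes and vice versa.
#'
#' @param peaks a `peak_set`.
#' @param genes a `gene_annotation`.
#' @param min_dist,max_dist absolute distance bounds in bp (exclusive
#'   lower, inclusive upper).
#' @return data.frame `peak_id, gene_id, tss_distance` (signed,
#'   strand-oriented).
#' @export
candidate_peak_gene_pairs <- function(peaks, genes, min_dist = 3000,
                                      max_dist = 500000) {
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- list()
  for (ch in intersect(unique(peaks$chrom), unique(genes$chrom))) {
    pk <- which(peaks$chrom == ch)
    gn <- which(genes$chrom == ch)
    d <- outer(mid[pk], genes$tss[gn], "-")
    hit <- which(abs(d) > min_dist & abs(d) <= max_dist, arr.ind = TRUE)
    if (!nrow(hit)) next
    gi <- gn[hit[, 2]]
    out[[ch]] <- data.frame(
      peak_id = peaks$peak_id[pk[hit[, 1]]],
      gene_id = genes$gene_id[gi],
      tss_distance = signed_tss_distance(mid[pk[hit[, 1]]], genes$tss[gi],
                                         genes$strand[gi]),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      tss_distance = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$peak_id, res$gene_id), , drop = FALSE]
}

#' Link peaks to genes by accessibility-expression correlation
#'
#' For each candidate pair, computes the Pearson correlation between the
#' peak's log2(CPM+1) accessibility and the gene's expression across the
#' shared samples. The mean and SD of all candidate-pair correlations form
#' an empirical null of nonspecific correlation; each pair's z score
#' against that null yields a two-sided normal p value, Benjamini-Hochberg
#' corrected across pairs, with links called significant at
#' `FDR < fdr_threshold`.
#'
#' @param logcpm_acc peaks x samples accessibility matrix.
#' @param expression genes x samples expression matrix.
#' @param pairs candidate pairs from [candidate_peak_gene_pairs()].
#' @param fdr_threshold significance cut-off (default 0.05).
#' @return data.frame of class `peak_gene_links`: `peak_id, gene_id,
#'   tss_distance, r, z, p, FDR, significant`.
#' @export
link_peaks_to_genes <- function(logcpm_acc, expression, pairs,
                                fdr_threshold = 0.05) {
  shared <- intersect(colnames(logcpm_acc), colnames(expression))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  acc <- logcpm_acc[, shared, drop = FALSE]
  expr <- expression[, shared, drop = FALSE]
  pairs <- pairs[pairs$peak_id %in% rownames(acc) &
                   pairs$gene_id %in% rownames(expr), , drop = FALSE]
  if (!nrow(pairs)) stop("no candidate pairs with data")

  zrow <- function(m) {
    mu <- rowMeans(m); sd <- sqrt(rowVars(m))
    list(z = (m - mu) / ifelse(sd > 0, sd, NA_real_), constant = sd == 0)
  }
  za <- zrow(acc[pairs$peak_id, , drop = FALSE])
  ze <- zrow(expr[pairs$gene_id, , drop = FALSE])
  drop <- za$constant | ze$constant
  if (any(drop))
    message(sum(drop), " pair(s) with constant profiles dropped")
  pairs <- pairs[!drop, , drop = FALSE]
  r <- rowSums(za$z[!drop, , drop = FALSE] * ze$z[!drop, , drop = FALSE]) /
    (length(shared) - 1)

  mu <- mean(r); sigma <- stats::sd(r)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate correlation null (zero SD)")
  z <- (r - mu) / sigma
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(pairs, r = r, z = z, p = p, FDR = fdr,
                    significant = fdr < fdr_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("peak_gene_links", "data.frame")
  out
}

#' Peaks linked to a set of genes
#'
#' Reverse lookup used by the cross-species conversion: the union of peaks
#' linked (significantly, by default) to any of the query genes.
#'
#' @param gene_ids character vector of gene ids.
#' @param links a `peak_gene_links` table.
#' @param significant_only restrict to FDR-significant links.
#' @return list: `peak_ids` (deduplicated), `genes_without_links`.
#' @export
genes_to_peaks <- function(gene_ids, links, significant_only = TRUE) {
  gene_ids <- unique(gene_ids)
  sel <- links$gene_id %in% gene_ids
  if (significant_only) sel <- sel & links$significant
  hit_genes <- unique(links$gene_id[sel])
  list(peak_ids = unique(links$peak_id[sel]),
       genes_without_links = setdiff(gene_ids, hit_genes))
}
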