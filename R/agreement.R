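#' Agreement between two clusterings
#'
#' Computes the contingency table of two labelings of the same samples, the
#' matched agreement (the maximal fraction of samples on the diagonal over
#' all one-to-one matchings of cluster labels, found exactly by
#' enumerating label permutations), and the adjusted Rand index.
#'
#' @param labels_a,labels_b vectors of cluster labels. When both are named,
#'   samples are aligned by name; otherwise they are matched by position.
#' @return list: `table` (contingency), `matched_agreement` in [0, 1],
#'   `ari`.
#' @export
cluster_agreement <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (!length(common)) stop("label vectors share no samples")
    if (length(common) < length(labels_a) || length(common) < length(labels_b))
      stop("label vectors cover different sample sets")
    labels_a <- labels_a[common]; labels_b <- labels_b[common]
  } else if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length")
  }
  keep <- !is.na(labels_a) & !is.na(labels_b)
  labels_a <- labels_a[keep]; labels_b <- labels_b[keep]
  tab <- table(labels_a, labels_b)
  list(table = tab,
       matched_agreement = matched_agreement(tab),
       ari = adjusted_rand_index(tab))
}

#' Matched agreement from a contingency table
#'
#' Maximises `sum(tab[i, sigma(i)]) / n` over one-to-one assignments
#' `sigma` of row labels to column labels, by exact enumeration of
#' permutations (cluster counts here are small, k <= 8).
#' @param tab contingency table/matrix.
#' @export
matched_agreement <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  k <- max(dim(tab))
  if (k > 9) stop("exact matching supported for up to 9 clusters")
  sq <- matrix(0, k, k)
  sq[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  best <- 0
  for (p in all_permutations(k)) {
    s <- sum(sq[cbind(seq_len(k), p)])
    if (s > best) best <- s
  }
  best / n
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in all_permutations(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Adjusted Rand index from a contingency table
#'
#' Standard permutation-model chance-corrected Rand index.
#' @param tab contingency table/matrix.
#' @export
adjusted_rand_index <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n < 2) return(NA_real_)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}
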