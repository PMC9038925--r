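#' Select the most variable peaks
#'
#' Ranks peaks by the row variance of their log2(CPM+1) accessibility and
#' returns the top fraction (default 20%) or a fixed count. Ties are broken
#' by peak id so the selection is deterministic.
#'
#' @param logcpm numeric matrix, peaks x samples, with peak-id rownames.
#' @param fraction fraction in (0, 1] of peaks to keep (default 0.2).
#' @param count absolute number of peaks; overrides `fraction` when given.
#' @return integer vector of row indices (named by peak id), ordered by
#'   decreasing variance.
#' @export
select_top_variance_peaks <- function(logcpm, fraction = 0.2, count = NULL) {
  if (ncol(logcpm) < 2) stop("need at least 2 samples")
  n <- if (!is.null(count)) {
    if (count < 1 || count > nrow(logcpm)) stop("count out of range")
    as.integer(count)
  } else {
    if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
    max(1L, round(fraction * nrow(logcpm)))
  }
  v <- rowVars(logcpm)
  ids <- rownames(logcpm)
  if (is.null(ids)) ids <- sprintf("row_%06d", seq_len(nrow(logcpm)))
  ord <- order(-v, ids)
  idx <- ord[seq_len(n)]
  stats::setNames(idx, ids[idx])
}

rowVars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Non-smooth NMF by KL-divergence multiplicative updates
#'
#' Factorises a non-negative matrix V (features x samples) as `W S H`,
#' where `S = (1 - theta) I + (theta/k) 11'` is the non-smooth NMF
#' smoothing matrix; `theta > 0` drives sparseness of the factors while `S`
#' absorbs the smooth part. Updates are the standard KL multiplicative
#' rules with `S H` substituted for `H` in the W step and `W S` for `W` in
#' the H step, so the objective `D(V || WSH)` is non-increasing. Entries
#' are floored at `eps` to keep the updates well defined on zero rows.
#'
#' @param V non-negative matrix, no all-zero matrix.
#' @param k factorisation rank, `k < min(dim(V))`.
#' @param theta smoothing in `[0, 1]` (0 = plain KL-NMF).
#' @param seed integer seed for the uniform (0,1] initialisation; `NULL`
#'   uses the current RNG state.
#' @param max_iter,tol stopping rule: relative objective change below `tol`
#'   (checked every `check_every` iterations) or `max_iter` iterations.
#' @param check_every objective recording/checking interval.
#' @param stable_stop when positive, also stop once the per-sample argmax
#'   factor of H has been unchanged for `stable_stop` consecutive label
#'   checks (every `label_every` iterations) — the stopping rule consensus
#'   clustering uses, since only the assignment pattern enters the
#'   connectivity matrix. 0 disables it.
#' @param label_every interval of the argmax-stability check.
#' @param single_precision run the multiplicative updates in single
#'   precision; only meaningful when the consumer needs the assignment
#'   pattern rather than a tightly converged objective.
#' @return list of class `nsnmf_fit`: `W`, `H`, `S`, `theta`, `objective`
#'   (recorded trace), `objective_iter`, `iterations`, `converged`, `seed`.
#' @export
nsnmf_factorize <- function(V, k, theta = 0.5, seed = NULL,
                            max_iter = 2000, tol = 1e-9, check_every = 10,
                            stable_stop = 0, label_every = 5,
                            single_precision = FALSE) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (all(V == 0)) stop("V must not be all zero")
  if (k >= min(dim(V))) stop("k must be smaller than both dimensions of V")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  # uniform (0,1] initialisation; randomness stays in R's RNG
  W0 <- matrix(1 - stats::runif(nrow(V) * k), nrow(V), k)
  H0 <- matrix(1 - stats::runif(k * ncol(V)), k, ncol(V))
  res <- nsnmf_core(V, W0, H0, theta, as.integer(max_iter), tol,
                    as.integer(check_every), as.integer(label_every),
                    1e-12, as.integer(stable_stop), single_precision)
  S <- (1 - theta) * diag(k) + theta / k
  dimnames(res$W) <- list(rownames(V), NULL)
  dimnames(res$H) <- list(NULL, colnames(V))
  structure(list(W = res$W, H = res$H, S = S, theta = theta,
                 objective = res$objective, objective_iter = res$objective_iter,
                 iterations = res$iterations, converged = res$converged,
                 seed = seed), class = "nsnmf_fit")
}

#' Assign samples to clusters from an H matrix
#'
#' Each sample takes the factor with the largest coefficient in its column
#' of H; ties go to the lowest factor index. All-zero columns are
#' unassignable and reported as `NA`.
#'
#' @param H k x samples non-negative matrix (or an `nsnmf_fit`).
#' @return integer vector of labels in 1..k, named by sample.
#' @export
assign_clusters <- function(H) {
  if (inherits(H, "nsnmf_fit")) H <- H$H
  lab <- max.col(t(H), ties.method = "first")
  zero <- colSums(H) == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with all-zero H column left unassigned")
    lab[zero] <- NA_integer_
  }
  stats::setNames(lab, colnames(H))
}

#' Consensus clustering with cophenetic model selection
#'
#' Runs `n_runs` nsNMF factorisations per candidate rank k. Each run's
#' connectivity matrix marks sample pairs sharing the argmax factor of H;
#' the consensus matrix is their mean. The cophenetic correlation of each
#' consensus (Pearson correlation between the condensed distances
#' `1 - consensus` and the cophenetic distances of their average-linkage
#' dendrogram) measures clustering stability; the chosen k is the largest
#' rank whose consensus resolves k majority-co-clustering blocks and whose
#' cophenetic correlation is within the consensus resolution (half of
#' 1/n_runs) of the maximum over such ranks. On strongly separable data a
#' coarser k can be perfectly stable as well (all runs merge the same
#' clusters), a finer k whose inconsistent extra splits collapse back to
#' fewer majority blocks is only re-finding a smaller model, and rho
#' differences below the shift a single deviant restart induces are not
#' evidence — so the informative rank is the last one before stability
#' genuinely begins to fall.
#'
#' @param V non-negative matrix, features x samples.
#' @param k_range candidate ranks (default 2:8).
#' @param n_runs factorisation restarts per k (>= 2).
#' @param theta nsNMF smoothing.
#' @param seed master seed; run seeds are derived from it.
#' @param max_iter,tol per-run stopping rule.
#' @param stable_stop consensus runs stop once the assignment pattern has
#'   been unchanged this many consecutive checks (see
#'   [nsnmf_factorize()]); the connectivity matrix only depends on that
#'   pattern, so deeper objective convergence would not change the
#'   consensus.
#' @param single_precision run consensus factorisations in single
#'   precision (default): only the argmax pattern of H is consumed.
#' @return list of class `cluster_result`: `chosen_k`, `labels`,
#'   `cophenetic` (named by k), `consensus` (list of matrices), `best_fit`
#'   (lowest-objective `nsnmf_fit` at the chosen k), `n_runs`, `seed`.
#' @export
consensus_cophenetic <- function(V, k_range = 2:8, n_runs = 30, theta = 0.5,
                                 seed = 1, max_iter = 500, tol = 1e-9,
                                 stable_stop = 8, single_precision = TRUE) {
  if (n_runs < 2) stop("need at least 2 runs")
  V <- as.matrix(V)
  n <- ncol(V)
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(k_range) * n_runs),
                      nrow = length(k_range))
  rho <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  consensus <- list()
  best_fits <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cons <- matrix(0, n, n)
    valid <- 0L
    best <- NULL
    for (r in seq_len(n_runs)) {
      fit <- nsnmf_factorize(V, k, theta = theta, seed = run_seeds[i, r],
                             max_iter = max_iter, tol = tol,
                             stable_stop = stable_stop,
                             single_precision = single_precision)
      lab <- suppressWarnings(assign_clusters(fit$H))
      if (anyNA(lab)) next   # degenerate run discarded
      cons <- cons + outer(lab, lab, "==")
      valid <- valid + 1L
      obj <- fit$objective[length(fit$objective)]
      if (is.null(best) || obj < best$objective[length(best$objective)])
        best <- fit
    }
    if (valid < 2) stop("fewer than 2 valid runs at k = ", k)
    cons <- cons / valid
    dimnames(cons) <- list(colnames(V), colnames(V))
    consensus[[as.character(k)]] <- cons
    best_fits[[as.character(k)]] <- best
    rho[i] <- cophenetic_score(cons)
  }
  usable <- which(is.finite(rho))
  if (!length(usable)) stop("cophenetic correlation undefined at every k")
  # Model selection: maximise the cophenetic correlation over the ranks
  # whose consensus actually resolves k majority-co-clustering blocks
  # (connected components of consensus >= 0.5). A coarser k than the true
  # structure can be perfectly stable too (every run merges the same
  # clusters), and a finer k whose inconsistent splits collapse back to
  # fewer majority blocks is only re-finding a smaller model; neither
  # says anything about rank k itself. Among near-maximal valid ranks the
  # largest wins — the informative rank is the last one before stability
  # begins to fall — where "near" means within the consensus resolution:
  # a single restart deviating shifts consensus entries by 1/n_runs, so
  # rho differences below ~1/(2 n_runs) are not evidence against a rank.
  n_blocks <- vapply(as.character(k_range), function(kk)
    consensus_block_count(consensus[[kk]]), integer(1))
  valid <- usable[n_blocks[usable] == k_range[usable]]
  if (!length(valid)) valid <- usable
  band <- 0.5 / n_runs
  top <- k_range[valid][rho[valid] >= max(rho[valid]) - band]
  chosen <- max(top)
  labels <- assign_clusters(best_fits[[as.character(chosen)]]$H)
  structure(list(chosen_k = chosen, labels = labels, cophenetic = rho,
                 consensus = consensus,
                 best_fit = best_fits[[as.character(chosen)]],
                 k_range = k_range, n_runs = n_runs, theta = theta,
                 seed = seed), class = "cluster_result")
}

#' Majority co-clustering blocks of a consensus matrix
#'
#' Number of connected components of the graph joining sample pairs that
#' co-cluster in at least `threshold` of the consensus runs.
#' @param consensus symmetric samples x samples matrix in [0, 1].
#' @param threshold co-clustering majority threshold (default 0.5).
#' @export
consensus_block_count <- function(consensus, threshold = 0.5) {
  n <- nrow(consensus)
  adj <- consensus >= threshold
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  cur
}

#' Cophenetic correlation of a consensus matrix
#'
#' @param consensus symmetric samples x samples matrix with entries in
#'   [0, 1] and unit diagonal.
#' @return Pearson correlation between the condensed distances
#'   `1 - consensus` and the cophenetic distances of their average-linkage
#'   tree; `NA` when the distances are constant. A perfectly binary
#'   block-structured consensus is ultrametric and scores exactly 1.
#' @export
cophenetic_score <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) {
    # all pairs identical: a perfect all-zero distance (single block) is a
    # perfectly stable consensus; define its score as 1
    return(if (all(d == 0)) 1 else NA_real_)
  }
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) return(NA_real_)
  stats::cor(d, cd)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: chosen k =", x$chosen_k, "\ncophenetic:",
      paste(sprintf("k=%s %.3f", names(x$cophenetic), x$cophenetic),
            collapse = ", "), "\n")
  invisible(x)
}
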