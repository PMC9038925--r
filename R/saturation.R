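#' Cumulative peak-discovery (saturation) curve
#'
#' Random-sampling saturation analysis: samples are drawn in random order
#' and the cumulative number of distinct peaks present in the first x
#' samples is recorded; the curve is averaged over `n_draws` random
#' orderings.
#'
#' @param presence binary matrix, peaks x samples.
#' @param n_draws number of random sample orderings (>= 1).
#' @param seed integer seed.
#' @return list of class `saturation_curve`: `x` (1..N), `mean`, `sd`
#'   (across draws), `n_draws`, `seed`.
#' @export
build_saturation_curve <- function(presence, n_draws = 100, seed = 1) {
  if (is.null(dim(presence)) || nrow(presence) == 0 || ncol(presence) == 0)
    stop("empty presence matrix")
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  N <- ncol(presence)
  any_row <- rowSums(presence) > 0
  m <- presence[any_row, , drop = FALSE]
  # weight columns so that the row-max identifies the first carrying sample
  w <- rev(seq_len(N))
  curves <- matrix(0, n_draws, N)
  for (d in seq_len(n_draws)) {
    perm <- sample.int(N)
    first <- max.col(m[, perm, drop = FALSE] *
                       matrix(w, nrow(m), N, byrow = TRUE), ties.method = "first")
    curves[d, ] <- cumsum(tabulate(first, nbins = N))
  }
  structure(list(x = seq_len(N), mean = colMeans(curves),
                 sd = apply(curves, 2, stats::sd), n_draws = n_draws,
                 seed = seed, total_peaks = sum(any_row)),
            class = "saturation_curve")
}

#' Fit the exponential saturation model
#'
#' Fits `P(x) = a + B * exp(c * x)` to a saturation curve by least squares.
#' The textbook four-parameter form `a + b * exp(c*x + d)` is
#' over-parameterised (only `b * exp(d)` enters the model), so the fit uses
#' the identifiable amplitude `B = b * exp(d)` and reports `d = 0`. For a
#' fixed rate `c` the remaining parameters solve a linear least-squares
#' problem, so the fit profiles out `(a, B)` and minimises the residual sum
#' of squares over `c` alone (self-starting from a log-linearised slope),
#' which is deterministic and needs no iterative convergence machinery.
#'
#' @param curve a `saturation_curve`, or a list/data.frame with `x` and
#'   `mean` (or `y`).
#' @return list of class `saturation_fit`: `a` (asymptote), `B`, `c`, `b`
#'   (= B), `d` (= 0), `sse`, `converged`, `saturating` (c < 0),
#'   `degenerate` (flat curve).
#' @export
fit_saturation_model <- function(curve) {
  x <- curve$x
  y <- if (!is.null(curve$mean)) curve$mean else curve$y
  if (length(x) < 4) stop("need at least 4 curve points")
  if (stats::sd(y) == 0) {
    return(structure(list(a = y[1], B = 0, c = NA_real_, b = 0, d = 0,
                          sse = 0, converged = TRUE, saturating = FALSE,
                          degenerate = TRUE), class = "saturation_fit"))
  }

  profile_sse <- function(cc) {
    e <- exp(cc * x)
    fit <- stats::lm.fit(cbind(1, e), y)
    sum(fit$residuals^2)
  }
  # self-start: log-linearise the residual from a ceiling just above max(y)
  a0 <- max(y) + 0.05 * (max(y) - min(y)) + 1e-9
  r <- a0 - y
  c0 <- if (all(r > 0)) {
    unname(stats::coef(stats::lm(log(r) ~ x))[2])
  } else {
    -1 / max(x)
  }
  if (!is.finite(c0) || c0 == 0) c0 <- -1 / max(x)
  # bracket the rate on a log grid around the self-start, both signs
  mag <- abs(c0)
  grid <- c(-1, 1) %o% (mag * 10^seq(-2, 2, by = 0.25))
  grid <- grid[abs(grid * max(x)) < 700]       # avoid exp overflow
  sse_grid <- vapply(grid, profile_sse, numeric(1))
  best <- grid[which.min(sse_grid)]
  lo <- best / 10^0.3; hi <- best * 10^0.3
  interval <- sort(c(lo, hi))
  opt <- stats::optimize(profile_sse, interval = interval, tol = 1e-12)
  cc <- opt$minimum
  e <- exp(cc * x)
  ab <- stats::lm.fit(cbind(1, e), y)$coefficients
  structure(list(a = unname(ab[1]), B = unname(ab[2]), c = cc,
                 b = unname(ab[2]), d = 0, sse = opt$objective,
                 converged = TRUE, saturating = is.finite(cc) && cc < 0,
                 degenerate = FALSE), class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("saturation_fit: P(x) = %.4g + %.4g * exp(%.4g x), SSE %.4g\n",
              x$a, x$B, x$c, x$sse))
  invisible(x)
}

#' Sample number at saturation
#'
#' Smallest integer n with `P(n) >= fraction * a`, where `a` is the fitted
#' asymptote (the predicted total number of accessible regions). The
#' criterion for "all regions detected" is a configurable fraction of the
#' asymptote since the asymptote itself is only attained in the limit.
#'
#' @param fit a `saturation_fit` with `c < 0`.
#' @param fraction target fraction of the asymptote, in (0, 1).
#' @return integer sample number.
#' @export
saturation_sample_size <- function(fit, fraction = 0.99) {
  if (isTRUE(fit$degenerate)) return(1L)
  if (!is.finite(fit$c) || fit$c >= 0)
    stop("saturation point undefined for non-saturating fit (c >= 0)")
  if (fit$B == 0) return(1L)
  if (fraction >= 1)
    stop("the asymptote is never attained; choose fraction < 1")
  if (fraction <= 0) stop("fraction must lie in (0, 1)")
  if (fit$B > 0)
    stop("saturation point undefined for a curve approaching from above (B > 0)")
  # a + B e^{cn} >= f a  <=>  e^{cn} <= a(1-f)/(-B)
  n <- ceiling((log(fit$a * (1 - fraction)) - log(-fit$B)) / fit$c)
  n <- max(n, 1)
  # guard against floating-point edge at the ceiling boundary
  while (fit$a + fit$B * exp(fit$c * n) < fraction * fit$a) n <- n + 1
  as.integer(n)
}
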