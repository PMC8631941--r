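#' Pairwise maximum-entropy model parameters
#'
#' Bundle of basal activities `h` (length N) and symmetric couplings `J`
#' (N x N, zero diagonal). Under the model the probability of an activity
#' pattern V is the Boltzmann weight exp(-E(V)) with
#' E(V) = -sum_i h_i sigma_i - 1/2 sum_ij J_ij sigma_i sigma_j.
#'
#' @param h numeric vector of basal activities.
#' @param J symmetric numeric matrix of pairwise couplings, zero diagonal.
#' @return an object of class `mem_params`.
#' @export
mem_params <- function(h, J) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  stopifnot(nrow(J) == n, ncol(J) == n)
  if (max(abs(J - t(J))) > 1e-10) stop("J must be symmetric")
  if (max(abs(diag(J))) > 1e-12) stop("J must have zero diagonal")
  J <- (J + t(J)) / 2
  diag(J) <- 0
  structure(list(h = h, J = J, n_roi = n), class = "mem_params")
}

#' @export
print.mem_params <- function(x, ...) {
  cat("Pairwise maximum-entropy model, N =", x$n_roi, "ROIs\n")
  cat("  h:", signif(x$h, 3), "\n")
  cat("  |J| range:", signif(range(abs(x$J[upper.tri(x$J)])), 3), "\n")
  invisible(x)
}

#' Energy of activity patterns
#'
#' E(V) = -sum_i h_i sigma_i - 1/2 sum_ij J_ij sigma_i sigma_j. With a
#' symmetric zero-diagonal J the double sum equals twice the sum over
#' distinct pairs, so the pairwise term is -sum_{i<j} J_ij sigma_i sigma_j.
#'
#' @param params a [mem_params()] object.
#' @param pattern a +1/-1 vector, or a matrix with one pattern per row.
#' @return numeric energy (one value per pattern).
#' @export
pattern_energy <- function(params, pattern) {
  stopifnot(inherits(params, "mem_params"))
  if (!is.matrix(pattern)) pattern <- matrix(pattern, nrow = 1)
  if (ncol(pattern) != params$n_roi) stop("pattern length does not match N")
  check_pm1(pattern)
  field <- pattern %*% params$h
  pair <- rowSums((pattern %*% params$J) * pattern) / 2
  drop(-field - pair)
}

#' Exact Boltzmann distribution over all patterns
#'
#' Enumerates all 2^N patterns and returns their energies and normalised
#' probabilities P(V_k) = exp(-E_k) / sum_l exp(-E_l), computed on the log
#' scale for numerical stability.
#'
#' @param params a [mem_params()] object (N <= 20).
#' @return an object of class `pattern_distribution` with elements
#'   `probs`, `energies`, `n_roi` and `log_z`.
#' @export
boltzmann_distribution <- function(params) {
  stopifnot(inherits(params, "mem_params"))
  if (params$n_roi > 20) stop("exact enumeration limited to N <= 20")
  e <- pattern_energy(params, all_patterns(params$n_roi))
  if (any(!is.finite(e))) stop("non-finite pattern energies")
  m <- max(-e)
  log_z <- m + log(sum(exp(-e - m)))
  structure(list(probs = exp(-e - log_z), energies = e,
                 n_roi = params$n_roi, log_z = log_z),
            class = "pattern_distribution")
}

#' Empirical moments and pattern frequencies of a binary series
#'
#' Time averages <sigma_i>, <sigma_i sigma_j> and the appearance frequency
#' of each of the 2^N patterns (zeros allowed), the sufficient statistics
#' for pairwise maximum-entropy fitting.
#'
#' @param series a `binary_series` (see [binarise()]) or a +1/-1 matrix
#'   with one time sample per row.
#' @return list with `mean` (length N), `corr` (N x N, unit diagonal),
#'   `freq` (length 2^N, sums to 1) and `n_samples`.
#' @export
empirical_moments <- function(series) {
  x <- series_matrix(series)
  if (nrow(x) < 1) stop("empty series")
  n <- ncol(x)
  m <- colMeans(x)
  cc <- crossprod(x) / nrow(x)
  idx <- pattern_to_index(x)
  freq <- tabulate(idx, nbins = 2^n) / nrow(x)
  list(mean = m, corr = cc, freq = freq, n_samples = nrow(x))
}

series_matrix <- function(series) {
  x <- if (inherits(series, "binary_series")) series$values else series
  x <- as.matrix(x)
  check_pm1(x)
  x
}

#' Fit the pairwise maximum-entropy model by gradient ascent
#'
#' Adjusts h and J until the model moments (from exact enumeration each
#' iteration) match the empirical moments:
#' h_i <- h_i + eta (<sigma_i> - <sigma_i>_m),
#' J_ij <- J_ij + eta (<sigma_i sigma_j> - <sigma_i sigma_j>_m).
#' These are the likelihood gradients, so the ascent maximises the
#' log-likelihood of the data. The step size decays geometrically when the
#' moment gap oscillates.
#'
#' @param series binary series or +1/-1 matrix (at least 2 distinct
#'   patterns).
#' @param learning_rate initial step size eta.
#' @param tol convergence tolerance on the largest absolute moment gap.
#' @param max_iter iteration cap.
#' @param strict if TRUE, failure to converge is an error; otherwise the
#'   report carries `converged = FALSE`.
#' @return list with `params` ([mem_params()]) and `report` (see
#'   [fit_quality()] for the fit metrics; here `n_iterations`, `converged`,
#'   `max_moment_gap` plus the quality metrics computed on the input).
#' @export
fit_pairwise_mem <- function(series, learning_rate = 0.1, tol = 1e-4,
                             max_iter = 1e5, strict = FALSE) {
  emp <- empirical_moments(series)
  n <- length(emp$mean)
  if (sum(emp$freq > 0) < 2) stop("series is degenerate (a single pattern)")
  pats <- all_patterns(n)
  h <- rep(0, n)
  J <- matrix(0, n, n)
  eta <- learning_rate
  prev_gap <- Inf
  gap <- Inf
  iter <- 0L
  off <- upper.tri(J) | lower.tri(J)
  while (iter < max_iter) {
    iter <- iter + 1L
    e <- -(pats %*% h) - rowSums((pats %*% J) * pats) / 2
    w <- exp(-(e - min(e)))
    p <- w / sum(w)
    m_mod <- drop(crossprod(pats, p))
    c_mod <- crossprod(pats, pats * drop(p))
    gh <- emp$mean - m_mod
    gJ <- emp$corr - c_mod
    diag(gJ) <- 0
    gap <- max(max(abs(gh)), max(abs(gJ[off])))
    if (gap < tol) break
    if (gap > prev_gap * 1.2) eta <- eta * 0.5  # damp oscillation
    prev_gap <- gap
    h <- h + eta * gh
    J <- J + eta * gJ
  }
  converged <- gap < tol
  if (!converged && strict) {
    stop(sprintf("MEM fit did not converge (gap %.3g after %d iterations)",
                 gap, iter))
  }
  params <- mem_params(h, J)
  report <- fit_quality(params, series)
  report$n_iterations <- iter
  report$converged <- converged
  report$max_moment_gap <- gap
  list(params = params, report = report)
}

#' Goodness of fit of a pairwise model
#'
#' Two metrics used to judge the fit: the Pearson correlation between the
#' model pattern probabilities and the empirical pattern frequencies, and
#' the KL-divergence accuracy (D1 - D2)/D1, where D1 is the divergence of
#' the empirical distribution from the best first-order (independent)
#' model and D2 its divergence from the pairwise model. Empirical-zero
#' patterns contribute 0 to both divergences (0 log 0 = 0 convention). The
#' first-order reference has J = 0 and h_i = atanh(<sigma_i>) (clipped for
#' degenerate means), which matches the empirical means exactly.
#'
#' @param params fitted [mem_params()].
#' @param series the binary series the model was fitted to.
#' @return list of class `mem_fit_report`: `pearson_r`, `kl_ratio`, `d1`,
#'   `d2`, `d1_zero` flag.
#' @export
fit_quality <- function(params, series) {
  emp <- empirical_moments(series)
  p2 <- boltzmann_distribution(params)$probs
  m_clip <- pmin(pmax(emp$mean, -1 + 1e-9), 1 - 1e-9)
  p1 <- boltzmann_distribution(
    mem_params(atanh(m_clip), matrix(0, length(m_clip), length(m_clip))))$probs
  kl <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * (log(p[nz]) - log(q[nz])))
  }
  d1 <- kl(emp$freq, p1)
  d2 <- kl(emp$freq, p2)
  d1_zero <- d1 <= 1e-12
  structure(list(
    pearson_r = if (stats::sd(p2) == 0 || stats::sd(emp$freq) == 0)
      NA_real_ else stats::cor(p2, emp$freq),
    kl_ratio = if (d1_zero) 0 else (d1 - d2) / d1,
    d1 = d1, d2 = d2, d1_zero = d1_zero,
    n_iterations = NA_integer_, converged = NA, max_moment_gap = NA_real_
  ), class = "mem_fit_report")
}

#' @export
print.mem_fit_report <- function(x, ...) {
  cat(sprintf("MEM fit: r = %.4f, (D1-D2)/D1 = %.4f", x$pearson_r, x$kl_ratio))
  if (!is.na(x$converged)) {
    cat(sprintf(" [%s after %d iterations, gap %.2g]",
                if (x$converged) "converged" else "NOT converged",
                x$n_iterations, x$max_moment_gap))
  }
  cat("\n")
  invisible(x)
}
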