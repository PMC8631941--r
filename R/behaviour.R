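#' Median percept duration of a run
#'
#' Median duration of the clear (non-mixed) percept events; mixed events
#' are excluded. The median is used because percept durations are
#' long-tailed.
#'
#' @param events data frame with `onset`, `offset` (seconds) and
#'   `percept` (`"up"`, `"down"`, or `"mixed"`).
#' @return median duration in seconds.
#' @export
median_percept_duration <- function(events) {
  stopifnot(all(c("onset", "offset", "percept") %in% names(events)))
  clear <- events[events$percept != "mixed", , drop = FALSE]
  if (nrow(clear) == 0) stop("no clear-percept events")
  durations <- clear$offset - clear$onset
  if (any(durations < 0)) stop("events with negative duration")
  stats::median(durations)
}

#' Proportional change of a stimulation condition vs control
#'
#' (TMS - control) / control.
#'
#' @param tms,control median percept durations in seconds (control > 0).
#' @return fraction (vectorised).
#' @export
proportional_change <- function(tms, control) {
  if (any(control <= 0)) stop("control duration must be positive")
  (tms - control) / control
}

#' Mean absolute percentage error
#'
#' mean(|pred - obs| / |obs|) * 100.
#'
#' @param pred,obs equal-length numeric vectors; obs must be non-zero.
#' @return percentage.
#' @export
mape <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (any(obs == 0)) stop("observations must be non-zero")
  mean(abs(pred - obs) / abs(obs)) * 100
}

#' Correlation-strength decay profile over sliding windows
#'
#' For each analysis-window start, the across-participant Pearson
#' correlation between the simulated barrier change and the neural
#' effect measured in that window, expressed as the absolute Fisher z.
#'
#' @param effect_matrix participants x windows matrix of neural effects.
#' @param barrier_deltas per-participant barrier changes.
#' @param window_starts window start times (seconds), one per column.
#' @return data frame with `t_start`, `r`, `abs_z`.
#' @export
decay_profile <- function(effect_matrix, barrier_deltas, window_starts) {
  effect_matrix <- as.matrix(effect_matrix)
  stopifnot(nrow(effect_matrix) == length(barrier_deltas),
            ncol(effect_matrix) == length(window_starts),
            nrow(effect_matrix) >= 3)
  out <- vapply(seq_along(window_starts), function(j) {
    y <- effect_matrix[, j]
    if (stats::sd(y) == 0 || stats::sd(barrier_deltas) == 0) {
      stop("degenerate variance in window ", j)
    }
    stats::cor(barrier_deltas, y)
  }, numeric(1))
  data.frame(t_start = window_starts, r = out, abs_z = abs(atanh(out)))
}

#' Mediation analysis by product of coefficients
#'
#' Ordinary-least-squares mediation of X -> M -> Y: alpha from M ~ X,
#' beta and gamma-prime from Y ~ X + M, gamma from Y ~ X. The indirect
#' effect alpha * beta gets a percentile bootstrap confidence interval
#' over participants. For these linear models gamma = gamma' +
#' alpha * beta holds identically.
#'
#' @param X,M,Y equal-length numeric vectors (>= 10 participants).
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return an object of class `mediation_result`: `alpha`, `beta`,
#'   `gamma`, `gamma_prime`, `indirect`, `ci` (percentile bounds),
#'   `n_boot`, `boot` (resampled indirect effects).
#' @export
mediate <- function(X, M, Y, n_boot = 5000, seed = 1, conf = 0.95) {
  n <- length(X)
  stopifnot(length(M) == n, length(Y) == n, n >= 10)
  if (abs(stats::cor(X, M)) > 0.999) {
    warning("X and M are nearly collinear; estimates are unstable")
  }
  coefs <- function(x, m, y) {
    a <- stats::coef(stats::lm(m ~ x))[["x"]]
    fit2 <- stats::coef(stats::lm(y ~ x + m))
    g <- stats::coef(stats::lm(y ~ x))[["x"]]
    c(alpha = a, beta = fit2[["m"]], gamma = g,
      gamma_prime = fit2[["x"]])
  }
  est <- coefs(X, M, Y)
  local_seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    cf <- tryCatch(coefs(X[i], M[i], Y[i]),
                   error = function(e) c(alpha = NA_real_, beta = NA_real_,
                                         gamma = NA_real_,
                                         gamma_prime = NA_real_))
    cf[["alpha"]] * cf[["beta"]]
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  alpha_lvl <- (1 - conf) / 2
  structure(list(alpha = est[["alpha"]], beta = est[["beta"]],
                 gamma = est[["gamma"]],
                 gamma_prime = est[["gamma_prime"]],
                 indirect = est[["alpha"]] * est[["beta"]],
                 ci = stats::quantile(boot, c(alpha_lvl, 1 - alpha_lvl),
                                      names = FALSE),
                 n_boot = n_boot, boot = boot),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation analysis (OLS, product of coefficients)\n")
  cat(sprintf("  alpha = %.4f, beta = %.4f, gamma = %.4f, gamma' = %.4f\n",
              x$alpha, x$beta, x$gamma, x$gamma_prime))
  cat(sprintf("  indirect (alpha x beta) = %.4f, CI [%.4f, %.4f] (%d boot)\n",
              x$indirect, x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Cohen's d for paired comparisons
#'
#' Convenience effect-size utility: mean difference divided by the SD of
#' the differences.
#'
#' @param x,y paired numeric vectors.
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y) {
  d <- x - y
  mean(d) / stats::sd(d)
}
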