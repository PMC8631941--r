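#' Metropolis random walk on the energy landscape
#'
#' Single-flip Metropolis dynamics: from pattern V_i one of the N
#' Hamming-1 neighbours V_j is proposed uniformly and accepted with
#' probability min(1, exp(E_i - E_j)); a rejected proposal repeats the
#' current pattern for one step. The stationary distribution is the
#' model's Boltzmann distribution. The first `burn_in` steps are
#' discarded.
#'
#' @param x a [mem_params()] object or an `energy_landscape`.
#' @param n_steps total steps (default 1e5).
#' @param burn_in initial steps discarded (default 100).
#' @param seed integer seed; the walk is reproducible given the seed.
#' @param start optional starting pattern index (default: uniform random).
#' @return integer vector of pattern indices of length
#'   `n_steps - burn_in`, with attributes `n_roi` and `class`
#'   `"pattern_walk"`.
#' @export
metropolis_walk <- function(x, n_steps = 1e5, burn_in = 100, seed = 1,
                            start = NULL) {
  if (inherits(x, "mem_params")) x <- enumerate_landscape(x)
  stopifnot(inherits(x, "energy_landscape"), n_steps > burn_in)
  e <- x$energies
  n <- x$n_roi
  nb <- neighbour_table(n)
  local_seed(seed)
  cur <- if (is.null(start)) sample.int(length(e), 1) else as.integer(start)
  dirs <- sample.int(n, n_steps, replace = TRUE)
  us <- stats::runif(n_steps)
  traj <- integer(n_steps)
  for (s in seq_len(n_steps)) {
    prop <- nb[cur, dirs[s]]
    if (us[s] < exp(e[cur] - e[prop])) cur <- prop
    traj[s] <- cur
  }
  out <- traj[(burn_in + 1):n_steps]
  attr(out, "n_roi") <- n
  class(out) <- "pattern_walk"
  out
}

# seed the RNG for the calling function only, restoring the caller's state
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}

#' Label a pattern trajectory with major brain states
#'
#' Looks each pattern up in a [coarse_grain()] map; patterns in non-major
#' basins are labelled "Other".
#'
#' @param patterns a `pattern_walk`, a `binary_series`, or a +1/-1
#'   matrix / index vector.
#' @param map a `major_state_map` of matching width.
#' @param dt seconds per sample. Defaults to the series' own sampling
#'   interval; for simulated walks one walk step is equated to one sample
#'   at 300 Hz (the offline analysis rate), so the 10 ms smoothing
#'   defaults act on 3-step windows.
#' @param origin provenance tag stored in the sequence.
#' @return a `state_sequence`: list of `labels` (character), `dt`,
#'   `origin`.
#' @export
label_states <- function(patterns, map, dt = NULL, origin = NULL) {
  stopifnot(inherits(map, "major_state_map"))
  if (inherits(patterns, "pattern_walk")) {
    if (attr(patterns, "n_roi") != map$n_roi) stop("ROI count mismatch")
    idx <- as.integer(patterns)
    if (is.null(dt)) dt <- 1 / 300
    if (is.null(origin)) origin <- "random_walk"
  } else if (inherits(patterns, "binary_series")) {
    if (ncol(patterns$values) != map$n_roi) stop("ROI count mismatch")
    idx <- pattern_to_index(patterns$values)
    if (is.null(dt)) dt <- 1 / patterns$fs
    if (is.null(origin)) origin <- "offline"
  } else if (is.matrix(patterns)) {
    if (ncol(patterns) != map$n_roi) stop("ROI count mismatch")
    idx <- pattern_to_index(patterns)
    if (is.null(dt)) dt <- 1 / 300
    if (is.null(origin)) origin <- "offline"
  } else {
    idx <- as.integer(patterns)
    if (any(idx < 1 | idx > 2^map$n_roi)) stop("pattern index out of range")
    if (is.null(dt)) dt <- 1 / 300
    if (is.null(origin)) origin <- "offline"
  }
  state_sequence(map$label_of[idx], dt, origin)
}

#' @rdname label_states
#' @param labels character vector over F/Int/V/Other.
#' @export
state_sequence <- function(labels, dt, origin = "offline") {
  stopifnot(all(labels %in% c("F", "Int", "V", "Other")), dt > 0)
  structure(list(labels = labels, dt = dt, origin = origin),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("F", "Int", "V", "Other")))
  cat(sprintf("State sequence (%s): %d samples, dt = %g s\n",
              x$origin, length(x$labels), x$dt))
  cat("  ", paste(names(tab), as.numeric(tab), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Temporal smoothing of a state sequence
#'
#' Two-stage smoothing that removes flicker and the Other label: (1) the
#' appearance frequency of each state in a centred sliding window
#' (`window` seconds; Other counts in the denominator but is not a
#' candidate), (2) Gaussian smoothing of the three frequency curves
#' (sigma = fwhm/2.3548), then (3) per-sample argmax over F/Int/V, ties
#' resolved towards the earlier state in the fixed order F, Int, V.
#' Windows and kernels are truncated and renormalised at the sequence
#' edges.
#'
#' @param seq a `state_sequence`.
#' @param window sliding-window length in seconds (default 0.010).
#' @param fwhm Gaussian full width at half maximum in seconds
#'   (default 0.010).
#' @return a `state_sequence` of the same length containing no Other.
#' @export
smooth_states <- function(seq, window = 0.010, fwhm = 0.010) {
  stopifnot(inherits(seq, "state_sequence"))
  n <- length(seq$labels)
  w <- max(1L, round(window / seq$dt))
  if (w %% 2 == 0) w <- w + 1L
  if (n < w) stop("sequence shorter than the smoothing window")
  half <- (w - 1L) / 2L
  states <- c("F", "Int", "V")
  freq <- sapply(states, function(s) {
    cs <- cumsum(c(0, seq$labels == s))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / seq$dt
  if (sigma > 0) {
    r <- max(1L, ceiling(3 * sigma))
    kern <- stats::dnorm(-r:r, sd = sigma)
    freq <- apply(freq, 2, function(f) {
      num <- stats::convolve(f, rev(kern), type = "open")[(r + 1):(r + n)]
      den <- stats::convolve(rep(1, n), rev(kern),
                             type = "open")[(r + 1):(r + n)]
      num / den
    })
  }
  pick <- apply(freq, 1, which.max)   # which.max: first maximum wins ties
  state_sequence(states[pick], seq$dt, seq$origin)
}

#' Dwelling-time and transition statistics
#'
#' Run-length encodes a smoothed state sequence into dwelling times per
#' major state and a 3x3 matrix of transition counts between distinct
#' states (self-continuation is dwelling, not a transition).
#'
#' @param seq a smoothed `state_sequence` (no Other).
#' @param analysis_window optional `c(start, end)` in seconds relative to
#'   the sequence start; only samples inside are analysed.
#' @return an object of class `dynamics_summary`: `dwell` (mean dwelling
#'   time per state, seconds), `dwell_n` (number of completed-or-censored
#'   runs), `transitions` (counts), `transition_freq` (row-normalised,
#'   zero diagonal), `n_samples`, `dt`.
#' @export
dynamics_summary <- function(seq, analysis_window = NULL) {
  stopifnot(inherits(seq, "state_sequence"))
  labels <- seq$labels
  if (!is.null(analysis_window)) {
    i0 <- max(1L, floor(analysis_window[1] / seq$dt) + 1L)
    i1 <- min(length(labels), ceiling(analysis_window[2] / seq$dt))
    if (i0 > i1) stop("empty analysis window")
    labels <- labels[i0:i1]
  }
  if (any(labels == "Other")) {
    stop("dynamics_summary expects a smoothed sequence without Other")
  }
  states <- c("F", "Int", "V")
  r <- rle(labels)
  dwell <- vapply(states,
                  function(s) mean(r$lengths[r$values == s]) * seq$dt,
                  numeric(1))
  dwell_n <- vapply(states, function(s) sum(r$values == s), numeric(1))
  trans <- matrix(0L, 3, 3, dimnames = list(from = states, to = states))
  if (length(r$values) > 1) {
    for (i in seq_len(length(r$values) - 1)) {
      trans[r$values[i], r$values[i + 1]] <-
        trans[r$values[i], r$values[i + 1]] + 1L
    }
  }
  rs <- rowSums(trans)
  tf <- trans / ifelse(rs == 0, 1, rs)
  structure(list(dwell = dwell, dwell_n = dwell_n, transitions = trans,
                 transition_freq = tf, n_samples = length(labels),
                 dt = seq$dt),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat("Brain-state dynamics summary\n")
  cat("  mean dwell (s):",
      paste(names(x$dwell), signif(x$dwell, 3), sep = "=", collapse = ", "),
      "\n  transitions:\n")
  print(x$transitions)
  invisible(x)
}

#' Mean length of the F-Int-V-Int-F travel
#'
#' A travel cycle starts when the sequence enters the F state and
#' completes at the first return to F after the V state has been visited;
#' its length is the number of samples (steps) between start and
#' completion, so back-and-forth moves are counted. The completing F entry
#' starts the next cycle.
#'
#' @param seq a smoothed `state_sequence`.
#' @return list with `mean_steps`, `mean_seconds`, `lengths` (per cycle,
#'   steps), `n_cycles`, and `defined` (FALSE when no cycle completes; the
#'   means are then NA, never silently zero).
#' @export
travel_length <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  r <- rle(seq$labels)
  pos <- cumsum(c(1, r$lengths[-length(r$lengths)]))  # run start indices
  start <- NA_integer_
  seen_v <- FALSE
  lengths <- integer(0)
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == "F") {
      if (!is.na(start) && seen_v) {
        lengths <- c(lengths, pos[i] - start)
        start <- pos[i]
        seen_v <- FALSE
      } else if (is.na(start)) {
        start <- pos[i]
        seen_v <- FALSE
      }
    } else if (v == "V") {
      seen_v <- TRUE
    }
  }
  n_cycles <- length(lengths)
  list(mean_steps = if (n_cycles) mean(lengths) else NA_real_,
       mean_seconds = if (n_cycles) mean(lengths) * seq$dt else NA_real_,
       lengths = lengths, n_cycles = n_cycles, defined = n_cycles > 0)
}
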