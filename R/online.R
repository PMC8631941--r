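#' Configuration of the online brain-state tracker
#'
#' Timing constants of the simulated closed loop. Times are relative to
#' T = 0 at the end of the current analysis window (the most recent
#' recorded sample). Defaults follow the study design this package
#' models: 1000 ms windows at 2 kHz, 100 ms edge trims, Yule-Walker
#' AR(30) forecasts of 280 ms (covering T = -100..180 ms), a trigger
#' decision span T = 25..175 ms with a >90 % dominance criterion, a
#' preceding history span T = -95..25 ms for history-dependent
#' conditions, a 21 ms processing buffer, a 150 ms stimulation burst and
#' a 9 s refractory period.
#'
#' @param window_len analysis window length (s).
#' @param fs_online online sampling rate (Hz).
#' @param edge_trim trim at each window edge (s).
#' @param ar_order Yule-Walker autoregressive order.
#' @param forecast_len forecast length (s); must equal
#'   `edge_trim + decision_span[2]`.
#' @param decision_span `c(start, end)` of the trigger decision span (s).
#' @param history_span `c(start, end)` of the history span (s).
#' @param dominance dominance fraction in (0.5, 1].
#' @param trigger_buffer processing buffer before the trigger fires (s).
#' @param refractory minimum spacing of honoured triggers (s).
#' @param burst_len stimulation burst length (s).
#' @param stride window stride of the simulated loop (s).
#' @param smooth_window,smooth_fwhm temporal smoothing constants (s).
#' @return a `tracker_config` list.
#' @export
tracker_config <- function(window_len = 1.0, fs_online = 2000,
                           edge_trim = 0.100, ar_order = 30,
                           forecast_len = 0.280,
                           decision_span = c(0.025, 0.175),
                           history_span = c(-0.095, 0.025),
                           dominance = 0.90, trigger_buffer = 0.021,
                           refractory = 9.0, burst_len = 0.150,
                           stride = 0.005,
                           smooth_window = 0.010, smooth_fwhm = 0.010) {
  stopifnot(dominance > 0.5, dominance <= 1)
  # the forecast spans T = -edge_trim .. forecast_len - edge_trim; it must
  # cover the decision span plus the half smoothing window lost at the edge
  if (forecast_len - edge_trim < decision_span[2] + smooth_window / 2 - 1e-9) {
    stop("forecast too short to cover the decision span after smoothing")
  }
  structure(list(window_len = window_len, fs_online = fs_online,
                 edge_trim = edge_trim, ar_order = ar_order,
                 forecast_len = forecast_len,
                 decision_span = decision_span,
                 history_span = history_span, dominance = dominance,
                 trigger_buffer = trigger_buffer, refractory = refractory,
                 burst_len = burst_len, stride = stride,
                 smooth_window = smooth_window, smooth_fwhm = smooth_fwhm),
            class = "tracker_config")
}

#' Windowed gamma envelope for the online loop
#'
#' One online analysis step on a single window of Hjorth ROI signals:
#' FFT band masking to the gamma band, analytic-signal envelope, then
#' removal of `edge_trim` at both window edges (1000 ms in, 800 ms out
#' at the defaults).
#'
#' @param window window_len * fs_online samples x ROIs matrix of Hjorth
#'   signals.
#' @param cfg a [tracker_config()].
#' @param band gamma band (Hz).
#' @return an `envelope_series` of the trimmed window.
#' @export
window_envelope <- function(window, cfg = tracker_config(),
                            band = c(30, 80)) {
  window <- as.matrix(window)
  n_expect <- round(cfg$window_len * cfg$fs_online)
  if (nrow(window) != n_expect) {
    stop(sprintf("window must have exactly %d samples", n_expect))
  }
  n <- nrow(window)
  f <- (seq_len(n) - 1) / n * cfg$fs_online
  f <- pmin(f, cfg$fs_online - f)
  mask <- f >= band[1] & f <= band[2]
  env <- apply(window, 2, function(ch) {
    sp <- stats::fft(ch)
    sp[!mask] <- 0i
    Mod(stats::fft(sp * analytic_weights(n), inverse = TRUE) / n)
  })
  trim <- round(cfg$edge_trim * cfg$fs_online)
  env <- env[(trim + 1):(n - trim), , drop = FALSE]
  structure(list(values = env, fs = cfg$fs_online, band = band),
            class = "envelope_series")
}

analytic_weights <- function(n) {
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  w
}

#' Yule-Walker autoregressive forward prediction
#'
#' Fits an AR model per ROI by the Yule-Walker equations and iterates it
#' forward to forecast `cfg$forecast_len` seconds beyond the trimmed
#' window (covering T = -100..+180 ms around the true recording end at
#' the defaults). A singular autocovariance falls back to the mean
#' prediction with a warning.
#'
#' @param envelope an `envelope_series` (the trimmed window).
#' @param cfg a [tracker_config()].
#' @param baseline optional per-ROI baseline level the forecast reverts
#'   to. By default the window mean is used (plain Yule-Walker). The
#'   closed loop passes the control-run mean (the binarisation
#'   threshold's own baseline), so that a window spanning a state
#'   transition does not drag the forecast back across the threshold
#'   towards the pre-transition level.
#' @return an `envelope_series` of the forecast samples.
#' @export
ar_forecast <- function(envelope, cfg = tracker_config(), baseline = NULL) {
  x <- envelope$values
  p <- cfg$ar_order
  if (nrow(x) < p + 1) stop("window too short for the AR order")
  if (!is.null(baseline) && length(baseline) != ncol(x)) {
    stop("one baseline level per ROI required")
  }
  n_ahead <- round(cfg$forecast_len * envelope$fs)
  fc <- vapply(seq_len(ncol(x)), function(j) {
    ch <- x[, j]
    mu <- if (is.null(baseline)) mean(ch) else baseline[[j]]
    fit <- tryCatch(
      stats::ar.yw(ch - mu, aic = FALSE, order.max = p, demean = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) {
      warning("singular autocovariance; falling back to mean prediction")
      return(rep(mu, n_ahead))
    }
    co <- fit$ar
    # recursive multi-step forecast: filter() runs the AR recursion in C
    init <- rev(utils::tail(ch, length(co)) - mu)
    pred <- stats::filter(rep(0, n_ahead), co, method = "recursive",
                          init = init)
    as.numeric(pred) + mu
  }, numeric(n_ahead))
  structure(list(values = fc, fs = envelope$fs, band = envelope$band),
            class = "envelope_series")
}

#' Classify a forecast into a predicted state sequence
#'
#' Binarises the forecast envelopes against control-run thresholds,
#' labels each sample by the major-state map and applies the standard
#' temporal smoothing, trimming half a smoothing window at each end
#' (T = -95..175 ms at the defaults).
#'
#' @param forecast `envelope_series` from [ar_forecast()].
#' @param thresholds per-ROI binarisation thresholds from a control run.
#' @param map a `major_state_map`.
#' @param cfg a [tracker_config()].
#' @return a `state_sequence` with origin `"online_predicted"`; attribute
#'   `t_start` gives the time of its first sample relative to T = 0.
#' @export
classify_forecast <- function(forecast, thresholds, map,
                              cfg = tracker_config()) {
  bs <- binarise(forecast$values, thresholds = thresholds, fs = forecast$fs)
  seq0 <- label_states(bs, map, dt = 1 / forecast$fs,
                       origin = "online_predicted")
  sm <- smooth_states(seq0, window = cfg$smooth_window,
                      fwhm = cfg$smooth_fwhm)
  half <- floor(round(cfg$smooth_window / sm$dt) / 2)
  out <- state_sequence(sm$labels[(half + 1):(length(sm$labels) - half)],
                        sm$dt, "online_predicted")
  # the forecast's first sample sits at T = -edge_trim; trimming half a
  # smoothing window moves the start to -edge_trim + half*dt (-95 ms)
  attr(out, "t_start") <- -cfg$edge_trim + half * sm$dt
  out
}

#' State-/state-history-dependent trigger decision
#'
#' A plain state condition (`"F"`, `"Int"`, `"V"`) triggers when the
#' target state occupies more than the dominance fraction of the
#' decision span. A history condition (`"PostF_Int"`, `"PostV_Int"`)
#' additionally requires the history state to dominate the preceding
#' history span. A qualifying trigger is honoured only if at least the
#' refractory time has passed since the last honoured trigger; an
#' honoured trigger is stamped at `now + trigger_buffer`.
#'
#' @param pred predicted `state_sequence` covering history and decision
#'   spans (attribute `t_start` as set by [classify_forecast()]).
#' @param condition one of `"F"`, `"Int"`, `"V"`, `"PostF_Int"`,
#'   `"PostV_Int"`.
#' @param now time of the window end (s).
#' @param last_trigger_time time of the last honoured trigger (-Inf if
#'   none).
#' @param cfg a [tracker_config()].
#' @return list: `fired` (dominance criteria met), `honoured` (fired and
#'   outside refractory), `evidence` (target fraction in the decision
#'   span), `history_evidence` (NA for plain conditions), `time`
#'   (trigger timestamp or NA).
#' @export
trigger_decision <- function(pred, condition, now = 0,
                             last_trigger_time = -Inf,
                             cfg = tracker_config()) {
  conds <- c("F", "Int", "V", "PostF_Int", "PostV_Int")
  if (!condition %in% conds) stop("unknown condition: ", condition)
  target <- switch(condition, PostF_Int = "Int", PostV_Int = "Int",
                   condition)
  history <- switch(condition, PostF_Int = "F", PostV_Int = "V", NULL)
  t0 <- attr(pred, "t_start")
  if (is.null(t0)) stop("pred lacks a t_start attribute")
  times <- t0 + (seq_along(pred$labels) - 1) * pred$dt
  in_dec <- times >= cfg$decision_span[1] & times <= cfg$decision_span[2]
  if (!any(in_dec)) stop("prediction does not cover the decision span")
  evidence <- mean(pred$labels[in_dec] == target)
  fired <- evidence > cfg$dominance
  hist_evidence <- NA_real_
  if (!is.null(history)) {
    in_hist <- times >= cfg$history_span[1] & times <= cfg$history_span[2]
    if (!any(in_hist)) stop("prediction does not cover the history span")
    hist_evidence <- mean(pred$labels[in_hist] == history)
    fired <- fired && hist_evidence > cfg$dominance
  }
  honoured <- fired && (now - last_trigger_time >= cfg$refractory)
  list(fired = fired, honoured = honoured, evidence = evidence,
       history_evidence = hist_evidence,
       time = if (honoured) now + cfg$trigger_buffer else NA_real_)
}

#' Binarisation thresholds from a control run
#'
#' Applies the online preprocessing (Hjorth derivation, windowed gamma
#' extraction, envelope, edge trims) to a control recording and returns
#' the mean envelope amplitude per ROI -- the thresholds used by the
#' online binarisation during subsequent stimulation runs. Windows are
#' tiled without overlap across the control run.
#'
#' @param recording a control-run recording at `cfg$fs_online`.
#' @param cfg a [tracker_config()].
#' @return named numeric vector, one threshold per ROI.
#' @export
online_thresholds <- function(recording, cfg = tracker_config()) {
  hj <- hjorth_all(recording$signals, recording$channel_map)
  win <- round(cfg$window_len * cfg$fs_online)
  starts <- seq(1, nrow(hj) - win + 1, by = win)
  if (!length(starts)) stop("control run shorter than one window")
  acc <- 0
  n <- 0L
  for (s in starts) {
    env <- window_envelope(hj[s:(s + win - 1), , drop = FALSE], cfg)
    acc <- acc + colSums(env$values)
    n <- n + nrow(env$values)
  }
  stats::setNames(acc / n, colnames(hj))
}

#' Run the simulated closed loop over a recording
#'
#' Slides the analysis window across the recording at the configured
#' stride. Each step applies the online chain (Hjorth signals are
#' computed once, then per window: FFT gamma extraction, envelope, edge
#' trim, AR forecast, binarisation, labelling, smoothing) and evaluates
#' the trigger rule. Deterministic given its inputs.
#'
#' @param recording a `synthetic_recording` (or list with `signals`,
#'   `fs`, `channel_map`) sampled at `cfg$fs_online`.
#' @param condition trigger condition (see [trigger_decision()]).
#' @param map `major_state_map` from the offline analysis.
#' @param thresholds per-ROI control-run thresholds.
#' @param cfg a [tracker_config()].
#' @return list of class `closed_loop_result`: `log` (a `trigger_log`
#'   data frame of every fired decision), `online_states` (a
#'   `state_sequence` of the predicted current state, one per window),
#'   `times` (window-end times), `condition`, `cfg`.
#' @export
run_closed_loop <- function(recording, condition, map, thresholds,
                            cfg = tracker_config()) {
  if (recording$fs != cfg$fs_online) {
    stop("recording must be sampled at cfg$fs_online")
  }
  hj <- hjorth_all(recording$signals, recording$channel_map)
  n <- nrow(hj)
  win <- round(cfg$window_len * cfg$fs_online)
  if (n < win) stop("recording shorter than one analysis window")
  stride <- max(1L, round(cfg$stride * cfg$fs_online))
  ends <- seq(win, n, by = stride)
  last_time <- -Inf
  labels <- character(length(ends))
  ev <- list()
  for (k in seq_along(ends)) {
    e <- ends[k]
    now <- e / cfg$fs_online
    env <- window_envelope(hj[(e - win + 1):e, , drop = FALSE], cfg)
    fc <- ar_forecast(env, cfg, baseline = thresholds)
    pred <- classify_forecast(fc, thresholds, map, cfg)
    # predicted state at the current instant (T = 0)
    t0 <- attr(pred, "t_start")
    i0 <- min(length(pred$labels), max(1L, 1L + round(-t0 / pred$dt)))
    labels[k] <- pred$labels[i0]
    dec <- trigger_decision(pred, condition, now = now,
                            last_trigger_time = last_time, cfg = cfg)
    if (dec$fired) {
      ev[[length(ev) + 1L]] <- data.frame(
        time = if (dec$honoured) dec$time else NA_real_,
        window_end = now, condition = condition,
        evidence = dec$evidence, history_evidence = dec$history_evidence,
        honoured = dec$honoured)
      if (dec$honoured) last_time <- now
    }
  }
  log <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), window_end = numeric(0),
               condition = character(0), evidence = numeric(0),
               history_evidence = numeric(0), honoured = logical(0))
  class(log) <- c("trigger_log", "data.frame")
  online <- state_sequence(labels, dt = stride / cfg$fs_online,
                           origin = "online_predicted")
  attr(online, "t_start") <- win / cfg$fs_online
  structure(list(log = log, online_states = online,
                 times = ends / cfg$fs_online, condition = condition,
                 cfg = cfg),
            class = "closed_loop_result")
}

#' Evaluate online tracking against the offline reference
#'
#' Per-state agreement is the fraction of offline-labelled samples of
#' each major state whose online label matches (`state_counts` and
#' `match_counts` support pooling several runs at the sample level, as a
#' participant's runs are pooled). Trigger accuracy is the fraction of
#' honoured triggers during whose stimulation burst the target state
#' holds for the majority of offline-labelled samples; offline state
#' labels flicker on the 10 ms scale even in clean data, so demanding
#' literally every burst sample would misread a correctly placed trigger
#' -- the all-sample variant is still reported as
#' `trigger_accuracy_strict`. Latency error is the difference between
#' the trigger timestamp and window end + buffer (exactly zero in this
#' simulator, reported for interface parity with a hardware loop).
#'
#' @param result a `closed_loop_result`.
#' @param offline a `state_sequence` of offline labels for the same
#'   recording (its sample k is taken at time k * dt).
#' @return list: `agreement` (named fraction per state), `overall`
#'   agreement, `state_counts`, `match_counts`, `trigger_accuracy`,
#'   `trigger_accuracy_strict`, `n_triggers`, `latency_error` (s).
#' @export
evaluate_online <- function(result, offline) {
  stopifnot(inherits(offline, "state_sequence"))
  on <- result$online_states
  t_on <- result$times
  idx <- round(t_on / offline$dt)
  ok <- idx >= 1 & idx <= length(offline$labels)
  if (!any(ok)) stop("sequences do not overlap in time")
  off_lab <- offline$labels[idx[ok]]
  on_lab <- on$labels[ok]
  states <- c("F", "Int", "V")
  state_counts <- vapply(states, function(s) sum(off_lab == s), numeric(1))
  match_counts <- vapply(states, function(s) {
    sum(off_lab == s & on_lab == s)
  }, numeric(1))
  agreement <- ifelse(state_counts > 0, match_counts / state_counts,
                      NA_real_)
  names(agreement) <- states
  log <- result$log
  hon <- log[log$honoured, , drop = FALSE]
  target <- switch(result$condition, PostF_Int = "Int", PostV_Int = "Int",
                   result$condition)
  burst_frac <- vapply(hon$time, function(tt) {
    span <- seq(from = max(1, round(tt / offline$dt)),
                to = min(length(offline$labels),
                         round((tt + result$cfg$burst_len) / offline$dt)))
    mean(offline$labels[span] == target)
  }, numeric(1))
  list(agreement = agreement,
       overall = mean(on_lab == off_lab),
       state_counts = state_counts, match_counts = match_counts,
       trigger_accuracy = if (nrow(hon)) mean(burst_frac > 0.5) else NA_real_,
       trigger_accuracy_strict = if (nrow(hon)) mean(burst_frac == 1) else
         NA_real_,
       n_triggers = nrow(hon),
       latency_error = if (nrow(hon)) 0 else NA_real_)
}
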