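test_that("windowed gamma extraction passes the band and trims the edges", {
  cfg <- tracker_config()
  fs <- cfg$fs_online
  t <- seq_len(2000) / fs
  env50 <- window_envelope(cbind(sin(2 * pi * 50 * t)), cfg)
  expect_equal(nrow(env50$values), 1600)           # 800 ms at 2 kHz
  interior <- 200:1400
  expect_lt(max(abs(env50$values[interior, 1] - 1)), 0.02)
  env10 <- window_envelope(cbind(sin(2 * pi * 10 * t)), cfg)
  expect_lt(20 * log10(stats::sd(env10$values[interior, 1] +
                                   1e-12) / (1 / sqrt(2))), -20)
  expect_error(window_envelope(cbind(t[1:100]), cfg), "exactly")
})

test_that("Yule-Walker forecasts behave at the theoretical reference points", {
  cfg <- tracker_config()
  const <- structure(list(values = cbind(rep(3.2, 1600)), fs = 2000,
                          band = c(30, 80)), class = "envelope_series")
  # a constant series has a singular autocovariance: the forecast falls
  # back to the mean, with the documented warning
  expect_warning(fc <- ar_forecast(const, cfg), "singular")
  expect_equal(nrow(fc$values), round(0.280 * 2000))
  expect_lt(max(abs(fc$values - 3.2)), 1e-6)
  # known AR(2): one-step forecast error variance ~ innovation variance
  phi <- c(1.4, -0.48)
  withr::with_seed(11, {
    x <- as.numeric(stats::arima.sim(list(ar = phi), 4000, sd = 1))
  })
  err <- vapply(seq(1600, 3600, by = 40), function(e) {
    win <- structure(list(values = cbind(x[(e - 1599):e]), fs = 2000,
                          band = c(30, 80)), class = "envelope_series")
    f <- ar_forecast(win, cfg)
    f$values[1, 1] - x[e + 1]
  }, numeric(1))
  expect_lt(abs(stats::var(err) - 1), 0.25)
  # white noise: the long-horizon forecast reverts to the process mean
  withr::with_seed(12, wn <- rnorm(1600, mean = 5))
  wfc <- ar_forecast(structure(list(values = cbind(wn), fs = 2000,
                                    band = c(30, 80)),
                               class = "envelope_series"), cfg)
  expect_lt(abs(mean(wfc$values[500:560, 1]) - 5), 0.3)
})

test_that("forecast classification maps envelope levels to major states", {
  cfg <- tracker_config()
  truth <- tb_truth()
  thr <- rep(1, 7)
  n <- round(0.280 * 2000)
  # frontal ROIs far above threshold, others below: the F pattern
  fc_f <- structure(list(values = cbind(2, 2, 2, 0.1, 0.1, 0.1, 0.1)[
    rep(1, n), ], fs = 2000, band = c(30, 80)), class = "envelope_series")
  pred <- classify_forecast(fc_f, thr, truth$map, cfg)
  expect_true(all(pred$labels == "F"))
  t0 <- attr(pred, "t_start")
  expect_equal(t0, -0.095, tolerance = 1e-6)
  # values exactly at threshold binarise to -1: the all-off Int pattern
  fc_t <- structure(list(values = matrix(1, n, 7), fs = 2000,
                         band = c(30, 80)), class = "envelope_series")
  pred_t <- classify_forecast(fc_t, thr, truth$map, cfg)
  expect_true(all(pred_t$labels == "Int"))
})

test_that("the trigger rule enforces dominance, history and refractory period", {
  cfg <- tracker_config()
  n <- 540   # 270 ms at 2 kHz
  mk <- function(labels) {
    s <- state_sequence(labels, 1 / 2000, "online_predicted")
    attr(s, "t_start") <- -0.095
    s
  }
  all_f <- mk(rep("F", n))
  d <- trigger_decision(all_f, "F", now = 20, last_trigger_time = -Inf,
                        cfg = cfg)
  expect_true(d$fired)
  expect_true(d$honoured)
  expect_equal(d$time, 20 + 0.021)
  expect_equal(d$evidence, 1)
  # 85 % dominance is below the 90 % bar
  mixed <- mk(rep(c("F", "F", "F", "F", "F", "F", "F", "F", "F", "F",
                    "F", "F", "F", "F", "F", "F", "F", "Int", "Int", "Int"),
                  length.out = n))
  d2 <- trigger_decision(mixed, "F", now = 20, cfg = cfg)
  expect_false(d2$fired)
  expect_lt(d2$evidence, 0.9)
  # qualifying event during the refractory window is suppressed
  d3 <- trigger_decision(all_f, "F", now = 20, last_trigger_time = 15,
                         cfg = cfg)
  expect_true(d3$fired)
  expect_false(d3$honoured)
  # history condition: Int must dominate the decision span and F the
  # preceding history span
  n_hist <- sum(seq(-0.095, 0.175, by = 1 / 2000) < 0.025)
  hist_f <- mk(c(rep("F", n_hist), rep("Int", n - n_hist)))
  d4 <- trigger_decision(hist_f, "PostF_Int", now = 20, cfg = cfg)
  expect_true(d4$fired)
  d5 <- trigger_decision(hist_f, "PostV_Int", now = 20, cfg = cfg)
  expect_false(d5$fired)
  expect_error(trigger_decision(all_f, "X", now = 0), "unknown")
})

test_that("the closed loop is deterministic and honours its invariants", {
  truth <- tb_truth()
  cfg <- tracker_config(stride = 0.050)
  lat <- sample_binary_series(truth, 25 * 14, persistence = 0.99,
                              seed = 21, fs = 25)
  rec <- synthesize_eeg(lat, fs = 2000, snr = 50, seed = 22)
  thr <- online_thresholds(rec, cfg)
  res1 <- run_closed_loop(rec, "F", truth$map, thr, cfg)
  res2 <- run_closed_loop(rec, "F", truth$map, thr, cfg)
  expect_identical(res1$log, res2$log)
  expect_identical(res1$online_states$labels, res2$online_states$labels)
  hon <- res1$log[res1$log$honoured, ]
  if (nrow(hon) > 1) {
    expect_true(all(diff(hon$time) >= cfg$refractory))
  }
  expect_true(all(res1$log$evidence[res1$log$honoured] > cfg$dominance))
})

test_that("online tracking matches the offline analysis on synthetic data", {
  # one control run provides the thresholds; three stimulation runs are
  # evaluated pooled at the sample level, as a participant's runs are
  truth <- tb_truth()
  cfg <- tracker_config(stride = 0.025)
  lat_c <- sample_binary_series(truth, 25 * 30, persistence = 0.985,
                                seed = 21, fs = 25)
  rec_c <- synthesize_eeg(lat_c, fs = 2000, snr = 100, seed = 22)
  thr <- online_thresholds(rec_c, cfg)
  state_counts <- match_counts <- c(F = 0, Int = 0, V = 0)
  n_trig <- 0
  n_trig_ok <- 0
  for (run in 1:3) {
    lat_m <- sample_binary_series(truth, 25 * 60, persistence = 0.985,
                                  seed = 100 + run, fs = 25)
    rec_m <- synthesize_eeg(lat_m, fs = 2000, snr = 100, seed = 200 + run)
    res <- run_closed_loop(rec_m, "F", truth$map, thr, cfg)
    off <- label_states(preprocess_recording(rec_m), truth$map)
    ev <- evaluate_online(res, off)
    state_counts <- state_counts + ev$state_counts
    match_counts <- match_counts + ev$match_counts
    n_trig <- n_trig + ev$n_triggers
    n_trig_ok <- n_trig_ok + round(ev$trigger_accuracy * ev$n_triggers)
    expect_equal(ev$latency_error, 0)
  }
  agreement <- match_counts / state_counts
  expect_true(all(agreement >= 0.823))
  expect_gte(n_trig, 5)
  expect_gte(n_trig_ok / n_trig, 0.848)
})

test_that("a condition whose state never appears produces no triggers", {
  truth <- tb_truth()
  cfg_s <- tracker_config(stride = 0.100)
  latF <- statescape:::new_binary_series(
    matrix(rep(index_to_pattern(truth$major_minima[["F"]], 7),
               each = 25 * 6), ncol = 7), 25, rep(NA, 7))
  recF <- synthesize_eeg(latF, fs = 2000, snr = 50, seed = 32)
  lat_c <- sample_binary_series(truth, 25 * 10, persistence = 0.9,
                                seed = 33, fs = 25)
  rec_c <- synthesize_eeg(lat_c, fs = 2000, snr = 50, seed = 34)
  thr <- online_thresholds(rec_c, cfg_s)
  resV <- run_closed_loop(recF, "V", truth$map, thr, cfg_s)
  expect_equal(sum(resV$log$honoured), 0L)
  resF <- run_closed_loop(recF, "F", truth$map, thr, cfg_s)
  expect_gte(sum(resF$log$honoured), 1L)
})

test_that("agreement is exact for identical sequences and near chance for lags", {
  cfg <- tracker_config(stride = 0.050)
  withr::with_seed(41, {
    labels <- sample(c("F", "Int", "V"), 4000, replace = TRUE,
                     prob = c(0.4, 0.2, 0.4))
  })
  off <- state_sequence(rep(labels, each = 5), dt = 0.01)  # 10 ms grid
  times <- seq(1, 150, by = 0.05)
  idx <- round(times / off$dt)
  fake <- structure(list(
    online_states = state_sequence(off$labels[idx], dt = 0.05,
                                   origin = "online_predicted"),
    times = times, log = data.frame(honoured = logical(0), time = numeric(0)),
    condition = "F", cfg = cfg), class = "closed_loop_result")
  ev <- evaluate_online(fake, off)
  expect_equal(ev$overall, 1)
  expect_equal(unname(ev$agreement), rep(1, 3))
  # a large shift reduces agreement to the state base rates
  fake$online_states <- state_sequence(off$labels[idx + 2000], dt = 0.05,
                                       origin = "online_predicted")
  ev2 <- evaluate_online(fake, off)
  base <- c(F = 0.4, Int = 0.2, V = 0.4)
  expect_equal(unname(ev2$agreement), unname(base), tolerance = 0.08)
})
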