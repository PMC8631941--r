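#' Re-reference, resample and band-filter a multichannel recording
#'
#' The offline front end: subtract the per-sample average across channels
#' (average reference), resample to `target_fs`, and apply a zero-phase
#' (forward-backward) Butterworth band-pass. Zero-phase filtering avoids
#' group delay so envelope timing is preserved.
#'
#' @param raw numeric matrix, samples x channels.
#' @param fs input sampling rate (Hz).
#' @param target_fs output rate (Hz, <= fs; default 300).
#' @param band `c(low, high)` pass band in Hz (default 1-80); the upper
#'   edge must lie below target_fs/2.
#' @param order Butterworth order (default 4).
#' @return list with `values` (matrix at target_fs) and `fs`.
#' @export
rereference_and_filter <- function(raw, fs, target_fs = 300,
                                   band = c(1, 80), order = 4) {
  raw <- as.matrix(raw)
  stopifnot(fs >= target_fs, band[1] > 0, band[1] < band[2])
  if (band[2] >= target_fs / 2) {
    stop("band upper edge must be below the output Nyquist frequency")
  }
  x <- raw - rowMeans(raw)
  if (target_fs != fs) {
    if (fs %% target_fs == 0) {
      # integer decimation: zero-phase anti-alias FIR via decimate
      q <- fs %/% target_fs
      x <- apply(x, 2, function(ch) signal::decimate(ch, q, ftype = "fir"))
    } else {
      r <- rational_ratio(target_fs / fs)
      x <- apply(x, 2, function(ch) signal::resample(ch, r[1], r[2]))
    }
  }
  bf <- signal::butter(order, band / (target_fs / 2), type = "pass")
  x <- apply(x, 2, function(ch) signal::filtfilt(bf, ch))
  list(values = x, fs = target_fs)
}

rational_ratio <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("resampling ratio has no small rational form")
}

#' Artifact epoch rejection by global field power
#'
#' Splits the recording into fixed-length epochs and excludes epochs
#' whose mean global field power (mean over channels and samples of the
#' squared re-referenced signal) exceeds the across-epoch mean by more
#' than `z_thresh` standard deviations.
#'
#' @param signals samples x channels matrix.
#' @param fs sampling rate (Hz).
#' @param epoch_len epoch length in seconds (default 1).
#' @param z_thresh exclusion threshold in SD multiples (default 5;
#'   `Inf` disables exclusion).
#' @return logical vector `keep` per epoch with attributes
#'   `keep_sample` (per retained-range sample) and `epoch_samples`.
#' @export
artifact_epoch_mask <- function(signals, fs, epoch_len = 1, z_thresh = 5) {
  stopifnot(z_thresh > 0)
  signals <- as.matrix(signals)
  len <- max(1L, floor(epoch_len * fs))
  n_ep <- floor(nrow(signals) / len)
  if (n_ep < 1) stop("recording shorter than one epoch")
  pow <- vapply(seq_len(n_ep), function(e) {
    mean(signals[((e - 1) * len + 1):(e * len), ]^2)
  }, numeric(1))
  keep <- if (is.infinite(z_thresh) || n_ep < 3 || stats::sd(pow) == 0) {
    rep(TRUE, n_ep)   # too few epochs for a meaningful spread estimate
  } else {
    pow <= mean(pow) + z_thresh * stats::sd(pow)
  }
  if (!any(keep)) stop("all epochs excluded by the artifact criterion")
  attr(keep, "keep_sample") <- rep(keep, each = len)
  attr(keep, "epoch_samples") <- len
  keep
}

#' Hilbert envelope of band-limited signals
#'
#' Magnitude of the analytic signal, computed per channel with the FFT
#' construction (positive frequencies doubled, negative zeroed).
#'
#' @param band_signals samples x channels matrix, already band-limited.
#' @param fs sampling rate (Hz).
#' @param band the nominal band, stored for provenance.
#' @return an `envelope_series`: `values` (non-negative), `fs`, `band`.
#' @export
hilbert_envelope <- function(band_signals, fs, band = c(30, 80)) {
  x <- as.matrix(band_signals)
  if (any(!is.finite(x))) stop("non-finite input")
  env <- apply(x, 2, function(ch) Mod(analytic_signal(ch)))
  structure(list(values = env, fs = fs, band = band),
            class = "envelope_series")
}

analytic_signal <- function(x) {
  n <- length(x)
  stats::fft(stats::fft(x) * analytic_weights(n), inverse = TRUE) / n
}

#' Hjorth (sum-of-difference) derivation
#'
#' Local spatial filter for one ROI: (centre - n1) + (centre - n2) +
#' (centre - n3) = 3 x centre - (n1 + n2 + n3). Common-mode signal shared
#' by the four electrodes cancels exactly.
#'
#' @param centre numeric vector, the electrode above the ROI.
#' @param neighbours matrix with 3 columns (or list of 3 vectors), the
#'   surrounding electrodes.
#' @return numeric vector of the same length.
#' @export
hjorth_derive <- function(centre, neighbours) {
  if (is.list(neighbours)) neighbours <- do.call(cbind, neighbours)
  neighbours <- as.matrix(neighbours)
  if (ncol(neighbours) != 3) stop("exactly three neighbour electrodes required")
  if (nrow(neighbours) != length(centre)) stop("length mismatch")
  3 * centre - rowSums(neighbours)
}

#' Apply the Hjorth derivation to all ROIs of a recording
#'
#' @param signals samples x channels matrix.
#' @param channel_map per-ROI list of `centre` and `neighbours` channel
#'   indices (see [default_channel_map()]).
#' @return samples x ROIs matrix, one Hjorth signal per ROI.
#' @export
hjorth_all <- function(signals, channel_map) {
  signals <- as.matrix(signals)
  out <- vapply(channel_map, function(cm) {
    hjorth_derive(signals[, cm$centre], signals[, cm$neighbours])
  }, numeric(nrow(signals)))
  colnames(out) <- names(channel_map)
  out
}

new_binary_series <- function(values, fs, thresholds) {
  check_pm1(values)
  structure(list(values = values, fs = fs, thresholds = thresholds),
            class = "binary_series")
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf("Binary pattern series: %d samples x %d ROIs at %g Hz\n",
              nrow(x$values), ncol(x$values), x$fs))
  cat("  active fraction:", round(colMeans(x$values == 1), 3), "\n")
  invisible(x)
}

#' Binarise ROI signals into +1/-1 activity patterns
#'
#' sigma_i(t) = +1 when the signal strictly exceeds the ROI's threshold,
#' -1 otherwise (so a constant signal maps to all -1). Offline analysis
#' thresholds default to each ROI's temporal mean; the online tracker
#' passes thresholds computed from a control run.
#'
#' @param env an `envelope_series`, or a samples x ROIs matrix.
#' @param thresholds per-ROI thresholds, or `NULL` to use column means.
#' @param fs sampling rate, required when `env` is a bare matrix.
#' @return a `binary_series`.
#' @export
binarise <- function(env, thresholds = NULL, fs = NULL) {
  if (inherits(env, "envelope_series")) {
    x <- env$values
    fs <- env$fs
  } else {
    x <- as.matrix(env)
    if (is.null(fs)) stop("fs required for matrix input")
  }
  if (is.null(thresholds)) thresholds <- colMeans(x)
  if (length(thresholds) != ncol(x)) stop("one threshold per ROI required")
  if (any(!is.finite(thresholds))) stop("non-finite thresholds")
  v <- ifelse(sweep(x, 2, thresholds, ">"), 1, -1)
  new_binary_series(v, fs, thresholds)
}

#' Offline preprocessing chain: raw recording to binary pattern series
#'
#' The full offline pipeline: average reference + resampling + broadband
#' filter, artifact-epoch exclusion, gamma band-pass, Hilbert envelope
#' per electrode, optional first-difference pre-whitening, Hjorth
#' derivation per ROI, binarisation at the per-ROI temporal mean.
#' Excluded epochs are dropped before thresholds and moments are
#' computed.
#'
#' @param recording a `synthetic_recording`, or a list with `signals`
#'   (samples x channels) and `fs`.
#' @param channel_map per-ROI electrode grouping (defaults to the
#'   recording's own map, else [default_channel_map()]).
#' @param config list of options: `band` (gamma band, default c(30, 80)),
#'   `broadband` (default c(1, 80)), `target_fs` (default 300),
#'   `artifact_z` (default 5), `epoch_len` (default 1 s), `prewhiten`
#'   (first-difference the envelopes before the Hjorth step, default
#'   FALSE), `thresholds` (supplied per-ROI binarisation thresholds,
#'   default NULL = temporal means).
#' @return a `binary_series` with attributes `envelope` (the per-ROI
#'   Hjorth envelope matrix) and `keep_sample` (artifact mask at
#'   target_fs resolution, before dropping).
#' @export
preprocess_recording <- function(recording, channel_map = NULL,
                                 config = list()) {
  cfg <- utils::modifyList(list(band = c(30, 80), broadband = c(1, 80),
                                target_fs = 300, artifact_z = 5,
                                epoch_len = 1, prewhiten = FALSE,
                                thresholds = NULL), config)
  if (is.null(channel_map)) {
    channel_map <- recording$channel_map
    if (is.null(channel_map)) channel_map <- default_channel_map()
  }
  pre <- rereference_and_filter(recording$signals, recording$fs,
                                target_fs = cfg$target_fs,
                                band = cfg$broadband)
  keep_ep <- artifact_epoch_mask(pre$values, pre$fs,
                                 epoch_len = cfg$epoch_len,
                                 z_thresh = cfg$artifact_z)
  keep <- attr(keep_ep, "keep_sample")
  keep <- c(keep, rep(TRUE, nrow(pre$values) - length(keep)))
  bf <- signal::butter(4, cfg$band / (pre$fs / 2), type = "pass")
  gamma <- apply(pre$values, 2, function(ch) signal::filtfilt(bf, ch))
  env <- hilbert_envelope(gamma, pre$fs, band = cfg$band)$values
  if (isTRUE(cfg$prewhiten)) {
    env <- rbind(env[1, , drop = FALSE] * 0, diff(env))
  }
  roi <- hjorth_all(env, channel_map)
  roi <- roi[keep, , drop = FALSE]
  out <- binarise(roi, thresholds = cfg$thresholds, fs = pre$fs)
  attr(out, "envelope") <- roi
  attr(out, "keep_sample") <- keep
  out
}
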