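#' Write / read a recording as a delimited matrix with a JSON sidecar
#'
#' The signal matrix goes to `<path>.tsv` (tab-separated, no header) and
#' the metadata (fs, channel map, seed, snr, latent state indices if
#' present) to `<path>.json`.
#'
#' @param recording a `synthetic_recording` or list with `signals`, `fs`.
#' @param path output stem (without extension).
#' @return `write_recording` returns the stem invisibly; `read_recording`
#'   returns a list matching the `synthetic_recording` layout.
#' @export
write_recording <- function(recording, path) {
  utils::write.table(recording$signals, paste0(path, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(fs = recording$fs, channel_map = recording$channel_map,
               seed = recording$seed, snr = recording$snr,
               latent = recording$latent)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  signals <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(signals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cmap <- NULL
  if (!is.null(meta$channel_map)) {
    cmap <- lapply(meta$channel_map, function(x) {
      list(centre = as.integer(x$centre),
           neighbours = as.integer(x$neighbours))
    })
  }
  structure(list(signals = signals, fs = meta$fs, channel_map = cmap,
                 seed = meta$seed, snr = meta$snr,
                 latent = if (is.null(meta$latent)) NULL else
                   as.integer(meta$latent)),
            class = "synthetic_recording")
}

#' Serialise / load a fitted pairwise model as JSON
#'
#' @param params a [mem_params()] object.
#' @param path output file.
#' @param report optional fit report stored alongside.
#' @export
write_model <- function(params, path, report = NULL) {
  stopifnot(inherits(params, "mem_params"))
  obj <- list(n_roi = params$n_roi, h = params$h, J = params$J)
  if (!is.null(report)) {
    obj$report <- report[c("pearson_r", "kl_ratio", "n_iterations",
                           "converged", "max_moment_gap")]
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mem_params(obj$h, matrix(unlist(obj$J), obj$n_roi, obj$n_roi))
}

#' Write / read a binary pattern series as a delimited table
#'
#' @param series a `binary_series`.
#' @param path output file (TSV of +1/-1 values; fs and thresholds in a
#'   `#`-comment header line).
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "binary_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g thresholds=%s", series$fs,
                     paste(series$thresholds, collapse = ",")), con)
  utils::write.table(series$values, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*fs=([0-9.eE+-]+).*", "\\1", hdr))
  th <- suppressWarnings(
    as.numeric(strsplit(sub(".*thresholds=", "", hdr), ",")[[1]]))
  v <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(v) <- NULL
  new_binary_series(v, fs, th)
}
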