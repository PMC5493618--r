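#' Multi-channel EMG recording
#'
#' Light container for a multi-channel surface-EMG signal sampled at a fixed
#' rate. Signals are stored as a numeric matrix (samples in rows, channels in
#' columns) because per-sample long tibbles are impractical at 2 kHz; use
#' [tibble::as_tibble()] to get a tidy view with a time column.
#'
#' @param signals Numeric matrix, samples x channels. All values must be finite.
#' @param fs Sampling frequency in Hz (default 2000).
#' @param meta Named list of free-form metadata (protocol, seed, subject tag...).
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, fs = 2000, meta = list()) {
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number", call. = FALSE)
  }
  if (!all(is.finite(signals))) {
    stop("all samples of an EMG recording must be finite", call. = FALSE)
  }
  if (is.null(colnames(signals))) {
    colnames(signals) <- paste0("ch", seq_len(ncol(signals)))
  }
  structure(
    list(signals = signals, fs = fs, meta = meta),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
    n_channels(x), n_samples(x), x$fs, duration(x)
  ))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recording dimensions
#'
#' @param x An `emg_recording`.
#' @return Integer count (`n_channels`, `n_samples`) or seconds (`duration`).
#' @export
n_channels <- function(x) ncol(x$signals)

#' @rdname n_channels
#' @export
n_samples <- function(x) nrow(x$signals)

#' @rdname n_channels
#' @export
duration <- function(x) nrow(x$signals) / x$fs

#' Sample time stamps of a recording
#'
#' Sample i (1-based) is stamped (i - 1) / fs, i.e. the first sample sits at
#' t = 0.
#'
#' @param x An `emg_recording`.
#' @return Numeric vector of times in seconds.
#' @export
sample_times <- function(x) (seq_len(n_samples(x)) - 1) / x$fs

#' @export
as_tibble.emg_recording <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$signals)) |>
    dplyr::mutate(time = sample_times(x), .before = 1L)
}

#' Truncate a recording to its first `duration` seconds
#'
#' @param x An `emg_recording`.
#' @param duration Seconds to keep from the start.
#' @return A shorter `emg_recording`; metadata is preserved.
#' @export
truncate_recording <- function(x, duration) {
  stopifnot(inherits(x, "emg_recording"))
  n_keep <- min(n_samples(x), round(duration * x$fs))
  emg_recording(x$signals[seq_len(n_keep), , drop = FALSE], fs = x$fs, meta = x$meta)
}
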