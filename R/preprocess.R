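#' Filtering chain specification
#'
#' The real-time preprocessing chain: a causal Butterworth band-pass
#' (prototype order `bp_order`, pass band `band`) followed by a 50 Hz comb
#' filter implemented as cascaded second-order notches at the fundamental and
#' every harmonic below Nyquist.
#'
#' @param fs Sampling frequency in Hz (default 2000).
#' @param band Pass band `(low, high)` in Hz (default `c(30, 500)`).
#' @param bp_order Butterworth prototype order (default 4; 8 poles after the
#'   band transform).
#' @param comb_fundamental Powerline fundamental in Hz (default 50; `NULL` or
#'   0 disables the comb).
#' @param comb_q Quality factor of each notch (default 35, i.e. about 1.4 Hz
#'   -3 dB width at 50 Hz).
#'
#' @return An object of class `filter_spec` holding the designed coefficient
#'   cascade.
#' @export
filter_spec <- function(fs = 2000, band = c(30, 500), bp_order = 4,
                        comb_fundamental = 50, comb_q = 35) {
  if (band[1] <= 0 || band[2] <= band[1]) stop("invalid pass band", call. = FALSE)
  if (band[2] >= fs / 2) stop("band edges must be below Nyquist", call. = FALSE)
  if (bp_order < 1) stop("`bp_order` must be positive", call. = FALSE)
  bp <- signal::butter(bp_order, band / (fs / 2), type = "pass")
  stages <- list(list(b = bp$b / bp$a[1], a = bp$a / bp$a[1]))
  if (!is.null(comb_fundamental) && comb_fundamental > 0) {
    harmonics <- seq(comb_fundamental, fs / 2 - 1e-9, by = comb_fundamental)
    for (f0 in harmonics) {
      stages <- c(stages, list(notch_biquad(f0, fs, comb_q)))
    }
  }
  structure(
    list(fs = fs, band = band, bp_order = bp_order,
         comb_fundamental = comb_fundamental, comb_q = comb_q,
         stages = stages),
    class = "filter_spec"
  )
}

# Standard second-order IIR notch (constrained biquad): unit gain away from
# f0, zero at f0, -3 dB width f0/Q.
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "<filter_spec> %g-%g Hz Butterworth (order %d) + comb @%g Hz (%d notches, Q=%g), fs=%g Hz\n",
    x$band[1], x$band[2], x$bp_order,
    x$comb_fundamental %||% 0, length(x$stages) - 1L, x$comb_q, x$fs
  ))
  invisible(x)
}

#' Causal filtering of a recording
#'
#' Applies the band-pass then the comb notches causally (no zero-phase
#' filtering: the chain must be realisable in a streaming real-time system)
#' to every channel.
#'
#' @param raw An [emg_recording()].
#' @param spec A [filter_spec()]; its sampling rate must match the recording.
#' @return A filtered `emg_recording` of the same shape.
#' @export
filter_signal <- function(raw, spec = filter_spec(fs = raw$fs)) {
  stopifnot(inherits(raw, "emg_recording"), inherits(spec, "filter_spec"))
  if (abs(spec$fs - raw$fs) > 1e-9) {
    stop("filter_spec and recording sampling rates differ", call. = FALSE)
  }
  out <- cascade_filter_cpp(raw$signals, lapply(spec$stages, `[[`, "b"),
                            lapply(spec$stages, `[[`, "a"),
                            numeric(state_size(spec) * ncol(raw$signals)))$block
  colnames(out) <- colnames(raw$signals)
  emg_recording(out, fs = raw$fs, meta = c(raw$meta, list(filtered = TRUE)))
}

state_size <- function(spec) {
  sum(vapply(spec$stages, function(st) 2L * (length(st$a) - 1L), integer(1)))
}

apply_cascade <- function(x, stages) {
  drop(cascade_filter_cpp(matrix(x, ncol = 1), lapply(stages, `[[`, "b"),
                          lapply(stages, `[[`, "a"),
                          numeric(sum(vapply(stages, function(st) {
                            2L * (length(st$a) - 1L)
                          }, integer(1)))))$block)
}

#' Streaming (block-wise) filtering with carried state
#'
#' `filter_state_init()` creates an empty state for `n_channels` channels;
#' `filter_signal_block()` filters one block of samples and returns the
#' filtered block together with the updated state. Processing a signal in
#' blocks of any size reproduces [filter_signal()] exactly.
#'
#' @param spec A [filter_spec()].
#' @param n_channels Number of channels the state tracks.
#' @return `filter_state_init()`: an opaque state object.
#' @export
filter_state_init <- function(spec, n_channels) {
  stopifnot(inherits(spec, "filter_spec"))
  structure(
    list(spec = spec,
         b = lapply(spec$stages, `[[`, "b"),
         a = lapply(spec$stages, `[[`, "a"),
         values = numeric(state_size(spec) * n_channels)),
    class = "emg_filter_state"
  )
}

#' @rdname filter_state_init
#' @param block Numeric matrix (samples x channels) of new raw samples.
#' @param state State from `filter_state_init()` or a previous block call.
#' @return `filter_signal_block()`: a list with `block` (filtered samples)
#'   and `state` (to pass to the next call).
#' @export
filter_signal_block <- function(block, state) {
  stopifnot(inherits(state, "emg_filter_state"))
  res <- cascade_filter_cpp(as.matrix(block), state$b, state$a, state$values)
  state$values <- res$state
  list(block = res$block, state = state)
}

#' Windowed RMS features
#'
#' Computes the root-mean-square of each channel over trailing windows of
#' `window` seconds advanced in steps of `step` seconds (defaults 160 ms /
#' 40 ms, i.e. 120 ms overlap at the 40 ms system update rate). The first
#' window covers the first `window` seconds and each feature frame is
#' time-stamped at its window end.
#'
#' @param filtered An [emg_recording()] (normally after [filter_signal()]).
#' @param window Window length in seconds (default 0.16).
#' @param step Step between windows in seconds (default 0.04).
#' @return A tibble of class `emg_features` with a `time` column and one RMS
#'   column per channel; frame count is
#'   `floor((n_samples - window_samples) / step_samples) + 1`.
#' @export
rms_features <- function(filtered, window = 0.16, step = 0.04) {
  stopifnot(inherits(filtered, "emg_recording"))
  fs <- filtered$fs
  wn <- round(window * fs)
  sn <- round(step * fs)
  if (wn < 1 || sn < 1) stop("window and step must span at least one sample", call. = FALSE)
  n <- n_samples(filtered)
  if (n < wn) stop("recording shorter than one feature window", call. = FALSE)
  nf <- (n - wn) %/% sn + 1L
  ends <- wn + (seq_len(nf) - 1L) * sn
  vals <- apply(filtered$signals, 2, function(x) {
    cs <- cumsum(c(0, x^2))
    sqrt((cs[ends + 1L] - cs[ends - wn + 1L]) / wn)
  })
  vals <- matrix(vals, nrow = nf,
                 dimnames = list(NULL, colnames(filtered$signals)))
  out <- tibble::as_tibble(as.data.frame(vals)) |>
    dplyr::mutate(time = window + (dplyr::row_number() - 1L) * step, .before = 1L)
  class(out) <- c("emg_features", class(out))
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Feature matrix of an `emg_features` tibble
#'
#' @param features An `emg_features` tibble (or any tibble with a `time`
#'   column followed by channel columns).
#' @return The numeric frames x channels matrix.
#' @export
feature_matrix <- function(features) {
  as.matrix(features[setdiff(names(features), "time")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
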