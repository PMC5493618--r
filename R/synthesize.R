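#' Synthesize a multi-channel EMG recording from an intent trajectory
#'
#' Surface EMG is emulated as amplitude-modulated band-limited Gaussian
#' noise: for each channel a zero-mean Gaussian carrier is band-shaped to
#' 20-450 Hz and normalised to unit local RMS, then multiplied by the
#' channel's activation envelope (the synergy model evaluated on the intent
#' trajectory, linearly interpolated to sample resolution). Optionally a
#' 50 Hz sinusoid of fixed amplitude is added to every channel to emulate
#' powerline interference. The construction targets the second-order
#' statistics that windowed-RMS feature extraction measures; it is not a
#' motor-unit level simulation.
#'
#' @param trajectory A single-run intent trajectory tibble
#'   ([make_calibration_protocol()] row-subset to one run, or
#'   [make_reach_protocol()]).
#' @param synergy A [synergy_model()].
#' @param fs Sampling frequency in Hz (default 2000). Must exceed twice the
#'   carrier band's upper edge.
#' @param interference_amp Amplitude of the additive 50 Hz interference
#'   (default 0.02 signal units; 0 disables it).
#' @param seed Integer seed; all randomness is derived from it.
#' @param carrier_band Carrier pass band in Hz (default `c(20, 450)`).
#'
#' @return An [emg_recording()] whose duration equals the trajectory span
#'   (last frame time + one frame period).
#' @export
synthesize_emg <- function(trajectory, synergy, fs = 2000, interference_amp = 0.02,
                           seed, carrier_band = c(20, 450)) {
  stopifnot(inherits(synergy, "synergy_model"))
  if (missing(seed)) stop("`seed` must be given; all randomness is explicit", call. = FALSE)
  if (fs <= 2 * carrier_band[2]) {
    stop("`fs` must exceed twice the carrier band's upper edge", call. = FALSE)
  }
  if ("run" %in% names(trajectory) && length(unique(trajectory$run)) > 1L) {
    stop("synthesize one run at a time", call. = FALSE)
  }
  dt <- diff(trajectory$time[1:2])
  t_end <- trajectory$time[nrow(trajectory)] + dt
  n <- round(t_end * fs)
  t_samp <- (seq_len(n) - 1) / fs

  act <- intent_to_activation(cbind(trajectory$x, trajectory$y), synergy)
  env <- apply(act, 2, function(a) {
    stats::approx(trajectory$time, a, xout = t_samp, rule = 2)$y
  })

  carriers <- withr::with_seed(seed, {
    vapply(seq_len(synergy$n_channels), function(i) {
      emg_carrier(n, fs, carrier_band)
    }, numeric(n))
  })

  sig <- env * carriers
  if (interference_amp != 0) {
    sig <- sig + interference_amp * sin(2 * pi * 50 * t_samp)
  }
  emg_recording(sig, fs = fs, meta = list(
    seed = seed, interference_amp = interference_amp,
    protocol = trajectory, fs_frames = 1 / dt
  ))
}

# Unit-local-RMS band-limited Gaussian carrier. The raw band-shaped noise is
# divided by its own 400 ms moving RMS so that any 160 ms window has RMS very
# close to 1; without this local normalisation the windowed RMS of the
# product would scatter ~6% around the commanded envelope.
emg_carrier <- function(n, fs, band, norm_window = 0.4) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  w <- max(3L, round(norm_window * fs))
  local_rms <- sqrt(pmax(moving_mean(x^2, w), .Machine$double.eps))
  x / local_rms
}

# Centred moving mean with edge windows truncated to the available samples.
moving_mean <- function(x, w) {
  n <- length(x)
  h <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
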