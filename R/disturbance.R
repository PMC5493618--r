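#' Artificial-noise specification
#'
#' Parameters of the two artificial non-stationarity protocols applied to a
#' single raw EMG channel: `"ramp"` adds white Gaussian noise whose RMS grows
#' linearly as `ramp_coeff * A_max * t`, `"step"` adds white Gaussian noise of
#' constant RMS `step_level * A_max` for `step_duration` seconds. Both start
#' `onset` seconds into the run.
#'
#' @param profile `"ramp"` or `"step"`.
#' @param channel Raw channel index to corrupt (1-8).
#' @param onset Noise onset in seconds (default 5).
#' @param ramp_coeff Ramp slope in units of `A_max` per second (default 0.1).
#' @param step_level Step intensity in units of `A_max` (default 0.4).
#' @param step_duration Step duration in seconds (default 10).
#' @param t_from For the ramp profile, whether t in the amplitude law counts
#'   from noise `"onset"` (default: amplitude rises continuously from zero)
#'   or from trial `"start"`.
#' @param seed Integer seed for the noise realisation.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(profile = c("ramp", "step"), channel, onset = 5,
                       ramp_coeff = 0.1, step_level = 0.4, step_duration = 10,
                       t_from = c("onset", "start"), seed) {
  profile <- match.arg(profile)
  t_from <- match.arg(t_from)
  if (missing(seed)) stop("`seed` must be given", call. = FALSE)
  if (onset < 0 || ramp_coeff < 0 || step_level < 0 || step_duration <= 0) {
    stop("invalid noise parameters", call. = FALSE)
  }
  structure(
    list(profile = profile, channel = as.integer(channel), onset = onset,
         ramp_coeff = ramp_coeff, step_level = step_level,
         step_duration = step_duration, t_from = t_from, seed = seed),
    class = "noise_spec"
  )
}

#' Maximal calibration amplitude A_max
#'
#' Estimates the noise-scaling reference `A_max`: the maximum over all
#' flexion and extension frames of the channel-averaged RMS envelope (160 ms
#' windows) of the raw calibration signals, taken across all supplied runs.
#'
#' @param recordings A raw [emg_recording()] or list of them (one per
#'   calibration run).
#' @param trajectories Matching intent trajectory (or list), used to label
#'   the feature frames.
#' @param flexion_class,extension_class Class ids of pure flexion and
#'   extension (defaults 5 and 1).
#' @return An object of class `amax_estimate` with elements `value` and
#'   `source`.
#' @export
compute_amax <- function(recordings, trajectories,
                         flexion_class = 5L, extension_class = 1L) {
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  stopifnot(length(recordings) == length(trajectories))
  per_run <- purrr::map2_dbl(recordings, trajectories, function(rec, traj) {
    feats <- rms_features(rec)
    lab <- trajectory_at(traj, feats$time)$label
    sel <- lab %in% c(flexion_class, extension_class)
    if (!any(sel)) return(NA_real_)
    max(rowMeans(feature_matrix(feats))[sel])
  })
  if (all(is.na(per_run))) {
    stop("no flexion/extension frames found in the calibration runs", call. = FALSE)
  }
  structure(
    list(value = max(per_run, na.rm = TRUE),
         source = sprintf("max channel-average RMS over flexion/extension frames of %d run(s)",
                          length(recordings))),
    class = "amax_estimate"
  )
}

#' @export
print.amax_estimate <- function(x, ...) {
  cat(sprintf("<amax_estimate> A_max = %.4g (%s)\n", x$value, x$source))
  invisible(x)
}

#' Inject artificial noise into one raw channel
#'
#' `inject_noise()` dispatches on the spec's profile; the profile-specific
#' functions can be called directly. The generated component is additive:
#' `output - input` is exactly the noise, all other channels are untouched,
#' and everything before the onset is bit-identical to the input. Noise is
#' meant to be injected into the raw recording, before filtering and feature
#' extraction.
#'
#' @param raw A raw [emg_recording()].
#' @param spec A [noise_spec()].
#' @param amax An [compute_amax()] estimate (or a bare positive number).
#' @param return_noise Also return the generated component (default FALSE).
#' @return The corrupted `emg_recording`; with `return_noise = TRUE`, a list
#'   with elements `recording` and `noise` (numeric vector).
#' @export
inject_noise <- function(raw, spec, amax, return_noise = FALSE) {
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$profile == "ramp") inject_ramp_noise(raw, spec, amax, return_noise)
  else inject_step_noise(raw, spec, amax, return_noise)
}

amax_value <- function(amax) {
  if (inherits(amax, "amax_estimate")) amax$value else as.numeric(amax)
}

check_noise_channel <- function(raw, spec) {
  if (spec$channel < 1L || spec$channel > n_channels(raw)) {
    stop("noise channel out of range", call. = FALSE)
  }
}

#' @rdname inject_noise
#' @export
inject_ramp_noise <- function(raw, spec, amax, return_noise = FALSE) {
  stopifnot(inherits(raw, "emg_recording"))
  check_noise_channel(raw, spec)
  if (duration(raw) < spec$onset) stop("recording shorter than the noise onset", call. = FALSE)
  t <- sample_times(raw)
  tt <- if (spec$t_from == "onset") pmax(0, t - spec$onset) else t
  sd_t <- ifelse(t >= spec$onset, spec$ramp_coeff * amax_value(amax) * tt, 0)
  add_noise_component(raw, spec, sd_t, return_noise)
}

#' @rdname inject_noise
#' @export
inject_step_noise <- function(raw, spec, amax, return_noise = FALSE) {
  stopifnot(inherits(raw, "emg_recording"))
  check_noise_channel(raw, spec)
  if (duration(raw) < spec$onset + spec$step_duration) {
    stop("recording shorter than onset + step duration", call. = FALSE)
  }
  t <- sample_times(raw)
  sd_t <- ifelse(t >= spec$onset & t < spec$onset + spec$step_duration,
                 spec$step_level * amax_value(amax), 0)
  add_noise_component(raw, spec, sd_t, return_noise)
}

# White Gaussian noise with per-sample standard deviation sd_t added to the
# spec'd channel; seeded, so the component is reproducible.
add_noise_component <- function(raw, spec, sd_t, return_noise) {
  noise <- withr::with_seed(spec$seed, stats::rnorm(n_samples(raw)) * sd_t)
  sig <- raw$signals
  sig[, spec$channel] <- sig[, spec$channel] + noise
  out <- emg_recording(sig, fs = raw$fs,
                       meta = c(raw$meta, list(noise = spec[c("profile", "channel", "onset", "seed")])))
  if (return_noise) list(recording = out, noise = noise) else out
}
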