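#' Channel tuning model for synthetic EMG
#'
#' Maps 2-D wrist intent to the RMS activation of 8 circumferential
#' electrodes. Each channel has a preferred direction on the intent circle
#' and responds with half-rectified cosine tuning above a small resting
#' baseline; a crosstalk term mixes part of each channel's supra-baseline
#' drive into its two neighbours, mimicking volume conduction between
#' adjacent electrodes.
#'
#' @param n_channels Number of electrodes (default 8).
#' @param tuning_angles Preferred directions in radians; default equally
#'   spaced around the circle.
#' @param gains Positive per-channel gain (RMS at full MVC along the
#'   preferred direction, above the baseline); default 1.
#' @param rest_floor Non-negative per-channel baseline RMS (default 0.02).
#' @param crosstalk Fraction in `[0, 1)` of each channel's drive shared with
#'   its neighbours (default 0.1).
#'
#' @return An object of class `synergy_model`.
#' @export
synergy_model <- function(n_channels = 8,
                          tuning_angles = seq(0, 2 * pi, length.out = n_channels + 1)[-(n_channels + 1)],
                          gains = rep(1, n_channels),
                          rest_floor = rep(0.02, n_channels),
                          crosstalk = 0.1) {
  gains <- rep_len(gains, n_channels)
  rest_floor <- rep_len(rest_floor, n_channels)
  stopifnot(length(tuning_angles) == n_channels)
  if (any(gains <= 0)) stop("`gains` must be positive", call. = FALSE)
  if (any(rest_floor < 0)) stop("`rest_floor` must be non-negative", call. = FALSE)
  if (crosstalk < 0 || crosstalk >= 1) stop("`crosstalk` must be in [0, 1)", call. = FALSE)
  dirs <- cbind(cos(tuning_angles), sin(tuning_angles))
  # circulant mixing of the supra-baseline drive: keep (1 - c), give c/2 to
  # each circular neighbour
  mix <- diag(1 - crosstalk, n_channels)
  for (i in seq_len(n_channels)) {
    mix[i, (i %% n_channels) + 1] <- crosstalk / 2
    mix[i, ((i - 2) %% n_channels) + 1] <- crosstalk / 2
  }
  structure(
    list(
      n_channels = n_channels, tuning_directions = dirs, tuning_gains = gains,
      rest_floor = rest_floor, crosstalk = crosstalk, mixing = mix
    ),
    class = "synergy_model"
  )
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf(
    "<synergy_model> %d channels, crosstalk %.2f, rest floor %.3g-%.3g\n",
    x$n_channels, x$crosstalk, min(x$rest_floor), max(x$rest_floor)
  ))
  invisible(x)
}

#' Randomised synergy for a synthetic subject
#'
#' Perturbs the default tuning model to emulate inter-subject variability:
#' preferred directions are jittered (Gaussian, `angle_jitter_sd`), gains are
#' log-normal around 1.
#'
#' @param seed Integer seed; the synergy is a deterministic function of it.
#' @param angle_jitter_sd SD of the angular jitter in radians (default 5 deg).
#' @param gain_sdlog SD of log-gains (default 0.15).
#' @inheritParams synergy_model
#' @return A `synergy_model`.
#' @export
random_synergy <- function(seed, n_channels = 8, angle_jitter_sd = 5 * pi / 180,
                           gain_sdlog = 0.15, rest_floor = 0.02, crosstalk = 0.1) {
  withr::with_seed(seed, {
    base <- seq(0, 2 * pi, length.out = n_channels + 1)[-(n_channels + 1)]
    ang <- base + stats::rnorm(n_channels, sd = angle_jitter_sd)
    g <- stats::rlnorm(n_channels, meanlog = 0, sdlog = gain_sdlog)
    synergy_model(
      n_channels = n_channels, tuning_angles = ang, gains = g,
      rest_floor = rep_len(rest_floor, n_channels), crosstalk = crosstalk
    )
  })
}

#' Map intent to per-channel RMS activation
#'
#' Activation of channel i is `rest_floor_i + gain_i * max(0, d_i . intent)`
#' with `d_i` the channel's preferred direction; the supra-baseline part is
#' then mixed across neighbouring channels by the synergy's crosstalk, so
#' every component stays at or above its resting baseline. Intents of norm
#' greater than 1 (beyond MVC) are clamped to the unit circle with a warning.
#'
#' @param intent A length-2 vector or an n x 2 matrix of `(x, y)` intents.
#' @param synergy A [synergy_model()].
#' @return An n x n_channels matrix of activations (a vector input gives a
#'   1-row matrix).
#' @export
intent_to_activation <- function(intent, synergy) {
  stopifnot(inherits(synergy, "synergy_model"))
  y <- if (is.matrix(intent)) intent else matrix(intent, ncol = 2)
  stopifnot(ncol(y) == 2)
  nrm <- sqrt(rowSums(y^2))
  over <- nrm > 1 + 1e-12
  if (any(over)) {
    warning("intent norm exceeds 1 (MVC); clamping to the unit circle")
    y[over, ] <- y[over, ] / nrm[over]
  }
  drive <- pmax(y %*% t(synergy$tuning_directions), 0)
  drive <- sweep(drive, 2, synergy$tuning_gains, `*`)
  mixed <- drive %*% t(synergy$mixing)
  sweep(mixed, 2, synergy$rest_floor, `+`)
}
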