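#' Motion-class directions
#'
#' The 2-D control space maps DOF 1 (wrist flexion/extension) to the
#' horizontal axis -- extension positive, flexion negative -- and DOF 2
#' (radial/ulnar deviation) to the vertical axis. Motion classes 1..8 sit at
#' 45 degree increments starting from pure extension at class 1; class 0 is
#' rest at the origin. The unit circle corresponds to maximal voluntary
#' contraction (MVC).
#'
#' @param class_id Integer vector of class ids in 0..8.
#' @return A numeric matrix with one `(x, y)` unit row vector per id (zero row
#'   for rest).
#' @export
class_direction <- function(class_id) {
  if (!all(class_id %in% 0:8)) {
    stop("motion class ids must be in 0..8", call. = FALSE)
  }
  ang <- (class_id - 1) * pi / 4
  out <- cbind(x = cos(ang), y = sin(ang))
  out[class_id == 0L, ] <- 0
  # snap exact axis directions (cos(pi/2) etc. are not exactly 0)
  out[abs(out) < 1e-12] <- 0
  out
}

rest_tolerance <- 0.01

intent_tbl <- function(time, x, y, phase, fs_frames) {
  x <- unname(x)
  y <- unname(y)
  nrm <- sqrt(x^2 + y^2)
  ang <- atan2(y, x) %% (2 * pi)
  k <- (round(ang / (pi / 4)) %% 8) + 1
  label <- ifelse(nrm < rest_tolerance, 0L, as.integer(k))
  tibble::tibble(
    time = time, x = x, y = y,
    label = label, phase = phase,
    fs_frames = fs_frames
  )
}

#' Cue-based calibration protocol
#'
#' Builds the commanded intent trajectory of a calibration run: for each of
#' the 8 directions (45 degree increments; classes 1-8) the cue ramps linearly
#' from the origin to `mvc_level` in 2 s, holds for 4 s and returns to the
#' origin in 2 s; an 8 s rest block closes each run. Intent is MVC-normalised
#' (unit circle = MVC).
#'
#' @param n_runs Number of calibration runs to generate (default 1).
#' @param mvc_level Cued contraction level as a fraction of MVC (default 0.8).
#' @param fs_frames Frame rate of the intent trajectory in Hz (default 25,
#'   i.e. one frame per 40 ms system update).
#' @param ramp_s,hold_s,return_s,rest_s Segment durations in seconds.
#'
#' @return A tibble with columns `run`, `time` (seconds within the run), `x`,
#'   `y` (intent), `label` (motion class, 0 = rest) and `phase` (`"ramp"`,
#'   `"hold"`, `"return"`, `"rest"`).
#' @export
make_calibration_protocol <- function(n_runs = 1, mvc_level = 0.8, fs_frames = 25,
                                      ramp_s = 2, hold_s = 4, return_s = 2,
                                      rest_s = 8) {
  if (n_runs < 1) stop("`n_runs` must be >= 1", call. = FALSE)
  if (!is.numeric(mvc_level) || mvc_level <= 0 || mvc_level > 1) {
    stop("`mvc_level` must be in (0, 1]", call. = FALSE)
  }
  if (any(c(ramp_s, hold_s, return_s, rest_s, fs_frames) <= 0)) {
    stop("durations and frame rate must be positive", call. = FALSE)
  }
  dt <- 1 / fs_frames
  seg_level <- function(t) { # level profile over one movement segment
    ifelse(t < ramp_s, t / ramp_s,
      ifelse(t < ramp_s + hold_s, 1,
        pmax(0, 1 - (t - ramp_s - hold_s) / return_s)
      )
    )
  }
  seg_dur <- ramp_s + hold_s + return_s
  one_run <- function(run) {
    t_total <- 8 * seg_dur + rest_s
    time <- seq(0, t_total - dt, by = dt)
    seg <- pmin(floor(time / seg_dur), 8) # 0..7 movements, 8 = rest
    t_loc <- time - seg * seg_dur
    level <- ifelse(seg < 8, mvc_level * seg_level(t_loc), 0)
    phase <- ifelse(seg == 8, "rest",
      ifelse(t_loc < ramp_s, "ramp",
        ifelse(t_loc < ramp_s + hold_s, "hold", "return")
      )
    )
    dir <- class_direction(ifelse(seg < 8, seg + 1, 0))
    out <- intent_tbl(time, level * dir[, "x"], level * dir[, "y"], phase, fs_frames)
    dplyr::mutate(out, run = run, .before = 1L)
  }
  purrr::map_dfr(seq_len(n_runs), one_run)
}

#' Constant-intent target-holding protocol
#'
#' Commanded intent for a target-holding run: the simulated subject holds a
#' constant contraction of `level` x MVC in one of the 8 directions for the
#' full run (as in the noise-robustness phases where the target stays on
#' screen for the whole trial).
#'
#' @param direction_id Motion class 1..8.
#' @param level Contraction level as a fraction of MVC (default 0.5).
#' @param duration Run duration in seconds (default 20).
#' @param fs_frames Intent frame rate in Hz (default 25).
#'
#' @return A tibble with columns `time`, `x`, `y`, `label`, `phase`
#'   (`"constant"`).
#' @export
make_reach_protocol <- function(direction_id, level = 0.5, duration = 20,
                                fs_frames = 25) {
  if (!(length(direction_id) == 1L && direction_id %in% 1:8)) {
    stop("`direction_id` must be a single class in 1..8", call. = FALSE)
  }
  if (level < 0 || level > 1) stop("`level` must be in [0, 1]", call. = FALSE)
  if (duration <= 0 || fs_frames <= 0) {
    stop("`duration` and `fs_frames` must be positive", call. = FALSE)
  }
  dt <- 1 / fs_frames
  time <- seq(0, duration - dt, by = dt)
  dir <- drop(class_direction(direction_id))
  intent_tbl(time, rep(level * dir["x"], length(time)),
             rep(level * dir["y"], length(time)),
             phase = "constant", fs_frames = fs_frames)
}

#' Look up intent and labels at arbitrary times
#'
#' `trajectory_at()` samples a trajectory tibble at the requested times:
#' intent (`x`, `y`) is linearly interpolated between frames, `label` and
#' `phase` are taken from the last frame at or before each time (piecewise
#' constant). Times beyond the trajectory are clamped to its ends.
#'
#' @param trajectory A trajectory tibble from [make_calibration_protocol()] or
#'   [make_reach_protocol()] (a single run).
#' @param times Numeric vector of times in seconds.
#' @return A tibble with columns `time`, `x`, `y`, `label`, `phase`.
#' @export
trajectory_at <- function(trajectory, times) {
  stopifnot(all(c("time", "x", "y", "label") %in% names(trajectory)))
  if ("run" %in% names(trajectory) && length(unique(trajectory$run)) > 1L) {
    stop("`trajectory_at()` expects a single run", call. = FALSE)
  }
  idx <- pmax(1L, findInterval(times, trajectory$time))
  tibble::tibble(
    time = times,
    x = stats::approx(trajectory$time, trajectory$x, xout = times, rule = 2)$y,
    y = stats::approx(trajectory$time, trajectory$y, xout = times, rule = 2)$y,
    label = trajectory$label[idx],
    phase = if ("phase" %in% names(trajectory)) trajectory$phase[idx] else NA_character_
  )
}
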