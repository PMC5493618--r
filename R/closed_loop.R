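#' Closed-loop simulation with a pluggable user policy
#'
#' Replays the experiment with a simulated user in the loop: at every 40 ms
#' frame the policy sees the current error vector (target minus cursor) and
#' the currently commanded intent, and returns the intent driving the next
#' signal block. The EMG carrier and the noise realisation are pre-generated
#' from the seeds, so with the static policy (always the commanded intent)
#' the synthesized signals are identical to the open-loop path and the
#' decoded trajectory matches [run_offline_experiment()]'s to numerical
#' precision. No model of human adaptation is claimed; the hook exists so
#' adaptation strategies can be studied.
#'
#' The policy contract: `function(error, intent)` returning a finite length-2
#' intent of norm at most 1; violations abort the trial with an error.
#'
#' @param config An [experiment_config()] (keep it small: closed-loop runs
#'   are simulated frame by frame).
#' @param user_policy A policy function; see [static_policy()] and
#'   [corrective_policy()].
#' @param progress Print progress to stderr.
#' @return An `offline_experiment`-shaped object (summary rows per trial).
#' @export
run_closed_loop <- function(config = experiment_config(n_subjects = 2),
                            user_policy = static_policy(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"), is.function(user_policy))
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    if (progress) message(sprintf("subject %d/%d", s, config$n_subjects))
    cal <- calibrate_subject(config, s)
    for (dir_id in config$test_directions) {
      target <- config$test_level * drop(class_direction(dir_id))
      for (rep in seq_len(config$repetitions)) {
        for (ch in config$noise_channels) {
          for (profile in config$noise_profiles) {
            dur <- if (profile == "ramp") config$ramp_duration else config$step_duration
            nspec <- noise_spec(profile, channel = ch,
                                seed = derive_seed(config$seed, s, 4, dir_id, rep,
                                                   ch, match(profile, c("ramp", "step"))))
            for (dec in config$decoders) {
              model <- if (dec == "lr") cal$lr else cal$lda
              reset <- attr(user_policy, "reset")
              if (is.function(reset)) reset()
              cursor <- closed_loop_trial(
                cal, model, user_policy, target,
                direction_id = dir_id, duration = dur, nspec = nspec,
                level = config$test_level, fs = config$fs,
                seed = derive_seed(config$seed, s, 3, dir_id, rep)
              )
              err <- tracking_error(cursor, target)
              bl <- baseline_error(err)
              rows[[length(rows) + 1L]] <- tibble::tibble(
                subject = s, decoder = dec, profile = profile, channel = ch,
                direction = dir_id, rep = rep, baseline = bl,
                time_below = time_below_threshold(err, bl),
                step_residual = if (profile == "step") step_residual(err, bl) else NA_real_,
                mean_post_onset = mean(err$error[err$time >= 5])
              )
            }
          }
        }
      }
    }
  }
  structure(list(summary = dplyr::bind_rows(rows), config = config),
            class = "closed_loop_experiment")
}

# One closed-loop trial: block-wise synthesis driven by the policy's intent,
# stateful filtering and decoding. Blocks are one 40 ms frame (80 samples at
# 2 kHz).
closed_loop_trial <- function(cal, model, user_policy, target, direction_id,
                              duration, nspec, level, fs, seed) {
  frame_dt <- 0.04
  block_n <- round(frame_dt * fs)
  n_frames <- round(duration / frame_dt)
  n <- n_frames * block_n
  commanded <- level * drop(class_direction(direction_id))

  # pre-generate carrier and noise exactly as the batch path would
  carriers <- withr::with_seed(seed, {
    vapply(seq_len(cal$synergy$n_channels), function(i) {
      emg_carrier(n, fs, c(20, 450))
    }, numeric(n))
  })
  t_samp <- (seq_len(n) - 1) / fs
  tt <- if (nspec$t_from == "onset") pmax(0, t_samp - nspec$onset) else t_samp
  sd_t <- switch(nspec$profile,
    ramp = ifelse(t_samp >= nspec$onset, nspec$ramp_coeff * cal$amax$value * tt, 0),
    step = ifelse(t_samp >= nspec$onset & t_samp < nspec$onset + nspec$step_duration,
                  nspec$step_level * cal$amax$value, 0)
  )
  noise <- withr::with_seed(nspec$seed, stats::rnorm(n) * sd_t)

  fstate <- filter_state_init(cal$filter, cal$synergy$n_channels)
  dstate <- decoder_state_init(model)
  win_n <- round(0.16 * fs)
  ring <- matrix(0, 0, cal$synergy$n_channels) # filtered-sample buffer
  interference_amp <- 0.02

  intent <- commanded
  prev_act <- drop(intent_to_activation(intent, cal$synergy))
  positions <- matrix(NA_real_, n_frames, 2)
  times <- numeric(n_frames)
  pos <- c(0, 0)
  for (f in seq_len(n_frames)) {
    nxt <- if (f == 1L) commanded else user_policy(target - pos, commanded)
    if (length(nxt) != 2 || !all(is.finite(nxt))) {
      stop("user policy returned a non-finite or malformed intent", call. = FALSE)
    }
    if (sqrt(sum(nxt^2)) > 1 + 1e-9) {
      stop("user policy returned an intent of norm > 1 (beyond MVC)", call. = FALSE)
    }
    act <- drop(intent_to_activation(nxt, cal$synergy))
    idx <- ((f - 1L) * block_n + 1L):(f * block_n)
    # linear interpolation of the activation across the block, matching the
    # batch path's sample-resolution interpolation between 40 ms frames
    w <- (idx - 1 - (f - 1) * block_n) / block_n
    env <- outer(1 - w, prev_act) + outer(w, act)
    block <- env * carriers[idx, , drop = FALSE] +
      interference_amp * sin(2 * pi * 50 * t_samp[idx])
    block[, nspec$channel] <- block[, nspec$channel] + noise[idx]
    fb <- filter_signal_block(block, fstate)
    fstate <- fb$state
    ring <- rbind(ring, fb$block)
    if (nrow(ring) > win_n) ring <- ring[(nrow(ring) - win_n + 1L):nrow(ring), , drop = FALSE]
    times[f] <- idx[length(idx)] / fs
    if (nrow(ring) >= win_n) {
      phi <- sqrt(colMeans(ring^2))
      st <- decode_step(dstate, phi)
      dstate <- st$state
      pos <- st$position
    }
    positions[f, ] <- pos
    prev_act <- act
    intent <- nxt
  }
  keep <- times >= 0.16 - 1e-9 # frames with a full feature window
  tibble::tibble(time = times[keep], x = positions[keep, 1], y = positions[keep, 2])
}

#' Built-in user policies
#'
#' `static_policy()` always returns the commanded intent (no adaptation):
#' closed-loop results reduce to the open-loop ones. `corrective_policy()`
#' is an illustrative integral-style corrector: it nudges its own intent by
#' `gain` times the current error vector each frame, clamped to the MVC
#' circle. It is a demonstration of the hook, not a model of the study's
#' human subjects.
#'
#' @param gain Correction gain per frame (default 0.02).
#' @return A policy `function(error, intent)`.
#' @export
static_policy <- function() {
  function(error, intent) intent
}

#' @rdname static_policy
#' @export
corrective_policy <- function(gain = 0.02) {
  env <- new.env()
  env$adjust <- c(0, 0)
  f <- function(error, intent) {
    env$adjust <- env$adjust + gain * error
    out <- intent + env$adjust
    nrm <- sqrt(sum(out^2))
    if (nrm > 1) out <- out / nrm
    out
  }
  # stateful policies carry a reset hook so each trial starts fresh
  attr(f, "reset") <- function() env$adjust <- c(0, 0)
  f
}
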