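#' Offline noise-robustness experiment configuration
#'
#' Defaults mirror one full session of the study protocol: 3 calibration
#' runs (8 directions cued to 80% MVC plus rest), target-holding test runs
#' at 50% MVC in flexion and extension (3 repetitions each), artificial
#' ramp (20 s trials) and step (15 s analysis window) noise injected into
#' each of the 8 raw channels, decoded open loop with both the regression
#' and the LDA chain. Synthetic subjects differ by their synergy model and
#' seeds only.
#'
#' @param n_subjects Number of synthetic subjects (default 10).
#' @param decoders Character subset of `c("lr", "lda")`.
#' @param calibration_runs Calibration runs per subject (default 3).
#' @param test_directions Class ids of the target-holding runs (default
#'   extension 1 and flexion 5).
#' @param repetitions Repetitions per direction (default 3).
#' @param noise_channels Channels to corrupt (default 1:8).
#' @param noise_profiles Disturbance profiles to run (default both `"ramp"`
#'   and `"step"`).
#' @param ramp_duration Ramp-trial duration in seconds (default 20).
#' @param step_duration Step-trial analysis duration in seconds (default 15).
#' @param test_level Target contraction level (default 0.5 x MVC).
#' @param mvc_level Calibration cue level (default 0.8 x MVC).
#' @param n_classes 9 (8 motions + rest) or 5 (the 4 single-DOF motions +
#'   rest; the reduced protocol used when combined contractions are not
#'   reliable).
#' @param fs Sampling rate in Hz (default 2000).
#' @param seed Master seed; every random draw in the experiment derives from
#'   it.
#' @param amax_override Optional fixed `A_max` (e.g. 0 to disable noise);
#'   default `NULL` estimates it from each subject's calibration runs.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 10, decoders = c("lr", "lda"),
                              calibration_runs = 3, test_directions = c(1L, 5L),
                              repetitions = 3, noise_channels = 1:8,
                              noise_profiles = c("ramp", "step"),
                              ramp_duration = 20, step_duration = 15,
                              test_level = 0.5, mvc_level = 0.8,
                              n_classes = 9, fs = 2000, seed = 1L,
                              amax_override = NULL) {
  decoders <- match.arg(decoders, several.ok = TRUE)
  noise_profiles <- match.arg(noise_profiles, several.ok = TRUE)
  if (!n_classes %in% c(5, 9)) stop("`n_classes` must be 5 or 9", call. = FALSE)
  if (any(c(n_subjects, calibration_runs, repetitions, ramp_duration,
            step_duration, fs) <= 0)) {
    stop("counts and durations must be positive", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, decoders = decoders,
         calibration_runs = calibration_runs, test_directions = test_directions,
         repetitions = repetitions, noise_channels = noise_channels,
         noise_profiles = noise_profiles,
         ramp_duration = ramp_duration, step_duration = step_duration,
         test_level = test_level, mvc_level = mvc_level,
         n_classes = n_classes, fs = fs, seed = as.integer(seed),
         amax_override = amax_override),
    class = "experiment_config"
  )
}

# Deterministic sub-seed: polynomial hash of the index path, kept within the
# 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed) %% 2147483587
  for (k in idx) h <- (h * 69069 + as.double(k) + 1) %% 2147483587
  as.integer(h) + 1L
}

# Calibration classes of the reduced (5-class) protocol: single-DOF motions.
protocol_classes <- function(n_classes) {
  if (n_classes == 9) 1:8 else c(1L, 3L, 5L, 7L)
}

#' Calibrate one synthetic subject
#'
#' Generates the calibration runs for one synthetic subject, fits both
#' decoders and estimates `A_max`. Used by [run_offline_experiment()];
#' exposed for interactive exploration.
#'
#' @param config An [experiment_config()].
#' @param subject Subject index (determines synergy and seeds).
#' @return A list with `synergy`, `recordings`, `trajectories`, `lr`, `lda`,
#'   `amax`.
#' @export
calibrate_subject <- function(config, subject) {
  syn <- random_synergy(derive_seed(config$seed, subject, 1))
  classes <- protocol_classes(config$n_classes)
  runs <- purrr::map(seq_len(config$calibration_runs), function(r) {
    traj <- make_calibration_protocol(1, mvc_level = config$mvc_level)
    if (config$n_classes == 5) {
      traj <- dplyr::filter(traj, .data$label %in% c(0L, classes))
      traj$time <- (seq_len(nrow(traj)) - 1) / traj$fs_frames[1]
    }
    rec <- synthesize_emg(traj, syn, fs = config$fs,
                          seed = derive_seed(config$seed, subject, 2, r))
    list(traj = traj, rec = rec)
  })
  spec <- filter_spec(fs = config$fs)
  feats <- purrr::map(runs, function(rn) rms_features(filter_signal(rn$rec, spec)))
  at <- purrr::map2(runs, feats, function(rn, ft) trajectory_at(rn$traj, ft$time))
  phi <- do.call(rbind, purrr::map(feats, feature_matrix))
  targets <- do.call(rbind, purrr::map(at, function(a) cbind(a$x, a$y)))
  labels <- unlist(purrr::map(at, "label"))
  static <- unlist(purrr::map(at, function(a) a$phase == "hold"))

  lr <- fit_lr(phi, targets)
  lda <- fit_lda(phi, labels)
  lda$scaling <- fit_proportional_scaling(phi, labels, static,
                                          cue_level = config$mvc_level)
  amax <- if (!is.null(config$amax_override)) {
    structure(list(value = config$amax_override, source = "override"),
              class = "amax_estimate")
  } else {
    compute_amax(purrr::map(runs, "rec"), purrr::map(runs, "traj"))
  }
  list(synergy = syn, recordings = purrr::map(runs, "rec"),
       trajectories = purrr::map(runs, "traj"),
       filter = spec, lr = lr, lda = lda, amax = amax)
}

#' Run the open-loop (offline) noise-robustness experiment
#'
#' For every synthetic subject: generate calibration data, fit both
#' decoders, synthesize target-holding test runs, inject ramp and step noise
#' into each raw channel in turn, decode the corrupted recordings open loop
#' (the commanded intent never reacts to the output), and compute the
#' robustness metrics. Clean filtered channels are shared across the
#' per-channel noise conditions; only the corrupted channel is re-filtered
#' (the filters are linear, so this is exact).
#'
#' @param config An [experiment_config()].
#' @param progress Print per-subject progress to stderr (default FALSE).
#' @return An object of class `offline_experiment`: a list with
#'   * `summary` — tibble, one row per trial condition (subject, decoder,
#'     profile, channel, direction, rep, baseline, time_below,
#'     step_residual);
#'   * `error_curves` — tibble of mean/SD residual error over time per
#'     decoder x profile;
#'   * `tests` — signed-rank comparisons (LDA vs LR per profile metric, and
#'     each decoder's step residual against zero);
#'   * `amax` — per-subject A_max estimates;
#'   * `config`.
#' @export
run_offline_experiment <- function(config = experiment_config(), progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  curves <- list() # accumulators keyed by decoder|profile
  amaxes <- numeric(config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    if (progress) message(sprintf("subject %d/%d", s, config$n_subjects))
    cal <- calibrate_subject(config, s)
    amaxes[s] <- cal$amax$value
    for (dir_id in config$test_directions) {
      target <- config$test_level * drop(class_direction(dir_id))
      for (rep in seq_len(config$repetitions)) {
        traj <- make_reach_protocol(dir_id, level = config$test_level,
                                    duration = config$ramp_duration)
        raw <- synthesize_emg(traj, cal$synergy, fs = config$fs,
                              seed = derive_seed(config$seed, s, 3, dir_id, rep))
        base_filt <- filter_signal(raw, cal$filter)
        raw_step <- truncate_recording(raw, config$step_duration)
        base_filt_step <- truncate_recording(base_filt, config$step_duration)
        for (ch in config$noise_channels) {
          for (profile in config$noise_profiles) {
            nspec <- noise_spec(profile, channel = ch,
                                seed = derive_seed(config$seed, s, 4, dir_id, rep,
                                                   ch, match(profile, c("ramp", "step"))))
            rawi <- if (profile == "ramp") raw else raw_step
            basei <- if (profile == "ramp") base_filt else base_filt_step
            noisy <- inject_noise(rawi, nspec, cal$amax)
            filt <- basei
            filt$signals[, ch] <- apply_cascade(noisy$signals[, ch], cal$filter$stages)
            feats <- rms_features(filt)
            for (dec in config$decoders) {
              model <- if (dec == "lr") cal$lr else cal$lda
              cursor <- decode_stream(model, feats)
              err <- tracking_error(cursor, target)
              bl <- baseline_error(err)
              resid <- err$error - bl
              key <- paste(dec, profile, sep = "|")
              acc <- curves[[key]]
              if (is.null(acc)) {
                acc <- list(time = err$time, sum = 0, sumsq = 0, n = 0L)
              }
              acc$sum <- acc$sum + resid
              acc$sumsq <- acc$sumsq + resid^2
              acc$n <- acc$n + 1L
              curves[[key]] <- acc
              rows[[length(rows) + 1L]] <- tibble::tibble(
                subject = s, decoder = dec, profile = profile, channel = ch,
                direction = dir_id, rep = rep, baseline = bl,
                time_below = time_below_threshold(err, bl),
                step_residual = if (profile == "step") step_residual(err, bl) else NA_real_
              )
            }
          }
        }
      }
    }
  }

  summary <- dplyr::bind_rows(rows)
  error_curves <- purrr::imap_dfr(curves, function(acc, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    m <- acc$sum / acc$n
    v <- pmax(0, acc$sumsq / acc$n - m^2)
    tibble::tibble(decoder = parts[1], profile = parts[2], time = acc$time,
                   mean_residual = m, sd_residual = sqrt(v), n_trials = acc$n)
  })
  tests <- offline_tests(summary, config)
  structure(
    list(summary = summary, error_curves = error_curves, tests = tests,
         amax = tibble::tibble(subject = seq_len(config$n_subjects), amax = amaxes),
         config = config),
    class = "offline_experiment"
  )
}

# Statistical comparisons on per-subject means.
offline_tests <- function(summary, config) {
  out <- list()
  per_subj <- summary |>
    dplyr::group_by(.data$subject, .data$decoder, .data$profile) |>
    dplyr::summarise(time_below = mean(.data$time_below),
                     step_residual = mean(.data$step_residual),
                     .groups = "drop")
  if (length(config$decoders) == 2 && config$n_subjects >= 5) {
    cmp <- list()
    if ("ramp" %in% config$noise_profiles) {
      ramp <- dplyr::filter(per_subj, .data$profile == "ramp")
      cmp$ramp <- dplyr::mutate(
        compare_conditions(ramp, "time_below", "decoder", "subject"),
        metric = "time_below", .before = 1L
      )
    }
    if ("step" %in% config$noise_profiles) {
      step <- dplyr::filter(per_subj, .data$profile == "step")
      cmp$step <- dplyr::mutate(
        compare_conditions(step, "step_residual", "decoder", "subject"),
        metric = "step_residual", .before = 1L
      )
    }
    out$lda_vs_lr <- dplyr::bind_rows(cmp)
  }
  if ("step" %in% config$noise_profiles) {
    out$step_vs_baseline <- per_subj |>
      dplyr::filter(.data$profile == "step") |>
      dplyr::group_by(.data$decoder) |>
      dplyr::group_modify(function(df, key) wilcoxon_signed_rank(df$step_residual)) |>
      dplyr::ungroup()
  }
  out
}

#' @export
print.offline_experiment <- function(x, ...) {
  cat(sprintf("<offline_experiment> %d subjects, %d trial rows\n",
              x$config$n_subjects, nrow(x$summary)))
  agg <- x$summary |>
    dplyr::group_by(.data$decoder, .data$profile) |>
    dplyr::summarise(
      baseline = mean(.data$baseline),
      time_below = mean(.data$time_below),
      step_residual = mean(.data$step_residual),
      .groups = "drop"
    )
  print(agg)
  invisible(x)
}

#' Summarise an offline experiment per subject
#'
#' @param experiment An `offline_experiment`.
#' @return Tibble of per-subject, per-decoder, per-profile means of the
#'   robustness metrics.
#' @export
subject_summary <- function(experiment) {
  experiment$summary |>
    dplyr::group_by(.data$subject, .data$decoder, .data$profile) |>
    dplyr::summarise(
      baseline = mean(.data$baseline),
      time_below = mean(.data$time_below),
      step_residual = mean(.data$step_residual),
      .groups = "drop"
    )
}
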