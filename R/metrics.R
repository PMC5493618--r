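#' Per-frame tracking error
#'
#' Euclidean distance between the cursor and the target centre over time.
#'
#' @param cursor A cursor tibble with `time`, `x`, `y` (from
#'   [decode_stream()]).
#' @param target Length-2 target centre `(x, y)` in MVC units.
#' @return A tibble with `time` and `error`.
#' @export
tracking_error <- function(cursor, target) {
  stopifnot(all(c("time", "x", "y") %in% names(cursor)), length(target) == 2)
  tibble::tibble(
    time = cursor$time,
    error = sqrt((cursor$x - target[1])^2 + (cursor$y - target[2])^2)
  )
}

#' Baseline error before noise onset
#'
#' Mean tracking error over the window immediately before the disturbance
#' (default 4-5 s).
#'
#' @param error A tibble with `time` and `error`.
#' @param window `(from, to)` in seconds; frames with `from <= t < to` count.
#' @return Scalar mean error.
#' @export
baseline_error <- function(error, window = c(4, 5)) {
  sel <- error$time >= window[1] & error$time < window[2]
  if (!any(sel)) stop("error series does not cover the baseline window", call. = FALSE)
  mean(error$error[sel])
}

#' Time the residual error stays below threshold
#'
#' Robustness measure for ramping disturbances: the time from noise onset to
#' the first sustained crossing of the residual error (error minus baseline)
#' above `threshold`. A crossing is sustained when the residual stays at or
#' above the threshold for at least `sustain` seconds (set `sustain = 0` for
#' the first-frame rule). If the threshold is never crossed the full
#' post-onset duration is returned.
#'
#' @param error A tibble with `time` and `error`.
#' @param baseline Baseline error (see [baseline_error()]).
#' @param threshold Residual threshold in MVC units (default 0.3).
#' @param onset Noise onset in seconds (default 5).
#' @param sustain Debounce duration in seconds (default 0.2).
#' @return Time below threshold in seconds.
#' @export
time_below_threshold <- function(error, baseline, threshold = 0.3, onset = 5,
                                 sustain = 0.2) {
  post <- error[error$time >= onset, ]
  if (nrow(post) == 0L) stop("no frames after the noise onset", call. = FALSE)
  dt <- if (nrow(post) > 1L) diff(post$time[1:2]) else 0.04
  need <- max(1L, ceiling(sustain / dt - 1e-9))
  above <- (post$error - baseline) >= threshold
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= need) {
      return(post$time[i - need + 1L] - onset)
    }
  }
  max(post$time) - onset
}

#' Residual error under sudden noise
#'
#' Mean error over the late measurement window (default 14-15 s) minus the
#' baseline error; quantifies how far a step disturbance pushed the cursor
#' off target once transients settled.
#'
#' @inheritParams time_below_threshold
#' @param window `(from, to)` seconds of the measurement interval.
#' @return Scalar residual error (can be negative if performance improved).
#' @export
step_residual <- function(error, baseline, window = c(14, 15)) {
  sel <- error$time >= window[1] & error$time < window[2]
  if (!any(sel)) stop("error series does not cover the residual window", call. = FALSE)
  mean(error$error[sel]) - baseline
}

#' Target-reaching metrics
#'
#' Summarises a set of target-reaching trials with the four standard
#' real-time myocontrol metrics. A trial is successful when the cursor enters
#' the target disc and stays inside for `dwell` seconds, with the
#' dwell-completing entry no later than `timeout`. Completion time is the
#' time of that final entry, averaged over successful trials; the overshoot
#' ratio counts target exits before the dwell completes, normalised by the
#' number of targets; path efficiency is the ratio of the straight-line
#' distance (start to position at the dwell-completing entry) to the path
#' length actually travelled up to that entry, averaged over successful
#' trials.
#'
#' @param trials List of trials; each a list with `cursor` (tibble `time`,
#'   `x`, `y`) and `target` (length-2 centre).
#' @param dwell Required dwell time in seconds (default 1).
#' @param timeout Maximum time to hit the target in seconds (default 10).
#' @param radius Target radius in MVC units (default 0.15).
#' @return A one-row tibble: `completion_rate`, `completion_time`,
#'   `overshoot_ratio`, `path_efficiency`, `n_trials`.
#' @export
reaching_metrics <- function(trials, dwell = 1, timeout = 10, radius = 0.15) {
  if (length(trials) == 0L) stop("no trials supplied", call. = FALSE)
  per <- purrr::map_dfr(trials, function(tr) {
    cur <- tr$cursor
    d <- sqrt((cur$x - tr$target[1])^2 + (cur$y - tr$target[2])^2)
    inside <- d <= radius
    n <- length(inside)
    dt <- if (n > 1L) diff(cur$time[1:2]) else 0.04
    need <- max(1L, round(dwell / dt))
    overshoots <- 0L
    success <- FALSE
    hit_time <- NA_real_
    hit_idx <- NA_integer_
    i <- 1L
    while (i <= n) {
      if (inside[i] && (i == 1L || !inside[i - 1L])) { # entry event
        j <- i
        while (j <= n && inside[j]) j <- j + 1L
        stay <- j - i
        if (stay >= need && cur$time[i] <= timeout) {
          success <- TRUE
          hit_time <- cur$time[i]
          hit_idx <- i
          break
        }
        overshoots <- overshoots + 1L # left (or ran out) before dwell completed
        i <- j
      } else {
        i <- i + 1L
      }
    }
    path_eff <- NA_real_
    if (success) {
      seg <- seq_len(hit_idx)
      steps <- sqrt(diff(cur$x[seg])^2 + diff(cur$y[seg])^2)
      travelled <- sum(steps)
      straight <- sqrt((cur$x[hit_idx] - cur$x[1])^2 + (cur$y[hit_idx] - cur$y[1])^2)
      path_eff <- if (travelled > 0) straight / travelled else 1
    }
    tibble::tibble(success = success, completion_time = hit_time,
                   overshoots = overshoots, path_efficiency = path_eff)
  })
  tibble::tibble(
    completion_rate = mean(per$success),
    completion_time = if (any(per$success)) mean(per$completion_time[per$success]) else NA_real_,
    overshoot_ratio = sum(per$overshoots) / nrow(per),
    path_efficiency = if (any(per$success)) mean(per$path_efficiency[per$success]) else NA_real_,
    n_trials = nrow(per)
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Thin wrapper around [stats::wilcox.test()] with the Wilcoxon convention
#' for zero differences (dropped before ranking). When every difference is
#' zero the test degenerates; by convention the statistic is reported as 0
#' and p = 1. The exact null distribution is used for n <= 25 when there are
#' no ties in the absolute differences.
#'
#' @param x,y Paired samples (y may be omitted for a one-sample test against
#'   zero).
#' @return A one-row tibble: `statistic`, `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
    x - y
  }
  d <- d[!is.na(d)]
  dz <- d[d != 0]
  if (length(dz) == 0L) {
    return(tibble::tibble(statistic = 0, p_value = 1, n_effective = 0L,
                          method = "all differences zero"))
  }
  exact <- length(dz) <= 25 && !anyDuplicated(abs(dz))
  res <- suppressWarnings(
    stats::wilcox.test(dz, exact = exact, correct = !exact)
  )
  tibble::tibble(statistic = unname(res$statistic), p_value = res$p.value,
                 n_effective = length(dz),
                 method = if (exact) "exact" else "normal approximation")
}

#' Compare conditions with paired signed-rank tests
#'
#' Runs a Wilcoxon signed-rank test for every pairwise combination of
#' conditions on subject-paired values and applies a Bonferroni correction
#' across the comparisons.
#'
#' @param data A tidy tibble with one value per subject x condition.
#' @param value Name of the value column (string).
#' @param condition Name of the condition column.
#' @param subject Name of the pairing (subject) column.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble with one row per comparison: the two condition levels,
#'   `statistic`, `p_value`, `p_adjusted` (Bonferroni), `significant`.
#' @export
compare_conditions <- function(data, value, condition, subject, alpha = 0.05) {
  wide <- tidyr::pivot_wider(
    dplyr::select(data, dplyr::all_of(c(subject, condition, value))),
    names_from = dplyr::all_of(condition), values_from = dplyr::all_of(value)
  )
  levels <- setdiff(names(wide), subject)
  if (length(levels) < 2L) stop("need at least two conditions", call. = FALSE)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(p) {
    x <- wide[[p[1]]]
    y <- wide[[p[2]]]
    if (anyNA(x) || anyNA(y)) stop("unpaired observations (missing cells)", call. = FALSE)
    if (length(x) < 5L) stop("need at least 5 paired subjects", call. = FALSE)
    res <- wilcoxon_signed_rank(x, y)
    dplyr::mutate(res, condition_a = p[1], condition_b = p[2], .before = 1L)
  })
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out$significant <- out$p_adjusted < alpha
  out
}
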