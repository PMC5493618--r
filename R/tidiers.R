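#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted regression decoder
#'
#' @param x An `lr_model`.
#' @param ... Unused.
#' @return One row per coefficient: `term` (channel or bias), `dof` (x/y)
#'   and `estimate`.
#' @export
tidy.lr_model <- function(x, ...) {
  W <- x$W
  tibble::tibble(
    term = rep(rownames(W), times = ncol(W)),
    dof = rep(colnames(W), each = nrow(W)),
    estimate = as.numeric(W)
  )
}

#' @rdname tidy.lr_model
#' @export
glance.lr_model <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$W) - x$use_bias,
    use_bias = x$use_bias,
    n_frames = x$n_frames
  )
}

#' Tidy a fitted LDA decoder
#'
#' @param x An `lda_model`.
#' @param ... Unused.
#' @return One row per class x channel: `class`, `channel`, `mean` plus the
#'   class `scaling` factor (NA before calibration).
#' @export
tidy.lda_model <- function(x, ...) {
  mu <- x$mu
  s <- if (is.null(x$scaling)) rep(NA_real_, nrow(mu)) else unname(x$scaling)
  tibble::tibble(
    class = rep(x$class_ids, times = ncol(mu)),
    channel = rep(colnames(mu) %||% paste0("ch", seq_len(ncol(mu))), each = nrow(mu)),
    mean = as.numeric(mu),
    scaling = rep(s, times = ncol(mu))
  )
}

#' @rdname tidy.lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$class_ids),
    n_features = ncol(x$mu),
    n_frames = x$n_frames,
    logdet_sigma = determinant(x$sigma, logarithm = TRUE)$modulus[1],
    scaled = !is.null(x$scaling)
  )
}

#' Tidy an offline experiment
#'
#' @param x An `offline_experiment`.
#' @param ... Unused.
#' @return The per-trial summary tibble (`tidy`) or a one-row overview
#'   (`glance`).
#' @export
tidy.offline_experiment <- function(x, ...) x$summary

#' @rdname tidy.offline_experiment
#' @export
glance.offline_experiment <- function(x, ...) {
  agg <- subject_summary(x) |>
    dplyr::group_by(.data$decoder, .data$profile) |>
    dplyr::summarise(
      time_below = mean(.data$time_below),
      step_residual = mean(.data$step_residual),
      .groups = "drop"
    )
  tidyr::pivot_wider(agg,
    names_from = dplyr::all_of(c("decoder", "profile")),
    values_from = dplyr::all_of(c("time_below", "step_residual"))
  ) |>
    dplyr::mutate(n_subjects = x$config$n_subjects, n_trials = nrow(x$summary))
}
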