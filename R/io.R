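#' Read and write EMG recordings as delimited text
#'
#' Recordings are stored as a CSV (one column per channel, one row per
#' sample) plus a JSON sidecar (`<path>.json`) holding the sampling rate,
#' channel count and any metadata, including per-frame labels when a
#' protocol trajectory is attached.
#'
#' @param rec An [emg_recording()].
#' @param path Path of the CSV file; the sidecar is written next to it.
#' @return `write_emg_recording()` returns `path` invisibly;
#'   `read_emg_recording()` returns an `emg_recording`.
#' @export
write_emg_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  readr::write_csv(tibble::as_tibble(as.data.frame(rec$signals)), path)
  meta <- rec$meta
  if (!is.null(meta$protocol)) {
    meta$labels <- meta$protocol$label
    meta$protocol <- NULL
  }
  side <- c(list(fs = rec$fs, n_channels = n_channels(rec)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_emg_recording
#' @export
read_emg_recording <- function(path) {
  sig <- as.matrix(readr::read_csv(path, show_col_types = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fs <- side$fs
  side$fs <- NULL
  side$n_channels <- NULL
  emg_recording(sig, fs = fs, meta = side)
}

#' Serialize a fitted decoder to JSON
#'
#' Both decoder types round-trip through JSON (matrices as nested arrays) so
#' experiments are reproducible from text artefacts alone.
#'
#' @param model An `lr_model` or `lda_model`.
#' @param path JSON file path.
#' @return `write_decoder_json()` returns `path` invisibly;
#'   `read_decoder_json()` the reconstructed model.
#' @export
write_decoder_json <- function(model, path) {
  if (inherits(model, "lr_model")) {
    obj <- list(type = "lr", W = model$W, use_bias = model$use_bias,
                channels = model$channels, n_frames = model$n_frames)
  } else if (inherits(model, "lda_model")) {
    obj <- list(type = "lda", class_ids = model$class_ids, mu = model$mu,
                sigma = model$sigma, priors = unname(model$priors),
                scaling = if (is.null(model$scaling)) NULL else unname(model$scaling),
                channels = model$channels, n_frames = model$n_frames)
  } else {
    stop("unsupported model type", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder_json
#' @export
read_decoder_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "lr") {
    W <- as.matrix(obj$W)
    dimnames(W) <- list(c(obj$channels, if (obj$use_bias) "bias"), c("x", "y"))
    return(structure(
      list(W = W, use_bias = obj$use_bias, channels = obj$channels,
           n_frames = obj$n_frames),
      class = "lr_model"
    ))
  }
  classes <- as.integer(obj$class_ids)
  mu <- as.matrix(obj$mu)
  dimnames(mu) <- list(classes, obj$channels)
  model <- structure(
    list(class_ids = classes, mu = mu, sigma = as.matrix(obj$sigma),
         priors = stats::setNames(obj$priors, classes),
         directions = class_direction(classes),
         scaling = if (is.null(obj$scaling)) NULL else stats::setNames(obj$scaling, classes),
         channels = obj$channels, n_frames = obj$n_frames),
    class = "lda_model"
  )
  model$discriminant <- lda_discriminant_terms(model)
  model
}

#' Write feature frames to CSV
#'
#' @param features An `emg_features` tibble.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Read an experiment configuration from JSON
#'
#' Accepts a JSON object whose fields match [experiment_config()] arguments;
#' missing fields take the defaults.
#'
#' @param path JSON file path.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(experiment_config, obj)
}

#' Write experiment results as tidy text artefacts
#'
#' Writes the per-trial summary as a tidy CSV, and the statistical tests and
#' per-subject aggregates as a JSON summary, into `dir`.
#'
#' @param experiment An `offline_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(experiment, dir) {
  stopifnot(inherits(experiment, "offline_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(experiment$summary, file.path(dir, "trials.csv"))
  readr::write_csv(experiment$error_curves, file.path(dir, "error_curves.csv"))
  jsonlite::write_json(
    list(
      subject_summary = subject_summary(experiment),
      tests = experiment$tests,
      amax = experiment$amax,
      seed = experiment$config$seed
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}
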