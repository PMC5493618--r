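#' Fit the linear-regression decoder
#'
#' Ordinary least squares from RMS features to the 2-D intent: the decoder is
#' the linear map `y_hat = W' phi` whose coefficients minimise the mean
#' squared error over the calibration frames. Because the resting RMS floor
#' of real electrodes is non-zero, the feature vector is augmented with a
#' constant 1 by default (`use_bias = TRUE`); set `use_bias = FALSE` for the
#' literal bias-free map.
#'
#' @param features An `emg_features` tibble (or frames x channels matrix).
#' @param targets Matching intent: a trajectory tibble with `x`, `y` sampled
#'   at the feature times (see [trajectory_at()]), or an n x 2 matrix.
#' @param use_bias Augment features with a constant-1 column (default TRUE).
#' @param method `"qr"` (error on rank deficiency) or `"pinv"` (minimum-norm
#'   pseudo-inverse solution).
#'
#' @return An object of class `lr_model` with the coefficient matrix `W`
#'   ((channels + bias) x 2).
#' @export
fit_lr <- function(features, targets, use_bias = TRUE, method = c("qr", "pinv")) {
  method <- match.arg(method)
  phi <- if (is.matrix(features)) features else feature_matrix(features)
  yy <- if (is.matrix(targets)) targets else cbind(targets$x, targets$y)
  if (nrow(phi) != nrow(yy)) stop("features and targets must align frame-by-frame", call. = FALSE)
  if (nrow(unique(phi)) < 2L) stop("need at least 2 distinct feature vectors", call. = FALSE)
  X <- if (use_bias) cbind(phi, bias = 1) else phi
  if (method == "qr") {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      stop("rank-deficient feature matrix; refit with method = \"pinv\" for the minimum-norm solution",
           call. = FALSE)
    }
    W <- qr.coef(qx, yy)
  } else {
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    W <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% yy) / sv$d[pos])
  }
  dimnames(W) <- list(colnames(X), c("x", "y"))
  structure(
    list(W = W, use_bias = use_bias, channels = colnames(phi),
         n_frames = nrow(phi)),
    class = "lr_model"
  )
}

#' Predict intent from features with a fitted regression decoder
#'
#' @param model An [fit_lr()] model.
#' @param phi A feature vector (length = channels) or frames x channels
#'   matrix.
#' @return An n x 2 matrix of `(x, y)` estimates (no clipping is applied).
#' @export
predict_lr <- function(model, phi) {
  stopifnot(inherits(model, "lr_model"))
  phi <- if (is.matrix(phi)) phi else matrix(phi, nrow = 1)
  d <- nrow(model$W) - model$use_bias
  if (ncol(phi) != d) {
    stop(sprintf("feature dimension %d does not match model (%d)", ncol(phi), d),
         call. = FALSE)
  }
  X <- if (model$use_bias) cbind(phi, 1) else phi
  out <- X %*% model$W
  colnames(out) <- c("x", "y")
  out
}

#' Fit the multiclass LDA decoder
#'
#' Linear discriminant analysis with a covariance matrix pooled over all
#' classes and equal priors 1/C. The pooled covariance is the
#' maximum-likelihood estimate (within-class scatter divided by the total
#' number of frames), which is invariant to duplicating the training set.
#' Class-specific proportional scaling factors and the class direction map
#' can be attached afterwards (see [fit_proportional_scaling()]).
#'
#' @param features An `emg_features` tibble or frames x channels matrix.
#' @param labels Integer class label per frame (0 = rest, 1-8 = motions).
#' @param ridge Ridge added to the pooled covariance diagonal if it is
#'   numerically singular, as a fraction of `trace/dim` (default 1e-6); a
#'   warning is emitted when it kicks in.
#'
#' @return An object of class `lda_model` with per-class means `mu`, pooled
#'   covariance `sigma`, equal `priors`, class `directions`, and (after
#'   scaling calibration) per-class `scaling`.
#' @export
fit_lda <- function(features, labels, ridge = 1e-6) {
  phi <- if (is.matrix(features)) features else feature_matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(phi) == length(labels))
  classes <- sort(unique(labels))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2)) stop("every class needs at least 2 frames", call. = FALSE)
  d <- ncol(phi)
  mu <- t(vapply(classes, function(c) colMeans(phi[labels == c, , drop = FALSE]),
                 numeric(d)))
  rownames(mu) <- classes
  scatter <- matrix(0, d, d)
  for (c in classes) {
    xc <- sweep(phi[labels == c, , drop = FALSE], 2, mu[as.character(c), ])
    scatter <- scatter + crossprod(xc)
  }
  sigma <- scatter / nrow(phi)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    warning("pooled covariance is numerically singular; adding a small ridge")
    sigma <- sigma + diag(ridge * sum(diag(sigma)) / d, d)
  }
  C <- length(classes)
  model <- structure(
    list(class_ids = classes, mu = mu, sigma = sigma,
         priors = stats::setNames(rep(1 / C, C), classes),
         directions = class_direction(classes),
         scaling = NULL, channels = colnames(phi), n_frames = nrow(phi)),
    class = "lda_model"
  )
  model$discriminant <- lda_discriminant_terms(model)
  model
}

# Precompute Sigma^-1 mu_c and the quadratic offsets of the discriminant
# delta_c(phi) = phi' Sigma^-1 mu_c - 0.5 mu_c' Sigma^-1 mu_c + log pi_c.
lda_discriminant_terms <- function(model) {
  A <- solve(model$sigma, t(model$mu)) # d x C
  off <- -0.5 * colSums(t(model$mu) * A) + log(model$priors)
  list(A = A, offset = off)
}

#' Classify feature frames with a fitted LDA decoder
#'
#' Returns, per frame, the class with the largest linear discriminant
#' `delta_c(phi) = phi' Sigma^-1 mu_c - mu_c' Sigma^-1 mu_c / 2 + log pi_c`
#' (equal-prior Gaussian posterior argmax under the shared covariance).
#'
#' @param model An [fit_lda()] model.
#' @param phi A feature vector or frames x channels matrix; must be finite.
#' @return Integer class id per frame.
#' @export
classify_lda <- function(model, phi) {
  stopifnot(inherits(model, "lda_model"))
  phi <- if (is.matrix(phi)) phi else matrix(phi, nrow = 1)
  if (!all(is.finite(phi))) stop("non-finite feature values", call. = FALSE)
  delta <- phi %*% model$discriminant$A
  delta <- sweep(delta, 2, model$discriminant$offset, `+`)
  model$class_ids[max.col(delta, ties.method = "first")]
}

#' Majority vote over recent classifier decisions
#'
#' Returns the most frequent class in the buffer of (up to) the last 5
#' decisions. Ties are resolved to `prev` (the previous voted output) when it
#' is among the tied classes, otherwise to the most recently observed tied
#' class.
#'
#' @param buffer Integer vector of recent class decisions, oldest first.
#' @param prev Previous voted output class, or `NULL`.
#' @return The winning class id.
#' @export
majority_vote <- function(buffer, prev = NULL) {
  if (length(buffer) == 0L) stop("vote buffer is empty", call. = FALSE)
  counts <- table(buffer)
  tied <- as.integer(names(counts)[counts == max(counts)])
  if (length(tied) == 1L) return(tied)
  if (!is.null(prev) && prev %in% tied) return(as.integer(prev))
  # most recently observed among the tied classes
  buffer[max(which(buffer %in% tied))]
}

#' Calibrate class-specific proportional scaling
#'
#' The LDA chain estimates contraction strength as the average RMS across all
#' channels. Because that average differs between classes, a per-class factor
#' `s_c` maps it to intent magnitude: `s_c` is chosen so that the mean
#' channel-average RMS over the static (hold) calibration frames of class c
#' maps to the cued contraction level. The rest class gets `s = 0`.
#'
#' @param features Calibration `emg_features` (or matrix).
#' @param labels Class label per frame.
#' @param static_mask Logical per frame, `TRUE` on static hold frames.
#' @param cue_level Cued contraction level of the calibration holds (default
#'   0.8 x MVC).
#' @return Named numeric vector of scaling factors, one per class present.
#' @export
fit_proportional_scaling <- function(features, labels, static_mask, cue_level = 0.8) {
  phi <- if (is.matrix(features)) features else feature_matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(phi) == length(labels), length(static_mask) == length(labels))
  classes <- sort(unique(labels))
  avg <- rowMeans(phi)
  s <- vapply(classes, function(c) {
    if (c == 0L) return(0)
    sel <- static_mask & labels == c
    if (!any(sel)) {
      stop(sprintf("class %d has no static calibration frames", c), call. = FALSE)
    }
    cue_level / mean(avg[sel])
  }, numeric(1))
  stats::setNames(s, classes)
}

#' Proportional intensity of one feature frame
#'
#' @param phi Feature vector (one frame).
#' @param cls Class id decided for the frame.
#' @param model An [fit_lda()] model carrying `scaling` factors.
#' @return Non-negative scalar intensity (`s_cls` x channel-average RMS).
#' @export
proportional_intensity <- function(phi, cls, model) {
  s <- model$scaling
  if (is.null(s)) stop("model has no proportional scaling; see fit_proportional_scaling()", call. = FALSE)
  unname(s[as.character(cls)] * mean(phi))
}

#' One exponential-moving-average update
#'
#' `out = (1 - alpha) * state + alpha * x`, applied componentwise. With the
#' default `alpha = 1/25` and the 40 ms frame rate the step response reaches
#' about 64% in 1 s without overshoot.
#'
#' @param state Previous output (scalar or vector).
#' @param x New input value(s).
#' @param alpha Filter constant in `(0, 1]` (default 1/25).
#' @return Updated output, same shape as `state`.
#' @export
ema_step <- function(state, x, alpha = 1 / 25) {
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1]", call. = FALSE)
  (1 - alpha) * state + alpha * x
}

# Vectorised causal EMA along a vector (state starts at `init`).
ema_filter <- function(x, alpha = 1 / 25, init = 0) {
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = init))
}

#' Decode a feature stream into a cursor trajectory
#'
#' Runs the full causal decoding chain frame by frame, one cursor position
#' per 40 ms feature frame.
#'
#' * Regression (`lr_model`): `y_hat = W' phi` followed by the EMA smoother
#'   on both components. Output spans the whole plane.
#' * Classification (`lda_model`): LDA decision, majority vote over the last
#'   5 decisions, proportional intensity of the voted class, EMA smoothing of
#'   the scalar intensity, and position = smoothed intensity x voted-class
#'   direction. Output is confined to the 8 class axes and the origin.
#'
#' @param model An `lr_model` or `lda_model` (the latter with scaling
#'   calibrated).
#' @param features An `emg_features` tibble or frames x channels matrix.
#' @param alpha EMA filter constant (default 1/25).
#' @param clip Clip cursor positions to the unit (MVC) circle (default
#'   FALSE).
#' @return A tibble with `time` (if available), `x`, `y` and, for LDA,
#'   `class` (the voted class per frame).
#' @export
decode_stream <- function(model, features, alpha = 1 / 25, clip = FALSE) {
  UseMethod("decode_stream")
}

decode_times <- function(features, n) {
  if (!is.matrix(features) && "time" %in% names(features)) features$time
  else seq_len(n) * 0.04
}

clip_unit <- function(xy) {
  nrm <- sqrt(rowSums(xy^2))
  over <- nrm > 1
  xy[over, ] <- xy[over, ] / nrm[over]
  xy
}

#' @export
decode_stream.lr_model <- function(model, features, alpha = 1 / 25, clip = FALSE) {
  phi <- if (is.matrix(features)) features else feature_matrix(features)
  yhat <- predict_lr(model, phi)
  out <- cbind(x = ema_filter(yhat[, 1], alpha), y = ema_filter(yhat[, 2], alpha))
  if (clip) out <- clip_unit(out)
  tibble::tibble(time = decode_times(features, nrow(out)),
                 x = out[, "x"], y = out[, "y"])
}

#' @export
decode_stream.lda_model <- function(model, features, alpha = 1 / 25, clip = FALSE) {
  phi <- if (is.matrix(features)) features else feature_matrix(features)
  raw_cls <- classify_lda(model, phi)
  n <- length(raw_cls)
  voted <- integer(n)
  prev <- NULL
  for (i in seq_len(n)) {
    buf <- raw_cls[max(1L, i - 4L):i]
    voted[i] <- majority_vote(buf, prev)
    prev <- voted[i]
  }
  s <- model$scaling
  if (is.null(s)) stop("LDA model has no proportional scaling; see fit_proportional_scaling()", call. = FALSE)
  intensity <- unname(s[as.character(voted)]) * rowMeans(phi)
  smoothed <- ema_filter(intensity, alpha)
  dirs <- class_direction(voted)
  out <- dirs * smoothed
  if (clip) out <- clip_unit(out)
  tibble::tibble(time = decode_times(features, n),
                 x = out[, "x"], y = out[, "y"], class = voted)
}

#' Single-frame decoder stepping (for closed-loop use)
#'
#' `decoder_state_init()` creates the per-stream state (vote buffer and EMA
#' state); `decode_step()` consumes one feature frame and returns the cursor
#' position plus the updated state. Streaming a feature matrix frame-by-frame
#' reproduces [decode_stream()] exactly.
#'
#' @param model An `lr_model` or `lda_model`.
#' @param alpha EMA filter constant.
#' @return `decoder_state_init()`: an opaque state list.
#' @export
decoder_state_init <- function(model, alpha = 1 / 25) {
  list(model = model, alpha = alpha, vote_buffer = integer(0),
       ema = c(0, 0), ema_intensity = 0, prev_class = NULL)
}

#' @rdname decoder_state_init
#' @param state State from `decoder_state_init()` or the previous step.
#' @param phi One feature frame (numeric vector).
#' @return `decode_step()`: list with `position` (length-2), `class` (LDA,
#'   else `NA`) and `state`.
#' @export
decode_step <- function(state, phi) {
  model <- state$model
  if (inherits(model, "lr_model")) {
    yhat <- drop(predict_lr(model, phi))
    state$ema <- ema_step(state$ema, yhat, state$alpha)
    return(list(position = unname(state$ema), class = NA_integer_, state = state))
  }
  cls <- classify_lda(model, phi)
  state$vote_buffer <- utils::tail(c(state$vote_buffer, cls), 5L)
  voted <- majority_vote(state$vote_buffer, state$prev_class)
  state$prev_class <- voted
  intensity <- proportional_intensity(phi, voted, model)
  state$ema_intensity <- ema_step(state$ema_intensity, intensity, state$alpha)
  pos <- drop(class_direction(voted)) * state$ema_intensity
  list(position = unname(pos), class = voted, state = state)
}
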