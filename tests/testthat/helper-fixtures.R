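# Shared fixtures, built once per test run. Everything is generated in code;
# the memo environment keeps the expensive calibration pipeline out of the
# per-test path.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

default_synergy <- function() synergy_model()

# One filtered calibration run with aligned intent/labels/features.
cal_fixture <- function() {
  memo("cal", {
    traj <- make_calibration_protocol(1)
    syn <- default_synergy()
    rec <- synthesize_emg(traj, syn, seed = 101)
    spec <- filter_spec()
    feats <- rms_features(filter_signal(rec, spec))
    at <- trajectory_at(traj, feats$time)
    list(traj = traj, syn = syn, rec = rec, spec = spec, feats = feats, at = at)
  })
}

# Decoders fitted on the calibration fixture.
models_fixture <- function() {
  memo("models", {
    cal <- cal_fixture()
    phi <- feature_matrix(cal$feats)
    lr <- fit_lr(phi, cbind(cal$at$x, cal$at$y))
    lda <- fit_lda(phi, cal$at$label)
    lda$scaling <- fit_proportional_scaling(phi, cal$at$label,
                                            cal$at$phase == "hold")
    list(lr = lr, lda = lda)
  })
}

# A second, held-out calibration run from the same synergy.
holdout_fixture <- function() {
  memo("holdout", {
    cal <- cal_fixture()
    traj <- make_calibration_protocol(1)
    rec <- synthesize_emg(traj, cal$syn, seed = 202)
    feats <- rms_features(filter_signal(rec, cal$spec))
    at <- trajectory_at(traj, feats$time)
    list(traj = traj, feats = feats, at = at)
  })
}

# Brute-force Gaussian-posterior oracle sharing the model's parameters:
# full log N(phi; mu_c, Sigma) + log prior, no linear-discriminant shortcut.
oracle_gaussian_argmax <- function(model, phi) {
  Sinv <- solve(model$sigma)
  logdet <- determinant(model$sigma, logarithm = TRUE)$modulus[1]
  apply(phi, 1, function(p) {
    lp <- vapply(seq_along(model$class_ids), function(i) {
      d <- p - model$mu[i, ]
      -0.5 * (d %*% Sinv %*% d) - 0.5 * logdet + log(model$priors[i])
    }, numeric(1))
    model$class_ids[which.max(lp)]
  })
}

# Minimum-norm least-squares oracle via the SVD pseudo-inverse, built from
# first principles (no qr/lm path shared with fit_lr).
oracle_pinv_fit <- function(X, Y) {
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d)
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% Y))
}

# Exact signed-rank null by enumerating all sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}
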