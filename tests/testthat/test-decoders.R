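test_that("fit_lr recovers an exact linear model and matches the pinv oracle", {
  set.seed(41)
  phi <- matrix(abs(rnorm(200 * 8, 0.4, 0.15)), 200, 8,
                dimnames = list(NULL, paste0("ch", 1:8)))
  W0 <- matrix(rnorm(16), 8, 2)
  Y <- phi %*% W0
  fit <- fit_lr(phi, Y, use_bias = FALSE)
  expect_equal(unname(fit$W), W0, tolerance = 1e-8)
  # with a bias column on bias-free data the bias comes back ~0
  fitb <- fit_lr(phi, Y, use_bias = TRUE)
  expect_equal(unname(fitb$W["bias", ]), c(0, 0), tolerance = 1e-8)
  # 10-frame toy set against the independent SVD pseudo-inverse oracle
  phi10 <- matrix(rexp(10 * 3), 10, 3)
  y10 <- matrix(rnorm(20), 10, 2)
  fit10 <- fit_lr(phi10, y10, use_bias = FALSE)
  expect_equal(unname(fit10$W), oracle_pinv_fit(phi10, y10), tolerance = 1e-8)
  # constant-zero targets give a zero map
  fit0 <- fit_lr(phi, matrix(0, 200, 2))
  expect_true(all(abs(fit0$W) < 1e-10))
})

test_that("fit_lr flags rank deficiency and offers the minimum-norm fallback", {
  set.seed(42)
  phi <- matrix(rnorm(30), 10, 3)
  phi <- cbind(phi, phi[, 1] + phi[, 2]) # collinear channel
  y <- matrix(rnorm(20), 10, 2)
  expect_error(fit_lr(phi, y, use_bias = FALSE), "pinv")
  fitp <- fit_lr(phi, y, use_bias = FALSE, method = "pinv")
  expect_equal(unname(fitp$W), oracle_pinv_fit(phi, y), tolerance = 1e-8)
})

test_that("predict_lr is the stated linear map", {
  W <- matrix(c(1, 2, 3, -1, 0.5, 0), 3, 2)
  model <- structure(list(W = W, use_bias = FALSE, channels = paste0("ch", 1:3)),
                     class = "lr_model")
  expect_equal(drop(predict_lr(model, c(0, 0, 0))), c(x = 0, y = 0))
  # hand-computed product on a toy feature vector
  phi <- c(2, 1, -1)
  expect_equal(drop(predict_lr(model, phi)),
               c(x = 1 * 2 + 2 * 1 + 3 * -1, y = -1 * 2 + 0.5 * 1 + 0 * -1),
               ignore_attr = TRUE)
  # additivity without bias
  p1 <- predict_lr(model, c(1, 0, 2)); p2 <- predict_lr(model, c(0.5, -1, 0))
  expect_equal(predict_lr(model, c(1.5, -1, 2)), p1 + p2, tolerance = 1e-12)
  expect_error(predict_lr(model, c(1, 2)), "dimension")
})

test_that("fit_lda pools covariance per the frame-weighted oracle", {
  set.seed(43)
  n <- c(30, 50, 20)
  X <- rbind(
    matrix(rnorm(n[1] * 4, 0), n[1], 4),
    matrix(rnorm(n[2] * 4, 2), n[2], 4),
    matrix(rnorm(n[3] * 4, -1), n[3], 4)
  )
  lab <- rep(0:2, n)
  fit <- fit_lda(X, lab)
  # class means
  for (c in 0:2) {
    expect_equal(fit$mu[as.character(c), ], colMeans(X[lab == c, ]),
                 ignore_attr = TRUE)
  }
  # brute-force oracle: frame-weighted average of per-class ML covariances
  S <- matrix(0, 4, 4)
  for (c in 0:2) {
    Xc <- X[lab == c, ]
    Cc <- crossprod(sweep(Xc, 2, colMeans(Xc))) / nrow(Xc)
    S <- S + nrow(Xc) / nrow(X) * Cc
  }
  expect_equal(fit$sigma, S, tolerance = 1e-12)
  expect_lt(max(abs(fit$sigma - t(fit$sigma))), 1e-10)
  expect_equal(unname(fit$priors), rep(1 / 3, 3))
  # duplicating the whole training set changes nothing
  fit2 <- fit_lda(rbind(X, X), c(lab, lab))
  expect_equal(fit2$mu, fit$mu)
  expect_equal(fit2$sigma, fit$sigma, tolerance = 1e-12)
})

test_that("classify_lda matches the brute-force Gaussian-posterior oracle", {
  models <- models_fixture()
  lda <- models$lda
  # own means classify to their class
  expect_equal(classify_lda(lda, lda$mu), lda$class_ids)
  # equal priors: dropping the log-prior never changes the argmax
  no_prior <- lda
  no_prior$priors[] <- 1 # log term becomes 0
  no_prior$discriminant <- myodecode:::lda_discriminant_terms(no_prior)
  set.seed(44)
  phi <- matrix(abs(rnorm(500 * 8, 0.3, 0.2)), 500, 8)
  expect_equal(classify_lda(lda, phi), classify_lda(no_prior, phi))
  # 1000 random feature vectors against the full Gaussian log-posterior
  phi2 <- matrix(abs(rnorm(1000 * 8, 0.3, 0.25)), 1000, 8)
  expect_equal(classify_lda(lda, phi2), unname(oracle_gaussian_argmax(lda, phi2)))
})

test_that("classify_lda agrees with MASS::lda on shared training data", {
  skip_if_not_installed("MASS")
  cal <- cal_fixture()
  phi <- feature_matrix(cal$feats)
  ours <- fit_lda(phi, cal$at$label)
  ref <- MASS::lda(phi, grouping = factor(cal$at$label),
                   prior = rep(1 / 9, 9))
  pred_ref <- as.integer(as.character(predict(ref, phi)$class))
  pred_ours <- classify_lda(ours, phi)
  # same model family; covariance conventions differ only by a scalar factor,
  # so decisions agree on essentially all frames
  expect_gt(mean(pred_ref == pred_ours), 0.999)
})

test_that("majority vote picks the mode with the documented tie rule", {
  expect_equal(majority_vote(c(1, 1, 1, 2, 2)), 1L)
  expect_equal(majority_vote(c(3, 3, 3, 3, 3)), 3L)
  # tie between 1 and 2: previous output wins when tied
  expect_equal(majority_vote(c(1, 1, 2, 2, 3), prev = 2L), 2L)
  # previous output not among the tied: most recent tied class wins
  expect_equal(majority_vote(c(1, 1, 2, 2, 3), prev = 3L), 2L)
  expect_equal(majority_vote(c(2, 2, 1, 1, 3), prev = NULL), 1L)
  expect_equal(majority_vote(5L), 5L)
  expect_error(majority_vote(integer(0)), "empty")
})

test_that("proportional scaling maps static calibration RMS to the cue level", {
  # class with constant channel-average RMS 0.4, cued at 0.8 -> s = 2
  phi <- matrix(0.4, 20, 8)
  lab <- rep(c(1L, 0L), each = 10)
  phi[lab == 0L, ] <- 0.02
  static <- rep(TRUE, 20)
  s <- fit_proportional_scaling(phi, lab, static, cue_level = 0.8)
  expect_equal(unname(s[c("0", "1")]), c(0, 2))
  # doubling the training amplitudes halves the factors
  s2 <- fit_proportional_scaling(2 * phi, lab, static, cue_level = 0.8)
  expect_equal(unname(s2["1"]), 1)
  expect_error(fit_proportional_scaling(phi, lab, !static), "static")
  # intensity: s_c * mean(phi), rest always 0
  model <- list(scaling = s)
  expect_equal(proportional_intensity(rep(0.4, 8), 1L, model), 0.8)
  expect_equal(proportional_intensity(rep(0.4, 8), 0L, model), 0)
  expect_equal(proportional_intensity(2 * rep(0.4, 8), 1L, model), 1.6)
})

test_that("EMA smoother follows its closed-form step response", {
  expect_equal(ema_step(0.5, 0.5), 0.5)                 # fixed point
  expect_equal(ema_step(0.2, 1, alpha = 1), 1)          # identity limit
  # step 0 -> 1: after n updates output is 1 - (24/25)^n
  out <- 0
  for (n in 1:25) out <- ema_step(out, 1)
  expect_equal(out, 1 - (24 / 25)^25, tolerance = 1e-12)
  expect_equal(1 - (24 / 25)^25, 0.6396, tolerance = 1e-4)
  expect_error(ema_step(0, 1, alpha = 0), "alpha")
})

test_that("decode_stream LDA output is confined to the class axes", {
  models <- models_fixture()
  cal <- cal_fixture()
  cursor <- decode_stream(models$lda, cal$feats)
  ang <- atan2(cursor$y, cursor$x) %% (2 * pi)
  on_axis <- abs(ang - round(ang / (pi / 4)) * (pi / 4)) < 1e-9
  at_origin <- sqrt(cursor$x^2 + cursor$y^2) < 1e-12
  expect_true(all(on_axis | at_origin))
  # rest-only stream pins the cursor at the origin
  rest_phi <- matrix(rep(models$lda$mu["0", ], each = 30), 30, 8)
  rest_cursor <- decode_stream(models$lda, rest_phi)
  expect_true(all(rest_cursor$x == 0 & rest_cursor$y == 0))
})

test_that("decode_stream is causal and matches frame-wise stepping", {
  models <- models_fixture()
  cal <- cal_fixture()
  feats <- cal$feats[1:100, ]
  for (model in models) {
    full <- decode_stream(model, feats)
    half <- decode_stream(model, feats[1:50, ])
    expect_equal(half[, c("x", "y")], full[1:50, c("x", "y")], tolerance = 1e-12)
    # frame-wise decode_step path agrees with the vectorised stream
    state <- decoder_state_init(model)
    phi <- feature_matrix(feats)
    pos <- matrix(NA_real_, 100, 2)
    for (i in 1:100) {
      st <- decode_step(state, phi[i, ])
      pos[i, ] <- st$position
      state <- st$state
    }
    expect_equal(pos, as.matrix(full[, c("x", "y")]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("regression decoder reproduces a held constant intent after the EMA transient", {
  models <- models_fixture()
  cal <- cal_fixture()
  traj <- make_reach_protocol(2, level = 0.5, duration = 10)
  rec <- synthesize_emg(traj, cal$syn, seed = 77)
  feats <- rms_features(filter_signal(rec, cal$spec))
  cursor <- decode_stream(models$lr, feats)
  target <- 0.5 * drop(class_direction(2L))
  late <- cursor[cursor$time > 5, ]
  rmse <- sqrt(mean((late$x - target[1])^2 + (late$y - target[2])^2))
  expect_lt(rmse, 0.05)
})
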