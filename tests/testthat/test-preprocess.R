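sine_recording <- function(freq, fs = 2000, dur = 2, amp = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  emg_recording(matrix(amp * sin(2 * pi * freq * t), ncol = 1), fs = fs)
}

test_that("band-pass kills DC and the comb notches the powerline", {
  spec <- filter_spec()
  # constant input decays to zero after the transient
  dc <- emg_recording(matrix(1, 4000, 1), fs = 2000)
  y <- filter_signal(dc, spec)$signals
  expect_lt(max(abs(y[2001:4000])), 1e-3)
  # steady-state gain from the designed frequency response (oracle), checked
  # against the measured sinusoid amplitudes
  gain_at <- function(f) {
    h <- 1 + 0i
    for (st in spec$stages) {
      z <- exp(-1i * 2 * pi * f / spec$fs * (seq_along(st$b) - 1))
      h <- h * sum(st$b * z) / sum(st$a * z)
    }
    Mod(h)
  }
  # 225 Hz: in-band (and not a powerline harmonic), within +/-1 dB of unity
  expect_lt(abs(20 * log10(gain_at(225))), 1)
  y225 <- filter_signal(sine_recording(225), spec)$signals[2001:4000]
  expect_equal(max(abs(y225)), gain_at(225), tolerance = 1e-2)
  # 50 Hz: attenuated by >= 20 dB
  expect_lt(20 * log10(gain_at(50)), -20)
  y50 <- filter_signal(sine_recording(50), spec)$signals[2001:4000]
  expect_lt(max(abs(y50)), 10^(-20 / 20))
  # harmonics are notched too
  for (f in c(100, 150, 450)) expect_lt(20 * log10(gain_at(f)), -20)
})

test_that("filtering is linear and validates its inputs", {
  spec <- filter_spec()
  zero <- emg_recording(matrix(0, 1000, 2), fs = 2000)
  expect_true(all(filter_signal(zero, spec)$signals == 0))
  set.seed(1)
  rec <- emg_recording(matrix(rnorm(2000), ncol = 2), fs = 2000)
  y1 <- filter_signal(rec, spec)$signals
  rec3 <- emg_recording(3 * rec$signals, fs = 2000)
  expect_equal(filter_signal(rec3, spec)$signals, 3 * y1, tolerance = 1e-8)
  expect_error(filter_spec(band = c(30, 1200)), "Nyquist")
  expect_error(filter_spec(band = c(0, 500)), "pass band")
  expect_error(filter_signal(emg_recording(matrix(0, 10, 1), fs = 1000), spec),
               "sampling rates")
})

test_that("RMS features have the documented frame schedule and values", {
  # constant signal: every RMS entry equals |a|
  const <- emg_recording(matrix(-0.7, 2000, 2), fs = 2000)
  f <- rms_features(const)
  expect_true(all(abs(feature_matrix(f) - 0.7) < 1e-12))
  # unit sine, integer cycles per 160 ms window: RMS = 1/sqrt(2)
  f50 <- rms_features(sine_recording(50, dur = 1))
  expect_equal(unname(feature_matrix(f50)[, 1]),
               rep(1 / sqrt(2), nrow(f50)), tolerance = 1e-6)
  # 4 s at 2000 Hz -> floor((8000 - 320)/80) + 1 = 97 frames
  expect_equal(nrow(rms_features(emg_recording(matrix(0, 8000, 1), fs = 2000))), 97)
  # frames step by exactly 40 ms, stamped at window ends
  expect_equal(f50$time[1], 0.16)
  expect_equal(unique(round(diff(f50$time), 10)), 0.04)
  expect_error(rms_features(emg_recording(matrix(0, 100, 1), fs = 2000)),
               "shorter")
})

test_that("RMS features scale equivariantly with the input", {
  set.seed(2)
  sig <- matrix(rnorm(4000), ncol = 2)
  f1 <- feature_matrix(rms_features(emg_recording(sig, fs = 2000)))
  f2 <- feature_matrix(rms_features(emg_recording(-2.5 * sig, fs = 2000)))
  expect_equal(f2, 2.5 * f1, tolerance = 1e-12)
})

test_that("block-wise filtering with carried state reproduces batch filtering", {
  spec <- filter_spec()
  traj <- make_reach_protocol(2, level = 0.6, duration = 2)
  rec <- synthesize_emg(traj, default_synergy(), seed = 31)
  batch <- filter_signal(rec, spec)$signals
  state <- filter_state_init(spec, n_channels(rec))
  out <- matrix(NA_real_, nrow(batch), ncol(batch))
  block_n <- 80 # 40 ms blocks at 2 kHz
  for (start in seq(1, nrow(batch), by = block_n)) {
    idx <- start:min(start + block_n - 1, nrow(batch))
    res <- filter_signal_block(rec$signals[idx, , drop = FALSE], state)
    out[idx, ] <- res$block
    state <- res$state
  }
  expect_equal(out, batch, tolerance = 1e-9, ignore_attr = TRUE)
  # and the features computed from both paths agree
  fb <- feature_matrix(rms_features(emg_recording(out, fs = rec$fs)))
  ff <- feature_matrix(rms_features(emg_recording(batch, fs = rec$fs)))
  expect_equal(fb, ff, tolerance = 1e-9)
})
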