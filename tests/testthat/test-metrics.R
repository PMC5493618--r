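err_tbl <- function(error, dt = 0.04, t0 = 0.16) {
  tibble::tibble(time = t0 + (seq_along(error) - 1) * dt, error = error)
}

test_that("tracking error is the Euclidean distance to the target centre", {
  cur <- tibble::tibble(time = 1:4 * 0.04,
                        x = c(0, 0.3, 0.3, 0.5), y = c(0, 0, 0.4, 0.5))
  tgt <- c(0.5, 0)
  expect_equal(tracking_error(cur, tgt)$error,
               c(0.5, 0.2, sqrt(0.04 + 0.16), 0.5))
  # cursor glued to the centre -> zero error
  on_target <- tibble::tibble(time = 1:3, x = 0.5, y = 0)
  expect_true(all(tracking_error(on_target, tgt)$error == 0))
  # cursor at origin, target at radius 0.5 -> constant 0.5
  at_origin <- tibble::tibble(time = 1:3, x = 0, y = 0)
  expect_equal(tracking_error(at_origin, tgt)$error, rep(0.5, 3))
})

test_that("baseline error averages the 4-5 s window", {
  e <- err_tbl(rep(0.08, 500))
  expect_equal(baseline_error(e), 0.08)
  # the window holds exactly 25 frames at the 40 ms frame rate
  expect_equal(sum(e$time >= 4 & e$time < 5), 25)
  # linear error 0 -> 0.2 over 0-20 s: mean over 4-5 s = 0.2 * 4.48/20
  lin <- err_tbl(seq_along(numeric(497)) * 0) # placeholder times
  lin$error <- 0.2 * lin$time / 20
  expect_equal(baseline_error(lin), 0.2 * mean(lin$time[lin$time >= 4 & lin$time < 5]) / 20)
  expect_equal(baseline_error(lin), 0.045, tolerance = 0.01)
  expect_error(baseline_error(err_tbl(rep(1, 10))), "window")
})

test_that("time below threshold finds the first sustained crossing", {
  # 20 s series, residual never reaches 0.3 -> full 15 s post-onset
  e <- err_tbl(rep(0.1, 497))
  expect_equal(time_below_threshold(e, baseline = 0.1), 15)
  # residual above threshold from the first post-onset frame -> 0
  e2 <- err_tbl(ifelse(seq(0.16, by = 0.04, length.out = 497) >= 5, 0.5, 0.05))
  expect_equal(time_below_threshold(e2, baseline = 0.05), 0)
  # residual ramping 0 at 5 s to 0.9 at 20 s crosses 0.3 at t = 10 s
  tm <- seq(0.16, by = 0.04, length.out = 497)
  e3 <- err_tbl(0.2 + pmax(0, tm - 5) * 0.9 / 15)
  expect_equal(time_below_threshold(e3, baseline = 0.2), 5, tolerance = 0.05)
  # a single-frame spike does not count as a sustained crossing...
  spike <- rep(0.0, 497); spike[300] <- 1
  expect_equal(time_below_threshold(err_tbl(spike), baseline = 0), 15)
  # ...unless debouncing is disabled
  expect_equal(time_below_threshold(err_tbl(spike), baseline = 0, sustain = 0),
               err_tbl(spike)$time[300] - 5)
})

test_that("time below threshold is monotone in pointwise error increases", {
  set.seed(71)
  tm <- seq(0.16, by = 0.04, length.out = 374)
  for (i in 1:20) {
    e <- err_tbl(cumsum(runif(374, 0, 0.01)))
    bump <- runif(374, 0, 0.05) * (tm >= 5)
    e2 <- e; e2$error <- e$error + bump
    expect_lte(time_below_threshold(e2, 0), time_below_threshold(e, 0))
  }
})

test_that("step residual subtracts the baseline and ignores offsets", {
  e <- err_tbl(rep(0.1, 374))
  expect_equal(step_residual(e, baseline = 0.1), 0)
  e2 <- err_tbl(ifelse(seq(0.16, by = 0.04, length.out = 374) >= 14, 0.5, 0.1))
  expect_equal(step_residual(e2, baseline = 0.1), 0.4)
  # invariance to adding a constant to the whole series (baseline recomputed)
  e3 <- e2; e3$error <- e3$error + 0.25
  expect_equal(step_residual(e3, baseline = baseline_error(e3)),
               step_residual(e2, baseline = baseline_error(e2)))
  # step of +0.33 at 5 s with small jitter recovers 0.33
  set.seed(72)
  tm <- seq(0.16, by = 0.04, length.out = 374)
  e4 <- err_tbl(0.05 + 0.33 * (tm >= 5) + rnorm(374, 0, 0.01))
  expect_equal(step_residual(e4, baseline_error(e4)), 0.33, tolerance = 0.01)
})

test_that("reaching metrics count hits, overshoots and path efficiency", {
  frame <- function(x, y) tibble::tibble(time = seq_along(x) * 0.04, x = x, y = y)
  tgt <- c(0.5, 0)
  # straight path at constant speed, then immediate 1 s dwell
  approach <- seq(0, 0.5, by = 0.01) # enters disc at x = 0.35
  straight <- frame(c(approach, rep(0.5, 30)), rep(0, length(approach) + 30))
  m1 <- reaching_metrics(list(list(cursor = straight, target = tgt)))
  expect_equal(m1$completion_rate, 1)
  expect_equal(m1$overshoot_ratio, 0)
  expect_equal(m1$path_efficiency, 1)
  # a longer, indirect path has efficiency = straight / travelled < 1; the
  # y-detour closes well before the disc so the entry frame is unambiguous
  xs <- seq(0, 0.36, by = 0.004)
  ys <- ifelse(xs < 0.1, xs, ifelse(xs < 0.2, 0.2 - xs, 0))
  zig <- frame(c(xs, rep(0.36, 30)), c(ys, rep(0, 30)))
  m2 <- reaching_metrics(list(list(cursor = zig, target = tgt)))
  entry <- which(sqrt((xs - 0.5)^2 + ys^2) <= 0.15)[1] # x = 0.352, d = 0.148
  travelled <- sum(sqrt(diff(xs[1:entry])^2 + diff(ys[1:entry])^2))
  expect_equal(m2$path_efficiency, xs[entry] / travelled, tolerance = 1e-9)
  expect_lt(m2$path_efficiency, 1)
  # entering and leaving twice before the final dwell adds 2 overshoots
  inout <- c(seq(0, 0.4, by = 0.01), seq(0.4, 0.3, by = -0.01),
             seq(0.3, 0.4, by = 0.01), seq(0.4, 0.3, by = -0.01),
             seq(0.3, 0.5, by = 0.01), rep(0.5, 30))
  wobble <- frame(inout, rep(0, length(inout)))
  m3 <- reaching_metrics(list(list(cursor = wobble, target = tgt)))
  expect_equal(m3$overshoot_ratio, 2)
  expect_equal(m3$completion_rate, 1)
  # 8 trials with 6 successes -> completion rate 0.75
  never <- frame(rep(0, 300), rep(0, 300))
  trials <- c(rep(list(list(cursor = straight, target = tgt)), 6),
              rep(list(list(cursor = never, target = tgt)), 2))
  expect_equal(reaching_metrics(trials)$completion_rate, 0.75)
  # a hit after the 10 s timeout does not count
  late <- frame(c(rep(0, 260), rep(0.5, 30)), rep(0, 290))
  expect_equal(reaching_metrics(list(list(cursor = late, target = tgt)))$completion_rate, 0)
  expect_error(reaching_metrics(list()), "trials")
})

test_that("signed-rank test matches exhaustive sign-flip enumeration", {
  set.seed(73)
  for (i in 1:5) {
    # distinct magnitudes with random signs keep the null distribution exact
    d <- sample(c(-1, 1), 6, replace = TRUE) * sample(seq(0.1, 1.2, by = 0.1), 6)
    x <- rnorm(6); y <- x - d
    got <- wilcoxon_signed_rank(x, y)
    expect_equal(got$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
  # identical samples: no difference, p = 1 by convention
  z <- wilcoxon_signed_rank(rep(1, 6), rep(1, 6))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("compare_conditions applies the Bonferroni correction", {
  set.seed(74)
  dat <- tidyr::expand_grid(subject = 1:8, condition = c("a", "b", "c", "d"))
  dat$value <- rnorm(nrow(dat)) + (dat$condition == "b") * 2
  res <- compare_conditions(dat, "value", "condition", "subject")
  m <- nrow(res)
  expect_equal(m, choose(4, 2))
  expect_equal(res$p_adjusted, pmin(1, res$p_value * m))
  # with m = 4 comparisons the per-test threshold would be 0.0125
  expect_equal(0.05 / 4, 0.0125)
  expect_true(all(res$significant == (res$p_adjusted < 0.05)))
  expect_error(compare_conditions(dat[dat$subject < 5, ], "value", "condition", "subject"),
               "at least 5")
})
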