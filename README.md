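# myodecode

Noise-robustness analysis of simultaneous and proportional myoelectric
decoding, end to end in R.

Myoelectric interfaces decode surface EMG into continuous commands — here a
2-D cursor whose axes are the wrist's two degrees of freedom
(flexion/extension, radial/ulnar deviation) and whose unit circle is the
maximal voluntary contraction (MVC). The package implements, for the people
who build and evaluate such interfaces, the two standard decoding chains and
a controlled-disturbance protocol for comparing their robustness:

* **Linear regression (LR)** — simultaneous proportional control via the
  least-squares map `ŷ = Wᵀφ` from windowed RMS features `φ` to the 2-D
  intent, smoothed by an exponential moving average (EMA, filter constant
  1/25 per 40 ms frame).
* **Multiclass LDA** — per-frame classification by the linear discriminant
  `δ_c(φ) = φᵀΣ⁻¹μ_c − ½ μ_cᵀΣ⁻¹μ_c + log π_c` (pooled covariance Σ, equal
  priors over 9 classes: 8 directions at 45° plus rest), majority vote over
  the last 5 decisions, and proportional intensity from the channel-average
  RMS with class-specific scaling — so the cursor moves continuously along
  one of 8 axes.
* **Disturbances** — seeded white Gaussian noise injected into a single raw
  channel: RMS ramping as `0.1·A_max·t` from 5 s on, or a sudden
  `0.4·A_max` step lasting 10 s, where `A_max` is the peak channel-average
  RMS during flexion/extension calibration.
* **Metrics** — per-frame tracking error, pre-onset baseline (4–5 s), time
  the residual error stays below 0.3 units above baseline, residual error
  at 14–15 s; target-reaching summaries (completion rate/time, overshoot
  ratio, path efficiency); paired Wilcoxon signed-rank tests with
  Bonferroni correction.

Since no real recordings of this protocol are publicly available, the
package also ships a synthetic-EMG generator (amplitude-modulated
band-limited Gaussian noise driven by a direction-tuned 8-channel synergy
model, with cue-based calibration trajectories and powerline interference)
so the complete analysis is reproducible from code alone. The processing
chain is the standard real-time one: causal 30–500 Hz Butterworth band-pass,
50 Hz comb filter, 160 ms RMS windows every 40 ms.

## Worked example

```r
library(myodecode)

ex <- run_offline_experiment(experiment_config(seed = 1), progress = TRUE)
ex
#> <offline_experiment> 10 subjects, 1920 trial rows
#> # A tibble: 4 × 5
#>   decoder profile baseline time_below step_residual
#>   <chr>   <chr>      <dbl>      <dbl>         <dbl>
#> 1 lda     ramp     0.0159        14.3       NA
#> 2 lda     step     0.0159        10          0.0217
#> 3 lr      ramp     0.00703       15         NA
#> 4 lr      step     0.00703       10          0.0165
```

Read: over 10 synthetic subjects, LDA trials sit ~0.016 units off target
before any disturbance and the sudden noise pushes them a further 0.022
units off (LR: 0.007 and 0.016); under the ramping disturbance the residual
error of these synthetic conditions stays below the 0.3-unit threshold for
most of the 15 s post-onset window (14.3 s / 15 s). Whether the step
elevation is significant, and how the decoders compare subject-by-subject:

```r
ex$tests$step_vs_baseline
#> # A tibble: 2 × 5
#>   decoder statistic p_value n_effective method
#>   <chr>       <dbl>   <dbl>       <int> <chr>
#> 1 lda            55 0.00195          10 exact
#> 2 lr             55 0.00195          10 exact
autoplot(ex)        # mean residual-error time courses (ramp / step panels)
subject_summary(ex) # per-subject means, tidy
```

Single pieces compose with the pipe and plain tibbles throughout — e.g.
`make_reach_protocol()` → `synthesize_emg()` → `inject_ramp_noise()` →
`filter_signal()` → `rms_features()` → `decode_stream()` →
`tracking_error()`. Fitted decoders have `tidy()`/`glance()` methods and
serialize to JSON; a closed-loop hook (`run_closed_loop()`) accepts a user
policy `function(error, intent)` for simulated-adaptation studies, with the
static policy reproducing the open-loop results exactly.

See the vignette (`vignettes/noise-robustness.Rmd`) for the model details,
parameter choices and the generator's known limitations.

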