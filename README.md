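# usvtools

Detection and statistical analysis of rat ultrasonic vocalisations (USVs)
emitted during standardised human–rat play ("tickling"), built around an
adaptive-threshold spectrogram detector and the mixed-model analysis that
turns per-session call counts into estimates of treatment effects and
individual repeatability.

## Who this is for

Behavioural scientists and bioacousticians who record juvenile rats during
tickling or rough-and-tumble play and need to (1) count positively valenced
50-kHz calls (≈35–68 kHz) and aversive 22-kHz calls (≈18–26 kHz) in
ultrasonic WAV recordings, (2) convert detections into session-level
variables (counts, per-contact-period emission rates, play asymmetry
scores), and (3) fit the corresponding statistical models. Everything runs
on synthetic data with exact ground truth, so the whole pipeline can be
validated without any recordings.

## The detector

Each recording is scanned in 0.5 s windows. Within a window, a spectrogram
is computed (Hann window, 1024 samples, 90% overlap: 1211 frames of
~0.41 ms and 244 Hz bands; 136 bands intersect 35–68 kHz at a 250 kHz
sampling rate). For every frame *t*, the mean μ_t and standard deviation
σ_t of the band magnitudes over 37.44–68 kHz are computed, and the frame is
*flagged* when at least 4 bands exceed

> μ_t + 2.1 σ_t

Flagged frames within 40 ms of each other are grouped; groups with at least
16 flagged frames become candidate calls, and candidates shorter than
6.6 ms are discarded. The window scan is repeated with a 0.25 s offset so
calls cut by a window edge are seen whole by the second pass, and the two
passes are combined by interval union. The threshold is relative to each
frame's own statistics, so detections are exactly invariant to recording
gain. For 22-kHz calls the band becomes 18–26 kHz, the multiplier 1.3 and
the band minimum 2.

The statistical stage mirrors the standard analysis of tickling studies:
a log-link Poisson GLM for received pinnings, OLS for the asymmetry score
(P_d − P_r)/(P_d + P_r), a Gaussian linear mixed model for per-session
50-kHz counts (treatment + batch fixed effects, day and order covariates,
rat and litter random intercepts), a Poisson mixed model for 22-kHz counts,
AICc = AIC + 2k(k+1)/(n−k−1) model ranking, variance-component
repeatability R = σ²_rat/(σ²_rat + σ²_litter + σ²_res) with
parametric-bootstrap intervals, and Tukey-adjusted estimated marginal
means.

## Worked example

```r
library(usvtools)

# synthesise 5 s of tilted ultrasonic noise with 8 planted 50-kHz calls
plan  <- recording_plan(duration_s = 5, n_calls = 8, seed = 42)
synth <- synth_recording(plan)

dets <- detect_recording(synth$recording)
dets
#> # A tibble: 8 × 7
#>   recording_id call_class onset_s offset_s duration_ms n_flagged_frames source
#> 1 synth_seed42 usv50        0.193    0.279        86.4              211 merged
#> 2 synth_seed42 usv50        1.66     1.75         91.1              222 merged
#> ... (8 rows: one detection per planted call)

evaluate_detections(dets, synth$truth)
#> <usv_eval: 8 truth, 8 detected, 8 matched | recall 1.000, precision 1.000, F1 1.000>
```

Every planted call is recovered: onsets/offsets bracket the truth
intervals, and `n_flagged_frames` counts the frames above the adaptive
threshold. On the cohort side:

```r
design   <- cohort_design()                    # 53 rats, 3 batches, 476 sessions
sessions <- simulate_usv_counts(design, seed = 1)
fit      <- fit_usv_lmm(sessions)              # Gaussian LMM, REML
tidy(fit)
#>   term                       estimate std.error statistic  p.value
#> 1 (Intercept)                  161.      21.3        7.55  3.7e-08
#> 6 day                            3.79     0.734      5.17  3.7e-07
#> 7 order                          5.40     1.21       4.48  5.7e-05
#> ...

repeatability(fit, "rat_id", n_boot = 200, seed = 1)
#> <repeatability rat_id: R = 0.406 [0.254, 0.557] (200 boot)>
```

The day and order slopes recover the generating values (3.09 and 4.31)
within their standard errors, and roughly 40–50% of the non-residual
variance in session counts is attributable to stable rat identity.

A thin command-line front end over the same functions lives in
`inst/cli/usv.R` (`detect`, `evaluate`, `simulate-audio`,
`simulate-cohort`, `rates`, `analyze`, `benchmark`, `full-synthetic`).

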