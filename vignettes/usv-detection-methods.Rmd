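---
title: "Adaptive-threshold USV detection and the tickling analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-threshold USV detection and the tickling analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

usvtools detects rat ultrasonic vocalisations (USVs) with a per-frame
adaptive spectrogram threshold and carries the resulting call counts
through the statistical models used in human–rat play ("tickling")
studies. This vignette documents the method, its parameters, the
numerical conventions the implementation commits to, what the synthetic
generators do and do not emulate, and the package's known limitations.

## The detection model

A mono recording sampled at `fs` (default 250 kHz — the rate at which a
1024-point transform gives the ~244 Hz bands and, for a 0.5 s window,
the 1211 frames of the documented analysis geometry) is processed in
0.5 s sliding windows. Each window is transformed with a Hann-tapered
short-time Fourier transform:

* `window_length = 1024` samples, `overlap_fraction = 0.9`, hence a
  *fractional* hop of 102.4 samples (0.4096 ms). Frame `m` starts at
  sample `round(m * 102.4)`; the frame count is
  `floor((n - 1024)/102.4) + 1`. The fractional hop is deliberate:
  integer hops of 102 or 103 samples give 1216 or 1204 frames for a
  0.5 s window instead of the documented 1211.
* Bands are half-open intervals `[b·Δf, (b+1)·Δf)` with `Δf = fs/1024`;
  a band belongs to a frequency range if its interval *intersects* the
  range. This intersection convention is what makes 136 bands intersect
  35–68 kHz (intervals containing band centres give a different count).

For every frame the mean and standard deviation (sample SD, divisor
`n − 1`; the convention is not dictated by the algorithm's description,
so it is configurable in spirit but fixed here and documented) of the
band magnitudes over the *stats band range* are computed, and bands
*strictly* above `mean + k_sd · SD` are counted. A frame is flagged when
at least `min_bands` bands exceed. The two built-in profiles:

| parameter | `usv50` | `usv22` | units |
|---|---|---|---|
| analysis band | 35000–68000 | 18000–26000 | Hz |
| stats band | 37440–68000 | 18000–26000 | Hz |
| `k_sd` | 2.1 | 1.3 | SD multiples |
| `min_bands` | 4 | 2 | bands |
| `max_gap_ms` | 40 | 40 | ms |
| `min_frames` | 16 | 16 | frames |
| `min_dur_ms` | 6.6 | 6.6 | ms |

The `usv22` profile changes only the three parameters its description
states (band, multiplier, band minimum) and inherits the rest; all are
configurable through `detector_profile()`.

Flagged frames whose start times differ by at most `max_gap_ms` are
chained into groups (the gap is measured between *start times* of
consecutive flagged frames). Groups with at least `min_frames` flagged
frames become candidates with onset at the first flagged frame's start
and offset one hop after the last flagged frame's start, so `k`
contiguous frames span `k × 0.4096` ms. A consequence worth noting: a
16-frame contiguous group spans 6.554 ms and is removed by the 6.6 ms
filter, so the effective minimum is 17 contiguous frames. The original
script's exact onset/offset conventions are not recoverable from its
description; ours are declared here and used consistently.

Two passes tile the recording, offset by 0 and 0.25 s, so any call
shorter than 0.25 s lies wholly inside at least one window of one pass;
a trailing partial window is processed when at least one STFT window
fits. Detections from both passes are combined by interval union:
overlapping *or abutting* detections of the same class are merged (the
flagged-frame count of a merged detection is the maximum over its
constituents), duplicates collapse, and the output is sorted and
pairwise disjoint.

### The amplitude scale

The per-frame statistics are computed on **decibel** magnitudes
(`20·log10`, floored at `1e-12` of the segment maximum so silence and
gain-scaling behave exactly). This is a deliberate design decision and
the package's most consequential one. On raw linear magnitudes, the
cross-band SD of stationary noise is small relative to its upper tail:
across ~126 approximately Rayleigh-distributed bands, about four bands
per frame are expected above `mean + 2.1·SD`, so noise frames are
flagged roughly half the time and the 40 ms gap rule chains them into
wall-to-wall spurious detections — for *any* noise amplitude, since the
threshold is scale-invariant. On the dB scale the deep lower tail of
fading bands inflates the SD, placing the threshold ~10 dB above the
noise ceiling (per-band exceedance ~2×10⁻⁴) while calls exceed it by
20 dB and more. A dB-referenced spectrogram is also what an
Avisoft-style "linear scale, dB re 20 µPa" display shows. The linear
scale remains available (`amplitude_scale = "linear"`) and its
degenerate behaviour on stationary noise is asserted in the test suite
as a documented property, not hidden. Both scales leave detections
exactly invariant under amplitude gain.

### Evaluation

Detections are matched to ground truth one-to-one, greedily by
descending temporal intersection-over-union (IoU); a pair is matchable
when IoU ≥ 0.3 or the onsets differ by ≤ 5 ms. The tolerances are the
package's own: manual-screening validation has no formal counterpart,
and these values are strict at typical 20–100 ms call durations while
forgiving the detector's habit of extending offsets slightly past faint
call tails. With no detections, precision is 1 by convention (no false
alarms); with no truth calls, recall is 1. Recall, precision and F1 are
all reported; "accuracy" claims for detectors of this family are
read as recall here, which is what the benchmark targets.

## The synthetic audio generator

`recording_plan()` + `synth_recording()` produce seeded recordings with
exact truth annotations. The background is Gaussian noise spectrally
shaped so amplitude ∝ f^(−α) with α = 1 by default (pink-like, matching
the falling noise floors of ultrasonic recording chains; α = 0 gives
white noise for stress tests). Calls are phase-continuous FM tones with
2 ms raised-cosine ramps:

* **flat** — a slowly drifting tone; the total drift is drawn from
  0.6–3 kHz. Mathematically constant tones are a measure-zero
  idealisation whose Hann mainlobe occupies only 3 DFT bins — one fewer
  than `min_bands` — and real "flat" calls carry a few hundred Hz to a
  few kHz of drift.
* **sweep** — linear frequency ramp at ±50–200 kHz/s.
* **trill** — sinusoidal FM with 2–6 kHz depth at 40–80 Hz.
* **long22** — a long (0.3–2 s) narrowband call in the 22-kHz band.

Default mix 40% flat / 30% sweep / 30% trill, durations uniform on
15–120 ms, minimum inter-call gap 50 ms, onsets placed by seeded
stick-breaking. The generator keeps 50-kHz calls above 38.5 kHz: the
detector's statistics only scan 37.44–68 kHz, so calls at 35–37.4 kHz
are structurally invisible to it regardless of SNR, and real 50-kHz
calls cluster well above that floor.

SNR is defined as in-band RMS of the call over in-band RMS of the
background (dB), measured on the realised noise via Parseval's
identity; per-call amplitudes are derived from target SNRs and the
*realised* SNR is stored in the truth table. Identical plans produce
byte-identical audio.

What the generator does **not** emulate: amplitude-modulated or
harmonically rich calls, overlapping calls, echoes and reverberation,
microphone directionality, transient broadband noise (cage scratching,
movement), and drifting noise floors. A clean pass on the synthetic
benchmark therefore bounds the detector's behaviour under stationary
noise with well-separated tonal calls — it does not certify performance
on noisy colony recordings.

## The cohort generators and statistical stage

`cohort_design()` reproduces the study design exactly: batches of
17/18/18 rats (batch A has a 5-rat control group), three treatments
(control, kinematically reduced play, socially reduced play), four
litters per batch with litter mates spread across treatments, ten
sessions per rat (seven in batch B; 476 sessions total), and a fixed,
randomly drawn tickling order within batch.

The generative parameters default to the published estimates: received
pinnings are Poisson with log-rate `3.20 − 0.45·social − 0.82·batchC`
(kinematically reduced rats receive and deliver none — the lowered
ceiling prevents pinning outright); 50-kHz session counts are Gaussian
with fixed effects `136.27 − 33.35·social − 8.59·kinematic + 3.09·day +
4.31·order − 25.56·batchB − 23.58·batchC`, rounded and floored at zero
(the Gaussian-on-counts choice follows the original analysis, which
found it the best-fitting family; it is honoured, not "corrected");
22-kHz counts are log-link Poisson with `−0.72 + 0.17·day + 2.13·batchB
− 0.01·batchC`. Variance components are not published, so defaults are
derived from published summary quantities: `sd_rat = 50`, `sd_litter =
26`, `sd_resid = 41.5` reproduce the reported session SD (~76) and
split the random variance in the reported repeatability shares (0.519
rat, 0.137 litter); the 22-kHz `sd_rat = 0.4` similarly matches the
reported latent-scale repeatability (~0.38) under this package's
distribution-variance convention (below).

Model fitting uses the field-standard engines (`stats::glm`/`lm`,
`lme4`/`lmerTest`) behind a tidy interface. Conventions:

* **ML vs REML** — ML when comparing fixed-effect structures by AICc,
  REML for reported coefficient tables; the standard defensible choice
  where the original analysis is silent.
* **AICc's k** — fixed effects + variance components + residual, i.e.
  the fitting engine's log-likelihood degrees of freedom.
* **Repeatability** — `R = σ²_term / (σ²_rat + σ²_litter + σ²_res)`
  from the REML fit; confidence intervals by seeded parametric
  bootstrap (simulate from the fit, refit, percentile interval; 1000
  draws by default). For log-link Poisson models the ratio is computed
  on the latent scale with the distribution-specific variance
  `ln(1 + 1/λ̄)`, `λ̄` the mean fitted rate, in place of the residual
  variance.
* **Marginal means** — equal weights over factor levels, covariates at
  observed means, inverse link for the response scale, Tukey-adjusted
  pairwise contrasts.
* **Degenerate inputs** — single-level factors abort with "degenerate
  design"; singular mixed fits are reported via a message, never
  silently simplified; an all-zero asymmetry denominator yields `NA`
  with a warning (the all-zero kinematic group is excluded from the
  pinning GLM for the same reason).

A caveat demonstrated in the test suite: with only ~12 litters and a
true litter variance near zero, the litter component sits on the
boundary of its parameter space and absorbs some rat variance, biasing
rat repeatability downward by several hundredths at the study's size.
Closed-form checks therefore use larger simulated cohorts (200+ rats,
30 litters), and recovery checks at the study size use a ±0.1 band.

## Problem sizes

The test suite validates at these sizes, chosen to exercise every code
path at comfortable margins: the detector benchmark uses 200 calls over
60 s at ≥ 15 dB SNR; property tests use 2–5 s recordings with 6–8
calls; grouping is checked against an exhaustive partition-enumeration
oracle on up to 50-frame sequences; parameter-recovery suites run 200
simulate-refit replicates for the GLM and LMM coverage checks and 10
REML refits for repeatability at the study design; the end-to-end
pipeline check plants 3–6 rats × 2–3 short sessions of audio and
requires detected counts to equal planted counts exactly.

## Known limitations

* The 22-kHz profile as documented (multiplier 1.3, 2 bands over ~34
  stats bands) is intrinsically permissive: on stationary noise roughly
  half of all frames get flagged *at any noise amplitude*, so it is
  only usable on recordings whose 18–26 kHz band is quiet between
  calls. The synthetic 22-kHz tests therefore use a silent background,
  and results from this profile on noisy recordings should be screened.
* Two calls closer than ~40 ms (plus ramp tails) are merged into one
  detection by design ("connecting" calls are unioned), which under
  one-to-one matching counts as a miss of the smaller call; at the
  default 50 ms minimum gap this costs the benchmark ~0–1 of 200 calls.
* Calls below the 37.44 kHz stats floor are undetectable by
  construction.
* No call-type classification, frequency-contour extraction or
  real-time processing; the detector is an offline counting tool.
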