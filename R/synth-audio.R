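# Seeded synthetic ultrasonic audio with ground-truth annotations.
# Calls are phase-continuous FM tones over a spectrally tilted noise floor.

#' In-band root-mean-square amplitude
#'
#' RMS of the signal restricted to a frequency band, computed via Parseval's
#' identity on the DFT. This is the package's SNR definition: realized SNR of
#' a call is the in-band RMS of the call waveform over the in-band RMS of the
#' background noise, in dB.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz.
#' @return RMS amplitude within the band.
#' @export
band_rms <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                       # two-sided
  sel <- f >= lo & f <= hi
  sqrt(sum(Mod(X[sel])^2) / n^2)
}

#' Specify synthetic calls
#'
#' Builds a calls tibble, one row per call. `flat` is a constant tone at
#' `f0`; `sweep` ramps linearly at `sweep_rate` Hz/s; `trill` modulates
#' sinusoidally with depth `fm_depth` and rate `fm_rate`; `long22` is a flat
#' narrowband call in the 22-kHz band. The instantaneous frequency of 50-kHz
#' call types must stay within 35-68 kHz and of `long22` within 18-26 kHz.
#'
#' @param call_type One of `"flat"`, `"sweep"`, `"trill"`, `"long22"`.
#' @param f0 Carrier frequency in Hz.
#' @param duration_s Call duration in seconds.
#' @param onset_s Call onset in seconds from recording start.
#' @param amplitude Linear peak amplitude (`NA` to derive from `snr_db` at
#'   synthesis time).
#' @param snr_db Target in-band SNR in dB (used when `amplitude` is `NA`).
#' @param sweep_rate Hz/s, sweeps only.
#' @param fm_depth,fm_rate Hz, trills only.
#' @return A tibble of call specifications.
#' @export
call_spec <- function(call_type, f0, duration_s, onset_s,
                      amplitude = NA_real_, snr_db = 20,
                      sweep_rate = 0, fm_depth = 0, fm_rate = 0) {
  tb <- tibble(call_type = call_type, f0 = f0, duration_s = duration_s,
               onset_s = onset_s, amplitude = amplitude, snr_db = snr_db,
               sweep_rate = sweep_rate, fm_depth = fm_depth, fm_rate = fm_rate)
  validate_call_specs(tb)
  tb
}

call_band <- function(call_type) {
  if (identical(call_type, "long22")) c(18000, 26000) else c(35000, 68000)
}

call_freq_range <- function(calls) {
  lo <- with(calls, f0 + pmin(0, sweep_rate * duration_s) - fm_depth)
  hi <- with(calls, f0 + pmax(0, sweep_rate * duration_s) + fm_depth)
  cbind(lo, hi)
}

validate_call_specs <- function(calls) {
  stopifnot(all(calls$duration_s > 0), all(calls$onset_s >= 0))
  rng <- call_freq_range(calls)
  for (i in seq_len(nrow(calls))) {
    band <- call_band(calls$call_type[i])
    if (rng[i, 1] < band[1] || rng[i, 2] > band[2]) {
      abort(sprintf(
        "call %d (%s): instantaneous frequency [%.0f, %.0f] Hz leaves its class band [%g, %g] Hz",
        i, calls$call_type[i], rng[i, 1], rng[i, 2], band[1], band[2]))
    }
  }
  invisible(calls)
}

#' Synthesise one call waveform
#'
#' Phase-continuous frequency-modulated tone with raised-cosine on/off ramps
#' (2 ms each, shortened to a quarter of the call for very short calls) to
#' avoid spectral splatter.
#'
#' @param spec One row of a calls tibble (see [call_spec()]).
#' @param fs Sampling rate in Hz; must exceed twice the maximum instantaneous
#'   frequency.
#' @param ramp_s Ramp duration in seconds.
#' @return Numeric waveform of length `round(duration_s * fs)`.
#' @export
synth_call_waveform <- function(spec, fs, ramp_s = 0.002) {
  spec <- as.list(spec)
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  f_inst <- switch(spec$call_type,
    flat = , long22 = , sweep = spec$f0 + spec$sweep_rate * t,
    trill = spec$f0 + spec$fm_depth * sin(2 * pi * spec$fm_rate * t),
    abort(sprintf("unknown call_type '%s'", spec$call_type))
  )
  if (max(f_inst) >= fs / 2) abort("aliasing risk: instantaneous frequency exceeds Nyquist")
  phase <- 2 * pi * cumsum(f_inst) / fs
  env <- rep(1, n)
  nr <- min(round(ramp_s * fs), floor(n / 4))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- ramp
    env[n + 1 - seq_len(nr)] <- rev(ramp)
  }
  amp <- spec$amplitude
  if (is.na(amp)) amp <- 1
  amp * env * sin(phase)
}

#' Plan a synthetic recording
#'
#' Draws a seeded set of non-colliding calls over a recording of the given
#' duration. Defaults emulate the 50-kHz repertoire: 40% flat, 30% sweep,
#' 30% trill, durations uniform on 15-120 ms, target in-band SNR uniform on
#' `snr_db_range`, over pink-like background noise (amplitude proportional
#' to `f^-alpha`, `alpha = 1`). `call_class = "usv22"` draws flat `long22`
#' calls of 0.3-2 s instead.
#'
#' @param duration_s Recording length in seconds.
#' @param n_calls Number of calls to place.
#' @param fs Sampling rate in Hz.
#' @param call_class `"usv50"` or `"usv22"`.
#' @param type_mix Named probabilities over 50-kHz call types.
#' @param dur_range_s Call-duration range in seconds.
#' @param snr_db_range Target SNR range in dB.
#' @param noise_sigma Broadband noise RMS (linear).
#' @param noise_tilt_alpha Spectral tilt exponent (0 = white, 1 = pink-like).
#' @param min_gap_s Minimum silence between consecutive calls.
#' @param seed Integer seed; the plan and the audio drawn from it are pure
#'   functions of the seed.
#' @param calls Optional pre-built calls tibble; overrides the random draw.
#' @return A list of class `recording_plan`.
#' @export
recording_plan <- function(duration_s = 60, n_calls = 200, fs = 250000,
                           call_class = c("usv50", "usv22"),
                           type_mix = c(flat = 0.4, sweep = 0.3, trill = 0.3),
                           dur_range_s = NULL,
                           snr_db_range = c(15, 30),
                           noise_sigma = 0.01, noise_tilt_alpha = 1,
                           min_gap_s = 0.05, seed = 1, calls = NULL) {
  call_class <- match.arg(call_class)
  dur_range_s <- dur_range_s %||%
    if (call_class == "usv50") c(0.015, 0.120) else c(0.3, 2.0)
  if (is.null(calls)) {
    withr::local_seed(seed)
    n <- n_calls
    if (n > 0) {
      types <- if (call_class == "usv50") {
        sample(names(type_mix), n, replace = TRUE, prob = type_mix)
      } else rep("long22", n)
      dur <- runif(n, dur_range_s[1], dur_range_s[2])
      sweep_rate <- fm_depth <- fm_rate <- rep(0, n)
      f0 <- numeric(n)
      for (i in seq_len(n)) {
        # keep 50-kHz calls above the detector's 37.44 kHz stats-band floor
        # (calls in 35-37.4 kHz fall outside the band the frame statistics
        # scan and are structurally undetectable); real calls cluster higher
        band <- if (types[i] == "long22") {
          call_band("long22") + c(1000, -1000)
        } else {
          c(38500, 67000)
        }
        if (types[i] == "sweep") {
          sweep_rate[i] <- sample(c(-1, 1), 1) * runif(1, 5e4, 2e5)
          span <- sweep_rate[i] * dur[i]
          f0[i] <- runif(1, band[1] - min(0, span), band[2] - max(0, span))
        } else if (types[i] == "trill") {
          fm_depth[i] <- runif(1, 2000, 6000)
          fm_rate[i] <- runif(1, 40, 80)
          f0[i] <- runif(1, band[1] + fm_depth[i], band[2] - fm_depth[i])
        } else {
          # "flat" rat calls carry a few hundred Hz to a few kHz of slow
          # drift; a mathematically constant tone is an idealisation whose
          # Hann mainlobe occupies only 3 DFT bins
          span_hz <- if (types[i] == "flat") runif(1, 600, 3000) else runif(1, 200, 800)
          span <- sample(c(-1, 1), 1) * span_hz
          sweep_rate[i] <- span / dur[i]
          f0[i] <- runif(1, band[1] - min(0, span), band[2] - max(0, span))
        }
      }
      need <- sum(dur) + (n + 1) * min_gap_s
      if (need > duration_s) {
        abort(sprintf("calls do not fit: need %.1f s, have %.1f s", need, duration_s))
      }
      slack <- diff(c(0, sort(runif(n)), 1)) * (duration_s - need)
      onset <- numeric(n)
      onset[1] <- slack[1] + min_gap_s
      if (n > 1) {
        for (i in 2:n) onset[i] <- onset[i - 1] + dur[i - 1] + min_gap_s + slack[i]
      }
      calls <- tibble(call_type = types, f0 = f0, duration_s = dur,
                      onset_s = onset, amplitude = NA_real_,
                      snr_db = runif(n, snr_db_range[1], snr_db_range[2]),
                      sweep_rate = sweep_rate, fm_depth = fm_depth,
                      fm_rate = fm_rate)
    } else {
      calls <- call_spec(character(), numeric(), numeric(), numeric())[0, ]
    }
  }
  if (nrow(calls) > 0) {
    validate_call_specs(calls)
    o <- order(calls$onset_s)
    cs <- calls[o, ]
    if (any(cs$onset_s + cs$duration_s > duration_s)) {
      abort("calls must fit within [0, duration_s]")
    }
    if (nrow(cs) > 1) {
      gap <- cs$onset_s[-1] - (cs$onset_s[-nrow(cs)] + cs$duration_s[-nrow(cs)])
      if (any(gap < 0)) abort("call collision: overlapping calls in plan")
    }
  }
  structure(list(duration_s = duration_s, fs = fs, call_class = call_class,
                 noise_sigma = noise_sigma, noise_tilt_alpha = noise_tilt_alpha,
                 min_gap_s = min_gap_s, calls = calls, seed = seed),
            class = "recording_plan")
}

# Gaussian noise shaped so amplitude spectral density ~ f^-alpha,
# generated in independent FFT chunks, then rescaled to target RMS.
shaped_noise <- function(n, fs, sigma, alpha, chunk = 2^19) {
  if (sigma <= 0) return(numeric(n))
  out <- numeric(n)
  pos <- 1
  while (pos <= n) {
    m <- min(chunk, n - pos + 1)
    w <- rnorm(m)
    if (alpha != 0 && m > 8) {
      k <- seq_len(m) - 1
      f <- pmin(k, m - k) * fs / m
      f1 <- fs / m
      s <- (pmax(f, f1) / f1)^(-alpha)
      w <- Re(fft(fft(w) * s, inverse = TRUE)) / m
    }
    out[pos:(pos + m - 1)] <- w
    pos <- pos + m
  }
  out * sigma / sqrt(mean(out^2))
}

#' Synthesise a recording with ground truth
#'
#' Generates the background noise of the plan, derives each call's amplitude
#' from its target in-band SNR (measured against the realised noise floor in
#' the call's class band), adds the calls at their onsets and returns the
#' audio together with exact truth annotations including realised SNR.
#' Byte-identical output for identical plans (the plan's seed governs all
#' randomness).
#'
#' @param plan A [recording_plan()].
#' @return A list with `recording` (an [audio_recording()]) and `truth` (a
#'   tibble: `recording_id`, `call_class`, `call_type`, `onset_s`,
#'   `offset_s`, `snr_db`).
#' @export
synth_recording <- function(plan) {
  stopifnot(inherits(plan, "recording_plan"))
  withr::local_seed(plan$seed + 1L)
  n <- round(plan$duration_s * plan$fs)
  x <- shaped_noise(n, plan$fs, plan$noise_sigma, plan$noise_tilt_alpha)
  calls <- plan$calls
  snr_real <- numeric(nrow(calls))
  if (nrow(calls) > 0) {
    # noise floor per class band, measured on a 0.5 s slice of the realised noise
    slice <- x[seq_len(min(n, round(0.5 * plan$fs)))]
    noise_rms <- vapply(unique(calls$call_type), function(ct) {
      b <- call_band(ct)
      band_rms(slice, plan$fs, b[1], b[2])
    }, numeric(1))
    for (i in seq_len(nrow(calls))) {
      b <- call_band(calls$call_type[i])
      nrms <- noise_rms[[calls$call_type[i]]]
      spec_i <- calls[i, ]
      if (is.na(spec_i$amplitude)) {
        spec_i$amplitude <- if (nrms > 0) {
          10^(spec_i$snr_db / 20) * nrms * sqrt(2)
        } else 0.1                    # silent background: nominal amplitude
      }
      w <- synth_call_waveform(spec_i, plan$fs)
      i0 <- round(spec_i$onset_s * plan$fs)
      idx <- i0 + seq_along(w)
      idx_ok <- idx <= n
      x[idx[idx_ok]] <- x[idx[idx_ok]] + w[idx_ok]
      crms <- band_rms(w, plan$fs, b[1], b[2])
      snr_real[i] <- if (nrms > 0) 20 * log10(crms / nrms) else Inf
    }
  }
  truth <- tibble(
    recording_id = sprintf("synth_seed%d", plan$seed),
    call_class = plan$call_class,
    call_type = calls$call_type,
    onset_s = calls$onset_s,
    offset_s = calls$onset_s + calls$duration_s,
    snr_db = snr_real
  )
  list(recording = audio_recording(x, plan$fs, sprintf("synth_seed%d", plan$seed)),
       truth = truth)
}
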