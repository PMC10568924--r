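# Short-time Fourier analysis: the deterministic front end the detector reads.

#' Construct an audio recording
#'
#' A light container for a mono pressure-sample sequence plus its sampling
#' rate. Samples are dimensionless normalised amplitudes.
#'
#' @param samples Numeric vector of finite sample amplitudes (length >= 1).
#' @param fs Sampling rate in Hz (> 0).
#' @param id Opaque recording label.
#' @return An object of class `usv_audio` with fields `samples`, `fs`, `id`.
#' @examples
#' rec <- audio_recording(sin(2 * pi * 50e3 * (0:999) / 250e3), fs = 250e3)
#' @export
audio_recording <- function(samples, fs, id = "rec") {
  samples <- as.numeric(samples)
  if (length(samples) < 1) abort("samples must have length >= 1")
  if (!all(is.finite(samples))) abort("samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("fs must be a positive scalar")
  structure(list(samples = samples, fs = fs, id = as.character(id)),
            class = "usv_audio")
}

#' @export
print.usv_audio <- function(x, ...) {
  cat(sprintf("<usv_audio '%s': %d samples @ %g Hz (%.3f s)>\n",
              x$id, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Short-time Fourier transform parameters
#'
#' Defaults follow the detector's analysis settings: a 1024-sample Hann
#' window with 90% overlap, giving a fractional hop of 102.4 samples and a
#' band width of `fs / 1024` (244.14 Hz at the default 250 kHz rate).
#' `amplitude_reference` (the 20 micropascal pressure reference) is carried
#' as metadata only: the adaptive threshold is invariant to amplitude
#' scaling, so magnitudes are kept linear and unreferenced.
#'
#' @param window_length Analysis window length in samples (>= 2).
#' @param overlap_fraction Fractional overlap in `[0, 1)`.
#' @param window_shape Taper name; only `"hanning"` is implemented.
#' @param fs Sampling rate in Hz.
#' @param amplitude_reference Pressure reference constant, metadata only.
#' @return A list of class `stft_params` with the derived `hop` (samples)
#'   and `band_width` (Hz).
#' @export
stft_params <- function(window_length = 1024, overlap_fraction = 0.9,
                        window_shape = "hanning", fs = 250000,
                        amplitude_reference = 2e-5) {
  if (window_length < 2) abort("window_length must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("overlap_fraction must lie in [0, 1)")
  }
  hop <- window_length * (1 - overlap_fraction)
  if (hop <= 0) abort("hop must be positive")
  window_shape <- match.arg(window_shape, "hanning")
  structure(list(window_length = as.integer(window_length),
                 overlap_fraction = overlap_fraction,
                 window_shape = window_shape,
                 fs = fs,
                 hop = hop,
                 band_width = fs / window_length,
                 amplitude_reference = amplitude_reference),
            class = "stft_params")
}

#' Number of STFT frames that fit in a segment
#'
#' Frame `m` (0-based) starts at sample `round(m * hop)`; the count is
#' `floor((n_samples - window_length) / hop) + 1`. With the default
#' parameters a 0.5 s segment at 250 kHz yields 1211 frames.
#'
#' @param n_samples Segment length in samples.
#' @param window_length Window length in samples.
#' @param hop Hop in samples; may be fractional (102.4 by default).
#' @return Integer frame count.
#' @export
frame_count <- function(n_samples, window_length, hop) {
  if (hop <= 0) abort("hop must be positive")
  if (n_samples < window_length) abort("segment too short")
  as.integer(floor((n_samples - window_length) / hop) + 1)
}

hann_window <- function(n) signal::hanning(n)

#' Compute a linear-magnitude spectrogram
#'
#' Applies a Hann-tapered discrete Fourier transform to each frame and keeps
#' the magnitude of the first `window_length / 2` coefficients (bands
#' `0 .. wl/2 - 1`, band `b` spanning `[b, b + 1) * fs / wl` Hz). Magnitudes
#' are raw linear `|FFT|` values: the detector's threshold is scale-invariant
#' so no dB conversion is applied.
#'
#' @param segment An [audio_recording()] or numeric vector.
#' @param params An [stft_params()] object.
#' @param t0 Time (seconds) of the segment's first sample, added to the
#'   returned frame start times.
#' @return An object of class `usv_spectrogram`: a list with the magnitude
#'   matrix `A` (`band x frame`), `frame_start_times` (s), `band_lo_freqs`
#'   (Hz) and `params`.
#' @export
stft_spectrogram <- function(segment, params = stft_params(), t0 = 0) {
  x <- if (inherits(segment, "usv_audio")) segment$samples else as.numeric(segment)
  wl <- params$window_length
  if (length(x) < wl) abort("segment too short")
  n_frames <- frame_count(length(x), wl, params$hop)
  starts <- round((seq_len(n_frames) - 1) * params$hop)   # 0-based sample starts
  idx <- outer(seq_len(wl), starts, `+`)
  frames <- matrix(x[idx], nrow = wl) * hann_window(wl)
  A <- Mod(stats::mvfft(frames))[seq_len(wl %/% 2), , drop = FALSE]
  structure(list(
    A = A,
    frame_start_times = t0 + starts / params$fs,
    band_lo_freqs = (seq_len(wl %/% 2) - 1) * params$band_width,
    params = params
  ), class = "usv_spectrogram")
}

#' @export
print.usv_spectrogram <- function(x, ...) {
  cat(sprintf("<usv_spectrogram: %d bands x %d frames, band width %.2f Hz, hop %.4f ms>\n",
              nrow(x$A), ncol(x$A), x$params$band_width,
              1000 * x$params$hop / x$params$fs))
  invisible(x)
}

#' Band indices intersecting a frequency range
#'
#' Returns the contiguous indices (1-based) of all spectrogram bands whose
#' interval `[b * df, (b + 1) * df)` intersects `[lo, hi]`. This
#' interval-intersection convention yields 136 bands for 35-68 kHz at the
#' default 250 kHz / 1024-sample analysis.
#'
#' @param params An [stft_params()] object.
#' @param lo,hi Frequency range in Hz, `0 <= lo < hi <= fs / 2`.
#' @return Integer vector of band indices (1-based).
#' @export
band_indices <- function(params, lo, hi) {
  if (lo < 0 || hi > params$fs / 2 || lo >= hi) {
    abort("need 0 <= lo < hi <= fs/2")
  }
  df <- params$band_width
  b <- seq_len(params$window_length %/% 2) - 1          # 0-based band numbers
  keep <- (b * df <= hi) & ((b + 1) * df > lo)
  if (!any(keep)) abort("no bands in range")
  which(keep)
}

#' Optional time-domain band-pass pre-filter
#'
#' The detector restricts analysis to in-range spectrogram bands, which is
#' equivalent to a band-pass for this algorithm; this 4th-order Butterworth
#' filter (applied forward-backward, zero phase) is provided for fidelity
#' experiments only.
#'
#' @param rec An [audio_recording()].
#' @param lo,hi Pass band in Hz.
#' @param order Filter order (per direction).
#' @return A filtered [audio_recording()].
#' @export
bandpass_filter <- function(rec, lo, hi, order = 4) {
  ny <- rec$fs / 2
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  audio_recording(signal::filtfilt(bf, rec$samples), rec$fs, paste0(rec$id, "_bp"))
}

#' Export a spectrogram as a tidy tibble
#'
#' Debug/export helper: one row per (band, frame) cell with the frame start
#' time and band low frequency, suitable for CSV dumping or ggplot2.
#'
#' @param spec A `usv_spectrogram`.
#' @return A tibble with columns `time_s`, `band_lo_hz`, `magnitude`.
#' @export
spectrogram_tbl <- function(spec) {
  tibble(
    time_s = rep(spec$frame_start_times, each = nrow(spec$A)),
    band_lo_hz = rep(spec$band_lo_freqs, times = ncol(spec$A)),
    magnitude = as.vector(spec$A)
  )
}

#' @rdname spectrogram_tbl
#' @param path CSV output path.
#' @export
write_spectrogram_csv <- function(spec, path) {
  utils::write.csv(spectrogram_tbl(spec), path, row.names = FALSE)
  invisible(path)
}

#' Plot a spectrogram
#'
#' @param object A `usv_spectrogram`.
#' @param max_cells Downsampling cap on plotted cells.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot usv_spectrogram
#' @export
autoplot.usv_spectrogram <- function(object, max_cells = 4e5, ...) {
  tb <- spectrogram_tbl(object)
  if (nrow(tb) > max_cells) {
    keep_t <- seq(1, ncol(object$A), by = ceiling(nrow(tb) / max_cells))
    tb <- filter(tb, .data$time_s %in% object$frame_start_times[keep_t])
  }
  ggplot2::ggplot(tb, ggplot2::aes(.data$time_s, .data$band_lo_hz / 1000,
                                   fill = log10(.data$magnitude + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 |A|") +
    ggplot2::labs(x = "time (s)", y = "frequency (kHz)") +
    ggplot2::theme_minimal()
}
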