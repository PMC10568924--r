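# Shared fixtures, built in code at test time.

# a short synthetic 50-kHz recording with a handful of well-separated calls
small_synth <- function(seed = 3, n_calls = 6, duration_s = 4,
                        snr_db_range = c(20, 30)) {
  synth_recording(recording_plan(duration_s = duration_s, n_calls = n_calls,
                                 snr_db_range = snr_db_range, seed = seed))
}

# frame-stats tibble with flags at given frame indices (0-based), default hop
flags_at <- function(flag_idx, n_frames, hop_s = 102.4 / 250000) {
  tibble::tibble(
    frame_index = seq_len(n_frames),
    time_s = (seq_len(n_frames) - 1) * hop_s,
    mu = 0, sigma = 0, n_exceeding = 0L,
    flagged = (seq_len(n_frames) - 1) %in% flag_idx
  )
}

# exhaustive grouping oracle: enumerate all contiguous partitions of the
# flagged times and keep the unique one in which every within-block
# consecutive gap is <= gap and every between-block boundary gap is > gap
brute_force_groups <- function(times, gap_s) {
  n <- length(times)
  if (n == 0) return(list())
  if (n == 1) return(list(times))
  cuts <- seq_len(n - 1)
  valid <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cut_here <- as.logical(bitwAnd(mask, 2^(cuts - 1)))
    blocks <- split(times, cumsum(c(0, cut_here)))
    ok <- TRUE
    for (b in blocks) {
      if (length(b) > 1 && any(diff(b) > gap_s)) { ok <- FALSE; break }
    }
    if (ok && length(blocks) > 1) {
      for (i in seq_len(length(blocks) - 1)) {
        boundary <- blocks[[i + 1]][1] - tail(blocks[[i]], 1)
        if (boundary <= gap_s) { ok <- FALSE; break }
      }
    }
    if (ok) { valid <- blocks; break }
  }
  valid
}
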