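test_that("per-frame threshold statistics follow the mean + k*SD rule", {
  p <- stft_params()
  prof_lin <- detector_profile("usv50", amplitude_scale = "linear")

  # build a fake spectrogram: 512 bands x 4 frames, stats bands are 154..279 (1-based)
  A <- matrix(1, 512, 4)
  stats_bands <- band_indices(p, 37440, 68000)
  # frame 2: five loud bands -> mu ~ 2.94, sigma ~ 9.56, threshold ~ 23 -> flagged
  A[stats_bands[10:14], 2] <- 50
  # frame 3: three loud bands -> exceeds threshold but < 4 bands -> not flagged
  A[stats_bands[10:12], 3] <- 50
  spec <- structure(list(A = A, frame_start_times = (0:3) * p$hop / p$fs,
                         band_lo_freqs = (0:511) * p$band_width, params = p),
                    class = "usv_spectrogram")
  fl <- flag_frames(spec, prof_lin)

  expect_equal(fl$mu[2], (121 * 1 + 5 * 50) / 126, tolerance = 1e-12)
  expect_equal(fl$sigma[2], sd(c(rep(1, 121), rep(50, 5))), tolerance = 1e-12)
  expect_identical(fl$n_exceeding, c(0L, 5L, 3L, 0L))
  expect_identical(fl$flagged, c(FALSE, TRUE, FALSE, FALSE))

  # constant frame: sigma = 0, strict inequality -> nothing exceeds
  expect_identical(fl$n_exceeding[1], 0L)

  # same construction is flagged identically on the dB scale
  fl_db <- flag_frames(spec, detector_profile("usv50"))
  expect_identical(fl_db$flagged, fl$flagged)

  # stats range narrower than two bands is refused
  prof_narrow <- detector_profile("usv50", stats_lo = 50060, stats_hi = 50062)
  expect_error(flag_frames(spec, prof_narrow), "too narrow")
})

test_that("flag grouping obeys the gap and minimum-frame rules", {
  prof <- detector_profile("usv50")
  hop_s <- 102.4 / 250000

  d1 <- group_flags(flags_at(0:19, 60), prof, hop_s)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$n_flagged_frames, 20L)
  expect_equal(d1$onset_s, 0)
  expect_equal(d1$offset_s, 19 * hop_s + hop_s)

  # two runs of 10 separated by ~50 ms: two groups, both below 16 frames
  gap50 <- round(0.050 / hop_s)
  d2 <- group_flags(flags_at(c(0:9, gap50 + 9 + 0:9), 600), prof, hop_s)
  expect_equal(nrow(d2), 0)

  # two runs of 12 separated by ~30 ms chain into one group of 24
  gap30 <- round(0.030 / hop_s)
  d3 <- group_flags(flags_at(c(0:11, gap30 + 11 + 0:11), 600), prof, hop_s)
  expect_equal(nrow(d3), 1)
  expect_equal(d3$n_flagged_frames, 24L)

  expect_equal(nrow(group_flags(flags_at(integer(), 10), prof, hop_s)), 0)
})

test_that("grouping agrees with an exhaustive partition-enumeration oracle", {
  prof <- detector_profile("usv50", min_frames = 1, min_dur_ms = 1e-9)
  hop_s <- 102.4 / 250000
  set.seed(21)
  for (rep in 1:30) {
    n_frames <- sample(20:50, 1)
    flag_idx <- sort(sample(0:(n_frames - 1), sample(1:12, 1)))
    fl <- flags_at(flag_idx, n_frames, hop_s)
    # spread some flags far apart to exercise the gap rule
    fl$time_s <- fl$time_s * sample(c(1, 40, 120), 1)
    got <- group_flags(fl, prof, hop_s)
    oracle <- brute_force_groups(fl$time_s[fl$flagged], prof$max_gap_ms / 1000)
    expect_equal(nrow(got), length(oracle))
    expect_equal(got$onset_s, vapply(oracle, function(b) b[1], numeric(1)),
                 ignore_attr = TRUE)
    expect_equal(got$n_flagged_frames, lengths(oracle),
                 ignore_attr = TRUE)
  }
})

test_that("the 6.6 ms duration filter removes 16-frame groups but keeps 17", {
  prof <- detector_profile("usv50")
  hop_s <- 102.4 / 250000
  d16 <- group_flags(flags_at(0:15, 40), prof, hop_s)   # 16 x 0.4096 = 6.55 ms
  expect_equal(nrow(d16), 1)
  expect_equal(nrow(filter_min_duration(d16, prof)), 0)

  d17 <- group_flags(flags_at(0:16, 40), prof, hop_s)   # 17 x 0.4096 = 6.96 ms
  expect_equal(nrow(filter_min_duration(d17, prof)), 1)

  d_long <- group_flags(flags_at(0:48, 60), prof, hop_s)  # ~20 ms
  expect_equal(nrow(filter_min_duration(d_long, prof)), 1)
  expect_equal(nrow(filter_min_duration(d16[0, ], prof)), 0)
})

test_that("merging takes interval unions, dedupes, and refuses mixed classes", {
  det <- function(on, off, cls = "usv50", n = 20L) {
    tibble::tibble(recording_id = "r", call_class = cls, onset_s = on,
                   offset_s = off, duration_ms = (off - on) * 1000,
                   n_flagged_frames = n, source = "pass1")
  }
  m1 <- merge_detections(rbind(det(0.10, 0.15, n = 20L), det(0.14, 0.20, n = 30L)))
  expect_equal(nrow(m1), 1)
  expect_equal(c(m1$onset_s, m1$offset_s), c(0.10, 0.20))
  expect_equal(m1$n_flagged_frames, 30L)

  m2 <- merge_detections(rbind(det(0.1, 0.15), det(0.1, 0.15)))
  expect_equal(nrow(m2), 1)

  m3 <- merge_detections(rbind(det(0.10, 0.15), det(0.20, 0.25)))
  expect_equal(nrow(m3), 2)

  # abutting intervals connect
  m4 <- merge_detections(rbind(det(0.1, 0.2), det(0.2, 0.3)))
  expect_equal(nrow(m4), 1)

  expect_error(merge_detections(rbind(det(0, 1), det(2, 3, cls = "usv22"))),
               "across classes")
})

test_that("silence yields no detections and detection is exactly gain-invariant", {
  silent <- audio_recording(numeric(250000), fs = 250000)
  expect_equal(nrow(detect_recording(silent)), 0)

  s <- small_synth(seed = 3)
  base <- detect_recording(s$recording)
  expect_gt(nrow(base), 0)
  for (gain in c(2, 0.5, 10)) {
    scaled <- audio_recording(gain * s$recording$samples, s$recording$fs)
    expect_equal(detect_recording(scaled)[, c("onset_s", "offset_s", "n_flagged_frames")],
                 base[, c("onset_s", "offset_s", "n_flagged_frames")])
  }
})

test_that("detections are sorted, disjoint, and satisfy the duration/frame minima", {
  prof <- detector_profile("usv50")
  for (seed in c(3, 9)) {
    s <- small_synth(seed = seed, n_calls = 8, duration_s = 5)
    d <- detect_recording(s$recording)
    expect_false(is.unsorted(d$onset_s))
    if (nrow(d) > 1) expect_true(all(d$onset_s[-1] > d$offset_s[-nrow(d)]))
    expect_true(all(d$duration_ms >= prof$min_dur_ms))
    expect_true(all(d$n_flagged_frames >= prof$min_frames))
  }
})

test_that("high-SNR calls are recovered one-for-one, including across window edges", {
  s <- small_synth(seed = 3, n_calls = 8, duration_s = 5, snr_db_range = c(20, 30))
  d <- detect_recording(s$recording)
  ev <- evaluate_detections(d, s$truth)
  expect_equal(ev$n_matched, 8)
  expect_equal(ev$recall, 1)

  # a call spanning the pass-1 segment edge at 0.5 s -> one detection, not two
  calls <- call_spec("trill", f0 = 55000, duration_s = 0.020, onset_s = 0.495,
                     snr_db = 25, fm_depth = 4000, fm_rate = 60)
  plan <- recording_plan(duration_s = 1.5, calls = calls, seed = 5)
  sb <- synth_recording(plan)
  db <- detect_recording(sb$recording)
  expect_equal(nrow(db), 1)
  expect_lt(db$onset_s, 0.5)
  expect_gt(db$offset_s, 0.5)
})

test_that("the 22-kHz profile detects long narrowband calls", {
  calls <- call_spec("long22", f0 = c(22000, 23500), duration_s = c(0.5, 0.8),
                     onset_s = c(0.3, 1.5), snr_db = 25,
                     sweep_rate = c(300, -200))
  plan <- recording_plan(duration_s = 3, call_class = "usv22", calls = calls,
                         noise_sigma = 0, seed = 2)
  s <- synth_recording(plan)
  d <- detect_recording(s$recording, detector_profile("usv22"))
  ev <- evaluate_detections(d, s$truth)
  expect_equal(ev$n_matched, 2)
})

test_that("linear-scale statistics flag stationary noise frames often (documented degeneracy)", {
  plan <- recording_plan(duration_s = 0.5, n_calls = 0, seed = 8)
  s <- synth_recording(plan)
  sp <- stft_spectrogram(s$recording$samples, stft_params())
  frac_linear <- mean(flag_frames(sp, detector_profile("usv50", amplitude_scale = "linear"))$flagged)
  frac_db <- mean(flag_frames(sp, detector_profile("usv50"))$flagged)
  expect_gt(frac_linear, 0.2)   # the linear threshold sits inside the noise bulk
  expect_lt(frac_db, 0.01)      # the dB threshold sits far above the floor
})
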