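test_that("resampling scales length and annotation indices", {
  rec <- ecg_record(sin(2 * pi * 2 * seq(0, 10 - 1 / 360, by = 1 / 360)), 360)
  out <- resample_record(rec, 256)
  expect_equal(out$sampling_rate, 256)
  expect_equal(length(out$signal), 2560)
  # identity at the same rate
  same <- resample_record(rec, 360)
  expect_identical(same$signal, rec$signal)
  # annotation rescaling
  ann <- beat_annotations(c(360L, 720L), c("N", "N"))
  res <- resample_record(rec, 64, ann)
  expect_equal(res$annotations$sample_index, c(64L, 128L))
})

test_that("downsampling preserves passband amplitude within 1%", {
  rec <- sine_record(5, fs = 256, dur = 10)
  out <- resample_record(rec, 64)
  mid <- out$signal[round(length(out$signal) * 0.25):
                      round(length(out$signal) * 0.75)]
  expect_equal(max(mid), 1, tolerance = 0.01)
  expect_equal(rms(mid), 1 / sqrt(2), tolerance = 0.01)
})

test_that("loose-contact exclusion finds sustained sub-zero windows", {
  g <- clean_record()
  fs <- g$record$sampling_rate
  noisy <- add_noise(g$record, noise_spec("loose_contact", 0.4, 10, 20),
                     seed = 4)
  exc <- exclude_loose_contact(noisy, g$annotations)
  expect_equal(nrow(exc$intervals), 1)
  expect_equal(exc$intervals$start_s, 10, tolerance = 0.2)
  expect_equal(exc$intervals$end_s, 20, tolerance = 0.2)
  in_window <- g$annotations$sample_index / fs >= 10 &
    g$annotations$sample_index / fs < 20
  expect_equal(exc$n_dropped, sum(in_window))
  expect_equal(nrow(exc$annotations), nrow(g$annotations) - sum(in_window))
})

test_that("exclusion degenerate cases behave", {
  pos <- ecg_record(abs(sin(seq(0, 20, by = 1 / 128))) + 0.01, 128)
  expect_equal(nrow(exclude_loose_contact(pos)$intervals), 0)
  neg <- ecg_record(rep(-0.5, 128 * 5), 128)
  exc <- exclude_loose_contact(neg, beat_annotations(c(10L, 300L),
                                                     c("N", "N")))
  expect_equal(nrow(exc$intervals), 1)
  expect_equal(exc$intervals$start_s, 0)
  expect_equal(exc$intervals$end_s, 5)
  expect_equal(nrow(exc$annotations), 0)
})

test_that("bandpass attenuates 60 Hz and DC but passes 10 Hz", {
  in60 <- sine_record(60, fs = 256, dur = 8)
  out60 <- bandpass(in60)
  expect_lte(rms(out60$signal) / rms(in60$signal), 0.10)
  # DC settles toward zero away from the filter's edge transients (the
  # 0.5 Hz corner has a multi-second time constant)
  dc <- ecg_record(rep(1, 256 * 20), 256)
  mid_dc <- bandpass(dc)$signal[2000:3200]
  expect_lt(max(abs(mid_dc)), 0.02)
  in10 <- sine_record(10, fs = 256, dur = 8)
  out10 <- bandpass(in10)
  mid <- 500:1500
  expect_equal(rms(out10$signal[mid]) / rms(in10$signal[mid]), 1,
               tolerance = 0.05)
})

test_that("infeasible cutoffs are rejected", {
  rec <- sine_record(5, fs = 64, dur = 4)
  expect_error(bandpass(rec), "Nyquist")
})

test_that("R-peak detection recovers annotated beats on clean records", {
  g <- clean_record()
  filt <- bandpass(g$record)
  peaks <- detect_r_peaks(filt)
  tol <- 0.04 * 256
  dist <- vapply(g$annotations$sample_index,
                 function(a) min(abs(peaks - a)), numeric(1))
  expect_gte(mean(dist <= tol), 0.99)
  false_det <- sum(vapply(peaks, function(p)
    min(abs(g$annotations$sample_index - p)), numeric(1)) > tol)
  expect_lte(false_det / length(peaks), 0.01)
})

test_that("R-peak detection is robust to moderate AC interference", {
  g <- clean_record()
  noisy <- add_noise(g$record, noise_spec("ac_60hz", 0.2, 0, 59), seed = 6)
  peaks <- detect_r_peaks(bandpass(noisy))
  tol <- 0.04 * 256
  dist <- vapply(g$annotations$sample_index,
                 function(a) min(abs(peaks - a)), numeric(1))
  expect_gte(mean(dist <= tol), 0.97)
})

test_that("degenerate detector inputs give empty results", {
  expect_length(detect_r_peaks(ecg_record(numeric(256 * 5), 256)), 0)
  expect_length(detect_r_peaks(ecg_record(numeric(10), 256)), 0)
})

test_that("bandpass is zero-phase: peak positions move at most 1 sample", {
  g <- clean_record()
  x <- g$record$signal
  filt <- bandpass(g$record)$signal
  for (i0 in g$annotations$sample_index) {
    w <- max(1L, i0 - 10L):min(length(x), i0 + 12L)
    raw_pk <- w[which.max(x[w])]
    fil_pk <- w[which.max(filt[w])]
    expect_lte(abs(raw_pk - fil_pk), 1L)
  }
})

test_that("3-beat segmentation emits one segment per interior peak", {
  g <- clean_record()
  peaks <- g$annotations$sample_index
  segs <- segment_3beat(g$record, peaks, g$annotations$aami_class)
  expect_length(segs, length(peaks) - 2L)
  expect_length(segment_3beat(g$record, peaks[1:2]), 0L)
  # each segment holds exactly its 3 peaks, strictly increasing
  for (s in segs[c(1, 10, length(segs))]) {
    expect_length(s$r_peak_indices, 3L)
    expect_true(all(diff(s$r_peak_indices) > 0))
    expect_true(all(s$r_peak_indices >= 0 &
                      s$r_peak_indices < length(s$samples)))
  }
})

test_that("constant-RR records yield constant segment lengths", {
  fs <- 256
  rr <- round(60 / 80 * fs)            # 80 bpm
  peaks <- seq(2 * rr, 50 * rr, by = rr)
  rec <- ecg_record(numeric(60 * fs), fs)
  segs <- segment_3beat(rec, peaks)
  lens <- vapply(segs, function(s) length(s$samples), integer(1))
  expect_lte(diff(range(lens)), 1L)
  expect_equal(lens[[2]], 2.5 * rr + 1, tolerance = 1)
})

test_that("segment lengths scale inversely with heart rate", {
  mean_len <- function(bpm, seed) {
    g <- generate_record(synth_config(60, 256, bpm, seed = seed))
    segs <- segment_3beat(g$record, g$annotations$sample_index)
    mean(vapply(segs, function(s) length(s$samples), integer(1)))
  }
  expect_gt(mean_len(60, 5), 1.4 * mean_len(100, 5))
})

test_that("STFT grid has the contractual shape", {
  x <- stats::rnorm(256)
  sp <- stft_mag(x, window = 64, hop = 32)
  expect_equal(dim(sp), c(33, 7))
  expect_error(stft_mag(x[1:30], window = 64), "shorter")
  expect_true(all(stft_mag(numeric(256), 64, 32) == 0))
})

test_that("a pure tone lands in the right STFT bin", {
  fs <- 64
  x <- sin(2 * pi * 10 * seq(0, 4 - 1 / fs, by = 1 / fs))
  sp <- stft_mag(x, window = 32, hop = 8, log_magnitude = FALSE)
  bin_hz <- fs / 32
  peak_bin <- which.max(rowMeans(sp))
  expect_equal((peak_bin - 1) * bin_hz, 10, tolerance = bin_hz)
})

test_that("pipeline accounting reconciles every beat", {
  g <- mixed_record()
  noisy <- add_noise(g$record, noise_spec("loose_contact", 0.4, 30, 45),
                     seed = 8)
  noisy <- add_noise(noisy, noise_spec("baseline_wander", 0.15, 0, 200),
                     seed = 9)
  pp <- preprocess_record(noisy, g$annotations, target_rate = 64)
  acc <- pp$accounting
  expect_equal(acc[["total"]], nrow(g$annotations))
  expect_equal(acc[["centers"]] + acc[["boundary"]] + acc[["excluded"]],
               acc[["total"]])
  expect_gt(acc[["excluded"]], 0)
  expect_equal(nrow(pp$excluded_intervals), 1)
})
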