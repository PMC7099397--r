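# Shared fixtures, all generated in code (no stored data). Cached within a
# test run to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

# a clean all-N 60 s record at 256 Hz
clean_record <- function(seed = 3) {
  key <- paste0("clean", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_record(
      synth_config(60, 256, 80, seed = seed))
  .fixture_env[[key]]
}

# a 5-class mixed record
mixed_record <- function(seed = 11, duration = 240) {
  key <- paste0("mixed", seed, "_", duration)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_record(
      synth_config(duration, 256, 80,
                   class_mixture = c(N = 0.3, S = 0.2, V = 0.2,
                                     F = 0.15, Q = 0.15),
                   seed = seed))
  .fixture_env[[key]]
}

# small labeled spectrogram set for model tests
small_segments <- function(seed = 7) {
  key <- paste0("segs", seed)
  if (is.null(.fixture_env[[key]])) {
    g <- mixed_record(seed, duration = 300)
    pp <- preprocess_record(g$record, g$annotations, target_rate = 64)
    .fixture_env[[key]] <- list(
      x = lapply(pp$segments, `[[`, "spectrogram"),
      labels = vapply(pp$segments, `[[`, character(1),
                      "center_beat_class"))
  }
  .fixture_env[[key]]
}

# random small RNN weights
random_rnn_weights <- function(d, h, seed = 1, scale = 0.3) {
  set.seed(seed)
  list(Wx = matrix(stats::rnorm(d * h, 0, scale), d, h),
       Wh = matrix(stats::rnorm(h * h, 0, scale), h, h),
       b = stats::rnorm(h, 0, scale))
}

# sine-wave record helper
sine_record <- function(freq, fs = 256, dur = 10, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ecg_record(amp * sin(2 * pi * freq * t), fs)
}

rms <- function(x) sqrt(mean(x^2))
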