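#' Beat morphology template
#'
#' Parameters of the Gaussian-bump beat synthesis: a P wave, an R wave with
#' small opposite-sign flanking lobes (the Q and S deflections), and a T
#' wave. \code{prematurity_factor} multiplies the RR interval *preceding*
#' a beat of this class; supraventricular ectopics use values well below 1.
#'
#' @param aami_class one of "N","S","V","F","Q"
#' @param p_wave_amplitude P-wave peak amplitude, mV
#' @param qrs_amplitude R-wave peak amplitude, mV
#' @param qrs_width QRS full width at half maximum, seconds (> 0)
#' @param t_wave_amplitude T-wave peak amplitude, mV (sign allowed)
#' @param prematurity_factor multiplier on the preceding RR interval, in (0, 2]
#' @return a \code{beat_template} list
#' @export
beat_template <- function(aami_class, p_wave_amplitude, qrs_amplitude,
                          qrs_width, t_wave_amplitude,
                          prematurity_factor = 1) {
  stopifnot(aami_class %in% AAMI_CLASSES, qrs_width > 0,
            prematurity_factor > 0, prematurity_factor <= 2)
  structure(list(aami_class = aami_class,
                 p_wave_amplitude = p_wave_amplitude,
                 qrs_amplitude = qrs_amplitude,
                 qrs_width = qrs_width,
                 t_wave_amplitude = t_wave_amplitude,
                 prematurity_factor = prematurity_factor),
            class = "beat_template")
}

#' Default per-class beat templates
#'
#' Morphologies follow the textbook contrasts between the five AAMI
#' classes: N has a clear P wave and narrow QRS; S resembles N but arrives
#' early (short preceding RR); V has a wide QRS, no P wave, and a
#' discordant T; F is synthesized as the 0.5/0.5 convex combination of the
#' N and V waveforms; Q is a paced pattern (sharp pacing spike then a wide
#' QRS) with per-beat random distortion.
#'
#' @return named list of \code{\link{beat_template}}s
#' @export
default_beat_templates <- function() {
  list(
    N = beat_template("N", p_wave_amplitude = 0.15, qrs_amplitude = 1.00,
                      qrs_width = 0.08, t_wave_amplitude = 0.25,
                      prematurity_factor = 1.0),
    S = beat_template("S", p_wave_amplitude = 0.10, qrs_amplitude = 0.95,
                      qrs_width = 0.08, t_wave_amplitude = 0.20,
                      prematurity_factor = 0.60),
    V = beat_template("V", p_wave_amplitude = 0.00, qrs_amplitude = 1.40,
                      qrs_width = 0.16, t_wave_amplitude = -0.30,
                      prematurity_factor = 1.0),
    F = beat_template("F", p_wave_amplitude = 0.075, qrs_amplitude = 1.20,
                      qrs_width = 0.12, t_wave_amplitude = -0.025,
                      prematurity_factor = 1.0),
    Q = beat_template("Q", p_wave_amplitude = 0.00, qrs_amplitude = 1.05,
                      qrs_width = 0.14, t_wave_amplitude = 0.10,
                      prematurity_factor = 1.0))
}

#' Noise specification
#'
#' One of the six noise families seen on ambulatory single-lead recordings.
#' The noise is applied only on the half-open interval
#' \code{[onset, offset)} seconds.
#'
#' @param kind one of "loose_contact", "motion_artifact", "emg",
#'   "baseline_wander", "ac_50hz", "ac_60hz"
#' @param amplitude noise amplitude, mV (0 leaves the record unchanged)
#' @param onset,offset interval bounds in seconds, onset < offset
#' @param frequency optional Hz override (baseline wander must stay
#'   below 0.5 Hz; AC kinds are fixed at 50/60 Hz)
#' @return a \code{noise_spec} list
#' @export
noise_spec <- function(kind, amplitude, onset, offset, frequency = NULL) {
  kinds <- c("loose_contact", "motion_artifact", "emg", "baseline_wander",
             "ac_50hz", "ac_60hz")
  if (!kind %in% kinds)
    stopf("unknown noise kind '%s' (expected one of %s)", kind,
          paste(kinds, collapse = ", "))
  stopifnot(onset < offset, amplitude >= 0)
  if (kind == "baseline_wander" && !is.null(frequency) && frequency >= 0.5)
    stopf("baseline wander frequency must be below 0.5 Hz")
  structure(list(kind = kind, amplitude = amplitude, onset = onset,
                 offset = offset, frequency = frequency),
            class = "noise_spec")
}

#' Synthetic record configuration
#'
#' @param duration record length, seconds
#' @param sampling_rate Hz
#' @param mean_heart_rate beats per minute, in [30, 220]
#' @param class_mixture named probability vector over the AAMI classes,
#'   summing to 1
#' @param noise_specs list of \code{\link{noise_spec}}s applied after beat
#'   synthesis
#' @param seed integer seed governing all draws
#' @param rr_jitter coefficient of variation of the RR interval (default
#'   0.03, a quiet sinus rhythm)
#' @param templates per-class morphology templates
#' @return a \code{synth_config} list
#' @export
synth_config <- function(duration, sampling_rate = 256, mean_heart_rate = 80,
                         class_mixture = c(N = 1, S = 0, V = 0, F = 0, Q = 0),
                         noise_specs = list(), seed = 1, rr_jitter = 0.03,
                         templates = default_beat_templates()) {
  stopifnot(duration > 0, sampling_rate > 0)
  if (mean_heart_rate < 30 || mean_heart_rate > 220)
    stopf("mean_heart_rate %g outside [30, 220] bpm", mean_heart_rate)
  mix <- rep(0, 5); names(mix) <- AAMI_CLASSES
  mix[names(class_mixture)] <- class_mixture
  if (abs(sum(mix) - 1) > 1e-8) stopf("class_mixture must sum to 1")
  structure(list(duration = duration, sampling_rate = sampling_rate,
                 mean_heart_rate = mean_heart_rate, class_mixture = mix,
                 noise_specs = noise_specs, seed = as.integer(seed),
                 rr_jitter = rr_jitter, templates = templates),
            class = "synth_config")
}

# Render one beat's waveform onto the sample grid around its center time.
# The R wave is a Gaussian whose FWHM is the template's qrs_width, flanked
# by small opposite-sign Q/S lobes; argmax sits exactly on the R center.
render_beat <- function(signal, fs, tc, tpl) {
  half <- 0.45
  i0 <- max(1L, floor((tc - half) * fs) + 1L)
  i1 <- min(length(signal), ceiling((tc + half) * fs) + 1L)
  if (i0 > i1) return(signal)
  t <- (seq(i0, i1) - 1) / fs - tc
  sd_r <- tpl$qrs_width / 2.355
  w <- tpl$qrs_amplitude * exp(-t^2 / (2 * sd_r^2))
  # Q and S lobes, symmetric so the global max stays at t = 0
  w <- w - 0.15 * tpl$qrs_amplitude *
    (exp(-(t - 0.75 * tpl$qrs_width)^2 / (2 * (sd_r / 2)^2)) +
     exp(-(t + 0.75 * tpl$qrs_width)^2 / (2 * (sd_r / 2)^2)))
  if (tpl$p_wave_amplitude != 0)
    w <- w + tpl$p_wave_amplitude * exp(-(t + 0.17)^2 / (2 * 0.025^2))
  if (tpl$t_wave_amplitude != 0)
    w <- w + tpl$t_wave_amplitude * exp(-(t - 0.28)^2 / (2 * 0.05^2))
  signal[i0:i1] <- signal[i0:i1] + w
  signal
}

# Pacing-spike variant used for class Q, with per-beat distortion draws.
render_q_beat <- function(signal, fs, tc, seed_k) {
  set.seed(seed_k)
  tpl <- beat_template("Q",
                       p_wave_amplitude = 0,
                       qrs_amplitude = stats::runif(1, 0.9, 1.2),
                       qrs_width = stats::runif(1, 0.12, 0.17),
                       t_wave_amplitude = stats::runif(1, 0.0, 0.2))
  signal <- render_beat(signal, fs, tc, tpl)
  # sharp pacing spike ahead of the QRS; small relative to the R wave, as
  # on a filtered surface lead
  spike_amp <- stats::runif(1, 0.25, 0.45)
  i0 <- max(1L, floor((tc - 0.16) * fs) + 1L)
  i1 <- min(length(signal), ceiling((tc - 0.04) * fs) + 1L)
  t <- (seq(i0, i1) - 1) / fs - (tc - 0.10)
  signal[i0:i1] <- signal[i0:i1] + spike_amp * exp(-t^2 / (2 * 0.008^2))
  signal
}

#' Generate a seeded synthetic annotated ECG record
#'
#' Beats are laid out sequentially: each beat's class is drawn from the
#' configured mixture, its RR interval from the mean heart rate with
#' multiplicative jitter, shortened by the class's prematurity factor, and
#' followed by the corresponding compensatory pause. Each annotation's
#' \code{sample_index} is the sample nearest the R-wave center, which is
#' the arg-max of the beat's QRS deflection. Identical configurations
#' (including seed) produce bit-identical output.
#'
#' @param config a \code{\link{synth_config}}
#' @return list with \code{record} (an \code{\link{ecg_record}}) and
#'   \code{annotations} (a \code{\link{beat_annotations}} table)
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  rr_base <- 60 / config$mean_heart_rate
  if (config$duration < rr_base + 0.8)
    stopf("duration %.2f s too short for one beat at %g bpm",
          config$duration, config$mean_heart_rate)
  set.seed(config$seed)
  margin <- 0.4
  t_max <- config$duration - margin
  times <- numeric(0); classes <- character(0)
  t_cur <- margin
  prev_pf <- 1
  repeat {
    cls <- sample(AAMI_CLASSES, 1, prob = config$class_mixture)
    pf <- config$templates[[cls]]$prematurity_factor
    if (length(times) == 0L) {
      t_next <- t_cur
    } else {
      jit <- max(0.5, 1 + stats::rnorm(1, 0, config$rr_jitter))
      # prematurity shortens the preceding RR; the beat after an ectopic
      # gets the compensatory remainder (2 - pf) of the cycle
      gap <- rr_base * jit * pf * (2 - prev_pf)
      t_next <- t_cur + gap
    }
    if (t_next > t_max) break
    times <- c(times, t_next); classes <- c(classes, cls)
    t_cur <- t_next
    prev_pf <- pf
  }
  if (length(times) == 0L)
    stopf("duration too short for one beat")
  # snap centers to the sample grid so annotation index == waveform argmax
  idx <- round(times * fs)
  times <- idx / fs
  signal <- numeric(n)
  for (k in seq_along(times)) {
    cls <- classes[k]
    if (cls == "F") {
      sN <- render_beat(numeric(n), fs, times[k], config$templates$N)
      sV <- render_beat(numeric(n), fs, times[k], config$templates$V)
      signal <- signal + 0.5 * sN + 0.5 * sV
    } else if (cls == "Q") {
      signal <- render_q_beat(signal, fs, times[k],
                              child_seed(config$seed, k))
    } else {
      signal <- render_beat(signal, fs, times[k], config$templates[[cls]])
    }
  }
  symbols <- c(N = "N", S = "A", V = "V", F = "F", Q = "/")[classes]
  record <- ecg_record(signal, fs, subject_id = sprintf("synth%04d", config$seed))
  for (k in seq_along(config$noise_specs))
    record <- add_noise(record, config$noise_specs[[k]],
                        seed = child_seed(config$seed, 999000L + k))
  ann <- beat_annotations(idx, symbols, aami_class = classes,
                          signal_length = n)
  list(record = record, annotations = ann)
}

#' Add a noise interval to a record
#'
#' The signal outside \code{[onset, offset)} is untouched. Loose contact
#' replaces the interval with a sub-zero drifting floor; the AC kinds add a
#' pure 50/60 Hz sinusoid; baseline wander adds a sub-0.5 Hz sinusoid; emg
#' adds band-limited (20 Hz-0.45 fs) noise scaled to the requested RMS;
#' motion artifact adds smooth transient step excursions.
#'
#' @param record an \code{\link{ecg_record}}
#' @param spec a \code{\link{noise_spec}}
#' @param seed integer seed for the stochastic kinds
#' @return the noisy \code{\link{ecg_record}}
#' @export
add_noise <- function(record, spec, seed = 1) {
  stopifnot(inherits(record, "ecg_record"), inherits(spec, "noise_spec"))
  fs <- record$sampling_rate
  dur <- duration(record)
  if (spec$onset < 0 || spec$offset > dur + 1e-9)
    stopf("noise interval [%g, %g) outside record duration %g s",
          spec$onset, spec$offset, dur)
  if (spec$amplitude == 0) return(record)
  tt <- (seq_along(record$signal) - 1) / fs
  sel <- which(tt >= spec$onset & tt < spec$offset)
  if (length(sel) == 0L) return(record)
  t_rel <- tt[sel] - spec$onset
  set.seed(seed)
  x <- record$signal
  if (spec$kind == "loose_contact") {
    drift <- 0.3 * sin(2 * pi * 0.1 * t_rel + stats::runif(1, 0, 2 * pi))
    x[sel] <- -spec$amplitude * (0.7 + drift) -
      abs(stats::rnorm(length(sel), 0, 0.02 * spec$amplitude)) - 1e-4
  } else if (spec$kind %in% c("ac_50hz", "ac_60hz")) {
    f <- if (spec$kind == "ac_50hz") 50 else 60
    x[sel] <- x[sel] + spec$amplitude * sin(2 * pi * f * t_rel)
  } else if (spec$kind == "baseline_wander") {
    f <- spec$frequency %||% 0.25
    x[sel] <- x[sel] + spec$amplitude *
      sin(2 * pi * f * t_rel + stats::runif(1, 0, 2 * pi))
  } else if (spec$kind == "emg") {
    w <- stats::rnorm(length(sel))
    hi <- min(0.45 * fs, 0.9 * fs / 2) / (fs / 2)
    lo <- min(20 / (fs / 2), hi * 0.5)
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    w <- signal::filtfilt(bf, w)
    w <- w / max(stats::sd(w), 1e-12) * spec$amplitude
    x[sel] <- x[sel] + w
  } else if (spec$kind == "motion_artifact") {
    n_ev <- sample(1:3, 1)
    bump <- numeric(length(sel))
    span <- max(t_rel)
    for (e in seq_len(n_ev)) {
      c0 <- stats::runif(1, 0, span)
      wdt <- stats::runif(1, 0.2, min(1.5, span / 2 + 0.2))
      amp <- spec$amplitude * stats::runif(1, 0.5, 1) * sample(c(-1, 1), 1)
      bump <- bump + amp / (1 + ((t_rel - c0) / wdt)^4)  # smooth transient
    }
    x[sel] <- x[sel] + bump
  }
  record$signal <- x
  record
}
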