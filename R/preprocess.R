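#' Bandpass filter specification
#'
#' @param low_cutoff low -3 dB edge, Hz (default 0.5)
#' @param high_cutoff high -3 dB edge, Hz (default 40)
#' @param order Butterworth order (default 4); applied forward-backward, so
#'   the effective magnitude response is the square of a single pass
#' @return a \code{filter_spec} list
#' @export
filter_spec <- function(low_cutoff = 0.5, high_cutoff = 40, order = 4) {
  stopifnot(low_cutoff > 0, high_cutoff > low_cutoff, order >= 1)
  structure(list(low_cutoff = low_cutoff, high_cutoff = high_cutoff,
                 order = order, family = "butterworth"),
            class = "filter_spec")
}

#' Resample a record to a target rate
#'
#' Downsampling first applies a zero-phase Butterworth anti-alias low-pass
#' at 0.45 of the target rate, then evaluates the signal on the new sample
#' grid by linear interpolation. Annotation indices are rescaled by
#' \code{target_rate / source_rate} and rounded to the nearest sample.
#' Upsampling is permitted (interpolation only) but flagged with a message
#' since it adds no information.
#'
#' @param record an \code{\link{ecg_record}}
#' @param target_rate Hz, positive
#' @param annotations optional \code{\link{beat_annotations}} to rescale
#' @return the resampled record, or (when annotations are given) a list
#'   \code{(record, annotations)}
#' @export
resample_record <- function(record, target_rate, annotations = NULL) {
  stopifnot(inherits(record, "ecg_record"), target_rate > 0)
  src <- record$sampling_rate
  n_out <- round(length(record$signal) * target_rate / src)
  if (target_rate == src) {
    out <- record
  } else {
    x <- record$signal
    if (target_rate < src) {
      bf <- signal::butter(6, 0.45 * target_rate / (src / 2), type = "low")
      x <- signal::filtfilt(bf, x)
    } else {
      message(sprintf("upsampling %g -> %g Hz adds no information", src,
                      target_rate))
    }
    t_src <- (seq_along(x) - 1) / src
    t_new <- (seq_len(n_out) - 1) / target_rate
    x_new <- stats::approx(t_src, x, xout = pmin(t_new, max(t_src)),
                           rule = 2)$y
    out <- ecg_record(x_new, target_rate, record$subject_id,
                      record$lead_label)
  }
  if (is.null(annotations)) return(out)
  ann <- annotations
  ann$sample_index <- pmin(as.integer(round(ann$sample_index *
                                            target_rate / src)),
                           length(out$signal) - 1L)
  list(record = out, annotations = ann)
}

#' Mark sustained sub-zero (loose contact) intervals
#'
#' An electrode losing contact produces a sustained signal floor below
#' 0 mV. Maximal runs of at least \code{min_duration} seconds in which
#' every sample is below 0 mV are marked for exclusion; beats annotated
#' inside them are dropped. A literal single-sample rule would delete
#' ordinary ECG (which oscillates below baseline), hence the sustained-run
#' interpretation.
#'
#' @param record an \code{\link{ecg_record}}
#' @param annotations optional \code{\link{beat_annotations}}
#' @param min_duration minimum run length in seconds (default 1)
#' @return list with \code{record} (unchanged), \code{intervals}
#'   (data.frame \code{start_s,end_s,start_index,end_index}, half-open),
#'   \code{annotations} (surviving beats), \code{n_dropped}
#' @export
exclude_loose_contact <- function(record, annotations = NULL,
                                  min_duration = 1) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate
  below <- record$signal < 0
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration * fs
  intervals <- data.frame(
    start_index = starts[keep] - 1L,           # 0-based, half-open
    end_index = ends[keep],
    start_s = (starts[keep] - 1L) / fs,
    end_s = ends[keep] / fs)
  n_dropped <- 0L
  if (!is.null(annotations) && nrow(intervals) > 0L && nrow(annotations)) {
    inside <- rep(FALSE, nrow(annotations))
    for (k in seq_len(nrow(intervals)))
      inside <- inside | (annotations$sample_index >= intervals$start_index[k] &
                          annotations$sample_index < intervals$end_index[k])
    n_dropped <- sum(inside)
    annotations <- annotations[!inside, , drop = FALSE]
  }
  list(record = record, intervals = intervals, annotations = annotations,
       n_dropped = n_dropped)
}

#' Zero-phase bandpass filter
#'
#' Butterworth design at the spec's cutoffs, applied forward-backward
#' (\code{signal::filtfilt}) so the group delay is zero and R-peak
#' positions are preserved.
#'
#' @param record an \code{\link{ecg_record}}
#' @param spec a \code{\link{filter_spec}} (default 0.5-40 Hz, order 4)
#' @return the filtered \code{\link{ecg_record}}, same length
#' @export
bandpass <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "ecg_record"), inherits(spec, "filter_spec"))
  nyq <- record$sampling_rate / 2
  if (spec$high_cutoff >= nyq)
    stopf("high cutoff %g Hz not below Nyquist %g Hz", spec$high_cutoff, nyq)
  bf <- signal::butter(spec$order,
                       c(spec$low_cutoff, spec$high_cutoff) / nyq,
                       type = "pass")
  record$signal <- signal::filtfilt(bf, record$signal)
  record
}

# O(n) running maximum over trailing windows via non-overlapping block
# maxima; adequate for an adaptive detection threshold.
block_max_envelope <- function(x, block) {
  nb <- ceiling(length(x) / block)
  pad <- nb * block - length(x)
  m <- matrix(c(x, rep(-Inf, pad)), nrow = block)
  bm <- apply(m, 2, max)
  # each sample sees the max of its own and the two neighboring blocks
  bm2 <- pmax(bm, c(bm[-1], bm[nb]), c(bm[1], bm[-nb]))
  rep(bm2, each = block)[seq_along(x)]
}

#' Detect R peaks
#'
#' A derivative-energy detector in the Pan-Tompkins tradition, applied to
#' an already bandpassed signal: Gaussian-smoothed differentiation,
#' squaring, 150 ms moving-window integration, an adaptive threshold (a
#' fraction of the local energy envelope), refractory suppression, then
#' refinement to the local maximum of the input signal within +-50 ms.
#'
#' @param record an \code{\link{ecg_record}}, already bandpassed
#' @param refractory minimum peak spacing, seconds (default 0.2)
#' @param threshold_frac fraction of the local energy envelope a candidate
#'   must exceed (default 0.2)
#' @return integer vector of strictly increasing 0-based sample indices
#' @export
detect_r_peaks <- function(record, refractory = 0.2, threshold_frac = 0.2) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate
  x <- record$signal
  if (length(x) < fs) return(integer(0))
  # smoothed derivative: derivative-of-Gaussian kernel, sd ~ 10 ms
  sd_s <- max(2, round(0.01 * fs))
  kt <- seq(-3 * sd_s, 3 * sd_s)
  kern <- -kt * exp(-kt^2 / (2 * sd_s^2))
  kern <- kern / sum(abs(kern)) * 2
  d <- stats::filter(x, kern, sides = 2)
  d[is.na(d)] <- 0
  e <- as.numeric(d)^2
  w <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(e, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  env <- block_max_envelope(integ, block = 2L * fs)
  if (max(env) <= 0) return(integer(0))
  thr <- pmax(threshold_frac * env, 1e-3 * max(integ))
  above <- integ > thr
  if (!any(above)) return(integer(0))
  runs <- rle(above)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  cand <- mapply(function(s, e) s - 1L + which.max(integ[s:e]),
                 starts[runs$values], ends[runs$values])
  # refine to local max of the bandpassed signal within +-50 ms
  hw <- round(0.05 * fs)
  refine <- function(c0) {
    lo <- max(1L, c0 - hw); hi <- min(length(x), c0 + hw)
    as.integer(lo - 1L + which.max(x[lo:hi]))
  }
  peaks <- vapply(as.integer(cand), refine, integer(1))
  peaks <- sort(unique(peaks))
  # refractory suppression: keep the larger of two close peaks
  min_gap <- round(refractory * fs)
  keep <- logical(length(peaks))
  last <- -Inf; last_i <- 0L
  for (i in seq_along(peaks)) {
    if (peaks[i] - last >= min_gap) {
      keep[i] <- TRUE; last <- peaks[i]; last_i <- i
    } else if (x[peaks[i]] > x[peaks[last_i]]) {
      keep[last_i] <- FALSE; keep[i] <- TRUE
      last <- peaks[i]; last_i <- i
    }
  }
  as.integer(peaks[keep] - 1L)   # 0-based
}

#' Cut three-beat segments around interior peaks
#'
#' For each interior peak i (second through next-to-last), the segment
#' spans \code{[p[i-1] - 0.25 RR_left, p[i+1] + 0.25 RR_right)} where
#' \code{RR_left = p[i] - p[i-1]} and \code{RR_right = p[i+1] - p[i]},
#' clipped to the record. This guarantees all three QRS complexes and
#' their flanking P/T waves are inside the window while the length tracks
#' the local heart rate.
#'
#' @param record an \code{\link{ecg_record}}
#' @param peaks strictly increasing 0-based R-peak indices
#' @param labels AAMI class per peak (the middle beat's label becomes the
#'   segment label); optional
#' @param margin_frac flank margin as a fraction of the adjacent RR
#'   interval (default 0.25)
#' @return list of \code{beat_segment}s: \code{samples},
#'   \code{r_peak_indices} (segment-relative, 0-based),
#'   \code{center_beat_class}, \code{subject_id}, \code{start_index}
#' @export
segment_3beat <- function(record, peaks, labels = NULL, margin_frac = 0.25) {
  stopifnot(inherits(record, "ecg_record"))
  peaks <- as.integer(peaks)
  if (is.unsorted(peaks, strictly = TRUE))
    stopf("peaks must be strictly increasing")
  if (!is.null(labels) && length(labels) != length(peaks))
    stopf("labels must align with peaks")
  K <- length(peaks)
  if (K < 3L) return(list())
  n <- length(record$signal)
  segs <- vector("list", K - 2L)
  for (i in 2:(K - 1)) {
    rr_l <- peaks[i] - peaks[i - 1]
    rr_r <- peaks[i + 1] - peaks[i]
    start <- max(0L, as.integer(peaks[i - 1] - round(margin_frac * rr_l)))
    end <- min(n, as.integer(peaks[i + 1] + round(margin_frac * rr_r)) + 1L)
    segs[[i - 1L]] <- structure(
      list(samples = record$signal[(start + 1L):end],
           r_peak_indices = peaks[(i - 1):(i + 1)] - start,
           center_beat_class = if (is.null(labels)) NA_character_
                               else labels[i],
           subject_id = record$subject_id,
           start_index = start),
      class = "beat_segment")
  }
  segs
}

#' Short-time Fourier transform magnitude grid
#'
#' Hann-tapered frames of \code{window} samples every \code{hop} samples;
#' frame count is \code{floor((length - window)/hop) + 1} and the grid has
#' \code{window/2 + 1} frequency rows. Log magnitude (\code{log1p}) is the
#' default feature scale fed to the classifier.
#'
#' @param x numeric vector (a segment's samples)
#' @param window frame length in samples (even)
#' @param hop hop size in samples
#' @param log_magnitude apply \code{log1p} to the magnitudes (default TRUE)
#' @return matrix of dimension \code{(window/2 + 1) x n_frames}
#' @export
stft_mag <- function(x, window = 32, hop = 8, log_magnitude = TRUE) {
  if (window %% 2 != 0) stopf("window length must be even")
  if (length(x) < window)
    stopf("segment of %d samples shorter than STFT window %d", length(x),
          window)
  n_frames <- (length(x) - window) %/% hop + 1L
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, window - 1) / window)  # Hann
  n_bins <- window %/% 2 + 1L
  out <- matrix(0, n_bins, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- x[((f - 1L) * hop + 1L):((f - 1L) * hop + window)] * taper
    sp <- stats::fft(seg)[seq_len(n_bins)]
    out[, f] <- Mod(sp)
  }
  if (log_magnitude) out <- log1p(out)
  out
}

#' Default STFT parameters per sampling rate
#'
#' 0.5 s windows with 1/4-window hops: 32/8 samples at 64 Hz, scaled x4
#' (128/32) at 256 Hz.
#'
#' @param sampling_rate Hz
#' @return list \code{(window, hop)}
#' @export
stft_params <- function(sampling_rate) {
  w <- max(8L, as.integer(2^round(log2(sampling_rate / 2))))
  list(window = w, hop = max(2L, w %/% 4L))
}

#' Run the full preprocessing pipeline on one record
#'
#' Resampling to \code{base_rate}, loose-contact exclusion, zero-phase
#' bandpass (applied at \code{base_rate}, where the 40 Hz cutoff is below
#' Nyquist), optional further downsampling to \code{target_rate}, R-peak
#' determination, three-beat segmentation, and STFT.
#' When annotations are supplied, peaks are taken from them (paired and
#' cross-checked against the detector if \code{detect = TRUE}) so segment
#' labels are exact; otherwise peaks come from the detector and labels are
#' NA. The returned accounting reconciles every input beat: center of one
#' segment, boundary beat, or dropped in an excluded interval.
#'
#' @param record an \code{\link{ecg_record}}
#' @param annotations optional \code{\link{beat_annotations}}
#' @param target_rate final rate for segmentation and STFT, Hz (default
#'   64, the lightweight pipeline; use 256 for the baseline)
#' @param base_rate rate at which exclusion and filtering run (default
#'   256)
#' @param spec bandpass \code{\link{filter_spec}}
#' @param detect also run the R-peak detector (default FALSE when
#'   annotations are given)
#' @param min_loose_contact seconds, see
#'   \code{\link{exclude_loose_contact}}
#' @return list with \code{segments} (each with a \code{spectrogram}),
#'   \code{excluded_intervals}, \code{accounting} (named counts:
#'   \code{total, centers, boundary, excluded}), \code{stft}
#'   (window/hop used)
#' @export
preprocess_record <- function(record, annotations = NULL, target_rate = 64,
                              base_rate = 256, spec = filter_spec(),
                              detect = is.null(annotations),
                              min_loose_contact = 1) {
  if (record$sampling_rate != base_rate) {
    res <- resample_record(record, base_rate, annotations)
    if (is.null(annotations)) { rec <- res; ann <- NULL }
    else { rec <- res$record; ann <- res$annotations }
  } else {
    rec <- record; ann <- annotations
  }
  exc <- exclude_loose_contact(rec, ann, min_duration = min_loose_contact)
  ann <- exc$annotations
  filt <- bandpass(rec, spec)
  if (target_rate != base_rate) {
    res <- resample_record(filt, target_rate, ann)
    if (is.null(ann)) filt <- res
    else { filt <- res$record; ann <- res$annotations }
  }
  if (!is.null(ann)) {
    peaks <- ann$sample_index
    labels <- ann$aami_class
    if (detect) {
      det <- detect_r_peaks(filt)
      attr(peaks, "detected") <- det
    }
  } else {
    peaks <- detect_r_peaks(filt)
    labels <- NULL
  }
  segs <- segment_3beat(filt, peaks, labels)
  sp <- stft_params(target_rate)
  segs <- lapply(segs, function(s) {
    if (length(s$samples) >= sp$window)
      s$spectrogram <- stft_mag(s$samples, sp$window, sp$hop)
    s
  })
  segs <- Filter(function(s) !is.null(s$spectrogram), segs)
  n_total <- if (!is.null(annotations)) nrow(annotations) else length(peaks)
  n_exc <- exc$n_dropped
  n_cent <- length(segs)
  list(segments = segs,
       excluded_intervals = exc$intervals,
       accounting = c(total = n_total, centers = n_cent,
                      boundary = max(0L, n_total - n_exc - n_cent),
                      excluded = n_exc),
       stft = sp)
}
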