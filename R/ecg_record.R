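#' Construct an ECG record
#'
#' A single-lead voltage series with its sampling rate and subject metadata.
#' Sample indices are 0-based throughout the package and interval spans are
#' half-open \code{[start, end)}.
#'
#' @param signal numeric vector of voltage samples, in millivolts
#' @param sampling_rate samples per second (Hz), positive
#' @param subject_id subject identifier string
#' @param lead_label free-text lead description (e.g. "MLII", "v2-v5 patch")
#' @return an object of class \code{ecg_record} with fields \code{signal},
#'   \code{sampling_rate}, \code{subject_id}, \code{lead_label}
#' @export
#' @examples
#' rec <- ecg_record(sin(2 * pi * 1 * seq(0, 5, by = 1/256)), 256, "demo")
#' duration(rec)
ecg_record <- function(signal, sampling_rate, subject_id = "unknown",
                       lead_label = "lead-I") {
  if (!is.numeric(signal) || length(signal) < 1L)
    stopf("signal must be a non-empty numeric vector")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stopf("sampling_rate must be a single positive number")
  structure(
    list(signal = as.numeric(signal),
         sampling_rate = as.numeric(sampling_rate),
         subject_id = as.character(subject_id),
         lead_label = as.character(lead_label)),
    class = "ecg_record")
}

#' Record duration in seconds
#' @param record an \code{ecg_record}
#' @return duration = length(signal) / sampling_rate, in seconds
#' @export
duration <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  length(record$signal) / record$sampling_rate
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> subject %s, lead %s\n", x$subject_id, x$lead_label))
  cat(sprintf("  %d samples @ %g Hz (%.2f s), range [%.3f, %.3f] mV\n",
              length(x$signal), x$sampling_rate, duration(x),
              min(x$signal), max(x$signal)))
  invisible(x)
}

#' Construct a beat-annotation table
#'
#' Each row marks one beat: its R-peak sample index (0-based), the original
#' annotation symbol, and the AAMI class the symbol maps to.
#'
#' @param sample_index integer vector of 0-based R-peak positions
#' @param symbol single-character source annotation codes
#' @param aami_class optional AAMI classes; derived from \code{symbol} via
#'   \code{\link{map_symbol_to_aami}} when omitted
#' @param signal_length optional record length used to validate indices
#' @return data.frame with columns \code{sample_index}, \code{symbol},
#'   \code{aami_class}, sorted by \code{sample_index}
#' @export
beat_annotations <- function(sample_index, symbol, aami_class = NULL,
                             signal_length = NULL) {
  sample_index <- as.integer(sample_index)
  symbol <- as.character(symbol)
  if (length(sample_index) != length(symbol))
    stopf("sample_index and symbol lengths differ")
  if (any(sample_index < 0L))
    stopf("negative annotation sample_index: %d", min(sample_index))
  if (!is.null(signal_length) && length(sample_index) &&
      max(sample_index) >= signal_length)
    stopf("annotation index %d beyond signal end (length %d)",
          max(sample_index), signal_length)
  if (is.null(aami_class))
    aami_class <- vapply(symbol, map_symbol_to_aami, character(1))
  ann <- data.frame(sample_index = sample_index, symbol = symbol,
                    aami_class = as.character(aami_class),
                    stringsAsFactors = FALSE)
  ann[order(ann$sample_index), , drop = FALSE]
}

#' The five AAMI beat classes, in canonical order
#' @export
AAMI_CLASSES <- c("N", "S", "V", "F", "Q")
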