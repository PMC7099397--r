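# EC57 mapping from MIT-BIH style annotation symbols to the five AAMI
# classes. Non-beat symbols (rhythm changes, signal-quality marks) are not
# in the table and are reported via the "unmapped symbol" condition.
.AAMI_SYMBOL_MAP <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N", "." = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q")

#' Map an annotation symbol to its AAMI class
#'
#' Uses the EC57 convention for MIT-BIH beat codes:
#' N = \{N, L, R, e, j\}, S = \{A, a, J, S\}, V = \{V, E\}, F = \{F\},
#' Q = \{/, f, Q\}. Non-beat symbols (e.g. '+', '~', '|') raise a condition
#' of class \code{ecgbeats_unmapped_symbol} carrying the symbol, so callers
#' can choose to skip or fail.
#'
#' @param symbol a single character annotation code
#' @return one of "N", "S", "V", "F", "Q"
#' @export
#' @examples
#' map_symbol_to_aami("L")  # left bundle branch block -> N
map_symbol_to_aami <- function(symbol) {
  if (length(symbol) != 1L) stopf("symbol must be a single character")
  cls <- unname(.AAMI_SYMBOL_MAP[symbol])
  if (is.na(cls)) {
    cond <- structure(
      class = c("ecgbeats_unmapped_symbol", "error", "condition"),
      list(message = sprintf("unmapped annotation symbol '%s'", symbol),
           call = sys.call(-1), symbol = symbol))
    stop(cond)
  }
  cls
}

#' All symbols covered by the AAMI mapping table
#' @return character vector of mappable beat symbols
#' @export
aami_symbol_table <- function() {
  data.frame(symbol = names(.AAMI_SYMBOL_MAP),
             aami_class = unname(.AAMI_SYMBOL_MAP),
             stringsAsFactors = FALSE)
}

#' Read an ECG record with beat annotations
#'
#' Two on-disk dialects are supported. \code{format = "csv"} expects
#' \code{<path>.csv} with columns \code{sample_index,voltage_mV} plus a
#' header line \code{# sampling_rate=<Hz> subject=<id> lead=<label>}, and
#' \code{<path>.ann.csv} with columns \code{sample_index,symbol}.
#' \code{format = "wfdb"} reads a WFDB header/signal/annotation triplet
#' (\code{<path>.hea}, \code{.dat}, \code{.atr}); non-beat annotation
#' symbols are skipped and their count attached as attribute
#' \code{n_skipped_symbols}.
#'
#' @param path file location without extension
#' @param format "csv" or "wfdb"
#' @return list with elements \code{record} (an \code{\link{ecg_record}})
#'   and \code{annotations} (a \code{\link{beat_annotations}} table)
#' @export
read_record <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") read_record_csv(path) else read_record_wfdb(path)
}

read_record_csv <- function(path) {
  sig_path <- paste0(path, ".csv")
  ann_path <- paste0(path, ".ann.csv")
  if (!file.exists(sig_path)) stopf("cannot read ECG signal file '%s'", sig_path)
  hdr <- readLines(sig_path, n = 1L)
  meta <- list(sampling_rate = 256, subject = "unknown", lead = "lead-I")
  if (startsWith(hdr, "#")) {
    kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[^ ]+", hdr))[[1]]
    for (pair in kv) {
      k <- sub("=.*", "", pair); v <- sub("^[^=]*=", "", pair)
      if (k == "sampling_rate") meta$sampling_rate <- as.numeric(v)
      if (k == "subject") meta$subject <- v
      if (k == "lead") meta$lead <- v
    }
  }
  sig <- utils::read.csv(sig_path, comment.char = "#")
  if (!all(c("sample_index", "voltage_mV") %in% names(sig)))
    stopf("'%s' lacks sample_index,voltage_mV columns", sig_path)
  sig <- sig[order(sig$sample_index), ]
  record <- ecg_record(sig$voltage_mV, meta$sampling_rate, meta$subject,
                       meta$lead)
  ann <- if (file.exists(ann_path)) {
    a <- utils::read.csv(ann_path, colClasses = c("integer", "character"))
    beat_annotations(a$sample_index, a$symbol,
                     signal_length = length(record$signal))
  } else {
    beat_annotations(integer(0), character(0))
  }
  list(record = record, annotations = ann)
}

#' Write an ECG record with beat annotations
#'
#' Inverse of \code{\link{read_record}}; voltages are written with enough
#' digits that a read-back reproduces them to within 1e-6 mV (csv) or the
#' ADC quantum (wfdb).
#'
#' @param record an \code{\link{ecg_record}}
#' @param annotations a \code{\link{beat_annotations}} table
#' @param path output location without extension
#' @param format "csv" or "wfdb"
#' @return \code{path}, invisibly
#' @export
write_record <- function(record, annotations, path,
                         format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  if (format == "csv") {
    sig_path <- paste0(path, ".csv")
    con <- file(sig_path, "w")
    writeLines(sprintf("# sampling_rate=%g subject=%s lead=%s",
                       record$sampling_rate, record$subject_id,
                       gsub(" ", "_", record$lead_label)), con)
    writeLines("sample_index,voltage_mV", con)
    writeLines(sprintf("%d,%.6f", seq_along(record$signal) - 1L,
                       record$signal), con)
    close(con)
    utils::write.csv(annotations[, c("sample_index", "symbol")],
                     paste0(path, ".ann.csv"), row.names = FALSE,
                     quote = FALSE)
  } else {
    write_record_wfdb(record, annotations, path)
  }
  invisible(path)
}

#' Summarize beat counts per dataset and AAMI class
#'
#' Produces the per-dataset class counts with percentages (2 decimals) and
#' grand totals, in the layout of a dataset-description table.
#'
#' @param annotations_list list of \code{\link{beat_annotations}} tables
#'   (one per record), or a single table
#' @param dataset_labels one dataset tag per element of
#'   \code{annotations_list}
#' @return data.frame with columns \code{dataset}, \code{aami_class},
#'   \code{count}, \code{percent}; per-dataset "Total" rows appended, plus a
#'   \code{grand_total} attribute
#' @export
summarize_dataset <- function(annotations_list, dataset_labels = NULL) {
  if (is.data.frame(annotations_list)) annotations_list <- list(annotations_list)
  if (is.null(dataset_labels)) dataset_labels <- rep("all", length(annotations_list))
  if (length(dataset_labels) != length(annotations_list))
    stopf("one dataset label per annotation table required")
  if (length(annotations_list) == 0L) {
    out <- data.frame(dataset = character(0), aami_class = character(0),
                      count = integer(0), percent = numeric(0))
    attr(out, "grand_total") <- 0L
    return(out)
  }
  cls <- unlist(lapply(annotations_list, function(a) a$aami_class))
  ds <- rep(dataset_labels, vapply(annotations_list, nrow, integer(1)))
  rows <- list()
  for (d in unique(dataset_labels)) {
    counts <- table(factor(cls[ds == d], levels = AAMI_CLASSES))
    total <- sum(counts)
    pct <- if (total > 0) round_half_up(100 * as.numeric(counts) / total, 2)
           else rep(0, length(counts))
    rows[[d]] <- data.frame(dataset = d, aami_class = AAMI_CLASSES,
                            count = as.integer(counts), percent = pct,
                            stringsAsFactors = FALSE)
    rows[[d]] <- rbind(rows[[d]],
                       data.frame(dataset = d, aami_class = "Total",
                                  count = total,
                                  percent = if (total > 0) 100 else 0))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grand_total") <- length(cls)
  out
}
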