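#' Build a 5x5 confusion matrix
#'
#' Rows are ground-truth classes, columns predicted classes, both in the
#' canonical order N, S, V, F, Q.
#'
#' @param truth,predicted equal-length label vectors over the AAMI
#'   alphabet
#' @return an integer matrix of class \code{ecg_confusion}
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stopf("truth and predicted lengths differ")
  bad <- setdiff(unique(c(truth, predicted)), AAMI_CLASSES)
  if (length(bad))
    stopf("label(s) outside the 5-class alphabet: %s",
          paste(bad, collapse = ", "))
  cm <- table(factor(truth, AAMI_CLASSES), factor(predicted, AAMI_CLASSES))
  m <- matrix(as.integer(cm), 5, 5,
              dimnames = list(truth = AAMI_CLASSES,
                              predicted = AAMI_CLASSES))
  structure(m, class = c("ecg_confusion", "matrix", "array"))
}

#' Construct a confusion matrix from a count table
#' @param counts 5x5 non-negative counts (rows truth, columns predicted)
#' @return an \code{ecg_confusion} matrix
#' @export
as_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(5, 5)) || any(counts < 0))
    stopf("counts must be a 5x5 non-negative matrix")
  m <- matrix(as.integer(round(counts)), 5, 5,
              dimnames = list(truth = AAMI_CLASSES,
                              predicted = AAMI_CLASSES))
  structure(m, class = c("ecg_confusion", "matrix", "array"))
}

#' Read a confusion matrix from CSV
#'
#' Expects a header row and a leading label column, both in N,S,V,F,Q
#' order (the format written by \code{\link{write_confusion_csv}}).
#'
#' @param path CSV file
#' @return an \code{ecg_confusion} matrix
#' @export
read_confusion_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as_confusion(as.matrix(d[AAMI_CLASSES, AAMI_CLASSES]))
}

#' Write a confusion matrix as CSV
#' @param cm an \code{ecg_confusion}
#' @param path output file
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path)
  invisible(path)
}

ovr_counts <- function(cm, class) {
  i <- match(class, AAMI_CLASSES)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Per-class one-vs-rest metrics
#'
#' For class c with one-vs-rest counts TP, TN, FP, FN:
#' ACC = (TP+TN)/(TP+TN+FP+FN), SEN = TP/(TP+FN), SPEC = TN/(TN+FP),
#' PPV = TP/(TP+FP), each as a percentage rounded half-up to 2 decimals.
#' A zero denominator yields \code{NA} (reported as not-applicable, never
#' as a number).
#'
#' @param cm an \code{ecg_confusion}
#' @param class one of "N","S","V","F","Q"; default all five
#' @param digits decimals to round to (\code{NULL} for unrounded)
#' @return data.frame with columns \code{class, ACC, SEN, SPEC, PPV}
#' @export
per_class_metrics <- function(cm, class = AAMI_CLASSES, digits = 2) {
  stopifnot(inherits(cm, "ecg_confusion"))
  rows <- lapply(class, function(cl) {
    k <- ovr_counts(cm, cl)
    safe <- function(num, den)
      if (den == 0) NA_real_ else unname(100 * num / den)
    v <- c(ACC = safe(k["tp"] + k["tn"], sum(k)),
           SEN = safe(k["tp"], k["tp"] + k["fn"]),
           SPEC = safe(k["tn"], k["tn"] + k["fp"]),
           PPV = safe(k["tp"], k["tp"] + k["fp"]))
    if (!is.null(digits)) v <- round_half_up(v, digits)
    data.frame(class = cl, ACC = v[["ACC"]], SEN = v[["SEN"]],
               SPEC = v[["SPEC"]], PPV = v[["PPV"]])
  })
  do.call(rbind, rows)
}

#' Overall accuracy (observed agreement)
#'
#' The fraction of beats on the confusion-matrix diagonal, as a
#' percentage.
#'
#' @param cm an \code{ecg_confusion}
#' @param digits decimals (default 2, half-up; \code{NULL} for unrounded)
#' @return percentage in [0, 100]
#' @export
overall_accuracy <- function(cm, digits = 2) {
  stopifnot(inherits(cm, "ecg_confusion"))
  if (sum(cm) == 0) stopf("empty confusion matrix")
  v <- 100 * sum(diag(cm)) / sum(cm)
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' Number of misclassified beats
#' @param cm an \code{ecg_confusion}
#' @return off-diagonal sum
#' @export
misclassified_count <- function(cm) {
  stopifnot(inherits(cm, "ecg_confusion"))
  sum(cm) - sum(diag(cm))
}

#' Mask classes with insufficient support
#'
#' Classes whose ground-truth row total falls below \code{threshold}
#' beats are marked not-applicable: too few events to report a stable
#' rate.
#'
#' @param cm an \code{ecg_confusion}
#' @param threshold minimum row total (default 20)
#' @return named logical vector; \code{TRUE} = reportable
#' @export
minimum_support_filter <- function(cm, threshold = 20) {
  stopifnot(inherits(cm, "ecg_confusion"), threshold >= 0)
  stats::setNames(rowSums(cm) >= threshold, AAMI_CLASSES)
}

#' Per-subject evaluation report
#'
#' One row per subject with its beat count and micro-averaged one-vs-rest
#' ACC/PPV/SEN/SPEC over the five classes (TP/TN/FP/FN pooled across
#' classes before the ratios), plus a pooled "overall" row. Micro
#' averaging is what makes a single accuracy per subject well-defined.
#'
#' @param truth,predicted label vectors
#' @param subjects subject id per beat
#' @param digits decimals (default 2)
#' @return data.frame with columns \code{subject, beats, ACC, PPV, SEN,
#'   SPEC}
#' @export
per_subject_report <- function(truth, predicted, subjects, digits = 2) {
  if (length(truth) != length(predicted) ||
      length(truth) != length(subjects))
    stopf("truth, predicted and subjects must align")
  micro <- function(tr, pr) {
    cm <- confusion_matrix(tr, pr)
    k <- rowSums(vapply(AAMI_CLASSES, function(cl) ovr_counts(cm, cl),
                        numeric(4)))
    c(ACC = unname(100 * (k["tp"] + k["tn"]) / sum(k)),
      PPV = unname(100 * k["tp"] / (k["tp"] + k["fp"])),
      SEN = unname(100 * k["tp"] / (k["tp"] + k["fn"])),
      SPEC = unname(100 * k["tn"] / (k["tn"] + k["fp"])))
  }
  rnd <- function(v) if (is.null(digits)) v else round_half_up(v, digits)
  ids <- unique(as.character(subjects))
  rows <- lapply(ids, function(s) {
    ix <- subjects == s
    v <- rnd(micro(truth[ix], predicted[ix]))
    data.frame(subject = s, beats = sum(ix), ACC = v[["ACC"]],
               PPV = v[["PPV"]], SEN = v[["SEN"]], SPEC = v[["SPEC"]])
  })
  v <- rnd(micro(truth, predicted))
  rbind(do.call(rbind, rows),
        data.frame(subject = "overall", beats = length(truth),
                   ACC = v[["ACC"]], PPV = v[["PPV"]], SEN = v[["SEN"]],
                   SPEC = v[["SPEC"]]))
}

#' Packaged reference confusion matrices
#'
#' Loads the published test-set confusion-count tables shipped with the
#' package: \code{"baseline"} (two-conv + vanilla RNN model) or
#' \code{"lightweight"} (one-conv + fused RNN model).
#'
#' @param which "baseline" or "lightweight"
#' @return an \code{ecg_confusion}
#' @export
reference_confusion <- function(which = c("baseline", "lightweight")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("confusion_%s.csv", which),
                   package = "ecgbeats", mustWork = TRUE)
  read_confusion_csv(f)
}

#' @export
print.ecg_confusion <- function(x, ...) {
  cat("<ecg_confusion> rows = truth, columns = predicted\n")
  print(unclass(x))
  cat(sprintf("overall accuracy %.2f%% (%d of %s beats misclassified)\n",
              overall_accuracy(x), misclassified_count(x),
              format(sum(x), big.mark = ",")))
  invisible(x)
}
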