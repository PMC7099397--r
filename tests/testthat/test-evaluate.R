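test_that("confusion matrix tallies match a brute-force count", {
  cm <- confusion_matrix(c("N", "N", "S"), c("N", "S", "S"))
  expect_equal(cm["N", "N"], 1L)
  expect_equal(cm["N", "S"], 1L)
  expect_equal(cm["S", "S"], 1L)
  expect_equal(sum(cm), 3L)
  # perfect predictions sit on the diagonal
  p <- rep(AAMI_CLASSES, 4)
  expect_true(all(confusion_matrix(p, p)[upper.tri(diag(5))] == 0))
  # 1000 random pairs vs an explicit double loop
  set.seed(13)
  tr <- sample(AAMI_CLASSES, 1000, TRUE)
  pr <- sample(AAMI_CLASSES, 1000, TRUE)
  cm2 <- confusion_matrix(tr, pr)
  for (i in 1:5) for (j in 1:5)
    expect_equal(cm2[i, j],
                 sum(tr == AAMI_CLASSES[i] & pr == AAMI_CLASSES[j]))
  expect_error(confusion_matrix("N", "X"), "alphabet")
  expect_error(confusion_matrix(c("N", "S"), "N"), "differ")
})

test_that("row/column sums conserve supports and predictions", {
  set.seed(14)
  tr <- sample(AAMI_CLASSES, 500, TRUE, prob = c(0.6, 0.1, 0.2, 0.02, 0.08))
  pr <- sample(AAMI_CLASSES, 500, TRUE)
  cm <- confusion_matrix(tr, pr)
  expect_equal(as.integer(rowSums(cm)),
               as.integer(table(factor(tr, AAMI_CLASSES))))
  expect_equal(as.integer(colSums(cm)),
               as.integer(table(factor(pr, AAMI_CLASSES))))
})

test_that("per-class metrics equal a brute-force one-vs-rest recount", {
  set.seed(15)
  for (rep in 1:25) {
    cm <- as_confusion(matrix(stats::rpois(25, 40), 5))
    for (cl in AAMI_CLASSES) {
      i <- match(cl, AAMI_CLASSES)
      tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp
      fp <- sum(cm[, i]) - tp; tn <- sum(cm) - tp - fn - fp
      m <- per_class_metrics(cm, cl, digits = NULL)
      expect_equal(m$ACC, 100 * (tp + tn) / sum(cm))
      expect_equal(m$SEN, 100 * tp / (tp + fn))
      expect_equal(m$SPEC, 100 * tn / (tn + fp))
      expect_equal(m$PPV, 100 * tp / (tp + fp))
      expect_equal(tp + tn + fp + fn, sum(cm))
    }
  }
})

test_that("zero-denominator metrics are not-applicable, not numbers", {
  cm <- as_confusion(matrix(c(10, 0, 0, 0, 0,
                              0, 0, 0, 0, 0,
                              0, 0, 5, 0, 0,
                              0, 0, 0, 0, 0,
                              0, 0, 0, 0, 2), 5, 5, byrow = TRUE))
  m <- per_class_metrics(cm, "S")
  expect_true(is.na(m$SEN))
  expect_true(is.na(m$PPV))
  # perfect diagonal gives 100 everywhere it applies
  mi <- per_class_metrics(as_confusion(diag(5) * 10))
  expect_true(all(mi$ACC == 100))
  expect_true(all(mi$SEN == 100))
})

test_that("overall accuracy is the diagonal fraction", {
  expect_equal(overall_accuracy(as_confusion(diag(5) * 3)), 100)
  set.seed(16)
  cm <- as_confusion(matrix(stats::rpois(25, 30), 5))
  expect_equal(overall_accuracy(cm, digits = NULL),
               100 * sum(diag(cm)) / sum(cm))
  # accuracy + error rate = 100
  expect_equal(overall_accuracy(cm, digits = NULL) +
                 100 * misclassified_count(cm) / sum(cm), 100)
  expect_error(overall_accuracy(as_confusion(matrix(0, 5, 5))), "empty")
})

test_that("misclassified count is the off-diagonal sum", {
  expect_equal(misclassified_count(as_confusion(diag(5) * 7)), 0)
  set.seed(17)
  cm <- as_confusion(matrix(stats::rpois(25, 10), 5))
  expect_equal(misclassified_count(cm), sum(cm) - sum(diag(cm)))
})

test_that("minimum support filter masks thin classes", {
  m <- matrix(50, 5, 5); m[4, ] <- 3   # class F row total 15
  cm <- as_confusion(m)
  mask <- minimum_support_filter(cm, 20)
  expect_false(mask[["F"]])
  expect_true(all(mask[c("N", "S", "V", "Q")]))
  expect_true(all(minimum_support_filter(cm, 0)))
  expect_false(any(minimum_support_filter(cm, 10000)))
})

test_that("per-subject report pools correctly", {
  tr <- c(rep("N", 30), rep("V", 10))
  pr <- tr
  sub <- rep(c("a", "b"), 20)
  rep1 <- per_subject_report(tr, pr, sub)
  expect_equal(rep1$ACC, c(100, 100, 100))
  expect_equal(rep1$beats[rep1$subject == "overall"], 40)
  # disjoint subjects: overall equals pooled recomputation
  set.seed(18)
  pr2 <- ifelse(stats::runif(40) < 0.2,
                sample(AAMI_CLASSES, 40, TRUE), tr)
  rep2 <- per_subject_report(tr, pr2, sub, digits = NULL)
  cm <- confusion_matrix(tr, pr2)
  pooled <- rowSums(vapply(AAMI_CLASSES, function(cl) {
    i <- match(cl, AAMI_CLASSES)
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    c(tp = tp, tn = sum(cm) - tp - fn - fp, fp = fp, fn = fn)
  }, numeric(4)))
  expect_equal(rep2$ACC[rep2$subject == "overall"],
               100 * (pooled["tp"] + pooled["tn"]) / sum(pooled),
               ignore_attr = TRUE)
  # single-subject all-N arithmetic: 6 errors among 2273 beats
  tr3 <- rep("N", 2273)
  pr3 <- tr3; pr3[1:6] <- "V"
  rep3 <- per_subject_report(tr3, pr3, rep("s100", 2273))
  expect_equal(rep3$SEN[1], round_half_up(100 * 2267 / 2273, 2))
  expect_equal(rep3$SEN[1], 99.74)
})

test_that("rounding is half-up at 2 decimals", {
  expect_equal(round_half_up(99.715, 2), 99.72)
  expect_equal(round_half_up(99.805, 2), 99.81)
  expect_equal(round_half_up(89.474999, 2), 89.47)
  expect_equal(round_half_up(0.005, 2), 0.01)
})

test_that("confusion CSV IO round-trips", {
  set.seed(19)
  cm <- as_confusion(matrix(stats::rpois(25, 20), 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, f)
  expect_equal(unclass(read_confusion_csv(f)), unclass(cm))
})
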