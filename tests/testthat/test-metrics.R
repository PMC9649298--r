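test_that("confusion counts: worked 4x4 grid against per-pixel enumeration", {
  # 15 FOV pixels (one corner excluded), 5 truth positives, 3 hits, 2 false alarms
  truth <- matrix(0, 4, 4); truth[c(1, 2, 3, 6, 11)] <- 1
  pred <- matrix(0, 4, 4); pred[c(1, 2, 6, 8, 12)] <- 1   # hits 1,2,6; alarms 8,12
  fov <- matrix(1, 4, 4); fov[16] <- 0
  cc <- confusion_counts(pred, truth, fov)
  # independent enumeration
  ref <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:16) {
    if (fov[i] == 0) next
    ref <- ref + c(TP = pred[i] == 1 && truth[i] == 1,
                   TN = pred[i] == 0 && truth[i] == 0,
                   FP = pred[i] == 1 && truth[i] == 0,
                   FN = pred[i] == 0 && truth[i] == 1)
  }
  expect_equal(unlist(unclass(cc)), ref)
  expect_identical(unclass(cc), list(TP = 3L, TN = 8L, FP = 2L, FN = 2L)[names(cc)])
  expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, sum(fov == 1))

  expect_error(confusion_counts(pred[1:3, ], truth, fov), "shape")
  expect_error(confusion_counts(pred * 0.5, truth, fov), "binary")
})

test_that("degenerate inputs: all-positive prediction on empty truth", {
  pred <- matrix(1, 10, 10); truth <- matrix(0, 10, 10)
  cc <- confusion_counts(pred, truth)
  expect_identical(unclass(cc), list(TP = 0L, TN = 0L, FP = 100L, FN = 0L)[names(cc)])
  expect_warning(expect_identical(sensitivity(cc), 0), "degenerate")
})

test_that("accuracy / sensitivity / specificity formulas and algebraic identity", {
  cc <- structure(list(TP = 8L, TN = 85L, FP = 5L, FN = 2L), class = "confusion_counts")
  expect_equal(accuracy(cc), 0.93)
  expect_equal(sensitivity(cc), 0.8)
  expect_equal(specificity(cc), 85 / 90)
  expect_equal(f1_score(structure(list(TP = 8L, TN = 0L, FP = 5L, FN = 2L),
                                  class = "confusion_counts")), 16 / 23)

  # perfect prediction
  set.seed(20)
  truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
  cc2 <- confusion_counts(truth, truth)
  expect_identical(c(accuracy(cc2), sensitivity(cc2), specificity(cc2),
                     f1_score(cc2)), rep(1, 4))

  # ACC = (SE*P + SP*N) / (P + N) on random counts
  for (i in 1:25) {
    v <- as.list(rpois(4, 20) + 1L)
    names(v) <- c("TP", "TN", "FP", "FN")
    cc3 <- structure(v, class = "confusion_counts")
    P <- v$TP + v$FN; N <- v$TN + v$FP
    expect_equal(accuracy(cc3),
                 (sensitivity(cc3) * P + specificity(cc3) * N) / (P + N),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant to pixel order", {
  set.seed(21)
  truth <- rbinom(400, 1, 0.2)
  pred <- rbinom(400, 1, 0.3)
  o <- sample(400)
  expect_identical(unclass(confusion_counts(pred, truth)),
                   unclass(confusion_counts(pred[o], truth[o])))
  s <- runif(400)
  expect_equal(roc_auc(s, truth)$auc, roc_auc(s[o], truth[o])$auc,
               tolerance = 1e-12)
})

test_that("AUC: limit cases and the six-pixel pairwise example", {
  truth <- c(1, 1, 0, 1, 0, 0)
  expect_equal(roc_auc(rep(0.5, 6), truth)$auc, 0.5)
  expect_equal(roc_auc(c(9, 8, 7, 3, 2, 1) / 10, c(1, 1, 1, 0, 0, 0))$auc, 1)
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  expect_equal(roc_auc(s, truth)$auc, pairwise_auc(s, truth), tolerance = 1e-12)
  expect_equal(roc_auc(s, truth)$auc, 8 / 9, tolerance = 1e-12)
  expect_error(roc_auc(s, rep(1, 6)), "single class")
})

test_that("trapezoid AUC equals the pairwise statistic on random instances", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(20:300, 1)
    truth <- rbinom(n, 1, runif(1, 0.1, 0.9))
    if (length(unique(truth)) < 2) next
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # include heavy ties
    r <- roc_auc(scores, truth)
    expect_lt(abs(r$auc - pairwise_auc(scores, truth)), 1e-12)
    # curve is a valid ROC: monotone from (0,0) to (1,1)
    expect_identical(c(r$curve$fpr[1], r$curve$tpr[1]), c(0, 0))
    expect_identical(c(tail(r$curve$fpr, 1), tail(r$curve$tpr, 1)), c(1, 1))
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  truth <- rbinom(500, 1, 0.15)
  scores <- runif(500) + 0.3 * truth
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, truth)$auc, ref, tolerance = 1e-10)
})

test_that("segmentation_metrics schema, perfect scores, and report writer", {
  set.seed(24)
  truth <- matrix(rbinom(64, 1, 0.3), 8, 8)
  m <- segmentation_metrics(truth + 0, truth)
  expect_identical(names(m), c("ACC", "SEN", "SP", "AUC", "F1"))
  expect_equal(as.numeric(m), rep(1, 5))
  tab <- cbind(data.frame(dataset = "synthetic"), m)
  csv <- tempfile(fileext = ".csv"); txt <- tempfile(fileext = ".txt")
  write_metrics_report(tab, csv, txt)
  back <- read.csv(csv)
  expect_equal(back$ACC, 1)
  expect_true(any(grepl("AUC", readLines(txt))))
})
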