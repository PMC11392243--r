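test_that("confusion counts match direct pair counting", {
  truth <- c(rep("RWMA", 60), rep("non-RWMA", 42))
  cm <- confusion(truth, truth)
  expect_equal(cm[c("TP", "TN", "FP", "FN")], list(TP = 60L, TN = 42L, FP = 0L, FN = 0L))

  allpos <- confusion(truth, rep("RWMA", 102))
  expect_equal(allpos$FP, 42L)
  expect_equal(allpos$FN, 0L)

  set.seed(12)
  for (i in 1:5) {
    t20 <- sample(c("RWMA", "non-RWMA"), 20, TRUE)
    p20 <- sample(c("RWMA", "non-RWMA"), 20, TRUE)
    cm <- confusion(t20, p20)
    bf <- brute_confusion(t20, p20)
    expect_equal(cm[c("TP", "TN", "FP", "FN")], bf)
    expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, 20L)
  }
  expect_error(confusion(truth, truth[-1]), "length")
})

test_that("metric identities hold: FPR + SPE = 100 and F1 is the harmonic mean", {
  set.seed(13)
  for (i in 1:10) {
    cm <- echoflow:::confusion_counts(sample(1:50, 1), sample(1:50, 1),
                                      sample(1:50, 1), sample(1:50, 1))
    m <- metrics(cm)
    expect_equal(unname(m["fpr"] + m["specificity"]), 100, tolerance = 1e-9)
    harm <- 2 / (1 / m["precision"] + 1 / m["sensitivity"])
    expect_equal(unname(m["f1"]), unname(harm), tolerance = 1e-9)
    expect_equal(unname(m["accuracy"]),
                 100 * (cm$TP + cm$TN) / (cm$TP + cm$TN + cm$FP + cm$FN))
  }
})

test_that("zero-denominator metrics are reported as NA with a warning, not 0", {
  cm <- echoflow:::confusion_counts(0, 10, 0, 0)
  w <- testthat::capture_warnings(m <- metrics(cm))
  expect_true(any(grepl("sensitivity", w)))
  expect_true(any(grepl("precision", w)))
  expect_true(is.na(m["sensitivity"]))
  expect_true(is.na(m["precision"]))
  expect_equal(unname(m["accuracy"]), 100)
})

test_that("AUC matches the O(n^2) concordance oracle, with ties at one half", {
  sep <- roc_auc(c(5, 4, 3, 2, 1), c("RWMA", "RWMA", "RWMA", "non-RWMA", "non-RWMA"))
  expect_equal(sep$auc, 1)
  expect_equal(sep$curve$fpr[1], 0)
  expect_equal(tail(sep$curve$tpr, 1), 1)

  tied <- roc_auc(rep(1, 6), rep(c("RWMA", "non-RWMA"), 3))
  expect_equal(tied$auc, 0.5)

  set.seed(14)
  for (i in 1:5) {
    truth <- sample(c("RWMA", "non-RWMA"), 12, TRUE, prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    scores <- sample(seq(0, 1, 0.25), 12, TRUE)  # coarse grid forces ties
    expect_equal(roc_auc(scores, truth)$auc, brute_auc(scores, truth),
                 tolerance = 1e-12)
    expect_equal(roc_auc(scores, truth)$auc,
                 as.numeric(suppressMessages(pROC::auc(pROC::roc(
                   truth, scores, levels = c("non-RWMA", "RWMA"),
                   direction = "<", quiet = TRUE)))),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("RWMA", 3)), "both classes")
})

test_that("the ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(15)
  truth <- sample(c("RWMA", "non-RWMA"), 30, TRUE)
  curve <- roc_auc(rnorm(30), truth)$curve
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
  expect_equal(unlist(curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(curve[nrow(curve), ]), c(fpr = 1, tpr = 1))
})

test_that("view-label fusion follows the OR rule and is monotone", {
  expect_equal(fuse_view_labels("MI", "non-MI")$fused, "RWMA")
  expect_equal(fuse_view_labels("non-MI", "non-MI")$fused, "non-RWMA")
  expect_equal(fuse_view_labels("non-MI", "MI")$fused, "RWMA")
  expect_error(fuse_view_labels("yes", "no"), "MI")

  set.seed(16)
  a4c <- sample(c("MI", "non-MI"), 40, TRUE)
  a2c <- sample(c("MI", "non-MI"), 40, TRUE)
  fused <- fuse_view_labels(a4c, a2c)$fused
  for (i in seq_along(a4c)) {
    a4c2 <- a4c
    a4c2[i] <- "MI"
    fused2 <- fuse_view_labels(a4c2, a2c)$fused
    expect_false(fused[i] == "RWMA" && fused2[i] == "non-RWMA")
  }
})

test_that("fold aggregation computes element-wise max, mean and min", {
  m1 <- c(accuracy = 80, sensitivity = 70)
  m2 <- c(accuracy = 90, sensitivity = 75)
  m3 <- c(accuracy = 100, sensitivity = 65)
  agg <- aggregate_folds(list(m1, m2, m3))
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(c(acc$max, acc$mean, acc$min), c(100, 90, 80))

  same <- aggregate_folds(list(m1, m1))
  expect_true(all(same$max == same$mean & same$mean == same$min))

  set.seed(17)
  folds <- lapply(1:4, function(i) c(a = runif(1, 0, 100), b = runif(1, 0, 100)))
  agg2 <- aggregate_folds(folds)
  expect_true(all(agg2$max >= agg2$mean & agg2$mean >= agg2$min))
  expect_error(aggregate_folds(list()), "at least one")
})
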