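test_that("view fusion concatenates A2C then A4C and rejects bad inputs", {
  a2c <- structure(list(values = rep(1, 1024), view = "A2C"),
                   class = "ef_motion_feature")
  a4c <- structure(list(values = rep(2, 1024), view = "A4C"),
                   class = "ef_motion_feature")
  fused <- fuse_views(a2c, a4c, subject_id = "S1", label = "RWMA")
  expect_length(fused$values, 2048L)
  expect_equal(fused$values[1:1024], rep(1, 1024))      # A2C block first
  expect_equal(fused$values[1025:2048], rep(2, 1024))
  expect_error(fuse_views(rep(0, 1024), rep(0, 512)), "512")
  expect_error(fuse_views(NULL, rep(0, 1024)), "missing A2C")
})

test_that("the stratified plan balances folds and classes and is reproducible", {
  labels <- c(rep("RWMA", 60), rep("non-RWMA", 42))
  plan <- make_cv_plan(labels, 5, seed = 11)
  sizes <- as.integer(table(plan$fold))
  expect_equal(sort(sizes, decreasing = TRUE), c(21L, 21L, 20L, 20L, 20L))
  expect_equal(sum(sizes), 102L)
  # every subject in exactly one test fold
  expect_true(all(plan$fold %in% 1:5))
  # per-fold positives within +-1 of the proportional share (60/5 = 12)
  pos_per_fold <- tapply(labels == "RWMA", plan$fold, sum)
  expect_true(all(abs(pos_per_fold - 12) <= 1))
  expect_identical(plan$fold, make_cv_plan(labels, 5, seed = 11)$fold)
  expect_false(identical(plan$fold, make_cv_plan(labels, 5, seed = 12)$fold))
  expect_error(make_cv_plan(c(rep("RWMA", 3), rep("non-RWMA", 40)), 5), "at least 5")
})

test_that("grid search picks the only point, breaks ties first-in-grid, and separates", {
  gf <- gaussian_features(12, p = 8, sep = 6)
  single <- grid_search_fit("KNN", list(k = 5), gf$x, gf$labels, seed = 1)
  expect_equal(single$params$k, 5)

  tied <- grid_search_fit("KNN", list(k = c(3, 3)), gf$x, gf$labels, seed = 1)
  expect_equal(which.max(tied$accuracy$accuracy), 1L)
  expect_equal(tied$accuracy$accuracy[1], tied$accuracy$accuracy[2])

  sv <- grid_search_fit("SVM", list(kernel = "linear", cost = 10), gf$x,
                        gf$labels, seed = 2)
  pr <- echoflow:::ef_predict_one("SVM", sv$model, gf$x, "RWMA")
  expect_equal(mean(pr$class == gf$labels), 1)  # separable: 100% training accuracy

  expect_error(grid_search_fit("XGB", list(a = 1), gf$x, gf$labels), "unknown")
  expect_error(grid_search_fit("KNN", list(), gf$x, gf$labels), "empty")
})

test_that("the bank separates well-separated synthetic features out of fold", {
  gf <- gaussian_features(20, p = 24, sep = 6, seed = 2)
  plan <- make_cv_plan(gf$labels, 5, seed = 3)
  rep <- run_detection(gf$x, gf$labels, plan,
                       spaces = list(KNN = list(k = 3), DT = list(maxdepth = 5),
                                     RF = list(ntree = 100),
                                     SVM = list(kernel = "linear", cost = 1),
                                     MLP = list(hidden = 32)),
                       seed = 5)
  # out-of-fold coverage: one prediction per subject per classifier
  for (clf in names(rep$overall)) {
    sub <- rep$predictions[rep$predictions$classifier == clf, ]
    expect_equal(sort(sub$subject), 1:40)
    expect_gt(unname(rep$overall[[clf]]$metrics["accuracy"]), 80)
    expect_gt(rep$overall[[clf]]$auc, 0.85)
  }
  # aggregate ordering
  for (clf in names(rep$summary)) {
    s <- rep$summary[[clf]]
    ok <- !is.na(s$mean)
    expect_true(all(s$max[ok] >= s$mean[ok] & s$mean[ok] >= s$min[ok]))
  }
})

test_that("shuffled labels collapse the AUC to chance", {
  gf <- gaussian_features(20, p = 24, sep = 6, seed = 2)
  set.seed(21)
  shuffled <- sample(gf$labels)
  plan <- make_cv_plan(shuffled, 5, seed = 4)
  rep <- run_detection(gf$x, shuffled, plan,
                       classifiers = c("KNN", "SVM"),
                       spaces = list(KNN = list(k = 5),
                                     SVM = list(kernel = "linear", cost = 1)),
                       seed = 6)
  aucs <- vapply(rep$overall, function(o) o$auc, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("a single requested classifier yields a report with exactly that classifier", {
  gf <- gaussian_features(8, p = 6, sep = 3, seed = 5)
  plan <- make_cv_plan(gf$labels, 2, seed = 1)
  rep <- run_detection(gf$x, gf$labels, plan, classifiers = "DT",
                       spaces = list(DT = list(maxdepth = 3)), seed = 2)
  expect_named(rep$overall, "DT")
  expect_equal(unique(rep$predictions$classifier), "DT")
})

test_that("detection runs are seed-deterministic", {
  gf <- gaussian_features(8, p = 6, sep = 3, seed = 6)
  plan <- make_cv_plan(gf$labels, 2, seed = 1)
  sp <- list(KNN = list(k = 3), RF = list(ntree = 50))
  r1 <- run_detection(gf$x, gf$labels, plan, classifiers = c("KNN", "RF"),
                      spaces = sp, seed = 9)
  r2 <- run_detection(gf$x, gf$labels, plan, classifiers = c("KNN", "RF"),
                      spaces = sp, seed = 9)
  expect_identical(r1$predictions, r2$predictions)
})
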