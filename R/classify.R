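# Multi-view feature fusion and the RWMA classifier bank: KNN, decision
# tree, random forest, SVM and MLP, tuned by exhaustive grid search with
# inner cross-validation and evaluated under a stratified k-fold plan.

#' Fuse per-view motion features
#'
#' Concatenates the A2C and A4C 1024-element motion feature vectors into a
#' single 2048-element descriptor, A2C block first. No imputation: both
#' views must be present.
#'
#' @param a2c,a4c `ef_motion_feature`s (or plain numeric vectors) of length
#'   1024.
#' @param subject_id,label Optional identifiers carried on the result.
#' @return An `ef_fused_feature` with `values` of length 2048.
#' @export
fuse_views <- function(a2c, a4c, subject_id = NULL, label = NULL) {
  val <- function(x, nm) {
    if (inherits(x, "ef_motion_feature")) x <- x$values
    if (is.null(x)) stop(sprintf("missing %s features; both views are required", nm))
    if (!is.numeric(x) || length(x) != 1024L) {
      stop(sprintf("%s feature vector has length %d; expected 1024", nm, length(x)))
    }
    as.numeric(x)
  }
  structure(list(values = c(val(a2c, "A2C"), val(a4c, "A4C")),
                 subject_id = subject_id, label = label),
            class = "ef_fused_feature")
}

#' Stratified cross-validation plan
#'
#' Partitions subjects into `n_folds` test folds, preserving class
#' proportions to within one subject per fold; deterministic for a fixed
#' seed.
#'
#' @param labels Class label per subject.
#' @param n_folds Number of folds (default 5: 80% train / 20% test).
#' @param seed Fold-assignment seed.
#' @return An `ef_cv_plan` with the per-subject `fold` vector.
#' @export
make_cv_plan <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.character(labels)
  classes <- radix_sort(labels)
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < n_folds)) {
    stop(sprintf("class '%s' has %d subjects; need at least %d for %d folds",
                 classes[which.min(counts)], min(counts), n_folds, n_folds))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  structure(list(fold = fold, n_folds = as.integer(n_folds), seed = seed,
                 labels = labels),
            class = "ef_cv_plan")
}

#' Default hyper-parameter grids for the classifier bank
#'
#' @return Named list of per-classifier grids (parameter name -> candidate
#'   values), enumerated first-to-last for tie breaking.
#' @export
default_grids <- function() {
  list(
    KNN = list(k = c(3, 5, 7, 9)),
    DT = list(maxdepth = c(3, 5, 10, 30)),
    RF = list(ntree = c(100, 300)),
    SVM = list(kernel = c("radial", "linear"), cost = c(0.1, 1, 10)),
    MLP = list(hidden = c(128, 256))
  )
}

classifier_names <- function() c("KNN", "DT", "RF", "SVM", "MLP")

# fit one classifier; x standardized upstream, y a 2-level factor
ef_fit_one <- function(name, params, x, y, seed) {
  with_seed(seed, switch(
    name,
    KNN = list(kind = "KNN", x = x, y = y, k = params$k),
    DT = {
      df <- as.data.frame(x)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = params$maxdepth,
                                                  minsplit = 5, cp = 0.005,
                                                  xval = 0))
    },
    RF = randomForest::randomForest(x, y, ntree = params$ntree),
    SVM = e1071::svm(x, y, kernel = params$kernel, cost = params$cost,
                     probability = TRUE, scale = FALSE),
    MLP = mlp_fit(x, y, hidden = params$hidden, seed = seed),
    stop(sprintf("unknown classifier '%s'", name))
  ))
}

# predicted class + positive-class score
ef_predict_one <- function(name, model, x, positive) {
  if (name == "KNN") {
    pr <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
    p <- attr(pr, "prob")
    score <- ifelse(as.character(pr) == positive, p, 1 - p)
    return(list(class = as.character(pr), score = score))
  }
  if (inherits(model, "rpart")) {
    df <- as.data.frame(x)
    prob <- predict(model, df, type = "prob")[, positive]
    cls <- as.character(predict(model, df, type = "class"))
    return(list(class = cls, score = prob))
  }
  if (inherits(model, "randomForest")) {
    prob <- predict(model, x, type = "prob")[, positive]
    cls <- as.character(predict(model, x, type = "response"))
    return(list(class = cls, score = prob))
  }
  if (inherits(model, "svm")) {
    pr <- predict(model, x, probability = TRUE)
    prob <- attr(pr, "probabilities")[, positive]
    return(list(class = as.character(pr), score = prob))
  }
  if (inherits(model, "ef_mlp")) {
    prob <- mlp_prob(model, x)[, positive]
    neg <- setdiff(model$levels, positive)
    return(list(class = ifelse(prob >= 0.5, positive, neg), score = prob))
  }
  stop("unknown model type")
}

#' Grid search with inner cross-validation
#'
#' Exhaustively evaluates a hyper-parameter grid by stratified inner CV on
#' the training data only, selecting the parameters with the best mean
#' accuracy; ties keep the first grid point in enumeration order. The
#' winning parameters are refitted on the full training set.
#'
#' @param name Classifier name (`"KNN"`, `"DT"`, `"RF"`, `"SVM"`, `"MLP"`).
#' @param space Named list of candidate values (see [default_grids()]).
#' @param x,y Training features (already standardized where relevant) and
#'   labels.
#' @param seed Seed for the inner folds and stochastic fitters.
#' @param inner_folds Inner CV folds.
#' @param positive Positive-class label.
#' @return List with the fitted `model`, chosen `params`, and the grid
#'   `accuracy` table.
#' @export
grid_search_fit <- function(name, space, x, y, seed = 1L, inner_folds = 3L,
                            positive = "RWMA") {
  if (!name %in% classifier_names()) stop(sprintf("unknown classifier '%s'", name))
  if (length(space) == 0L) stop("empty hyper-parameter grid")
  y <- factor(as.character(y), levels = class_level_order(y, positive))
  grid <- expand.grid(space, stringsAsFactors = FALSE)
  smallest <- min(table(y))
  if (smallest < inner_folds) {
    inner_folds <- max(2L, smallest)
    warning(sprintf("training set too small for the requested inner CV; using %d folds",
                    inner_folds), call. = FALSE)
  }
  inner <- make_cv_plan(as.character(y), inner_folds, derive_seed(seed, "inner"))
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    correct <- 0L
    total <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- inner$fold != f
      if (length(unique(y[tr])) < 2L) next
      m <- ef_fit_one(name, params, x[tr, , drop = FALSE], droplevels(y[tr]),
                      derive_seed(seed, paste0(name, g, f)))
      pr <- ef_predict_one(name, m, x[!tr, , drop = FALSE], positive)
      correct <- correct + sum(pr$class == as.character(y[!tr]))
      total <- total + sum(!tr)
    }
    acc[g] <- correct / max(total, 1L)
  }
  best <- which.max(acc)  # which.max keeps the first maximum: tie rule
  params <- as.list(grid[best, , drop = FALSE])
  model <- ef_fit_one(name, params, x, y, derive_seed(seed, paste0(name, "final")))
  list(model = model, params = params,
       accuracy = cbind(grid, accuracy = acc), name = name)
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu, "-"), 2, sc$sd, "/")
}

#' Run the RWMA detection bank under cross-validation
#'
#' For every fold of the plan: standardizes features on the training fold
#' only, grid-searches each requested classifier by inner CV on the
#' training fold, refits, and predicts the held-out fold. Test subjects
#' never touch fitting, scaling, or model selection; each subject receives
#' exactly one out-of-fold prediction per classifier.
#'
#' @param features Numeric matrix (subjects x features) or list of
#'   `ef_fused_feature`s.
#' @param labels Class label per subject.
#' @param plan An [make_cv_plan()] result for these labels.
#' @param classifiers Which bank members to run.
#' @param spaces Hyper-parameter grids, as [default_grids()].
#' @param seed Seed stream for classifier fitting and inner CV.
#' @param inner_folds Inner CV folds for grid search (shrunk with a warning
#'   when a training fold is too small).
#' @param positive Positive-class label.
#' @return An `ef_detection_report`: `predictions` (subject, fold,
#'   classifier, score, predicted, true), `fold_metrics`, `summary`
#'   (max/mean/min per metric per classifier), and `overall` (pooled
#'   confusion, metrics and AUC per classifier).
#' @export
run_detection <- function(features, labels, plan = NULL,
                          classifiers = classifier_names(),
                          spaces = default_grids(), seed = 1L,
                          inner_folds = 3L, positive = "RWMA") {
  if (is.list(features) && !is.matrix(features)) {
    features <- do.call(rbind, lapply(features, function(f) {
      if (inherits(f, "ef_fused_feature")) f$values else as.numeric(f)
    }))
  }
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (is.null(plan)) plan <- make_cv_plan(labels, seed = seed)
  if (length(plan$fold) != length(labels)) stop("plan does not match the label vector")
  stopifnot(all(classifiers %in% classifier_names()))

  preds <- list()
  with_seed(derive_seed(seed, "outer"), for (f in seq_len(plan$n_folds)) {
    tr <- which(plan$fold != f)
    te <- which(plan$fold == f)
    if (length(intersect(tr, te)) > 0L) {
      stop("internal error: train/test overlap in fold ", f)  # leakage guard
    }
    sc <- standardize_fit(features[tr, , drop = FALSE])
    xtr <- standardize_apply(features[tr, , drop = FALSE], sc)
    xte <- standardize_apply(features[te, , drop = FALSE], sc)
    ytr <- factor(labels[tr], levels = class_level_order(labels, positive))
    for (clf in classifiers) {
      gs <- grid_search_fit(clf, spaces[[clf]], xtr, ytr,
                            seed = derive_seed(seed, paste0(clf, "fold", f)),
                            inner_folds = inner_folds, positive = positive)
      pr <- ef_predict_one(clf, gs$model, xte, positive)
      preds[[length(preds) + 1L]] <- data.frame(
        subject = te, fold = f, classifier = clf, score = pr$score,
        predicted = pr$class, true = labels[te], stringsAsFactors = FALSE
      )
    }
  })
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL

  fold_metrics <- list()
  summary <- list()
  overall <- list()
  for (clf in classifiers) {
    sub <- predictions[predictions$classifier == clf, ]
    per_fold <- lapply(seq_len(plan$n_folds), function(f) {
      ff <- sub[sub$fold == f, ]
      suppressWarnings(metrics(confusion(ff$true, ff$predicted, positive)))
    })
    fold_metrics[[clf]] <- per_fold
    summary[[clf]] <- suppressWarnings(aggregate_folds(per_fold))
    cm <- confusion(sub$true, sub$predicted, positive)
    overall[[clf]] <- list(
      confusion = cm,
      metrics = suppressWarnings(metrics(cm)),
      auc = roc_auc(sub$score, sub$true, positive)$auc
    )
  }
  structure(list(predictions = predictions, fold_metrics = fold_metrics,
                 summary = summary, overall = overall, plan = plan,
                 positive = positive),
            class = "ef_detection_report")
}

#' @export
print.ef_detection_report <- function(x, ...) {
  cat("<detection report>\n")
  for (clf in names(x$overall)) {
    m <- x$overall[[clf]]$metrics
    cat(sprintf("  %-4s acc %5.2f%%  sens %5.2f%%  spec %5.2f%%  AUC %.3f\n",
                clf, m["accuracy"], m["sensitivity"], m["specificity"],
                x$overall[[clf]]$auc))
  }
  invisible(x)
}
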