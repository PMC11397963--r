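# Feature selection and classification.
#
# Protocol: subject-grouped 5-fold cross-validation throughout (all cycles of
# a subject stay on one side of every split). Feature selection is recursive
# feature elimination within each training fold (drop the least important
# feature per round); the subset size is chosen by mean test accuracy across
# folds and the final subset by majority vote across folds at that size.
# Classifier families: linear-kernel SVM, random forest (gini), and
# gradient-boosted trees (eta 0.3, depth 6).

CLASSIFY_TASKS <- c("normal-abnormal", "normal-knee", "normal-ankle",
                    "knee-ankle", "three-class")

#' Classifier specification
#'
#' Hyperparameters follow the study protocol: SVM with a linear kernel;
#' random forest with the gini split criterion (100 trees); gradient
#' boosting with a tree booster, learning rate 0.3, maximum depth 6,
#' 100 rounds. Any element of `...` overrides the family defaults.
#'
#' @param family `"svm"`, `"rf"`, or `"xgb"`.
#' @param ... Named hyperparameter overrides (`cost`, `num_trees`,
#'   `max_depth`, `eta`, `nrounds`).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("svm", "rf", "xgb"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    svm = list(cost = 1),
    rf = list(num_trees = 100L),
    xgb = list(eta = 0.3, max_depth = 6L, nrounds = 100L))
  over <- list(...)
  abort_if(length(over) > 0 && is.null(names(over)),
           "hyperparameter overrides must be named")
  bad <- setdiff(names(over), names(defaults))
  abort_if(length(bad) > 0, "unknown hyperparameter(s) for %s: %s", family,
           paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(list(family = family, params = defaults), class = "classifier_spec")
}

#' Build a feature matrix for a classification task
#'
#' @param features Parameter table from [cohort_parameter_table()] (keys +
#'   parameter columns).
#' @param task One of `r paste0('"', CLASSIFY_TASKS, '"', collapse = ", ")`.
#'   `"normal-abnormal"` pools the knee and ankle conditions into one
#'   `abnormal` class.
#' @return A `feature_matrix`: list with `x` (numeric matrix), `y` (factor),
#'   `groups` (subject per row), `feature_names`.
#' @export
build_feature_matrix <- function(features, task = CLASSIFY_TASKS) {
  task <- match.arg(task)
  keys <- c("subject_id", "condition", "trial_index", "cycle_index")
  feat_cols <- setdiff(names(features), keys)
  conds <- switch(task,
    "normal-abnormal" = c("normal", "knee", "ankle"),
    "normal-knee" = c("normal", "knee"),
    "normal-ankle" = c("normal", "ankle"),
    "knee-ankle" = c("knee", "ankle"),
    "three-class" = c("normal", "knee", "ankle"))
  abort_if(!all(conds %in% unique(features$condition)),
           "features table lacks condition(s): %s",
           paste(setdiff(conds, unique(features$condition)), collapse = ", "))
  sub <- features[features$condition %in% conds, , drop = FALSE]
  y <- if (task == "normal-abnormal")
    factor(ifelse(sub$condition == "normal", "normal", "abnormal"),
           levels = c("normal", "abnormal"))
  else factor(sub$condition, levels = conds)
  x <- as.matrix(sub[, feat_cols, drop = FALSE])
  abort_if(anyNA(x), "feature matrix contains missing values")
  abort_if(nlevels(droplevels(y)) < 2L, "need at least 2 classes")
  structure(list(x = x, y = y, groups = as.character(sub$subject_id),
                 feature_names = feat_cols, task = task),
            class = "feature_matrix")
}

#' Subject-grouped k-fold splits
#'
#' Every group (subject) appears in exactly one test fold; fold sizes are
#' balanced within one group.
#'
#' @param groups Character vector, one group id per sample.
#' @param k Number of folds.
#' @param seed Seed controlling the group shuffle.
#' @return List of `k` lists with `train` and `test` group-id vectors.
#' @export
group_kfold_splits <- function(groups, k = 5L, seed = 1L) {
  ids <- unique(groups)
  abort_if(length(ids) < k, "need at least %d distinct groups, got %d",
           k, length(ids))
  ids <- with_stream(seed, "group_kfold", expr = sample(ids))
  fold_of <- rep(seq_len(k), length.out = length(ids))
  lapply(seq_len(k), function(f)
    list(train = ids[fold_of != f], test = ids[fold_of == f]))
}

# ---- classifier backends ----------------------------------------------------

fit_classifier <- function(spec, x, y, seed = 1L) {
  y <- droplevels(y)
  if (spec$family == "svm") {
    m <- suppressWarnings(e1071::svm(x = x, y = y, kernel = "linear",
                                     cost = spec$params$cost, scale = TRUE))
    return(list(family = "svm", model = m, levels = levels(y)))
  }
  if (spec$family == "rf") {
    m <- ranger::ranger(x = as.data.frame(x), y = y,
                        num.trees = spec$params$num_trees,
                        importance = "impurity", seed = stream_seed(seed, "rf"),
                        num.threads = 1L)
    return(list(family = "rf", model = m, levels = levels(y)))
  }
  # xgb
  lv <- levels(y)
  label <- as.integer(y) - 1L
  params <- list(eta = spec$params$eta, max_depth = spec$params$max_depth,
                 nthread = 1L)
  if (length(lv) > 2L) {
    params$objective <- "multi:softmax"; params$num_class <- length(lv)
  } else params$objective <- "binary:logistic"
  dtrain <- xgboost::xgb.DMatrix(x, label = label)
  set.seed(stream_seed(seed, "xgb"))
  m <- xgboost::xgb.train(params = params, data = dtrain,
                          nrounds = spec$params$nrounds, verbose = 0)
  list(family = "xgb", model = m, levels = lv, feature_names = colnames(x))
}

predict_classifier <- function(fit, x) {
  if (fit$family == "svm")
    return(as.character(stats::predict(fit$model, x)))
  if (fit$family == "rf")
    return(as.character(stats::predict(fit$model, data = as.data.frame(x),
                                       num.threads = 1L)$predictions))
  p <- stats::predict(fit$model, xgboost::xgb.DMatrix(x))
  if (length(fit$levels) > 2L) fit$levels[p + 1L]
  else fit$levels[(p > 0.5) + 1L]
}

# Per-feature importance: |margin coefficient| aggregate for the linear SVM,
# impurity decrease for RF, split gain for XGB. Always named, >= 0, finite.
importance_scores <- function(fit, feature_names) {
  if (length(feature_names) == 1L)
    return(stats::setNames(1, feature_names))
  imp <- if (fit$family == "svm") {
    w <- t(fit$model$coefs) %*% fit$model$SV
    colSums(w^2)[feature_names]
  } else if (fit$family == "rf") {
    fit$model$variable.importance[feature_names]
  } else {
    tab <- xgboost::xgb.importance(model = fit$model)
    stats::setNames(tab$Gain[match(feature_names, tab$Feature)], feature_names)
  }
  imp[is.na(imp)] <- 0
  abort_if(any(!is.finite(imp)), "non-finite feature importances")
  stats::setNames(as.numeric(imp), feature_names)
}

# ---- metrics ----------------------------------------------------------------

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the fraction of correct predictions. Precision, recall
#' (sensitivity) and F1 are computed per class in one-vs-rest fashion from
#' the true/false positive/negative counts and averaged weighted by class
#' support; classes absent from the truth are excluded from the average.
#'
#' @param confusion Square contingency matrix, rows = truth, cols = predicted.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  abort_if(nrow(confusion) != ncol(confusion), "confusion matrix must be square")
  total <- sum(confusion)
  abort_if(total == 0, "empty confusion matrix")
  support <- rowSums(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- support - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  keep <- support > 0
  w <- support[keep] / sum(support[keep])
  list(accuracy = sum(tp) / total,
       precision = sum(w * prec[keep]),
       recall = sum(w * rec[keep]),
       f1 = sum(w * f1[keep]))
}

.fold_indices <- function(fm, split) {
  list(train = which(fm$groups %in% split$train),
       test = which(fm$groups %in% split$test))
}

.fold_accuracy <- function(fm, spec, feats, idx, seed) {
  fit <- fit_classifier(spec, fm$x[idx$train, feats, drop = FALSE],
                        fm$y[idx$train], seed)
  pred <- predict_classifier(fit, fm$x[idx$test, feats, drop = FALSE])
  mean(pred == as.character(fm$y[idx$test]))
}

# ---- RFECV ------------------------------------------------------------------

#' Recursive feature elimination with grouped cross-validation
#'
#' Within each training fold, all features are fitted, the test accuracy
#' recorded, and the least important feature dropped; repeating down to one
#' feature traces an accuracy curve per fold. The optimal feature count
#' maximises the fold-mean accuracy (ties resolved toward fewer features);
#' the optimal subset is the majority vote across folds of the features
#' surviving at that count, ties broken by mean importance of the
#' full-feature fits.
#'
#' @param fm A `feature_matrix`.
#' @param spec A `classifier_spec`.
#' @param k Number of grouped folds.
#' @param seed Seed for fold assignment and stochastic fits.
#' @return A `feature_selection` list: `cv_curve` (mean accuracy per feature
#'   count), `optimal_count`, `optimal_features`, `ranking` (mean elimination
#'   round per feature, higher = kept longer), `fold_subsets`.
#' @export
recursive_feature_elimination <- function(fm, spec, k = 5L, seed = 1L) {
  abort_if(!inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  abort_if(!inherits(spec, "classifier_spec"), "spec must be a classifier_spec")
  p <- length(fm$feature_names)
  splits <- group_kfold_splits(fm$groups, k, seed)
  acc <- matrix(NA_real_, nrow = k, ncol = p,
                dimnames = list(NULL, as.character(seq_len(p))))
  elim_round <- matrix(NA_real_, nrow = k, ncol = p,
                       dimnames = list(NULL, fm$feature_names))
  surv <- vector("list", k)      # per fold: features surviving at each count
  full_imp <- matrix(NA_real_, nrow = k, ncol = p,
                     dimnames = list(NULL, fm$feature_names))
  for (f in seq_len(k)) {
    idx <- .fold_indices(fm, splits[[f]])
    feats <- fm$feature_names
    surv[[f]] <- vector("list", p)
    for (m in seq(p, 1L)) {
      fit <- fit_classifier(spec, fm$x[idx$train, feats, drop = FALSE],
                            fm$y[idx$train], stream_seed(seed, "rfe", f, m))
      pred <- predict_classifier(fit, fm$x[idx$test, feats, drop = FALSE])
      acc[f, m] <- mean(pred == as.character(fm$y[idx$test]))
      surv[[f]][[m]] <- feats
      imp <- importance_scores(fit, feats)
      if (m == p) full_imp[f, ] <- imp
      if (m > 1L) {
        drop_feat <- names(imp)[which.min(imp)]
        elim_round[f, drop_feat] <- p - m + 1L
        feats <- setdiff(feats, drop_feat)
      } else elim_round[f, feats] <- p
    }
  }
  cv_curve <- colMeans(acc)
  optimal_count <- as.integer(which.max(cv_curve))  # which.max takes first max
  votes <- colSums(do.call(rbind, lapply(surv, function(s)
    fm$feature_names %in% s[[optimal_count]])))
  names(votes) <- fm$feature_names
  mean_imp <- colMeans(full_imp)
  ord <- order(-votes, -mean_imp)
  optimal_features <- fm$feature_names[ord][seq_len(optimal_count)]
  structure(list(cv_curve = cv_curve, optimal_count = optimal_count,
                 optimal_features = optimal_features,
                 ranking = colMeans(elim_round), votes = votes,
                 fold_subsets = lapply(surv, `[[`, optimal_count)),
            class = "feature_selection")
}

#' Evaluate a classifier under grouped cross-validation
#'
#' Fits on the training groups and predicts the test groups of each fold;
#' reports per-fold and mean accuracy/precision/recall/F1 (support-weighted)
#' and the confusion matrix aggregated over all folds.
#'
#' @param fm A `feature_matrix`.
#' @param spec A `classifier_spec`.
#' @param features Feature subset to use (default: all).
#' @param k Number of grouped folds.
#' @param seed Seed for folds and stochastic fits.
#' @return A `classification_report`: `per_fold` data.frame, `mean` metrics,
#'   `confusion` matrix, `classifier`, `task`, `features`, and a fold
#'   `manifest` (train/test groups per fold).
#' @export
evaluate_model <- function(fm, spec, features = fm$feature_names, k = 5L,
                           seed = 1L) {
  abort_if(!inherits(fm, "feature_matrix"), "fm must be a feature_matrix")
  abort_if(length(features) == 0L, "features must be nonempty")
  abort_if(!all(features %in% fm$feature_names), "unknown feature(s): %s",
           paste(setdiff(features, fm$feature_names), collapse = ", "))
  splits <- group_kfold_splits(fm$groups, k, seed)
  lv <- levels(fm$y)
  conf_total <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  fold_rows <- list()
  for (f in seq_len(k)) {
    idx <- .fold_indices(fm, splits[[f]])
    fit <- fit_classifier(spec, fm$x[idx$train, features, drop = FALSE],
                          fm$y[idx$train], stream_seed(seed, "eval", f))
    pred <- predict_classifier(fit, fm$x[idx$test, features, drop = FALSE])
    truth <- fm$y[idx$test]
    if (nlevels(droplevels(truth)) < length(lv))
      warning(sprintf("fold %d test set is missing a class; metrics computed on present classes", f))
    conf <- table(factor(as.character(truth), levels = lv),
                  factor(pred, levels = lv))
    conf_total <- conf_total + conf
    met <- classification_metrics(conf)
    fold_rows[[f]] <- data.frame(fold = f, accuracy = met$accuracy,
                                 precision = met$precision,
                                 recall = met$recall, f1 = met$f1)
  }
  per_fold <- do.call(rbind, fold_rows)
  structure(list(per_fold = per_fold,
                 mean = as.list(colMeans(per_fold[, -1])),
                 confusion = conf_total,
                 classifier = spec$family, task = fm$task, features = features,
                 manifest = splits),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s / %s, %d feature(s)\n",
              x$task %||% "?", x$classifier, length(x$features)))
  cat(sprintf("  mean accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              x$mean$accuracy, x$mean$precision, x$mean$recall, x$mean$f1))
  invisible(x)
}

#' Run feature selection plus evaluation for one task
#'
#' @param features Parameter table from [cohort_parameter_table()].
#' @param task Classification task, see [build_feature_matrix()].
#' @param system Label recorded in the summary row (`"imu"` or `"walkway"`).
#' @param spec A [classifier_spec()].
#' @param k Number of grouped folds.
#' @param seed Seed.
#' @return List with `selection`, `report`, and a one-row `summary`
#'   data.frame (system, task, classifier, optimal feature count, mean
#'   metrics).
#' @export
run_task <- function(features, task, system = c("imu", "walkway"),
                     spec = classifier_spec("rf"), k = 5L, seed = 1L) {
  system <- match.arg(system)
  abort_if(!task %in% CLASSIFY_TASKS, "unknown task: %s", task)
  fm <- build_feature_matrix(features, task)
  sel <- recursive_feature_elimination(fm, spec, k, seed)
  rep <- evaluate_model(fm, spec, sel$optimal_features, k, seed)
  summary <- data.frame(system = system, task = task, classifier = spec$family,
                        optimal_n_features = sel$optimal_count,
                        accuracy = rep$mean$accuracy,
                        precision = rep$mean$precision,
                        recall = rep$mean$recall, f1 = rep$mean$f1)
  list(selection = sel, report = rep, summary = summary)
}
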