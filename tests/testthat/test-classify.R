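# Classification: grouped folds, metric formulas, recursive feature
# elimination behaviour, and task construction.

# small synthetic feature set: g groups, n rows per group, p noise features,
# plus optionally one perfectly separating feature
toy_features <- function(n_groups = 10, per_group = 12, p_noise = 9,
                         separating = TRUE, n_classes = 2, seed = 5) {
  set.seed(seed)
  groups <- rep(sprintf("G%02d", seq_len(n_groups)), each = per_group)
  y <- factor(rep(rep(paste0("c", seq_len(n_classes)), length.out = n_groups),
                  each = per_group))
  x <- matrix(rnorm(length(groups) * p_noise), ncol = p_noise,
              dimnames = list(NULL, paste0("noise", seq_len(p_noise))))
  if (separating)
    x <- cbind(x, signal = as.integer(y) * 10 + rnorm(length(y), sd = 0.1))
  structure(list(x = x, y = y, groups = groups,
                 feature_names = colnames(x), task = "toy"),
            class = "feature_matrix")
}

test_that("grouped k-fold splits partition groups without leakage", {
  groups <- rep(sprintf("S%02d", 1:10), each = 7)
  splits <- group_kfold_splits(groups, k = 5, seed = 3)
  expect_length(splits, 5L)
  test_groups <- unlist(lapply(splits, `[[`, "test"))
  expect_setequal(test_groups, unique(groups))
  expect_length(test_groups, 10L)          # each group in exactly one test fold
  for (s in splits) {
    expect_length(intersect(s$train, s$test), 0L)
    expect_length(s$test, 2L)              # balanced: 10 groups over 5 folds
  }
  expect_identical(group_kfold_splits(groups, 5, seed = 3), splits)
  expect_error(group_kfold_splits(rep("A", 10), 5), "at least 5")
})

test_that("metric formulas match hand arithmetic on constructed confusions", {
  # binary: TP 45, FP 5, FN 5, TN 45
  conf <- matrix(c(45, 5, 5, 45), 2, 2, byrow = TRUE,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- classification_metrics(conf)
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$precision, 0.90)
  expect_equal(m$recall, 0.90)
  expect_equal(m$f1, 0.90)
  # perfect predictor
  mp <- classification_metrics(diag(c(10, 20, 30)))
  expect_equal(unlist(mp), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # asymmetric binary, hand-computed weighted averages
  conf2 <- matrix(c(8, 2, 4, 6), 2, 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- classification_metrics(conf2)
  expect_equal(m2$accuracy, 14 / 20)
  prec_a <- 8 / 12; prec_b <- 6 / 8
  rec_a <- 8 / 10; rec_b <- 6 / 10
  f1_a <- 2 * prec_a * rec_a / (prec_a + rec_a)
  f1_b <- 2 * prec_b * rec_b / (prec_b + rec_b)
  expect_equal(m2$precision, 0.5 * prec_a + 0.5 * prec_b)
  expect_equal(m2$recall, 0.5 * rec_a + 0.5 * rec_b)
  expect_equal(m2$f1, 0.5 * f1_a + 0.5 * f1_b)
  # balanced binary: accuracy equals support-weighted recall
  expect_equal(m2$accuracy, m2$recall)
})

test_that("RFECV finds a single perfectly separating feature", {
  fm <- toy_features()
  for (family in c("svm", "rf")) {
    sel <- recursive_feature_elimination(fm, classifier_spec(family), seed = 2)
    expect_equal(sel$optimal_count, 1L, label = family)
    expect_identical(sel$optimal_features, "signal")
    expect_equal(max(sel$cv_curve), 1.0)
    expect_named(sel$cv_curve, as.character(1:10))
    rep <- suppressWarnings(   # single-class test folds warn by design
      evaluate_model(fm, classifier_spec(family), sel$optimal_features,
                     seed = 2))
    expect_equal(rep$mean$accuracy, 1.0)
  }
})

test_that("the accuracy curve is defined for every feature count", {
  fm <- toy_features(p_noise = 5)
  sel <- recursive_feature_elimination(fm, classifier_spec("rf"), seed = 2)
  expect_length(sel$cv_curve, 6L)
  expect_true(all(is.finite(sel$cv_curve)))
  expect_true(all(sel$cv_curve >= 0 & sel$cv_curve <= 1))
})

test_that("permuted labels drive the accuracy curve to chance", {
  fm <- toy_features(n_groups = 10, per_group = 8, p_noise = 4)
  set.seed(99)
  curves <- replicate(20, {
    perm <- fm
    perm$y <- factor(sample(as.character(fm$y)), levels = levels(fm$y))
    mean(recursive_feature_elimination(perm, classifier_spec("rf"),
                                       seed = sample.int(1e6, 1))$cv_curve)
  })
  se <- sd(curves) / sqrt(length(curves))
  expect_lt(abs(mean(curves) - 0.5), 3 * se + 0.05)
})

test_that("task construction builds the expected labels", {
  feats <- ref_features("imu")
  fm <- build_feature_matrix(feats, "normal-abnormal")
  expect_setequal(levels(fm$y), c("normal", "abnormal"))
  expect_equal(sum(fm$y == "abnormal"),
               sum(feats$condition %in% c("knee", "ankle")))
  fm3 <- build_feature_matrix(feats, "three-class")
  expect_equal(nlevels(fm3$y), 3L)
  fmka <- build_feature_matrix(feats, "knee-ankle")
  expect_setequal(unique(as.character(fmka$y)), c("knee", "ankle"))
  expect_error(build_feature_matrix(feats[feats$condition != "knee", ],
                                    "knee-ankle"), "knee")
})

test_that("three-class evaluation yields a 3x3 confusion and no group leakage", {
  feats <- ref_features("imu")
  fm <- build_feature_matrix(feats, "three-class")
  rep <- evaluate_model(fm, classifier_spec("rf"),
                        features = c("knee_sagittal_angle_R", "ssr2", "tsr"),
                        seed = 1)
  expect_equal(dim(rep$confusion), c(3L, 3L))
  expect_equal(sum(rep$confusion), length(fm$y))
  # row sums = per-class sample counts
  expect_equal(as.vector(rowSums(rep$confusion)),
               as.vector(table(fm$y)[rownames(rep$confusion)]))
  # manifest proves subject-disjoint folds
  for (s in rep$manifest) expect_length(intersect(s$train, s$test), 0L)
  expect_setequal(unlist(lapply(rep$manifest, `[[`, "test")),
                  unique(fm$groups))
})

test_that("xgboost backend fits, predicts, and reports importances", {
  fm <- toy_features(n_groups = 6, per_group = 10, p_noise = 3)
  sel <- recursive_feature_elimination(fm, classifier_spec("xgb"), seed = 4)
  expect_equal(sel$optimal_features[1], "signal")
  expect_gte(max(sel$cv_curve), 0.95)
  # three-class xgb round trip (tiny folds miss classes; warnings expected)
  fm3 <- toy_features(n_groups = 6, per_group = 10, p_noise = 3, n_classes = 3)
  rep <- suppressWarnings(
    evaluate_model(fm3, classifier_spec("xgb"), "signal", seed = 4))
  expect_gte(rep$mean$accuracy, 0.9)
  expect_equal(sum(rep$confusion), length(fm3$y))
})

test_that("classification degrades to chance when condition effects vanish", {
  # all three "conditions" share the normal-condition targets
  tab <- default_condition_effects()
  normal <- tab[tab$condition == "normal", ]
  ov <- do.call(rbind, lapply(c("knee", "ankle"), function(cc) {
    o <- normal[, c("system", "parameter", "side", "mean", "sd")]
    o$condition <- cc
    o
  }))
  cohort <- simulate_cohort(sim_config(n_subjects = 6, n_trials = 2, seed = 8,
                                       effects_overrides = ov))
  feats <- cohort_parameter_table(cohort, "imu")
  fm <- build_feature_matrix(feats, "three-class")
  rep <- suppressWarnings(evaluate_model(fm, classifier_spec("rf"), k = 5,
                                         seed = 8))
  expect_lt(rep$mean$accuracy, 0.55)   # chance is 1/3
})

test_that("a test fold without a class warns and still reports metrics", {
  fm <- toy_features(n_groups = 6, per_group = 6, p_noise = 2, n_classes = 3)
  ws <- capture_warnings(rep <- evaluate_model(fm, classifier_spec("rf"),
                                               seed = 3))
  expect_true(any(grepl("missing a class", ws)))
  expect_true(is.finite(rep$mean$accuracy))
})

test_that("classifier specs validate their hyperparameters", {
  expect_error(classifier_spec("rf", bogus = 1), "bogus")
  sp <- classifier_spec("xgb", max_depth = 3L)
  expect_equal(sp$params$max_depth, 3L)
  expect_equal(sp$params$eta, 0.3)
})
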