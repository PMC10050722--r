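test_that("ROC curve: staircase shape, tie handling and edge cases", {
  # perfect separation passes through (0, 1)
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("AD", "AD", "HC", "HC"))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))
  # all scores tied: endpoints of the diagonal only
  rc <- roc_curve(rep(0.5, 4), c("AD", "AD", "HC", "HC"))
  expect_equal(rc$fpr, c(0, 1))
  expect_equal(rc$tpr, c(0, 1))
  # interleaved example: 5-point staircase
  rc <- roc_curve(c(0.9, 0.4, 0.5, 0.1), c("AD", "AD", "HC", "HC"))
  expect_equal(nrow(rc), 5)
  expect_equal(rc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(rc$tpr, c(0, 0.5, 0.5, 1, 1))
  # monotone from (0,0) to (1,1)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_error(roc_curve(c(1, 2), c("AD", "AD")), "both classes")
})

test_that("AUC equals the pairwise-comparison statistic on random cases", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c("AD", "AD", "HC", "HC")), 1)
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.1), c("AD", "AD", "HC", "HC")), 0.75)
  set.seed(4)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    labels <- c("AD", "HC", sample(c("AD", "HC"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # plenty of ties
    expect_equal(auc(scores, labels), naive_auc(scores, labels))
    # label-flip symmetry
    flipped <- ifelse(labels == "AD", "HC", "AD")
    expect_equal(auc(scores, flipped), 1 - auc(scores, labels))
  }
})

test_that("AUC of random labels concentrates at 0.5", {
  set.seed(6)
  scores <- runif(60)
  aucs <- replicate(400, auc(scores, sample(rep(c("AD", "HC"), 30))))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("Youden threshold maximizes J with ties toward sensitivity", {
  r <- youden_threshold(c(0.9, 0.8, 0.2, 0.1), c("AD", "AD", "HC", "HC"))
  expect_equal(r$J, 1)
  r <- youden_threshold(rep(0.3, 4), c("AD", "AD", "HC", "HC"))
  expect_equal(r$J, 0)
  # tie between thresholds 0.9 and 0.4 -> lower wins (higher sensitivity)
  r <- youden_threshold(c(0.9, 0.4, 0.5, 0.1), c("AD", "AD", "HC", "HC"))
  expect_equal(r$J, 0.5)
  expect_equal(r$threshold, 0.4)
  expect_equal(r$sensitivity, 1)
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:10, 1)
    labels <- c("AD", "HC", sample(c("AD", "HC"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.2), n, replace = TRUE)
    mine <- youden_threshold(scores, labels)
    oracle <- naive_youden(scores, labels)
    expect_equal(mine$J, oracle$J)
    expect_equal(mine$threshold, oracle$threshold)
  }
})

test_that("confusion metrics count the 2x2 cells correctly", {
  cm <- confusion_metrics(c(0.9, 0.8, 0.3, 0.2),
                          c("AD", "AD", "HC", "HC"), 0.85)
  expect_equal(cm$sensitivity, 0.5)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$ppv, 1)
  expect_equal(cm$npv, 2 / 3)
  expect_equal(cm$accuracy, 0.75)
  # threshold below all scores
  cm <- confusion_metrics(c(0.9, 0.8, 0.3, 0.2),
                          c("AD", "AD", "HC", "HC"), 0)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0)
  expect_true(is.nan(cm$npv))
  expect_match(cm$note, "undefined")
  # report identity: accuracy decomposes over the class mix
  set.seed(12)
  scores <- runif(30)
  labels <- sample(rep(c("AD", "HC"), c(12, 18)))
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(cm$accuracy,
               (cm$sensitivity * 12 + cm$specificity * 18) / 30)
})

test_that("trapezoidal AUC under the reported curve matches the scalar auc", {
  set.seed(3)
  for (rep in 1:20) {
    scores <- sample(seq(0, 1, 0.1), 12, replace = TRUE)
    labels <- c("AD", "HC", sample(c("AD", "HC"), 10, replace = TRUE))
    rc <- roc_curve(scores, labels)
    trap <- sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-nrow(rc)]) / 2)
    expect_equal(trap, auc(scores, labels))
  }
})

test_that("self-built ROC/AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (rep in 1:10) {
    scores <- round(runif(40), 2)
    labels <- sample(rep(c("AD", "HC"), 20))
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("HC", "AD"),
      direction = "<")))
    expect_equal(auc(scores, labels), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("the harness runs the full roster and reports are reproducible", {
  cfg <- cohort_config(n_ad = 8, n_hc = 8, tasks = 1, seed = 3,
                       ad_profile = fast_profiles()$ad,
                       hc_profile = fast_profiles()$hc)
  ft <- extract_features(generate_cohort(cfg))
  x <- ft[, objective_feature_names()]
  rep1 <- run_classifiers(x, ft$group, seed = 11)
  expect_equal(nrow(rep1), 7)
  expect_setequal(rep1$classifier,
                  c("LR", "KNN", "SVM", "GNB", "RF", "XGB", "AdaBoost"))
  expect_true(all(rep1$status == "ok"))
  ok_cols <- c("accuracy", "sensitivity", "specificity", "auc")
  for (cn in ok_cols) {
    expect_true(all(rep1[[cn]] >= 0 & rep1[[cn]] <= 1))
  }
  # J at the chosen threshold is consistent with Se + Sp - 1
  expect_equal(rep1$youden_j,
               rep1$sensitivity + rep1$specificity - 1, tolerance = 1e-12)
  rep2 <- run_classifiers(x, ft$group, seed = 11)
  expect_identical(rep1, rep2)
  # grouped folds keep a writer's strokes in one fold
  rep3 <- run_classifiers(x, ft$group, groups = ft$participant_id,
                          seed = 11)
  expect_true(all(rep3$status == "ok"))
  # resubstitution mode scores the training data
  rep4 <- run_classifiers(x, ft$group, protocol = "resubstitution",
                          seed = 11)
  expect_true(all(rep4$auc >= rep1$auc - 0.1))
})

test_that("a failing adapter is reported but does not stop the harness", {
  ft <- tibble::tibble(f1 = rnorm(20))
  labels <- rep(c("AD", "HC"), 10)
  roster <- list(BAD = function(xtr, ytr, xte) stop("boom"),
                 LR = handkin:::adapter_lr)
  expect_warning(rep <- run_classifiers(ft, labels, roster = roster,
                                        seed = 2), "BAD failed")
  expect_equal(rep$status, c("failed", "ok"))
  expect_true(is.na(rep$auc[1]))
})
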