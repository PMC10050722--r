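# Classifier adapters: each maps (standardized train matrix, factor
# labels with levels HC/AD, test matrix) to AD-probability-like scores in
# [0, 1]. Monotone calibration does not affect AUC, so probability-style
# outputs are used wherever the learner provides them.

adapter_lr <- function(xtr, ytr, xte) {
  df <- as.data.frame(xtr)
  fit <- suppressWarnings(glm(y ~ ., data = cbind(df, y = ytr),
                              family = binomial()))
  as.numeric(suppressWarnings(
    predict(fit, newdata = as.data.frame(xte), type = "response")))
}

adapter_knn <- function(xtr, ytr, xte, k = 5) {
  k <- min(k, nrow(xtr))
  pred <- class::knn(xtr, xte, ytr, k = k, prob = TRUE)
  p <- attr(pred, "prob")
  ifelse(pred == "AD", p, 1 - p)
}

adapter_svm <- function(xtr, ytr, xte) {
  fit <- e1071::svm(xtr, ytr, probability = TRUE, kernel = "radial",
                    scale = FALSE)
  attr(predict(fit, xte, probability = TRUE), "probabilities")[, "AD"]
}

adapter_gnb <- function(xtr, ytr, xte) {
  fit <- e1071::naiveBayes(as.data.frame(xtr), ytr)
  predict(fit, as.data.frame(xte), type = "raw")[, "AD"]
}

adapter_rf <- function(xtr, ytr, xte, ntree = 200) {
  fit <- randomForest::randomForest(xtr, ytr, ntree = ntree)
  predict(fit, xte, type = "prob")[, "AD"]
}

adapter_xgb <- function(xtr, ytr, xte, nrounds = 60) {
  strip <- function(m) matrix(as.numeric(m), nrow(m))
  dtr <- xgboost::xgb.DMatrix(strip(xtr),
                              label = as.numeric(ytr == "AD"))
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3,
                  eta = 0.3, nthread = 1),
    dtr, nrounds = nrounds, verbose = 0)
  as.numeric(predict(fit, xgboost::xgb.DMatrix(strip(xte))))
}

# AdaBoost.M1 over depth-1 rpart stumps; weighted resampling-free fitting
# via rpart's case weights. Scores map the additive margin through a
# logistic link.
adaboost_fit <- function(xtr, ytr, n_rounds = 50, maxdepth = 1) {
  df <- as.data.frame(xtr)
  yy <- ifelse(ytr == "AD", 1, -1)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(
      y ~ ., data = cbind(df, y = factor(yy, levels = c(-1, 1))),
      weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = -1,
                                     minsplit = 2, xval = 0))
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_score <- function(model, xte) {
  df <- as.data.frame(xte)
  if (length(model$stumps) == 0) return(rep(0.5, nrow(df)))
  f <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[m]], df, type = "class") == "1",
                   1, -1)
    f <- f + model$alphas[m] * pred
  }
  1 / (1 + exp(-2 * f))
}

adapter_adaboost <- function(xtr, ytr, xte) {
  adaboost_score(adaboost_fit(xtr, ytr), xte)
}

#' The default seven-classifier roster
#'
#' Logistic regression (LR), k-nearest neighbours (KNN, k = 5),
#' radial-kernel support vector machine (SVM), Gaussian naive Bayes
#' (GNB), random forest (RF), gradient-boosted trees (XGB) and adaptive
#' boosting over decision stumps (AdaBoost). Each entry is an adapter
#' `function(train_x, train_y, test_x)` returning AD scores in `[0, 1]`;
#' users can pass any subset, or their own adapters, to
#' [run_classifiers()].
#'
#' @return a named list of 7 adapter functions.
#' @export
default_classifiers <- function() {
  list(LR = adapter_lr,
       KNN = adapter_knn,
       SVM = adapter_svm,
       GNB = adapter_gnb,
       RF = adapter_rf,
       XGB = adapter_xgb,
       AdaBoost = adapter_adaboost)
}
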