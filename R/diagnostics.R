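check_scored <- function(scores, labels, what) {
  if (length(scores) != length(labels)) {
    stop_hk("%s: scores and labels must have equal length", what)
  }
  if (anyNA(scores) || anyNA(labels)) stop_hk("%s: NA not allowed", what)
  if (!all(labels %in% GROUP_LEVELS)) {
    stop_hk("%s: labels must be 'AD' or 'HC'", what)
  }
  if (length(unique(labels)) < 2) {
    stop_hk("%s: both classes must be present", what)
  }
  invisible(NULL)
}

# cumulative true/false positive counts at thresholds swept down the
# unique scores (ties grouped into one step); shared by roc/auc/youden
roc_steps <- function(scores, labels) {
  pos <- labels == "AD"
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  last <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  list(threshold = s[last], tp = tp, fp = fp,
       n_pos = sum(pos), n_neg = sum(!pos))
}

#' ROC curve of a scored set
#'
#' Thresholds sweep the unique score values (plus +Inf); the decision
#' rule is `score >= threshold` predicts AD. Tied scores collapse into a
#' single step, so the curve is the exact empirical ROC from `(0, 0)` to
#' `(1, 1)`.
#'
#' @param scores continuous classifier scores (higher = more AD-like).
#' @param labels class labels, `"AD"` (positive) or `"HC"`.
#' @return tibble with columns `threshold`, `fpr` (1 - specificity) and
#'   `tpr` (sensitivity), monotone non-decreasing in both rates.
#' @export
roc_curve <- function(scores, labels) {
  check_scored(scores, labels, "roc_curve")
  st <- roc_steps(scores, labels)
  tibble::tibble(threshold = c(Inf, st$threshold),
                 fpr = c(0, st$fp / st$n_neg),
                 tpr = c(0, st$tp / st$n_pos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; numerically identical to the
#' normalized Mann-Whitney statistic
#' `(#\{AD > HC\} + 0.5 #ties) / (n_AD n_HC)`.
#'
#' @inheritParams roc_curve
#' @return area in `[0, 1]`.
#' @examples
#' auc(c(0.9, 0.4, 0.5, 0.1), c("AD", "AD", "HC", "HC"))  # 0.75
#' @export
auc <- function(scores, labels) {
  check_scored(scores, labels, "auc")
  st <- roc_steps(scores, labels)
  fpr <- c(0, st$fp / st$n_neg)
  tpr <- c(0, st$tp / st$n_pos)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Youden-optimal threshold
#'
#' Maximizes `J = sensitivity + specificity - 1` over all candidate
#' thresholds (the unique scores plus +Inf) under the rule
#' `score >= threshold` predicts AD. Ties in `J` are broken toward the
#' lower threshold, favouring sensitivity — the screening use-case.
#'
#' @inheritParams roc_curve
#' @return list with `threshold`, `J`, `sensitivity` and `specificity`
#'   at the optimum.
#' @export
youden_threshold <- function(scores, labels) {
  check_scored(scores, labels, "youden_threshold")
  st <- roc_steps(scores, labels)
  se <- c(0, st$tp / st$n_pos)
  sp <- c(1, 1 - st$fp / st$n_neg)
  thr <- c(Inf, st$threshold)
  j <- se + sp - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(thr[best])]
  list(threshold = thr[pick], J = j[pick],
       sensitivity = se[pick], specificity = sp[pick])
}

#' Confusion-matrix metrics at a threshold
#'
#' Standard 2x2 formulas with AD as the positive class and the rule
#' `score >= threshold` predicts AD. Ratios with a zero denominator are
#' reported as `NaN` and flagged in `note`.
#'
#' @inheritParams roc_curve
#' @param threshold decision threshold.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, the four confusion cells and `note`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  check_scored(scores, labels, "confusion_metrics")
  pred <- scores >= threshold
  pos <- labels == "AD"
  tp <- sum(pred & pos); fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos); fp <- sum(pred & !pos)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  note <- if (tp + fp == 0 || tn + fn == 0) {
    "undefined predictive value (empty predicted class)"
  } else NA_character_
  list(accuracy = (tp + tn) / length(scores),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       tp = tp, fp = fp, tn = tn, fn = fn, note = note)
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(mu = mu, sg = sg)
}

standardize_apply <- function(x, fit) {
  scale(x, center = fit$mu, scale = fit$sg)
}

stratified_folds <- function(y, k, groups = NULL) {
  n <- length(y)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    # all strokes of a participant share a fold (no identity leakage)
    for (cl in unique(y)) {
      gids <- sample(unique(groups[y == cl]))
      gf <- rep_len(seq_len(k), length(gids))
      for (j in seq_along(gids)) fold[groups == gids[j]] <- gf[j]
    }
  }
  fold
}

#' Run the classifier harness and assemble diagnostic reports
#'
#' Each classifier in the roster is fitted under the evaluation protocol
#' (default: stratified 5-fold cross-validation with pooled out-of-fold
#' scores) and its pooled scores are summarized with [roc_curve()],
#' [auc()], [youden_threshold()] and [confusion_metrics()] at the
#' Youden-optimal operating point. Features are standardized with the
#' training fold's moments. `protocol = "resubstitution"` scores the
#' training data itself; `groups` switches to participant-grouped folds
#' so strokes of one writer never straddle a train/test split. A failing
#' classifier yields a row with `status = "failed"` and the pipeline
#' continues.
#'
#' @param features data frame / matrix of numeric feature columns.
#' @param labels class labels (`"AD"` / `"HC"`).
#' @param roster named list of classifier adapters (see
#'   [default_classifiers()]).
#' @param protocol `"cv5"` or `"resubstitution"`.
#' @param groups optional participant ids for grouped folds.
#' @param n_folds folds for cross-validation.
#' @param seed RNG seed for fold assignment and stochastic learners;
#'   recorded in the result's `seed` attribute.
#' @return a tibble with one row per classifier (`classifier`, `status`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `auc`,
#'   `optimal_threshold`, `youden_j`, `n_ad`, `n_hc`) and a `roc`
#'   list-column of ROC point tables.
#' @export
run_classifiers <- function(features, labels,
                            roster = default_classifiers(),
                            protocol = c("cv5", "resubstitution"),
                            groups = NULL, n_folds = 5, seed = 1L) {
  protocol <- match.arg(protocol)
  x <- as.matrix(as.data.frame(features))
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop_hk("run_classifiers: both classes must be present")
  }
  if (ncol(x) < 1) stop_hk("run_classifiers: need at least one feature")
  y <- factor(labels, levels = GROUP_LEVELS)

  set_seed_fixed(seed)
  fold <- if (protocol == "cv5") {
    stratified_folds(labels, n_folds, groups)
  } else {
    rep(1L, length(labels))
  }

  rows <- vector("list", length(roster))
  for (ci in seq_along(roster)) {
    name <- names(roster)[ci]
    scores <- rep(NA_real_, length(labels))
    res <- tryCatch({
      for (f in sort(unique(fold))) {
        if (protocol == "cv5") {
          tr <- fold != f
          te <- fold == f
        } else {
          tr <- te <- rep(TRUE, length(labels))
        }
        sf <- standardize_fit(x[tr, , drop = FALSE])
        xtr <- standardize_apply(x[tr, , drop = FALSE], sf)
        xte <- standardize_apply(x[te, , drop = FALSE], sf)
        set_seed_fixed(mix_seed(seed, name, f))
        scores[te] <- clamp(roster[[ci]](xtr, y[tr], xte), 0, 1)
      }
      yt <- youden_threshold(scores, labels)
      cm <- confusion_metrics(scores, labels, yt$threshold)
      tibble::tibble(classifier = name, status = "ok",
                     accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                     specificity = cm$specificity, ppv = cm$ppv,
                     npv = cm$npv, auc = auc(scores, labels),
                     optimal_threshold = yt$threshold, youden_j = yt$J,
                     n_ad = sum(labels == "AD"), n_hc = sum(labels == "HC"),
                     roc = list(roc_curve(scores, labels)))
    }, error = function(e) {
      warn_hk("classifier %s failed: %s", name, conditionMessage(e))
      tibble::tibble(classifier = name, status = "failed",
                     accuracy = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                     auc = NA_real_, optimal_threshold = NA_real_,
                     youden_j = NA_real_,
                     n_ad = sum(labels == "AD"), n_hc = sum(labels == "HC"),
                     roc = list(NULL))
    })
    rows[[ci]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  attr(out, "protocol") <- protocol
  out
}

#' Plot ROC curves of a diagnostic report set
#'
#' One curve per classifier plus the chance diagonal.
#'
#' @param reports a [run_classifiers()] result.
#' @param main plot title.
#' @return invisibly, `reports`.
#' @export
plot_roc <- function(reports, main = "ROC") {
  ok <- reports[reports$status == "ok", , drop = FALSE]
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey40",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = main)
  for (i in seq_len(nrow(ok))) {
    rc <- ok$roc[[i]]
    graphics::lines(rc$fpr, rc$tpr, col = i + 1)
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", ok$classifier, ok$auc),
                   col = seq_len(nrow(ok)) + 1, lty = 1, cex = 0.8)
  invisible(reports)
}
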