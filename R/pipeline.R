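#' Configuration of a full pipeline run
#'
#' Bundles the cohort configuration with the analysis knobs: entropy
#' binning, screening level, evaluation protocol and classifier roster.
#' The seed is recorded in every output artifact.
#'
#' @param cohort a [cohort_config()].
#' @param n_bins entropy bins for feature extraction.
#' @param alpha screening significance level.
#' @param protocol `"cv5"` or `"resubstitution"`.
#' @param roster names of classifiers from [default_classifiers()] to run.
#' @param unit screening unit (`"stroke"` or `"participant"`).
#' @param group_folds if `TRUE`, use participant-grouped CV folds.
#' @param seed seed for fold assignment and stochastic learners.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), n_bins = 16,
                            alpha = 0.05,
                            protocol = c("cv5", "resubstitution"),
                            roster = names(default_classifiers()),
                            unit = c("stroke", "participant"),
                            group_folds = FALSE, seed = cohort$seed) {
  protocol <- match.arg(protocol)
  unit <- match.arg(unit)
  known <- names(default_classifiers())
  if (!all(roster %in% known)) {
    stop_hk("pipeline_config: unknown classifiers: %s",
            paste(setdiff(roster, known), collapse = ", "))
  }
  if (!is_count(n_bins) || n_bins < 1) {
    stop_hk("pipeline_config: n_bins must be a positive count")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_hk("pipeline_config: alpha must lie in (0, 1]")
  }
  structure(list(cohort = cohort, n_bins = as.integer(n_bins),
                 alpha = alpha, protocol = protocol, roster = roster,
                 unit = unit, group_folds = isTRUE(group_folds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

config_as_list <- function(config) {
  ch <- config$cohort
  list(cohort = list(n_ad = ch$n_ad, n_hc = ch$n_hc, tasks = ch$tasks,
                     seed = ch$seed, sample_rate = ch$sample_rate,
                     ad_profile = unclass(ch$ad_profile),
                     hc_profile = unclass(ch$hc_profile)),
       n_bins = config$n_bins, alpha = config$alpha,
       protocol = config$protocol, roster = config$roster,
       unit = config$unit, group_folds = config$group_folds,
       seed = config$seed)
}

#' Read a pipeline configuration from YAML
#'
#' The YAML schema mirrors [pipeline_config()]/[cohort_config()]; any
#' omitted field keeps its default, and group profiles may override
#' individual [group_profile()] fields.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  prof <- default_profiles()
  patch_profile <- function(base, over) {
    if (is.null(over)) return(base)
    flds <- modifyList(unclass(base), over)
    do.call(group_profile, flds)
  }
  ch <- y$cohort %||% list()
  cohort <- cohort_config(
    n_ad = ch$n_ad %||% 34, n_hc = ch$n_hc %||% 45,
    tasks = unlist(ch$tasks %||% 1:4),
    ad_profile = patch_profile(prof$ad, ch$ad_profile),
    hc_profile = patch_profile(prof$hc, ch$hc_profile),
    seed = ch$seed %||% 1L, sample_rate = ch$sample_rate %||% 100)
  pipeline_config(cohort = cohort,
                  n_bins = y$n_bins %||% 16,
                  alpha = y$alpha %||% 0.05,
                  protocol = y$protocol %||% "cv5",
                  roster = unlist(y$roster %||% names(default_classifiers())),
                  unit = y$unit %||% "stroke",
                  group_folds = y$group_folds %||% FALSE,
                  seed = y$seed %||% cohort$seed)
}

report_to_json <- function(reports, task, path, seed) {
  entries <- lapply(seq_len(nrow(reports)), function(i) {
    r <- reports[i, ]
    roc <- r$roc[[1]]
    list(classifier = r$classifier, status = r$status,
         accuracy = r$accuracy, sensitivity = r$sensitivity,
         specificity = r$specificity, ppv = r$ppv, npv = r$npv,
         auc = r$auc, optimal_threshold = r$optimal_threshold,
         youden_j = r$youden_j, n_ad = r$n_ad, n_hc = r$n_hc,
         roc_points = if (is.null(roc)) NULL else
           list(threshold = roc$threshold, fpr = roc$fpr, tpr = roc$tpr))
  })
  jsonlite::write_json(list(task_id = task, seed = seed,
                            classifiers = entries),
                       path, auto_unbox = TRUE, digits = NA, na = "string")
  invisible(path)
}

#' Run the full simulate -> extract -> screen -> classify pipeline
#'
#' Writes `cohort.csv` (+ annotation sidecar), `features.csv`,
#' `comparisons.csv`, one `report_task<k>.json` per task, a `run.log`
#' and a `manifest.json` capturing the configuration, package/R versions
#' and artifact checksums. Re-running with the same configuration
#' reproduces every artifact bit-for-bit (the log carries timings and is
#' excluded from the manifest checksums). If a task has no significant
#' feature at the configured level, its classification stage is skipped
#' with a notice.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logi <- function(fmt, ...) {
    writeLines(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS1"),
                       sprintf(fmt, ...)), log_con)
  }
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) file.remove(fail_marker)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      logi("stage %s FAILED: %s", name, conditionMessage(e))
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 fail_marker)
      stop_hk("pipeline stage %s failed: %s", name, conditionMessage(e))
    })
    logi("stage %s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  logi("pipeline start, seed %d", config$seed)
  cohort <- stage("simulate", generate_cohort(config$cohort))
  cohort_path <- file.path(out_dir, "cohort.csv")
  stage("write_cohort", write_pen_stream(cohort, cohort_path))

  features <- stage("extract",
                    extract_features(cohort, n_bins = config$n_bins))
  readr::write_csv(features, file.path(out_dir, "features.csv"),
                   progress = FALSE)

  comparisons <- stage("screen",
                       screen_features(features, alpha = config$alpha,
                                       unit = config$unit))
  readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"),
                   progress = FALSE)

  roster <- default_classifiers()[config$roster]
  for (task in config$cohort$tasks) {
    sig <- comparisons$feature[comparisons$task_id == task &
                                 comparisons$significant]
    if (length(sig) == 0) {
      logi("task %d: no significant features at alpha=%g; classify skipped",
           task, config$alpha)
      next
    }
    ft <- features[features$task_id == task, , drop = FALSE]
    reports <- stage(sprintf("classify_task%d", task), run_classifiers(
      ft[, sig, drop = FALSE], ft$group, roster = roster,
      protocol = config$protocol,
      groups = if (config$group_folds) ft$participant_id else NULL,
      seed = config$seed))
    report_to_json(reports, task,
                   file.path(out_dir, sprintf("report_task%d.json", task)),
                   config$seed)
  }

  artifacts <- sort(setdiff(list.files(out_dir),
                            c("run.log", "manifest.json", "FAILED")))
  manifest <- list(
    package = "handkin",
    package_version = as.character(packageVersion("handkin")),
    r_version = R.version.string,
    seed = config$seed,
    config = config_as_list(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts))))
  names(manifest$checksums) <- artifacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logi("pipeline complete: %d artifacts", length(artifacts))
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' One row per (task, classifier) with the standard diagnostic metrics,
#' in the layout of a per-task classifier performance table.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @return a tibble with columns `task_id`, `classifier`, `status`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `auc`,
#'   `optimal_threshold`.
#' @export
report_summary <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_hk("missing artifact: %s", manifest_path)
  }
  paths <- sort(list.files(run_dir, pattern = "^report_task[0-9]+\\.json$",
                           full.names = TRUE))
  if (length(paths) == 0) {
    stop_hk("missing artifact: no report_task*.json in %s", run_dir)
  }
  rows <- lapply(paths, function(p) {
    rep <- jsonlite::read_json(p, simplifyVector = FALSE)
    dplyr::bind_rows(lapply(rep$classifiers, function(cl) {
      num <- function(v) if (is.null(v) || is.character(v)) NA_real_
        else as.numeric(v)
      tibble::tibble(task_id = rep$task_id, classifier = cl$classifier,
                     status = cl$status, accuracy = num(cl$accuracy),
                     sensitivity = num(cl$sensitivity),
                     specificity = num(cl$specificity),
                     ppv = num(cl$ppv), npv = num(cl$npv),
                     auc = num(cl$auc),
                     optimal_threshold = num(cl$optimal_threshold))
    }))
  })
  dplyr::bind_rows(rows)
}
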