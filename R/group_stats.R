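#' Pooled-variance two-sample Student t test
#'
#' Two-sided independent-samples t with pooled variance,
#' `df = n_a + n_b - 2`. Sign convention: positive when group A exceeds
#' group B.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return list with `t`, `p` and `df`.
#' @examples
#' students_t(c(1, 2, 3), c(2, 3, 4))$t  # -1.2247
#' @export
students_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_hk("students_t: both groups need >= 2 values")
  }
  if (var(group_a) + var(group_b) == 0) {
    stop_hk("students_t: degenerate (zero) pooled variance; use mann_whitney_u")
  }
  ht <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

# U statistic of group A from midranks
u_statistic <- function(ranks_a, n_a) sum(ranks_a) - n_a * (n_a + 1) / 2

#' Mann-Whitney U test
#'
#' `U` is computed from rank sums with midranks for ties. The default p
#' value comes from the normal approximation with tie correction and a
#' 0.5 continuity correction; when the pooled size is at most 10 (or
#' `exact = TRUE`), an exact two-sided p is obtained by enumerating all
#' assignments of the pooled midranks to the groups and accumulating
#' configurations at least as extreme (in `|U - n_a n_b / 2|`) as the
#' observed one.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact
#'   enumeration; `NULL` (default) enumerates when `n_a + n_b <= 10`.
#' @return list with `U` (group A), `z` (continuity-corrected,
#'   tie-corrected normal deviate, sign of `U - mean`), `p` (exact or
#'   approximate as selected), `p_approx`, and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact 0.1
#' @export
mann_whitney_u <- function(group_a, group_b, exact = NULL) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a == 0 || n_b == 0) {
    stop_hk("mann_whitney_u: both groups must be non-empty")
  }
  pooled <- c(group_a, group_b)
  n <- n_a + n_b
  r <- rank(pooled)
  u <- u_statistic(r[seq_len(n_a)], n_a)
  mu <- n_a * n_b / 2

  tie_sizes <- table(pooled)
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  s2 <- n_a * n_b / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (s2 <= 0) {
    z <- 0
    p_approx <- 1
  } else {
    dev <- abs(u - mu)
    z_abs <- max(0, dev - 0.5) / sqrt(s2)
    z <- sign(u - mu) * z_abs
    p_approx <- min(1, 2 * pnorm(-z_abs))
  }

  do_exact <- exact %||% (n <= 10)
  if (do_exact) {
    idx <- combn(n, n_a)
    us <- apply(idx, 2, function(ix) u_statistic(r[ix], n_a))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    p <- p_approx
    method <- "normal_approx"
  }
  list(U = u, z = z, p = p, p_approx = p_approx, method = method)
}

#' Choose between Student t and Mann-Whitney U
#'
#' Mirrors the common SPSS-style gate: the parametric test is used only
#' when both groups pass Shapiro-Wilk normality at `alpha_gate` and a
#' Levene (median-centered) variance-homogeneity check passes; otherwise
#' the rank test is used. Groups too small for the gate (n < 3) or
#' constant fall through to Mann-Whitney.
#'
#' @param group_a,group_b numeric vectors.
#' @param alpha_gate gate level (default 0.05).
#' @return `"t"` or `"mann_whitney"`.
#' @export
choose_test <- function(group_a, group_b, alpha_gate = 0.05) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3) return("mann_whitney")
  sw_p <- function(x) {
    if (length(unique(x)) < 3 || var(x) == 0) return(0)
    x <- if (length(x) > 5000) x[seq_len(5000)] else x
    tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  }
  if (sw_p(group_a) <= alpha_gate || sw_p(group_b) <= alpha_gate) {
    return("mann_whitney")
  }
  y <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  lev_p <- tryCatch(car::leveneTest(y, g, center = median)[1, "Pr(>F)"],
                    error = function(e) 0)
  if (is.na(lev_p) || lev_p <= alpha_gate) return("mann_whitney")
  "t"
}

#' Spearman correlation against MoCA-BC
#'
#' Rank correlation with midranks; two-sided p via the t approximation.
#'
#' @param values feature values.
#' @param moca matching MoCA-BC scores.
#' @return list with `rho` and `p`.
#' @export
spearman_vs_moca <- function(values, moca) {
  ok <- complete.cases(values, moca)
  values <- values[ok]
  moca <- moca[ok]
  if (length(values) < 3) stop_hk("spearman_vs_moca: need >= 3 pairs")
  if (var(values) == 0 || var(moca) == 0) {
    stop_hk("spearman_vs_moca: rho undefined for constant input")
  }
  ct <- suppressWarnings(cor.test(values, moca, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Screen every feature for group differences, per task
#'
#' For each (feature, task): missing values are mean-imputed from the
#' observed values of that feature/task column; [choose_test()] picks the
#' test; group summaries are mean +/- SD for t-tested features and
#' median + IQR for rank-tested ones; Spearman correlation against
#' MoCA-BC is attached. Strokes are pooled as independent observations by
#' default (`unit = "stroke"`); `unit = "participant"` first averages
#' each participant's strokes, which respects within-writer correlation
#' and is the mode to use for calibrated inference. No multiplicity
#' correction is applied by default (`adjust = "none"`);
#' Benjamini-Hochberg is available via `adjust = "BH"` (applied within
#' task).
#'
#' @param features a feature table from [extract_features()].
#' @param alpha significance level for the `significant` flag.
#' @param unit `"stroke"` (pooled) or `"participant"` (aggregated means).
#' @param alpha_gate normality-gate level passed to [choose_test()].
#' @param adjust p-value adjustment method (see [stats::p.adjust()]).
#' @return a tibble with one row per (task, feature): `test_used`,
#'   `statistic`, `p_value`, group centers/spreads, `spearman_rho`,
#'   `spearman_p`, `significant`, sizes and imputation count.
#' @export
screen_features <- function(features, alpha = 0.05,
                            unit = c("stroke", "participant"),
                            alpha_gate = 0.05, adjust = "none") {
  unit <- match.arg(unit)
  if (!"group" %in% names(features) || anyNA(features$group)) {
    stop_hk("screen_features: feature table must carry group labels")
  }
  feats <- intersect(feature_names(), names(features))
  if (length(feats) == 0) stop_hk("screen_features: no feature columns found")

  out <- list()
  for (task in sort(unique(features$task_id))) {
    ft <- features[features$task_id == task, , drop = FALSE]
    grp <- ft$group
    moca <- ft$moca_bc

    # per-participant aggregation (means of imputed stroke values)
    pid <- ft$participant_id
    rows <- lapply(feats, function(fn) {
      vals <- ft[[fn]]
      n_imputed <- sum(is.na(vals))
      untestable <- FALSE
      note <- NA_character_
      if (n_imputed > 0) {
        if (all(is.na(vals[grp == "AD"])) || all(is.na(vals[grp == "HC"]))) {
          warn_hk("task %s, feature %s: column entirely missing in one group",
                  task, fn)
          untestable <- TRUE
          note <- "untestable: feature missing in one group"
        } else {
          vals[is.na(vals)] <- mean(vals, na.rm = TRUE)
        }
      }
      if (unit == "participant" && !untestable) {
        agg <- tapply(vals, pid, mean)
        g2 <- tapply(grp, pid, `[`, 1)[names(agg)]
        m2 <- tapply(moca, pid, `[`, 1)[names(agg)]
        vals <- as.numeric(agg)
        grp_u <- as.character(g2)
        moca_u <- as.numeric(m2)
      } else {
        grp_u <- grp
        moca_u <- moca
      }
      a <- vals[grp_u == "AD"]
      h <- vals[grp_u == "HC"]

      row <- list(feature = fn, task_id = task, test_used = NA_character_,
                  statistic = NA_real_, p_value = NA_real_,
                  ad_center = NA_real_, ad_spread = NA_real_,
                  hc_center = NA_real_, hc_spread = NA_real_,
                  summary_type = NA_character_,
                  spearman_rho = NA_real_, spearman_p = NA_real_,
                  n_ad = length(a), n_hc = length(h),
                  n_imputed = n_imputed, note = note)
      if (untestable) return(row)

      test <- choose_test(a, h, alpha_gate)
      if (test == "t" && var(a) + var(h) > 0) {
        tt <- students_t(a, h)
        row$test_used <- "t"
        row$statistic <- tt$t
        row$p_value <- tt$p
        row$ad_center <- mean(a); row$ad_spread <- sd(a)
        row$hc_center <- mean(h); row$hc_spread <- sd(h)
        row$summary_type <- "mean_sd"
      } else {
        mw <- mann_whitney_u(a, h)
        row$test_used <- "mann_whitney"
        row$statistic <- mw$z
        row$p_value <- mw$p
        row$ad_center <- median(a); row$ad_spread <- IQR(a)
        row$hc_center <- median(h); row$hc_spread <- IQR(h)
        row$summary_type <- "median_iqr"
      }
      sp <- tryCatch(spearman_vs_moca(vals, moca_u), error = function(e) NULL)
      if (!is.null(sp)) {
        row$spearman_rho <- sp$rho
        row$spearman_p <- sp$p
      }
      row
    })
    tk <- dplyr::bind_rows(rows)
    tk$p_adjusted <- p.adjust(tk$p_value, method = adjust)
    out[[length(out) + 1L]] <- tk
  }
  res <- dplyr::bind_rows(out)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res
}

#' Demographic balance of a cohort
#'
#' One test per demographic variable at participant level: chi-square
#' (without continuity correction) for categorical variables,
#' Mann-Whitney for continuous/score variables, Kruskal-Wallis for the
#' ordinal income bands. Variables with a single observed category are
#' skipped with a note.
#'
#' @param records a list of `writing_record`s carrying demographics.
#' @return tibble with `variable`, `test`, `statistic`, `p_value`, `note`.
#' @export
cohort_balance <- function(records) {
  pid <- vapply(records, `[[`, character(1), "participant_id")
  first <- !duplicated(pid)
  recs <- records[first]
  grp <- vapply(recs, `[[`, character(1), "group")
  if (length(unique(grp)) < 2) stop_hk("cohort_balance: need both groups")

  demo_val <- function(field) {
    vapply(recs, function(r) {
      v <- r$demographics[[field]]
      if (is.null(v)) NA else as.character(v)
    }, character(1))
  }
  num_val <- function(field, from_demo = TRUE) {
    if (from_demo) as.numeric(demo_val(field))
    else vapply(recs, function(r) as.numeric(r[[field]]), numeric(1))
  }

  rows <- list()
  add <- function(variable, test, statistic, p, note = NA_character_) {
    rows[[length(rows) + 1L]] <<- list(variable = variable, test = test,
                                       statistic = statistic, p_value = p,
                                       note = note)
  }
  categorical <- c("gender", "work_nature", "residence_status",
                   "residence_area")
  for (v in categorical) {
    x <- demo_val(v)
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      add(v, "chi_square", NA_real_, NA_real_, "skipped: single category")
      next
    }
    ht <- suppressWarnings(chisq.test(table(grp[ok], x[ok]),
                                      correct = FALSE))
    add(v, "chi_square", unname(ht$statistic), ht$p.value)
  }
  continuous <- list(age = "age", education_years = "education_years")
  for (v in names(continuous)) {
    x <- num_val(continuous[[v]])
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2) {
      add(v, "mann_whitney", NA_real_, NA_real_, "skipped: constant")
      next
    }
    mw <- mann_whitney_u(x[ok & grp == "AD"], x[ok & grp == "HC"])
    add(v, "mann_whitney", mw$z, mw$p)
  }
  for (v in c("moca_bc", "mmse")) {
    x <- num_val(v, from_demo = FALSE)
    ok <- !is.na(x)
    if (sum(ok & grp == "AD") == 0 || sum(ok & grp == "HC") == 0 ||
        length(unique(x[ok])) < 2) {
      add(v, "mann_whitney", NA_real_, NA_real_, "skipped: unavailable")
      next
    }
    mw <- mann_whitney_u(x[ok & grp == "AD"], x[ok & grp == "HC"])
    add(v, "mann_whitney", mw$z, mw$p)
  }
  inc <- demo_val("income_band")
  ok <- !is.na(inc)
  if (length(unique(inc[ok])) < 2) {
    add("income_band", "kruskal_wallis", NA_real_, NA_real_,
        "skipped: single category")
  } else {
    lv <- c("<=1000", "1001-2999", "3000-4999", ">=5000")
    xo <- as.integer(factor(inc[ok], levels = intersect(lv, unique(inc[ok]))))
    ht <- kruskal.test(xo, factor(grp[ok]))
    add("income_band", "kruskal_wallis", unname(ht$statistic), ht$p.value)
  }
  dplyr::bind_rows(rows)
}
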