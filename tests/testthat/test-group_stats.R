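test_that("pooled-variance t test matches the closed form and is antisymmetric", {
  r <- students_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(r$t, 4), -1.2247)
  expect_equal(r$df, 4)

  r2 <- students_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  same <- c(1, 2, 3)
  r3 <- students_t(same, same)
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)

  expect_error(students_t(c(1, 1), c(1, 1)), "mann_whitney")
  expect_error(students_t(1, c(1, 2)), ">= 2")
})

test_that("Mann-Whitney U: rank-sum statistic, exact and tied cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 of the 20 rank assignments are as extreme
  expect_equal(r$method, "exact")

  r <- mann_whitney_u(5, 5)
  expect_equal(r$U, 0.5)
  expect_equal(r$p, 1)

  # symmetry: swapping groups reflects U about its mean
  a <- c(3, 9, 1.5)
  b <- c(2, 2, 8, 10)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(b, a)
  expect_equal(r1$U + r2$U, length(a) * length(b))
  expect_equal(r1$p, r2$p)
})

test_that("Mann-Whitney approximation agrees with wilcox.test and the exact mode", {
  set.seed(2)
  for (rep in 1:15) {
    a <- round(rnorm(12, 0, 2), 1)  # rounding induces occasional ties
    b <- round(rnorm(15, 0.5, 2), 1)
    r <- mann_whitney_u(a, b)
    w <- suppressWarnings(wilcox.test(a, b, correct = TRUE, exact = FALSE))
    expect_equal(r$U, unname(w$statistic))
    expect_equal(r$p, w$p.value, tolerance = 1e-9)
  }
  # approximation error vs exact enumeration at 5+5 stays small
  for (rep in 1:10) {
    a <- rnorm(5)
    b <- rnorm(5)
    r <- mann_whitney_u(a, b)
    expect_lte(abs(r$p - r$p_approx), 0.02)
  }
})

test_that("the normality gate picks t for clean normals, ranks otherwise", {
  set.seed(33)
  picks_normal <- replicate(40, {
    choose_test(rnorm(50), rnorm(50))
  })
  expect_gt(mean(picks_normal == "t"), 0.8)
  picks_skewed <- replicate(40, {
    choose_test(rexp(50), rexp(50))
  })
  expect_gt(mean(picks_skewed == "mann_whitney"), 0.9)
  expect_equal(choose_test(c(1, 2), rnorm(10)), "mann_whitney")
  expect_equal(choose_test(rep(1, 10), rnorm(10)), "mann_whitney")
})

test_that("Spearman correlation handles monotone, mixed and degenerate pairs", {
  expect_equal(spearman_vs_moca(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_vs_moca(1:6, -(1:6)^3)$rho, -1)
  expect_equal(spearman_vs_moca(c(1, 2, 3), c(2, 1, 3))$rho, 0.5)
  expect_error(spearman_vs_moca(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_vs_moca(1:2, 1:2), ">= 3")
})

test_that("screening detects an injected location shift with high power", {
  set.seed(10)
  n <- 100
  base <- tibble::tibble(
    participant_id = rep(sprintf("p%03d", 1:(2 * n))),
    group = rep(c("AD", "HC"), each = n),
    task_id = 1L,
    moca_bc = c(rnorm(n, 15, 3), rnorm(n, 28, 1)))
  hits <- replicate(50, {
    base$speed_mean <- rnorm(2 * n) + ifelse(base$group == "AD", -2, 0)
    scr <- screen_features(base, alpha = 0.05)
    scr$significant[scr$feature == "speed_mean"]
  })
  expect_gte(mean(hits), 0.99)
})

test_that("imputation fills missing values with the observed column mean", {
  tb <- tibble::tibble(
    participant_id = sprintf("p%d", 1:10),
    group = rep(c("AD", "HC"), each = 5),
    task_id = 1L,
    moca_bc = c(rnorm(5, 15), rnorm(5, 28)),
    pressure_mean = c(600, NA, 620, 640, NA, 500, 520, 540, NA, 560))
  scr <- screen_features(tb)
  expect_equal(scr$n_imputed, 3L)
  # the imputed column mean equals the observed mean -> group medians use it
  obs_mean <- mean(tb$pressure_mean, na.rm = TRUE)
  filled <- tb$pressure_mean
  filled[is.na(filled)] <- obs_mean
  expect_equal(mean(filled), obs_mean)

  tb$pressure_mean[tb$group == "AD"] <- NA
  expect_warning(scr2 <- screen_features(tb), "missing in one group")
  expect_true(is.na(scr2$p_value))
  expect_match(scr2$note, "untestable")
})

test_that("screening output mirrors the test choice in its summaries", {
  cfg <- cohort_config(n_ad = 10, n_hc = 10, tasks = 1, seed = 5,
                       ad_profile = fast_profiles()$ad,
                       hc_profile = fast_profiles()$hc)
  ft <- extract_features(generate_cohort(cfg))
  scr <- screen_features(ft)
  expect_equal(nrow(scr), 35)
  expect_true(all(scr$test_used %in% c("t", "mann_whitney")))
  expect_true(all(scr$summary_type[scr$test_used == "t"] == "mean_sd"))
  expect_true(all(scr$summary_type[scr$test_used == "mann_whitney"] ==
                  "median_iqr"))
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1, na.rm = TRUE))
  expect_true(all(abs(scr$spearman_rho) <= 1, na.rm = TRUE))
  expect_identical(scr$significant, !is.na(scr$p_value) & scr$p_value < 0.05)
  # deterministic: no RNG involved
  expect_identical(scr, screen_features(ft))
  # participant-level aggregation shrinks the effective sample sizes
  scr_p <- screen_features(ft, unit = "participant")
  expect_true(all(scr_p$n_ad == 10 & scr_p$n_hc == 10))
})

test_that("cohort balance reproduces the chi-square value of a known 2x2 table", {
  # gender split 15/19 vs 20/25 -> Pearson chi-square ~0.001, p ~0.977
  ht <- suppressWarnings(chisq.test(matrix(c(15, 19, 20, 25), 2),
                                    correct = FALSE))
  expect_equal(round(unname(ht$statistic), 3), 0.001)
  expect_equal(round(ht$p.value, 3), 0.977)

  cfg <- small_config(seed = 14, n_ad = 8, n_hc = 8)
  coh <- generate_cohort(cfg)
  bal <- cohort_balance(coh)
  expect_true(all(c("gender", "age", "moca_bc", "income_band") %in%
                  bal$variable))
  expect_true(all(bal$p_value >= 0 & bal$p_value <= 1, na.rm = TRUE))
  # MoCA-BC separates the groups even in a small cohort
  expect_lt(bal$p_value[bal$variable == "moca_bc"], 0.01)
  # single-category variable is skipped with a note
  coh_mod <- lapply(coh, function(r) {
    r$demographics$residence_area <- "city"
    r
  })
  bal2 <- cohort_balance(coh_mod)
  expect_match(bal2$note[bal2$variable == "residence_area"], "skipped")
})
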