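test_that("finite-difference kinematics match hand-computed values", {
  st <- make_stroke(t = c(0, 10), x = c(0, 3), y = c(0, 4))
  kin <- derive_kinematics(st)
  expect_equal(kin$v, 500)  # 5 mm over 10 ms
  expect_equal(kin$vx, 300)
  expect_equal(kin$vy, 400)

  # stationary pen
  st <- make_stroke(t = c(0, 10, 20), x = c(1, 1, 1), y = c(2, 2, 2))
  kin <- derive_kinematics(st)
  expect_equal(kin$v, c(0, 0))
  expect_equal(kin$a, 0)

  # uniform motion: constant v, zero a
  st <- make_stroke(t = seq(0, 50, 10), x = seq(0, 5, 1), y = rep(0, 6))
  kin <- derive_kinematics(st)
  expect_true(all(abs(kin$v - 100) < 1e-9))
  expect_true(all(abs(kin$a) < 1e-9))
  expect_equal(length(kin$v), 5)
  expect_equal(length(kin$a), 4)
  # speed decomposition
  expect_equal(kin$v^2, kin$vx^2 + kin$vy^2)

  # duplicate timestamps slip past construction only on raw tables
  st <- handkin:::new_stroke(
    tibble::tibble(t = c(0, 0, 10), x = 1:3, y = 1:3,
                   pressure = rep(500L, 3), on_paper = rep(TRUE, 3)), 1L)
  expect_error(derive_kinematics(st), "timestamps")
})

test_that("Shannon entropy matches the histogram definition", {
  expect_equal(shannon_entropy(rep(7, 4)), 0)
  expect_equal(shannon_entropy(c(0.5, 1.5, 2.5, 3.5, 0.6, 1.6, 2.6, 3.6,
                                 0.7, 1.7, 2.7, 3.7, 0.8, 1.8, 2.8, 3.8),
                               n_bins = 4), 2)
  expect_equal(shannon_entropy(c(1, 1, 2, 2, 2, 2), n_bins = 2),
               -(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3),
               tolerance = 1e-12)
  expect_equal(round(shannon_entropy(c(1, 1, 2, 2, 2, 2), n_bins = 2), 4),
               0.9183)
  expect_error(shannon_entropy(numeric(0)), "empty")
  expect_error(shannon_entropy(1:3, n_bins = 0), "n_bins")
  # bounded by log2(n_bins)
  set.seed(5)
  for (i in 1:10) {
    v <- rnorm(50)
    h <- shannon_entropy(v, 8)
    expect_gte(h, 0)
    expect_lte(h, 3)
  }
})

test_that("slowdown count is the number of deceleration episodes", {
  expect_equal(count_slowdowns(1:10), 0L)
  expect_equal(count_slowdowns(c(10, 5, 10, 5)), 2L)
  expect_equal(count_slowdowns(3), 0L)
  expect_equal(count_slowdowns(c(5, 4, 3, 2)), 1L)
  expect_equal(count_slowdowns(c(1, 2, 2, 1, 0, 3, 1)), 2L)
})

test_that("stroke geometry: lengths, dispersions and tilt", {
  st <- make_stroke(t = c(0, 10), x = c(0, 10), y = c(0, 0))
  g <- stroke_geometry(st)
  expect_equal(g$single_stroke_length, 10)
  expect_equal(g$horizontal_length, 10)
  expect_equal(g$vertical_length, 0)
  expect_equal(g$tilt_angle, 0)

  # ascending 45-degree stroke in the writer's (y-up) frame; stored
  # coordinates are y-down so the stored y decreases
  st <- make_stroke(t = c(0, 10), x = c(0, 5), y = c(0, -5))
  expect_equal(stroke_geometry(st)$tilt_angle, 45)
  # descending stroke: negative tilt
  st <- make_stroke(t = c(0, 10), x = c(0, 5), y = c(0, 5))
  expect_equal(stroke_geometry(st)$tilt_angle, -45)

  # L-shaped path
  st <- make_stroke(t = c(0, 10, 20), x = c(0, 3, 3), y = c(0, 0, 4))
  g <- stroke_geometry(st)
  expect_equal(g$single_stroke_length, 7)
  expect_equal(g$horizontal_length, 3)
  expect_equal(g$vertical_length, 4)
  expect_equal(g$horizontal_length_var, handkin:::pop_var(c(3, 0)))
  # tilt stays in (-90, 90]
  set.seed(8)
  for (i in 1:20) {
    st <- make_stroke(t = seq(0, 40, 10), x = rnorm(5), y = rnorm(5))
    tl <- stroke_geometry(st)$tilt_angle
    expect_gt(tl, -90 - 1e-9)
    expect_lte(tl, 90)
  }
})

test_that("pressure features are population moments plus entropy", {
  st <- make_stroke(t = c(0, 10, 20), x = 1:3, y = 1:3,
                    pressure = rep(100L, 3))
  expect_equal(pressure_features(st),
               list(pressure_mean = 100, pressure_var = 0, pressure_sd = 0,
                    pressure_entropy = 0))
  st <- make_stroke(t = c(0, 10), x = 1:2, y = 1:2,
                    pressure = c(100L, 300L))
  pf <- pressure_features(st)
  expect_equal(pf$pressure_mean, 200)
  expect_equal(pf$pressure_var, 10000)
  expect_equal(pf$pressure_sd, 100)
  expect_equal(pf$pressure_sd^2, pf$pressure_var)
})

test_that("velocity features: extrema, order property, slowdowns", {
  # v = 100, 200, 100 via x increments 1, 2, 1 at 10 ms
  st <- make_stroke(t = c(0, 10, 20, 30), x = c(0, 1, 3, 4), y = rep(0, 4))
  vf <- velocity_features(derive_kinematics(st))
  expect_equal(vf$speed_max, 200)
  expect_equal(vf$speed_min, 100)
  expect_equal(vf$speed_mean, 400 / 3)
  expect_equal(vf$velocity_slowdowns, 1L)
  expect_true(vf$speed_min <= vf$speed_mean &&
              vf$speed_mean <= vf$speed_max)
  # constant velocity: zero variance, entropy, slowdowns
  st <- make_stroke(t = seq(0, 30, 10), x = seq(0, 3, 1), y = rep(0, 4))
  vf <- velocity_features(derive_kinematics(st))
  expect_equal(vf$speed_var, 0)
  expect_equal(vf$velocity_entropy, 0)
  expect_equal(vf$velocity_slowdowns, 0L)
  expect_equal(vf$acceleration_slowdowns, 0L)
})

test_that("temporal features: contact time and preceding in-air interval", {
  rec <- make_record(c(TRUE, TRUE, FALSE, TRUE, TRUE),
                     t = c(0, 90, 100, 150, 200))
  st <- segment_strokes(rec)
  tf <- temporal_features(rec, st)
  expect_equal(tf$single_stroke_time, c(90, 50))
  expect_equal(tf$time_in_air, c(0, 60))
})

test_that("extraction yields one 35-feature vector per stroke", {
  cfg <- small_config(seed = 21)
  rec <- generate_record(cfg, "AD", 1, "AD001")
  ft <- extract_features(rec)
  n_strokes <- length(segment_strokes(rec))
  expect_equal(nrow(ft), n_strokes)
  expect_true(all(feature_names() %in% names(ft)))
  expect_equal(sum(names(ft) %in% feature_names()), 35L)
  expect_true(all(ft$stroke_count == n_strokes))
  expect_true(all(ft$task_score == rec$task_score))
  # locality: task score only affects its own column
  rec2 <- rec
  rec2$task_score <- (rec$task_score + 1L) %% 3L
  ft2 <- extract_features(rec2)
  expect_identical(ft[setdiff(names(ft), "task_score")],
                   ft2[setdiff(names(ft2), "task_score")])
  expect_false(all(ft$task_score == ft2$task_score))
})

test_that("a record with no segmentable strokes yields an empty table", {
  rec <- make_record(c(FALSE, FALSE, TRUE, FALSE))
  expect_warning(ft <- extract_features(rec), "no segmentable")
  expect_equal(nrow(ft), 0)
  expect_true(all(feature_names() %in% names(ft)))
})

test_that("features are scale-equivariant and time-shift invariant", {
  cfg <- small_config(seed = 13)
  rec <- generate_record(cfg, "HC", 1, "HC003")
  ft <- extract_features(rec)

  scaled <- rec
  scaled$samples$x <- 3 * scaled$samples$x
  scaled$samples$y <- 3 * scaled$samples$y
  fs <- extract_features(scaled)
  length_feats <- c("single_stroke_length", "horizontal_length",
                    "vertical_length", "speed_mean", "speed_max",
                    "speed_min", "speed_sd", "horizontal_speed_mean",
                    "vertical_speed_mean", "horizontal_velocity_max",
                    "vertical_velocity_sd")
  for (f in length_feats) expect_equal(fs[[f]], 3 * ft[[f]], tolerance = 1e-9)
  for (f in c("speed_var", "horizontal_velocity_var")) {
    expect_equal(fs[[f]], 9 * ft[[f]], tolerance = 1e-9)
  }
  invariant <- c("tilt_angle", "pressure_entropy", "velocity_entropy",
                 "acceleration_entropy", "velocity_slowdowns",
                 "acceleration_slowdowns", "single_stroke_time",
                 "time_in_air", "stroke_count", "task_score")
  for (f in invariant) expect_equal(fs[[f]], ft[[f]], tolerance = 1e-9)

  shifted <- rec
  shifted$samples$t <- shifted$samples$t + 5000
  fsh <- extract_features(shifted)
  expect_equal(as.data.frame(fsh[feature_names()]),
               as.data.frame(ft[feature_names()]), tolerance = 1e-12)
})

test_that("every feature matches a brute-force oracle on tiny strokes", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    t <- cumsum(c(0, sample(5:20, n - 1, replace = TRUE)))
    x <- round(rnorm(n, 0, 3), 3)
    y <- round(rnorm(n, 0, 3), 3)
    pr <- as.integer(sample(100:900, n, replace = TRUE))
    on <- rep(TRUE, n)
    rec <- writing_record("o", "HC", 1,
                          pen_samples(t, x, y, pr, on), 1, moca_bc = 25)
    ft <- extract_features(rec)
    oracle <- naive_stroke_features(t, x, y, pr)
    for (f in names(oracle)) {
      expect_equal(ft[[f]], oracle[[f]], tolerance = 1e-10,
                   info = sprintf("feature %s, rep %d", f, rep))
    }
  }
})

test_that("the canonical name sets have the right sizes", {
  expect_length(feature_names(), 35)
  expect_length(objective_feature_names(), 33)
  expect_false(any(duplicated(feature_names())))
  expect_true(all(c("task_score", "stroke_count") %in% feature_names()))
})
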