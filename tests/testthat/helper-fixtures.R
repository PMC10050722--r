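# in-code fixtures shared across the suite

make_samples <- function(on_paper, t = NULL, x = NULL, y = NULL,
                         pressure = NULL) {
  n <- length(on_paper)
  pen_samples(t = t %||% seq(0, by = 10, length.out = n),
              x = x %||% seq_len(n),
              y = y %||% rep(0, n),
              pressure = pressure %||% ifelse(on_paper, 500L, 0L),
              on_paper = on_paper)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_record <- function(on_paper = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                        t = NULL, x = NULL, y = NULL, pressure = NULL,
                        task_id = 1, task_score = 1, group = "HC",
                        participant_id = "p1", moca_bc = 28) {
  writing_record(participant_id, group, task_id,
                 make_samples(on_paper, t = t, x = x, y = y,
                              pressure = pressure), task_score,
                 moca_bc = moca_bc)
}

make_stroke <- function(t, x, y, pressure = NULL) {
  handkin:::new_stroke(
    pen_samples(t = t, x = x, y = y,
                pressure = pressure %||% rep(500L, length(t)),
                on_paper = rep(TRUE, length(t))), 1L)
}

small_config <- function(seed = 1, tasks = 1, n_ad = 3, n_hc = 3, ...) {
  cohort_config(n_ad = n_ad, n_hc = n_hc, tasks = tasks, seed = seed, ...)
}

# fast low-volume profiles for simulation-heavy tests: fewer/shorter
# strokes, otherwise the default group contrasts
fast_profiles <- function(identical_groups = FALSE) {
  p <- default_profiles()
  shrink <- function(pr) {
    pr$stroke_count_mean <- 5
    pr$stroke_count_sd <- 1
    pr
  }
  ad <- shrink(p$ad)
  hc <- shrink(p$hc)
  if (identical_groups) ad <- hc
  list(ad = ad, hc = hc)
}

null_config <- function(seed, n_ad = 12, n_hc = 12, tasks = 1) {
  fp <- fast_profiles(identical_groups = TRUE)
  cohort_config(n_ad = n_ad, n_hc = n_hc, tasks = tasks,
                ad_profile = fp$ad, hc_profile = fp$hc, seed = seed)
}

# independent brute-force recomputation of the objective features of one
# stroke, written from the definitions with plain loops (no vectorized
# reuse of package internals)
naive_entropy <- function(v, n_bins = 16) {
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(0)
  counts <- rep(0, n_bins)
  for (val in v) {
    b <- floor((val - lo) / ((hi - lo) / n_bins)) + 1
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1
  }
  h <- 0
  for (cnt in counts) {
    if (cnt > 0) {
      p <- cnt / length(v)
      h <- h - p * log2(p)
    }
  }
  h
}

naive_slowdowns <- function(v) {
  cnt <- 0; in_run <- FALSE
  for (i in seq_along(v)[-1]) {
    if (v[i] < v[i - 1]) {
      if (!in_run) cnt <- cnt + 1
      in_run <- TRUE
    } else in_run <- FALSE
  }
  cnt
}

naive_pvar <- function(v) {
  m <- 0
  for (val in v) m <- m + val
  m <- m / length(v)
  s <- 0
  for (val in v) s <- s + (val - m)^2
  s / length(v)
}

naive_stroke_features <- function(t, x, y, pressure, n_bins = 16) {
  n <- length(t)
  vx <- vy <- v <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    dt <- (t[i + 1] - t[i]) / 1000
    vx[i] <- (x[i + 1] - x[i]) / dt
    vy[i] <- (y[i + 1] - y[i]) / dt
    v[i] <- sqrt(vx[i]^2 + vy[i]^2)
  }
  tv <- numeric(n - 1)
  for (i in 1:(n - 1)) tv[i] <- (t[i] + t[i + 1]) / 2
  a <- if (n >= 3) {
    out <- numeric(n - 2)
    for (j in 1:(n - 2)) out[j] <- (v[j + 1] - v[j]) / ((tv[j + 1] - tv[j]) / 1000)
    out
  } else numeric(0)
  adx <- ady <- seglen <- numeric(n - 1)
  for (i in 1:(n - 1)) {
    adx[i] <- abs(x[i + 1] - x[i])
    ady[i] <- abs(y[i + 1] - y[i])
    seglen[i] <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  xc <- x - mean(x); yc <- -(y - mean(y))
  ang <- 0.5 * atan2(2 * mean(xc * yc), mean(xc^2) - mean(yc^2)) * 180 / pi
  if (mean(xc^2) + mean(yc^2) < 1e-24) ang <- 0
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(
    pressure_mean = mean(pressure),
    pressure_entropy = naive_entropy(pressure, n_bins),
    pressure_var = naive_pvar(pressure),
    pressure_sd = sqrt(naive_pvar(pressure)),
    tilt_angle = ang,
    single_stroke_time = t[n] - t[1],
    horizontal_length = sum(adx),
    vertical_length = sum(ady),
    single_stroke_length = sum(seglen),
    horizontal_length_var = naive_pvar(adx),
    horizontal_length_sd = sqrt(naive_pvar(adx)),
    vertical_length_var = naive_pvar(ady),
    vertical_length_sd = sqrt(naive_pvar(ady)),
    speed_mean = mean(v),
    horizontal_speed_mean = mean(abs(vx)),
    vertical_speed_mean = mean(abs(vy)),
    speed_max = max(v), speed_min = min(v),
    velocity_entropy = naive_entropy(v, n_bins),
    velocity_slowdowns = naive_slowdowns(v),
    speed_var = naive_pvar(v), speed_sd = sqrt(naive_pvar(v)),
    horizontal_velocity_max = max(abs(vx)),
    horizontal_velocity_min = min(abs(vx)),
    vertical_velocity_max = max(abs(vy)),
    vertical_velocity_min = min(abs(vy)),
    horizontal_velocity_var = naive_pvar(abs(vx)),
    horizontal_velocity_sd = sqrt(naive_pvar(abs(vx))),
    vertical_velocity_var = naive_pvar(abs(vy)),
    vertical_velocity_sd = sqrt(naive_pvar(abs(vy))),
    acceleration_entropy = if (length(a) > 0) naive_entropy(a, n_bins) else 0,
    acceleration_slowdowns = naive_slowdowns(a))
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# pairwise-comparison AUC oracle
naive_auc <- function(scores, labels) {
  sa <- scores[labels == "AD"]
  sh <- scores[labels == "HC"]
  wins <- 0
  for (i in seq_along(sa)) for (j in seq_along(sh)) {
    if (sa[i] > sh[j]) wins <- wins + 1
    else if (sa[i] == sh[j]) wins <- wins + 0.5
  }
  wins / (length(sa) * length(sh))
}

# brute-force Youden search over all candidate thresholds
naive_youden <- function(scores, labels) {
  cand <- sort(unique(c(scores, Inf)))
  best_j <- -Inf; best_thr <- Inf
  for (thr in cand) {
    pred <- scores >= thr
    se <- sum(pred & labels == "AD") / sum(labels == "AD")
    sp <- sum(!pred & labels == "HC") / sum(labels == "HC")
    j <- se + sp - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && thr < best_thr)) {
      best_j <- j
      best_thr <- thr
    }
  }
  list(threshold = best_thr, J = best_j)
}
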