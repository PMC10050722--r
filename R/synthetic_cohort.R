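#' Group-level generating profile for synthetic pen streams
#'
#' A profile states the distributional parameters from which one group's
#' handwriting is simulated: log-normal per-segment speed, clamped-normal
#' per-sample pressure, normal positional tremor, exponential in-air
#' pauses, a normal stroke count, and a score distribution per task.
#' Writer-level heterogeneity (a per-record speed multiplier and pressure
#' offset) makes strokes within a record correlated, as in real cohorts.
#'
#' @param speed_mean mean writing speed (mm/s).
#' @param speed_cv coefficient of variation of per-segment speed.
#' @param pressure_mean,pressure_sd per-sample pressure level moments;
#'   the clamped-normal draw must satisfy
#'   `pressure_mean + 4 * pressure_sd <= 1024`.
#' @param pause_rate expected number of genuine hesitation pauses per task
#'   (the remaining inter-stroke gaps are short pen transits).
#' @param pause_mean_ms mean duration of a hesitation pause (ms).
#' @param stroke_count_mean,stroke_count_sd normal draw for the number of
#'   strokes per task (rounded, floored at 2).
#' @param tremor_sd positional jitter SD (mm) added to every sample.
#' @param score_dist list of per-task probability weights over the scores
#'   `0:TASK_MAX_SCORE[task]`, named by task id.
#' @param writer_speed_cv between-writer CV of the record-level speed
#'   multiplier.
#' @param writer_pressure_sd between-writer SD of the record-level
#'   pressure offset (levels).
#' @param moca_mean,moca_sd,mmse_mean,mmse_sd group-level cognitive-score
#'   distributions (clamped to 0--30).
#' @return an object of class `group_profile`.
#' @seealso [default_profiles()]
#' @export
group_profile <- function(speed_mean, speed_cv, pressure_mean, pressure_sd,
                          pause_rate, pause_mean_ms, stroke_count_mean,
                          stroke_count_sd, tremor_sd, score_dist,
                          writer_speed_cv = 0.15, writer_pressure_sd = 35,
                          moca_mean = 26, moca_sd = 2,
                          mmse_mean = 27, mmse_sd = 2) {
  p <- structure(
    list(speed_mean = speed_mean, speed_cv = speed_cv,
         pressure_mean = pressure_mean, pressure_sd = pressure_sd,
         pause_rate = pause_rate, pause_mean_ms = pause_mean_ms,
         stroke_count_mean = stroke_count_mean,
         stroke_count_sd = stroke_count_sd,
         tremor_sd = tremor_sd, score_dist = score_dist,
         writer_speed_cv = writer_speed_cv,
         writer_pressure_sd = writer_pressure_sd,
         moca_mean = moca_mean, moca_sd = moca_sd,
         mmse_mean = mmse_mean, mmse_sd = mmse_sd),
    class = "group_profile")
  validate_group_profile(p)
  p
}

#' @rdname group_profile
#' @param profile a `group_profile`.
#' @export
validate_group_profile <- function(profile) {
  pos <- c("speed_mean", "pressure_mean", "pressure_sd", "pause_mean_ms",
           "stroke_count_mean")
  for (f in pos) {
    if (!is.numeric(profile[[f]]) || profile[[f]] <= 0) {
      stop_hk("group_profile: %s must be positive", f)
    }
  }
  nonneg <- c("speed_cv", "pause_rate", "stroke_count_sd", "tremor_sd",
              "writer_speed_cv", "writer_pressure_sd")
  for (f in nonneg) {
    if (!is.numeric(profile[[f]]) || profile[[f]] < 0) {
      stop_hk("group_profile: %s must be non-negative", f)
    }
  }
  if (profile$pressure_mean + 4 * profile$pressure_sd > PRESSURE_LEVEL_MAX) {
    stop_hk("group_profile: pressure_mean + 4*pressure_sd must be <= %d",
            PRESSURE_LEVEL_MAX)
  }
  for (task in names(profile$score_dist)) {
    w <- profile$score_dist[[task]]
    if (length(w) != TASK_MAX_SCORE[[task]] + 1L || any(w < 0) ||
        sum(w) <= 0) {
      stop_hk("group_profile: score_dist[['%s']] must be %d non-negative weights",
              task, TASK_MAX_SCORE[[task]] + 1L)
    }
  }
  invisible(profile)
}

#' Default AD-like and control-like generating profiles
#'
#' The defaults encode the group differences consistently reported for
#' Alzheimer's handwriting relative to healthy controls: slower writing
#' speed, higher and more variable pen pressure, longer and more frequent
#' in-air pauses, more strokes, larger tremor, lower task scores, and much
#' lower MoCA-BC/MMSE scores. Magnitudes are set to the scale of published
#' per-stroke medians (speeds around 10--15 mm/s, pressure levels around
#' 550--650, in-air medians of roughly 0.2 s for controls versus 0.5 s for
#' patients).
#'
#' @return a list with elements `ad` and `hc`, both [group_profile()]s.
#' @examples
#' p <- default_profiles()
#' p$ad$speed_mean < p$hc$speed_mean
#' @export
default_profiles <- function() {
  hc <- group_profile(
    speed_mean = 15, speed_cv = 0.35,
    pressure_mean = 545, pressure_sd = 60,
    pause_rate = 3, pause_mean_ms = 220,
    stroke_count_mean = 8, stroke_count_sd = 1.5,
    tremor_sd = 0.06,
    score_dist = list(`1` = c(0.02, 0.18, 0.80),
                      `2` = c(0.01, 0.04, 0.20, 0.75),
                      `3` = c(0.01, 0.04, 0.20, 0.75),
                      `4` = c(0.01, 0.02, 0.04, 0.08, 0.25, 0.60)),
    moca_mean = 28.9, moca_sd = 1.2, mmse_mean = 27.9, mmse_sd = 1.5)
  ad <- group_profile(
    speed_mean = 9.5, speed_cv = 0.45,
    pressure_mean = 650, pressure_sd = 90,
    pause_rate = 6, pause_mean_ms = 520,
    stroke_count_mean = 10, stroke_count_sd = 2.5,
    tremor_sd = 0.18,
    score_dist = list(`1` = c(0.25, 0.45, 0.30),
                      `2` = c(0.15, 0.30, 0.35, 0.20),
                      `3` = c(0.15, 0.30, 0.35, 0.20),
                      `4` = c(0.10, 0.20, 0.25, 0.25, 0.15, 0.05)),
    moca_mean = 14.9, moca_sd = 4.0, mmse_mean = 18.2, mmse_sd = 4.0)
  list(ad = ad, hc = hc)
}

#' Configuration of a synthetic cohort
#'
#' @param n_ad,n_hc participants per group (defaults mirror a typical
#'   early-AD screening study: 34 patients, 45 controls).
#' @param tasks subset of `1:4`.
#' @param ad_profile,hc_profile [group_profile()]s.
#' @param seed master integer seed; every record derives a substream seed
#'   from `(seed, participant, task)`.
#' @param sample_rate device sampling rate in Hz (default 100, the frame
#'   rate of dot-matrix pen cameras).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_ad = 34, n_hc = 45, tasks = 1:4,
                          ad_profile = default_profiles()$ad,
                          hc_profile = default_profiles()$hc,
                          seed = 1L, sample_rate = 100) {
  if (!is_count(n_ad) || !is_count(n_hc)) {
    stop_hk("cohort_config: n_ad and n_hc must be non-negative counts")
  }
  if (length(tasks) == 0 || !all(tasks %in% 1:4)) {
    stop_hk("cohort_config: tasks must be a non-empty subset of 1..4")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop_hk("cohort_config: sample_rate must be positive")
  }
  validate_group_profile(ad_profile)
  validate_group_profile(hc_profile)
  structure(list(n_ad = as.integer(n_ad), n_hc = as.integer(n_hc),
                 tasks = as.integer(sort(unique(tasks))),
                 ad_profile = ad_profile, hc_profile = hc_profile,
                 seed = as.integer(seed), sample_rate = sample_rate),
            class = "cohort_config")
}

#' Simulate one stroke along a target polyline
#'
#' Samples positions at the device rate while traversing the template with
#' a per-segment speed drawn from a log-normal with the profile's
#' mean/CV, adds `N(0, tremor_sd)` positional jitter, and draws per-sample
#' pressure from a normal clamped to `[1, 1024]`. Uses the session RNG
#' state (callers seed substreams).
#'
#' @param profile a [group_profile()].
#' @param template two-column matrix of target vertices (mm), at least 2.
#' @param sample_rate sampling rate (Hz).
#' @param t0 timestamp of the first sample (ms).
#' @return a `stroke` sample table (tibble, all samples on-paper).
#' @export
generate_stroke <- function(profile, template, sample_rate = 100, t0 = 0) {
  validate_group_profile(profile)
  if (!is.matrix(template) || nrow(template) < 2) {
    stop_hk("generate_stroke: template needs at least 2 vertices")
  }
  dxy <- diff(template)
  len <- sqrt(rowSums(dxy^2))
  keep <- len > 0
  if (!any(keep)) stop_hk("generate_stroke: template has zero length")
  dxy <- dxy[keep, , drop = FALSE]
  len <- len[keep]
  v0 <- template[-nrow(template), , drop = FALSE][keep, , drop = FALSE]

  cv <- profile$speed_cv
  if (cv < 1e-8) {
    speeds <- rep(profile$speed_mean, length(len))
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(profile$speed_mean) - sdlog^2 / 2
    speeds <- rlnorm(length(len), meanlog, sdlog)
  }
  durs <- len / speeds
  bounds <- cumsum(c(0, durs))
  total <- bounds[length(bounds)]

  dt <- 1 / sample_rate
  n <- max(2L, floor(total / dt) + 1L)
  times <- (seq_len(n) - 1L) * dt
  seg <- clamp(findInterval(times, bounds, rightmost.closed = TRUE),
               1L, length(len))
  frac <- clamp((times - bounds[seg]) / durs[seg], 0, 1)
  x <- v0[seg, 1] + frac * dxy[seg, 1]
  y <- v0[seg, 2] + frac * dxy[seg, 2]
  if (profile$tremor_sd > 0) {
    # tremor as a smooth oscillation in the physiological 4--7 Hz band;
    # per-sample white noise would alias into implausibly large apparent
    # speeds at a 100 Hz frame rate
    freq <- runif(1, 4, 7)
    phase <- runif(2, 0, 2 * pi)
    x <- x + profile$tremor_sd * sin(2 * pi * freq * times + phase[1])
    y <- y + profile$tremor_sd * sin(2 * pi * freq * times + phase[2])
  }
  pressure <- as.integer(round(clamp(
    rnorm(n, profile$pressure_mean, profile$pressure_sd),
    1, PRESSURE_LEVEL_MAX)))

  t_ms <- t0 + round(times * 1000)
  # guard against duplicate ms stamps at exotic sample rates
  if (anyDuplicated(t_ms)) t_ms <- t0 + cumsum(c(0, pmax(1, diff(t_ms))))
  tibble::new_tibble(list(t = as.numeric(t_ms), x = unname(x),
                          y = unname(y), pressure = pressure,
                          on_paper = rep(TRUE, n)), nrow = n)
}

draw_demographics <- function(group) {
  age_mean <- if (group == "AD") 77.2 else 74.8
  edu_mean <- if (group == "AD") 7.8 else 8.9
  list(
    gender = sample(c("male", "female"), 1, prob = c(0.44, 0.56)),
    age = round(clamp(rnorm(1, age_mean, 6), 60, 95)),
    education_years = round(clamp(rnorm(1, edu_mean, 3.5), 0, 20)),
    work_nature = sample(c("mental", "physical"), 1, prob = c(0.51, 0.49)),
    residence_status = sample(
      c("with_spouse", "with_spouse_children", "alone", "with_children",
        "other"), 1, prob = c(0.57, 0.05, 0.14, 0.14, 0.10)),
    residence_area = sample(c("city", "rural"), 1, prob = c(0.62, 0.38)),
    income_band = sample(c("<=1000", "1001-2999", "3000-4999", ">=5000"),
                         1, prob = c(0.215, 0.228, 0.177, 0.38)))
}

#' Simulate one writing record
#'
#' Draws a stroke count, cycles the task's stroke templates (with a small
#' placement jitter), simulates each stroke with [generate_stroke()],
#' fills inter-stroke gaps with off-paper samples (gap durations mix short
#' pen transits with exponential hesitation pauses at the profile's
#' `pause_rate`), and annotates the record with a drawn task score,
#' group-dependent MoCA-BC/MMSE and plausible demographics. Deterministic
#' given `(config$seed, participant_id, task_id)`.
#'
#' @param config a [cohort_config()].
#' @param group `"AD"` or `"HC"`.
#' @param task_id task in `config$tasks`.
#' @param participant_id identifier (drives the RNG substream).
#' @return a `writing_record`.
#' @export
generate_record <- function(config, group, task_id,
                            participant_id = paste0(group, "001")) {
  if (!task_id %in% config$tasks) {
    stop_hk("generate_record: task %s not in config$tasks", task_id)
  }
  profile <- if (group == "AD") config$ad_profile else config$hc_profile
  set_seed_fixed(mix_seed(config$seed, participant_id, task_id))

  # writer-level heterogeneity, shared by all strokes of the record
  wspeed <- if (profile$writer_speed_cv < 1e-8) 1 else {
    sdlog <- sqrt(log(1 + profile$writer_speed_cv^2))
    rlnorm(1, -sdlog^2 / 2, sdlog)
  }
  wpress <- rnorm(1, 0, profile$writer_pressure_sd)
  prof <- profile
  prof$speed_mean <- profile$speed_mean * wspeed
  prof$pressure_mean <- clamp(profile$pressure_mean + wpress,
                              1, PRESSURE_LEVEL_MAX - 4 * profile$pressure_sd)

  n_strokes <- max(2L, as.integer(round(rnorm(1, profile$stroke_count_mean,
                                              profile$stroke_count_sd))))
  templates <- task_templates(task_id)
  n_tpl <- length(templates)
  dt_ms <- 1000 / config$sample_rate

  n_gaps <- n_strokes - 1L
  p_pause <- if (n_gaps > 0) min(1, profile$pause_rate / n_gaps) else 0
  is_pause <- rbinom(max(n_gaps, 0), 1, p_pause) == 1
  gaps <- round(ifelse(is_pause,
                       rexp(n_gaps, 1 / profile$pause_mean_ms),
                       rexp(n_gaps, 1 / 120)) + dt_ms)

  pieces <- vector("list", 2L * n_strokes - 1L)
  t0 <- 0
  prev_last <- NULL
  for (i in seq_len(n_strokes)) {
    tpl <- templates[[((i - 1L) %% n_tpl) + 1L]]
    cycle <- (i - 1L) %/% n_tpl
    shift <- c(rnorm(1, 0, 0.4), 4 * cycle + rnorm(1, 0, 0.4))
    tpl <- sweep(tpl, 2, shift, "+")
    st <- generate_stroke(prof, tpl, config$sample_rate, t0)
    pieces[[2L * i - 1L]] <- st
    last_t <- st$t[nrow(st)]
    if (i < n_strokes) {
      gap <- gaps[i]
      t_next <- last_t + gap
      air_t <- if (t_next - dt_ms / 2 >= last_t + dt_ms) {
        round(seq(last_t + dt_ms, t_next - dt_ms / 2, by = dt_ms))
      } else numeric(0)
      air_t <- air_t[air_t > last_t & air_t < t_next]
      if (length(air_t) > 0) {
        nxt_tpl <- templates[[(i %% n_tpl) + 1L]]
        frac <- (air_t - last_t) / gap
        x_end <- st$x[nrow(st)]
        y_end <- st$y[nrow(st)]
        n_air <- length(air_t)
        pieces[[2L * i]] <- tibble::new_tibble(list(
          t = as.numeric(air_t),
          x = unname(x_end + frac * (nxt_tpl[[1, 1]] - x_end)),
          y = unname(y_end + frac * (nxt_tpl[[1, 2]] - y_end)),
          pressure = rep(0L, n_air),
          on_paper = rep(FALSE, n_air)), nrow = n_air)
      }
      t0 <- t_next
    }
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  col <- function(cn) unlist(lapply(pieces, `[[`, cn), use.names = FALSE)
  samples <- tibble::new_tibble(
    list(t = col("t"), x = col("x"), y = col("y"),
         pressure = col("pressure"), on_paper = col("on_paper")),
    nrow = sum(vapply(pieces, nrow, integer(1))))

  score_w <- profile$score_dist[[as.character(task_id)]]
  score <- sample(0:(length(score_w) - 1L), 1, prob = score_w)
  moca <- round(clamp(rnorm(1, profile$moca_mean, profile$moca_sd), 0, 30))
  mmse <- round(clamp(rnorm(1, profile$mmse_mean, profile$mmse_sd), 0, 30))

  writing_record(participant_id, group, task_id, samples, score,
                 moca, mmse, draw_demographics(group))
}

#' Simulate a full cohort
#'
#' One record per participant and selected task. Each record is generated
#' from its own RNG substream derived from `(seed, participant, task)`, so
#' the output is bit-identical across runs and independent of generation
#' order.
#'
#' @param config a [cohort_config()].
#' @return a list of `writing_record`s (class `writing_cohort`), ordered
#'   by task, then group (AD before HC), then participant.
#' @examples
#' cfg <- cohort_config(n_ad = 2, n_hc = 2, tasks = 1, seed = 7)
#' length(generate_cohort(cfg))  # 4
#' @export
generate_cohort <- function(config) {
  ids <- c(if (config$n_ad > 0) sprintf("AD%03d", seq_len(config$n_ad)),
           if (config$n_hc > 0) sprintf("HC%03d", seq_len(config$n_hc)))
  groups <- c(rep("AD", config$n_ad), rep("HC", config$n_hc))
  records <- list()
  for (task in config$tasks) {
    for (i in seq_along(ids)) {
      records[[length(records) + 1L]] <-
        generate_record(config, groups[i], task, ids[i])
    }
  }
  structure(records, class = "writing_cohort")
}

#' @export
print.writing_cohort <- function(x, ...) {
  groups <- vapply(x, function(r) r$group, character(1))
  tasks <- vapply(x, function(r) r$task_id, integer(1))
  cat(sprintf("<writing_cohort> %d records (%d AD, %d HC), tasks: %s\n",
              length(x), sum(groups == "AD"), sum(groups == "HC"),
              paste(sort(unique(tasks)), collapse = ", ")))
  invisible(x)
}
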