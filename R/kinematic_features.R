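#' Canonical names of the 35 handwriting characteristics
#'
#' Ordered by their conventional row numbering: pressure moments and
#' entropy (1, 2, 4, 5), in-air time (3), tilt angle (6), single-stroke
#' time (7), stroke lengths and their within-stroke dispersions (8--14),
#' average/component speeds (15--17), speed extrema and dispersions
#' (18, 19, 22, 23), velocity entropy (20), slowdown counts (21, 33),
#' component-velocity extrema and dispersions (24--31), acceleration
#' entropy (32), task score (34) and stroke count (35).
#'
#' @return character vector of length 35.
#' @export
feature_names <- function() {
  c("pressure_mean", "pressure_entropy", "time_in_air", "pressure_var",
    "pressure_sd", "tilt_angle", "single_stroke_time",
    "horizontal_length", "vertical_length", "single_stroke_length",
    "horizontal_length_var", "horizontal_length_sd",
    "vertical_length_var", "vertical_length_sd",
    "speed_mean", "horizontal_speed_mean", "vertical_speed_mean",
    "speed_max", "speed_min", "velocity_entropy", "velocity_slowdowns",
    "speed_var", "speed_sd",
    "horizontal_velocity_max", "horizontal_velocity_min",
    "vertical_velocity_max", "vertical_velocity_min",
    "horizontal_velocity_var", "horizontal_velocity_sd",
    "vertical_velocity_var", "vertical_velocity_sd",
    "acceleration_entropy", "acceleration_slowdowns",
    "task_score", "stroke_count")
}

#' @rdname feature_names
#' @details `objective_feature_names()` returns the 33 objective
#'   (instrument-derived) characteristics, i.e. everything except the
#'   rater-assigned task score and the per-task stroke count.
#' @export
objective_feature_names <- function() {
  setdiff(feature_names(), c("task_score", "stroke_count"))
}

feature_key_cols <- function() {
  c("participant_id", "group", "task_id", "stroke_index", "moca_bc", "mmse")
}

#' Finite-difference kinematics of a stroke
#'
#' Component velocities are first differences of position over time
#' (`vx_i = dx_i / dt_i`, dt in seconds), speed is their Euclidean norm,
#' and acceleration is the first difference of speed over the midpoint
#' time grid. No smoothing is applied by default; an optional centered
#' moving average of window 3 can be enabled for noisy traces.
#'
#' @param stroke a `stroke` (at least 2 samples, strictly increasing
#'   timestamps).
#' @param smooth if `TRUE`, apply a centered moving average (window 3) to
#'   the velocity components before deriving speed and acceleration.
#' @return an object of class `kinematic_series` with fields `v` (speed,
#'   mm/s), `vx`, `vy` (signed components), `a` (mm/s^2, length
#'   `length(v) - 1`), and aligned timestamps `t_v`, `t_a` (ms).
#' @examples
#' st <- handkin:::new_stroke(
#'   pen_samples(t = c(0, 10), x = c(0, 3), y = c(0, 4),
#'               pressure = c(500L, 500L), on_paper = c(TRUE, TRUE)), 1)
#' derive_kinematics(st)$v  # 500 mm/s
#' @export
derive_kinematics <- function(stroke, smooth = FALSE) {
  s <- stroke$samples
  if (nrow(s) < 2) stop_hk("derive_kinematics: stroke needs >= 2 samples")
  dt <- diff(s$t)
  if (any(dt <= 0)) {
    stop_hk("derive_kinematics: duplicate or unordered timestamps")
  }
  dts <- dt / 1000
  vx <- diff(s$x) / dts
  vy <- diff(s$y) / dts
  if (smooth && length(vx) >= 3) {
    ma3 <- function(z) {
      out <- z
      out[2:(length(z) - 1)] <- (z[1:(length(z) - 2)] +
                                 z[2:(length(z) - 1)] +
                                 z[3:length(z)]) / 3
      out
    }
    vx <- ma3(vx)
    vy <- ma3(vy)
  }
  v <- sqrt(vx^2 + vy^2)
  t_v <- (s$t[-1] + s$t[-nrow(s)]) / 2
  if (length(v) >= 2) {
    a <- diff(v) / (diff(t_v) / 1000)
    t_a <- (t_v[-1] + t_v[-length(t_v)]) / 2
  } else {
    a <- numeric(0)
    t_a <- numeric(0)
  }
  structure(list(v = v, vx = vx, vy = vy, a = a, t_v = t_v, t_a = t_a),
            class = "kinematic_series")
}

#' Shannon entropy of a numeric series (bits)
#'
#' The empirical distribution is estimated with `n_bins` equal-width bins
#' over `[min, max]`; `H = -sum(p_k log2 p_k)` over non-empty bins. A
#' constant series has zero entropy. Used as a writing-stability proxy
#' for pressure, velocity and acceleration series.
#'
#' @param values non-empty numeric series.
#' @param n_bins number of histogram bins (default 16).
#' @return entropy in bits (`>= 0`, at most `log2(n_bins)`).
#' @examples
#' shannon_entropy(rep(7, 4))                 # 0
#' shannon_entropy(c(1, 1, 2, 2, 2, 2), 2)    # 0.9183
#' @export
shannon_entropy <- function(values, n_bins = 16) {
  if (length(values) == 0) stop_hk("shannon_entropy: empty series")
  if (!is_count(n_bins) || n_bins < 1) {
    stop_hk("shannon_entropy: n_bins must be a positive count")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(n_bins, floor((values - rng[1]) / width) + 1L)
  p <- tabulate(bin, nbins = n_bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Count deceleration episodes
#'
#' A slowdown is a maximal contiguous run of negative first differences —
#' one deceleration episode, however many samples it spans.
#'
#' @param series numeric series (length >= 1).
#' @return non-negative integer count.
#' @examples
#' count_slowdowns(c(10, 5, 10, 5))  # 2
#' @export
count_slowdowns <- function(series) {
  if (length(series) < 2) return(0L)
  neg <- diff(series) < 0
  sum(neg & !c(FALSE, neg[-length(neg)]))
}

#' Geometric features of a stroke
#'
#' Path length is the summed Euclidean displacement; horizontal/vertical
#' lengths are summed absolute component displacements; their dispersions
#' are population variance/SD of the per-sample absolute displacements
#' within the stroke. The tilt angle is the orientation of the first
#' principal axis of the point cloud in the writer's visual frame (y up),
#' measured against the horizontal in `(-90, 90]` degrees — ascending
#' strokes positive. Stored coordinates are y-down, so y is flipped
#' before the principal-axis fit.
#'
#' @param stroke a `stroke` with at least 2 samples.
#' @return named list: `single_stroke_length`, `horizontal_length`,
#'   `vertical_length`, `horizontal_length_var`, `horizontal_length_sd`,
#'   `vertical_length_var`, `vertical_length_sd`, `tilt_angle`.
#' @export
stroke_geometry <- function(stroke) {
  s <- stroke$samples
  if (nrow(s) < 2) stop_hk("stroke_geometry: stroke needs >= 2 samples")
  dx <- diff(s$x)
  dy <- diff(s$y)
  adx <- abs(dx)
  ady <- abs(dy)

  xc <- s$x - mean(s$x)
  yc <- -(s$y - mean(s$y))  # writer frame: y up
  cxx <- mean(xc^2); cyy <- mean(yc^2); cxy <- mean(xc * yc)
  if (cxx + cyy < 1e-24) {
    tilt <- 0
  } else {
    # first principal axis of the 2x2 covariance, closed form
    ang <- 0.5 * atan2(2 * cxy, cxx - cyy)
    tilt <- ang * 180 / pi
    if (tilt <= -90) tilt <- tilt + 180
    if (tilt > 90) tilt <- tilt - 180
  }

  list(single_stroke_length = sum(sqrt(dx^2 + dy^2)),
       horizontal_length = sum(adx),
       vertical_length = sum(ady),
       horizontal_length_var = pop_var(adx),
       horizontal_length_sd = pop_sd(adx),
       vertical_length_var = pop_var(ady),
       vertical_length_sd = pop_sd(ady),
       tilt_angle = tilt)
}

#' Pressure features of a stroke
#'
#' Population mean, variance and SD of the on-paper pressure series, plus
#' its Shannon entropy via [shannon_entropy()].
#'
#' @param stroke a `stroke` with at least 1 sample.
#' @param n_bins entropy bins.
#' @return named list: `pressure_mean`, `pressure_var`, `pressure_sd`,
#'   `pressure_entropy`.
#' @export
pressure_features <- function(stroke, n_bins = 16) {
  p <- stroke$samples$pressure
  if (length(p) == 0) stop_hk("pressure_features: empty stroke")
  list(pressure_mean = mean(p),
       pressure_var = pop_var(p),
       pressure_sd = pop_sd(p),
       pressure_entropy = shannon_entropy(p, n_bins))
}

#' Velocity and acceleration features of a stroke
#'
#' Mean/extrema/dispersion of speed and of the absolute component
#' velocities (signed means would cancel on round trips), Shannon
#' entropies of the speed and acceleration series, and slowdown counts of
#' both. A two-sample stroke has an empty acceleration series; its
#' acceleration entropy and slowdown count are defined as 0.
#'
#' @param kin a [derive_kinematics()] result.
#' @param n_bins entropy bins.
#' @return named list of the 19 speed/acceleration characteristics.
#' @export
velocity_features <- function(kin, n_bins = 16) {
  v <- kin$v
  avx <- abs(kin$vx)
  avy <- abs(kin$vy)
  list(speed_mean = mean(v),
       horizontal_speed_mean = mean(avx),
       vertical_speed_mean = mean(avy),
       speed_max = max(v),
       speed_min = min(v),
       velocity_entropy = shannon_entropy(v, n_bins),
       velocity_slowdowns = count_slowdowns(v),
       speed_var = pop_var(v),
       speed_sd = pop_sd(v),
       horizontal_velocity_max = max(avx),
       horizontal_velocity_min = min(avx),
       vertical_velocity_max = max(avy),
       vertical_velocity_min = min(avy),
       horizontal_velocity_var = pop_var(avx),
       horizontal_velocity_sd = pop_sd(avx),
       vertical_velocity_var = pop_var(avy),
       vertical_velocity_sd = pop_sd(avy),
       acceleration_entropy = if (length(kin$a) > 0)
         shannon_entropy(kin$a, n_bins) else 0,
       acceleration_slowdowns = count_slowdowns(kin$a))
}

#' Per-stroke timing features
#'
#' `single_stroke_time` is the paper-contact duration of the stroke;
#' `time_in_air` is the in-air interval preceding it (0 for the first
#' stroke by convention).
#'
#' @param record the source `writing_record`.
#' @param strokes strokes segmented from `record`.
#' @return tibble with columns `stroke_index`, `single_stroke_time`,
#'   `time_in_air` (ms).
#' @export
temporal_features <- function(record, strokes) {
  if (length(strokes) == 0) {
    return(tibble::tibble(stroke_index = integer(),
                          single_stroke_time = numeric(),
                          time_in_air = numeric()))
  }
  firsts <- vapply(strokes, function(st) st$samples$t[1], numeric(1))
  lasts <- vapply(strokes, function(st) st$samples$t[nrow(st$samples)],
                  numeric(1))
  tibble::tibble(
    stroke_index = vapply(strokes, `[[`, integer(1), "stroke_index"),
    single_stroke_time = lasts - firsts,
    time_in_air = c(0, in_air_intervals(record, strokes)))
}

#' Extract the 35-characteristic feature vectors of a record
#'
#' Segments the record, computes every per-stroke characteristic, and
#' replicates the per-task annotations (task score, stroke count) onto
#' each stroke — each stroke is one analysis unit. Key columns
#' (`participant_id`, `group`, `task_id`, `stroke_index`, `moca_bc`,
#' `mmse`) precede the 35 feature columns.
#'
#' @param record a `writing_record`, or a list of them (e.g. a
#'   [generate_cohort()] result), in which case rows are concatenated.
#' @param n_bins entropy bins (default 16).
#' @param smooth passed to [derive_kinematics()].
#' @return a tibble with one row per stroke; zero rows (with a warning)
#'   if no stroke is segmentable.
#' @export
extract_features <- function(record, n_bins = 16, smooth = FALSE) {
  UseMethod("extract_features")
}

#' @export
extract_features.writing_record <- function(record, n_bins = 16,
                                            smooth = FALSE) {
  strokes <- segment_strokes(record)
  if (length(strokes) == 0) {
    warn_hk("record %s/task %s: no segmentable strokes",
            record$participant_id, record$task_id)
    empty <- stats::setNames(
      rep(list(numeric()), length(feature_names())), feature_names())
    return(tibble::as_tibble(c(
      list(participant_id = character(), group = character(),
           task_id = integer(), stroke_index = integer(),
           moca_bc = numeric(), mmse = numeric()), empty)))
  }
  tf <- temporal_features(record, strokes)
  n_st <- length(strokes)
  fn <- feature_names()
  fv <- matrix(NA_real_, nrow = n_st, ncol = length(fn),
               dimnames = list(NULL, fn))
  for (i in seq_len(n_st)) {
    st <- strokes[[i]]
    kin <- derive_kinematics(st, smooth = smooth)
    vals <- c(pressure_features(st, n_bins),
              list(time_in_air = tf$time_in_air[i],
                   single_stroke_time = tf$single_stroke_time[i]),
              stroke_geometry(st),
              velocity_features(kin, n_bins),
              list(task_score = as.numeric(record$task_score),
                   stroke_count = as.numeric(n_st)))
    fv[i, names(vals)] <- unlist(vals, use.names = FALSE)
  }
  keys <- list(participant_id = rep(record$participant_id, n_st),
               group = rep(record$group, n_st),
               task_id = rep(record$task_id, n_st),
               stroke_index = vapply(strokes, `[[`, integer(1),
                                     "stroke_index"),
               moca_bc = rep(record$moca_bc, n_st),
               mmse = rep(record$mmse, n_st))
  tibble::new_tibble(c(keys, as.list(as.data.frame(fv))), nrow = n_st)
}

#' @export
extract_features.list <- function(record, n_bins = 16, smooth = FALSE) {
  dplyr::bind_rows(lapply(record, extract_features, n_bins = n_bins,
                          smooth = smooth))
}

#' @export
extract_features.writing_cohort <- extract_features.list
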