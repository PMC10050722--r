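#' Pressure-sensor resolution of the pen
#'
#' Digital dot-matrix pens report tip force as an integer level on a
#' 0--1024 scale; samples outside this range are rejected at validation.
#'
#' @format integer scalar.
#' @export
PRESSURE_LEVEL_MAX <- 1024L

#' Maximal attainable score per writing task
#'
#' Task 1 (connecting fixed points) is scored out of 2 (orientation and
#' angle accuracy); task 2 (copying intersecting pentagons) out of 3
#' (pentagon shape, closed intersection, roughly equal side lengths);
#' tasks 3 and 4 award one point per correctly written word (three
#' dictated words, five-word copied phrase).
#'
#' @format named integer vector, one entry per task id `1:4`.
#' @export
TASK_MAX_SCORE <- c(`1` = 2L, `2` = 3L, `3` = 3L, `4` = 5L)

GROUP_LEVELS <- c("HC", "AD")

SAMPLE_COLS <- c("t", "x", "y", "pressure", "on_paper")

#' Build a pen-sample table
#'
#' One row per sensor frame: position in mm (page frame, origin top-left,
#' y increasing downward), timestamp in ms, integer pressure level and the
#' pen-contact flag. Invariants: pressure in `[0, 1024]`; positive
#' pressure implies pen-on-paper; off-paper samples carry zero pressure.
#'
#' @param t numeric timestamps (ms, non-negative, strictly increasing).
#' @param x,y numeric positions (mm).
#' @param pressure integer pressure levels.
#' @param on_paper logical pen-contact states.
#' @return a validated tibble with columns `t, x, y, pressure, on_paper`.
#' @examples
#' pen_samples(t = c(0, 10), x = c(0, 1), y = c(0, 0),
#'             pressure = c(500L, 510L), on_paper = c(TRUE, TRUE))
#' @export
pen_samples <- function(t = numeric(), x = numeric(), y = numeric(),
                        pressure = integer(), on_paper = logical()) {
  s <- tibble::tibble(t = as.numeric(t), x = as.numeric(x),
                      y = as.numeric(y), pressure = as.integer(pressure),
                      on_paper = as.logical(on_paper))
  validate_pen_samples(s)
  s
}

#' Validate a pen-sample table
#'
#' @param samples a data frame with columns `t, x, y, pressure, on_paper`.
#' @param where label used in error messages (e.g. a record id).
#' @return the samples, invisibly; errors name the violated rule.
#' @export
validate_pen_samples <- function(samples, where = "samples") {
  missing_cols <- setdiff(SAMPLE_COLS, names(samples))
  if (length(missing_cols) > 0) {
    stop_hk("%s: missing columns: %s", where,
            paste(missing_cols, collapse = ", "))
  }
  if (nrow(samples) == 0) return(invisible(samples))
  if (anyNA(samples[SAMPLE_COLS])) {
    stop_hk("%s: NA values are not allowed in sample columns", where)
  }
  if (any(samples$t < 0)) {
    stop_hk("%s: timestamps must be non-negative", where)
  }
  if (is.unsorted(samples$t, strictly = TRUE)) {
    stop_hk("%s: timestamps must be strictly increasing", where)
  }
  if (any(samples$pressure < 0L | samples$pressure > PRESSURE_LEVEL_MAX)) {
    stop_hk("%s: pressure must lie in [0, %d]", where, PRESSURE_LEVEL_MAX)
  }
  if (any(samples$pressure > 0L & !samples$on_paper)) {
    stop_hk("%s: positive pressure requires on_paper = TRUE", where)
  }
  if (any(!samples$on_paper & samples$pressure != 0L)) {
    stop_hk("%s: off-paper samples must have pressure = 0", where)
  }
  invisible(samples)
}

#' Construct one writing record (participant x task)
#'
#' A record bundles the full ordered pen stream of one participant writing
#' one task (on- and off-paper samples) with its annotations: group label,
#' task score, cognitive scores and demographics.
#'
#' @param participant_id character identifier.
#' @param group `"AD"` or `"HC"`.
#' @param task_id integer task in `1:4`.
#' @param samples a [pen_samples()] table.
#' @param task_score non-negative integer, at most [TASK_MAX_SCORE] for the
#'   task.
#' @param moca_bc,mmse cognitive screening scores, 0--30 (may be `NA`).
#' @param demographics named list (gender, age, education years, work
#'   nature, residence, income band, ...).
#' @return an object of class `writing_record`.
#' @export
writing_record <- function(participant_id, group, task_id, samples,
                           task_score, moca_bc = NA_real_, mmse = NA_real_,
                           demographics = list()) {
  rec <- structure(
    list(participant_id = as.character(participant_id),
         group = as.character(group),
         task_id = as.integer(task_id),
         samples = tibble::as_tibble(samples),
         task_score = as.integer(task_score),
         moca_bc = as.numeric(moca_bc),
         mmse = as.numeric(mmse),
         demographics = demographics),
    class = "writing_record")
  validate_writing_record(rec)
  rec
}

#' Validate a writing record
#'
#' @param record a `writing_record`.
#' @return the record, invisibly; errors name the record and the rule.
#' @export
validate_writing_record <- function(record) {
  id <- sprintf("record %s/task %s", record$participant_id, record$task_id)
  if (!record$group %in% GROUP_LEVELS) {
    stop_hk("%s: group must be one of %s", id,
            paste(GROUP_LEVELS, collapse = ", "))
  }
  if (!record$task_id %in% 1:4) stop_hk("%s: task_id must be in 1..4", id)
  if (is.na(record$task_score) || record$task_score < 0L ||
      record$task_score > TASK_MAX_SCORE[[as.character(record$task_id)]]) {
    stop_hk("%s: task_score must lie in [0, %d] for task %d", id,
            TASK_MAX_SCORE[[as.character(record$task_id)]], record$task_id)
  }
  for (sc in c("moca_bc", "mmse")) {
    v <- record[[sc]]
    if (!is.na(v) && (v < 0 || v > 30)) {
      stop_hk("%s: %s must lie in [0, 30]", id, sc)
    }
  }
  validate_pen_samples(record$samples, where = id)
  invisible(record)
}

#' @export
print.writing_record <- function(x, ...) {
  cat(sprintf(
    "<writing_record> %s  group=%s task=%d  %d samples (%d on-paper)  score=%d\n",
    x$participant_id, x$group, x$task_id, nrow(x$samples),
    sum(x$samples$on_paper), x$task_score))
  invisible(x)
}

new_stroke <- function(samples, stroke_index) {
  structure(list(samples = samples, stroke_index = as.integer(stroke_index)),
            class = "stroke")
}

#' @export
print.stroke <- function(x, ...) {
  cat(sprintf("<stroke #%d> %d samples, t = %g..%g ms\n", x$stroke_index,
              nrow(x$samples), x$samples$t[1], x$samples$t[nrow(x$samples)]))
  invisible(x)
}

#' Segment a record into strokes
#'
#' A stroke is a maximal contiguous run of pen-on-paper samples. Runs
#' shorter than two samples cannot support finite-difference kinematics
#' and are dropped; the drop count is attached as attribute `n_dropped`.
#'
#' @param record a `writing_record` with time-ordered samples.
#' @return a list of `stroke` objects in temporal order, with attribute
#'   `n_dropped` counting discarded singleton contacts.
#' @examples
#' rec <- writing_record("p1", "HC", 1,
#'   pen_samples(t = c(0, 10, 20, 30, 40, 50), x = 0:5, y = rep(0, 6),
#'               pressure = c(500L, 500L, 0L, 0L, 500L, 500L),
#'               on_paper = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)),
#'   task_score = 2)
#' length(segment_strokes(rec))  # 2
#' @export
segment_strokes <- function(record) {
  s <- record$samples
  if (nrow(s) == 0) {
    return(structure(list(), n_dropped = 0L))
  }
  if (is.unsorted(s$t, strictly = TRUE)) {
    stop_hk("record %s/task %s: timestamps must be strictly increasing",
            record$participant_id, record$task_id)
  }
  r <- rle(s$on_paper)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= 2L)
  dropped <- sum(r$values & r$lengths < 2L)
  strokes <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    strokes[[k]] <- new_stroke(s[starts[i]:ends[i], , drop = FALSE], k)
  }
  structure(strokes, n_dropped = as.integer(dropped))
}

#' In-air intervals between consecutive strokes
#'
#' Interval `i` is the time from the last sample of stroke `i` to the
#' first sample of stroke `i + 1` — the pen-in-air (hesitation) time.
#'
#' @param record the source `writing_record` (kept for interface symmetry;
#'   the intervals derive from the strokes alone).
#' @param strokes strokes produced by [segment_strokes()] from `record`.
#' @return numeric vector of durations in ms, length `length(strokes) - 1`
#'   (empty for fewer than two strokes).
#' @export
in_air_intervals <- function(record, strokes) {
  if (length(strokes) < 2) return(numeric(0))
  firsts <- vapply(strokes, function(st) st$samples$t[1], numeric(1))
  lasts <- vapply(strokes, function(st) st$samples$t[nrow(st$samples)],
                  numeric(1))
  firsts[-1] - lasts[-length(lasts)]
}

## ---- I/O -------------------------------------------------------------

record_key <- function(participant_id, task_id) {
  paste0(participant_id, "|", task_id)
}

annotation_list <- function(rec) {
  list(group = rec$group,
       task_score = rec$task_score,
       moca_bc = rec$moca_bc,
       mmse = rec$mmse,
       demographics = rec$demographics)
}

#' Write writing records to disk
#'
#' Two dialects are supported. `"csv"` (default) writes one row per sample
#' (columns `participant_id, task_id, t_ms, x_mm, y_mm, pressure,
#' on_paper`) plus a JSON annotation sidecar keyed by
#' `participant_id|task_id`. `"json"` writes a single self-contained JSON
#' file. Both round-trip exactly through [read_pen_stream()] (numbers are
#' serialized at full precision).
#'
#' @param records a list of `writing_record`s (or a single record).
#' @param path output file.
#' @param dialect `"csv"` or `"json"`.
#' @param sidecar_path annotation sidecar path for the CSV dialect;
#'   defaults to `<path without extension>.annotations.json`.
#' @return `path`, invisibly.
#' @export
write_pen_stream <- function(records, path, dialect = c("csv", "json"),
                             sidecar_path = NULL) {
  dialect <- match.arg(dialect)
  if (inherits(records, "writing_record")) records <- list(records)
  for (rec in records) validate_writing_record(rec)

  if (dialect == "json") {
    payload <- lapply(records, function(rec) {
      c(list(participant_id = rec$participant_id, task_id = rec$task_id),
        annotation_list(rec),
        list(samples = as.list(rec$samples)))
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         na = "null", null = "null")
    return(invisible(path))
  }

  sidecar_path <- sidecar_path %||%
    paste0(tools::file_path_sans_ext(path), ".annotations.json")
  rows <- lapply(records, function(rec) {
    s <- rec$samples
    # %.17g guarantees an exact decimal round trip for IEEE doubles
    tibble::tibble(participant_id = rep(rec$participant_id, nrow(s)),
                   task_id = rep(rec$task_id, nrow(s)),
                   t_ms = s$t,
                   x_mm = sprintf("%.17g", s$x),
                   y_mm = sprintf("%.17g", s$y),
                   pressure = s$pressure,
                   on_paper = as.integer(s$on_paper))
  })
  readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  ann <- lapply(records, annotation_list)
  names(ann) <- vapply(records,
                       function(r) record_key(r$participant_id, r$task_id),
                       character(1))
  jsonlite::write_json(ann, sidecar_path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null")
  invisible(path)
}

read_annotation <- function(a) {
  demo <- a$demographics
  if (is.null(demo) || length(demo) == 0) demo <- list()
  list(group = a$group,
       task_score = a$task_score,
       moca_bc = if (is.null(a$moca_bc)) NA_real_ else as.numeric(a$moca_bc),
       mmse = if (is.null(a$mmse)) NA_real_ else as.numeric(a$mmse),
       demographics = demo)
}

#' Read writing records from disk
#'
#' Counterpart of [write_pen_stream()]. Every record is validated on
#' ingest; malformed rows raise a parse error naming the line and
#' invariant violations raise a validation error naming the record and
#' rule. An annotation entry without sample rows yields a record with an
#' empty sample table.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"json"`.
#' @param sidecar_path annotation sidecar (CSV dialect); default as in
#'   [write_pen_stream()].
#' @return a list of `writing_record`s in file order (empty, with a
#'   warning, for an empty file).
#' @export
read_pen_stream <- function(path, dialect = c("csv", "json"),
                            sidecar_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_hk("file not found: %s", path)

  if (dialect == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
    if (length(payload) == 0) {
      warn_hk("%s: empty pen-stream file", path)
      return(list())
    }
    return(lapply(payload, function(p) {
      a <- read_annotation(p)
      smp <- p$samples
      samples <- tibble::tibble(
        t = as.numeric(smp$t %||% numeric()),
        x = as.numeric(smp$x %||% numeric()),
        y = as.numeric(smp$y %||% numeric()),
        pressure = as.integer(smp$pressure %||% integer()),
        on_paper = as.logical(smp$on_paper %||% logical()))
      writing_record(p$participant_id, a$group, p$task_id, samples,
                     a$task_score, a$moca_bc, a$mmse, a$demographics)
    }))
  }

  if (file.size(path) == 0) {
    warn_hk("%s: empty pen-stream file", path)
    return(list())
  }
  # base read.csv parses doubles with strtod and so round-trips the
  # %.17g output exactly (fast approximate parsers can be 1 ulp off)
  col_classes <- c(participant_id = "character", task_id = "integer",
                   t_ms = "numeric", x_mm = "numeric", y_mm = "numeric",
                   pressure = "integer", on_paper = "integer")
  header <- names(utils::read.csv(path, nrows = 0))
  missing_cols <- setdiff(names(col_classes), header)
  if (length(missing_cols) > 0) {
    stop_hk("%s: missing columns: %s", path,
            paste(missing_cols, collapse = ", "))
  }
  df <- tryCatch(
    utils::read.csv(path, colClasses = col_classes[header]),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(df)) {
    raw <- utils::read.csv(path, colClasses = "character")
    for (cn in c("task_id", "t_ms", "x_mm", "y_mm", "pressure",
                 "on_paper")) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[cn]]))))
      if (length(bad) > 0) {
        stop_hk("%s: malformed row at line %d: column %s value '%s' is not numeric",
                path, bad[1] + 1L, cn, raw[[cn]][bad[1]])
      }
    }
    stop_hk("%s: malformed file", path)
  }
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0 && is.null(sidecar_path) &&
      !file.exists(paste0(tools::file_path_sans_ext(path),
                          ".annotations.json"))) {
    warn_hk("%s: empty pen-stream file", path)
    return(list())
  }

  sidecar_path <- sidecar_path %||%
    paste0(tools::file_path_sans_ext(path), ".annotations.json")
  if (!file.exists(sidecar_path)) {
    stop_hk("annotation sidecar not found: %s", sidecar_path)
  }
  ann <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)

  keys_csv <- unique(record_key(df$participant_id, df$task_id))
  keys <- c(keys_csv, setdiff(names(ann), keys_csv))
  key_all <- record_key(df$participant_id, df$task_id)
  lapply(keys, function(k) {
    if (is.null(ann[[k]])) {
      stop_hk("%s: no annotation entry for record %s", sidecar_path, k)
    }
    a <- read_annotation(ann[[k]])
    sub <- df[key_all == k, , drop = FALSE]
    samples <- tibble::tibble(t = sub$t_ms, x = sub$x_mm, y = sub$y_mm,
                              pressure = sub$pressure,
                              on_paper = as.logical(sub$on_paper))
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    writing_record(parts[1], a$group, as.integer(parts[2]), samples,
                   a$task_score, a$moca_bc, a$mmse, a$demographics)
  })
}
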