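`%||%` <- function(a, b) if (is.null(a)) b else a

# population (divide-by-n) moments; the per-stroke dispersion features use
# these by default because a stroke is treated as a complete observation
# window, not a sample from a longer one
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

stop_hk <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_hk <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == round(x)

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a participant/task key to a 31-bit seed with a
#' polynomial rolling hash. Records generated from `(seed, participant,
#' task)` substreams are therefore independent of the order in which a
#' cohort is assembled.
#'
#' @param seed master integer seed.
#' @param participant_id participant identifier (coerced to character).
#' @param task_id task identifier.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' mix_seed(1, "AD001", 2)
#' @export
mix_seed <- function(seed, participant_id, task_id) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(paste0(participant_id, "#", task_id))) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# seed the session RNG reproducibly regardless of the user's RNG settings
set_seed_fixed <- function(seed) {
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion",
                            sample.kind = "Rejection"))
}
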