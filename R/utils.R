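# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Deterministic "round half up" used for all reported percentages, so that
#' e.g. 14.75 prints as 14.8 regardless of the platform's banker's rounding.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation functions are reproducible without clobbering
# the session RNG. A NULL seed uses (and advances) the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Maximal runs of TRUE in a logical vector, keeping only runs of at least
# `min_length` bins. Returns data.frame(start, end, length) in bin indices.
find_runs <- function(x, min_length = 1L) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  r <- rle(x)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(start = start[keep], end = end[keep], length = r$lengths[keep])
}

# Count spikes of a sorted timestamp vector in half-open windows.
# side = "right": (a, b]; side = "left": [a, b).
count_in_window <- function(ts, a, b, side = c("right", "left")) {
  side <- match.arg(side)
  if (side == "right") {
    findInterval(b, ts) - findInterval(a, ts)
  } else {
    findInterval(b, ts, left.open = TRUE) - findInterval(a, ts, left.open = TRUE)
  }
}

stop_invalid <- function(...) stop(..., call. = FALSE)
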