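#' Spike train of one sorted unit
#'
#' The atomic input of the analysis: sorted spike timestamps of a single unit
#' (or multi-unit) together with its identity and recording metadata. All
#' timestamps are seconds from the start of the recording.
#'
#' @param timestamps numeric vector of spike times in seconds, strictly
#'   increasing, all within `[recording_start, recording_end]`.
#' @param unit_id character scalar identifying the unit.
#' @param region recording structure; one of `"PUTAMEN"`, `"GPE"`, `"VL"`,
#'   `"OTHER"`.
#' @param sort_quality `"SINGLE"` for well-isolated units, `"MULTI"` when
#'   spikes from more than one neuron could not be separated.
#' @param recording_start,recording_end recording epoch bounds in seconds.
#'   `recording_end` defaults to the last spike time (or `recording_start`
#'   for an empty train).
#' @param distance_to_injection distance to the nearest viral injection site
#'   in mm, or `NA` when unknown.
#'
#' @return an object of class `"spike_train"`.
#' @seealso [unit_qc()], [baseline_stats()], [build_psth()]
#' @export
#' @examples
#' st <- spike_train(c(0.1, 0.35, 1.2), unit_id = "u1", region = "PUTAMEN")
#' st
spike_train <- function(timestamps, unit_id = "u1",
                        region = c("PUTAMEN", "GPE", "VL", "OTHER"),
                        sort_quality = c("SINGLE", "MULTI"),
                        recording_start = 0, recording_end = NULL,
                        distance_to_injection = NA_real_) {
  region <- match.arg(region)
  sort_quality <- match.arg(sort_quality)
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) stop_invalid("spike timestamps contain NA")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop_invalid("timestamps of unit '", unit_id, "' are not strictly increasing")
  }
  if (is.null(recording_end)) {
    recording_end <- if (length(timestamps)) max(timestamps) else recording_start
  }
  if (recording_end < recording_start) {
    stop_invalid("recording_end precedes recording_start")
  }
  if (length(timestamps) &&
      (timestamps[1] < recording_start || timestamps[length(timestamps)] > recording_end)) {
    stop_invalid("timestamps of unit '", unit_id,
                 "' fall outside [recording_start, recording_end]")
  }
  structure(
    list(
      unit_id = as.character(unit_id),
      region = region,
      sort_quality = sort_quality,
      timestamps = timestamps,
      recording_start = recording_start,
      recording_end = recording_end,
      distance_to_injection = as.numeric(distance_to_injection)
    ),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  dur <- x$recording_end - x$recording_start
  cat(sprintf(
    "<spike_train> %s  [%s, %s]  %d spikes over %.1f s (%.2f spikes/s)\n",
    x$unit_id, x$region, x$sort_quality, length(x$timestamps), dur,
    if (dur > 0) length(x$timestamps) / dur else 0
  ))
  invisible(x)
}

#' One train of light pulses
#'
#' Describes a regular train of identical light pulses. Single-pulse
#' experiments are trains with `n_pulses = 1` and varying `pulse_width`.
#'
#' @param onset train onset (first pulse onset) in seconds.
#' @param n_pulses number of pulses (>= 1).
#' @param pulse_width pulse duration in ms; must be strictly shorter than the
#'   inter-pulse period `1000 / pulse_rate` so pulses cannot overlap.
#' @param pulse_rate pulse rate within the train, Hz.
#' @param intensity irradiance at the fiber tip in mW/mm^2 (optional; falls
#'   back to the protocol-level intensity).
#' @return a one-row data.frame used by [stim_protocol()].
#' @export
train_spec <- function(onset, n_pulses = 10, pulse_width = 20, pulse_rate = 30,
                       intensity = NA_real_) {
  if (n_pulses < 1) stop_invalid("n_pulses must be >= 1")
  if (pulse_width < 0) stop_invalid("pulse_width must be non-negative")
  if (pulse_rate <= 0) stop_invalid("pulse_rate must be positive")
  if (n_pulses > 1 && pulse_width >= 1000 / pulse_rate) {
    stop_invalid("pulse_width must be shorter than the inter-pulse period (",
                 format(1000 / pulse_rate), " ms)")
  }
  data.frame(onset = onset, n_pulses = as.integer(n_pulses),
             pulse_width = pulse_width, pulse_rate = pulse_rate,
             intensity = as.numeric(intensity))
}

#' Light-stimulation protocol
#'
#' The full description of one stimulation session: a time-ordered set of
#' non-overlapping pulse trains plus session-level light metadata.
#'
#' @param trains a data.frame with columns `onset`, `n_pulses`, `pulse_width`,
#'   `pulse_rate` (and optionally `intensity`), e.g. built by row-binding
#'   [train_spec()] calls.
#' @param intensity default irradiance in mW/mm^2 for trains that do not carry
#'   their own.
#' @param fiber_diameter optical fiber diameter in micrometers (metadata only).
#' @return an object of class `"stim_protocol"`.
#' @export
#' @examples
#' p <- stim_protocol(rbind(train_spec(0), train_spec(1.5)), intensity = 127)
#' p
stim_protocol <- function(trains, intensity = NA_real_, fiber_diameter = NA_real_) {
  if (is.list(trains) && !is.data.frame(trains)) trains <- do.call(rbind, trains)
  trains <- as.data.frame(trains)
  req <- c("onset", "n_pulses", "pulse_width", "pulse_rate")
  if (!all(req %in% names(trains))) {
    stop_invalid("trains must have columns ", paste(req, collapse = ", "))
  }
  if (!"intensity" %in% names(trains)) trains$intensity <- NA_real_
  trains$intensity[is.na(trains$intensity)] <- intensity
  trains <- trains[order(trains$onset), req <- c(req, "intensity"), drop = FALSE]
  rownames(trains) <- NULL
  for (i in seq_len(nrow(trains))) {
    # re-validate per-train invariants (trains may come from files)
    train_spec(trains$onset[i], trains$n_pulses[i], trains$pulse_width[i],
               trains$pulse_rate[i])
  }
  ends <- trains$onset + train_duration(trains)
  if (nrow(trains) > 1 && any(trains$onset[-1] < ends[-nrow(trains)] - 1e-9)) {
    stop_invalid("stimulation trains overlap")
  }
  structure(
    list(trains = trains, intensity = intensity, fiber_diameter = fiber_diameter),
    class = "stim_protocol"
  )
}

# Duration in seconds of each train (onset of first pulse to offset of last).
train_duration <- function(trains) {
  if (inherits(trains, "stim_protocol")) trains <- trains$trains
  (trains$n_pulses - 1) / trains$pulse_rate + trains$pulse_width / 1000
}

#' @export
print.stim_protocol <- function(x, ...) {
  tr <- x$trains
  cat(sprintf("<stim_protocol> %d trains", nrow(tr)))
  if (nrow(tr)) {
    cat(sprintf(", %s pulses x %s ms at %s Hz",
                paste(unique(tr$n_pulses), collapse = "/"),
                paste(unique(signif(tr$pulse_width, 4)), collapse = "/"),
                paste(unique(tr$pulse_rate), collapse = "/")))
  }
  if (!is.na(x$intensity)) cat(sprintf(", %.4g mW/mm2", x$intensity))
  cat("\n")
  invisible(x)
}

#' Expand a protocol into per-pulse onsets
#'
#' @param protocol a [stim_protocol()].
#' @return data.frame with one row per pulse: `train_id`, `pulse_index`,
#'   `onset_s`, `width_ms`, `rate_hz`, `intensity_mw_mm2`.
#' @export
pulse_onsets <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tr <- protocol$trains
  if (!nrow(tr)) {
    return(data.frame(train_id = integer(), pulse_index = integer(),
                      onset_s = numeric(), width_ms = numeric(),
                      rate_hz = numeric(), intensity_mw_mm2 = numeric()))
  }
  out <- lapply(seq_len(nrow(tr)), function(i) {
    p <- seq_len(tr$n_pulses[i])
    data.frame(train_id = i, pulse_index = p,
               onset_s = tr$onset[i] + (p - 1) / tr$pulse_rate[i],
               width_ms = tr$pulse_width[i], rate_hz = tr$pulse_rate[i],
               intensity_mw_mm2 = tr$intensity[i])
  })
  do.call(rbind, out)
}

#' Recording session container
#'
#' Bundles the spike trains of one recording session with its stimulation
#' protocol (and, for simulated sessions, the generating ground truth).
#'
#' @param units list of [spike_train()] objects with unique ids.
#' @param protocol a [stim_protocol()].
#' @param ground_truth optional data.frame of generating labels (simulation).
#' @return an object of class `"opto_session"`.
#' @export
opto_session <- function(units, protocol, ground_truth = NULL) {
  if (inherits(units, "spike_train")) units <- list(units)
  stopifnot(all(vapply(units, inherits, logical(1), "spike_train")),
            inherits(protocol, "stim_protocol"))
  ids <- vapply(units, `[[`, character(1), "unit_id")
  if (anyDuplicated(ids)) stop_invalid("duplicate unit ids: ",
                                       paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(units) <- ids
  structure(list(units = units, protocol = protocol, ground_truth = ground_truth),
            class = "opto_session")
}

#' @export
print.opto_session <- function(x, ...) {
  cat(sprintf("<opto_session> %d units, %d trains%s\n",
              length(x$units), nrow(x$protocol$trains),
              if (!is.null(x$ground_truth)) ", with ground truth" else ""))
  invisible(x)
}
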