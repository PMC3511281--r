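#' Pulse-width dose-response curve
#'
#' For single-pulse experiments at a set of pulse widths, computes per width
#' the response magnitude as the number of spikes during the 20 ms after pulse
#' onset (regardless of pulse length, the longest width tested) divided by the
#' number of spikes in the 20 ms immediately preceding it, summed over trials.
#' Both windows are half-open, `(onset, onset + 20]` and
#' `(onset - 20, onset]` ms. Significance at each width reuses the 2-SD run
#' detector on a pulse-aligned PSTH with 1 ms bins.
#'
#' @param train a [spike_train()].
#' @param protocol a [stim_protocol()] containing `n_pulses = 1` trains at the
#'   tested widths.
#' @param config a [detection_config()].
#' @param window_ms length of the magnitude windows, ms.
#' @param sig_bin_ms bin width of the significance PSTH, ms.
#' @param sig_pre_bins number of baseline bins of the significance PSTH; the
#'   default 40 matches the train-aligned detector geometry (a longer baseline
#'   window than the 20 ms magnitude window, for a stable SD estimate at low
#'   spontaneous rates).
#' @return data.frame with one row per width: `width_ms`, `magnitude`,
#'   `significant`, `n_trials`.
#' @export
pulse_width_curve <- function(train, protocol, config = detection_config(),
                              window_ms = 20, sig_bin_ms = 1,
                              sig_pre_bins = 40) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tr <- protocol$trains
  single <- tr[tr$n_pulses == 1, , drop = FALSE]
  if (!nrow(single)) stop_invalid("protocol contains no single-pulse trains")
  ts <- if (inherits(train, "spike_train")) train$timestamps else train
  widths <- sort(unique(single$pulse_width))
  w_s <- window_ms / 1000
  nb <- ceiling(window_ms / sig_bin_ms)
  out <- lapply(widths, function(wd) {
    on <- single$onset[single$pulse_width == wd]
    post <- sum(count_in_window(ts, on, on + w_s, side = "right"))
    pre <- sum(count_in_window(ts, on - w_s, on, side = "right"))
    mag <- post / max(pre, config$baseline_floor_spikes)
    det <- tryCatch({
      p <- build_psth(train, on, bin_width = sig_bin_ms, n_pre = sig_pre_bins,
                      n_post = nb, alignment = "PULSE_ONSET")
      detect_response(p, config)
    }, error = function(e) NULL)
    sig <- !is.null(det) &&
      as.character(det$category) %in% c("INCREASE", "COMBINATION")
    data.frame(width_ms = wd, magnitude = mag, significant = sig,
               n_trials = length(on))
  })
  do.call(rbind, out)
}

#' Light-intensity dose-response curve
#'
#' Groups the protocol's trains by irradiance and, per intensity block,
#' computes the train-aligned response magnitude and 2-SD significance, for
#' experiments in which the laser output is varied while the pulse pattern is
#' kept fixed.
#'
#' @param train a [spike_train()].
#' @param protocol a [stim_protocol()] whose trains carry per-train
#'   `intensity` values (one intensity per block of trains).
#' @param config a [detection_config()].
#' @return data.frame with one row per intensity: `intensity`, `magnitude`,
#'   `significant`, `n_trials`, `unreliable` (single-trial block).
#' @export
intensity_curve <- function(train, protocol, config = detection_config()) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tr <- protocol$trains
  if (all(is.na(tr$intensity))) stop_invalid("protocol carries no intensities")
  levels <- sort(unique(tr$intensity))
  out <- lapply(levels, function(I) {
    on <- tr$onset[tr$intensity == I]
    p <- build_psth(train, on, bin_width = config$bin_width_train,
                    n_pre = 40, n_post = 40)
    det <- detect_response(p, config)
    data.frame(intensity = I,
               magnitude = as.numeric(response_magnitude(p, config)),
               significant = as.character(det$category) %in%
                 c("INCREASE", "COMBINATION"),
               n_trials = length(on), unreliable = length(on) < 2)
  })
  do.call(rbind, out)
}

#' Baseline-corrected evoked spikes per pulse position
#'
#' For multi-pulse trains, counts the spikes in `(pulse onset, next pulse
#' onset]` at each within-train pulse position, summed over trains, and
#' subtracts the expected baseline count (`rate x window x n_trains`). The
#' baseline rate is estimated from the pre-train epochs unless supplied.
#'
#' @param train a [spike_train()].
#' @param protocol a [stim_protocol()]; only trains with more than one pulse
#'   are used, and they must share `n_pulses` and `pulse_rate`.
#' @param baseline_rate optional known baseline rate, spikes/s.
#' @param pre_window_s length of the per-train pre-onset epoch used to
#'   estimate the baseline rate, s.
#' @return list with `per_pulse_evoked` (numeric, one per pulse position),
#'   `n_trials`, `baseline_rate`.
#' @export
per_pulse_evoked <- function(train, protocol, baseline_rate = NULL,
                             pre_window_s = 0.325) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tr <- protocol$trains[protocol$trains$n_pulses > 1, , drop = FALSE]
  if (!nrow(tr)) stop_invalid("protocol contains no multi-pulse trains")
  if (length(unique(tr$n_pulses)) > 1 || length(unique(tr$pulse_rate)) > 1) {
    stop_invalid("trains must share n_pulses and pulse_rate")
  }
  ts <- if (inherits(train, "spike_train")) train$timestamps else train
  n_p <- tr$n_pulses[1]
  period <- 1 / tr$pulse_rate[1]
  if (is.null(baseline_rate)) {
    pre <- sum(count_in_window(ts, tr$onset - pre_window_s, tr$onset, "right"))
    baseline_rate <- pre / (pre_window_s * nrow(tr))
  }
  raw <- vapply(seq_len(n_p), function(p) {
    on <- tr$onset + (p - 1) * period
    sum(count_in_window(ts, on, on + period, side = "right"))
  }, numeric(1))
  evoked <- raw - baseline_rate * period * nrow(tr)
  list(per_pulse_evoked = evoked, n_trials = nrow(tr),
       baseline_rate = baseline_rate)
}

#' Within-train response decrement
#'
#' Ratio of the evoked response to the first pulse of a train over the mean
#' evoked response to the remaining pulses; 1 means no decrement, 1.3 means
#' the first pulse evokes 30% more spikes than the later ones.
#'
#' @param evoked numeric vector of (baseline-corrected) evoked counts per
#'   pulse position, or the result of [per_pulse_evoked()].
#' @return list with `per_pulse_evoked` and `first_vs_rest_ratio` (`NA` with a
#'   warning when the later pulses evoke nothing on average).
#' @export
#' @examples
#' train_decrement(c(130, 100, 100, 100, 100))$first_vs_rest_ratio  # 1.3
train_decrement <- function(evoked) {
  if (is.list(evoked)) evoked <- evoked$per_pulse_evoked
  if (length(evoked) < 2) stop_invalid("need evoked counts for >= 2 pulses")
  rest <- mean(evoked[-1])
  ratio <- if (rest <= 0) {
    warning("mean evoked count of later pulses is <= 0; ratio undefined",
            call. = FALSE)
    NA_real_
  } else {
    evoked[1] / rest
  }
  list(per_pulse_evoked = evoked, first_vs_rest_ratio = ratio)
}
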