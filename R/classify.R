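#' Single-unit quality check on short inter-spike intervals
#'
#' A unit is accepted as a single cell when fewer than 1% of its inter-spike
#' intervals are shorter than 2 ms; the check fails when the fraction reaches
#' the 1% threshold. `MULTI`-quality units bypass the rule (they are expected
#' to violate it) and are flagged as bypassed.
#'
#' @param train a [spike_train()] or a numeric vector of spike times.
#' @param short_isi_ms threshold below which an ISI counts as "short", ms.
#' @param max_fraction failure threshold on the fraction of short ISIs.
#' @param time_unit unit of the supplied timestamps (`"s"` or `"ms"`), so the
#'   verdict does not depend on how times are expressed.
#' @return list with `pass` (logical), `fraction_short` and `bypassed`.
#' @export
#' @examples
#' unit_qc(cumsum(rep(0.01, 100)))         # regular 100 Hz unit: pass
unit_qc <- function(train, short_isi_ms = 2, max_fraction = 0.01,
                    time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  quality <- "SINGLE"
  if (inherits(train, "spike_train")) {
    quality <- train$sort_quality
    train <- train$timestamps
  }
  if (length(train) < 2) {
    stop_invalid("unit_qc needs at least 2 spikes")
  }
  thr <- if (time_unit == "s") short_isi_ms / 1000 else short_isi_ms
  frac <- mean(diff(train) < thr)
  if (quality == "MULTI") {
    return(list(pass = TRUE, fraction_short = frac, bypassed = TRUE))
  }
  list(pass = frac < max_fraction, fraction_short = frac, bypassed = FALSE)
}

#' Baseline firing statistics over a pre-stimulation epoch
#'
#' Computes the mean firing rate and the ISI coefficient of variation
#' (sample SD / mean of the intervals fully inside the epoch), the two axes of
#' the striatal electrophysiological classification. The epoch must cover at
#' least 120 s of pre-stimulation recording; shorter epochs are a
#' configuration error unless explicitly overridden (useful in simulations).
#'
#' @param train a [spike_train()] or numeric vector of spike times (s).
#' @param epoch numeric `c(t0, t1)` bounding the baseline epoch, s.
#' @param min_epoch_s minimum accepted epoch length, s.
#' @param enforce_min set `FALSE` to allow shorter epochs.
#' @return object of class `"baseline_stats"`: list with `firing_rate`
#'   (spikes/s), `cv` (`NA` and flagged when fewer than 3 spikes), `n_spikes`,
#'   `epoch_duration`.
#' @export
#' @examples
#' st <- simulate_baseline_train(default_profiles()$tan, 150, seed = 2)
#' baseline_stats(st, c(0, 150))
baseline_stats <- function(train, epoch, min_epoch_s = 120, enforce_min = TRUE) {
  if (inherits(train, "spike_train")) train <- train$timestamps
  stopifnot(length(epoch) == 2, epoch[2] > epoch[1])
  dur <- epoch[2] - epoch[1]
  if (enforce_min && dur < min_epoch_s) {
    stop_invalid("baseline epoch must be at least ", min_epoch_s,
                 " s (got ", format(dur), " s); use enforce_min = FALSE to override")
  }
  ts <- train[train >= epoch[1] & train < epoch[2]]
  n <- length(ts)
  cv <- NA_real_
  if (n >= 3) {
    isi <- diff(ts)
    cv <- stats::sd(isi) / mean(isi)
  }
  structure(list(firing_rate = n / dur, cv = cv, n_spikes = n,
                 epoch_duration = dur),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> %.3g spikes/s, CV %s (%d spikes / %.0f s)\n",
              x$firing_rate, if (is.na(x$cv)) "undefined" else sprintf("%.3f", x$cv),
              x$n_spikes, x$epoch_duration))
  invisible(x)
}

#' Electrophysiological classification of striatal units
#'
#' Applies the rate/CV rules for striatal cell classes, in order:
#' phasically active neurons (PAN, projection neurons) have firing rate
#' <= 2.5 spikes/s with CV >= 1; tonically active neurons (TAN, cholinergic
#' interneurons) fire between 2 and 12 spikes/s with CV < 1; fast-spiking
#' neurons (FSN, GABAergic interneurons) fire above 12 spikes/s regardless of
#' CV. Units matching no rule (or with undefined CV) are `UNCLASSIFIED`. The
#' TAN interval is read as the closed interval `[2, 12]`; the PAN/TAN overlap
#' at 2-2.5 spikes/s is resolved by the CV, and rule precedence
#' PAN > TAN > FSN settles any pathological tie.
#'
#' @param stats a [baseline_stats()] object, or a firing rate in spikes/s
#'   (then `cv` must be given).
#' @param cv ISI coefficient of variation, when `stats` is a plain rate.
#' @return factor with levels `PAN`, `TAN`, `FSN`, `UNCLASSIFIED`.
#' @export
#' @examples
#' classify_striatal(1.0, cv = 1.5)   # PAN
#' classify_striatal(5.0, cv = 0.5)   # TAN
#' classify_striatal(20.0, cv = 0.8)  # FSN
classify_striatal <- function(stats, cv = NULL) {
  if (inherits(stats, "baseline_stats")) {
    rate <- stats$firing_rate
    cv <- stats$cv
  } else {
    rate <- stats
    if (is.null(cv)) stop_invalid("cv must be supplied with a plain firing rate")
  }
  lv <- c("PAN", "TAN", "FSN", "UNCLASSIFIED")
  if (is.na(cv)) {
    warning("CV undefined; unit left UNCLASSIFIED", call. = FALSE)
    return(factor("UNCLASSIFIED", levels = lv))
  }
  cls <- if (rate <= 2.5 && cv >= 1) "PAN"
         else if (rate >= 2 && rate <= 12 && cv < 1) "TAN"
         else if (rate > 12) "FSN"
         else "UNCLASSIFIED"
  factor(cls, levels = lv)
}
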