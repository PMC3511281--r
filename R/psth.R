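#' Detection configuration
#'
#' Parameters of the evoked-response detector and derived statistics.
#'
#' @param sd_multiplier number of baseline standard deviations a bin must
#'   exceed (default 2).
#' @param min_consecutive_bins minimum run length of exceeding bins
#'   (default 2).
#' @param min_trials minimum number of trials for a non-provisional verdict
#'   (default 30).
#' @param bin_width_train PSTH bin width for train-aligned analysis, ms
#'   (default 8.125, i.e. 40 bins per 325 ms window).
#' @param bin_width_pulse PSTH bin width for single-pulse-aligned analysis, ms
#'   (default 0.25).
#' @param baseline_floor_spikes floor applied to the baseline spike count in
#'   the fold-change magnitude, so a silent baseline yields a finite ratio.
#' @return object of class `"detection_config"`.
#' @export
detection_config <- function(sd_multiplier = 2, min_consecutive_bins = 2,
                             min_trials = 30, bin_width_train = 8.125,
                             bin_width_pulse = 0.25, baseline_floor_spikes = 1) {
  vals <- c(sd_multiplier, min_consecutive_bins, min_trials,
            bin_width_train, bin_width_pulse, baseline_floor_spikes)
  if (any(vals <= 0)) stop_invalid("all detection parameters must be positive")
  structure(list(sd_multiplier = sd_multiplier,
                 min_consecutive_bins = as.integer(min_consecutive_bins),
                 min_trials = as.integer(min_trials),
                 bin_width_train = bin_width_train,
                 bin_width_pulse = bin_width_pulse,
                 baseline_floor_spikes = baseline_floor_spikes),
            class = "detection_config")
}

#' Peri-stimulus time histogram
#'
#' Bins spikes relative to repeated alignment events into
#' `n_pre + n_post` left-closed right-open bins of `bin_width` ms, summed over
#' trials (per-trial counts are kept for trial-resolved statistics). A spike
#' at time `t` relative to its event falls in bin
#' `floor((t - e)/w) + n_pre + 1` for `t - e` in `[-n_pre*w, n_post*w)`.
#' Events whose window extends beyond the recording are dropped with a
#' warning.
#'
#' @param train a [spike_train()] (or numeric vector of spike times, s).
#' @param events alignment times, s (train onsets or pulse onsets).
#' @param bin_width bin width, ms.
#' @param n_pre,n_post number of bins before/after the alignment time.
#' @param alignment label recording what the events are
#'   (`"TRAIN_ONSET"` or `"PULSE_ONSET"`).
#' @return object of class `"psth"`: list with `counts` (summed over trials),
#'   `per_trial` (trials x bins integer matrix), `n_trials`, `bin_width`,
#'   `n_pre`, `n_post`, `alignment`.
#' @seealso [detect_response()], [response_magnitude()], [latency_to_peak()]
#' @export
build_psth <- function(train, events, bin_width, n_pre = 40, n_post = 40,
                       alignment = c("TRAIN_ONSET", "PULSE_ONSET")) {
  alignment <- match.arg(alignment)
  rec <- c(-Inf, Inf)
  if (inherits(train, "spike_train")) {
    rec <- c(train$recording_start, train$recording_end)
    train <- train$timestamps
  }
  if (bin_width <= 0 || n_pre < 0 || n_post < 0 || n_pre + n_post < 1) {
    stop_invalid("invalid PSTH geometry")
  }
  w <- bin_width / 1000
  lo <- -n_pre * w
  hi <- n_post * w
  ok <- events + lo >= rec[1] - 1e-9 & events + hi <= rec[2] + 1e-9
  if (any(!ok)) {
    warning(sum(!ok), " event(s) dropped: window outside the recording",
            call. = FALSE)
    events <- events[ok]
  }
  if (!length(events)) stop_invalid("no usable alignment events")
  nb <- n_pre + n_post
  per_trial <- matrix(0L, nrow = length(events), ncol = nb)
  for (i in seq_along(events)) {
    a <- events[i] + lo
    b <- events[i] + hi
    j1 <- findInterval(a, train, left.open = TRUE)   # spikes < a
    j2 <- findInterval(b, train, left.open = TRUE)   # spikes < b
    if (j2 > j1) {
      rel <- train[(j1 + 1):j2] - events[i]
      bins <- floor(rel / w) + n_pre + 1
      bins <- bins[bins >= 1 & bins <= nb]           # guards float edge cases
      per_trial[i, ] <- tabulate(bins, nbins = nb)
    }
  }
  structure(list(counts = as.integer(colSums(per_trial)),
                 per_trial = per_trial, n_trials = length(events),
                 bin_width = bin_width, n_pre = as.integer(n_pre),
                 n_post = as.integer(n_post), alignment = alignment),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %s: %d+%d bins x %.4g ms, %d trials, %d spikes\n",
              x$alignment, x$n_pre, x$n_post, x$bin_width, x$n_trials,
              sum(x$counts)))
  invisible(x)
}

#' @export
plot.psth <- function(x, ...) {
  mid <- (seq_len(x$n_pre + x$n_post) - x$n_pre - 0.5) * x$bin_width
  graphics::barplot(x$counts, names.arg = signif(mid, 3), space = 0,
                    xlab = "time from event (ms)", ylab = "spike count", ...)
  graphics::abline(v = x$n_pre, col = "blue", lty = 2)
  invisible(x)
}

#' Detect an evoked response in a PSTH
#'
#' Implements the 2-SD criterion: with `mu` and `sigma` the mean and sample SD
#' of the `n_pre` baseline bin counts of the trial-summed PSTH, an excitatory
#' (inhibitory) response is a run of at least `min_consecutive_bins`
#' post-onset bins strictly above `mu + k*sigma` (strictly below
#' `mu - k*sigma`). The category is `INCREASE`, `DECREASE`, `COMBINATION`
#' (an increase run ending before a decrease run begins) or `NONE`. With a
#' perfectly regular baseline (`sigma = 0`) the criterion degenerates to
#' "above/below the baseline mean"; such results carry a `sigma_zero` flag.
#' Results from fewer than `min_trials` trials are flagged provisional.
#'
#' @param psth a [build_psth()] result (or a plain integer vector of bin
#'   counts, in which case `n_pre` must be given).
#' @param config a [detection_config()].
#' @param n_pre number of baseline bins when `psth` is a plain vector.
#' @return object of class `"response_result"`: list with `category` (factor),
#'   `significant_bins` (data.frame `bin`, `direction`, post-onset indices),
#'   `baseline_mean`, `baseline_sd`, `n_trials_used`, and logical flags
#'   `sigma_zero`, `provisional`.
#' @export
detect_response <- function(psth, config = detection_config(), n_pre = NULL) {
  n_trials <- NA_integer_
  if (inherits(psth, "psth")) {
    counts <- psth$counts
    n_pre <- psth$n_pre
    n_trials <- psth$n_trials
  } else {
    counts <- as.numeric(psth)
    if (is.null(n_pre)) stop_invalid("n_pre required for plain count vectors")
  }
  n_post <- length(counts) - n_pre
  if (n_pre < 2) stop_invalid("need at least 2 baseline bins to estimate SD")
  if (n_post < config$min_consecutive_bins) stop_invalid("post-onset window too short")
  base <- counts[seq_len(n_pre)]
  post <- counts[(n_pre + 1):length(counts)]
  mu <- mean(base)
  sigma <- stats::sd(base)
  k <- config$sd_multiplier
  up <- post > mu + k * sigma
  down <- post < mu - k * sigma
  runs_up <- find_runs(up, config$min_consecutive_bins)
  runs_down <- find_runs(down, config$min_consecutive_bins)
  category <- if (nrow(runs_up) == 0 && nrow(runs_down) == 0) {
    "NONE"
  } else if (nrow(runs_down) == 0) {
    "INCREASE"
  } else if (nrow(runs_up) == 0) {
    "DECREASE"
  } else if (min(runs_up$end) < max(runs_down$start)) {
    "COMBINATION"   # an increase run entirely precedes a decrease run
  } else if (min(runs_up$start) <= min(runs_down$start)) {
    "INCREASE"      # both present, decrease first: earliest run decides
  } else {
    "DECREASE"
  }
  sig <- rbind(
    if (nrow(runs_up)) data.frame(
      bin = unlist(Map(seq, runs_up$start, runs_up$end)), direction = "INCREASE"),
    if (nrow(runs_down)) data.frame(
      bin = unlist(Map(seq, runs_down$start, runs_down$end)), direction = "DECREASE")
  )
  if (is.null(sig)) sig <- data.frame(bin = integer(), direction = character())
  structure(list(
    category = factor(category, levels = response_levels()),
    significant_bins = sig[order(sig$bin), , drop = FALSE],
    baseline_mean = mu, baseline_sd = sigma,
    n_trials_used = n_trials,
    sigma_zero = sigma == 0,
    provisional = !is.na(n_trials) && n_trials < config$min_trials
  ), class = "response_result")
}

response_levels <- function() c("NONE", "INCREASE", "DECREASE", "COMBINATION")

#' @export
print.response_result <- function(x, ...) {
  cat(sprintf("<response_result> %s (%d significant bins%s%s)\n",
              as.character(x$category), nrow(x$significant_bins),
              if (isTRUE(x$provisional)) ", provisional" else "",
              if (isTRUE(x$sigma_zero)) ", sigma = 0" else ""))
  invisible(x)
}

#' Response magnitude (fold change)
#'
#' Total spikes in the stimulation window divided by total spikes in the
#' equal-duration pre-stimulation window. A silent baseline is floored at
#' `baseline_floor_spikes` spikes to keep the ratio finite; the result then
#' carries a `zero_baseline` attribute.
#'
#' @param psth a [build_psth()] result with `n_pre == n_post`.
#' @param config a [detection_config()].
#' @return the fold change (numeric scalar, attribute `zero_baseline`).
#' @export
response_magnitude <- function(psth, config = detection_config()) {
  stopifnot(inherits(psth, "psth"))
  if (psth$n_pre != psth$n_post) {
    stop_invalid("magnitude needs equal-duration pre and stimulation windows")
  }
  pre <- sum(psth$counts[seq_len(psth$n_pre)])
  post <- sum(psth$counts[(psth$n_pre + 1):length(psth$counts)])
  m <- post / max(pre, config$baseline_floor_spikes)
  attr(m, "zero_baseline") <- pre == 0
  m
}

#' Latency to the maximal effect
#'
#' The time from illumination onset to the center of the post-onset bin with
#' the largest spike count, in a PSTH aligned to the first pulse of each
#' train. Ties go to the earliest bin.
#'
#' @param psth a [build_psth()] result aligned to pulse onsets.
#' @return latency in ms (bin center), or `NA` with a warning if the
#'   post-onset window contains no spikes.
#' @export
latency_to_peak <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  post <- psth$counts[(psth$n_pre + 1):length(psth$counts)]
  if (all(post == 0)) {
    warning("no post-onset spikes; latency undefined", call. = FALSE)
    return(NA_real_)
  }
  (which.max(post) - 0.5) * psth$bin_width
}

#' Population-normalized mean response trace
#'
#' Divides each unit's PSTH by its own maximal bin count, then averages the
#' normalized traces across units, so units with very different response
#' magnitudes contribute equally to the population time course.
#'
#' @param psths list of [build_psth()] results with identical binning.
#' @return numeric vector in \[0, 1\], one value per bin.
#' @export
normalize_population <- function(psths) {
  stopifnot(length(psths) >= 1, all(vapply(psths, inherits, logical(1), "psth")))
  geom <- vapply(psths, function(p) c(p$bin_width, p$n_pre, p$n_post), numeric(3))
  if (any(geom != geom[, 1])) stop_invalid("PSTHs must share binning")
  mx <- vapply(psths, function(p) max(p$counts), numeric(1))
  if (any(mx == 0)) {
    warning(sum(mx == 0), " all-zero unit(s) excluded from the population trace",
            call. = FALSE)
    psths <- psths[mx > 0]
    mx <- mx[mx > 0]
  }
  if (!length(psths)) stop_invalid("no non-empty PSTHs to average")
  traces <- mapply(function(p, m) p$counts / m, psths, mx)
  rowMeans(traces)
}

#' Post-train suppression duration
#'
#' Scans the bins after the end of the stimulation train for the first run of
#' at least `min_consecutive_bins` bins below `mu - k*sigma` (baseline mean
#' and SD as in [detect_response()]). The suppression duration is the time
#' from the first bin of that run to the first subsequent bin back at or above
#' the threshold. The PSTH window must extend at least 400 ms past the train
#' end.
#'
#' @param psth a train-aligned [build_psth()] with an extended post window.
#' @param train_end_ms end of the stimulation train relative to the alignment
#'   time, ms.
#' @param config a [detection_config()].
#' @return list with `detected`, `duration_ms`, `onset_ms` (start of the
#'   suppression run relative to train onset), `truncated` (run still below
#'   threshold at the end of the window).
#' @export
post_train_suppression <- function(psth, train_end_ms,
                                   config = detection_config()) {
  stopifnot(inherits(psth, "psth"))
  w <- psth$bin_width
  if (psth$n_post * w < train_end_ms + 400) {
    stop_invalid("PSTH window must extend at least 400 ms past the train end")
  }
  base <- psth$counts[seq_len(psth$n_pre)]
  post <- psth$counts[(psth$n_pre + 1):length(psth$counts)]
  thr <- mean(base) - config$sd_multiplier * stats::sd(base)
  starts <- (seq_len(psth$n_post) - 1) * w
  eligible <- starts >= train_end_ms - 1e-9
  below <- post < thr & eligible
  runs <- find_runs(below, config$min_consecutive_bins)
  if (!nrow(runs)) {
    return(list(detected = FALSE, duration_ms = NA_real_, onset_ms = NA_real_,
                truncated = FALSE))
  }
  j0 <- runs$start[1]
  rec <- which(post >= thr & seq_along(post) > j0)
  truncated <- !length(rec)
  j1 <- if (truncated) psth$n_post + 1L else min(rec)
  list(detected = TRUE, duration_ms = (j1 - j0) * w,
       onset_ms = starts[j0], truncated = truncated)
}

#' Full per-unit response characterization
#'
#' The per-unit pipeline applied to a train-stimulation session: a
#' train-aligned 40+40-bin PSTH feeds the 2-SD detector and the fold-change
#' magnitude; an extended PSTH past the train end feeds the post-train
#' suppression scan; a first-pulse-aligned fine-binned PSTH yields the latency
#' to the maximal effect for excited units. Units whose in-train category is
#' `INCREASE` and that also show significant post-train suppression are
#' labeled `COMBINATION` (an increase followed by a decrease in firing).
#'
#' @param train a [spike_train()].
#' @param protocol a [stim_protocol()] of pulse trains.
#' @param config a [detection_config()].
#' @return list with `category`, `magnitude`, `latency_ms`,
#'   `suppression` (see [post_train_suppression()]), `detection`
#'   (the [detect_response()] result) and `n_trials`.
#' @export
classify_response <- function(train, protocol, config = detection_config()) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tr <- protocol$trains
  onsets <- tr$onset
  w <- config$bin_width_train
  psth <- build_psth(train, onsets, bin_width = w, n_pre = 40, n_post = 40)
  det <- detect_response(psth, config)
  category <- as.character(det$category)
  magnitude <- if (category %in% c("INCREASE", "COMBINATION")) {
    as.numeric(response_magnitude(psth, config))
  } else NA_real_
  # suppression scan on a window reaching 400 ms past the train end
  train_end_ms <- max(train_duration(tr)) * 1000
  n_post_ext <- ceiling((train_end_ms + 400) / w) + 1
  supp <- tryCatch({
    ep <- build_psth(train, onsets, bin_width = w, n_pre = 40,
                     n_post = n_post_ext)
    post_train_suppression(ep, train_end_ms, config)
  }, error = function(e) list(detected = FALSE, duration_ms = NA_real_,
                              onset_ms = NA_real_, truncated = FALSE))
  if (category == "INCREASE" && isTRUE(supp$detected)) category <- "COMBINATION"
  latency <- NA_real_
  if (category %in% c("INCREASE", "COMBINATION")) {
    first <- pulse_onsets(protocol)
    first <- first$onset_s[first$pulse_index == 1]
    wp <- config$bin_width_pulse
    pp <- build_psth(train, first, bin_width = wp,
                     n_pre = ceiling(10 / wp), n_post = ceiling(20 / wp),
                     alignment = "PULSE_ONSET")
    latency <- suppressWarnings(latency_to_peak(pp))
  }
  list(category = factor(category, levels = response_levels()),
       magnitude = magnitude, latency_ms = latency, suppression = supp,
       detection = det, n_trials = psth$n_trials)
}
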