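#' Simulate baseline (unstimulated) firing
#'
#' Draws a stationary gamma-renewal spike train with mean rate
#' `profile$baseline_rate` and ISI coefficient of variation
#' `profile$target_cv` (gamma shape `k = 1/cv^2`). The process is warmed up
#' before time zero so the first interval is approximately equilibrium
#' distributed.
#'
#' @param profile a [cell_profile()]; only the baseline fields are used.
#' @param duration recording duration in seconds (> 0).
#' @param seed integer seed; fixes the output exactly.
#' @param unit_id id given to the returned unit.
#' @return a [spike_train()] covering `[0, duration]`.
#' @export
#' @examples
#' st <- simulate_baseline_train(default_profiles()$tan, duration = 200, seed = 1)
#' baseline_stats(st, c(0, 200))
simulate_baseline_train <- function(profile, duration, seed = NULL,
                                    unit_id = "sim1") {
  stopifnot(inherits(profile, "cell_profile"))
  if (!is.numeric(duration) || duration <= 0) {
    stop_invalid("duration must be positive")
  }
  rate <- profile$baseline_rate
  region <- region_of_class(profile$cell_class)
  if (rate == 0) {
    return(spike_train(numeric(0), unit_id = unit_id, region = region,
                       recording_start = 0, recording_end = duration))
  }
  k <- 1 / profile$target_cv^2
  ts <- with_seed(seed, {
    t0 <- -20 / rate  # ~20 ISI warm-up towards the equilibrium age distribution
    draw_renewal(total = duration - t0, shape = k, rate = rate) + t0
  })
  ts <- ts[ts >= 0 & ts <= duration]
  spike_train(ts, unit_id = unit_id, region = region,
              recording_start = 0, recording_end = duration)
}

# Cumulative gamma-renewal event times on (0, total]; shape k, mean ISI 1/rate.
draw_renewal <- function(total, shape, rate) {
  n <- ceiling(total * rate + 4 * sqrt(total * rate + 1) + 20)
  ts <- cumsum(stats::rgamma(n, shape = shape, rate = shape * rate))
  while (length(ts) && ts[length(ts)] < total) {
    extra <- cumsum(stats::rgamma(n, shape = shape, rate = shape * rate))
    ts <- c(ts, ts[length(ts)] + extra)
  }
  ts[ts <= total]
}

region_of_class <- function(cell_class) {
  switch(cell_class,
         PAN = , TAN = , FSN = "PUTAMEN",
         GPE = "GPE",
         VL_PROJ = "VL",
         "OTHER")
}

#' Channel activation trace
#'
#' Closed-form open-fraction trace of the two-state light-gated channel model:
#' during a pulse `do/dt = (1 - o)/tau_on`, after it `do/dt = -o/tau_off`.
#' Each segment is an exact exponential; the trace is continuous, starts at 0
#' before the first pulse and stays in \[0, 1\].
#'
#' @param kinetics a [chr2_kinetics()].
#' @param pulse_onsets pulse onset times in ms, increasing.
#' @param pulse_width pulse duration(s) in ms (scalar or one per pulse).
#' @param t_grid times (ms) at which to evaluate the trace; non-decreasing.
#' @return numeric vector of open fractions in \[0, 1\], one per `t_grid`.
#' @export
#' @examples
#' # a 20 ms pulse saturates the channel; a 0.1 ms pulse barely opens it
#' k <- chr2_kinetics(tau_on = 1, tau_off = 20)
#' channel_activation(k, 0, 20, t_grid = 20)    # ~1
#' channel_activation(k, 0, 0.1, t_grid = 0.1)  # ~0.095
channel_activation <- function(kinetics, pulse_onsets, pulse_width, t_grid) {
  stopifnot(inherits(kinetics, "chr2_kinetics"))
  n <- length(pulse_onsets)
  if (n == 0) return(numeric(length(t_grid)))
  w <- rep_len(pulse_width, n)
  if (any(w < 0)) stop_invalid("pulse_width must be >= 0")
  if (is.unsorted(pulse_onsets, strictly = n > 1)) {
    stop_invalid("pulse_onsets must be increasing")
  }
  if (length(t_grid) > 1 && is.unsorted(t_grid)) {
    stop_invalid("t_grid must be non-decreasing")
  }
  offs <- pulse_onsets + w
  if (n > 1 && any(pulse_onsets[-1] < offs[-n])) {
    stop_invalid("light pulses overlap")
  }
  tau_on <- kinetics$tau_on
  tau_off <- kinetics$tau_off
  # open fraction at each pulse onset/offset, carried across pulses
  o_on <- o_off <- numeric(n)
  prev_o <- 0
  prev_t <- -Inf
  for (i in seq_len(n)) {
    o_on[i] <- if (is.finite(prev_t)) prev_o * exp(-(pulse_onsets[i] - prev_t) / tau_off) else 0
    o_off[i] <- 1 - (1 - o_on[i]) * exp(-w[i] / tau_on)
    prev_o <- o_off[i]
    prev_t <- offs[i]
  }
  bnd <- as.vector(rbind(pulse_onsets, offs))
  seg <- findInterval(t_grid, bnd)
  o <- numeric(length(t_grid))
  inside <- seg %% 2 == 1
  if (any(inside)) {
    j <- (seg[inside] + 1) %/% 2
    o[inside] <- 1 - (1 - o_on[j]) * exp(-(t_grid[inside] - pulse_onsets[j]) / tau_on)
  }
  after <- seg > 0 & !inside
  if (any(after)) {
    j <- seg[after] %/% 2
    o[after] <- o_off[j] * exp(-(t_grid[after] - offs[j]) / tau_off)
  }
  o
}

#' Standard pulse-train protocol
#'
#' Trains of 10 pulses of 20 ms delivered at 30 Hz with randomized inter-train
#' intervals drawn uniformly on `iti_range` (seconds), the standard stimulus
#' used for response screening.
#'
#' @param n_trains number of trains.
#' @param n_pulses,pulse_width,pulse_rate per-train pulse parameters
#'   (count, ms, Hz).
#' @param iti_range range of the uniform inter-train interval, s.
#' @param start onset of the first train, s (use >= 120 when the session is
#'   also meant to support baseline classification).
#' @param intensity irradiance, mW/mm^2.
#' @param seed integer seed for the randomized intervals.
#' @return a [stim_protocol()].
#' @export
standard_train_protocol <- function(n_trains = 50, n_pulses = 10,
                                    pulse_width = 20, pulse_rate = 30,
                                    iti_range = c(1, 2), start = 0,
                                    intensity = NA_real_, seed = NULL) {
  stopifnot(n_trains >= 1, length(iti_range) == 2, iti_range[1] <= iti_range[2])
  dur <- (n_pulses - 1) / pulse_rate + pulse_width / 1000
  iti <- with_seed(seed, stats::runif(n_trains - 1, iti_range[1], iti_range[2]))
  onsets <- round(start + c(0, cumsum(dur + iti)), 5)  # 10 us timing grid
  trains <- data.frame(onset = onsets, n_pulses = n_pulses,
                       pulse_width = pulse_width, pulse_rate = pulse_rate,
                       intensity = intensity)
  stim_protocol(trains, intensity = intensity)
}

#' Single-pulse protocol over a set of pulse widths
#'
#' One-pulse "trains" at each requested width, repeated `trials_per_width`
#' times in shuffled order, used for the pulse-width dose-response analysis.
#'
#' @param widths pulse widths to test, ms.
#' @param trials_per_width repetitions of each width.
#' @param iti_range uniform inter-pulse interval range, s.
#' @param start onset of the first pulse, s.
#' @param intensity irradiance, mW/mm^2.
#' @param seed integer seed (interval draws and width order).
#' @return a [stim_protocol()].
#' @export
single_pulse_protocol <- function(widths = c(0.1, 0.3, 0.6, 1.2, 2.5, 5, 10, 20),
                                  trials_per_width = 50, iti_range = c(1, 2),
                                  start = 0, intensity = NA_real_, seed = NULL) {
  with_seed(seed, {
    w <- sample(rep(widths, each = trials_per_width))
    iti <- stats::runif(length(w) - 1, iti_range[1], iti_range[2])
    onsets <- round(start + c(0, cumsum(iti)), 5)  # 10 us timing grid
    trains <- data.frame(onset = onsets, n_pulses = 1L, pulse_width = w,
                         pulse_rate = 1, intensity = intensity)
    stim_protocol(trains, intensity = intensity)
  })
}

#' Simulate one stimulation session
#'
#' Generates a spike train whose conditional intensity is the gamma-renewal
#' baseline of `profile` modulated multiplicatively by the light:
#' `lambda(t) = baseline_rate * g^(s * o(t - latency) * d(p))`, with `o` the
#' channel activation, `d(p) = decrement_factor^(p-1)` the within-train
#' per-pulse attenuation, `s = +1` (excitation) or `-1` (inhibition), and
#' `g = gain^L(I)` where `L` is a logistic function of log-irradiance centered
#' at `intensity_half_max` (irradiance missing from the protocol means full
#' effect). `COMBINATION` profiles are excited during the train and then have
#' their rate multiplied by `1 - suppression_depth` for `suppression_duration`
#' ms after the last pulse. Sampling is by exact time rescaling of the
#' operational-time gamma renewal process, so with `gain = 1` (or
#' `response_type = "NONE"`) the session is distributed exactly as the
#' baseline process.
#'
#' @param profile a [cell_profile()].
#' @param config a [sim_config()] carrying the protocol, duration and seed.
#' @param kinetics a [chr2_kinetics()].
#' @param unit_id id of the simulated unit.
#' @return an [opto_session()] with one unit, the protocol, and a one-row
#'   `ground_truth` data.frame of the generating labels.
#' @export
#' @examples
#' prof <- default_profiles()$tan
#' cfg <- sim_config(standard_train_protocol(10, seed = 1), seed = 1)
#' sess <- simulate_session(prof, cfg)
#' sess
simulate_session <- function(profile, config, kinetics = chr2_kinetics(),
                             unit_id = "sim1") {
  stopifnot(inherits(profile, "cell_profile"), inherits(config, "sim_config"),
            inherits(kinetics, "chr2_kinetics"))
  proto <- config$protocol
  T_end <- config$session_duration
  rate <- profile$baseline_rate
  region <- region_of_class(profile$cell_class)
  gt <- ground_truth_row(profile, unit_id)
  if (rate == 0) {
    st <- spike_train(numeric(0), unit_id = unit_id, region = region,
                      recording_start = 0, recording_end = T_end)
    return(opto_session(st, proto, gt))
  }
  modulated <- profile$response_type != "NONE" && nrow(proto$trains) > 0
  ts <- with_seed(config$seed, {
    if (!modulated) {
      t0 <- -20 / rate
      draw_renewal(total = T_end - t0, shape = 1 / profile$target_cv^2,
                   rate = rate) + t0
    } else {
      grid <- modulation_grid(profile, kinetics, proto, config, T_end)
      lam <- rate * grid$m
      Lam <- c(0, cumsum(diff(grid$t) * (lam[-length(lam)] + lam[-1]) / 2))
      total <- Lam[length(Lam)]
      # unit-mean renewal in operational time, warmed up, then mapped back
      s0 <- -20
      s <- draw_renewal(total = total - s0, shape = 1 / profile$target_cv^2,
                        rate = 1) + s0
      s <- s[s >= 0 & s <= total]
      stats::approx(Lam, grid$t, xout = s, ties = "ordered")$y
    }
  })
  ts <- sort(ts[ts >= 0 & ts <= T_end])
  ts <- ts[!duplicated(ts)]
  st <- spike_train(ts, unit_id = unit_id, region = region,
                    recording_start = 0, recording_end = T_end)
  opto_session(st, proto, gt)
}

ground_truth_row <- function(profile, unit_id) {
  data.frame(unit_id = unit_id, cell_class = profile$cell_class,
             response_type = profile$response_type,
             baseline_rate = profile$baseline_rate, target_cv = profile$target_cv,
             gain = profile$gain, response_latency = profile$response_latency,
             decrement_factor = profile$decrement_factor,
             suppression_depth = profile$suppression_depth,
             suppression_duration = profile$suppression_duration,
             stringsAsFactors = FALSE)
}

# Piecewise-linear grid (times in s, multiplier m >= 0) of the rate modulation.
# Fine-grained only around trains; the baseline in between is exactly linear.
modulation_grid <- function(profile, kinetics, proto, config, T_end) {
  tr <- proto$trains
  po <- pulse_onsets(proto)
  lat_s <- profile$response_latency / 1000
  dt <- config$grid_dt_ms / 1000
  tail_s <- 8 * kinetics$tau_off / 1000
  supp <- profile$response_type == "COMBINATION" && profile$suppression_depth > 0 &&
    profile$suppression_duration > 0
  t_train_end <- tr$onset + train_duration(tr)
  win_end_s <- t_train_end + lat_s +
    pmax(tail_s, if (supp) profile$suppression_duration / 1000 + 2 * dt else 0)
  pieces <- lapply(seq_len(nrow(tr)), function(i) {
    seq(tr$onset[i] + lat_s, min(win_end_s[i], T_end), by = dt)
  })
  tg <- c(0, unlist(pieces), T_end)
  tg <- tg[tg >= 0 & tg <= T_end]
  tg <- sort(unique(tg))
  # channel activation, shifted by the response latency
  o <- channel_activation(kinetics, po$onset_s * 1000, po$width_ms,
                          tg * 1000 - profile$response_latency)
  # per-pulse decrement: index of the most recent (latency-shifted) pulse
  idx <- findInterval(tg - lat_s, po$onset_s)
  p_idx <- ifelse(idx > 0, po$pulse_index[pmax(idx, 1)], 1)
  d <- profile$decrement_factor^(p_idx - 1)
  # intensity scaling of the log-gain, per train
  tr_idx <- ifelse(idx > 0, po$train_id[pmax(idx, 1)], 1)
  g_tr <- effective_gain(profile$gain, tr$intensity,
                         config$intensity_half_max, config$intensity_slope)
  s_dir <- if (profile$response_type == "INHIBITED") -1 else 1
  m <- g_tr[tr_idx]^(s_dir * o * d)
  if (supp) {
    s_on <- t_train_end + lat_s
    s_off <- s_on + profile$suppression_duration / 1000
    k <- findInterval(tg, s_on)
    in_supp <- k > 0 & tg <= s_off[pmax(k, 1)]
    m[in_supp] <- m[in_supp] * (1 - profile$suppression_depth)
  }
  list(t = tg, m = m)
}

# gain^L(I): logistic scaling of the log-gain with irradiance; NA irradiance
# (intensity not recorded) means full effect.
effective_gain <- function(gain, intensity, half_max, slope) {
  L <- ifelse(is.na(intensity), 1,
              stats::plogis(slope * (log(intensity) - log(half_max))))
  gain^L
}

#' Simulate a cohort of units
#'
#' Repeats [simulate_session()] over a list of profiles
#' (`n_units_per_profile` units each, with per-unit seeds derived from
#' `config$seed`). Optionally assigns each unit a distance to the nearest
#' injection site and attenuates its log-gain with a logistic function of
#' distance, emulating the fall-off of transfection density.
#'
#' @param profiles list of [cell_profile()] objects (named names are used in
#'   unit ids).
#' @param config a [sim_config()].
#' @param kinetics a [chr2_kinetics()].
#' @param distances optional numeric vector (recycled across units) of
#'   distances to the injection site, mm.
#' @param transfection_radius when finite and `distances` are given, the
#'   log-gain is scaled by `plogis(-(d - radius)/0.25)` so units beyond the
#'   radius are effectively untransfected.
#' @return an [opto_session()] with one spike train per unit and a
#'   `ground_truth` data.frame (including `distance_mm` when given).
#' @export
simulate_cohort <- function(profiles, config, kinetics = chr2_kinetics(),
                            distances = NULL, transfection_radius = Inf) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(profiles, "cell_profile")) profiles <- list(profiles)
  nm <- names(profiles) %||% paste0("p", seq_along(profiles))
  nm[nm == ""] <- paste0("p", which(nm == ""))
  n_per <- config$n_units_per_profile
  units <- list()
  gts <- list()
  u <- 0
  for (i in seq_along(profiles)) {
    for (j in seq_len(n_per)) {
      u <- u + 1
      prof <- profiles[[i]]
      d_mm <- if (!is.null(distances)) distances[(u - 1) %% length(distances) + 1] else NA_real_
      if (!is.na(d_mm) && is.finite(transfection_radius)) {
        scale <- stats::plogis(-(d_mm - transfection_radius) / 0.25)
        prof$gain <- prof$gain^scale
      }
      uid <- sprintf("%s_%02d", nm[i], j)
      seed_u <- if (is.null(config$seed)) NULL else (config$seed + 7919 * u) %% .Machine$integer.max
      cfg_u <- config
      cfg_u$seed <- seed_u
      sess <- simulate_session(prof, cfg_u, kinetics, unit_id = uid)
      st <- sess$units[[1]]
      st$distance_to_injection <- d_mm
      units[[uid]] <- st
      gt <- sess$ground_truth
      gt$distance_mm <- d_mm
      gts[[uid]] <- gt
    }
  }
  opto_session(units, config$protocol, do.call(rbind, gts))
}
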