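#' Generative profile of a simulated cell
#'
#' Describes the baseline firing statistics and the light-response phenotype of
#' a simulated unit. Baseline spiking is a gamma-renewal process whose shape
#' parameter `k = 1/target_cv^2` gives independent control of mean rate and
#' inter-spike-interval (ISI) coefficient of variation, the two axes of the
#' striatal electrophysiological classification.
#'
#' Light modulates the firing rate multiplicatively: the conditional intensity
#' is `baseline_rate * gain^(s * o(t) * d(p))`, where `o(t)` in \[0, 1\] is the
#' channel activation ([channel_activation()]), `s = +1` for excitation and
#' `-1` for inhibition, and `d(p) = decrement_factor^(p - 1)` attenuates the
#' response to successive pulses within a train. The multiplicative form keeps
#' the rate strictly positive under inhibition. `COMBINATION` cells are excited
#' during the train and then suppressed (rate multiplied by
#' `1 - suppression_depth`) for `suppression_duration` ms after the train ends.
#'
#' @param cell_class one of `"PAN"`, `"TAN"`, `"FSN"`, `"GPE"`, `"VL_PROJ"`.
#' @param baseline_rate mean spontaneous firing rate, spikes/s (>= 0).
#' @param target_cv target ISI coefficient of variation (> 0); values above 1
#'   give burstier-than-Poisson firing (gamma shape < 1).
#' @param gain multiplicative rate factor at full channel activation (>= 1 for
#'   meaningful excitation/inhibition; 1 disables modulation).
#' @param response_type `"NONE"`, `"EXCITED"`, `"INHIBITED"` or
#'   `"COMBINATION"`. With `"NONE"` the light has no effect on the output.
#' @param response_latency latency of the rate modulation, ms (a pure shift of
#'   the activation trace).
#' @param decrement_factor per-pulse attenuation of the evoked response, in
#'   (0, 1]; 1 means every pulse in a train is equally effective.
#' @param suppression_depth fractional rate reduction after the train for
#'   `COMBINATION` cells, in \[0, 1\].
#' @param suppression_duration duration of the post-train suppression, ms.
#' @return an object of class `"cell_profile"`.
#' @seealso [default_profiles()], [simulate_baseline_train()],
#'   [simulate_session()]
#' @export
#' @examples
#' cell_profile("TAN", baseline_rate = 5, target_cv = 0.5,
#'              gain = 20, response_type = "EXCITED", response_latency = 5)
cell_profile <- function(cell_class = c("PAN", "TAN", "FSN", "GPE", "VL_PROJ"),
                         baseline_rate, target_cv, gain = 1,
                         response_type = c("NONE", "EXCITED", "INHIBITED", "COMBINATION"),
                         response_latency = 0, decrement_factor = 1,
                         suppression_depth = 0, suppression_duration = 0) {
  cell_class <- match.arg(cell_class)
  response_type <- match.arg(response_type)
  if (baseline_rate < 0) stop_invalid("baseline_rate must be >= 0")
  if (target_cv <= 0) stop_invalid("target_cv must be > 0")
  if (gain <= 0) stop_invalid("gain must be > 0")
  if (decrement_factor <= 0 || decrement_factor > 1) {
    stop_invalid("decrement_factor must be in (0, 1]")
  }
  if (suppression_depth < 0 || suppression_depth > 1) {
    stop_invalid("suppression_depth must be in [0, 1]")
  }
  if (suppression_duration < 0) stop_invalid("suppression_duration must be >= 0")
  if (response_latency < 0) stop_invalid("response_latency must be >= 0")
  structure(
    list(cell_class = cell_class, baseline_rate = baseline_rate,
         target_cv = target_cv, gain = gain, response_type = response_type,
         response_latency = response_latency, decrement_factor = decrement_factor,
         suppression_depth = suppression_depth,
         suppression_duration = suppression_duration),
    class = "cell_profile"
  )
}

#' @export
print.cell_profile <- function(x, ...) {
  cat(sprintf("<cell_profile> %s  %.3g spikes/s, CV %.2f, %s (gain %.3g)\n",
              x$cell_class, x$baseline_rate, x$target_cv, x$response_type, x$gain))
  invisible(x)
}

#' First-order channel kinetics
#'
#' Two-parameter light-gated channel model: during illumination the open
#' fraction relaxes towards 1 with time constant `tau_on`; in darkness it
#' decays to 0 with time constant `tau_off`. Defaults are the activation and
#' deactivation time constants of the ChR2(H134R) variant.
#'
#' @param tau_on activation time constant, ms (> 0). Default 1 ms.
#' @param tau_off deactivation time constant, ms (> 0). Default 20 ms.
#' @return an object of class `"chr2_kinetics"`.
#' @export
chr2_kinetics <- function(tau_on = 1, tau_off = 20) {
  if (tau_on <= 0 || tau_off <= 0) stop_invalid("time constants must be > 0")
  structure(list(tau_on = tau_on, tau_off = tau_off), class = "chr2_kinetics")
}

#' Reference cell profiles
#'
#' A set of generative profiles emulating the firing phenomenology of the
#' recorded populations: low-rate irregular phasically active striatal
#' projection neurons (PAN), tonically active interneurons (TAN), fast-spiking
#' interneurons (FSN), high-frequency pallidal units (GPE) and bursting
#' thalamic projection units (VL) with short-latency light responses and
#' post-train suppression. Baseline rates and CVs sit at the centers of the
#' classification rule ranges; gains reflect that thalamic evoked responses
#' are substantially larger than striatal ones. The per-pulse decrement factor
#' 0.98 is calibrated (via the closed-form evoked-count expectation) so the
#' first pulse of a standard train evokes ~25-30% more spikes than the later
#' pulses.
#'
#' @return named list of [cell_profile()] objects
#'   (`pan`, `tan`, `fsn`, `gpe`, `vl`).
#' @export
default_profiles <- function() {
  list(
    pan = cell_profile("PAN", baseline_rate = 1, target_cv = 1.5,
                       gain = 20, response_type = "EXCITED",
                       response_latency = 5, decrement_factor = 0.98),
    tan = cell_profile("TAN", baseline_rate = 5, target_cv = 0.5,
                       gain = 20, response_type = "EXCITED",
                       response_latency = 5, decrement_factor = 0.98),
    fsn = cell_profile("FSN", baseline_rate = 20, target_cv = 0.8,
                       gain = 10, response_type = "EXCITED",
                       response_latency = 5, decrement_factor = 0.98),
    gpe = cell_profile("GPE", baseline_rate = 60, target_cv = 0.8,
                       gain = 1, response_type = "NONE"),
    vl = cell_profile("VL_PROJ", baseline_rate = 15, target_cv = 1.3,
                      gain = 50, response_type = "EXCITED",
                      response_latency = 2, decrement_factor = 0.98,
                      suppression_depth = 0.9, suppression_duration = 150)
  )
}

#' Simulation configuration
#'
#' @param protocol the [stim_protocol()] to simulate against.
#' @param session_duration total recording duration, s. Defaults to 1 s past
#'   the end of the last train. Sessions meant to be run through the
#'   electrophysiological classifier should include at least 120 s of
#'   pre-stimulation baseline.
#' @param seed integer seed; together with the profile it fully determines the
#'   simulated output.
#' @param n_units_per_profile number of units to draw per profile in
#'   [simulate_cohort()].
#' @param intensity_half_max irradiance at which the logistic intensity
#'   scaling reaches half of the log-gain, mW/mm^2.
#' @param intensity_slope slope of the logistic intensity scaling on the
#'   log-irradiance axis (dimensionless).
#' @param grid_dt_ms time step of the intensity-function grid used by the
#'   time-rescaling sampler during light-modulated epochs, ms. 0.1 ms resolves
#'   the 1 ms activation time constant.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(protocol, session_duration = NULL, seed = NULL,
                       n_units_per_profile = 1, intensity_half_max = 4,
                       intensity_slope = 2, grid_dt_ms = 0.1) {
  stopifnot(inherits(protocol, "stim_protocol"))
  tr <- protocol$trains
  proto_end <- if (nrow(tr)) max(tr$onset + train_duration(tr)) else 0
  if (is.null(session_duration)) session_duration <- proto_end + 1
  if (session_duration < proto_end) {
    stop_invalid("session_duration ends before the last stimulation train")
  }
  if (grid_dt_ms <= 0) stop_invalid("grid_dt_ms must be > 0")
  structure(
    list(protocol = protocol, session_duration = session_duration, seed = seed,
         n_units_per_profile = n_units_per_profile,
         intensity_half_max = intensity_half_max,
         intensity_slope = intensity_slope, grid_dt_ms = grid_dt_ms),
    class = "sim_config"
  )
}
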