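test_that("gamma-renewal baseline matches target rate and CV", {
  cases <- list(c(rate = 5, cv = 1.0), c(rate = 5, cv = 0.5), c(rate = 20, cv = 0.8))
  for (cc in cases) {
    st <- simulate_baseline_train(
      cell_profile("TAN", cc[["rate"]], cc[["cv"]]), duration = 1000,
      seed = 100 + round(10 * cc[["cv"]]))
    emp_rate <- length(st$timestamps) / 1000
    isi <- diff(st$timestamps)
    expect_lt(abs(emp_rate - cc[["rate"]]) / cc[["rate"]], 0.05)
    expect_lt(abs(stats::sd(isi) / mean(isi) - cc[["cv"]]), 0.1)
  }
})

test_that("zero-rate profiles yield empty trains; bad arguments signal errors", {
  st <- simulate_baseline_train(cell_profile("PAN", 0, 1), duration = 100, seed = 1)
  expect_length(st$timestamps, 0)
  expect_error(simulate_baseline_train(cell_profile("PAN", 1, 1), duration = -5),
               "positive")
  expect_error(cell_profile("PAN", -1, 1), "baseline_rate")
  expect_error(cell_profile("PAN", 1, 0), "target_cv")
  expect_error(cell_profile("PAN", 1, 1, decrement_factor = 0), "decrement")
})

test_that("channel activation follows the closed-form exponentials", {
  k <- chr2_kinetics(tau_on = 1, tau_off = 20)
  # rise during a pulse
  expect_equal(channel_activation(k, 0, 20, 20), 1 - exp(-20), tolerance = 1e-12)
  expect_equal(channel_activation(k, 0, 0.1, 0.1), 1 - exp(-0.1), tolerance = 1e-12)
  # decay after the pulse
  o_end <- 1 - exp(-5)
  expect_equal(channel_activation(k, 0, 5, 25), o_end * exp(-1), tolerance = 1e-12)
  # zero-width pulse leaves the channel closed
  expect_equal(channel_activation(k, 0, 0, c(0, 1, 10)), c(0, 0, 0))
  # before the first pulse the trace is identically zero
  expect_equal(channel_activation(k, 10, 5, c(0, 5, 9.9)), c(0, 0, 0))
  # carry-over between pulses keeps continuity
  o <- channel_activation(k, c(0, 10), 5, c(5, 10, 15))
  expect_equal(o[2], o[1] * exp(-5 / 20), tolerance = 1e-12)
  expect_equal(o[3], 1 - (1 - o[2]) * exp(-5), tolerance = 1e-12)
})

test_that("activation trace stays in [0, 1] for random protocols", {
  set.seed(7)
  k <- chr2_kinetics()
  for (i in 1:25) {
    n <- sample(1:15, 1)
    gaps <- stats::runif(n, 1, 40)
    w <- stats::runif(n, 0, 0.9) * c(gaps[-1], 50)
    on <- cumsum(gaps)
    tg <- sort(stats::runif(300, 0, max(on) + 100))
    o <- channel_activation(k, on, w, tg)
    expect_true(all(o >= 0 & o <= 1))
  }
})

test_that("overlapping pulses and invalid grids are rejected", {
  k <- chr2_kinetics()
  expect_error(channel_activation(k, c(0, 5), 10, 1:10), "overlap")
  expect_error(channel_activation(k, c(5, 0), 1, 1:10), "increasing")
  expect_error(channel_activation(k, 0, -1, 1:10), ">= 0")
  expect_error(channel_activation(k, 0, 1, c(3, 2, 1)), "non-decreasing")
  expect_error(chr2_kinetics(tau_on = 0), "> 0")
})

test_that("identical configuration reproduces identical sessions", {
  prof <- default_profiles()$tan
  proto <- standard_train_protocol(5, start = 1, seed = 2)
  a <- simulate_session(prof, sim_config(proto, seed = 9))
  b <- simulate_session(prof, sim_config(proto, seed = 9))
  expect_identical(a$units[[1]]$timestamps, b$units[[1]]$timestamps)
  expect_identical(a$ground_truth, b$ground_truth)
  d <- simulate_session(prof, sim_config(proto, seed = 10))
  expect_false(identical(a$units[[1]]$timestamps, d$units[[1]]$timestamps))
})

test_that("with gain 1 the stimulated process is distributed as the baseline", {
  # KS test on ISIs, 100 replicate pairs at alpha = 0.01: the number of
  # rejections should look like a Binomial(100, 0.01) draw
  proto <- standard_train_protocol(30, start = 1, seed = 5)
  prof1 <- cell_profile("TAN", 5, 0.5, gain = 1, response_type = "EXCITED")
  prof0 <- cell_profile("TAN", 5, 0.5)
  rejections <- 0
  for (i in 1:100) {
    s1 <- simulate_session(prof1, sim_config(proto, session_duration = 60, seed = i))
    s0 <- simulate_baseline_train(prof0, 60, seed = 10000 + i)
    ks <- suppressWarnings(
      stats::ks.test(diff(s1$units[[1]]$timestamps), diff(s0$timestamps)))
    if (ks$p.value < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 5)
})

test_that("expected evoked spikes per pulse are non-decreasing in pulse width", {
  widths <- c(0.1, 0.3, 0.6, 1.2, 2.5, 5, 10, 20)
  # 500 trials per width, aggregated into one long session
  proto <- single_pulse_protocol(widths, trials_per_width = 500, start = 1,
                                 iti_range = c(0.4, 0.6), seed = 31)
  prof <- cell_profile("TAN", 5, 1.0, gain = 100, response_type = "EXCITED",
                       response_latency = 2)
  sess <- simulate_session(prof, sim_config(proto, seed = 32))
  pw <- pulse_width_curve(sess$units[[1]], sess$protocol)
  expect_identical(pw$width_ms, widths)
  expect_true(all(diff(pw$magnitude) > 0))
})

test_that("latency shift is recovered from short-pulse responses", {
  # with a 2 ms pulse the modulated rate peaks at the end of the pulse, so the
  # peak bin recovers latency + pulse width
  prof <- cell_profile("VL_PROJ", 15, 1.0, gain = 50, response_type = "EXCITED",
                       response_latency = 2)
  hits <- 0
  for (i in 1:20) {
    proto <- single_pulse_protocol(2, trials_per_width = 50, start = 1,
                                   seed = 40 + i)
    sess <- simulate_session(prof, sim_config(proto, seed = 60 + i))
    ps <- build_psth(sess$units[[1]], sess$protocol$trains$onset,
                     bin_width = 0.25, n_pre = 40, n_post = 80,
                     alignment = "PULSE_ONSET")
    lat <- latency_to_peak(ps)
    if (lat >= 2 && lat <= 8) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("intensity scaling is logistic in log-irradiance and disabled when unknown", {
  prof <- default_profiles()$vl
  proto_hi <- standard_train_protocol(5, start = 1, intensity = 270, seed = 3)
  proto_na <- standard_train_protocol(5, start = 1, seed = 3)
  cfg_hi <- sim_config(proto_hi, seed = 4, intensity_half_max = 8)
  cfg_na <- sim_config(proto_na, seed = 4, intensity_half_max = 8)
  # at 270 mW/mm2 (far above half max) the response matches the unscaled one
  n_hi <- length(simulate_session(prof, cfg_hi)$units[[1]]$timestamps)
  n_na <- length(simulate_session(prof, cfg_na)$units[[1]]$timestamps)
  expect_lt(abs(n_hi - n_na) / n_na, 0.1)
  # a very low irradiance all but abolishes the evoked response
  proto_lo <- standard_train_protocol(5, start = 1, intensity = 0.25, seed = 3)
  n_lo <- length(simulate_session(prof, sim_config(proto_lo, seed = 4,
                                                   intensity_half_max = 8))$units[[1]]$timestamps)
  base <- prof$baseline_rate * simulate_session(prof, cfg_hi)$units[[1]]$recording_end
  expect_lt(n_lo, n_hi * 0.5)
  expect_lt(abs(n_lo - base) / base, 0.25)
})

test_that("cohorts carry per-unit ground truth and distance-attenuated gains", {
  profs <- list(resp = default_profiles()$tan)
  proto <- standard_train_protocol(40, start = 1, seed = 8)
  cfg <- sim_config(proto, seed = 9, n_units_per_profile = 8)
  distances <- c(0.3, 0.5, 1.0, 1.2, 2.5, 3.0, 3.5, 4.0)
  sess <- simulate_cohort(profs, cfg, distances = distances,
                          transfection_radius = 1.5)
  expect_length(sess$units, 8)
  expect_equal(sess$ground_truth$distance_mm, distances)
  cats <- vapply(sess$units, function(u) {
    as.character(classify_response(u, proto)$category)
  }, character(1))
  near <- cats[distances <= 1.5]
  far <- cats[distances >= 2.5]
  expect_true(all(near != "NONE"))
  # far units are effectively untransfected; allow the detector's nominal
  # false-positive rate
  expect_gte(sum(far == "NONE"), length(far) - 1)
})
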