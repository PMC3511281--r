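test_that("spikes land in the documented PSTH bins", {
  # one event, one spike 4 ms after it: bin n_pre + 1
  st <- spike_train(10.004, recording_start = 0, recording_end = 20)
  ps <- build_psth(st, 10, bin_width = 8.125, n_pre = 40, n_post = 40)
  expect_identical(sum(ps$counts), 1L)
  expect_identical(ps$counts[41], 1L)
  # empty train: all-zero counts
  ps0 <- build_psth(spike_train(numeric(0), recording_end = 20), 10,
                    bin_width = 8.125, n_pre = 40, n_post = 40)
  expect_true(all(ps0$counts == 0L))
  # left-closed right-open bin edges (times chosen exactly representable)
  st2 <- spike_train(c(100, 108.125), recording_start = 0, recording_end = 200)
  ps2 <- build_psth(st2, 100, bin_width = 8125, n_pre = 2, n_post = 2)
  expect_identical(ps2$counts, c(0L, 0L, 1L, 1L))
})

test_that("a homogeneous Poisson unit fills bins at the Poisson expectation", {
  st <- simulate_baseline_train(cell_profile("FSN", 100, 1), 110, seed = 17)
  events <- seq(5, 104, length.out = 50)
  ps <- build_psth(st, events, bin_width = 8.125, n_pre = 40, n_post = 40)
  expected <- 100 * 0.008125 * 50  # rate x bin width x trials ~ 40.6
  expect_lt(abs(mean(ps$counts) - expected) / expected, 0.1)
})

test_that("events whose windows leave the recording are dropped with a warning", {
  st <- spike_train(c(1, 2, 3), recording_start = 0, recording_end = 10)
  expect_warning(
    ps <- build_psth(st, c(0.1, 5), bin_width = 8.125, n_pre = 40, n_post = 40),
    "dropped")
  expect_identical(ps$n_trials, 1L)
  expect_error(
    suppressWarnings(build_psth(st, 0.1, bin_width = 8.125, n_pre = 40,
                                n_post = 40)),
    "events")
})

test_that("the 2-SD detector reproduces the documented verdicts", {
  cfg <- detection_config()
  # flat baseline, flat stimulation: strict inequality keeps it NONE
  flat <- detect_response(psth_from_counts(rep(10, 80), 40), cfg)
  expect_identical(as.character(flat$category), "NONE")
  expect_true(flat$sigma_zero)
  # alternating 8/12 baseline (mu 10, sigma ~2.03) with a [30, 31, 29] run
  base <- rep(c(8, 12), 20)
  post <- rep(10, 40)
  post[10:12] <- c(30, 31, 29)
  det <- detect_response(psth_from_counts(c(base, post), 40), cfg)
  expect_identical(as.character(det$category), "INCREASE")
  expect_identical(det$significant_bins$bin, 10:12)
  # an increase run followed by a clear decrease run: COMBINATION
  base2 <- rep(c(8, 12), 20)
  post2 <- rep(10, 40)
  post2[5:6] <- c(30, 31)
  post2[20:21] <- 0
  det2 <- detect_response(psth_from_counts(c(base2, post2), 40), cfg)
  expect_identical(as.character(det2$category), "COMBINATION")
  # decrease alone
  post3 <- rep(10, 40)
  post3[8:9] <- 0
  det3 <- detect_response(psth_from_counts(c(base2, post3), 40), cfg)
  expect_identical(as.character(det3$category), "DECREASE")
  # fewer than min_trials flags the verdict provisional
  few <- psth_from_counts(c(base, post), 40, n_trials = 10)
  expect_true(detect_response(few, cfg)$provisional)
})

test_that("adding spikes inside the stimulation window never hides an increase", {
  set.seed(23)
  cfg <- detection_config()
  for (i in 1:100) {
    counts <- rpois(80, 5)
    det <- detect_response(psth_from_counts(counts, 40), cfg)
    if (as.character(det$category) != "INCREASE") next
    extra <- counts
    add_at <- sample(41:80, sample(1:10, 1), replace = TRUE)
    for (a in add_at) extra[a] <- extra[a] + sample(1:20, 1)
    det2 <- detect_response(psth_from_counts(extra, 40), cfg)
    expect_true(as.character(det2$category) != "NONE")
  }
})

test_that("response magnitude is the floored fold change", {
  cfg <- detection_config()
  mk <- function(pre_total, post_total) {
    psth_from_counts(c(pre_total, rep(0, 39), post_total, rep(0, 39)), 40)
  }
  expect_equal(as.numeric(response_magnitude(mk(100, 100), cfg)), 1)
  expect_equal(as.numeric(response_magnitude(mk(10, 450), cfg)), 45)
  m <- response_magnitude(mk(0, 50), cfg)
  expect_equal(as.numeric(m), 50)
  expect_true(attr(m, "zero_baseline"))
  # unequal windows are rejected
  expect_error(response_magnitude(psth_from_counts(rep(1, 60), 40), cfg),
               "equal-duration")
})

test_that("magnitude is invariant to trial order and time rescaling", {
  st <- simulate_baseline_train(cell_profile("FSN", 30, 1), 100, seed = 29)
  events <- seq(2, 97, by = 2)
  ps <- build_psth(st, events, bin_width = 8.125, n_pre = 40, n_post = 40)
  m1 <- as.numeric(response_magnitude(ps))
  ps_rev <- build_psth(st, rev(events), bin_width = 8.125, n_pre = 40, n_post = 40)
  expect_equal(as.numeric(response_magnitude(ps_rev)), m1)
  # same spikes expressed in ms with ms bins
  st_ms <- spike_train(st$timestamps * 1000, recording_start = 0,
                       recording_end = 100 * 1000)
  ps_ms <- build_psth(st_ms, events * 1000, bin_width = 8125, n_pre = 40,
                      n_post = 40)
  expect_equal(as.numeric(response_magnitude(ps_ms)), m1)
})

test_that("latency to peak reports bin centers with earliest-bin ties", {
  # a spike 5.1 ms after onset in every trial: bin center 5.125 ms
  events <- seq(10, 100, by = 2)
  st <- spike_train(events + 0.0051, recording_start = 0, recording_end = 110)
  ps <- build_psth(st, events, bin_width = 0.25, n_pre = 40, n_post = 80,
                   alignment = "PULSE_ONSET")
  expect_equal(latency_to_peak(ps), 5.125)
  # flat response: earliest maximal bin wins
  flat <- psth_from_counts(c(rep(0, 40), rep(7, 80)), 40, bin_width = 0.25)
  expect_equal(latency_to_peak(flat), 0.125)
  # all-zero window: undefined and flagged
  none <- psth_from_counts(rep(0, 120), 40, bin_width = 0.25)
  expect_warning(lat <- latency_to_peak(none), "undefined")
  expect_true(is.na(lat))
})

test_that("population normalization rescales each unit to its own maximum", {
  p1 <- psth_from_counts(c(0, 0, 4, 2), 2)
  tr1 <- normalize_population(list(p1))
  expect_equal(tr1, c(0, 0, 1, 0.5))
  # two identical units average to the same trace
  expect_equal(normalize_population(list(p1, p1)), tr1)
  # units peaking at different bins both leave their mark
  p2 <- psth_from_counts(c(0, 0, 1, 8), 2)
  tr <- normalize_population(list(p1, p2))
  expect_equal(tr, c(0, 0, (1 + 1 / 8) / 2, (0.5 + 1) / 2))
  expect_true(all(tr >= 0 & tr <= 1))
  # all-zero units are excluded with a warning
  expect_warning(normalize_population(list(p1, psth_from_counts(rep(0, 4), 2))),
                 "excluded")
  expect_error(normalize_population(list(p1, psth_from_counts(rep(0, 6), 3))),
               "binning")
})

test_that("post-train suppression measures run length past the train end", {
  base <- rep(c(8, 12), 20)  # mu 10, sigma ~2.03, lower threshold ~5.9
  post <- rep(10, 90)
  post[41:45] <- 0           # 5 bins below threshold, starting 325 ms in
  ps <- psth_from_counts(c(base, post), 40)
  s <- post_train_suppression(ps, train_end_ms = 320)
  expect_true(s$detected)
  expect_equal(s$duration_ms, 5 * 8.125)  # 40.625 ms
  # no qualifying run
  s0 <- post_train_suppression(psth_from_counts(c(base, rep(10, 90)), 40), 320)
  expect_false(s0$detected)
  # sub-threshold runs before the train end do not count
  pre_end <- rep(10, 90)
  pre_end[10:20] <- 0
  s1 <- post_train_suppression(psth_from_counts(c(base, pre_end), 40), 320)
  expect_false(s1$detected)
  # window too short is a configuration error
  expect_error(post_train_suppression(psth_from_counts(c(base, rep(10, 40)), 40),
                                      320), "400 ms")
})

test_that("simulated post-train suppression duration is recovered", {
  # tonic 30 spikes/s unit, suppression depth 0.9 for 150 ms after each train
  prof <- cell_profile("FSN", 30, 0.8, gain = 20, response_type = "COMBINATION",
                       response_latency = 5, suppression_depth = 0.9,
                       suppression_duration = 150)
  proto <- fixture_protocol(seed = 71)
  hits <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    sess <- simulate_session(prof, sim_config(proto, seed = 400 + i))
    ps <- build_psth(sess$units[[1]], proto$trains$onset, bin_width = 8.125,
                     n_pre = 40, n_post = 90)
    s <- post_train_suppression(ps, train_end_ms = 320)
    if (s$detected && abs(s$duration_ms - 150) <= 50) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})
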