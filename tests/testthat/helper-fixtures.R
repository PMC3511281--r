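# Shared fixture builders for the test suite. Everything is generated in code;
# seeds are fixed so the suite is deterministic.

# a perfectly periodic unit at `rate` Hz over `dur` seconds
periodic_train <- function(rate, dur, start = 0) {
  spike_train(seq(start + 1 / rate, start + dur, by = 1 / rate),
              recording_start = start, recording_end = start + dur)
}

# response-phenotype profiles used by the recovery suites
fixture_profiles <- function() {
  list(
    excited = cell_profile("TAN", baseline_rate = 5, target_cv = 0.5, gain = 20,
                           response_type = "EXCITED", response_latency = 5,
                           decrement_factor = 0.9),
    inhibited = cell_profile("FSN", baseline_rate = 30, target_cv = 0.8, gain = 10,
                             response_type = "INHIBITED", response_latency = 5),
    combination = cell_profile("FSN", baseline_rate = 20, target_cv = 0.8, gain = 20,
                               response_type = "COMBINATION", response_latency = 5,
                               suppression_depth = 0.9, suppression_duration = 150),
    none = cell_profile("FSN", baseline_rate = 20, target_cv = 1.0)
  )
}

# standard screening protocol: 50 trains of 10 x 20 ms pulses at 30 Hz
fixture_protocol <- function(n_trains = 50, seed = 1234) {
  standard_train_protocol(n_trains, start = 2, seed = seed)
}

# a synthetic PSTH object from explicit counts (for detector arithmetic tests)
psth_from_counts <- function(counts, n_pre, bin_width = 8.125, n_trials = 50) {
  structure(list(counts = as.integer(counts), per_trial = NULL,
                 n_trials = n_trials, bin_width = bin_width,
                 n_pre = as.integer(n_pre),
                 n_post = length(counts) - as.integer(n_pre),
                 alignment = "TRAIN_ONSET"),
            class = "psth")
}

# independent brute-force run scanner: the oracle for the 2-SD detector
oracle_detect <- function(counts, n_pre, k = 2, min_bins = 2) {
  base <- counts[1:n_pre]
  post <- counts[(n_pre + 1):length(counts)]
  mu <- mean(base)
  s <- stats::sd(base)
  up_runs <- list()
  dn_runs <- list()
  n <- length(post)
  for (start in seq_len(n)) {
    for (end in start:n) {
      seg <- post[start:end]
      len <- end - start + 1
      if (len >= min_bins) {
        if (all(seg > mu + k * s)) up_runs[[length(up_runs) + 1]] <- c(start, end)
        if (all(seg < mu - k * s)) dn_runs[[length(dn_runs) + 1]] <- c(start, end)
      }
    }
  }
  has_up <- length(up_runs) > 0
  has_dn <- length(dn_runs) > 0
  if (!has_up && !has_dn) return("NONE")
  if (has_up && !has_dn) return("INCREASE")
  if (!has_up) return("DECREASE")
  up_end <- min(vapply(up_runs, `[`, numeric(1), 2))
  dn_start <- max(vapply(dn_runs, `[`, numeric(1), 1))
  if (up_end < dn_start) return("COMBINATION")
  up_first <- min(vapply(up_runs, `[`, numeric(1), 1))
  dn_first <- min(vapply(dn_runs, `[`, numeric(1), 1))
  if (up_first <= dn_first) "INCREASE" else "DECREASE"
}

# independent Mann-Whitney oracle: U by pairwise counting, exact two-sided p by
# complete enumeration of group assignments
oracle_mw <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  U <- u_of(a, b)
  pool <- c(a, b)
  N <- n1 + n2
  mu <- n1 * n2 / 2
  idx <- utils::combn(N, n1)
  devs <- apply(idx, 2, function(ii) abs(u_of(pool[ii], pool[-ii]) - mu))
  list(U = U, p = mean(devs >= abs(U - mu) - 1e-9))
}
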