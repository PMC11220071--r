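# Shared fixtures, built once per test run and memoised. All synthetic.

memoise_fixture <- function(builder) {
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- builder()
    cache
  }
}

# 30-trial expert session + full design, reused by design/glm/decoding tests
small_bundle <- memoise_fixture(function() {
  simulate_trial_events(session_config(n_trials = 30, seed = 101))
})

small_design <- memoise_fixture(function() {
  assemble_design_matrix(small_bundle())
})

# a driven neuron on the small session (inhalation + odour kernels)
small_driven <- memoise_fixture(function() {
  d <- small_design()
  model <- make_ground_truth_kernels(d$specs, c("Inhal", "Odour"),
                                     seed = 7, base_rate_hz = 8)
  sim <- simulate_spikes(model, d, seed = 8)
  list(model = model, counts = sim$counts, lambda = sim$lambda)
})

# single-trial bundle with hand-placed events, for convolution oracles
toy_bundle <- memoise_fixture(function() {
  b <- simulate_trial_events(session_config(n_trials = 3, seed = 11))
  b
})

# brute-force discrete convolution of a kernel with a delta train, per trial
oracle_convolve <- function(bundle, event_times, kernel, lag_bins) {
  delta <- bundle$config$delta
  out <- numeric(nrow(bundle$traces))
  offset <- 0L
  for (i in seq_len(nrow(bundle$events))) {
    rows <- which(bundle$traces$trial == bundle$events$trial[i])
    t0 <- bundle$events$t_start[i]
    ev <- event_times[event_times >= t0 &
                        event_times < t0 + length(rows) * delta]
    for (et in ev) {
      b0 <- floor((et - t0) / delta) + 1L
      for (l in seq_along(lag_bins)) {
        idx <- b0 + lag_bins[l]
        if (idx >= 1L && idx <= length(rows)) {
          out[offset + idx] <- out[offset + idx] + kernel[l]
        }
      }
    }
    offset <- offset + length(rows)
  }
  out
}
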