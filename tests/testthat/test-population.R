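test_that("event PSTHs integrate to the spikes per trial and average correctly", {
  events <- c(10, 20, 30, 40)
  spikes <- events + 0.25   # one spike 250 ms after every event
  p <- event_psth(spikes, events, window = c(-0.5, 1), sigma = 0.03)
  expect_equal(sum(p$rate) * 0.01, 1, tolerance = 1e-6)
  expect_equal(p$time[which.max(p$rate)], 0.255, tolerance = 0.02)
  # doubling the events with identical relative spikes changes nothing
  e2 <- c(events, events + 100)
  p2 <- event_psth(c(spikes, spikes + 100), e2, window = c(-0.5, 1))
  expect_equal(p2$rate, p$rate, tolerance = 1e-9)
  # empty spike train: flat zero
  expect_true(all(event_psth(numeric(0), events)$rate == 0))
})

test_that("a homogeneous Poisson train gives a flat PSTH at its rate", {
  set.seed(91)
  rate <- 25
  spikes <- cumsum(rexp(20000, rate))
  events <- seq(50, 700, by = 13)
  p <- event_psth(spikes, events, window = c(-1, 1), sigma = 0.03)
  se <- sqrt(rate / (length(events) * 0.01))   # pre-smoothing bin SE
  expect_true(all(abs(p$rate - rate) < 4 * se))
})

test_that("stitching averages overlaps and accepts the expert alignment", {
  tgrid <- seq(0, 0.5, by = 0.01)
  seg <- function(val) data.frame(time = tgrid, rate = rep(val, length(tgrid)))
  out <- stitch_trial_psth(list(a = seg(4), b = seg(4)), c(a = 0, b = 0.25))
  ov <- out$time >= 0.25 & out$time <= 0.5
  expect_equal(out$rate[ov], rep(4, sum(ov)))
  out2 <- stitch_trial_psth(list(a = seg(2), b = seg(6)), c(a = 0, b = 0.25))
  expect_equal(out2$rate[out2$time > 0.251 & out2$time < 0.499],
               rep(4, sum(out2$time > 0.251 & out2$time < 0.499)))
  # idempotent on an already-continuous series
  again <- stitch_trial_psth(list(x = out), c(x = 0))
  expect_equal(again$rate, out$rate, tolerance = 1e-9)
  # the expert-session C/O/L/R alignment is a valid configuration for
  # event PSTHs spanning [-1, 1] s around each event
  long <- function(val) data.frame(time = seq(-1, 1, by = 0.01),
                                   rate = rep(val, 201))
  expert <- stitch_trial_psth(list(C = long(1), O = long(2), L = long(3),
                                   R = long(4)),
                              c(C = -0.43, O = 0, L = 1.38, R = 1.96))
  expect_error(expert_gap <- stitch_trial_psth(
    list(C = long(1), O = long(2), L = long(3)),
    c(C = -0.43, O = 0, L = 5)), "gaps")
})

test_that("population vector correlations have unit diagonal and catch duplicates", {
  set.seed(92)
  M <- matrix(rnorm(200 * 8), 200, 8)
  M[, 2] <- M[, 1]
  cc <- population_correlation_matrix(M)
  expect_equal(diag(cc), rep(1, 8), ignore_attr = TRUE)
  expect_equal(cc[1, 2], 1)
  expect_equal(cc, t(cc))
  # orthogonal constructions decorrelate at large N
  a <- rnorm(400)
  b <- rnorm(400); b <- b - a * sum(a * b) / sum(a^2)
  cc2 <- population_correlation_matrix(cbind(a, b))
  expect_lt(abs(cc2[1, 2] - (-1 / (400 - 1)) * 0), 0.05)
  expect_warning(population_correlation_matrix(cbind(a, rep(1, 400))),
                 "zero-variance")
  expect_error(population_correlation_matrix(M[1, , drop = FALSE]), "2 neurons")
})

test_that("PCA trajectories reconstruct the data and order the variance", {
  set.seed(93)
  Xbar <- array(rnorm(20 * 2 * 2 * 15), c(20, 2, 2, 15))
  res <- pca_trajectories(Xbar)
  expect_true(all(diff(res$explained) <= 1e-12))
  M <- matrix(Xbar, nrow = 20)
  expect_lt(max(abs(res$reconstruction - Xbar)), 1e-10)
  # rank-1 data has exactly one nonzero singular value
  u <- rnorm(20); v <- rnorm(60)
  X1 <- array(outer(u, v), c(20, 2, 2, 15))
  res1 <- pca_trajectories(X1)
  expect_lt(res1$singular_values[2] / res1$singular_values[1], 1e-10)
  expect_warning(pca_trajectories(array(rnorm(2 * 60), c(2, 2, 2, 15))),
                 "component")
})

test_that("the variance decomposition matches a brute-force oracle", {
  set.seed(94)
  d <- c(3, 2, 2, 4, 5)   # N, C, O, T, K
  X <- array(rnorm(prod(d), mean = 5), d)
  res <- signal_variance_decomposition(X)
  # independent literal evaluation with explicit loops
  Xbar <- apply(X, 1:4, mean)
  total_o <- 0
  for (n in 1:d[1]) {
    mn <- mean(Xbar[n, , , ])
    for (c in 1:d[2]) for (o in 1:d[3]) for (t in 1:d[4]) {
      total_o <- total_o + (Xbar[n, c, o, t] - mn)^2
    }
  }
  theta_o <- 0
  for (n in 1:d[1]) {
    cn <- 0
    for (c in 1:d[2]) for (o in 1:d[3]) for (t in 1:d[4]) for (k in 1:d[5]) {
      cn <- cn + (X[n, c, o, t, k] - Xbar[n, c, o, t])^2 / d[5]
    }
    cn_avg <- cn / (d[2] * d[3] * d[4])            # average over conditions
    theta_o <- theta_o + d[2] * d[3] * d[4] * cn_avg / d[5]
  }
  expect_equal(res$total_variance, total_o, tolerance = 1e-10)
  expect_equal(res$noise, theta_o, tolerance = 1e-10)
  expect_equal(res$signal_variance, total_o - theta_o, tolerance = 1e-10)
})

test_that("zero trial noise gives a 100% signal fraction", {
  set.seed(95)
  base <- array(rnorm(4 * 2 * 2 * 6), c(4, 2, 2, 6))
  X <- array(rep(base, 3), c(4, 2, 2, 6, 3))
  res <- signal_variance_decomposition(X)
  expect_equal(res$noise, 0)
  expect_equal(res$fraction, 100)
})

test_that("pure noise gives a near-zero signal fraction", {
  set.seed(96)
  d <- c(100, 2, 2, 10, 20)
  X <- array(rpois(prod(d), 5), d)
  res <- signal_variance_decomposition(X)
  expect_lt(abs(res$fraction), 12)
  expect_error(signal_variance_decomposition(X[, , , , 1, drop = FALSE]),
               "fewer than 2")
})

test_that("dimensionality counts components up to the signal fraction", {
  set.seed(97)
  # equal-share case: isotropic rows
  M <- diag(10) * 3
  M <- M - rowMeans(M)
  expect_equal(dimensionality_estimate(M, 50)$n_components, 5)
  u <- rnorm(30); v <- rnorm(40)
  expect_equal(dimensionality_estimate(outer(u, v), 60)$n_components, 1)
  # brute-force cumulative scan agreement on random data
  R <- matrix(rnorm(25 * 40), 25, 40)
  frac <- 80
  res <- dimensionality_estimate(R, frac)
  ev <- svd(R - rowMeans(R))$d^2
  oracle <- which(cumsum(ev) / sum(ev) >= frac / 100)[1]
  expect_equal(res$n_components, oracle)
})

test_that("spike-count variability follows Poisson scaling", {
  set.seed(98)
  counts <- matrix(rpois(40000, 16), nrow = 4, ncol = 10000)
  cv <- spikecount_cv(counts)
  expect_true(all(abs(cv - 1 / 4) < 3 * 0.25 / sqrt(10000) * 3))
  expect_equal(spikecount_cv(matrix(7, 2, 5)), c(0, 0), ignore_attr = TRUE)
  expect_equal(spikecount_cv(counts * 3), cv, tolerance = 1e-12,
               ignore_attr = TRUE)
  cv0 <- spikecount_cv(matrix(0, 1, 4))
  expect_true(is.na(cv0[1]))
  expect_equal(attr(cv0, "undefined"), 1L)
})

test_that("the pooled activity array tracks trial counts and averages", {
  b <- simulate_trial_events(session_config(n_trials = 24, seed = 99))
  d <- assemble_design_matrix(b, variables = "Inhal")
  m <- make_ground_truth_kernels(d$specs, "Inhal", seed = 1)
  b <- add_unit_counts(b, 1L, simulate_spikes(m, d, seed = 2)$counts)
  b <- add_unit_counts(b, 2L, simulate_spikes(m, d, seed = 3)$counts)
  arr <- pooled_activity_array(b, window = c(-0.2, 0.8), dt = 0.1)
  expect_equal(dim(arr$X)[1:3], c(2, 2, 2))
  expect_equal(sum(arr$trial_num[1, , ]), 24)
  got <- apply(arr$X, 1:4, mean, na.rm = TRUE)
  expect_equal(got, arr$Xbar, tolerance = 1e-12)
})
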