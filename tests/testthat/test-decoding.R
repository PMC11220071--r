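# session with strongly separated odour kernels and several units
decode_setup <- memoise_fixture(function() {
  b <- simulate_trial_events(session_config(n_trials = 40, seed = 501))
  d <- assemble_design_matrix(b)
  designs <- decoding_designs(b, "odour", specs = d$specs)
  units <- lapply(1:4, function(u) {
    m <- make_ground_truth_kernels(d$specs, c("Inhal", "Odour"),
                                   seed = 510 + u, amplitude = 1.2)
    sim <- simulate_spikes(m, d, seed = 520 + u)
    list(model = m, fit = as_glm_fit(m, d), counts = sim$counts)
  })
  list(bundle = b, design = d, designs = designs, units = units,
       counts = vapply(units, `[[`, numeric(nrow(d$X)), "counts"))
})

test_that("counterfactual designs differ only in the decoded variable", {
  s <- decode_setup()
  A <- s$designs$A; B <- s$designs$B
  same <- c("Inhal", "Licks", "Speed")
  for (v in same) {
    cols <- spikeglm:::design_columns(A, v)
    expect_equal(A$X[, cols], B$X[, cols])
  }
  oc <- spikeglm:::design_columns(A, "Odour")
  expect_gt(sum(abs(A$X[, oc] - B$X[, oc])), 0)
  expect_identical(s$designs$labels,
                   ifelse(s$bundle$events$odour == "R", "A", "B"))
})

test_that("identical category kernels give an identically zero LLR", {
  s <- decode_setup()
  f <- s$units[[1]]$fit
  n10 <- sum(grepl("^O_R\\.", names(f$weights)))
  f$weights[grepl("^O_U\\.", names(f$weights))] <-
    f$weights[grepl("^O_R\\.", names(f$weights))]
  tc <- llr_timecourse(f, s$designs$A, s$designs$B, s$units[[1]]$counts)
  expect_equal(max(abs(tc$llr)), 0)
})

test_that("population LLR is the sum of single-neuron LLRs and flips with relabeling", {
  s <- decode_setup()
  t1 <- llr_timecourse(s$units[[1]]$fit, s$designs$A, s$designs$B,
                       s$units[[1]]$counts)
  t2 <- llr_timecourse(s$units[[2]]$fit, s$designs$A, s$designs$B,
                       s$units[[2]]$counts)
  pop <- t1$llr + t2$llr
  expect_equal(pop, llr_timecourse(s$units[[1]]$fit, s$designs$A, s$designs$B,
                                   s$units[[1]]$counts)$llr +
                 llr_timecourse(s$units[[2]]$fit, s$designs$A, s$designs$B,
                                s$units[[2]]$counts)$llr)
  swapped <- llr_timecourse(s$units[[1]]$fit, s$designs$B, s$designs$A,
                            s$units[[1]]$counts)
  expect_equal(swapped$llr, -t1$llr)
})

test_that("trials simulated under a category accumulate evidence for it", {
  s <- decode_setup()
  ev <- s$bundle$events
  end_llr <- vapply(seq_len(nrow(ev)), function(i) {
    tc <- llr_timecourse(s$units[[1]]$fit, s$designs$A, s$designs$B,
                         s$units[[1]]$counts)
    tail(tc$llr[tc$trial == ev$trial[i]], 1)
  }, numeric(1))
  expect_gt(mean(end_llr[ev$odour == "R"]), 0)
  expect_lt(mean(end_llr[ev$odour == "U"]), 0)
  # weaker kernels separate less
  d <- s$design
  m_weak <- make_ground_truth_kernels(d$specs, c("Inhal", "Odour"),
                                      seed = 511, amplitude = 0.3)
  sim_w <- simulate_spikes(m_weak, d, seed = 521)
  tcw <- llr_timecourse(as_glm_fit(m_weak, d), s$designs$A, s$designs$B,
                        sim_w$counts)
  end_w <- vapply(which(ev$odour == "R"), function(i) {
    tail(tcw$llr[tcw$trial == ev$trial[i]], 1)
  }, numeric(1))
  expect_lt(mean(end_w), mean(end_llr[ev$odour == "R"]))
})

test_that("posteriors are the logistic transform of the LLR and sum to one", {
  expect_equal(posterior_probability(0), 0.5)
  set.seed(6)
  llr <- rnorm(50, sd = 4)
  pA <- posterior_probability(llr)
  pB <- posterior_probability(-llr)
  expect_true(all(pA >= 0 & pA <= 1))
  expect_equal(pA + pB, rep(1, 50), tolerance = 1e-12)
  # algebraic oracle: likelihood ratio form on moderate values
  la <- exp(llr / 2); lb <- exp(-llr / 2)
  expect_equal(pA, la / (la + lb), tolerance = 1e-10)
  # extreme LLRs never produce NaN
  expect_false(any(is.nan(posterior_probability(c(-1e4, 1e4)))))
  expect_true(all(sign(llr) == sign(pA - 0.5)))
})

test_that("population decoding is accurate and its shuffle control is at chance", {
  s <- decode_setup()
  res <- population_decode(lapply(s$units, `[[`, "fit"), s$counts, s$bundle,
                           "odour", designs = s$designs,
                           pop_sizes = c(1, 4), n_repeats = 20, seed = 3)
  acc <- res$accuracy_by_size$accuracy
  expect_gt(acc[2], 0.9)
  expect_true(all(diff(res$accuracy_by_size$accuracy) >= -0.05))
  n_dec <- 2 * res$n_matched * res$n_repeats
  band <- qbinom(c(0.005, 0.995), n_dec, 0.5) / n_dec
  expect_gt(res$shuffle_by_size$accuracy[2], band[1])
  expect_lt(res$shuffle_by_size$accuracy[2], band[2])
  expect_error(population_decode(lapply(s$units, `[[`, "fit"), s$counts,
                                 s$bundle, "odour", designs = s$designs,
                                 pop_sizes = 10), "exceeds")
})

test_that("decoding a variable absent from every model is at chance", {
  s <- decode_setup()
  ctx <- decoding_designs(s$bundle, "context", specs = s$design$specs)
  res <- population_decode(lapply(s$units, `[[`, "fit"), s$counts, s$bundle,
                           "context", designs = ctx, pop_sizes = 4,
                           n_repeats = 20, seed = 4)
  n_dec <- 2 * res$n_matched * res$n_repeats
  band <- qbinom(c(0.005, 0.995), n_dec, 0.5) / n_dec
  expect_gt(res$accuracy_by_size$accuracy, band[1] - 0.02)
  expect_lt(res$accuracy_by_size$accuracy, band[2] + 0.02)
})

test_that("ablation zeroes exactly the non-kept kernels", {
  s <- decode_setup()
  d <- s$design
  m <- make_ground_truth_kernels(d$specs, c("Inhal", "Odour", "Context"),
                                 seed = 530)
  f <- as_glm_fit(m, d)
  ab <- ablate_kernels(list(f), keep = "Odour")[[1]]
  expect_equal(ab$ablated, c("Inhal", "Context"))
  lam <- predict_rate(ab, d)
  oc <- grepl("^(O_R|O_U)\\.|^bias$", names(f$weights))
  w_kept <- f$weights
  w_kept[!oc] <- 0
  cols <- spikeglm:::design_columns(d, f$variables)
  expect_equal(lam, as.numeric(exp(d$X[, cols] %*% w_kept)), tolerance = 1e-12)
  # odour-only neuron passes through unchanged
  f2 <- s$units[[1]]$fit
  f2$variables <- "Odour"
  f2$weights <- f2$weights[grepl("^(O_R|O_U)\\.|^bias$", names(f2$weights))]
  f2$coefficients <- f2$coefficients[c("O_R", "O_U")]
  f2$kernels <- f2$kernels[c("O_R", "O_U")]
  ab2 <- ablate_kernels(list(f2), keep = "Odour")[[1]]
  expect_equal(ab2$weights, f2$weights)
  # no kept variables: flagged, unchanged
  f3 <- ablate_kernels(list(s$units[[1]]$fit), keep = "Reward")[[1]]
  expect_true(isTRUE(f3$untouched))
  expect_equal(f3$weights, s$units[[1]]$fit$weights)
  expect_error(ablate_kernels(list(f2), keep = character(0)), "nonempty")
})

test_that("linear classifiers separate noiseless classes and not shuffled ones", {
  set.seed(61)
  n <- 24
  x <- rbind(matrix(rnorm(n * 6, 0), n, 6), matrix(rnorm(n * 6, 3), n, 6))
  y <- rep(c("a", "b"), each = n)
  res <- linear_classifier_decode(x, y, pop_sizes = c(2, 6), n_repeats = 10,
                                  seed = 9)
  expect_equal(res$accuracy[2], 1)
  expect_lt(abs(res$shuffle_accuracy[2] - 0.5), 0.15)
  # halving trials per class does not help
  res_small <- linear_classifier_decode(x[c(1:12, n + 1:12), ],
                                        y[c(1:12, n + 1:12)],
                                        pop_sizes = 6, n_repeats = 10, seed = 9)
  expect_lte(res_small$accuracy, res$accuracy[2] + 1e-9)
  expect_error(linear_classifier_decode(x[c(1:2, n + 1:2), ],
                                        y[c(1:2, n + 1:2)]), "fewer than")
})

test_that("overlapping noisy classes are harder for the classifier", {
  set.seed(62)
  n <- 30
  x_hard <- rbind(matrix(rnorm(n * 4, 0, 2), n, 4),
                  matrix(rnorm(n * 4, 0.5, 2), n, 4))
  y <- rep(c("a", "b"), each = n)
  res <- linear_classifier_decode(x_hard, y, pop_sizes = 4, n_repeats = 10,
                                  seed = 10)
  expect_lt(res$accuracy, 0.95)
})

test_that("response delays follow the GO/NO-GO convention", {
  b <- small_bundle()
  delays <- response_delays(b$events)
  expect_equal(length(delays), nrow(b$events))
  expect_true(all(delays > 0))
  go <- b$events$go
  expect_equal(delays[go],
               (b$events$t_first_lick_after_odour -
                  b$events$t_first_odour_inhalation)[go])
})

test_that("delay regression isolates the interaction term", {
  set.seed(71)
  n <- 200
  p_or <- runif(n); p_cr <- runif(n)
  delay <- 2 - 1.5 * p_or * p_cr
  res <- suppressWarnings(delay_regression(delay, p_or, p_cr))
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
  expect_lt(res$p_interaction, 1e-6)
  # power at alpha = 0.05 under noise
  hits <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    p_or <- runif(n); p_cr <- runif(n)
    delay <- 2 - 1.5 * p_or * p_cr + rnorm(n, sd = 0.4)
    if (delay_regression(delay, p_or, p_cr)$p_interaction < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 18)
  # null: rejection near the nominal level
  null_hits <- 0L
  for (s in 1:50) {
    set.seed(800 + s)
    p_or <- runif(n); p_cr <- runif(n)
    delay <- rnorm(n)
    if (delay_regression(delay, p_or, p_cr)$p_interaction < 0.05) {
      null_hits <- null_hits + 1L
    }
  }
  expect_lte(null_hits, 8)   # 99th percentile of Binomial(50, 0.05)
  expect_error(delay_regression(rnorm(5), runif(5), runif(5)), "10 trials")
  expect_error(delay_regression(rnorm(20), rep(1, 20), rep(1, 20)),
               "rank-deficient")
})
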