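test_that("the Poisson log-likelihood matches hand-computed values", {
  expect_equal(poisson_log_likelihood(rep(0L, 10), rep(10, 10), 0.01), -1)
  expect_equal(poisson_log_likelihood(1L, 100, 0.01), -1)   # log(1) - 1
  expect_equal(poisson_log_likelihood(2L, 100, 0.01, include_constant = TRUE),
               -1 - log(2))
  expect_error(poisson_log_likelihood(1L, 0, 0.01), "-Inf|negative rate")
})

test_that("the MAP optimum is unique and the objective non-decreasing", {
  d <- small_design()
  s <- small_driven()
  f1 <- fit_map(d, s$counts, xi = 1, variables = c("Inhal", "Odour"))
  init <- rnorm(length(f1$weights), sd = 0.3)
  names(init) <- names(f1$weights)
  f2 <- fit_map(d, s$counts, xi = 1, variables = c("Inhal", "Odour"),
                w_init = init)
  expect_lt(max(abs(f1$weights - f2$weights)), 1e-6)
  expect_true(all(diff(f1$objective_trace) >= -1e-8))
  expect_true(all(diff(f2$objective_trace) >= -1e-8))
})

test_that("an overwhelming ridge shrinks kernels to zero but spares the bias", {
  d <- small_design()
  s <- small_driven()
  f <- fit_map(d, s$counts, xi = 1e8, variables = c("Inhal", "Odour"))
  kw <- f$weights[names(f$weights) != "bias"]
  expect_lt(max(abs(kw)), 1e-3)
  empirical <- sum(s$counts) / (length(s$counts) * d$delta)
  expect_equal(exp(f$bias), empirical, tolerance = 1e-3)
})

test_that("unpenalized fits agree with an independent Poisson GLM", {
  b <- toy_bundle()
  d <- assemble_design_matrix(b, variables = "Inhal")
  m <- make_ground_truth_kernels(d$specs, "Inhal", seed = 31)
  counts <- simulate_spikes(m, d, seed = 32)$counts
  f <- fit_map(d, counts, xi = 0, variables = "Inhal")
  Xd <- as.matrix(d$X[, -1])
  ref <- glm(counts ~ Xd, family = poisson(),
             offset = rep(log(d$delta), length(counts)))
  expect_equal(unname(f$weights["bias"]), unname(coef(ref)[1]),
               tolerance = 1e-4)
  expect_equal(unname(f$weights[-1]), unname(coef(ref)[-1]), tolerance = 1e-4)
})

test_that("fits to simulated data recover the generating kernels", {
  b <- simulate_trial_events(session_config(n_trials = 100, seed = 301))
  d <- assemble_design_matrix(b)
  m <- make_ground_truth_kernels(d$specs, c("Inhal", "Odour"), seed = 302)
  counts <- simulate_spikes(m, d, seed = 303)$counts
  f <- fit_map(d, counts, xi = 1, variables = c("Inhal", "Odour"))
  expect_gt(kernel_recovery_correlation(m, f, d), 0.9)
  # multiplicative gains are recovered too
  tg <- exp(unlist(m$kernels))
  eg <- exp(unlist(f$kernels))
  expect_gt(cor(tg, eg), 0.9)
})

test_that("adding a variable never hurts the unpenalized training likelihood", {
  d <- small_design()
  s <- small_driven()
  ll <- vapply(list("Inhal", c("Inhal", "Odour"), c("Inhal", "Odour", "Licks")),
               function(v) fit_map(d, s$counts, xi = 0, variables = v)$logLik,
               numeric(1))
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("evidence selection prefers stronger smoothing for unstructured data", {
  d <- small_design()
  s <- small_driven()
  grid <- 10^seq(-1, 3, length.out = 9)
  sel_smooth <- select_ridge_by_evidence(d, s$counts, grid,
                                         variables = c("Inhal", "Odour"))
  expect_true(all(is.finite(sel_smooth$evidence$log_evidence)))
  # rough neuron: same marginal counts, alignment destroyed by a circular
  # shift of half the session, so the kernel estimate is pure noise
  rough <- c(s$counts[(length(s$counts) %/% 2):length(s$counts)],
             s$counts[1:(length(s$counts) %/% 2 - 1)])
  sel_rough <- select_ridge_by_evidence(d, rough, grid,
                                        variables = c("Inhal", "Odour"))
  expect_gte(sel_rough$xi, sel_smooth$xi)
  expect_equal(select_ridge_by_evidence(d, s$counts, 3.7,
                                        variables = "Inhal")$xi, 3.7)
})

test_that("cross-validation credits the generating model over a flat one", {
  d <- small_design()
  s <- small_driven()
  folds <- make_cv_folds(d$bin_trial, 10, seed = 5)
  folds2 <- make_cv_folds(d$bin_trial, 10, seed = 5)
  expect_identical(folds, folds2)
  cv_true <- crossvalidated_performance(d, s$counts, 1, c("Inhal", "Odour"),
                                        folds = folds)
  cv_bias <- crossvalidated_performance(d, s$counts, 1, character(0),
                                        folds = folds)
  expect_gte(sum(cv_true$fold_ll > cv_bias$fold_ll), 9)
  # destroying the alignment destroys the advantage
  shifted <- c(s$counts[(length(s$counts) %/% 2):length(s$counts)],
               s$counts[1:(length(s$counts) %/% 2 - 1)])
  cv_shift <- crossvalidated_performance(d, shifted, 1, c("Inhal", "Odour"),
                                         folds = folds)
  cv_shift_bias <- crossvalidated_performance(d, shifted, 1, character(0),
                                              folds = folds)
  p <- suppressWarnings(wilcox.test(cv_shift$fold_ll, cv_shift_bias$fold_ll,
                                    paired = TRUE,
                                    alternative = "greater")$p.value)
  expect_gt(p, 0.05)
})

test_that("forward selection finds a driven variable and stops", {
  b <- simulate_trial_events(session_config(n_trials = 60, seed = 311))
  d <- assemble_design_matrix(b)
  m <- make_ground_truth_kernels(d$specs, "Inhal", seed = 312)
  counts <- simulate_spikes(m, d, seed = 313)$counts
  sel <- forward_model_selection(d, counts, xi = 3, seed = 314)
  expect_true("Inhal" %in% sel$variables)
  expect_lte(length(sel$variables), 2)
})

test_that("the exponential nonlinearity is confirmed on exponential-link data", {
  b <- simulate_trial_events(session_config(n_trials = 80, seed = 321))
  d <- assemble_design_matrix(b)
  m <- make_ground_truth_kernels(d$specs, c("Inhal", "Odour"), seed = 322,
                                 amplitude = 1.2)
  counts <- simulate_spikes(m, d, seed = 323)$counts
  f <- fit_map(d, counts, xi = 1, variables = c("Inhal", "Odour"))
  tab <- validate_exponential_nonlinearity(f, d, counts, n_bins = 15)
  well <- which(tab$n >= 200)
  inside <- vapply(well, function(i) {
    ci <- qpois(c(0.025, 0.975), tab$predicted_rate[i] * tab$n[i] * d$delta)
    obs <- tab$observed_rate[i] * tab$n[i] * d$delta
    obs >= ci[1] && obs <= ci[2]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
  expect_error(validate_exponential_nonlinearity(f, d, counts, n_bins = 1),
               ">= 2")
})

test_that("a constant-rate neuron occupies a single kernel-output bin", {
  d <- assemble_design_matrix(small_bundle(), variables = character(0))
  counts <- {set.seed(1); rpois(nrow(d$X), 0.08)}
  f <- fit_map(d, counts, xi = 0, variables = character(0))
  tab <- validate_exponential_nonlinearity(f, d, counts)
  expect_equal(nrow(tab), 1L)
})

test_that("a non-exponential link is flagged by the validation", {
  b <- simulate_trial_events(session_config(n_trials = 80, seed = 331))
  d <- assemble_design_matrix(b)
  m <- make_ground_truth_kernels(d$specs, c("Inhal", "Odour"), seed = 332,
                                 amplitude = 1.5)
  # linear link: rate = a + b * (kernel output), same range as exp data
  w <- spikeglm:::design_weight_vector(d, m)
  g <- as.numeric(d$X %*% w) - m$bias
  lam_lin <- pmax(0.5, 8 * (1 + 1.2 * g))
  counts <- {set.seed(333); rpois(length(g), lam_lin * d$delta)}
  f <- fit_map(d, counts, xi = 1, variables = c("Inhal", "Odour"))
  tab <- validate_exponential_nonlinearity(f, d, counts, n_bins = 15)
  well <- tab$n >= 50
  rel_err <- abs(tab$observed_rate - tab$predicted_rate) / tab$predicted_rate
  expect_gt(max(rel_err[well], na.rm = TRUE), 0.2)
})

test_that("predicted rates obey the exponential algebra and a convolution oracle", {
  d <- small_design()
  s <- small_driven()
  f0 <- fit_map(d, s$counts, xi = 1, variables = character(0))
  expect_equal(predict_rate(f0, d), rep(exp(f0$bias), nrow(d$X)))
  f <- fit_map(d, s$counts, xi = 1, variables = "Inhal")
  f2 <- f
  idx <- names(f$weights) != "bias"
  f2$weights[idx] <- 2 * f$weights[idx]
  lam1 <- predict_rate(f, d)
  lam2 <- predict_rate(f2, d)
  expect_equal(lam2, lam1^2 / exp(f$bias), tolerance = 1e-10)
  # oracle equivalence on the toy session
  b <- toy_bundle()
  dt <- assemble_design_matrix(b, variables = "Inhal")
  mt <- make_ground_truth_kernels(dt$specs, "Inhal", seed = 41)
  ft <- fit_map(dt, simulate_spikes(mt, dt, seed = 42)$counts, xi = 0.5,
                variables = "Inhal")
  basis <- dt$kernels$Inhal$basis
  lag_bins <- as.integer(round(basis$grid / b$config$delta))
  oracle_eta <- oracle_convolve(b, b$inhalations$time,
                                ft$kernels$Inhal, lag_bins) + ft$bias
  expect_lt(max(abs(predict_rate(ft, dt) - exp(oracle_eta))), 1e-10)
  fit_wrong <- ft
  fit_wrong$variables <- c("Inhal", "Odour")
  expect_error(predict_rate(fit_wrong, dt))
})
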