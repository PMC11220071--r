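#' Poisson log-likelihood of binned spike counts
#'
#' Computes `sum_t [ r_t log(lambda_t * delta) - lambda_t * delta ]`, the
#' Poisson log-likelihood without the count-factorial constant; with
#' `include_constant = TRUE` the `- sum_t log(r_t!)` term is added.
#'
#' @param counts non-negative integer counts.
#' @param rate rate in Hz per bin (must be positive wherever `counts > 0`).
#' @param delta bin size (s).
#' @param include_constant add the factorial constant.
#' @return scalar log-likelihood.
#' @export
poisson_log_likelihood <- function(counts, rate, delta, include_constant = FALSE) {
  if (length(counts) != length(rate)) stop("length mismatch", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers", call. = FALSE)
  }
  mu <- rate * delta
  pos <- counts > 0
  if (any(mu[pos] <= 0)) {
    stop("zero or negative rate in a bin with nonzero count (log-likelihood -Inf)",
         call. = FALSE)
  }
  ll <- -sum(mu) + sum(counts[pos] * log(mu[pos]))
  if (include_constant) ll <- ll - sum(lfactorial(counts))
  ll
}

penalized_objective <- function(eta, counts, delta, w, pen, xi) {
  mu <- delta * exp(pmin(eta, 40))
  sum(counts * eta) - sum(mu) - xi * sum(w[pen]^2)
}

#' Ridge-MAP fit of the Poisson encoding model
#'
#' Maximizes the log-posterior `L(k) = sum_t [r_t log(lambda_t delta) -
#' lambda_t delta] - xi ||k||^2` over the basis weights of the included
#' variables plus the (unpenalized) bias, by Newton ascent with step halving.
#' The objective is concave, so the optimum is unique; the recorded objective
#' trace is non-decreasing.
#'
#' @param design a [assemble_design_matrix()] design.
#' @param counts per-bin spike counts aligned with the design.
#' @param xi ridge strength (>= 0) on kernel weights.
#' @param variables character vector of included variables
#'   (default: all in the design; `character(0)` fits the bias-only model).
#' @param w_init optional named warm-start weight vector.
#' @param rows optional row subset (training bins) for cross-validation.
#' @param tol convergence tolerance: the max absolute gradient entry must fall
#'   below `tol * max(1, sum(counts))`.
#' @param max_iter maximum Newton iterations.
#' @return an object of class `glm_fit`: `weights` (named, including `bias`),
#'   `variables`, `xi`, `kernels` (reconstructed kernel values on each basis
#'   grid), `bias`, `coefficients` (per-kernel weight vectors), `logLik`
#'   (unpenalized, constant-free), `objective_trace`, `converged`,
#'   `iterations`, `gradient_norm`, `delta`.
#' @export
fit_map <- function(design, counts, xi, variables = NULL, w_init = NULL,
                    rows = NULL, tol = 1e-6, max_iter = 200) {
  stopifnot(inherits(design, "design_matrix"), xi >= 0)
  if (is.null(variables)) variables <- names(design$variables)
  cols <- design_columns(design, variables)
  X <- design$X[, cols, drop = FALSE]
  if (!is.null(rows)) {
    X <- X[rows, , drop = FALSE]
    counts <- counts[rows]
  }
  delta <- design$delta
  P <- ncol(X)
  pen <- colnames(X) != "bias"
  w <- numeric(P)
  names(w) <- colnames(X)
  mean_rate <- max(sum(counts), 0.5) / (nrow(X) * delta)
  w["bias"] <- log(mean_rate)
  if (!is.null(w_init)) {
    shared <- intersect(names(w_init), names(w))
    w[shared] <- w_init[shared]
  }

  gtol <- tol * max(1, sum(counts))
  res <- poisson_newton_cpp(X, as.numeric(counts), delta, xi,
                            as.integer(pen), w, gtol, max_iter)
  if (!is.null(res$error)) {
    stop("Newton step failed: singular Hessian (try a larger ridge xi)",
         call. = FALSE)
  }
  if (!res$converged) {
    stop(sprintf("MAP fit did not converge in %d iterations (|grad| = %.3g, tol %.3g)",
                 max_iter, res$gradient_norm, gtol), call. = FALSE)
  }
  w <- stats::setNames(as.numeric(res$w), colnames(X))
  eta <- as.numeric(X %*% w)
  obj <- res$objective
  trace <- as.numeric(res$trace)
  it <- res$iterations
  gnorm <- res$gradient_norm
  converged <- res$converged
  coefs <- list()
  kernels <- list()
  for (v in variables) {
    for (kn in design$variables[[v]]$kernels) {
      b <- design$kernels[[kn]]$basis
      wk <- w[paste0(kn, ".", seq_len(b$n))]
      coefs[[kn]] <- unname(wk)
      kernels[[kn]] <- basis_kernel(b, unname(wk))
    }
  }
  structure(list(weights = w, variables = variables, xi = xi,
                 coefficients = coefs, kernels = kernels,
                 bias = unname(w["bias"]),
                 logLik = sum(counts * eta) - sum(delta * exp(pmin(eta, 40))),
                 objective = obj, objective_trace = trace,
                 converged = converged, iterations = it,
                 gradient_norm = gnorm, delta = delta),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %s + bias | xi = %.4g | logLik = %.2f | %d iter\n",
              if (length(x$variables)) paste(x$variables, collapse = " + ")
              else "(bias only)",
              x$xi, x$logLik, x$iterations))
  invisible(x)
}

#' Predicted firing rate of a fitted model
#'
#' `lambda_t = exp(sum_i (k_i (*) x_i)_t)`, evaluated through the design
#' matrix: `exp(X w)`, in Hz.
#'
#' @param fit a `glm_fit` (or ground-truth model coerced via weights).
#' @param design a design matrix containing the fit's columns.
#' @return strictly positive numeric rate series (Hz).
#' @export
predict_rate <- function(fit, design) {
  stopifnot(inherits(fit, "glm_fit"), inherits(design, "design_matrix"))
  cols <- design_columns(design, fit$variables)
  X <- design$X[, cols, drop = FALSE]
  if (!identical(colnames(X), names(fit$weights))) {
    stop("design does not match the fitted model's variable set", call. = FALSE)
  }
  as.numeric(exp(X %*% fit$weights))
}

#' Select the ridge strength by Laplace-approximated evidence
#'
#' For each candidate `xi` the model is refit on all trials and the marginal
#' likelihood is approximated as `L(k_MAP) + (P/2) log(2 xi) - (1/2) log det
#' (-Hessian)`, where P counts the penalized weights and the Hessian is that
#' of the log-posterior at the mode.
#'
#' @param design,counts as in [fit_map()].
#' @param xi_grid candidate grid (default 13 log-spaced points, 1e-2..1e4).
#' @param variables included variables.
#' @return list with `xi` (the maximizer), `evidence` (data frame of the grid
#'   and log-evidence values) and `fit` (the MAP fit at the selected `xi`).
#' @export
select_ridge_by_evidence <- function(design, counts,
                                     xi_grid = 10^seq(-2, 4, length.out = 13),
                                     variables = NULL) {
  if (!length(xi_grid)) stop("empty xi grid", call. = FALSE)
  if (is.null(variables)) variables <- names(design$variables)
  xi_grid <- sort(xi_grid, decreasing = TRUE)  # start strongly smoothed
  ev <- numeric(length(xi_grid))
  fits <- vector("list", length(xi_grid))
  w_warm <- NULL
  for (i in seq_along(xi_grid)) {
    xi <- xi_grid[i]
    fit <- fit_map(design, counts, xi, variables, w_init = w_warm)
    w_warm <- fit$weights
    cols <- design_columns(design, variables)
    X <- design$X[, cols, drop = FALSE]
    pen <- colnames(X) != "bias"
    mu <- design$delta * exp(pmin(as.numeric(X %*% fit$weights), 40))
    logdet <- weighted_hessian_logdet_cpp(X, mu,
                                          2 * xi * as.numeric(pen) + 1e-9)
    if (!is.finite(logdet)) {
      stop("singular Hessian in evidence computation: raise the xi grid floor",
           call. = FALSE)
    }
    ev[i] <- fit$objective + 0.5 * sum(pen) * log(2 * xi) - 0.5 * logdet
    fits[[i]] <- fit
  }
  best <- which.max(ev)
  list(xi = xi_grid[best],
       evidence = data.frame(xi = xi_grid, log_evidence = ev)[order(xi_grid), ],
       fit = fits[[best]])
}

#' Assign trials to cross-validation folds
#'
#' Seeded uniform random partition of trials into folds of (near-)equal size;
#' trials are never split across folds.
#'
#' @param trials vector of trial ids.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return named integer vector: fold of each trial.
#' @export
make_cv_folds <- function(trials, n_folds = 10, seed = 1L) {
  trials <- unique(trials)
  if (length(trials) < n_folds) {
    stop(sprintf("need at least %d trials for %d folds", n_folds, n_folds),
         call. = FALSE)
  }
  with_seed(seed, {
    perm <- sample(trials)
    fold <- rep(seq_len(n_folds), length.out = length(trials))
    stats::setNames(fold[match(trials, perm)], trials)
  })
}

#' Cross-validated model performance
#'
#' 10-fold cross-validation by trial: the model is refit excluding each fold
#' and the held-out log-likelihood is normalized by the number of spikes in
#' the fold (folds with zero spikes are flagged and normalized by 1).
#'
#' @param design,counts,xi,variables as in [fit_map()].
#' @param folds trial-to-fold assignment from [make_cv_folds()]; built from
#'   `seed` if missing.
#' @param n_folds,seed used when `folds` is missing.
#' @param warm_fit optional all-trials `glm_fit` used to warm-start each fold.
#' @return an object of class `cv_performance`: `fold_ll`
#'   (spike-normalized held-out log-likelihood per fold), `fold_spikes`,
#'   `flagged` (zero-spike folds), `folds`.
#' @export
crossvalidated_performance <- function(design, counts, xi, variables = NULL,
                                       folds = NULL, n_folds = 10, seed = 1L,
                                       warm_fit = NULL) {
  if (is.null(variables)) variables <- names(design$variables)
  if (is.null(folds)) folds <- make_cv_folds(design$bin_trial, n_folds, seed)
  n_folds <- max(folds)
  if (is.null(warm_fit)) {
    warm_fit <- fit_map(design, counts, xi, variables)
  }
  bin_fold <- folds[as.character(design$bin_trial)]
  fold_ll <- numeric(n_folds)
  fold_spikes <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    train <- which(bin_fold != f)
    test <- which(bin_fold == f)
    fit <- fit_map(design, counts, xi, variables, w_init = warm_fit$weights,
                   rows = train)
    cols <- design_columns(design, variables)
    eta <- as.numeric(design$X[test, cols, drop = FALSE] %*% fit$weights)
    ll <- sum(counts[test] * (eta + log(design$delta))) -
      sum(design$delta * exp(pmin(eta, 40)))
    fold_spikes[f] <- sum(counts[test])
    fold_ll[f] <- ll / max(1L, fold_spikes[f])
  }
  structure(list(fold_ll = fold_ll, fold_spikes = fold_spikes,
                 flagged = which(fold_spikes == 0L), folds = folds,
                 variables = variables, xi = xi),
            class = "cv_performance")
}

# one-sided paired signed-rank test that 'a' improves on 'b'
signed_rank_p <- function(a, b) {
  if (all(a == b)) return(1)
  p <- tryCatch(
    suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                         exact = TRUE)$p.value),
    error = function(e) NA_real_)
  if (!is.finite(p)) 1 else p
}

n_basis_columns <- function(design, variables) {
  length(design_columns(design, variables)) - 1L
}

#' Forward-search model selection
#'
#' Greedy growth of the variable set: the best single-variable model (by mean
#' spike-normalized held-out log-likelihood across 10 folds) is accepted only
#' if it beats the constant-mean-rate (bias-only) model under a one-sided
#' paired signed-rank test at `alpha`; larger models are accepted while the
#' best extension significantly beats the current model. Neurons whose best
#' model never beats the bias-only model are labelled not modulated (zero
#' variables). Ties in mean fold performance are broken towards the candidate
#' with fewer basis coefficients.
#'
#' @param design,counts as in [fit_map()].
#' @param xi ridge strength; if `NULL`, selected once by
#'   [select_ridge_by_evidence()] on the full candidate model.
#' @param candidates candidate variables (default: all in the design).
#' @param alpha signed-rank significance level.
#' @param n_folds,seed cross-validation controls (one fixed partition is used
#'   for every model so fold performances are paired).
#' @param xi_grid grid passed to the evidence selection when `xi` is `NULL`.
#' @return a `glm_fit` on all trials with the selected variables (or the
#'   bias-only fit), with a `selection` element recording the search path,
#'   p-values, fold table and `xi`.
#' @export
forward_model_selection <- function(design, counts, xi = NULL,
                                    candidates = NULL, alpha = 0.05,
                                    n_folds = 10, seed = 1L,
                                    xi_grid = 10^seq(-2, 4, length.out = 13)) {
  if (is.null(candidates)) candidates <- names(design$variables)
  if (is.null(xi)) {
    xi <- select_ridge_by_evidence(design, counts, xi_grid, candidates)$xi
  }
  folds <- make_cv_folds(design$bin_trial, n_folds, seed)
  base_cv <- crossvalidated_performance(design, counts, xi, character(0),
                                        folds = folds)
  current <- character(0)
  current_perf <- base_cv$fold_ll
  current_fit <- NULL
  path <- list()
  repeat {
    remaining <- setdiff(candidates, current)
    if (!length(remaining)) break
    perfs <- vector("list", length(remaining))
    fits <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      vars <- c(current, remaining[i])
      warm <- fit_map(design, counts, xi, vars,
                      w_init = if (!is.null(current_fit)) current_fit$weights)
      fits[[i]] <- warm
      perfs[[i]] <- crossvalidated_performance(design, counts, xi, vars,
                                               folds = folds,
                                               warm_fit = warm)$fold_ll
    }
    means <- vapply(perfs, mean, numeric(1))
    sizes <- vapply(remaining, function(v)
      n_basis_columns(design, c(current, v)), integer(1))
    best <- order(-means, sizes)[1]
    p <- signed_rank_p(perfs[[best]], current_perf)
    path[[length(path) + 1L]] <- data.frame(
      step = length(current) + 1L, candidate = remaining[best],
      mean_ll = means[best], p_value = p, accepted = is.finite(p) && p < alpha)
    if (!is.finite(p) || p >= alpha) break
    current <- c(current, remaining[best])
    current_perf <- perfs[[best]]
    current_fit <- fits[[best]]
  }
  fit <- fit_map(design, counts, xi, current,
                 w_init = if (!is.null(current_fit)) current_fit$weights)
  fit$selection <- list(path = do.call(rbind, path), xi = xi, folds = folds,
                        baseline_fold_ll = base_cv$fold_ll,
                        selected_fold_ll = current_perf)
  fit
}

#' Check the exponential nonlinearity of a fitted model
#'
#' Bins the kernel output (the linear predictor) across recorded bins and
#' compares the observed spike rate in each bin with the exponential
#' prediction at the bin centre.
#'
#' @param fit a `glm_fit`.
#' @param design,counts the data the model was fit to.
#' @param n_bins number of equal-width kernel-output bins (>= 2).
#' @return data frame with `centre`, `n` (time bins), `observed_rate`,
#'   `predicted_rate` (Hz), plus a `"correlation"` attribute (Pearson r
#'   between observed and predicted rates over occupied bins).
#' @export
validate_exponential_nonlinearity <- function(fit, design, counts, n_bins = 20) {
  if (n_bins < 2) stop("'n_bins' must be >= 2", call. = FALSE)
  cols <- design_columns(design, fit$variables)
  eta <- as.numeric(design$X[, cols, drop = FALSE] %*% fit$weights)
  rng <- range(eta)
  if (diff(rng) == 0) {
    out <- data.frame(centre = rng[1], n = length(eta),
                      observed_rate = sum(counts) / (length(eta) * design$delta),
                      predicted_rate = exp(rng[1]))
    attr(out, "correlation") <- NA_real_
    return(out)
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(n_bins, findInterval(eta, edges, rightmost.closed = TRUE))
  n <- tabulate(idx, n_bins)
  obs <- vapply(seq_len(n_bins), function(b) {
    if (n[b] == 0) return(NA_real_)
    sum(counts[idx == b]) / (n[b] * design$delta)
  }, numeric(1))
  centre <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  out <- data.frame(centre = centre, n = n, observed_rate = obs,
                    predicted_rate = exp(centre))
  occ <- n > 0 & !is.na(obs)
  attr(out, "correlation") <-
    if (sum(occ) > 2) stats::cor(obs[occ], exp(centre[occ])) else NA_real_
  out
}

#' Wrap a ground-truth model as a fitted-model object
#'
#' Builds a `glm_fit` whose weights are a ground-truth model's coefficients,
#' so simulation studies can run decoding and ablation on models with known
#' kernels without a fitting step.
#'
#' @param model a `ground_truth_model`.
#' @param design the design the model's kernels refer to.
#' @return a `glm_fit`.
#' @export
as_glm_fit <- function(model, design) {
  variables <- model$variables
  cols <- design_columns(design, variables)
  w <- design_weight_vector(design, model)[cols]
  kernels <- list()
  for (v in variables) {
    for (kn in design$variables[[v]]$kernels) {
      kernels[[kn]] <- basis_kernel(design$kernels[[kn]]$basis,
                                    model$coefficients[[kn]])
    }
  }
  structure(list(weights = w, variables = variables, xi = 0,
                 coefficients = model$coefficients[names(kernels)],
                 kernels = kernels, bias = model$bias,
                 logLik = NA_real_, objective = NA_real_,
                 objective_trace = numeric(0), converged = TRUE,
                 iterations = 0L, gradient_norm = 0, delta = design$delta),
            class = "glm_fit")
}

#' Correlation between true and estimated kernels
#'
#' Concatenates the kernel curves of the union of a ground-truth model's and
#' a fit's variables (absent kernels contribute zeros) and returns the
#' Pearson correlation, the headline recovery statistic of the
#' simulation-based validation.
#'
#' @param truth a `ground_truth_model`.
#' @param fit a `glm_fit`.
#' @param design the design both refer to.
#' @return Pearson correlation between concatenated kernels.
#' @export
kernel_recovery_correlation <- function(truth, fit, design) {
  kns <- union(names(truth$kernels), names(fit$kernels))
  tv <- unlist(lapply(kns, function(kn) {
    if (!is.null(truth$kernels[[kn]])) truth$kernels[[kn]]
    else numeric(length(design$kernels[[kn]]$basis$grid))
  }))
  fv <- unlist(lapply(kns, function(kn) {
    if (!is.null(fit$kernels[[kn]])) fit$kernels[[kn]]
    else numeric(length(design$kernels[[kn]]$basis$grid))
  }))
  stats::cor(tv, fv)
}
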