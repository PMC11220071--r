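#' Counterfactual designs for binary category decoding
#'
#' Builds the pair of design matrices that differ only in the decoded
#' variable's category: for odour decoding, every trial is relabelled as
#' carrying the rewarded odour (design A) or the unrewarded odour (design B),
#' which switches the odour-inhalation and odour-modulation kernels; for
#' context decoding the context label switches the position-tuning kernels
#' and the rewarded-context gating; for reward decoding, design A places
#' consumption events at the licks following the response event and design B
#' has none. All other regressors are identical.
#'
#' @param bundle a `session_bundle`.
#' @param variable `"odour"`, `"context"` or `"reward"`.
#' @param specs optional precomputed [variable_specs()] shared with the fits.
#' @return list with designs `A`, `B` and the per-trial true `labels`
#'   (`"A"`/`"B"`).
#' @export
decoding_designs <- function(bundle, variable = c("odour", "context", "reward"),
                             specs = NULL) {
  variable <- match.arg(variable)
  if (is.null(specs)) specs <- variable_specs(bundle)
  bA <- bundle
  bB <- bundle
  if (variable == "odour") {
    bA$events$odour[] <- "R"
    bB$events$odour[] <- "U"
    labels <- ifelse(bundle$events$odour == "R", "A", "B")
  } else if (variable == "context") {
    bA$events$context[] <- "R"
    bB$events$context[] <- "U"
    labels <- ifelse(bundle$events$context == "R", "A", "B")
  } else {
    bA$events$outcome[] <- "HIT"
    bA$events$t_reward <- ifelse(
      is.na(bundle$events$t_first_lick_after_odour),
      NA_real_, bundle$events$t_first_lick_after_odour)
    bB$events$outcome[] <- "CR"
    bB$events$t_reward[] <- NA_real_
    labels <- ifelse(bundle$events$outcome == "HIT", "A", "B")
  }
  list(A = assemble_design_matrix(bA, specs = specs),
       B = assemble_design_matrix(bB, specs = specs),
       labels = labels)
}

#' Cumulative log-likelihood-ratio time course
#'
#' For each trial, the running log-likelihood ratio of the observed spikes
#' under the category-A versus category-B rate model, accumulated from trial
#' start: positive values indicate the neuron's spikes are more probable
#' under A. Population LLRs are the sum of single-neuron LLRs.
#'
#' @param fit a `glm_fit`.
#' @param design_A,design_B designs from [decoding_designs()].
#' @param counts the neuron's observed per-bin counts.
#' @return data frame with `trial`, `time` (global bin time) and `llr`
#'   (cumulative within trial).
#' @export
llr_timecourse <- function(fit, design_A, design_B, counts) {
  cols <- design_columns(design_A, fit$variables)
  etaA <- as.numeric(design_A$X[, cols, drop = FALSE] %*% fit$weights)
  etaB <- as.numeric(design_B$X[, cols, drop = FALSE] %*% fit$weights)
  delta <- design_A$delta
  per_bin <- counts * (etaA - etaB) -
    delta * (exp(pmin(etaA, 40)) - exp(pmin(etaB, 40)))
  llr <- stats::ave(per_bin, design_A$bin_trial, FUN = cumsum)
  data.frame(trial = design_A$bin_trial, time = design_A$bin_time, llr = llr)
}

#' Posterior probability of category A
#'
#' Equal-prior Bayes posterior `p(A | spikes) = L_A / (L_A + L_B)`, computed
#' in log space as the logistic transform of the LLR so it never over- or
#' underflows; `p(A) + p(B) = 1` by construction.
#'
#' @param llr log-likelihood ratio(s).
#' @return posterior probabilities in `[0, 1]`.
#' @export
posterior_probability <- function(llr) {
  stats::plogis(llr)
}

# cumulative LLR per trial at (event-aligned) evaluation times
llr_at_time <- function(llr_df, events, align_col = "t_first_odour_inhalation",
                        offset = 0.5) {
  vapply(seq_len(nrow(events)), function(i) {
    tt <- events[[align_col]][i] + offset
    rows <- which(llr_df$trial == events$trial[i] & llr_df$time <= tt)
    if (!length(rows)) 0 else llr_df$llr[rows[length(rows)]]
  }, numeric(1))
}

#' Population decoding of a binary task variable by GLM likelihood ratio
#'
#' Computes per-neuron, per-trial cumulative LLRs at evaluation times aligned
#' to the first odour inhalation, matches trial counts across the two
#' categories by seeded down-sampling, and reports decoding accuracy (sign of
#' the summed population LLR, ties scored 0.5) as a function of time and of
#' population size. Pseudopopulations are sampled without replacement within
#' each of `n_repeats` repeats and accuracies averaged; a label-shuffled
#' control is reported alongside.
#'
#' @param fits list of `glm_fit`s, one per unit.
#' @param counts_matrix matrix of per-bin counts, one column per unit, rows
#'   aligned with the designs.
#' @param bundle the session the fits refer to.
#' @param variable decoded variable, see [decoding_designs()].
#' @param designs optionally precomputed [decoding_designs()].
#' @param t_eval evaluation time (s after first odour inhalation) for the
#'   size curve.
#' @param time_grid offsets (s) for the accuracy-versus-time curve.
#' @param pop_sizes population sizes (default: 1, 2, 4, ... up to all units).
#' @param n_repeats pseudopopulation/matching repeats.
#' @param seed integer seed.
#' @return an object of class `decode_result` with `accuracy_by_time`,
#'   `accuracy_by_size`, `shuffle_by_size`, `llr` (units x trials at
#'   `t_eval`), `labels` and the matching bookkeeping.
#' @export
population_decode <- function(fits, counts_matrix, bundle,
                              variable = c("odour", "context", "reward"),
                              designs = NULL,
                              t_eval = 0.5,
                              time_grid = seq(-0.5, 1.5, by = 0.25),
                              pop_sizes = NULL, n_repeats = 50, seed = 1L) {
  variable <- match.arg(variable)
  n_units <- length(fits)
  if (is.null(designs)) designs <- decoding_designs(bundle, variable)
  labels <- designs$labels
  if (min(table(labels)) < 2) {
    stop("need at least 2 trials per category after matching", call. = FALSE)
  }
  if (is.null(pop_sizes)) {
    pop_sizes <- unique(pmin(n_units, c(2^(0:20))))
    pop_sizes <- pop_sizes[pop_sizes <= n_units]
  }
  if (max(pop_sizes) > n_units) {
    stop("population size exceeds available neurons", call. = FALSE)
  }
  ev <- bundle$events
  offsets <- sort(unique(c(time_grid, t_eval)))
  # units x trials x offsets cumulative LLR
  llr_arr <- array(0, c(n_units, nrow(ev), length(offsets)))
  for (u in seq_len(n_units)) {
    tc <- llr_timecourse(fits[[u]], designs$A, designs$B, counts_matrix[, u])
    for (k in seq_along(offsets)) {
      llr_arr[u, , k] <- llr_at_time(tc, ev, offset = offsets[k])
    }
  }
  k_eval <- match(t_eval, offsets)
  acc <- function(total_llr, labs) {
    dec <- ifelse(total_llr > 0, "A", ifelse(total_llr < 0, "B", "tie"))
    mean(ifelse(dec == "tie", 0.5, dec == labs))
  }
  with_seed(seed, {
    idx_A <- which(labels == "A")
    idx_B <- which(labels == "B")
    n_match <- min(length(idx_A), length(idx_B))
    by_size <- matrix(NA_real_, length(pop_sizes), n_repeats)
    sh_size <- matrix(NA_real_, length(pop_sizes), n_repeats)
    by_time <- matrix(NA_real_, length(offsets), n_repeats)
    for (r in seq_len(n_repeats)) {
      trials <- c(sample(idx_A, n_match), sample(idx_B, n_match))
      labs <- labels[trials]
      for (si in seq_along(pop_sizes)) {
        units <- sample.int(n_units, pop_sizes[si])
        tot <- colSums(llr_arr[units, trials, k_eval, drop = FALSE])
        by_size[si, r] <- acc(as.numeric(tot), labs)
        sh_size[si, r] <- acc(as.numeric(tot), sample(labs))
      }
      for (k in seq_along(offsets)) {
        tot <- colSums(llr_arr[, trials, k, drop = FALSE])
        by_time[k, r] <- acc(as.numeric(tot), labs)
      }
    }
    structure(list(
      accuracy_by_time = data.frame(offset = offsets,
                                    accuracy = rowMeans(by_time)),
      accuracy_by_size = data.frame(size = pop_sizes,
                                    accuracy = rowMeans(by_size)),
      shuffle_by_size = data.frame(size = pop_sizes,
                                   accuracy = rowMeans(sh_size)),
      llr = llr_arr[, , k_eval, drop = TRUE], labels = labels,
      t_eval = t_eval, n_matched = n_match, n_repeats = n_repeats),
      class = "decode_result")
  })
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("<decode_result> %d matched trials/category, t_eval = %g s\n",
              x$n_matched, x$t_eval))
  print(x$accuracy_by_size)
  invisible(x)
}

#' Remove non-kept kernel contributions from fitted models
#'
#' Zeroes the weights of every variable outside `keep` (the bias is always
#' retained), yielding e.g. "only odour" rate models whose rate equals
#' `exp(bias + kept blocks x weights)` exactly. Neurons with no kept
#' variables pass through unchanged and are flagged.
#'
#' @param fits list of `glm_fit`s.
#' @param keep character vector of variables to keep (nonempty).
#' @return list of modified fits; each carries an `ablated` element listing
#'   the zeroed variables, and `untouched = TRUE` where nothing was kept.
#' @export
ablate_kernels <- function(fits, keep) {
  if (!length(keep)) stop("'keep' must be nonempty", call. = FALSE)
  lapply(fits, function(fit) {
    kept <- intersect(fit$variables, keep)
    if (!length(kept)) {
      fit$untouched <- TRUE
      return(fit)
    }
    drop_vars <- setdiff(fit$variables, keep)
    for (v in drop_vars) {
      for (kn in names(fit$kernels)) {
        idx <- grep(paste0("^", kn, "\\."), names(fit$weights))
        if (length(idx) && kn %in% kernel_names_of(fit, v)) {
          fit$weights[idx] <- 0
          fit$coefficients[[kn]][] <- 0
          fit$kernels[[kn]][] <- 0
        }
      }
    }
    fit$ablated <- drop_vars
    fit
  })
}

# kernels belonging to a variable, from the fit's bookkeeping
kernel_names_of <- function(fit, variable) {
  kns <- names(fit$coefficients)
  pair <- list(Odour = c("O_R", "O_U"), modOdour = c("modO_R", "modO_U"),
               Context = c("C_R", "C_U"))
  if (variable %in% names(pair)) intersect(kns, pair[[variable]])
  else intersect(kns, variable)
}

#' Linear-classifier decoding of odour identity
#'
#' L2-regularized logistic regression with 3-fold cross-validation on
#' trial-by-neuron response matrices (responses averaged over a 0.5-s window
#' after first odour inhalation by the caller). Trials per class are
#' equalized by seeded down-sampling, pseudopopulations of each size are
#' drawn `n_repeats` times and accuracies averaged; a label-shuffled control
#' is reported.
#'
#' @param responses trials x neurons numeric matrix.
#' @param labels binary trial labels (factor or character).
#' @param pop_sizes population sizes (default: doubling up to all neurons).
#' @param n_repeats pseudopopulation repeats.
#' @param n_folds cross-validation folds.
#' @param lambda ridge penalty passed to glmnet.
#' @param seed integer seed.
#' @return data frame with `size`, `accuracy`, `shuffle_accuracy`.
#' @export
linear_classifier_decode <- function(responses, labels, pop_sizes = NULL,
                                     n_repeats = 50, n_folds = 3,
                                     lambda = 1e-4, seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("need exactly 2 classes", call. = FALSE)
  if (min(table(labels)) < n_folds) {
    stop(sprintf("a class has fewer than %d trials: cannot %d-fold cross-validate",
                 n_folds, n_folds), call. = FALSE)
  }
  n_neurons <- ncol(responses)
  if (is.null(pop_sizes)) {
    pop_sizes <- unique(pmin(n_neurons, 2^(0:20)))
    pop_sizes <- pop_sizes[pop_sizes <= n_neurons]
  }
  cv_accuracy <- function(x, y) {
    if (ncol(x) == 1L) x <- cbind(x, 0)   # glmnet needs >= 2 columns
    folds <- integer(length(y))
    for (cl in classes) {
      idx <- which(y == cl)
      folds[idx] <- rep(seq_len(n_folds), length.out = length(idx))[
        sample.int(length(idx))]
    }
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], factor(y[tr], classes),
                            family = "binomial", alpha = 0,
                            lambda = lambda, standardize = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE], type = "class")
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }
  with_seed(seed, {
    n_match <- min(table(labels))
    out <- matrix(NA_real_, length(pop_sizes), n_repeats)
    sh <- matrix(NA_real_, length(pop_sizes), n_repeats)
    for (r in seq_len(n_repeats)) {
      trials <- unlist(lapply(classes, function(cl) {
        sample(which(labels == cl), n_match)
      }))
      y <- labels[trials]
      for (si in seq_along(pop_sizes)) {
        units <- sample.int(n_neurons, pop_sizes[si])
        x <- responses[trials, units, drop = FALSE]
        out[si, r] <- cv_accuracy(x, y)
        sh[si, r] <- cv_accuracy(x, sample(y))
      }
    }
    data.frame(size = pop_sizes, accuracy = rowMeans(out),
               shuffle_accuracy = rowMeans(sh))
  })
}

#' Window-averaged responses for linear decoding
#'
#' Per-trial spike counts of each unit in a window after the first odour
#' inhalation, expressed as rates.
#'
#' @param bundle a `session_bundle` with spikes attached.
#' @param units unit ids (default: all).
#' @param window window after first odour inhalation (s).
#' @return trials x units rate matrix.
#' @export
odour_window_responses <- function(bundle, units = NULL, window = 0.5) {
  if (is.null(units)) units <- sort(unique(bundle$spikes$unit))
  ev <- bundle$events
  out <- matrix(0, nrow(ev), length(units),
                dimnames = list(NULL, as.character(units)))
  for (j in seq_along(units)) {
    st <- bundle$spikes$time[bundle$spikes$unit == units[j]]
    for (i in seq_len(nrow(ev))) {
      t0 <- ev$t_first_odour_inhalation[i]
      out[i, j] <- sum(st >= t0 & st < t0 + window) / window
    }
  }
  out
}

#' Behavioural response delays of a session
#'
#' The per-trial delay of the behavioural response relative to the first
#' odour inhalation: the reaction time to the first lick in GO trials, and
#' the delay to leave the context zone in NO-GO trials.
#'
#' @param events the `events` table of a `session_bundle`.
#' @return numeric vector of delays (s), one per trial.
#' @export
response_delays <- function(events) {
  ifelse(events$go,
         events$t_first_lick_after_odour - events$t_first_odour_inhalation,
         events$t_context_exit - events$t_first_odour_inhalation)
}

#' Regression of behavioural response delay on decoding posteriors
#'
#' Multiple linear regression of the per-trial response delay against
#' `p(O_R | spikes)`, `p(C_R | spikes)` and their interaction, with an F-test
#' of the interaction term (full model versus the model without it) and the
#' Pearson correlation of the delay with the interaction product.
#'
#' @param delay behavioural response delays (s).
#' @param p_or,p_cr per-trial posterior probabilities.
#' @return list with `coefficients`, `F_interaction`, `p_interaction`,
#'   `r_squared`, `pearson_r`, `pearson_p` and the fitted `model`.
#' @export
delay_regression <- function(delay, p_or, p_cr) {
  if (length(delay) < 10) stop("need at least 10 trials", call. = FALSE)
  stop_if_not_finite(c(delay, p_or, p_cr), "predictors")
  df <- data.frame(delay = delay, p_or = p_or, p_cr = p_cr)
  full <- stats::lm(delay ~ p_or + p_cr + p_or:p_cr, data = df)
  if (full$rank < 4) stop("rank-deficient predictor matrix", call. = FALSE)
  reduced <- stats::lm(delay ~ p_or + p_cr, data = df)
  an <- stats::anova(reduced, full)
  ct <- stats::cor.test(delay, p_or * p_cr)
  list(coefficients = stats::coef(full),
       F_interaction = an$F[2], p_interaction = an$`Pr(>F)`[2],
       r_squared = summary(full)$r.squared,
       pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
       model = full)
}
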