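#' Contribution of one variable to an encoding model
#'
#' The spike-normalized log-likelihood increase, in bits per spike, of the
#' selected model over the same model refit without the variable, restricted
#' to the time bins where the variable's kernels contributed to the rate:
#' `[LL(full) - LL(reduced)] / (log(2) (1 + sum of counts in the mask))`.
#' The `+1` in the normalizer guards the case of no spikes in the mask.
#'
#' @param fit_full the selected model fit.
#' @param fit_reduced the model refit with exactly one variable removed.
#' @param design,counts the data both models were fit to.
#' @return contribution in bits per spike (0, with a warning, when the
#'   variable's mask is empty).
#' @export
variable_contribution <- function(fit_full, fit_reduced, design, counts) {
  removed <- setdiff(fit_full$variables, fit_reduced$variables)
  if (length(removed) != 1L) {
    stop("'fit_reduced' must drop exactly one of 'fit_full''s variables",
         call. = FALSE)
  }
  mask <- design$variables[[removed]]$mask
  if (!length(mask)) {
    warning(sprintf("variable '%s' has an empty mask; contribution 0", removed))
    return(0)
  }
  lam_f <- predict_rate(fit_full, design)[mask]
  lam_r <- predict_rate(fit_reduced, design)[mask]
  r <- counts[mask]
  ll_f <- poisson_log_likelihood(r, lam_f, design$delta)
  ll_r <- poisson_log_likelihood(r, lam_r, design$delta)
  (ll_f - ll_r) / (log(2) * (1 + sum(r)))
}

#' Relative contributions
#'
#' Each variable's contribution divided by the sum over all variables.
#' Negative raw contributions are preserved in the profile, but a
#' non-positive total is refused (relative values would leave `[0, 1]`).
#'
#' @param contributions named numeric vector of per-variable contributions.
#' @return named fractions summing to 1.
#' @export
relative_contributions <- function(contributions) {
  if (!length(contributions)) stop("no included variables", call. = FALSE)
  s <- sum(contributions)
  if (s == 0) stop("contributions sum to zero", call. = FALSE)
  if (s < 0) {
    stop("contributions sum is negative (weak model flagged); relative values undefined",
         call. = FALSE)
  }
  contributions / s
}

#' Contribution profile of a fitted neuron
#'
#' Refits the selected model once per included variable with that variable
#' removed (paired kernels are removed together) and assembles absolute
#' contributions, relative contributions and per-kernel gain amplitudes.
#'
#' @param fit a `glm_fit` with at least one variable.
#' @param design,counts the fitted data.
#' @return an object of class `contribution_profile` with `contributions`,
#'   `relative` (both named by variable) and `gain_amplitude` (named by
#'   kernel).
#' @export
contribution_profile <- function(fit, design, counts) {
  if (!length(fit$variables)) {
    stop("fit has no included variables", call. = FALSE)
  }
  contr <- vapply(fit$variables, function(v) {
    reduced <- fit_map(design, counts, fit$xi, setdiff(fit$variables, v),
                       w_init = fit$weights)
    variable_contribution(fit, reduced, design, counts)
  }, numeric(1))
  gains <- vapply(names(fit$kernels), function(kn) {
    kernel_gain(fit, kn)$amplitude
  }, numeric(1))
  structure(list(contributions = contr,
                 relative = relative_contributions(contr),
                 gain_amplitude = gains),
            class = "contribution_profile")
}

#' @export
print.contribution_profile <- function(x, ...) {
  cat("<contribution_profile>\n")
  print(round(rbind(bits_per_spike = x$contributions,
                    relative = x$relative), 4))
  invisible(x)
}

#' Multiplicative gain of a kernel
#'
#' `gain(t) = exp(k(t))`; the amplitude is the largest absolute deviation of
#' the gain from 1 over the kernel support.
#'
#' @param fit a `glm_fit`.
#' @param kernel kernel name present in the fit.
#' @return list with `gain` (curve on the basis grid) and `amplitude`.
#' @export
kernel_gain <- function(fit, kernel) {
  k <- fit$kernels[[kernel]]
  if (is.null(k)) {
    stop(sprintf("kernel '%s' not in fit", kernel), call. = FALSE)
  }
  g <- exp(k)
  list(gain = g, amplitude = max(abs(g - 1)))
}

#' Relative-contribution matrix for a set of fitted neurons
#'
#' Convenience wrapper assembling the clustering feature matrix: one row per
#' neuron, one column per model variable, zero for variables outside a
#' neuron's selected model.
#'
#' @param profiles list of `contribution_profile`s.
#' @param variables column order (default: union of all profiles).
#' @return numeric matrix (neurons x variables).
#' @export
relative_contribution_matrix <- function(profiles, variables = NULL) {
  if (is.null(variables)) {
    variables <- unique(unlist(lapply(profiles, function(p) names(p$relative))))
  }
  out <- matrix(0, length(profiles), length(variables),
                dimnames = list(names(profiles), variables))
  for (i in seq_along(profiles)) {
    rel <- profiles[[i]]$relative
    out[i, names(rel)] <- rel
  }
  out
}
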