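gaussian_smooth <- function(x, sigma, dt, padding = c("reflect", "zero")) {
  padding <- match.arg(padding)
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern)
  n <- length(x)
  padded <- if (padding == "reflect") {
    c(x[pmin(n, half:1)], x, x[pmax(1, n - (1:half) + 1L)])
  } else {
    c(numeric(half), x, numeric(half))
  }
  as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(n)]
}

#' Event-aligned peri-stimulus time histogram
#'
#' Trial-averaged firing rate around a set of alignment events, temporally
#' smoothed with a Gaussian filter (default s.d. 30 ms, reflection padding at
#' the window edges). The integral of the PSTH over the window approximates
#' the mean number of spikes per trial in the window.
#'
#' @param spike_times spike times (s).
#' @param event_times alignment event times (s), one per trial.
#' @param window time window around the event (s).
#' @param sigma Gaussian smoothing s.d. (s).
#' @param dt output sampling step (s).
#' @param padding edge padding mode for the smoother.
#' @return data frame with `time` (relative to the event, bin centres) and
#'   `rate` (Hz). An empty spike train yields a zero PSTH.
#' @export
event_psth <- function(spike_times, event_times, window = c(-1, 2),
                       sigma = 0.03, dt = 0.01,
                       padding = c("reflect", "zero")) {
  if (!length(event_times)) stop("need at least one event", call. = FALSE)
  edges <- seq(window[1], window[2], by = dt)
  n_bins <- length(edges) - 1L
  counts <- numeric(n_bins)
  for (et in event_times) {
    rel <- spike_times - et
    rel <- rel[rel >= window[1] & rel < window[1] + n_bins * dt]
    if (length(rel)) {
      counts <- counts + tabulate(floor((rel - window[1]) / dt) + 1L, n_bins)
    }
  }
  rate <- counts / (length(event_times) * dt)
  data.frame(time = edges[-length(edges)] + dt / 2,
             rate = gaussian_smooth(rate, sigma, dt, match.arg(padding)))
}

#' Stitch event PSTHs into a full-trial PSTH
#'
#' Each event PSTH (e.g. context entry `C`, first odour inhalation `O`,
#' animal response `L`, trial outcome `R`) is shifted to its median event
#' time relative to the first odour inhalation; where shifted segments
#' overlap, the stitched series is their pointwise mean. Disjoint segments
#' (temporal gaps) are an error listing the gap intervals.
#'
#' @param psths named list of event PSTHs from [event_psth()].
#' @param align_times numeric vector (same names/order) of alignment times
#'   (s) relative to the reference event.
#' @param dt output step (s).
#' @return data frame with `time` and `rate`.
#' @export
stitch_trial_psth <- function(psths, align_times, dt = 0.01) {
  stopifnot(length(psths) == length(align_times))
  segs <- lapply(seq_along(psths), function(i) {
    data.frame(time = psths[[i]]$time + align_times[i], rate = psths[[i]]$rate)
  })
  lo <- min(vapply(segs, function(s) min(s$time), numeric(1)))
  hi <- max(vapply(segs, function(s) max(s$time), numeric(1)))
  grid <- seq(lo, hi, by = dt)
  vals <- matrix(NA_real_, length(grid), length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    inside <- grid >= min(s$time) - dt / 2 & grid <= max(s$time) + dt / 2
    vals[inside, i] <- stats::approx(s$time, s$rate, xout = grid[inside],
                                     rule = 2)$y
  }
  covered <- rowSums(!is.na(vals)) > 0
  if (!all(covered)) {
    runs <- rle(covered)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    gaps <- paste(sprintf("[%.3f, %.3f]", grid[starts[!runs$values]],
                          grid[ends[!runs$values]]), collapse = ", ")
    stop("event PSTHs leave temporal gaps: ", gaps, call. = FALSE)
  }
  data.frame(time = grid, rate = rowMeans(vals, na.rm = TRUE))
}

#' Pooled condition-wise activity array
#'
#' Arranges per-trial binned firing rates in the `N x C x O x T x K` layout
#' (neurons, contexts, odours, time, trials) aligned to the first odour
#' inhalation, tracking per-condition trial counts; conditions with fewer
#' than `K` trials are padded with `NA`, never imputed.
#'
#' @param bundle a `session_bundle` with spikes attached.
#' @param units unit ids (default: all in the bundle).
#' @param window window around the first odour inhalation (s).
#' @param dt rate bin (s).
#' @param sigma optional Gaussian smoothing s.d. (s); 0 disables.
#' @return list with the array `X`, the trial average `Xbar`
#'   (`N x C x O x T`), `trial_num` (`N x C x O`), `time` and the dimension
#'   labels.
#' @export
pooled_activity_array <- function(bundle, units = NULL, window = c(-0.5, 1.5),
                                  dt = 0.05, sigma = 0) {
  if (is.null(units)) units <- sort(unique(bundle$spikes$unit))
  ev <- bundle$events
  edges <- seq(window[1], window[2], by = dt)
  Tn <- length(edges) - 1L
  contexts <- c("R", "U")
  odours <- c("R", "U")
  Kmax <- max(table(ev$context, ev$odour))
  X <- array(NA_real_, c(length(units), 2, 2, Tn, Kmax),
             dimnames = list(unit = as.character(units),
                             context = contexts, odour = odours,
                             time = NULL, trial = NULL))
  for (ci in 1:2) for (oi in 1:2) {
    rows <- which(ev$context == contexts[ci] & ev$odour == odours[oi])
    for (k in seq_along(rows)) {
      t0 <- ev$t_first_odour_inhalation[rows[k]]
      for (u in seq_along(units)) {
        st <- bundle$spikes$time[bundle$spikes$unit == units[u]] - t0
        st <- st[st >= window[1] & st < window[1] + Tn * dt]
        r <- tabulate(floor((st - window[1]) / dt) + 1L, Tn) / dt
        if (sigma > 0) r <- gaussian_smooth(r, sigma, dt)
        X[u, ci, oi, , k] <- r
      }
    }
  }
  trial_num <- apply(!is.na(X[, , , 1, , drop = FALSE]), c(1, 2, 3), sum)
  Xbar <- apply(X, 1:4, mean, na.rm = TRUE)
  list(X = X, Xbar = Xbar, trial_num = trial_num,
       time = edges[-length(edges)] + dt / 2, units = units)
}

#' Pearson similarity of population activity vectors
#'
#' Correlates population activity vectors (one per condition and time bin)
#' across all pairs; zero-variance vectors give `NA` entries with a warning.
#'
#' @param Xbar `N x C x O x T` trial-averaged array (or an `N x M` matrix
#'   whose columns are population vectors).
#' @return symmetric correlation matrix with unit diagonal where defined,
#'   with condition/time labels when an array is supplied.
#' @export
population_correlation_matrix <- function(Xbar) {
  if (is.array(Xbar) && length(dim(Xbar)) == 4L) {
    d <- dim(Xbar)
    M <- matrix(Xbar, nrow = d[1])
    lab <- as.vector(outer(outer(dimnames(Xbar)[[2]], dimnames(Xbar)[[3]],
                                 function(a, b) paste0("C", a, ":O", b)),
                           seq_len(d[4]), paste, sep = ":t"))
    colnames(M) <- lab
  } else {
    M <- as.matrix(Xbar)
  }
  if (nrow(M) < 2) stop("need at least 2 neurons", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance population vector(s); correlations set to NA")
  }
  suppressWarnings(stats::cor(M))
}

#' Principal-component trajectories of condition-averaged activity
#'
#' Centres each neuron's trial-averaged rate, applies singular value
#' decomposition to the `N x (C O T)` reshaped matrix and projects the data
#' onto the top components, returning per-condition time trajectories and the
#' explained variance per component.
#'
#' @param Xbar `N x C x O x T` array.
#' @param n_components number of components to return (default 3; fewer, with
#'   a warning, when fewer neurons are available).
#' @return list with `trajectories` (`component x C x O x T`),
#'   `explained` (fraction of variance per returned component, non-increasing),
#'   `rotation` (`N x n_components`), and `reconstruction` of the centred
#'   data from all components.
#' @export
pca_trajectories <- function(Xbar, n_components = 3) {
  d <- dim(Xbar)
  if (is.null(d) || length(d) != 4L) stop("'Xbar' must be N x C x O x T", call. = FALSE)
  M <- matrix(Xbar, nrow = d[1])
  M <- M - rowMeans(M)
  nc <- min(n_components, d[1], ncol(M))
  if (nc < n_components) {
    warning(sprintf("only %d component(s) available", nc))
  }
  sv <- svd(M)
  proj <- t(M) %*% sv$u    # scores of each population vector
  traj <- array(t(proj[, seq_len(nc), drop = FALSE]),
                c(nc, d[2], d[3], d[4]))
  list(trajectories = traj,
       explained = (sv$d^2 / sum(sv$d^2))[seq_len(nc)],
       singular_values = sv$d,
       rotation = sv$u[, seq_len(nc), drop = FALSE],
       reconstruction = array(sv$u %*% diag(sv$d, length(sv$d)) %*% t(sv$v) +
                                rowMeans(matrix(Xbar, nrow = d[1])), d))
}

#' Signal-variance decomposition of trial-averaged responses
#'
#' Splits the total variance of trial-averaged responses into residual trial
#' noise and signal: the per-neuron noise estimate is the trial-averaged
#' squared deviation of single trials from their condition mean, scaled by
#' the condition trial counts; the total residual noise sum of squares
#' rebalances neurons by their mean trial count so sequentially recorded
#' neurons with unequal trial counts pool correctly; the signal variance is
#' the total minus the noise term.
#'
#' @param X `N x C x O x T x K` array with `NA` padding for missing trials.
#' @return list with `total_variance`, `noise` (the residual noise sum of
#'   squares), `signal_variance`, `fraction` (percent of total variance that
#'   is signal) and the per-neuron noise estimates `C_n`.
#' @export
signal_variance_decomposition <- function(X) {
  d <- dim(X)
  if (length(d) != 5L) stop("'X' must be N x C x O x T x K", call. = FALSE)
  N <- d[1]
  trial_num <- apply(!is.na(X[, , , 1, , drop = FALSE]), c(1, 2, 3), sum)
  if (any(trial_num < 2)) {
    bad <- which(trial_num < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("condition (context %d, odour %d) of neuron %d has fewer than 2 trials",
                 bad[2], bad[3], bad[1]), call. = FALSE)
  }
  Xbar <- apply(X, 1:4, mean, na.rm = TRUE)
  # total variance: squared deviations of Xbar around each neuron's mean
  neuron_mean <- apply(Xbar, 1, mean)
  total <- sum((Xbar - array(neuron_mean, d[1:4]))^2)
  # per-neuron noise
  C_n <- numeric(N)
  for (n in seq_len(N)) {
    for (ci in seq_len(d[2])) for (oi in seq_len(d[3])) {
      resid <- X[n, ci, oi, , ] - Xbar[n, ci, oi, ]
      C_n[n] <- C_n[n] + sum(resid^2, na.rm = TRUE) / trial_num[n, ci, oi]
    }
  }
  # C_n sums squared residuals over trials, conditions and time, so the
  # noise term is its trial-count-rebalanced sum over neurons
  trial_num_bar <- apply(trial_num, 1, mean)
  theta <- sum(C_n / trial_num_bar)
  signal <- total - theta
  list(total_variance = total, noise = theta, signal_variance = signal,
       fraction = 100 * (1 - theta / total), C_n = C_n,
       trial_num = trial_num)
}

#' Number of components explaining the signal variance
#'
#' The smallest number of principal components of the trial-averaged,
#' row-centred data whose cumulative explained variance reaches the given
#' fraction of the total variance.
#'
#' @param Xbar `N x C x O x T` array or `N x M` matrix.
#' @param signal_fraction target percentage in `(0, 100]`.
#' @return list with `n_components` and `per_neuron`
#'   (components per recorded neuron).
#' @export
dimensionality_estimate <- function(Xbar, signal_fraction) {
  if (signal_fraction <= 0 || signal_fraction > 100) {
    stop("'signal_fraction' must be in (0, 100]", call. = FALSE)
  }
  M <- if (is.array(Xbar) && length(dim(Xbar)) == 4L) {
    matrix(Xbar, nrow = dim(Xbar)[1])
  } else as.matrix(Xbar)
  M <- M - rowMeans(M)
  ev <- svd(M)$d^2
  cum <- 100 * cumsum(ev) / sum(ev)
  n <- which(cum >= signal_fraction - 1e-9)[1]
  list(n_components = n, per_neuron = n / nrow(M))
}

#' Trial-to-trial coefficient of variation of spike counts
#'
#' @param counts neurons x trials matrix of window spike counts.
#' @return per-neuron `sd/mean` across trials; `NA` (flagged via attribute)
#'   for neurons with zero mean count.
#' @export
spikecount_cv <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least 2 trials", call. = FALSE)
  m <- rowMeans(counts)
  s <- apply(counts, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, NA_real_)
  attr(cv, "undefined") <- which(m == 0)
  cv
}
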