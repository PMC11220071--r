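TRIAL_TYPES <- c("O_R C_R", "O_R C_U", "O_U C_R", "O_U C_U")

#' Configuration for a simulated task session
#'
#' Describes one go/no-go virtual-corridor session: mice run down an
#' approaching aisle, enter a visual context zone where a 1-s odour pulse is
#' delivered at context entry, and respond by licking (GO) or running on
#' (NO-GO). Only the rewarded odour in the rewarded context (`O_R C_R`) pays
#' out. Defaults emulate an expert animal; `behavior_policy = "first_session"`
#' licks indiscriminately.
#'
#' @param n_trials number of trials.
#' @param trial_type_probs probabilities of the four odour-by-context trial
#'   types, in the order `O_R C_R`, `O_R C_U`, `O_U C_R`, `O_U C_U`.
#' @param aisle_length,context_length,corridor_length corridor geometry (cm).
#'   The context zone spans `[aisle_length, aisle_length + context_length)`;
#'   the trial ends when the animal reaches `corridor_length`.
#' @param odour_pulse odour pulse duration (s), delivered at context entry.
#' @param delta time bin size (s).
#' @param sniff_rate,sniff_rate_anticipation baseline inhalation rate (Hz) and
#'   the elevated rate in the second before entering a rewarded context
#'   (expert animals sniff faster in anticipation).
#' @param speed_mean,speed_sd,speed_jitter_sd running speed distribution
#'   across trials (cm/s) and the within-trial jitter.
#' @param lick_rate,lick_bout lick rate (Hz) and bout duration (s) of a GO
#'   response.
#' @param consume_time duration of reward-consumption licking after reward
#'   delivery (s); reward is delivered at the second lick of a HIT bout.
#' @param reaction_meanlog,reaction_sdlog log-normal parameters of the
#'   reaction time from first odour inhalation to first lick (s).
#' @param behavior_policy `"expert"` or `"first_session"`.
#' @param p_go named probabilities of a GO response; default
#'   `c(rewarded = 0.95, other = 0.05)` for experts and a flat 0.8 for first
#'   sessions.
#' @param iti inter-trial gap (s); no regressor bins are placed in the gap and
#'   kernels never span trial boundaries.
#' @param reward_volume reward size in microlitres (metadata only).
#' @param seed integer seed; the same configuration and seed always produce a
#'   byte-identical session.
#' @return an object of class `session_config`.
#' @export
session_config <- function(n_trials = 200,
                           trial_type_probs = rep(0.25, 4),
                           aisle_length = 83, context_length = 33,
                           corridor_length = 168,
                           odour_pulse = 1.0, delta = 0.010,
                           sniff_rate = 3, sniff_rate_anticipation = 5,
                           speed_mean = 30, speed_sd = 6, speed_jitter_sd = 1.5,
                           lick_rate = 7, lick_bout = 1.2, consume_time = 1.0,
                           reaction_meanlog = log(0.45), reaction_sdlog = 0.25,
                           behavior_policy = c("expert", "first_session"),
                           p_go = NULL, iti = 0.5,
                           reward_volume = 4, seed = 1L) {
  behavior_policy <- match.arg(behavior_policy)
  if (is.null(p_go)) {
    p_go <- if (behavior_policy == "expert") {
      c(rewarded = 0.95, other = 0.05)
    } else {
      c(rewarded = 0.80, other = 0.80)
    }
  }
  if (length(trial_type_probs) != 4L || any(!is.finite(trial_type_probs)) ||
      any(trial_type_probs < 0) || abs(sum(trial_type_probs) - 1) > 1e-8) {
    stop("'trial_type_probs' must be 4 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  stop_if_not_positive(c(aisle_length, context_length, corridor_length,
                         odour_pulse, delta, sniff_rate,
                         sniff_rate_anticipation, lick_rate, lick_bout),
                       "geometry/rate parameters")
  if (corridor_length < aisle_length + context_length) {
    stop("'corridor_length' must cover aisle plus context zone", call. = FALSE)
  }
  if (!is.finite(speed_mean) || speed_mean <= 0) {
    stop("'speed_mean' must be positive: the animal never reaches the context",
         call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("'n_trials' must be >= 1", call. = FALSE)
  structure(list(
    n_trials = n_trials,
    trial_type_probs = stats::setNames(as.numeric(trial_type_probs), TRIAL_TYPES),
    aisle_length = aisle_length, context_length = context_length,
    corridor_length = corridor_length,
    odour_pulse = odour_pulse, delta = delta,
    sniff_rate = sniff_rate, sniff_rate_anticipation = sniff_rate_anticipation,
    speed_mean = speed_mean, speed_sd = speed_sd,
    speed_jitter_sd = speed_jitter_sd,
    lick_rate = lick_rate, lick_bout = lick_bout, consume_time = consume_time,
    reaction_meanlog = reaction_meanlog, reaction_sdlog = reaction_sdlog,
    behavior_policy = behavior_policy, p_go = p_go, iti = iti,
    reward_volume = reward_volume, seed = as.integer(seed)),
    class = "session_config")
}

# Simulate one trial in local time. Returns event times, point processes and
# per-bin traces; all times are relative to trial start.
simulate_one_trial <- function(cfg, odour, context) {
  delta <- cfg$delta
  v <- max(8, stats::rnorm(1, cfg$speed_mean, cfg$speed_sd))
  horizon <- cfg$corridor_length / (0.5 * v) + 4
  nb <- ceiling(horizon / delta)
  jit <- as.numeric(stats::filter(stats::rnorm(nb, 0, cfg$speed_jitter_sd),
                                  0.9, method = "recursive"))
  speed_move <- pmin(pmax(v + jit, 0.5 * v), 1.5 * v)
  pos_move <- cumsum(speed_move) * delta
  entry_bin <- which(pos_move >= cfg$aisle_length)[1]
  t_entry <- entry_bin * delta
  t_odour <- t_entry

  # GO decision under the behavioural policy
  rewarded_trial <- odour == "R" && context == "R"
  p <- if (rewarded_trial) cfg$p_go[["rewarded"]] else cfg$p_go[["other"]]
  go <- stats::runif(1) < p

  # inhalations: gamma-renewal point process whose rate rises in the second
  # before entering a rewarded context (anticipatory sniffing, expert policy)
  t_total_max <- horizon + cfg$lick_bout + cfg$consume_time + 3
  inh <- numeric(0)
  t_cur <- stats::rexp(1, cfg$sniff_rate)
  while (t_cur < t_total_max) {
    inh <- c(inh, t_cur)
    rate <- cfg$sniff_rate
    if (cfg$behavior_policy == "expert" && context == "R" &&
        t_cur >= t_entry - 1 && t_cur < t_entry) {
      rate <- cfg$sniff_rate_anticipation
    }
    shape <- 4
    t_cur <- t_cur + stats::rgamma(1, shape = shape, rate = shape * rate)
  }
  # first odour inhalation: ensure the animal samples the pulse (operant
  # control: animals reliably sniff on odour arrival)
  in_pulse <- inh > t_odour & inh <= t_odour + cfg$odour_pulse
  if (!any(in_pulse)) {
    inh <- sort(c(inh, t_odour + stats::runif(1, 0.05, 0.3) * cfg$odour_pulse))
    in_pulse <- inh > t_odour & inh <= t_odour + cfg$odour_pulse
  }
  t_foi <- inh[in_pulse][1]

  licks <- numeric(0)
  t_first_lick <- NA_real_
  t_reward <- NA_real_
  stop_start_bin <- NA_integer_
  stop_bins <- 0L
  if (go) {
    t_first_lick <- t_foi + stats::rlnorm(1, cfg$reaction_meanlog, cfg$reaction_sdlog)
    # lick bout at lick_rate; reward (HIT) delivered at the second lick,
    # followed by consumption licking
    t_l <- t_first_lick
    bout_end <- t_first_lick + cfg$lick_bout
    while (t_l < bout_end || length(licks) < 2L) {
      licks <- c(licks, t_l)
      t_l <- t_l + max(0.06, stats::rexp(1, cfg$lick_rate))
    }
    if (rewarded_trial) {
      t_reward <- licks[2]
      cons_end <- t_reward + cfg$consume_time
      while (t_l < cons_end) {
        licks <- c(licks, t_l)
        t_l <- t_l + max(0.06, stats::rexp(1, cfg$lick_rate))
      }
    }
    stop_start_bin <- min(nb - 1L, max(entry_bin, floor(t_first_lick / delta)))
    stop_end <- max(licks) + 0.3
    stop_bins <- max(0L, ceiling((stop_end - t_first_lick) / delta))
  }

  if (go && stop_bins > 0L) {
    speed <- c(speed_move[seq_len(stop_start_bin)], rep(0, stop_bins),
               speed_move[(stop_start_bin + 1L):nb])
  } else {
    speed <- speed_move
  }
  pos <- pmin(cumsum(speed) * delta, cfg$corridor_length)
  end_bin <- which(pos >= cfg$corridor_length)[1]
  if (is.na(end_bin)) end_bin <- length(pos)
  exit_bin <- which(pos >= cfg$aisle_length + cfg$context_length)[1]
  t_exit <- exit_bin * delta
  t_end <- end_bin * delta

  outcome <- classify_trial_outcomes(paste0("O_", odour, " C_", context), go)
  inh <- inh[inh < t_end]
  licks <- licks[licks < t_end]

  list(odour = odour, context = context, go = go, outcome = outcome,
       t_entry = t_entry, t_odour = t_odour, t_exit = t_exit, t_end = t_end,
       t_foi = t_foi, t_first_lick = t_first_lick, t_reward = t_reward,
       inhalations = inh, licks = licks,
       n_bins = end_bin,
       speed = speed[seq_len(end_bin)], position = pos[seq_len(end_bin)])
}

#' Simulate trial events and behaviour traces for a session
#'
#' Generates trial types, corridor running, inhalation and lick point
#' processes, and trial outcomes under the configured behavioural policy. No
#' spikes are generated; see [simulate_spikes()].
#'
#' @param config a [session_config()].
#' @return an object of class `session_bundle` with elements
#'   `config`, `events` (one row per trial), `inhalations`, `licks`,
#'   `traces` (one row per time bin: trial, bin, time, position, speed) and
#'   an empty `spikes` slot. All times are in seconds on a global session
#'   clock; time bins are half-open `[t, t + delta)` and 0-based within trial.
#' @export
simulate_trial_events <- function(config) {
  stopifnot(inherits(config, "session_config"))
  with_seed(config$seed, {
    types <- sample(TRIAL_TYPES, config$n_trials, replace = TRUE,
                    prob = config$trial_type_probs)
    odour <- ifelse(types %in% c("O_R C_R", "O_R C_U"), "R", "U")
    context <- ifelse(types %in% c("O_R C_R", "O_U C_R"), "R", "U")
    trials <- lapply(seq_len(config$n_trials), function(i) {
      simulate_one_trial(config, odour[i], context[i])
    })
    offset <- 0
    ev <- vector("list", config$n_trials)
    inh_l <- vector("list", config$n_trials)
    lick_l <- vector("list", config$n_trials)
    trace_l <- vector("list", config$n_trials)
    for (i in seq_len(config$n_trials)) {
      tr <- trials[[i]]
      ev[[i]] <- data.frame(
        trial = i, trial_type = types[i], odour = tr$odour,
        context = tr$context,
        t_start = offset, t_context_entry = offset + tr$t_entry,
        t_odour_on = offset + tr$t_odour,
        t_context_exit = offset + tr$t_exit,
        t_end = offset + tr$t_end,
        t_first_odour_inhalation = offset + tr$t_foi,
        t_first_lick_after_odour = offset + tr$t_first_lick,
        t_reward = offset + tr$t_reward,
        go = tr$go, outcome = tr$outcome,
        stringsAsFactors = FALSE)
      if (length(tr$inhalations)) {
        inh_l[[i]] <- data.frame(trial = i, time = offset + tr$inhalations)
      }
      if (length(tr$licks)) {
        lick_l[[i]] <- data.frame(trial = i, time = offset + tr$licks)
      }
      trace_l[[i]] <- data.frame(
        trial = i, bin = seq_len(tr$n_bins) - 1L,
        time = offset + (seq_len(tr$n_bins) - 1L) * config$delta,
        position = tr$position, speed = tr$speed)
      offset <- offset + tr$t_end + config$iti
    }
    structure(list(
      config = config,
      events = do.call(rbind, ev),
      inhalations = if (length(ii <- Filter(Negate(is.null), inh_l))) do.call(rbind, ii)
                    else data.frame(trial = integer(0), time = numeric(0)),
      licks = if (length(ll <- Filter(Negate(is.null), lick_l))) do.call(rbind, ll)
              else data.frame(trial = integer(0), time = numeric(0)),
      traces = do.call(rbind, trace_l),
      spikes = data.frame(unit = integer(0), time = numeric(0))),
      class = "session_bundle")
  })
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d trials, %d bins (delta = %g s), %d units\n",
              nrow(x$events), nrow(x$traces), x$config$delta,
              length(unique(x$spikes$unit))))
  print(table(x$events$trial_type))
  invisible(x)
}

#' Attach spike times to a session bundle
#'
#' Binned counts produced by [simulate_spikes()] are converted to spike times
#' by spacing the spikes evenly within their 10-ms bin, which keeps re-binning
#' exact.
#'
#' @param bundle a `session_bundle`.
#' @param unit unit identifier (integer).
#' @param counts integer vector of per-bin counts aligned with `bundle$traces`.
#' @return the bundle with the unit's spikes added.
#' @export
add_unit_counts <- function(bundle, unit, counts) {
  stopifnot(inherits(bundle, "session_bundle"),
            length(counts) == nrow(bundle$traces))
  nz <- which(counts > 0L)
  if (length(nz)) {
    times <- unlist(lapply(nz, function(b) {
      k <- counts[b]
      bundle$traces$time[b] + bundle$config$delta * seq_len(k) / (k + 1)
    }))
    bundle$spikes <- rbind(bundle$spikes,
                           data.frame(unit = as.integer(unit), time = times))
    bundle$spikes <- bundle$spikes[order(bundle$spikes$unit, bundle$spikes$time), ,
                                   drop = FALSE]
    rownames(bundle$spikes) <- NULL
  }
  bundle
}

#' Bin a unit's spike times onto the session's design bins
#'
#' @param bundle a `session_bundle`.
#' @param unit unit identifier present in `bundle$spikes`.
#' @return integer vector of counts, one per row of `bundle$traces`.
#' @export
unit_counts <- function(bundle, unit) {
  stopifnot(inherits(bundle, "session_bundle"))
  times <- bundle$spikes$time[bundle$spikes$unit == unit]
  counts <- integer(nrow(bundle$traces))
  if (!length(times)) return(counts)
  delta <- bundle$config$delta
  for (i in seq_len(nrow(bundle$events))) {
    e <- bundle$events[i, ]
    rows <- which(bundle$traces$trial == e$trial)
    tt <- times[times >= e$t_start & times < e$t_start + length(rows) * delta]
    if (length(tt)) {
      b <- floor((tt - e$t_start) / delta) + 1L
      tab <- tabulate(b, nbins = length(rows))
      counts[rows] <- counts[rows] + tab
    }
  }
  counts
}

#' Ground-truth kernels for spike simulation
#'
#' Draws a smooth random kernel, exactly in the span of its raised-cosine
#' basis, for each requested variable, plus a bias term fixing the baseline
#' firing rate. Kernel peak amplitudes (in log-rate units) are drawn uniformly
#' around `amplitude`.
#'
#' @param specs kernel specifications from [variable_specs()].
#' @param variables character subset of variable names to include (default
#'   none: bias-only model).
#' @param seed integer seed.
#' @param base_rate_hz baseline firing rate; the bias is its logarithm.
#' @param amplitude typical peak absolute value of each kernel (log-rate
#'   units); individual kernels draw their amplitude from
#'   `U(0.6, 1.2) * amplitude` with random sign pattern.
#' @return an object of class `ground_truth_model` with per-kernel coefficient
#'   vectors, reconstructed kernels and the bias.
#' @export
make_ground_truth_kernels <- function(specs, variables = character(0), seed = 1L,
                                      base_rate_hz = 8, amplitude = 1) {
  unknown <- setdiff(variables, names(specs$variables))
  if (length(unknown)) {
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    coefs <- list()
    kernels <- list()
    for (v in variables) {
      for (kn in specs$variables[[v]]$kernels) {
        basis <- specs$kernels[[kn]]$basis
        w <- as.numeric(stats::filter(stats::rnorm(basis$n + 2), rep(1 / 3, 3),
                                      sides = 2))[2:(basis$n + 1)]
        k <- basis_kernel(basis, w)
        amp <- stats::runif(1, 0.6, 1.2) * amplitude
        sc <- amp / max(abs(k))
        coefs[[kn]] <- w * sc
        kernels[[kn]] <- k * sc
      }
    }
    structure(list(variables = variables, coefficients = coefs,
                   kernels = kernels, bias = log(base_rate_hz),
                   seed = as.integer(seed)),
              class = "ground_truth_model")
  })
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf("<ground_truth_model> bias %.3f (%.2f Hz), variables: %s\n",
              x$bias, exp(x$bias),
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Simulate Poisson spike counts from known kernels
#'
#' The per-bin rate is the exponential of the summed kernel outputs,
#' `lambda_t = exp(sum_i (k_i (*) x_i)_t)`, and counts are drawn independently
#' per bin as `Poisson(lambda_t * delta)`. The rate is a deterministic
#' function of the model and design; only the counts use the seed.
#'
#' @param model a [make_ground_truth_kernels()] model (or any object with
#'   `coefficients`, `variables`, `bias`).
#' @param design a [assemble_design_matrix()] design covering the session.
#' @param seed integer seed.
#' @return a list with `counts` (integer per-bin spike counts), `lambda`
#'   (rate in Hz per bin) and `unit_seed`.
#' @export
simulate_spikes <- function(model, design, seed = 1L) {
  w <- design_weight_vector(design, model)
  eta <- as.numeric(design$X %*% w)
  lambda <- exp(eta)
  mu <- lambda * design$delta
  if (any(!is.finite(mu)) || any(mu > 1e6)) {
    bad <- which(!is.finite(mu) | mu > 1e6)[1]
    stop(sprintf("rate overflow at bin %d (lambda*delta = %g); kernel output too large",
                 bad, mu[bad]), call. = FALSE)
  }
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  list(counts = as.integer(counts), lambda = lambda, unit_seed = as.integer(seed))
}

# expand a ground-truth model (or glm_fit) into a full design-column weight
# vector, zeros for absent variables
design_weight_vector <- function(design, model) {
  w <- numeric(ncol(design$X))
  names(w) <- colnames(design$X)
  w["bias"] <- model$bias
  for (kn in names(model$coefficients)) {
    cols <- design$kernels[[kn]]$cols
    if (is.null(cols)) {
      stop(sprintf("kernel '%s' not present in design", kn), call. = FALSE)
    }
    w[cols] <- model$coefficients[[kn]]
  }
  w
}
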