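#' Kernel and variable specifications for the encoding model
#'
#' Defines the eight regression variables and their kernels. Event kernels are
#' delta trains convolved with raised-cosine bumps over a time-lag window;
#' tuning kernels are one-hot animal-state vectors (position or speed bins)
#' weighted by bumps over the value grid. Three variables carry a pair of
#' kernels keyed by odour or context identity:
#'
#' * `Inhal`: 10 bases, 460 ms after every inhalation onset.
#' * `Odour` (`O_R`, `O_U`): 10 bases, 460 ms after each odour inhalation
#'   (inhalations during the odour pulse), split by odour identity.
#' * `Licks`: 15 bases, 360 ms after each lick.
#' * `Reward`: 15 bases, 360 ms after each reward-consumption lick
#'   (licks from reward delivery onward, HIT trials).
#' * `preGO`: 22 bases, the 2000 ms before the first lick that follows
#'   odorant stimulation (acausal support).
#' * `modOdour` (`modO_R`, `modO_U`): 20 bases, 1500 ms after the first
#'   odour inhalation, active only in rewarded-context trials; captures the
#'   odour-by-context interaction.
#' * `Context` (`C_R`, `C_U`): 42 bases over the corridor discretized in
#'   4-cm position bins, each kernel active only in trials of its context.
#' * `Speed`: one basis per 1 cm/s bin up to the session's maximum running
#'   speed.
#'
#' A bias column of ones (constantly active) is always appended by
#' [assemble_design_matrix()].
#'
#' @param bundle a `session_bundle` (used for the bin size and the session's
#'   maximum speed, which sets the Speed basis count).
#' @param position_bin_cm width of position bins (cm).
#' @return a list with `kernels` (per-kernel spec incl. its
#'   [raised_cosine_basis()]) and `variables` (variable -> kernel grouping).
#' @export
variable_specs <- function(bundle, position_bin_cm = 4) {
  delta <- bundle$config$delta
  n_pos <- ceiling(bundle$config$corridor_length / position_bin_cm)
  max_speed <- max(bundle$traces$speed)
  n_speed <- max(2L, ceiling(max_speed))
  ev <- function(n, support) {
    list(kind = "event", basis = raised_cosine_basis(n, support, delta, "event"))
  }
  tun <- function(n, n_bins, bin_width, source) {
    list(kind = "tuning",
         basis = raised_cosine_basis(n, c(1, n_bins), 1, "tuning"),
         n_value_bins = n_bins, bin_width = bin_width, source = source)
  }
  kernels <- list(
    Inhal  = ev(10, c(0, 0.46)),
    O_R    = ev(10, c(0, 0.46)),
    O_U    = ev(10, c(0, 0.46)),
    Licks  = ev(15, c(0, 0.36)),
    Reward = ev(15, c(0, 0.36)),
    preGO  = ev(22, c(-2, 0)),
    modO_R = ev(20, c(0, 1.5)),
    modO_U = ev(20, c(0, 1.5)),
    C_R    = tun(n_pos, n_pos, position_bin_cm, "position"),
    C_U    = tun(n_pos, n_pos, position_bin_cm, "position"),
    Speed  = tun(n_speed, n_speed, 1, "speed"))
  variables <- list(
    Inhal = list(kernels = "Inhal"),
    Odour = list(kernels = c("O_R", "O_U")),
    Licks = list(kernels = "Licks"),
    Reward = list(kernels = "Reward"),
    preGO = list(kernels = "preGO"),
    modOdour = list(kernels = c("modO_R", "modO_U")),
    Context = list(kernels = c("C_R", "C_U")),
    Speed = list(kernels = "Speed"))
  list(kernels = kernels, variables = variables,
       position_bin_cm = position_bin_cm, delta = delta)
}

# event times (global, seconds) driving each kernel
kernel_events <- function(bundle, name) {
  ev <- bundle$events
  switch(name,
    Inhal = bundle$inhalations$time,
    O_R = odour_inhalation_times(bundle, "R"),
    O_U = odour_inhalation_times(bundle, "U"),
    Licks = bundle$licks$time,
    Reward = {
      hit <- ev[ev$outcome == "HIT" & !is.na(ev$t_reward), ]
      if (!nrow(hit)) numeric(0) else {
        unlist(lapply(seq_len(nrow(hit)), function(i) {
          l <- bundle$licks$time[bundle$licks$trial == hit$trial[i]]
          l[l >= hit$t_reward[i]]
        }))
      }
    },
    preGO = ev$t_first_lick_after_odour[!is.na(ev$t_first_lick_after_odour)],
    modO_R = ev$t_first_odour_inhalation[ev$odour == "R" & ev$context == "R"],
    modO_U = ev$t_first_odour_inhalation[ev$odour == "U" & ev$context == "R"],
    stop(sprintf("kernel '%s' has no event source", name), call. = FALSE))
}

odour_inhalation_times <- function(bundle, odour) {
  ev <- bundle$events[bundle$events$odour == odour, ]
  unlist(lapply(seq_len(nrow(ev)), function(i) {
    tt <- bundle$inhalations$time[bundle$inhalations$trial == ev$trial[i]]
    tt[tt > ev$t_odour_on[i] & tt <= ev$t_odour_on[i] + bundle$config$odour_pulse]
  }))
}

#' Build the regressor block for one kernel
#'
#' Event kernels: each event becomes a delta at its time bin and is convolved
#' with every basis bump, truncated at the trial boundaries (events within one
#' bin of trial end are truncated, not dropped). Tuning kernels: each time bin
#' contributes the basis evaluated at the occupied value bin, restricted to
#' the trials where the kernel is active.
#'
#' @param bundle a `session_bundle`.
#' @param specs from [variable_specs()].
#' @param name kernel name (e.g. `"O_R"`).
#' @param layout internal bin layout (computed by [assemble_design_matrix()]
#'   if missing).
#' @return a list with `block` (sparse `T x n_bases` matrix) and `rows`
#'   (bins with any nonzero entry).
#' @export
build_variable_regressors <- function(bundle, specs, name, layout = NULL) {
  if (is.null(layout)) layout <- bin_layout(bundle)
  sp <- specs$kernels[[name]]
  if (is.null(sp)) stop(sprintf("unknown kernel '%s'", name), call. = FALSE)
  nT <- layout$n_bins
  if (sp$kind == "event") {
    basis <- sp$basis
    lag_bins <- as.integer(round(basis$grid / bundle$config$delta))
    times <- kernel_events(bundle, name)
    acc_i <- vector("list", length(times))
    acc_j <- vector("list", length(times))
    acc_x <- vector("list", length(times))
    if (length(times)) {
      nzB <- which(basis$B != 0, arr.ind = TRUE)
      nzx <- basis$B[nzB]
      tr <- layout$trial_of_time(times)
      if (anyNA(tr)) stop("event outside session span", call. = FALSE)
      for (e in seq_along(times)) {
        t0 <- layout$trial_start[tr[e]]
        b <- layout$trial_first_row[tr[e]] +
          floor((times[e] - t0) / bundle$config$delta)
        rows <- b + lag_bins[nzB[, 1]]
        ok <- rows >= layout$trial_first_row[tr[e]] &
              rows <= layout$trial_last_row[tr[e]]
        if (!any(ok)) next
        acc_i[[e]] <- rows[ok]
        acc_j[[e]] <- nzB[ok, 2]
        acc_x[[e]] <- nzx[ok]
      }
    }
    ti <- unlist(acc_i); tj <- unlist(acc_j); tx <- unlist(acc_x)
    if (is.null(ti)) { ti <- integer(0); tj <- integer(0); tx <- numeric(0) }
    block <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                  dims = c(nT, basis$n))
  } else {
    basis <- sp$basis
    if (sp$source == "position") {
      ctx <- substr(name, 3, 3)   # C_R -> "R"
      trials <- bundle$events$trial[bundle$events$context == ctx]
      rows <- which(bundle$traces$trial %in% trials)
      vals <- bundle$traces$position[rows]
      vb <- pmin(sp$n_value_bins, pmax(1L, floor(vals / sp$bin_width) + 1L))
    } else {
      rows <- seq_len(nT)
      vals <- bundle$traces$speed[rows]
      if (any(vals > sp$n_value_bins)) {
        stop("speed exceeds the declared maximum for the Speed basis", call. = FALSE)
      }
      vb <- pmax(1L, ceiling(vals))
      vb[vals == 0] <- 1L
    }
    nzlist <- lapply(seq_len(sp$n_value_bins), function(v) {
      j <- which(basis$B[v, ] != 0)
      list(j = j, x = basis$B[v, j])
    })
    nnz_per <- vapply(nzlist, function(z) length(z$j), integer(1))
    trip_i <- rep(rows, nnz_per[vb])
    trip_j <- unlist(lapply(vb, function(v) nzlist[[v]]$j))
    trip_x <- unlist(lapply(vb, function(v) nzlist[[v]]$x))
    if (is.null(trip_j)) { trip_j <- integer(0); trip_x <- numeric(0) }
    block <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                  dims = c(nT, basis$n))
  }
  list(block = block, rows = sort(unique(block@i + 1L)))
}

# bin layout: map global rows <-> trials
bin_layout <- function(bundle) {
  ev <- bundle$events
  nb <- as.integer(table(factor(bundle$traces$trial, levels = ev$trial)))
  first <- cumsum(c(1L, utils::head(nb, -1L)))
  last <- cumsum(nb)
  t_start <- ev$t_start
  t_stop <- ev$t_start + nb * bundle$config$delta
  trial_of_time <- function(tt) {
    idx <- vapply(tt, function(x) {
      w <- which(x >= t_start & x < t_stop)
      if (length(w)) w[1] else NA_integer_
    }, integer(1))
    idx
  }
  list(n_bins = nrow(bundle$traces), n_per_trial = nb,
       trial_first_row = first, trial_last_row = last,
       trial_start = t_start, trial_of_time = trial_of_time)
}

#' Assemble the full design matrix for a session
#'
#' Stacks the regressor blocks of the requested variables plus a bias column
#' of ones, recording per-variable valid-bin masks (the bins where each
#' variable's kernels contributed to the rate) and the bin-to-trial map.
#'
#' @param bundle a `session_bundle`.
#' @param variables character vector of variable names (default: all eight).
#' @param specs optionally a precomputed [variable_specs()] (must match the
#'   bundle).
#' @return an object of class `design_matrix`: sparse matrix `X`
#'   (`T x P`, column names `kernel.basisIndex` plus `bias`), `kernels`
#'   (per-kernel columns and basis), `variables` (kernel grouping and masks),
#'   `bin_trial`, `bin_time`, `delta`, `specs`.
#' @export
assemble_design_matrix <- function(bundle, variables = NULL, specs = NULL) {
  stopifnot(inherits(bundle, "session_bundle"))
  if (is.null(specs)) specs <- variable_specs(bundle)
  if (is.null(variables)) variables <- names(specs$variables)
  if (anyDuplicated(variables)) stop("duplicated variable names", call. = FALSE)
  unknown <- setdiff(variables, names(specs$variables))
  if (length(unknown)) {
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  layout <- bin_layout(bundle)
  blocks <- list(Matrix::Matrix(1, nrow = layout$n_bins, ncol = 1, sparse = TRUE))
  colnames(blocks[[1]]) <- "bias"
  kernels <- list()
  vars <- list()
  col_at <- 1L
  for (v in variables) {
    mask <- integer(0)
    for (kn in specs$variables[[v]]$kernels) {
      br <- build_variable_regressors(bundle, specs, kn, layout)
      colnames(br$block) <- paste0(kn, ".", seq_len(ncol(br$block)))
      blocks[[length(blocks) + 1L]] <- br$block
      kernels[[kn]] <- list(variable = v,
                            cols = col_at + seq_len(ncol(br$block)),
                            basis = specs$kernels[[kn]]$basis)
      col_at <- col_at + ncol(br$block)
      mask <- union(mask, br$rows)
    }
    vars[[v]] <- list(kernels = specs$variables[[v]]$kernels,
                      mask = sort(mask))
  }
  X <- do.call(cbind, blocks)
  structure(list(X = X, kernels = kernels, variables = vars,
                 bin_trial = bundle$traces$trial,
                 bin_time = bundle$traces$time,
                 delta = bundle$config$delta, specs = specs),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d bins x %d columns (%d variables + bias), delta = %g s\n",
              nrow(x$X), ncol(x$X), length(x$variables), x$delta))
  invisible(x)
}

# columns for a set of variables (bias always first)
design_columns <- function(design, variables) {
  cols <- 1L
  for (v in variables) {
    if (is.null(design$variables[[v]])) {
      stop(sprintf("variable '%s' is not in the design", v), call. = FALSE)
    }
    for (kn in design$variables[[v]]$kernels) {
      cols <- c(cols, design$kernels[[kn]]$cols)
    }
  }
  cols
}

#' Export a design matrix as a sparse triplet table
#'
#' @param design a `design_matrix`.
#' @return a data frame with columns `bin`, `column`, `value`.
#' @export
design_triplets <- function(design) {
  tm <- as(design$X, "TsparseMatrix")
  data.frame(bin = tm@i + 1L, column = colnames(design$X)[tm@j + 1L],
             value = tm@x)
}
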