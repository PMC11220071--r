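#' Signal-detection metrics of task performance
#'
#' Computes the sensitivity `d' = Z(Hit rate) - Z(FA rate)` and the response
#' bias `criterion = -0.5 [Z(Hit rate) + Z(FA rate)]`, where `Z` is the
#' inverse normal cumulative distribution function. Rates of exactly 0 or 1
#' are replaced by `1/(2N)` and `1 - 1/(2N)` (the standard correction; `Z` is
#' undefined at the extremes), which requires the corresponding trial counts.
#'
#' Either supply `hit_rate`/`fa_rate` directly, or the four outcome counts.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @param hits,misses,false_alarms,correct_rejections outcome counts; used to
#'   compute the rates (and the extreme-rate correction) when given.
#' @return a list with `d_prime`, `criterion`, `hit_rate`, `fa_rate`.
#' @examples
#' sdt_metrics(hit_rate = 0.95, fa_rate = 0.05)$d_prime  # 3.29
#' @export
sdt_metrics <- function(hit_rate = NULL, fa_rate = NULL,
                        hits = NULL, misses = NULL,
                        false_alarms = NULL, correct_rejections = NULL) {
  if (is.null(hit_rate)) {
    n_go <- hits + misses
    n_nogo <- false_alarms + correct_rejections
    if (any(c(hits, misses, false_alarms, correct_rejections) < 0)) {
      stop("outcome counts must be non-negative", call. = FALSE)
    }
    if (n_go == 0 || n_nogo == 0) {
      stop("zero trials in the target or non-target category", call. = FALSE)
    }
    hit_rate <- correct_extreme_rate(hits / n_go, n_go)
    fa_rate <- correct_extreme_rate(false_alarms / n_nogo, n_nogo)
  }
  if (any(c(hit_rate, fa_rate) < 0) || any(c(hit_rate, fa_rate) > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(hit_rate, fa_rate) %in% c(0, 1))) {
    stop("rate of exactly 0 or 1: supply counts so the 1/(2N) correction can be applied",
         call. = FALSE)
  }
  zh <- stats::qnorm(hit_rate)
  zf <- stats::qnorm(fa_rate)
  list(d_prime = zh - zf, criterion = -0.5 * (zh + zf),
       hit_rate = hit_rate, fa_rate = fa_rate)
}

correct_extreme_rate <- function(r, n) {
  if (r <= 0) 1 / (2 * n) else if (r >= 1) 1 - 1 / (2 * n) else r
}

#' Trial outcome from trial type and GO response
#'
#' GO in a rewarded-odour/rewarded-context trial is a HIT, NO-GO there a
#' MISS; in any other trial type GO is a false alarm and NO-GO a correct
#' rejection.
#'
#' @param trial_type character vector over
#'   `"O_R C_R"`, `"O_R C_U"`, `"O_U C_R"`, `"O_U C_U"`.
#' @param go logical vector: did the animal lick after the odour?
#' @return character vector over `"HIT"`, `"MISS"`, `"FA"`, `"CR"`.
#' @export
classify_trial_outcomes <- function(trial_type, go) {
  if (!all(trial_type %in% TRIAL_TYPES)) {
    stop("unknown trial type: ",
         paste(setdiff(trial_type, TRIAL_TYPES), collapse = ", "), call. = FALSE)
  }
  target <- trial_type == "O_R C_R"
  ifelse(target, ifelse(go, "HIT", "MISS"), ifelse(go, "FA", "CR"))
}

#' Count outcomes of a session
#'
#' @param events the `events` table of a `session_bundle` (needs `outcome`).
#' @return a list of counts: `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`.
#' @export
outcome_counts <- function(events) {
  list(hits = sum(events$outcome == "HIT"),
       misses = sum(events$outcome == "MISS"),
       false_alarms = sum(events$outcome == "FA"),
       correct_rejections = sum(events$outcome == "CR"))
}

#' Detect inhalation onsets in a respiration trace
#'
#' Negative airflow corresponds to inhalation. The trace is smoothed with a
#' second-order Savitzky-Golay filter in 100-ms frames, detrended by
#' subtracting its 1-s median-filtered copy, and inhalation onsets are the
#' negative-going zero crossings preceding negative peaks that exceed
#' `k_mad` median absolute deviations of the detrended trace. Onsets within
#' a 1-s window starting immediately after the odour pulse arrival are
#' labelled odour inhalations.
#'
#' @param airflow airflow samples (arbitrary units).
#' @param fs sampling rate in Hz (>= 100).
#' @param t0 time of the first sample (s).
#' @param frame Savitzky-Golay frame length (s).
#' @param detrend_window median-filter window (s).
#' @param k_mad peak threshold in median absolute deviations of the
#'   detrended trace. The default 0.5 accepts any peak exceeding half the
#'   trace's typical excursion; note a pure sinusoid has MAD about 1.05
#'   times its amplitude, so thresholds at or above 1 would reject even
#'   noise-free periodic breathing.
#' @param min_interval minimum spacing between onsets (s).
#' @param t_odour_on optional odour pulse arrival times (s) for labelling.
#' @param odour_window length of the odour-inhalation window (s).
#' @return data frame with `time` and logical `odour` (all `FALSE` when
#'   `t_odour_on` is `NULL`). A flat trace yields zero rows.
#' @export
detect_inhalations <- function(airflow, fs, t0 = 0, frame = 0.1,
                               detrend_window = 1, k_mad = 0.5,
                               min_interval = 0.05,
                               t_odour_on = NULL, odour_window = 1) {
  if (anyNA(airflow)) stop("airflow trace contains NA", call. = FALSE)
  if (fs < 100) stop("sampling rate must be >= 100 Hz", call. = FALSE)
  if (length(airflow) <= detrend_window * fs) {
    stop("trace shorter than the detrending window", call. = FALSE)
  }
  sg <- signal::sgolayfilt(airflow, p = 2, n = odd_window(frame * fs))
  # reflection-pad so the running median behaves like the interior at edges
  nw <- odd_window(detrend_window * fs)
  half <- (nw - 1L) %/% 2L
  nsg <- length(sg)
  padded <- c(sg[pmin(nsg, (half + 1L):2L)], sg, sg[pmax(1L, (nsg - 1L):(nsg - half))])
  trend <- stats::runmed(padded, nw)[half + seq_len(nsg)]
  det <- sg - trend
  thr <- -k_mad * stats::mad(det)
  n <- length(det)
  onsets <- integer(0)
  if (thr < 0) {
    # local minima below threshold
    peak <- which(det < thr &
                    det <= c(Inf, det[-n]) & det <= c(det[-1], Inf))
    neg_cross <- which(det[-1] < 0 & det[-n] >= 0) + 1L
    if (length(peak) && length(neg_cross)) {
      onsets <- unique(vapply(peak, function(p) {
        cand <- neg_cross[neg_cross <= p]
        if (length(cand)) cand[length(cand)] else NA_integer_
      }, integer(1)))
      onsets <- sort(onsets[!is.na(onsets)])
      if (length(onsets) > 1L) {
        keep <- c(TRUE, diff(onsets) >= min_interval * fs)
        onsets <- onsets[keep]
      }
    }
  }
  times <- t0 + (onsets - 1L) / fs
  odour <- rep(FALSE, length(times))
  if (!is.null(t_odour_on) && length(times)) {
    for (tt in t_odour_on) {
      odour <- odour | (times > tt & times <= tt + odour_window)
    }
  }
  data.frame(time = times, odour = odour)
}

#' Occupancy-normalized position tuning map
#'
#' Firing rate per position bin: spike count in the bin divided by the time
#' the animal spent there. Unvisited bins are `NA`, never zero.
#'
#' @param spike_times spike times (s).
#' @param trace data frame with `time` and `position` sampled at a fixed
#'   interval (e.g. a `session_bundle$traces`).
#' @param bin_cm position bin width (cm).
#' @return data frame with `position` (bin left edge), `occupancy` (s),
#'   `count` and `rate` (Hz; `NA` where occupancy is zero).
#' @export
position_occupancy_map <- function(spike_times, trace, bin_cm = 4) {
  stop_if_not_positive(bin_cm, "bin_cm")
  if (!nrow(trace)) stop("empty position trace", call. = FALSE)
  dt <- stats::median(diff(trace$time))
  n_bins <- floor(max(trace$position) / bin_cm) + 1L
  pb <- pmin(n_bins, floor(trace$position / bin_cm) + 1L)
  occupancy <- tabulate(pb, n_bins) * dt
  if (sum(occupancy) == 0) stop("total occupancy is zero", call. = FALSE)
  counts <- integer(n_bins)
  if (length(spike_times)) {
    pos_at <- stats::approx(trace$time, trace$position, xout = spike_times,
                            rule = 2)$y
    sb <- pmin(n_bins, floor(pos_at / bin_cm) + 1L)
    counts <- tabulate(sb, n_bins)
  }
  rate <- ifelse(occupancy > 0, counts / occupancy, NA_real_)
  data.frame(position = (seq_len(n_bins) - 1L) * bin_cm,
             occupancy = occupancy, count = counts, rate = rate)
}
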