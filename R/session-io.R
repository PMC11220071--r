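SESSION_TABLES <- c(events = "events.tsv", inhalations = "inhalations.tsv",
                    licks = "licks.tsv", traces = "traces.tsv",
                    spikes = "spikes.tsv")

REQUIRED_EVENT_COLS <- c("trial", "trial_type", "odour", "context", "t_start",
                         "t_context_entry", "t_odour_on", "t_context_exit",
                         "t_end", "t_first_odour_inhalation",
                         "t_first_lick_after_odour", "t_reward", "go",
                         "outcome")

#' Write a session bundle to a directory
#'
#' Serializes the bundle as a directory of tab-separated tables
#' (`events.tsv`, `inhalations.tsv`, `licks.tsv`, `traces.tsv`,
#' `spikes.tsv`) plus `manifest.yaml` holding the configuration and seed.
#' Numeric values are written at full (17 significant digit) precision, so
#' [read_session()] reproduces the bundle exactly.
#'
#' @param bundle a `session_bundle`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(SESSION_TABLES)) {
    df <- bundle[[nm]]
    out <- df
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    }
    utils::write.table(out, file.path(path, SESSION_TABLES[[nm]]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- bundle$config
  cfg_plain <- lapply(unclass(cfg), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else if (is.numeric(x)) as.numeric(x)
    else x
  })
  yaml::write_yaml(list(format = "spikeglm-session/1",
                        config = cfg_plain,
                        seed = cfg$seed),
                   file.path(path, "manifest.yaml"),
                   precision = 17)
  invisible(path)
}

#' Read a session bundle from a directory
#'
#' Validates the manifest, the presence of every table and required column,
#' sortedness of spike times and known trial types; a violation raises a
#' descriptive parse error naming the offending table or column.
#'
#' @param path directory written by [write_session()].
#' @return a `session_bundle`.
#' @export
read_session <- function(path) {
  mf_path <- file.path(path, "manifest.yaml")
  if (!file.exists(mf_path)) stop("missing manifest.yaml", call. = FALSE)
  mf <- yaml::read_yaml(mf_path)
  cfg_l <- mf$config
  cfg_l$trial_type_probs <- as.numeric(unlist(cfg_l$trial_type_probs))
  cfg_l$p_go <- unlist(cfg_l$p_go)
  cfg <- do.call(session_config, cfg_l)
  tabs <- list()
  for (nm in names(SESSION_TABLES)) {
    f <- file.path(path, SESSION_TABLES[[nm]])
    if (!file.exists(f)) {
      stop(sprintf("missing table '%s'", SESSION_TABLES[[nm]]), call. = FALSE)
    }
    tabs[[nm]] <- utils::read.table(f, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(REQUIRED_EVENT_COLS, names(tabs$events))
  if (length(missing_cols)) {
    stop("events table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(tabs$events$trial_type %in% TRIAL_TYPES)) {
    stop("events table contains unknown trial type", call. = FALSE)
  }
  for (nm in c("inhalations", "licks", "spikes")) {
    if (nrow(tabs[[nm]]) && any(tabs[[nm]]$time < 0)) {
      stop(sprintf("negative time in '%s'", SESSION_TABLES[[nm]]), call. = FALSE)
    }
  }
  if (nrow(tabs$spikes)) {
    sp <- tabs$spikes
    for (u in unique(sp$unit)) {
      if (is.unsorted(sp$time[sp$unit == u])) {
        stop(sprintf("unsorted spike times for unit %s", u), call. = FALSE)
      }
    }
  }
  if (!nrow(tabs$inhalations)) {
    tabs$inhalations <- data.frame(trial = integer(0), time = numeric(0))
  }
  if (!nrow(tabs$licks)) {
    tabs$licks <- data.frame(trial = integer(0), time = numeric(0))
  }
  if (!nrow(tabs$spikes)) {
    tabs$spikes <- data.frame(unit = integer(0), time = numeric(0))
  }
  structure(list(config = cfg, events = tabs$events,
                 inhalations = tabs$inhalations, licks = tabs$licks,
                 traces = tabs$traces, spikes = tabs$spikes),
            class = "session_bundle")
}
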