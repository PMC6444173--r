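#' Pipeline configuration
#'
#' A single configuration object drives the whole workflow (epoch selection,
#' filtering, quantification, curve fitting, curve comparison), so a run is
#' fully described by its inputs plus one config. Every field defaults to
#' the standard analysis values: an 8-22 ms epoch, filtering off with a
#' 5-600 Hz band when enabled, fit tolerance 0.1, and 50% metric cutoffs
#' (MEP50 / Stim50). Configs persist between runs via [write_config()] /
#' [read_config()].
#'
#' @param epoch_start_ms,epoch_stop_ms,channel Epoch window and channel
#'   (see [epoch_spec()]).
#' @param filter_enabled,low_hz,high_hz,passband_ripple_db,stopband_atten_db
#'   Band-pass settings (see [filter_spec()]).
#' @param notch_enabled,notch_harmonics,notch_q Mains-notch settings.
#' @param metric Quantification metric (`"auc"`, `"rms"`, `"p2p"`,
#'   `"latency"`).
#' @param latency_pct,baseline_ms Latency-metric parameters.
#' @param tolerance,stall_delta,stall_iters,q Curve-fit settings (see
#'   [fit_recruitment()]); `q = NULL` fixes `Q` from the data.
#' @param metrics Curve-comparison metrics to run, subset of
#'   `c("mep", "stim", "slope")`.
#' @param mep_cutoff,stim_cutoff Cut percentages for the MEP and
#'   stimulation metrics.
#' @param as_change Report percent change from baseline instead of percent
#'   of baseline.
#' @return An object of class `mep_config`.
#' @export
run_config <- function(epoch_start_ms = 8, epoch_stop_ms = 22, channel = 1L,
                       filter_enabled = FALSE, low_hz = 5, high_hz = 600,
                       passband_ripple_db = 4, stopband_atten_db = 30,
                       notch_enabled = FALSE, notch_harmonics = 2L, notch_q = 30,
                       metric = "auc", latency_pct = 20, baseline_ms = 2,
                       tolerance = 0.1, stall_delta = 0.01, stall_iters = 10L,
                       q = NULL, metrics = c("mep", "stim", "slope"),
                       mep_cutoff = 50, stim_cutoff = 50, as_change = FALSE) {
  metric <- match.arg(metric, c("auc", "rms", "p2p", "latency"))
  metrics <- match.arg(metrics, c("mep", "stim", "slope"), several.ok = TRUE)
  # constructors validate ranges
  epoch_spec(epoch_start_ms, epoch_stop_ms, channel)
  filter_spec(
    filter_enabled, low_hz, high_hz, passband_ripple_db, stopband_atten_db,
    notch_enabled, 60, notch_harmonics, notch_q
  )
  structure(
    list(
      version = 1L,
      epoch_start_ms = as.numeric(epoch_start_ms),
      epoch_stop_ms = as.numeric(epoch_stop_ms),
      channel = as.integer(channel),
      filter_enabled = isTRUE(filter_enabled),
      low_hz = as.numeric(low_hz),
      high_hz = as.numeric(high_hz),
      passband_ripple_db = as.numeric(passband_ripple_db),
      stopband_atten_db = as.numeric(stopband_atten_db),
      notch_enabled = isTRUE(notch_enabled),
      notch_harmonics = as.integer(notch_harmonics),
      notch_q = as.numeric(notch_q),
      metric = metric,
      latency_pct = as.numeric(latency_pct),
      baseline_ms = as.numeric(baseline_ms),
      tolerance = as.numeric(tolerance),
      stall_delta = as.numeric(stall_delta),
      stall_iters = as.integer(stall_iters),
      q = if (is.null(q)) NULL else as.numeric(q),
      metrics = metrics,
      mep_cutoff = as.numeric(mep_cutoff),
      stim_cutoff = as.numeric(stim_cutoff),
      as_change = isTRUE(as_change)
    ),
    class = "mep_config"
  )
}

#' @rdname run_config
#' @param config An `mep_config`.
#' @param path Config file path (JSON).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "mep_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = I(17), null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file does not exist: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(doc$version) || doc$version != 1L) {
    abort("unsupported or missing config version")
  }
  known <- names(formals(run_config))
  keys <- setdiff(names(doc), "version")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, doc[keys])
}

config_epoch_spec <- function(config) {
  epoch_spec(config$epoch_start_ms, config$epoch_stop_ms, config$channel)
}

config_filter_spec <- function(config) {
  filter_spec(
    config$filter_enabled, config$low_hz, config$high_hz,
    config$passband_ripple_db, config$stopband_atten_db,
    config$notch_enabled, 60, config$notch_harmonics, config$notch_q
  )
}

resolve_session <- function(row, base_dir) {
  if ("session" %in% names(row)) {
    return(row$session[[1]])
  }
  p <- row$path
  full <- if (file.exists(p)) p else file.path(base_dir, p)
  if (!file.exists(full)) {
    abort(sprintf("[load] session container not found: %s", p))
  }
  load_session(full)
}

#' Run the full analysis pipeline
#'
#' Wires the modules into the standard workflow: load every session of
#' every record, optionally filter, quantify, fit recruitment curves
#' (baseline first), compare curves within each record, and aggregate the
#' normalized metrics across records. The run is deterministic given its
#' inputs and config; each stage logs counts via `message()`, and
#' non-fatal issues (non-saturating curves, unattainable horizontal cuts)
#' are collected as warnings in the result rather than halting the run.
#'
#' Curve-based metrics require a sigmoidal stimulus-response profile, so a
#' config with `metric = "latency"` skips curve fitting and produces only
#' the direct mean-MEP comparison.
#'
#' @param master An [build_master()] object or the path to a master
#'   manifest (see [write_master()]).
#' @param config An [run_config()].
#' @param out_dir Optional directory; when given, the results bundle
#'   (JSON + CSV, including `bars.csv`) is exported there.
#' @return An object of class `mep_results`: the [results_bundle()], a
#'   `bars` tibble (metric, condition, group mean, standard error, n), the
#'   per-record metric results, and the collected `warnings`.
#' @export
run_pipeline <- function(master, config = run_config(), out_dir = NULL) {
  if (is.character(master)) master <- read_master(master)
  stopifnot(inherits(master, "mep_master"))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  espec <- config_epoch_spec(config)
  fspec <- config_filter_spec(config)
  fit_curves <- config$metric != "latency"
  entries <- list()
  record_results <- list()
  quantified_all <- list()
  quantified_conditions <- character(0)
  for (rec in master$records) {
    base_dir <- attr(rec, "base_dir")
    if (is.null(base_dir)) base_dir <- "."
    n_sess <- nrow(rec$sessions)
    curves <- vector("list", n_sess)
    for (i in seq_len(n_sess)) {
      row <- rec$sessions[i, ]
      session <- withCallingHandlers(
        resolve_session(row, base_dir),
        error = function(e) e
      )
      if (inherits(session, "error")) stop(session)
      filtered <- fspec$enabled || fspec$notch_enabled
      if (filtered) session <- filter_session(session, fspec)
      quantified <- quantify_session(
        session, espec,
        metric = config$metric,
        latency_pct = config$latency_pct, baseline_ms = config$baseline_ms
      )
      curve <- NULL
      if (fit_curves) {
        curve <- withCallingHandlers(
          fit_recruitment(
            quantified$per_intensity$intensity,
            quantified$per_intensity$mean_value,
            tolerance = config$tolerance,
            stall_delta = config$stall_delta,
            stall_iters = config$stall_iters,
            q = config$q
          ),
          mepkit_no_saturation = function(w) {
            note(w)
            invokeRestart("muffleWarning")
          }
        )
      }
      curves[[i]] <- curve
      entries[[length(entries) + 1]] <- session_entry(
        session, quantified, curve,
        subject = rec$subject_id, condition = row$condition, filtered = filtered
      )
      quantified_all[[length(quantified_all) + 1]] <- quantified
      quantified_conditions <- c(quantified_conditions, row$condition)
      message(sprintf(
        "[quantify] %s / %s: %d sweeps, %d intensities%s",
        rec$subject_id, row$condition, nrow(quantified$per_trial),
        length(session$stim_intensities),
        if (fit_curves) sprintf(", fit R^2 = %.3f", curve$r_squared) else ""
      ))
    }
    if (fit_curves) {
      cs <- curve_set(
        curves[[1]],
        conditions = curves[-1],
        labels = rec$sessions$condition[-1],
        baseline_label = rec$sessions$condition[1]
      )
      res <- list()
      if ("mep" %in% config$metrics) {
        res$mep <- mep_metric(cs, config$mep_cutoff, as_change = config$as_change)
      }
      if ("stim" %in% config$metrics) {
        res$stim <- withCallingHandlers(
          stim_metric(cs, config$stim_cutoff, as_change = config$as_change),
          mepkit_unattainable = function(w) {
            note(w)
            invokeRestart("muffleWarning")
          }
        )
      }
      if ("slope" %in% config$metrics) res$slope <- slope_metric(cs)
      record_results[[rec$subject_id]] <- res
    }
  }
  message(sprintf(
    "[pipeline] %d records, %d sessions processed, %d warning(s)",
    length(master$records), length(entries), length(warnings_log)
  ))
  bars <- NULL
  summaries <- list()
  if (fit_curves && length(record_results) > 0) {
    for (m in config$metrics) {
      summaries[[m]] <- group_aggregate(lapply(record_results, `[[`, m))
    }
    bars <- dplyr::bind_rows(lapply(names(summaries), function(m) {
      dplyr::mutate(as_tibble(summaries[[m]]),
        metric = toupper(m),
        cutoff = attr(summaries[[m]], "cutoff_pct"), .before = 1
      )
    }))
  }
  direct <- direct_mep_comparison(quantified_all, quantified_conditions)
  analyses <- if (!is.null(bars)) {
    list(
      metric_types = toupper(config$metrics),
      cutoffs = c(
        mep = config$mep_cutoff, stim = config$stim_cutoff,
        slope = NA_real_
      )[config$metrics],
      bars = lapply(summaries, as.data.frame)
    )
  } else {
    NULL
  }
  bundle <- results_bundle(entries, analyses)
  if (!is.null(out_dir)) {
    export_results(bundle, out_dir)
    message(sprintf("[export] results written to %s", out_dir))
  }
  structure(
    list(
      bundle = bundle, bars = bars, record_results = record_results,
      group_summaries = summaries, direct = direct, warnings = warnings_log,
      config = config
    ),
    class = "mep_results"
  )
}

#' @export
print.mep_results <- function(x, ...) {
  cat(sprintf(
    "<mep_results> %d session(s), %d record(s)\n",
    length(x$bundle$sessions), length(x$record_results)
  ))
  if (!is.null(x$bars)) print(x$bars)
  if (length(x$warnings) > 0) {
    cat(sprintf("%d warning(s); see $warnings\n", length(x$warnings)))
  }
  invisible(x)
}
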