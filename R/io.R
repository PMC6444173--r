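#' Write a session to a portable JSON container
#'
#' Sessions are serialized as a single JSON document with the sweep array
#' stored flat (column-major) next to its dimensions, full numeric
#' precision, and the annotation fields alongside. The layout is
#' deliberately plain so containers can be produced by any acquisition
#' export script:
#'
#' ```
#' { "format": "mepkit-session", "version": 1,
#'   "session_id": 1, "sampling_rate_hz": 5000,
#'   "channel_labels": ["biceps"],
#'   "stim_intensities": [...], "trials_per_stim": [...],
#'   "sweeps": { "dim": [samples, channels, sweeps], "values": [...] } }
#' ```
#'
#' Proprietary acquisition formats (CED, TDT, ADInstruments) are not parsed
#' directly; export from the acquisition software first.
#'
#' @param session An [mep_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "mep_session"))
  doc <- list(
    format = "mepkit-session",
    version = 1L,
    session_id = session$session_id,
    sampling_rate_hz = session$sampling_rate_hz,
    channel_labels = session$channel_labels,
    stim_intensities = session$stim_intensities,
    trials_per_stim = session$trials_per_stim,
    sweeps = pack_array(session$sweeps)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

pack_array <- function(a) list(dim = dim(a), values = as.numeric(a))

unpack_array <- function(x) {
  if (is.list(x) && !is.null(x$dim)) {
    array(as.numeric(unlist(x$values)), dim = as.integer(unlist(x$dim)))
  } else {
    x
  }
}

#' Load sweeps from a session container
#'
#' Reads a JSON session container — either the layout written by
#' [write_session()] or a foreign export holding a bare numeric array under
#' `dataset_key` — and returns the sweeps in the canonical
#' `[samples x channels x sweeps]` order regardless of how the exporting
#' system arranged the axes. A 2-axis array is treated as single-channel.
#' Annotation present in the container is attached; otherwise annotate with
#' [annotate_session()].
#'
#' @param path Path to the container file.
#' @param dataset_key Name of the array field for foreign containers.
#' @param layout Character vector naming the stored axis order, a
#'   permutation of `c("samples", "channels", "sweeps")` (drop `"channels"`
#'   for 2-axis data). The default assumes canonical order.
#' @return An [mep_session()] (unannotated when the container carries no
#'   annotation).
#' @export
load_session <- function(path, dataset_key = "sweeps",
                         layout = c("samples", "channels", "sweeps")) {
  if (!file.exists(path)) abort(sprintf("file does not exist: %s", path))
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) abort(sprintf("unreadable container: %s (%s)", path, conditionMessage(e)))
  )
  is_native <- is.list(parsed) && identical(parsed$format, "mepkit-session")
  payload <- if (is_native) {
    unpack_array(parsed$sweeps)
  } else if (is.list(parsed) && !is.null(parsed[[dataset_key]])) {
    unpack_array(parsed[[dataset_key]])
  } else {
    parsed
  }
  if (is.list(payload) || !is.numeric(unlist(payload))) {
    abort(sprintf("unreadable container: no numeric payload in %s", path))
  }
  payload <- if (is.null(dim(payload))) as.array(payload) else payload
  nd <- length(dim(payload))
  if (nd > 3) abort(sprintf("sweep array has %d axes; at most 3 supported", nd))
  if (nd < 2) abort("sweep array must have 2 or 3 axes")
  layout <- match.arg(layout, c("samples", "channels", "sweeps"), several.ok = TRUE)
  if (nd == 2) {
    want <- setdiff(c("samples", "sweeps"), character(0))
    if (length(layout) == 3) layout <- c("samples", "sweeps")
    if (length(layout) != 2 || !setequal(layout, want)) {
      abort("layout for 2-axis data must be a permutation of samples, sweeps")
    }
    payload <- aperm(payload, match(want, layout))
    dim(payload) <- c(dim(payload)[1], 1L, dim(payload)[2])
  } else {
    want <- c("samples", "channels", "sweeps")
    if (length(layout) != 3 || !setequal(layout, want)) {
      abort("layout for 3-axis data must be a permutation of samples, channels, sweeps")
    }
    payload <- aperm(payload, match(want, layout))
  }
  if (is_native) {
    mep_session(
      payload,
      sampling_rate_hz = parsed$sampling_rate_hz,
      stim_intensities = parsed$stim_intensities,
      trials_per_stim = parsed$trials_per_stim,
      channel_labels = parsed$channel_labels,
      session_id = if (is.null(parsed$session_id)) 1L else parsed$session_id
    )
  } else {
    mep_session(payload)
  }
}

#' Record and master manifests
#'
#' Records and masters are stored as small JSON manifests that reference
#' session containers by path (relative paths are resolved against the
#' manifest's directory on read). Manifests are plain text and diff
#' cleanly, which makes the annotation step reviewable.
#'
#' @param record An [build_record()] whose sessions are referenced by path.
#' @param path Manifest file path.
#' @return `path` invisibly for writers; the reconstructed object for
#'   readers.
#' @name manifests
NULL

#' @rdname manifests
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "mep_record"))
  if (!"path" %in% names(record$sessions)) {
    abort("record sessions must be path references; write_session() them first")
  }
  doc <- list(
    format = "mepkit-record",
    version = 1L,
    subject_id = record$subject_id,
    sessions = lapply(seq_len(nrow(record$sessions)), function(i) {
      list(
        session_id = record$sessions$session_id[i],
        condition = record$sessions$condition[i],
        path = record$sessions$path[i]
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname manifests
#' @export
read_record <- function(path) {
  if (!file.exists(path)) abort(sprintf("record manifest does not exist: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mepkit-record")) {
    abort(sprintf("not a record manifest: %s", path))
  }
  paths <- vapply(doc$sessions, function(s) s$path, character(1))
  conditions <- vapply(doc$sessions, function(s) s$condition, character(1))
  rec <- build_record(doc$subject_id, paths, conditions)
  rec$sessions$session_id <- vapply(doc$sessions, function(s) as.integer(s$session_id), integer(1))
  attr(rec, "base_dir") <- dirname(path)
  rec
}

#' @rdname manifests
#' @param record_paths Character vector of record manifest paths.
#' @export
write_master <- function(record_paths, path) {
  records <- lapply(record_paths, read_record)
  build_master(records) # validates the equal-session-count rule
  base <- dirname(path)
  rel <- vapply(record_paths, function(p) {
    if (startsWith(normalizePath(p, mustWork = FALSE), normalizePath(base, mustWork = FALSE))) {
      sub(paste0("^", normalizePath(base, mustWork = FALSE), "/?"), "",
        normalizePath(p, mustWork = FALSE)
      )
    } else {
      p
    }
  }, character(1))
  doc <- list(format = "mepkit-master", version = 1L, records = as.list(unname(rel)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname manifests
#' @export
read_master <- function(path) {
  if (!file.exists(path)) abort(sprintf("master manifest does not exist: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "mepkit-master")) {
    abort(sprintf("not a master manifest: %s", path))
  }
  base <- dirname(path)
  records <- lapply(doc$records, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_record(full)
  })
  build_master(records)
}

## ---- results bundle -----------------------------------------------------

#' Assemble a results bundle
#'
#' The results bundle mirrors every stage of the processing pipeline for
#' full data transparency: per session the analysis window, channel,
#' filtering flag, sampling rate, annotation, the unprocessed segmented
#' epochs, per-trial and per-intensity quantified values, and the fitted
#' curve (parameters, error, tolerance, dense samples); per analysis the
#' metric types, cutoffs and the group means with standard errors. A bundle
#' missing its per-intensity means (or with means inconsistent with the
#' annotation) is refused — downstream consumers rely on completeness.
#'
#' @param sessions List of per-session entries; see [session_entry()].
#' @param analyses Optional list with `metric_types`, `cutoffs` and `bars`
#'   (a named list of group-summary data frames).
#' @return An object of class `results_bundle`.
#' @export
results_bundle <- function(sessions, analyses = NULL) {
  if (length(sessions) < 1) abort("a results bundle needs at least one session entry")
  for (s in sessions) {
    need <- c(
      "subject", "condition", "start_msec", "end_msec", "analysis_channel",
      "filtered", "sampling_freq", "stim_range", "trials_per_stim",
      "segmented_epochs", "quantified", "mean_quantified", "metric"
    )
    miss <- setdiff(need, names(s))
    if (length(miss) > 0) {
      abort(sprintf("partial bundle: session entry missing %s", paste(miss, collapse = ", ")))
    }
    if (length(s$mean_quantified) != length(s$stim_range)) {
      abort("partial bundle: per-intensity means do not match the stimulation range")
    }
    if (!is.null(s$curve_fit)) {
      rng <- range(s$curve_fit$rec_curve_x)
      if (abs(rng[1] - min(s$stim_range)) > 1e-9 || abs(rng[2] - max(s$stim_range)) > 1e-9) {
        abort("curve samples must span the session's intensity range")
      }
    }
  }
  structure(list(sessions = sessions, analyses = analyses), class = "results_bundle")
}

#' Build one per-session bundle entry
#'
#' Convenience constructor collecting the products of one session's
#' processing into the field layout used by [results_bundle()].
#'
#' @param session The (possibly filtered) [mep_session()].
#' @param quantified Its [quantify_session()] result.
#' @param curve Its [fit_recruitment()] result, or `NULL` (e.g. latency).
#' @param subject,condition Labels.
#' @param filtered Whether filtering was applied.
#' @return A list suitable for [results_bundle()].
#' @export
session_entry <- function(session, quantified, curve = NULL,
                          subject = "", condition = "", filtered = FALSE) {
  ep <- extract_epochs(session, quantified$epoch)
  seg <- do.call(cbind, ep$epoch)
  list(
    subject = subject,
    condition = condition,
    session_id = session$session_id,
    start_msec = quantified$epoch$start_ms,
    end_msec = quantified$epoch$stop_ms,
    analysis_channel = quantified$epoch$channel_index,
    filtered = isTRUE(filtered),
    sampling_freq = session$sampling_rate_hz,
    stim_range = session$stim_intensities,
    trials_per_stim = session$trials_per_stim,
    segmented_epochs = seg,
    quantified = as.data.frame(quantified$per_trial),
    mean_quantified = quantified$per_intensity$mean_value,
    metric = quantified$metric,
    curve_fit = if (is.null(curve)) {
      NULL
    } else {
      list(
        parameters = unlist(curve$params),
        error = curve$fit_error,
        tolerance = curve$tolerance_used,
        r_squared = curve$r_squared,
        saturated = curve$saturated,
        iterations = curve$iterations,
        rec_curve_x = curve$x_dense,
        rec_curve_y = curve$y_dense
      )
    }
  )
}

#' Export a results bundle to disk
#'
#' Writes the bundle as a full-precision JSON document (the round trip
#' through [read_results()] reproduces every numeric field exactly) and,
#' optionally, as flat CSV tables: per-trial values, per-intensity means
#' (one row per intensity), dense curve samples and group bar data.
#'
#' @param bundle A [results_bundle()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "csv")`.
#' @return Named character vector of the files written, invisibly.
#' @export
export_results <- function(bundle, dir, formats = c("json", "csv")) {
  stopifnot(inherits(bundle, "results_bundle"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("json" %in% formats) {
    doc <- bundle
    doc$sessions <- lapply(doc$sessions, function(s) {
      s$segmented_epochs <- pack_array(as.matrix(s$segmented_epochs))
      s
    })
    p <- file.path(dir, "results.json")
    jsonlite::write_json(unclass(doc), p,
      auto_unbox = TRUE, digits = I(17), null = "null", na = "null"
    )
    written["json"] <- p
  }
  if ("csv" %in% formats) {
    per_trial <- dplyr::bind_rows(lapply(bundle$sessions, function(s) {
      dplyr::mutate(as_tibble(s$quantified),
        subject = s$subject, condition = s$condition, .before = 1
      )
    }))
    per_intensity <- dplyr::bind_rows(lapply(bundle$sessions, function(s) {
      tibble(
        subject = s$subject, condition = s$condition, metric = s$metric,
        intensity = s$stim_range, n_trials = s$trials_per_stim,
        mean_value = s$mean_quantified
      )
    }))
    curves <- dplyr::bind_rows(lapply(
      Filter(function(s) !is.null(s$curve_fit), bundle$sessions),
      function(s) {
        tibble(
          subject = s$subject, condition = s$condition,
          x = s$curve_fit$rec_curve_x, y = s$curve_fit$rec_curve_y
        )
      }
    ))
    readr::write_csv(per_trial, file.path(dir, "per_trial.csv"))
    readr::write_csv(per_intensity, file.path(dir, "per_intensity.csv"))
    written["per_trial"] <- file.path(dir, "per_trial.csv")
    written["per_intensity"] <- file.path(dir, "per_intensity.csv")
    if (nrow(curves) > 0) {
      readr::write_csv(curves, file.path(dir, "curves.csv"))
      written["curves"] <- file.path(dir, "curves.csv")
    }
    if (!is.null(bundle$analyses)) {
      bars <- dplyr::bind_rows(lapply(names(bundle$analyses$bars), function(m) {
        dplyr::mutate(as_tibble(bundle$analyses$bars[[m]]), metric = m, .before = 1)
      }))
      readr::write_csv(bars, file.path(dir, "bars.csv"))
      written["bars"] <- file.path(dir, "bars.csv")
    }
  }
  invisible(written)
}

#' @rdname export_results
#' @param path Path to a `results.json` written by [export_results()].
#' @export
read_results <- function(path) {
  # fromJSON simplification of a heterogeneous session list is unreliable;
  # read without simplification and rebuild field by field
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sessions <- lapply(raw$sessions, function(s) {
    s$stim_range <- as.numeric(unlist(s$stim_range))
    s$trials_per_stim <- as.integer(unlist(s$trials_per_stim))
    s$mean_quantified <- as.numeric(unlist(s$mean_quantified))
    s$segmented_epochs <- unpack_array(s$segmented_epochs)
    q <- s$quantified
    s$quantified <- data.frame(
      intensity_idx = as.integer(unlist(lapply(q, `[[`, "intensity_idx"))),
      intensity = as.numeric(unlist(lapply(q, `[[`, "intensity"))),
      trial = as.integer(unlist(lapply(q, `[[`, "trial"))),
      value = as.numeric(unlist(lapply(q, function(r) {
        if (is.null(r$value)) NA_real_ else r$value
      })))
    )
    if (!is.null(s$curve_fit)) {
      cf <- s$curve_fit
      cf$parameters <- unlist(cf$parameters)
      cf$rec_curve_x <- as.numeric(unlist(cf$rec_curve_x))
      cf$rec_curve_y <- as.numeric(unlist(cf$rec_curve_y))
      s$curve_fit <- cf
    }
    s
  })
  analyses <- raw$analyses
  if (!is.null(analyses)) {
    analyses$metric_types <- as.character(unlist(analyses$metric_types))
    analyses$cutoffs <- as.numeric(unlist(analyses$cutoffs))
    analyses$bars <- lapply(analyses$bars, function(b) {
      data.frame(
        condition = as.character(unlist(lapply(b, `[[`, "condition"))),
        n = as.integer(unlist(lapply(b, `[[`, "n"))),
        mean = as.numeric(unlist(lapply(b, function(r) if (is.null(r$mean)) NA_real_ else r$mean))),
        se = as.numeric(unlist(lapply(b, function(r) if (is.null(r$se)) NA_real_ else r$se))),
        n_undefined = as.integer(unlist(lapply(b, `[[`, "n_undefined")))
      )
    })
  }
  results_bundle(sessions, analyses)
}
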