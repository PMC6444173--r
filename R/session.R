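#' Construct an MEP recording session
#'
#' A session holds every sweep recorded while building one recruitment curve
#' under a single experimental condition. Sweeps are stored in canonical
#' `[samples x channels x sweeps]` order; a 2-D matrix is treated as a
#' single-channel session. Annotation (stimulation intensities, trials per
#' intensity, sampling rate) can be supplied here or attached later with
#' [annotate_session()] — e.g. when sweeps are first loaded from a container
#' file that carries no annotation.
#'
#' Sweeps are assumed to be ordered by ascending stimulation intensity, with
#' the trials of each intensity contiguous; [reorder_by_intensity()] restores
#' that order for randomized acquisitions.
#'
#' @param sweeps Numeric array `[samples x channels x sweeps]` (or a
#'   `[samples x sweeps]` matrix for one channel), amplitudes in signal units
#'   (e.g. mV).
#' @param sampling_rate_hz Sampling rate in Hz (positive), or `NULL` if not
#'   yet annotated.
#' @param stim_intensities Strictly ascending stimulation intensities
#'   (device units, e.g. mA), or `NULL`.
#' @param trials_per_stim Positive integer count of trials at each intensity;
#'   must sum to the number of sweeps. Counts may differ between intensities.
#' @param channel_labels Optional character labels, one per channel.
#' @param session_id Integer label, unique within a record.
#' @return An object of class `mep_session`.
#' @export
mep_session <- function(sweeps, sampling_rate_hz = NULL, stim_intensities = NULL,
                        trials_per_stim = NULL, channel_labels = NULL,
                        session_id = 1L) {
  if (!is.numeric(sweeps)) abort("sweeps must be numeric")
  if (is.matrix(sweeps)) dim(sweeps) <- c(nrow(sweeps), 1L, ncol(sweeps))
  if (length(dim(sweeps)) != 3) abort("sweeps must have 2 or 3 axes")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(sweeps)[2]))
  x <- structure(
    list(
      sweeps = sweeps,
      sampling_rate_hz = sampling_rate_hz,
      stim_intensities = stim_intensities,
      trials_per_stim = trials_per_stim,
      channel_labels = as.character(channel_labels),
      session_id = as.integer(session_id)
    ),
    class = "mep_session"
  )
  validate_session(x)
}

#' @export
print.mep_session <- function(x, ...) {
  d <- dim(x$sweeps)
  cat(sprintf(
    "<mep_session %d> %d samples x %d channel%s x %d sweeps\n",
    x$session_id, d[1], d[2], if (d[2] == 1) "" else "s", d[3]
  ))
  if (is_annotated(x)) {
    cat(sprintf(
      "  fs %g Hz | %d intensities [%g..%g] | trials per intensity: %s\n",
      x$sampling_rate_hz, length(x$stim_intensities),
      min(x$stim_intensities), max(x$stim_intensities),
      paste(x$trials_per_stim, collapse = ",")
    ))
  } else {
    cat("  (unannotated)\n")
  }
  invisible(x)
}

is_annotated <- function(session) {
  !is.null(session$stim_intensities) && !is.null(session$trials_per_stim) &&
    !is.null(session$sampling_rate_hz)
}

# invariant checks; run after every construction/mutation
validate_session <- function(session) {
  d <- dim(session$sweeps)
  if (length(session$channel_labels) != d[2]) {
    abort("channel_labels must have one entry per channel")
  }
  fs <- session$sampling_rate_hz
  if (!is.null(fs) && (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)) {
    abort("sampling_rate_hz must be a positive number")
  }
  si <- session$stim_intensities
  tp <- session$trials_per_stim
  if (xor(is.null(si), is.null(tp))) {
    abort("stim_intensities and trials_per_stim must be annotated together")
  }
  if (!is.null(si)) {
    if (length(si) != length(tp)) {
      abort("stim_intensities and trials_per_stim must have the same length")
    }
    if (length(si) == 0) abort("annotation must list at least one intensity")
    if (is.unsorted(si, strictly = TRUE)) {
      abort("stim_intensities must be strictly ascending (see reorder_by_intensity)")
    }
    if (any(tp < 1) || any(tp != round(tp))) {
      abort("trials_per_stim must be positive integers")
    }
    if (sum(tp) != d[3]) {
      abort(sprintf(
        "annotation/sweep mismatch: trials_per_stim sums to %d but the session has %d sweeps",
        sum(tp), d[3]
      ))
    }
  }
  session
}

#' Attach annotation to a session
#'
#' Recording systems export raw sweeps without stimulus metadata; annotation
#' supplies the ascending stimulation intensities, the number of trials
#' recorded at each intensity, and the sampling rate. The trial counts must
#' account for every sweep (e.g. 6 intensities x 10 trials for a 60-sweep
#' session) and may differ between intensities.
#'
#' @param session An [mep_session()].
#' @param intensities Strictly ascending stimulation intensities.
#' @param trials Positive integer trial counts, one per intensity.
#' @param fs Sampling rate in Hz.
#' @return The annotated session.
#' @export
annotate_session <- function(session, intensities, trials, fs) {
  stopifnot(inherits(session, "mep_session"))
  if (length(intensities) != length(trials)) {
    abort("intensities and trials must have the same length")
  }
  session$stim_intensities <- as.numeric(intensities)
  session$trials_per_stim <- as.integer(trials)
  session$sampling_rate_hz <- as.numeric(fs)
  validate_session(session)
}

# first sweep index (1-based) of each intensity block, plus one past the end
sweep_offsets <- function(trials_per_stim) {
  cumsum(c(1L, as.integer(trials_per_stim)))
}

# global sweep index for (intensity_idx, trial)
sweep_index <- function(session, intensity_idx, trial) {
  tp <- session$trials_per_stim
  if (any(intensity_idx < 1 | intensity_idx > length(tp))) {
    abort("intensity index out of range")
  }
  if (any(trial < 1 | trial > tp[intensity_idx])) {
    abort("trial index out of range for its intensity")
  }
  sweep_offsets(tp)[intensity_idx] + trial - 1L
}

#' Reorder randomized sweeps into ascending intensity order
#'
#' When stimulation intensities were randomized during acquisition, each
#' sweep carries its own intensity label. This stably sorts the sweeps into
#' ascending label order (ties keep acquisition order), rebuilds the
#' annotation from the label multiplicities, and preserves every sweep's
#' content — the operation is a pure permutation, and applying it twice is a
#' no-op.
#'
#' @param session An [mep_session()].
#' @param per_sweep_labels One stimulation intensity per sweep.
#' @return The session with sweeps sorted and annotation rebuilt. The
#'   sampling rate is kept as-is (annotate it separately if absent).
#' @export
reorder_by_intensity <- function(session, per_sweep_labels) {
  stopifnot(inherits(session, "mep_session"))
  n_sweeps <- dim(session$sweeps)[3]
  if (length(per_sweep_labels) != n_sweeps) {
    abort(sprintf(
      "expected one label per sweep (%d), got %d",
      n_sweeps, length(per_sweep_labels)
    ))
  }
  labels <- as.numeric(per_sweep_labels)
  perm <- order(labels) # stable
  session$sweeps <- session$sweeps[, , perm, drop = FALSE]
  lvl <- sort(unique(labels))
  session$stim_intensities <- lvl
  session$trials_per_stim <- as.integer(vapply(lvl, function(v) sum(labels == v), numeric(1)))
  validate_session(session)
}

#' Remove flagged trials from a session
#'
#' Drops sweeps flagged as artifacts (screening is always manual or
#' advisory; see [suggest_outliers()]). Whole sweeps are removed across all
#' channels, trial counts are decremented, and downstream per-intensity means
#' exclude the removed trials. Removing every trial of an intensity is
#' refused, since the recruitment curve would lose that point entirely.
#'
#' @param session An annotated [mep_session()].
#' @param flagged A data frame with columns `intensity_idx` and `trial`
#'   (1-based indices, as returned by [suggest_outliers()]), or `NULL` /
#'   zero rows for a no-op.
#' @return The session with flagged sweeps removed.
#' @export
remove_trials <- function(session, flagged) {
  stopifnot(inherits(session, "mep_session"))
  if (!is_annotated(session)) abort("session must be annotated before trial removal")
  if (is.null(flagged) || nrow(as.data.frame(flagged)) == 0) {
    return(session)
  }
  flagged <- as.data.frame(flagged)
  if (!all(c("intensity_idx", "trial") %in% names(flagged))) {
    abort("flagged must have columns intensity_idx and trial")
  }
  flagged <- unique(flagged[, c("intensity_idx", "trial")])
  idx <- sweep_index(session, flagged$intensity_idx, flagged$trial)
  removed_per_int <- table(factor(flagged$intensity_idx,
    levels = seq_along(session$trials_per_stim)
  ))
  new_trials <- session$trials_per_stim - as.integer(removed_per_int)
  if (any(new_trials < 1)) {
    abort(sprintf(
      "intensity left empty: removing all trials at intensity index %s",
      paste(which(new_trials < 1), collapse = ", ")
    ))
  }
  session$sweeps <- session$sweeps[, , -idx, drop = FALSE]
  session$trials_per_stim <- new_trials
  validate_session(session)
}

#' Group sessions into a per-subject record
#'
#' A record collects every recruitment-curve session of one subject. The
#' first session is always the baseline (control) condition against which
#' the others are compared, so order matters.
#'
#' @param subject_id Subject identifier (string).
#' @param sessions List of [mep_session()] objects, or character paths to
#'   session container files (see [write_session()]); the baseline session
#'   first.
#' @param conditions Character condition labels, one per session.
#' @return An object of class `mep_record`.
#' @export
build_record <- function(subject_id, sessions, conditions) {
  if (length(sessions) < 1) abort("a record needs at least one session")
  if (length(conditions) != length(sessions)) {
    abort("conditions must have one label per session")
  }
  by_path <- is.character(sessions)
  if (by_path) {
    ids <- seq_along(sessions)
    tbl <- tibble(
      session_id = as.integer(ids),
      condition = as.character(conditions),
      path = as.character(sessions)
    )
  } else {
    if (!all(vapply(sessions, inherits, logical(1), "mep_session"))) {
      abort("sessions must be mep_session objects or file paths")
    }
    ids <- vapply(sessions, function(s) s$session_id, integer(1))
    tbl <- tibble(
      session_id = ids,
      condition = as.character(conditions),
      session = sessions
    )
  }
  if (anyDuplicated(ids)) abort("session ids must be unique within a record")
  structure(
    list(subject_id = as.character(subject_id), sessions = tbl, baseline_index = 1L),
    class = "mep_record"
  )
}

#' Group records into a master
#'
#' A master file collects the records of several subjects that share the
#' same sequence of experimental conditions, enabling cross-subject
#' aggregation. Every record must contain the same number of sessions.
#'
#' @param records List of [build_record()] objects.
#' @return An object of class `mep_master` with shared `condition_labels`.
#' @export
build_master <- function(records) {
  if (length(records) < 1) abort("a master needs at least one record")
  if (!all(vapply(records, inherits, logical(1), "mep_record"))) {
    abort("records must be mep_record objects")
  }
  counts <- vapply(records, function(r) nrow(r$sessions), integer(1))
  if (length(unique(counts)) != 1) {
    abort(sprintf(
      "every record must have the same number of sessions (got %s)",
      paste(counts, collapse = ", ")
    ))
  }
  structure(
    list(records = records, condition_labels = records[[1]]$sessions$condition),
    class = "mep_master"
  )
}

#' @export
print.mep_record <- function(x, ...) {
  cat(sprintf(
    "<mep_record %s> %d session(s), baseline = %s\n",
    x$subject_id, nrow(x$sessions), x$sessions$condition[1]
  ))
  invisible(x)
}

#' @export
print.mep_master <- function(x, ...) {
  cat(sprintf(
    "<mep_master> %d record(s) x %d condition(s): %s\n",
    length(x$records), length(x$condition_labels),
    paste(x$condition_labels, collapse = ", ")
  ))
  invisible(x)
}
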