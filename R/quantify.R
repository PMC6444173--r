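#' MEP epoch metrics
#'
#' Scalar quantifications of a single MEP epoch, the uniformly sampled
#' amplitude trace `f(t)` extracted by [extract_epochs()]:
#'
#' * `mep_auc()` — area under the rectified epoch,
#'   \eqn{\int_a^b |f(t)|\,dt}, by the trapezoidal rule (signal units x
#'   seconds);
#' * `mep_rms()` — root-mean-square amplitude,
#'   \eqn{\sqrt{\frac{1}{T_2 - T_1}\int_{T_1}^{T_2} f(t)^2\,dt}}, with the
#'   integral also discretized by the trapezoidal rule so that the classic
#'   relation RMS >= AUC / duration holds exactly (equality only for
#'   constant-magnitude signals);
#' * `mep_p2p()` — peak-to-peak amplitude `max(f) - min(f)` of the raw
#'   (unrectified) epoch, invariant to any additive offset;
#' * `mep_latency()` — response onset delay, in ms from the start of the
#'   epoch (i.e. from the end of stimulation when the window starts there):
#'   the first time the rectified trace reaches
#'   `baseline + threshold_pct/100 * (max|f| - baseline)`, where the
#'   baseline is the mean rectified amplitude over the leading
#'   `baseline_ms` window. Returns `NA` if the threshold is never crossed.
#'   The rectified trace is used so negative-going onsets are detected.
#'
#' @param x Numeric epoch (at least 2 samples, uniform sampling).
#' @param fs Sampling rate in Hz.
#' @param threshold_pct Percentage (0, 100] of the baseline-to-maximum span.
#' @param baseline_ms Leading window used to estimate the baseline (default
#'   2 ms; must be shorter than the epoch, 0 uses the first sample).
#' @return A scalar; `mep_latency()` may return `NA`.
#' @name mep_metrics
NULL

trapz <- function(v, dt) dt * sum((v[-length(v)] + v[-1]) / 2)

check_epoch <- function(x) {
  if (length(x) < 2) abort("an epoch needs at least 2 samples")
  if (!all(is.finite(x))) abort("epoch contains non-finite values")
}

#' @rdname mep_metrics
#' @export
mep_auc <- function(x, fs) {
  check_epoch(x)
  trapz(abs(x), 1 / fs)
}

#' @rdname mep_metrics
#' @export
mep_rms <- function(x, fs) {
  check_epoch(x)
  duration <- (length(x) - 1) / fs
  sqrt(trapz(x^2, 1 / fs) / duration)
}

#' @rdname mep_metrics
#' @export
mep_p2p <- function(x) {
  check_epoch(x)
  max(x) - min(x)
}

#' @rdname mep_metrics
#' @export
mep_latency <- function(x, fs, threshold_pct = 20, baseline_ms = 2) {
  check_epoch(x)
  if (!is.finite(threshold_pct) || threshold_pct <= 0 || threshold_pct > 100) {
    abort("threshold_pct must be in (0, 100]")
  }
  if (baseline_ms < 0 || baseline_ms >= (length(x) - 1) / fs * 1000) {
    abort("baseline window must be non-negative and shorter than the epoch")
  }
  r <- abs(x)
  n_base <- max(1L, as.integer(floor(baseline_ms / 1000 * fs)))
  base <- mean(r[seq_len(n_base)])
  threshold <- base + threshold_pct / 100 * (max(r) - base)
  hit <- which(r >= threshold)
  if (length(hit) == 0) {
    return(NA_real_)
  }
  (hit[1] - 1) / fs * 1000
}

#' Quantify every trial of a session
#'
#' Applies one MEP metric to the extracted epoch of every surviving sweep
#' and averages the per-trial values within each stimulation intensity.
#' Means are plain arithmetic means over the surviving trials; undefined
#' latencies (`NA`, threshold never crossed) are excluded from the means and
#' counted.
#'
#' @param session An annotated [mep_session()] (filter it first with
#'   [filter_session()] if desired).
#' @param spec An [epoch_spec()].
#' @param metric One of `"auc"`, `"rms"`, `"p2p"`, `"latency"`.
#' @param latency_pct,baseline_ms Passed to [mep_latency()] when
#'   `metric = "latency"`.
#' @return An object of class `mep_quantified` with tibbles `per_trial`
#'   (`intensity_idx`, `intensity`, `trial`, `value`) and `per_intensity`
#'   (`intensity`, `n_trials`, `n_undefined`, `mean_value`).
#' @examples
#' s <- generate_session(synth_truth(), seed = 1)$session
#' q <- quantify_session(s, epoch_spec(4, 24), metric = "p2p")
#' q$per_intensity
#' @export
quantify_session <- function(session, spec = epoch_spec(),
                             metric = c("auc", "rms", "p2p", "latency"),
                             latency_pct = 20, baseline_ms = 2) {
  metric <- match.arg(metric)
  ep <- extract_epochs(session, spec)
  fs <- attr(ep, "fs")
  f <- switch(metric,
    auc = function(v) mep_auc(v, fs),
    rms = function(v) mep_rms(v, fs),
    p2p = mep_p2p,
    latency = function(v) mep_latency(v, fs, latency_pct, baseline_ms)
  )
  per_trial <- dplyr::mutate(
    ep[, c("intensity_idx", "intensity", "trial")],
    value = vapply(ep$epoch, f, numeric(1))
  )
  per_intensity <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$intensity_idx, .data$intensity),
    n_trials = dplyr::n(),
    n_undefined = sum(is.na(.data$value)),
    mean_value = mean(.data$value, na.rm = TRUE),
    .groups = "drop"
  )
  per_intensity$mean_value[is.nan(per_intensity$mean_value)] <- NA_real_
  structure(
    list(
      metric = metric,
      per_trial = per_trial,
      per_intensity = per_intensity[, c("intensity", "n_trials", "n_undefined", "mean_value")],
      stim_intensities = session$stim_intensities,
      sampling_rate_hz = fs,
      session_id = session$session_id,
      epoch = spec,
      latency_pct = if (metric == "latency") latency_pct else NA_real_,
      baseline_ms = if (metric == "latency") baseline_ms else NA_real_
    ),
    class = "mep_quantified"
  )
}

#' @export
print.mep_quantified <- function(x, ...) {
  cat(sprintf(
    "<mep_quantified session %d> metric %s | %d trials over %d intensities\n",
    x$session_id, x$metric, nrow(x$per_trial), length(x$stim_intensities)
  ))
  print(x$per_intensity)
  invisible(x)
}

#' @describeIn quantify_session Per-trial values as a tibble.
#' @param x,object An `mep_quantified`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mep_quantified <- function(x, ...) x$per_trial

#' @describeIn quantify_session One-row session summary.
#' @exportS3Method generics::glance
glance.mep_quantified <- function(x, ...) {
  tibble(
    metric = x$metric,
    n_intensities = length(x$stim_intensities),
    n_trials = nrow(x$per_trial),
    n_undefined = sum(is.na(x$per_trial$value)),
    fs = x$sampling_rate_hz
  )
}
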