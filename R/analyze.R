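#' Bundle fitted curves for cross-condition comparison
#'
#' Groups the fitted recruitment curves of one record: the baseline curve
#' (the record's first session) plus the curves of the other conditions.
#'
#' @param baseline The baseline [fit_recruitment()] curve.
#' @param conditions List of `recruitment_curve` objects for the other
#'   conditions (possibly empty).
#' @param labels Condition labels; defaults to `names(conditions)` or
#'   `"condition 1"`, `"condition 2"`, ...
#' @param baseline_label Label for the baseline condition.
#' @return An object of class `mep_curve_set`.
#' @export
curve_set <- function(baseline, conditions = list(), labels = NULL,
                      baseline_label = "baseline") {
  stopifnot(inherits(baseline, "recruitment_curve"))
  if (inherits(conditions, "recruitment_curve")) conditions <- list(conditions)
  if (!all(vapply(conditions, inherits, logical(1), "recruitment_curve"))) {
    abort("conditions must be recruitment_curve objects")
  }
  if (is.null(labels)) {
    labels <- names(conditions)
    if (is.null(labels) || any(labels == "")) {
      labels <- paste("condition", seq_along(conditions))
    }
  }
  if (length(labels) != length(conditions)) {
    abort("labels must have one entry per condition curve")
  }
  structure(
    list(
      baseline = baseline, conditions = conditions,
      labels = as.character(labels), baseline_label = as.character(baseline_label)
    ),
    class = "mep_curve_set"
  )
}

new_metric_result <- function(tbl, metric_type, cutoff_pct = NA_real_) {
  structure(
    tbl,
    metric_type = metric_type,
    cutoff_pct = cutoff_pct,
    class = c("mep_metric_result", class(tbl))
  )
}

#' MEP metric: vertical cut through the curves
#'
#' Compares MEP magnitudes at a fixed stimulation intensity. The cut is
#' anchored on the baseline: `m_pct`% of the baseline's upper asymptote
#' defines a target response, the baseline curve is inverted to find the
#' intensity `Stim_M` that elicits it, and every curve is then evaluated at
#' that same intensity. Values are reported as percent of the baseline
#' response (baseline = 100); use `as_change = TRUE` for percent change
#' (baseline = 0) instead.
#'
#' @param curves A [curve_set()].
#' @param m_pct Vertical cut percentage, strictly between 0 and 100
#'   (default 50, the "MEP50" metric).
#' @param as_change Report `value - 100` instead of percent-of-baseline.
#' @return A `mep_metric_result` tibble: `condition`, `raw` (response in
#'   metric units), `normalized` (percent of baseline), with the cut
#'   intensity in attribute `stim_ref`.
#' @export
mep_metric <- function(curves, m_pct = 50, as_change = FALSE) {
  stopifnot(inherits(curves, "mep_curve_set"))
  if (!is.finite(m_pct) || m_pct <= 0 || m_pct >= 100) {
    abort("m_pct must be strictly between 0 and 100")
  }
  b <- curves$baseline$params
  target <- m_pct / 100 * b$M
  stim_m <- invert_sigmoid(b, target) # errors if outside the open range
  base_val <- sigmoid_eval(b, stim_m)
  cond_vals <- vapply(
    curves$conditions,
    function(cv) sigmoid_eval(cv$params, stim_m), numeric(1)
  )
  all_vals <- c(base_val, cond_vals)
  tbl <- tibble(
    condition = c(curves$baseline_label, curves$labels),
    raw = all_vals,
    normalized = 100 * all_vals / base_val
  )
  if (as_change) tbl$normalized <- tbl$normalized - 100
  out <- new_metric_result(tbl, "MEP", m_pct)
  attr(out, "stim_ref") <- stim_m
  out
}

#' Stimulation metric: horizontal cut through the curves
#'
#' Compares the stimulation intensities needed to elicit a fixed MEP
#' magnitude. The reference intensity is `s_pct`% of the baseline session's
#' maximum intensity; the baseline response at that intensity (`MEP_S`)
#' defines the horizontal cut, and each condition curve is inverted to find
#' the intensity at which it reaches `MEP_S`. Intensities are reported as
#' percent of the reference (baseline = 100). A condition whose curve never
#' attains `MEP_S` (e.g. its upper asymptote lies below the cut) gets an
#' `NA` marker and a warning rather than an error, so group summaries
#' degrade gracefully.
#'
#' @inheritParams mep_metric
#' @param s_pct Percent of the baseline's maximum intensity, in (0, 100]
#'   (default 50, the "Stim50" metric).
#' @return A `mep_metric_result` tibble: `condition`, `raw` (intensity),
#'   `normalized`, with the cut response in attribute `mep_ref`.
#' @export
stim_metric <- function(curves, s_pct = 50, as_change = FALSE) {
  stopifnot(inherits(curves, "mep_curve_set"))
  if (!is.finite(s_pct) || s_pct <= 0 || s_pct > 100) {
    abort("s_pct must be in (0, 100]")
  }
  b <- curves$baseline
  stim_ref <- s_pct / 100 * max(b$x_dense)
  mep_s <- sigmoid_eval(b$params, stim_ref)
  invert_or_na <- function(cv, label) {
    tryCatch(invert_sigmoid(cv$params, mep_s),
      mepkit_out_of_range = function(e) {
        warn(sprintf(
          "condition '%s' cannot attain the reference MEP (%.4g); marked undefined",
          label, mep_s
        ), class = "mepkit_unattainable")
        NA_real_
      }
    )
  }
  raw <- c(
    stim_ref,
    unlist(Map(invert_or_na, curves$conditions, curves$labels))
  )
  tbl <- tibble(
    condition = c(curves$baseline_label, curves$labels),
    raw = raw,
    normalized = 100 * raw / stim_ref
  )
  if (as_change) tbl$normalized <- tbl$normalized - 100
  out <- new_metric_result(tbl, "STIM", s_pct)
  attr(out, "mep_ref") <- mep_s
  out
}

# regression slope over the near-linear mid-segment of a fitted curve: the
# maximal contiguous dense-grid run (containing the steepest point) where the
# numerical derivative is at least `frac` of its maximum
linear_portion_slope <- function(curve, frac = 0.9) {
  dx <- diff(curve$x_dense)
  dy <- diff(curve$y_dense)
  d <- dy / dx
  d_max <- max(abs(d))
  if (d_max == 0) {
    return(0)
  }
  keep <- abs(d) >= frac * d_max
  i_peak <- which.max(abs(d))
  lo <- i_peak
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- i_peak
  while (hi < length(keep) && keep[hi + 1]) hi <- hi + 1
  idx <- lo:(hi + 1)
  unname(coef(lm(curve$y_dense[idx] ~ curve$x_dense[idx]))[2])
}

#' Slope metric: gain of the linear portion
#'
#' Compares how fast MEPs grow with stimulation in the steep part of each
#' curve. A smooth sigmoid has no exactly-linear segment, so the "linear
#' portion" is operationalized as the contiguous region of the dense curve
#' where the derivative stays at or above `frac` (default 90%) of its
#' maximum; the slope is the least-squares regression slope over that
#' region. In normalized mode slopes are divided by the baseline slope
#' (baseline = 1.0); a near-zero baseline slope is an error in that mode.
#'
#' @inheritParams mep_metric
#' @param normalize Divide by the baseline slope.
#' @param frac Fraction of the maximum derivative defining the linear
#'   portion.
#' @return A `mep_metric_result` tibble: `condition`, `raw` (metric units
#'   per intensity unit), `normalized` (ratio to baseline, or `NA` column
#'   if `normalize = FALSE`).
#' @export
slope_metric <- function(curves, normalize = TRUE, frac = 0.9) {
  stopifnot(inherits(curves, "mep_curve_set"))
  slopes <- c(
    linear_portion_slope(curves$baseline, frac),
    vapply(curves$conditions, linear_portion_slope, numeric(1), frac = frac)
  )
  base_slope <- slopes[1]
  if (normalize && abs(base_slope) < 1e-12) {
    abort("baseline slope is ~0; use normalize = FALSE to compare raw slopes")
  }
  tbl <- tibble(
    condition = c(curves$baseline_label, curves$labels),
    raw = slopes,
    normalized = if (normalize) slopes / base_slope else NA_real_
  )
  new_metric_result(tbl, "SLOPE")
}

#' Aggregate metric results across subjects
#'
#' Averages the normalized per-condition values of several records
#' (subjects) into group bar data: per-condition mean and standard error
#' (sample SD over the square root of the number of contributing records).
#' Undefined markers (`NA`, e.g. unattainable horizontal cuts) are excluded
#' and counted. All records must share the same condition sequence, the
#' master-file rule.
#'
#' @param results List of `mep_metric_result` objects, one per record, all
#'   from the same metric with the same conditions.
#' @return An object of class `mep_group_summary`: tibble `condition`, `n`,
#'   `mean`, `se`, `n_undefined`. With a single record the standard error is
#'   `NA`.
#' @export
group_aggregate <- function(results) {
  if (inherits(results, "mep_metric_result")) results <- list(results)
  if (length(results) < 1) abort("no metric results to aggregate")
  if (!all(vapply(results, inherits, logical(1), "mep_metric_result"))) {
    abort("results must be mep_metric_result objects")
  }
  conds <- lapply(results, function(r) r$condition)
  if (length(unique(vapply(conds, length, integer(1)))) != 1 ||
    !all(vapply(conds, identical, logical(1), conds[[1]]))) {
    abort("all records must share the same conditions (master-file rule)")
  }
  vals <- do.call(rbind, lapply(results, function(r) r$normalized))
  summarise_col <- function(v) {
    ok <- v[!is.na(v)]
    tibble(
      n = length(ok),
      mean = if (length(ok) > 0) mean(ok) else NA_real_,
      se = if (length(ok) > 1) sd(ok) / sqrt(length(ok)) else NA_real_,
      n_undefined = sum(is.na(v))
    )
  }
  out <- dplyr::bind_cols(
    tibble(condition = conds[[1]]),
    dplyr::bind_rows(lapply(seq_len(ncol(vals)), function(j) summarise_col(vals[, j])))
  )
  structure(
    out,
    metric_type = attr(results[[1]], "metric_type"),
    cutoff_pct = attr(results[[1]], "cutoff_pct"),
    class = c("mep_group_summary", class(out))
  )
}

#' @describeIn group_aggregate Bar plot of group means with standard-error bars.
#' @param object A `mep_group_summary`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mep_group_summary <- function(object, ...) {
  metric <- attr(object, "metric_type")
  cutoff <- attr(object, "cutoff_pct")
  lbl <- if (is.na(cutoff)) metric else sprintf("%s%g", metric, cutoff)
  df <- as_tibble(object)
  df$condition <- factor(df$condition, levels = df$condition)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "#74add1") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$se,
        ymax = .data$mean + .data$se
      ),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = NULL, y = sprintf("%s (%% of baseline)", lbl),
      title = sprintf("Group %s metric", lbl)
    ) +
    ggplot2::theme_minimal()
}

#' Compare mean MEPs directly, without recruitment curves
#'
#' For data that are not part of a recruitment curve (or when curve fitting
#' is not wanted), quantified MEP magnitudes are compared directly across
#' conditions: all per-trial values of each condition are pooled, and the
#' grand mean and standard error over trials are reported. No fitting is
#' involved.
#'
#' @param quantified List of [quantify_session()] results.
#' @param conditions Condition label for each quantified session (sessions
#'   sharing a label are pooled).
#' @return Tibble: `condition`, `n_trials`, `mean`, `se`.
#' @export
direct_mep_comparison <- function(quantified, conditions) {
  if (inherits(quantified, "mep_quantified")) quantified <- list(quantified)
  if (length(conditions) != length(quantified)) {
    abort("conditions must have one label per quantified session")
  }
  if (!all(vapply(quantified, inherits, logical(1), "mep_quantified"))) {
    abort("quantified must be quantify_session() results")
  }
  trials <- dplyr::bind_rows(Map(
    function(q, cond) tibble(condition = cond, value = q$per_trial$value),
    quantified, as.character(conditions)
  ))
  trials <- trials[!is.na(trials$value), ]
  out <- dplyr::summarise(
    dplyr::group_by(trials, .data$condition),
    n_trials = dplyr::n(),
    mean = mean(.data$value),
    se = if (dplyr::n() > 1) sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop"
  )
  missing <- setdiff(unique(as.character(conditions)), out$condition)
  if (length(missing) > 0) {
    abort(sprintf("condition with no trials: %s", paste(missing, collapse = ", ")))
  }
  out[match(unique(as.character(conditions)), out$condition), ]
}
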