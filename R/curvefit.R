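#' Initial estimates for recruitment-curve fitting
#'
#' Heuristic starting values for the sigmoid parameters, computed from the
#' per-intensity mean responses:
#'
#' * `P` — median of the 5 sorted response values in a window centred on the
#'   nearest-rank 5th-percentile position (window clipped at the vector ends);
#' * `M` — the symmetric estimate at the 95th percentile;
#' * `K` — mean of the two intensities whose responses are closest to
#'   `(P + M) / 2`;
#' * `L` — from the steepest discrete slope `s_max` of the data via the
#'   logistic identity (maximum derivative `= exp(L) (M - P) / 4`), i.e.
#'   `L = log(4 s_max / (M - P))`;
#' * `Q` — the response at the lowest intensity (floored at `1e-6`), held
#'   fixed during optimization.
#'
#' Flat data (`M <= P` after windowing) take a degenerate path: all level
#' parameters are set to `mean(y)` and the slope to zero, with no error.
#'
#' @param x Ascending stimulation intensities (length >= 4).
#' @param y Per-intensity mean responses, same length as `x`.
#' @param q Optional override for the fixed shape offset `Q` (e.g. `q = 1`
#'   for a standard logistic).
#' @return A list with elements `P`, `M`, `L`, `K`, `Q` and a logical
#'   `degenerate` flag.
#' @export
initial_estimates <- function(x, y, q = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (length(y) < 4) abort("at least 4 points are required to fit a recruitment curve")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite values in fit input")
  n <- length(y)
  s <- sort(y)
  pct_window <- function(centre) {
    start <- max(1L, centre - 2L)
    stop <- min(n, max(centre + 2L, start + 4L))
    s[start:stop]
  }
  P0 <- median(pct_window(max(1L, as.integer(ceiling(0.05 * n)))))
  M0 <- median(pct_window(min(n, as.integer(ceiling(0.95 * n)))))
  Q0 <- if (is.null(q)) max(y[1], 1e-6) else as.numeric(q)
  if (Q0 <= 0) abort("Q must be positive")
  if (!(M0 > P0)) {
    return(list(P = mean(y), M = mean(y), L = 0, K = mean(x), Q = Q0, degenerate = TRUE))
  }
  mid <- (P0 + M0) / 2
  K0 <- mean(x[order(abs(y - mid))[1:2]])
  s_max <- max(diff(y) / diff(x))
  L0 <- if (s_max > 0) log(4 * s_max / (M0 - P0)) else 0
  list(P = P0, M = M0, L = L0, K = K0, Q = Q0, degenerate = FALSE)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. A perfect fit gives 1. When the data are constant
#' (`SS_tot == 0`) the value is 1 if the residuals are all zero and `NA`
#' otherwise.
#'
#' @param y Observed values.
#' @param y_hat Fitted values, same length.
#' @return A scalar, at most 1, possibly `NA`.
#' @export
r_squared <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("y and y_hat must have the same length")
  if (length(y) < 2) abort("at least 2 points are required")
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    if (ss_res == 0) 1 else NA_real_
  } else {
    1 - ss_res / ss_tot
  }
}

#' Saturation check on the last three points of a recruitment curve
#'
#' A valid recruitment curve should saturate: the last three per-intensity
#' mean responses should lie nearly flat. The responses are normalized by the
#' session maximum and the intensities by the median intensity step, so the
#' test is dimensionless; a least-squares line is fitted through the last
#' three normalized points and the curve is called saturated when its slope
#' is strictly below `threshold` (default 0.2). A non-saturated result
#' raises a warning, never an error: the analysis may still proceed.
#'
#' @param x Stimulation intensities (length >= 3, ascending).
#' @param y Per-intensity mean responses.
#' @param threshold Dimensionless slope bound (strict `<`).
#' @param warn Emit a warning when the curve does not saturate.
#' @return List with `saturated` (logical) and `slope` (the normalized slope).
#' @export
saturation_check <- function(x, y, threshold = 0.2, warn = TRUE) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (length(x) < 3) abort("at least 3 points are required for the saturation check")
  y_max <- max(abs(y))
  y_n <- if (y_max > 0) y / y_max else y
  step <- median(diff(x))
  x_n <- if (is.finite(step) && step > 0) x / step else x
  n <- length(x)
  last <- (n - 2):n
  # least-squares slope in centered closed form (sum(xc) = 0, so the
  # intercept drops out); avoids spurious rounding at the 0.2 boundary
  xc <- x_n[last] - mean(x_n[last])
  slope <- sum(xc * y_n[last]) / sum(xc^2)
  saturated <- slope < threshold
  if (!saturated && warn) {
    warn(sprintf(
      "recruitment curve does not appear to saturate (last-three-point slope %.3f >= %.3f)",
      slope, threshold
    ), class = "mepkit_no_saturation")
  }
  list(saturated = saturated, slope = slope)
}

#' Fit a recruitment curve to per-intensity mean responses
#'
#' Fits the four-parameter sigmoid (see [sigmoid_eval()]) to quantified mean
#' MEP values by Nelder-Mead least squares. Fitting happens on responses
#' normalized by their range, so the procedure is exactly equivariant under
#' rescaling of `y` (`P` and `M` are mapped back to data units afterwards).
#' `Q` is fixed from the data — the range-normalized response at the lowest
#' intensity — and `P`, `M`, `L`, `K` are optimized. `Q` only sets the
#' parameterization's gauge: compare horizontal positions across fits via
#' `midpoint`, not raw `K`.
#'
#' The fit error is the scale-free root-mean-square residual,
#' `RMSE / (max(y) - min(y))` (plain RMSE for constant data). Optimization
#' proceeds in cycles: each cycle runs the Nelder-Mead simplex from the
#' current best parameters to local convergence, and after every cycle the
#' stopping rules are checked in order of precedence:
#'
#' 1. the error has fallen below `tolerance` (default 0.1) — this is also
#'    checked before the first cycle, so a very loose tolerance returns the
#'    initial estimates unchanged;
#' 2. the cycle improved the error by less than `stall_delta` (default 0.01);
#' 3. the error has not improved over `stall_iters` (default 10) consecutive
#'    cycles (the counter resets on any strict improvement).
#'
#' If the fit ends by rule 2 or 3 with error still above `tolerance`, one
#' deterministic restart is attempted from perturbed parameters
#' (`K` and `L` scaled by 1.1) and kept if it improves the error.
#'
#' After fitting, the goodness of fit (R squared) and the saturation check
#' (see [saturation_check()]) are computed on the data. Latency values do not
#' follow a sigmoidal stimulus-response profile, so fitting a quantified
#' session whose metric is `latency` is refused upstream in
#' [run_pipeline()]; this function is metric-agnostic.
#'
#' @param x Ascending stimulation intensities (length >= 4).
#' @param y Per-intensity mean responses.
#' @param tolerance Target scale-free fit error (stopping rule 1).
#' @param stall_delta Minimum per-cycle improvement (stopping rule 2).
#' @param stall_iters Consecutive non-improving cycles allowed (stopping rule 3).
#' @param q Optional fixed `Q` override (`q = 1` gives the standard logistic).
#' @param n_dense Number of points of the densely evaluated fitted curve,
#'   spanning exactly `[min(x), max(x)]`.
#' @param max_cycles Hard cap on optimization cycles.
#' @param warn Forwarded to [saturation_check()].
#' @return An object of class `recruitment_curve`: fitted `params`
#'   (`P`, `M`, `L`, `K`, `Q`), the gauge-invariant `midpoint`, dense curve
#'   samples `x_dense`/`y_dense`, `fit_error`, `r_squared`, `tolerance_used`,
#'   `saturated` and `sat_slope`, `iterations` (optimization cycles),
#'   `stall_count` at termination, the terminating `stop_rule`
#'   (`"tolerance"`, `"delta"`, `"stall"` or `"max_cycles"`), a `restarted`
#'   flag, and the input data `x`, `y`.
#' @examples
#' x <- 1:9
#' y <- sigmoid_eval(list(P = 0.1, M = 2, L = 0, K = 5, Q = 1), x)
#' fit <- fit_recruitment(x, y)
#' glance(fit)
#' @export
fit_recruitment <- function(x, y, tolerance = 0.1, stall_delta = 0.01,
                            stall_iters = 10, q = NULL, n_dense = 200,
                            max_cycles = 50, warn = TRUE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (is.unsorted(x, strictly = TRUE)) abort("stimulation intensities must be strictly ascending")
  if (!is.finite(tolerance) || tolerance < 0) abort("tolerance must be a non-negative number")
  # fit on range-normalized responses so the whole procedure (not just the
  # error) is exactly equivariant under rescaling of y; P and M are mapped
  # back to data units afterwards
  y_range <- diff(range(as.numeric(y)))
  y_scale <- if (y_range > 0) y_range else 1
  ys <- as.numeric(y) / y_scale
  est <- initial_estimates(x, ys, q = q)
  objective <- function(theta) {
    fit <- sigmoid_eval(list(P = theta[1], M = theta[2], L = theta[3], K = theta[4], Q = est$Q), x)
    sqrt(mean((ys - fit)^2))
  }
  theta <- c(est$P, est$M, est$L, est$K)
  err <- objective(theta)
  iterations <- 0L
  stall <- 0L
  restarted <- FALSE
  if (err < tolerance) {
    stop_rule <- "tolerance"
  } else {
    stop_rule <- "max_cycles"
    while (iterations < max_cycles) {
      iterations <- iterations + 1L
      opt <- optim(theta, objective,
        method = "Nelder-Mead",
        control = list(maxit = 500, reltol = 1e-10)
      )
      delta <- err - opt$value
      if (opt$value <= err) {
        theta <- opt$par
        err <- opt$value
      }
      if (err < tolerance) {
        stop_rule <- "tolerance"
        break
      }
      if (delta > 0 && delta < stall_delta) {
        stop_rule <- "delta"
        break
      }
      if (delta <= 0) {
        stall <- stall + 1L
        if (stall >= stall_iters) {
          stop_rule <- "stall"
          break
        }
      } else {
        stall <- 0L
      }
    }
    if (stop_rule %in% c("delta", "stall", "max_cycles") && err > tolerance) {
      theta2 <- theta
      theta2[3] <- theta2[3] * 1.1
      theta2[4] <- theta2[4] * 1.1
      opt <- optim(theta2, objective,
        method = "Nelder-Mead",
        control = list(maxit = 500, reltol = 1e-10)
      )
      restarted <- TRUE
      if (opt$value < err) {
        theta <- opt$par
        err <- opt$value
      }
    }
  }
  params <- list(
    P = theta[1] * y_scale, M = theta[2] * y_scale,
    L = theta[3], K = theta[4], Q = est$Q
  )
  x_dense <- seq(min(x), max(x), length.out = n_dense)
  sat <- saturation_check(x, y, warn = warn)
  out <- list(
    params = params,
    midpoint = sigmoid_midpoint(params),
    x_dense = x_dense,
    y_dense = sigmoid_eval(params, x_dense),
    fit_error = err,
    r_squared = r_squared(y, sigmoid_eval(params, x)),
    tolerance_used = tolerance,
    stall_delta = stall_delta,
    stall_iters = stall_iters,
    saturated = sat$saturated,
    sat_slope = sat$slope,
    iterations = iterations,
    stall_count = stall,
    stop_rule = stop_rule,
    restarted = restarted,
    degenerate = est$degenerate,
    x = x,
    y = y
  )
  structure(out, class = "recruitment_curve")
}

#' @export
print.recruitment_curve <- function(x, ...) {
  p <- x$params
  cat("<recruitment_curve>\n")
  cat(sprintf(
    "  P = %.4g, M = %.4g, L = %.4g, K = %.4g (Q fixed at %.4g)\n",
    p$P, p$M, p$L, p$K, p$Q
  ))
  cat(sprintf(
    "  midpoint %.4g | fit error %.4g (tolerance %.3g, stopped by %s after %d cycle%s)\n",
    x$midpoint, x$fit_error, x$tolerance_used, x$stop_rule,
    x$iterations, if (x$iterations == 1) "" else "s"
  ))
  cat(sprintf(
    "  R^2 = %.4f | %s\n", x$r_squared,
    if (x$saturated) "saturated" else sprintf("NOT saturated (slope %.3f)", x$sat_slope)
  ))
  invisible(x)
}

#' @describeIn fit_recruitment One row per fitted parameter
#'   (`term`, `estimate`, and whether the parameter was `fixed`).
#' @param x,object A `recruitment_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.recruitment_curve <- function(x, ...) {
  tibble(
    term = c("P", "M", "L", "K", "Q"),
    estimate = as.numeric(x$params[c("P", "M", "L", "K", "Q")]),
    fixed = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' @describeIn fit_recruitment One-row fit summary.
#' @exportS3Method generics::glance
glance.recruitment_curve <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    fit_error = x$fit_error,
    midpoint = x$midpoint,
    iterations = x$iterations,
    stop_rule = x$stop_rule,
    saturated = x$saturated,
    n = length(x$x)
  )
}

#' @describeIn fit_recruitment Plot the data points and the fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.recruitment_curve <- function(object, ...) {
  pts <- tibble(x = object$x, y = object$y)
  crv <- tibble(x = object$x_dense, y = object$y_dense)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = crv, colour = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "stimulation intensity",
      y = "mean quantified MEP",
      title = sprintf("Recruitment curve (R² = %.3f)", object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
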