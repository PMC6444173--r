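#' Evaluate the recruitment-curve sigmoid
#'
#' The recruitment curve is modelled as a four-parameter Boltzmann
#' (generalized logistic) function
#' \deqn{y(x) = P + \frac{M - P}{1 + Q\,e^{-e^{L}(x - K)}}}
#' where `P` is the lower asymptote (sub-threshold response), `M` the upper
#' asymptote (saturated response), `L` the logarithmic slope (the growth rate
#' per intensity unit is `exp(L)`, so any real `L` gives a positive rate),
#' `K` the curve centre and `Q` a fixed positive shape offset that is set
#' from the data and never optimized.
#'
#' Note that `K` and `Q` parameterize the horizontal position jointly: the
#' intensity at which the curve is halfway between its asymptotes is
#' `K + log(Q) / exp(L)` (see [sigmoid_midpoint()]).
#'
#' @param params Named list or vector with elements `P`, `M`, `L`, `K`, `Q`.
#' @param x Stimulation intensity (scalar or vector, device units such as mA).
#' @return Numeric vector of modelled responses, same length as `x`.
#' @seealso [invert_sigmoid()], [fit_recruitment()]
#' @examples
#' p <- list(P = 0, M = 10, L = 0, K = 5, Q = 1)
#' sigmoid_eval(p, 5) # midpoint: 5
#' @export
sigmoid_eval <- function(params, x) {
  p <- as_sigmoid_params(params)
  p$P + (p$M - p$P) / (1 + p$Q * exp(-exp(p$L) * (x - p$K)))
}

#' Invert the recruitment-curve sigmoid
#'
#' Finds the stimulation intensity at which the curve attains a target
#' response, using the closed form
#' `x = K - log((M - P) / (Q (y - P)) - 1/Q) / exp(L)`.
#' The target must lie strictly between the two asymptotes; outside that open
#' range the sigmoid never attains the value and a classed error
#' (`mepkit_out_of_range`) is thrown so callers can decide how to degrade.
#'
#' @inheritParams sigmoid_eval
#' @param y_target Response value strictly between `min(P, M)` and `max(P, M)`.
#' @return The stimulation intensity `x` with `sigmoid_eval(params, x) == y_target`.
#' @export
invert_sigmoid <- function(params, y_target) {
  p <- as_sigmoid_params(params)
  lo <- min(p$P, p$M)
  hi <- max(p$P, p$M)
  if (!is.finite(y_target) || y_target <= lo || y_target >= hi) {
    abort(
      sprintf(
        "target response %.6g is not strictly inside the curve range (%.6g, %.6g)",
        y_target, lo, hi
      ),
      class = "mepkit_out_of_range"
    )
  }
  p$K - log((p$M - p$P) / (p$Q * (y_target - p$P)) - 1 / p$Q) / exp(p$L)
}

#' Half-maximum intensity of a sigmoid
#'
#' The intensity at which the curve is halfway between its asymptotes,
#' `K + log(Q)/exp(L)`. Unlike the raw `K`, this quantity does not depend on
#' the gauge freedom between `K` and the fixed shape offset `Q`, which makes
#' it the right thing to compare across fits (and against a simulation
#' ground truth) when `Q` is set from the data.
#'
#' @inheritParams sigmoid_eval
#' @return The half-maximum intensity (scalar).
#' @export
sigmoid_midpoint <- function(params) {
  p <- as_sigmoid_params(params)
  p$K + log(p$Q) / exp(p$L)
}

# coerce/validate a P,M,L,K,Q parameter set
as_sigmoid_params <- function(params) {
  p <- as.list(params)
  need <- c("P", "M", "L", "K", "Q")
  if (!all(need %in% names(p))) {
    abort(paste0(
      "sigmoid parameters must be named P, M, L, K, Q; missing: ",
      paste(setdiff(need, names(p)), collapse = ", ")
    ))
  }
  p <- lapply(p[need], as.numeric)
  if (!all(vapply(p, is.finite, logical(1)))) abort("sigmoid parameters must be finite")
  if (p$Q <= 0) abort("Q must be positive")
  p
}
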