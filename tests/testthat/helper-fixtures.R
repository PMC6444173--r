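# Shared fixtures, all built in code.

# a recruitment_curve object with known parameters, bypassing the fitter
make_curve <- function(P, M, L, K, Q, span = c(0, 10), n_dense = 501) {
  params <- list(P = P, M = M, L = L, K = K, Q = Q)
  x_dense <- seq(span[1], span[2], length.out = n_dense)
  structure(
    list(
      params = params,
      midpoint = sigmoid_midpoint(params),
      x_dense = x_dense,
      y_dense = sigmoid_eval(params, x_dense),
      fit_error = 0, r_squared = 1, tolerance_used = 0.1,
      saturated = TRUE, sat_slope = 0, iterations = 0L, stall_count = 0L,
      stop_rule = "tolerance", restarted = FALSE, degenerate = FALSE,
      x = span, y = sigmoid_eval(params, span)
    ),
    class = "recruitment_curve"
  )
}

# a small annotated session with deterministic sweep content: sweep k on
# channel c holds value base + k + c/10 at every sample (easy to track
# through permutations and removals)
make_tracked_session <- function(intensities, trials, n_samp = 20, n_chan = 1,
                                 fs = 1000, base = 0) {
  n_sweeps <- sum(trials)
  sweeps <- array(0, dim = c(n_samp, n_chan, n_sweeps))
  for (k in seq_len(n_sweeps)) {
    for (ch in seq_len(n_chan)) sweeps[, ch, k] <- base + k + ch / 10
  }
  mep_session(sweeps,
    sampling_rate_hz = fs, stim_intensities = intensities,
    trials_per_stim = trials
  )
}

# default synthetic scenario used across tests: 9 intensities x 5 trials
recovery_truth <- function(noise_sd = 0.05 * 2, trials = 5) {
  synth_truth(
    P = 0.1, M = 2, L = 0.7, K = 2.5, Q = 1,
    intensities = seq(0.5, by = 0.5, length.out = 9),
    trials_per_stim = trials, noise_sd = noise_sd
  )
}

recovery_epoch <- function() epoch_spec(4, 24)
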