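#' Ground truth for a synthetic MEP session
#'
#' Parameters of the synthetic-data generator. Each simulated MEP is a
#' sinusoid under a Gaussian envelope (a Morlet-like wavelet), chosen
#' because its peak-to-peak amplitude, AUC and RMS have closed forms that
#' downstream oracles can check. The per-sweep peak-to-peak amplitude
#' follows a ground-truth sigmoid of stimulation intensity with additive
#' Gaussian amplitude noise; the waveform is placed at a jittered onset
#' latency, and optional 60 Hz line noise, slow baseline drift and white
#' background noise can be superimposed.
#'
#' Defaults mirror a typical rodent cortical-stimulation experiment:
#' 5000 Hz sampling, intensities from 0.5 in steps of 0.5 (mA), 10 trials
#' per intensity, 50 ms sweeps, a 300 Hz carrier under a 1.5 ms envelope at
#' a 10 ms onset, and amplitude noise of 5% of the upper asymptote.
#'
#' @param P,M,L,K,Q Ground-truth sigmoid parameters (see [sigmoid_eval()]);
#'   amplitudes in mV.
#' @param intensities Ascending stimulation intensities.
#' @param trials_per_stim Trials per intensity (recycled to
#'   `length(intensities)`).
#' @param sampling_rate_hz,sweep_ms Sampling rate and sweep duration.
#' @param carrier_hz,envelope_sd_ms Waveform carrier frequency and Gaussian
#'   envelope SD.
#' @param onset_ms,jitter_sd_ms Mean onset latency (from sweep start = end
#'   of stimulation) and its per-trial Gaussian jitter SD.
#' @param noise_sd SD of the Gaussian noise added to each sweep's target
#'   peak-to-peak amplitude (signal units; amplitudes are floored at 0).
#' @param line_noise_amp Amplitude of superimposed 60 Hz line noise.
#' @param drift_amp Amplitude of a slow (half-sine over the sweep) baseline
#'   drift.
#' @param background_sd SD of white per-sample background noise.
#' @return An object of class `synth_truth`.
#' @export
synth_truth <- function(P = 0.1, M = 2, L = 0.7, K = 2.5, Q = 1,
                        intensities = seq(0.5, by = 0.5, length.out = 9),
                        trials_per_stim = 10,
                        sampling_rate_hz = 5000, sweep_ms = 50,
                        carrier_hz = 300, envelope_sd_ms = 1.5,
                        onset_ms = 10, jitter_sd_ms = 0.3,
                        noise_sd = 0.05 * M, line_noise_amp = 0,
                        drift_amp = 0, background_sd = 0) {
  if (is.unsorted(intensities, strictly = TRUE)) {
    abort("intensities must be strictly ascending")
  }
  trials <- rep_len(as.integer(trials_per_stim), length(intensities))
  if (any(trials < 1)) abort("trials_per_stim must be positive")
  if (sampling_rate_hz <= 0 || sweep_ms <= 0) abort("invalid sampling parameters")
  if (noise_sd < 0 || background_sd < 0) abort("noise SDs must be non-negative")
  structure(
    list(
      params = as_sigmoid_params(list(P = P, M = M, L = L, K = K, Q = Q)),
      intensities = as.numeric(intensities),
      trials_per_stim = trials,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      sweep_ms = as.numeric(sweep_ms),
      carrier_hz = as.numeric(carrier_hz),
      envelope_sd_ms = as.numeric(envelope_sd_ms),
      onset_ms = as.numeric(onset_ms),
      jitter_sd_ms = as.numeric(jitter_sd_ms),
      noise_sd = as.numeric(noise_sd),
      line_noise_amp = as.numeric(line_noise_amp),
      drift_amp = as.numeric(drift_amp),
      background_sd = as.numeric(background_sd)
    ),
    class = "synth_truth"
  )
}

#' Generate a synthetic MEP session
#'
#' Simulates a full recruitment-curve session from a [synth_truth()]: one
#' Gaussian-enveloped sinusoid per sweep, scaled so that its realized
#' peak-to-peak amplitude equals the truth sigmoid at that sweep's intensity
#' plus amplitude noise (exactly, after discretization, when `noise_sd = 0`).
#' All randomness flows from a single seeded generator with a fixed draw
#' order, so the same seed reproduces the session bit for bit.
#'
#' @param truth A [synth_truth()].
#' @param seed Integer seed.
#' @param session_id Session label for the generated [mep_session()].
#' @return A list with elements `session` (an annotated, single-channel
#'   [mep_session()]) and `truth` (the generating [synth_truth()]).
#' @examples
#' out <- generate_session(synth_truth(trials_per_stim = 5), seed = 42)
#' out$session
#' @export
generate_session <- function(truth, seed = 1L, session_id = 1L) {
  stopifnot(inherits(truth, "synth_truth"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  fs <- truth$sampling_rate_hz
  n_samp <- as.integer(round(truth$sweep_ms / 1000 * fs))
  n_sweeps <- sum(truth$trials_per_stim)
  sweep_intensity <- rep(truth$intensities, truth$trials_per_stim)
  # fixed draw order: all amplitude noises, then all jitters, then background
  amp_noise <- rnorm(n_sweeps, 0, truth$noise_sd)
  jitter <- rnorm(n_sweeps, 0, truth$jitter_sd_ms)
  t_ms <- (seq_len(n_samp) - 1) / fs * 1000
  line <- truth$line_noise_amp * sin(2 * pi * 60 * t_ms / 1000)
  drift <- truth$drift_amp * sin(pi * t_ms / truth$sweep_ms)
  sweeps <- array(0, dim = c(n_samp, 1L, n_sweeps))
  for (i in seq_len(n_sweeps)) {
    t0 <- truth$onset_ms + jitter[i]
    w <- cos(2 * pi * truth$carrier_hz * (t_ms - t0) / 1000) *
      exp(-(t_ms - t0)^2 / (2 * truth$envelope_sd_ms^2))
    p2p_w <- max(w) - min(w)
    amp <- max(0, sigmoid_eval(truth$params, sweep_intensity[i]) + amp_noise[i])
    v <- if (p2p_w > 0) amp / p2p_w * w else w * 0
    v <- v + line + drift
    if (truth$background_sd > 0) v <- v + rnorm(n_samp, 0, truth$background_sd)
    sweeps[, 1L, i] <- v
  }
  session <- mep_session(
    sweeps,
    sampling_rate_hz = fs,
    stim_intensities = truth$intensities,
    trials_per_stim = truth$trials_per_stim,
    channel_labels = "sim",
    session_id = session_id
  )
  list(session = session, truth = truth)
}

#' Inject an artifact trial into a session
#'
#' Corrupts one sweep the way a motion or interference artifact would:
#' the sweep is multiplied by `scale` and a square transient is added over
#' the middle fifth of the sweep. Used to exercise the screening tools
#' ([heatmap_matrix()], [suggest_outliers()]).
#'
#' @param session An annotated [mep_session()].
#' @param intensity_idx,trial_idx 1-based location of the trial to corrupt.
#' @param scale Multiplicative corruption factor.
#' @param transient_amp Amplitude of the added square transient; defaults to
#'   `scale` times the sweep's maximum absolute amplitude. Pass 0 for a
#'   purely multiplicative artifact.
#' @return The session with the corrupted sweep; all other sweeps untouched.
#' @export
inject_artifact <- function(session, intensity_idx, trial_idx, scale = 50,
                            transient_amp = NULL) {
  stopifnot(inherits(session, "mep_session"))
  if (!is_annotated(session)) abort("session must be annotated")
  if (!is.finite(scale) || scale <= 0) abort("scale must be positive")
  idx <- sweep_index(session, intensity_idx, trial_idx)
  d <- dim(session$sweeps)
  lo <- floor(2 * d[1] / 5) + 1
  hi <- floor(3 * d[1] / 5)
  for (ch in seq_len(d[2])) {
    v <- session$sweeps[, ch, idx]
    if (is.null(transient_amp)) {
      ta <- scale * max(abs(v))
    } else {
      ta <- transient_amp
    }
    v <- v * scale
    v[lo:hi] <- v[lo:hi] + ta
    session$sweeps[, ch, idx] <- v
  }
  session
}
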