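#' Epoch selection window
#'
#' The time window, relative to sweep onset (end of stimulation), that
#' contains the MEP. Windows are half-open `[start, stop)` in milliseconds;
#' an epoch holds `floor((stop - start) / 1000 * fs)` samples. Rodent
#' cortical MEPs recorded at 5000 Hz are typically windowed at 8-22 ms.
#'
#' @param start_ms,stop_ms Window bounds in ms, `0 <= start_ms < stop_ms`.
#' @param channel_index 1-based recording channel (muscle) to extract.
#' @return An `epoch_spec` list.
#' @export
epoch_spec <- function(start_ms = 8, stop_ms = 22, channel_index = 1L) {
  if (!is.finite(start_ms) || !is.finite(stop_ms) || start_ms < 0 || start_ms >= stop_ms) {
    abort("epoch window must satisfy 0 <= start_ms < stop_ms")
  }
  structure(
    list(
      start_ms = as.numeric(start_ms), stop_ms = as.numeric(stop_ms),
      channel_index = as.integer(channel_index)
    ),
    class = "epoch_spec"
  )
}

#' Filtering configuration
#'
#' Settings for the optional zero-phase band-pass Butterworth filter and the
#' optional mains-harmonic notch. The band-pass corrects baseline drift and
#' wire-movement artifact; defaults are a 5-600 Hz passband with the filter
#' order chosen for at most 4 dB passband ripple and at least 30 dB stopband
#' attenuation. The notch removes power-line interference at 60 Hz and up to
#' 6 of its harmonics. Filtering is off by default: clean recordings do not
#' need it.
#'
#' @param enabled Apply the band-pass filter.
#' @param low_hz,high_hz Passband edges in Hz (`0 < low_hz < high_hz`, and
#'   `high_hz` below the Nyquist frequency of the data).
#' @param passband_ripple_db,stopband_atten_db Design constraints used for
#'   automatic order selection.
#' @param notch_enabled Apply the mains notch filter.
#' @param notch_base_hz Mains fundamental (60 Hz).
#' @param notch_harmonics Number of harmonics to remove, 1-6.
#' @param notch_q Notch quality factor (bandwidth = frequency / Q).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(enabled = FALSE, low_hz = 5, high_hz = 600,
                        passband_ripple_db = 4, stopband_atten_db = 30,
                        notch_enabled = FALSE, notch_base_hz = 60,
                        notch_harmonics = 2L, notch_q = 30) {
  if (!is.finite(low_hz) || !is.finite(high_hz) || low_hz <= 0 || low_hz >= high_hz) {
    abort("filter band must satisfy 0 < low_hz < high_hz")
  }
  if (notch_harmonics < 1 || notch_harmonics > 6) {
    abort("notch_harmonics must be between 1 and 6")
  }
  structure(
    list(
      enabled = isTRUE(enabled),
      low_hz = as.numeric(low_hz),
      high_hz = as.numeric(high_hz),
      passband_ripple_db = as.numeric(passband_ripple_db),
      stopband_atten_db = as.numeric(stopband_atten_db),
      notch_enabled = isTRUE(notch_enabled),
      notch_base_hz = as.numeric(notch_base_hz),
      notch_harmonics = as.integer(notch_harmonics),
      notch_q = as.numeric(notch_q)
    ),
    class = "filter_spec"
  )
}

## ---- zero-phase IIR machinery ------------------------------------------

# Butterworth realized as cascaded first/second-order sections computed from
# the closed-form analog poles + bilinear transform. Expanding high-order
# designs into a single (b, a) polynomial is numerically unusable at low
# normalized cutoffs (poles cluster near z = 1), so each section is kept
# factored.
butter_sections <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- 2 * fs * tan(pi * fc / fs) # prewarped analog cutoff, rad/s
  k <- seq_len(n)
  p <- wc * exp(1i * pi * (2 * k + n - 1) / (2 * n))
  if (type == "high") p <- wc^2 / p
  zp <- (2 * fs + p) / (2 * fs - p)
  z_zero <- if (type == "high") 1 else -1
  z_ref <- if (type == "high") -1 else 1 # gain pinned at Nyquist (hp) / DC (lp)
  secs <- list()
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    if (abs(Im(zp[i])) > 1e-10) {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-8 & seq_len(n) != i)[1]
      used[c(i, j)] <- TRUE
      a <- Re(c(1, -(zp[i] + zp[j]), zp[i] * zp[j]))
      b <- c(1, -2 * z_zero, 1)
    } else {
      used[i] <- TRUE
      a <- Re(c(1, -zp[i]))
      b <- c(1, -z_zero)
    }
    g <- abs(sum(b * z_ref^(seq_along(b) - 1)) / sum(a * z_ref^(seq_along(a) - 1)))
    secs[[length(secs) + 1]] <- list(b = b / g, a = a)
  }
  secs
}

# RBJ cookbook second-order notch at f0
notch_section <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# one causal pass of a section with steady-state initial conditions
section_pass <- function(sec, x) {
  n_ord <- length(sec$a) - 1
  g <- sum(sec$b) / sum(sec$a)
  as.numeric(signal::filter(sec$b, sec$a, x,
    init.x = rep(x[1], n_ord), init.y = rep(g * x[1], n_ord)
  ))
}

# forward-backward application of a list of sections, with odd-reflection
# padding; output length equals input length, net phase response is zero and
# magnitude response is squared (effective attenuation doubles in dB)
zero_phase_apply <- function(sections, x, fs, pad_s = 0.05) {
  n <- length(x)
  if (n < 3) return(x)
  npad <- min(n - 1, max(12L, as.integer(ceiling(pad_s * fs))))
  xx <- c(
    2 * x[1] - x[(npad + 1):2],
    x,
    2 * x[n] - x[(n - 1):(n - npad)]
  )
  for (sec in sections) xx <- section_pass(sec, xx)
  xx <- rev(xx)
  for (sec in sections) xx <- section_pass(sec, xx)
  rev(xx)[(npad + 1):(npad + n)]
}

## ---- public filtering ---------------------------------------------------

#' Zero-phase band-pass Butterworth filter
#'
#' Applies the band-pass of a [filter_spec()] to a signal, forward and
#' backward so the net phase response is zero (no temporal distortion of MEP
#' onset). The filter order is selected automatically ([signal::buttord()])
#' from the passband ripple and stopband attenuation constraints, with
#' stopband edges at `0.5 * low_hz` and `min(1.25 * high_hz, 0.98 * Nyquist)`;
#' the band is realized as a high-pass/low-pass cascade of biquad sections.
#' Edge transients are handled by odd-reflection padding with steady-state
#' filter initialization.
#'
#' @param x Numeric signal (a sweep or an extracted epoch).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()]; only the band-pass fields are used here.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, fs, spec = filter_spec(enabled = TRUE)) {
  nyq <- fs / 2
  if (spec$high_hz >= nyq) {
    abort(sprintf("cutoff at/above Nyquist: high_hz = %g with fs = %g", spec$high_hz, fs))
  }
  rp <- spec$passband_ripple_db
  rs <- spec$stopband_atten_db
  hp_ord <- signal::buttord(spec$low_hz / nyq, 0.5 * spec$low_hz / nyq, rp, rs)
  lp_ord <- signal::buttord(
    spec$high_hz / nyq, min(1.25 * spec$high_hz, 0.98 * nyq) / nyq, rp, rs
  )
  hp <- butter_sections(hp_ord$n, hp_ord$Wc * nyq, fs, "high")
  lp <- butter_sections(lp_ord$n, lp_ord$Wc * nyq, fs, "low")
  zero_phase_apply(c(hp, lp), as.numeric(x), fs)
}

#' Zero-phase mains-harmonic notch filter
#'
#' Removes power-line interference with second-order notch sections at
#' `base_hz, 2 * base_hz, ..., n_harmonics * base_hz`, each applied forward
#' and backward (zero phase). At most 6 harmonics may be removed, and every
#' notch frequency must lie below the Nyquist frequency.
#'
#' @inheritParams bandpass_zero_phase
#' @param n_harmonics Number of harmonics to remove (1-6).
#' @param base_hz Mains fundamental frequency (default 60 Hz).
#' @param q Notch quality factor.
#' @return Filtered signal, same length as `x`.
#' @export
notch_harmonics <- function(x, fs, n_harmonics, base_hz = 60, q = 30) {
  if (n_harmonics < 1 || n_harmonics > 6) {
    abort("n_harmonics must be between 1 and 6")
  }
  if (n_harmonics * base_hz >= fs / 2) {
    abort(sprintf(
      "harmonic at/above Nyquist: %g Hz with fs = %g", n_harmonics * base_hz, fs
    ))
  }
  secs <- lapply(seq_len(n_harmonics) * base_hz, notch_section, fs = fs, q = q)
  zero_phase_apply(secs, as.numeric(x), fs)
}

#' Filter every sweep of a session
#'
#' Applies the enabled parts of a [filter_spec()] (band-pass, then notch) to
#' each whole sweep on each channel. Whole sweeps are filtered before epoch
#' extraction so the epoch window never sits on a filter edge transient.
#'
#' @param session An [mep_session()] with a sampling rate.
#' @param spec A [filter_spec()].
#' @return The session with filtered sweeps and an attribute `filtered`
#'   recording that filtering took place.
#' @export
filter_session <- function(session, spec = filter_spec()) {
  stopifnot(inherits(session, "mep_session"))
  if (is.null(session$sampling_rate_hz)) abort("session has no sampling rate")
  if (!spec$enabled && !spec$notch_enabled) {
    return(session)
  }
  fs <- session$sampling_rate_hz
  d <- dim(session$sweeps)
  for (ch in seq_len(d[2])) {
    for (sw in seq_len(d[3])) {
      v <- session$sweeps[, ch, sw]
      if (spec$enabled) v <- bandpass_zero_phase(v, fs, spec)
      if (spec$notch_enabled) {
        v <- notch_harmonics(v, fs, spec$notch_harmonics, spec$notch_base_hz, spec$notch_q)
      }
      session$sweeps[, ch, sw] <- v
    }
  }
  attr(session, "filtered") <- TRUE
  session
}

## ---- epoch extraction ---------------------------------------------------

#' Extract MEP epochs from a session
#'
#' Cuts the epoch window of a [epoch_spec()] out of every sweep on the
#' selected channel. Sample indexing is 0-based with half-open windows: the
#' epoch starts at sample `floor(start_ms / 1000 * fs)` and holds
#' `floor((stop_ms - start_ms) / 1000 * fs)` samples (so a 8-22 ms window at
#' 5000 Hz gives 70 samples).
#'
#' @param session An annotated [mep_session()].
#' @param spec An [epoch_spec()].
#' @return A tibble with one row per sweep: `intensity_idx`, `intensity`,
#'   `trial` and a list-column `epoch` of numeric vectors; the sampling rate
#'   and window are stored as attributes `fs`, `start_ms`, `stop_ms`.
#' @export
extract_epochs <- function(session, spec = epoch_spec()) {
  stopifnot(inherits(session, "mep_session"))
  if (!is_annotated(session)) abort("session must be annotated before epoch extraction")
  d <- dim(session$sweeps)
  fs <- session$sampling_rate_hz
  if (spec$channel_index < 1 || spec$channel_index > d[2]) {
    abort(sprintf("bad channel index %d (session has %d)", spec$channel_index, d[2]))
  }
  i0 <- floor(spec$start_ms / 1000 * fs)
  n_ep <- floor((spec$stop_ms - spec$start_ms) / 1000 * fs)
  if (n_ep < 2) abort("epoch window too short for this sampling rate")
  if (i0 + n_ep > d[1]) {
    abort(sprintf(
      "epoch window [%g, %g) ms exceeds the %g ms sweep",
      spec$start_ms, spec$stop_ms, d[1] / fs * 1000
    ))
  }
  tp <- session$trials_per_stim
  intensity_idx <- rep(seq_along(tp), tp)
  trial <- unlist(lapply(tp, seq_len))
  epochs <- lapply(seq_len(d[3]), function(sw) {
    session$sweeps[(i0 + 1):(i0 + n_ep), spec$channel_index, sw]
  })
  out <- tibble(
    intensity_idx = intensity_idx,
    intensity = session$stim_intensities[intensity_idx],
    trial = trial,
    epoch = epochs
  )
  attr(out, "fs") <- fs
  attr(out, "start_ms") <- spec$start_ms
  attr(out, "stop_ms") <- spec$stop_ms
  out
}

## ---- screening ----------------------------------------------------------

#' Per-trial value matrix for heat-map screening
#'
#' Arranges the per-trial quantified values of a session as an
#' `intensities x max(trials)` matrix, the layout used to eyeball a whole
#' session for artifacts: a discontinuous cell in an otherwise smooth
#' colour gradient is a candidate artifact. Ragged sessions leave `NA` in
#' the missing cells.
#'
#' @param quantified A [quantify_session()] result.
#' @return Numeric matrix with intensities as rows (dimnames set to the
#'   intensity values) and trials as columns.
#' @export
heatmap_matrix <- function(quantified) {
  stopifnot(inherits(quantified, "mep_quantified"))
  pt <- quantified$per_trial
  n_int <- length(quantified$stim_intensities)
  n_max <- max(pt$trial)
  m <- matrix(NA_real_, nrow = n_int, ncol = n_max)
  m[cbind(pt$intensity_idx, pt$trial)] <- pt$value
  dimnames(m) <- list(
    intensity = as.character(quantified$stim_intensities),
    trial = as.character(seq_len(n_max))
  )
  m
}

#' Heat-map plot of per-trial values
#'
#' @param quantified A [quantify_session()] result.
#' @return A ggplot object (intensity x trial tiles coloured by value).
#' @export
plot_heatmap <- function(quantified) {
  stopifnot(inherits(quantified, "mep_quantified"))
  pt <- quantified$per_trial
  ggplot2::ggplot(pt, ggplot2::aes(
    x = factor(.data$trial), y = factor(.data$intensity),
    fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "turbo") +
    ggplot2::labs(
      x = "trial", y = "stimulation intensity",
      fill = quantified$metric,
      title = "Per-trial quantified MEPs"
    ) +
    ggplot2::theme_minimal()
}

# median |x - median(x)| of a standard normal sample of size n, used to make
# the pooled deviation scale consistent for sigma at small per-intensity
# trial counts (Monte Carlo calibrated, 4e5 replicates per n; the asymptote
# is qnorm(0.75) = 0.6745)
mad_consistency <- function(n) {
  gamma_tbl <- c(
    0.4772, 0.3131, 0.4862, 0.4902, 0.5271, 0.5514, 0.5637, 0.5822, 0.5874,
    0.6001, 0.6041, 0.6138, 0.6154, 0.6222, 0.6232, 0.6287, 0.6294, 0.6334,
    0.6344
  )
  ifelse(n >= 2 & n <= 20, gamma_tbl[pmax(1, n - 1)], 0.674490)
}

#' Suggest outlier trials for manual review
#'
#' Advisory artifact screening: trials whose quantified value deviates from
#' their intensity's median by more than `z_threshold` robust standard
#' deviations are flagged for visual inspection. Deviations are taken from
#' the per-intensity median, and the scale is estimated by pooling the
#' absolute deviations of all assessable intensities (with a small-sample
#' consistency correction per trial count), since a within-intensity MAD
#' over a handful of trials is too unstable to threshold. Intensities with a
#' single trial are skipped. Nothing is deleted automatically — pipe the
#' flags into [remove_trials()] only after inspecting them.
#'
#' @param quantified A [quantify_session()] result.
#' @param z_threshold Robust z-score threshold (default 5).
#' @return Tibble of flags: `intensity_idx`, `trial`, `value`, `z`.
#' @export
suggest_outliers <- function(quantified, z_threshold = 5) {
  stopifnot(inherits(quantified, "mep_quantified"))
  pt <- quantified$per_trial
  pt <- pt[!is.na(pt$value), , drop = FALSE]
  grp <- split(pt, pt$intensity_idx)
  grp <- grp[vapply(grp, nrow, integer(1)) >= 2]
  if (length(grp) == 0) {
    return(tibble(
      intensity_idx = integer(), trial = integer(),
      value = numeric(), z = numeric()
    ))
  }
  devs <- lapply(grp, function(g) {
    d <- abs(g$value - median(g$value))
    tibble(
      intensity_idx = g$intensity_idx, trial = g$trial, value = g$value,
      dev = d, dev_c = d / mad_consistency(nrow(g))
    )
  })
  all <- dplyr::bind_rows(devs)
  sigma_hat <- median(all$dev_c)
  if (sigma_hat <= 0) {
    return(tibble(
      intensity_idx = integer(), trial = integer(),
      value = numeric(), z = numeric()
    ))
  }
  all$z <- all$dev / sigma_hat
  out <- all[all$z > z_threshold, c("intensity_idx", "trial", "value", "z")]
  dplyr::arrange(as_tibble(out), dplyr::desc(.data$z))
}
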