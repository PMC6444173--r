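test_that("AUC matches analytic oracles", {
  expect_equal(mep_auc(rep(0, 100), 1000), 0)
  # constant magnitude over exactly 1 s: trapezoid is exact
  expect_equal(mep_auc(rep(-2, 101), 100), 2)
  # rectified sine over one period: analytic limit 2/pi
  t <- seq(0, 1, length.out = 1001)
  expect_equal(mep_auc(sin(2 * pi * t), 1000), 2 / pi, tolerance = 1e-4)
})

test_that("RMS matches hand-computed trapezoidal values", {
  expect_equal(mep_rms(rep(3, 50), 1000), 3)
  # hand trapezoid of squares: (1+4)/2 + (4+9)/2 = 9 over T = 2
  expect_equal(mep_rms(c(1, -2, 3), 1), sqrt(9 / 2))
  # 2*sin over integer periods: analytic limit 2/sqrt(2)
  t <- seq(0, 1, length.out = 2001)
  expect_equal(mep_rms(2 * sin(2 * pi * 5 * t), 2000), sqrt(2), tolerance = 1e-3)
})

test_that("peak-to-peak is max minus min and offset-invariant", {
  expect_equal(mep_p2p(rep(1.5, 10)), 0)
  expect_equal(mep_p2p(c(-1.5, 0, 2.5)), 4)
  set.seed(41)
  v <- rnorm(200)
  # brute-force scan oracle
  mx <- v[1]
  mn <- v[1]
  for (u in v) {
    if (u > mx) mx <- u
    if (u < mn) mn <- u
  }
  expect_equal(mep_p2p(v), mx - mn)
  expect_equal(mep_p2p(v + 17.3), mep_p2p(v))
})

test_that("latency finds the first baseline-referenced threshold crossing", {
  fs <- 1000
  # zero baseline, step to max at 8 ms
  step <- c(rep(0, 8), rep(1, 12))
  expect_equal(mep_latency(step, fs, threshold_pct = 20, baseline_ms = 2), 8)
  # already at max from sample 0
  expect_equal(mep_latency(rep(1, 10), fs, threshold_pct = 50, baseline_ms = 2), 0)
  # linear ramp 0 -> 1 over 10 ms, 50% crossing at 5 ms
  ramp <- seq(0, 1, length.out = 11)
  expect_equal(mep_latency(ramp, fs, threshold_pct = 50, baseline_ms = 0), 5)
  # negative-going onsets are detected through rectification
  expect_equal(mep_latency(-step, fs, threshold_pct = 20, baseline_ms = 2), 8)
  # threshold at 100% lands on the rectified maximum itself
  expect_equal(
    mep_latency(c(rep(0, 10), 0.5, 1, 0.5), fs, threshold_pct = 100, baseline_ms = 2),
    11
  )
  expect_error(mep_latency(step, fs, threshold_pct = 0), "threshold_pct")
  expect_error(mep_latency(step, fs, threshold_pct = 20, baseline_ms = 30), "baseline")
})

test_that("latency is non-decreasing in the threshold percentage", {
  set.seed(43)
  fs <- 5000
  for (rep in 1:10) {
    v <- cumsum(rnorm(100))
    v <- abs(v) / max(abs(v))
    lats <- vapply(
      c(5, 20, 40, 60, 80, 100),
      function(p) mep_latency(v, fs, p, baseline_ms = 1), numeric(1)
    )
    lats <- lats[!is.na(lats)]
    expect_true(all(diff(lats) >= 0))
  }
})

test_that("metric scaling identities hold", {
  set.seed(47)
  v <- rnorm(80)
  fs <- 2000
  for (a in c(-3.2, 0.5, 7)) {
    expect_equal(mep_auc(a * v, fs), abs(a) * mep_auc(v, fs))
    expect_equal(mep_rms(a * v, fs), abs(a) * mep_rms(v, fs))
  }
  expect_gte(mep_auc(v, fs), 0)
})

test_that("RMS dominates AUC/duration (Jensen), with equality for constant magnitude", {
  set.seed(53)
  fs <- 1000
  for (rep in 1:200) {
    v <- rnorm(sample(20:100, 1))
    duration <- (length(v) - 1) / fs
    expect_gte(mep_rms(v, fs), mep_auc(v, fs) / duration - 1e-12)
  }
  const <- rep(2.5, 64)
  expect_equal(mep_rms(const, fs), mep_auc(const, fs) / ((64 - 1) / fs))
})

test_that("session quantification aggregates per-trial values into per-intensity means", {
  out <- generate_session(synth_truth(
    intensities = seq(0.5, 3, 0.5),
    trials_per_stim = 10
  ), seed = 19)
  q <- quantify_session(out$session, recovery_epoch(), metric = "p2p")
  expect_equal(nrow(q$per_trial), 60)
  expect_equal(nrow(q$per_intensity), 6)
  # independent group-by-mean oracle
  oracle <- tapply(q$per_trial$value, q$per_trial$intensity_idx, mean)
  expect_equal(unname(q$per_intensity$mean_value), unname(as.numeric(oracle)))

  # removing a trial recomputes that intensity's mean over the survivors
  s2 <- remove_trials(out$session, data.frame(intensity_idx = 2, trial = 3))
  q2 <- quantify_session(s2, recovery_epoch(), metric = "p2p")
  kept <- q$per_trial$value[q$per_trial$intensity_idx == 2][-3]
  expect_equal(q2$per_intensity$mean_value[2], mean(kept))
  expect_equal(q2$per_intensity$mean_value[-2], q$per_intensity$mean_value[-2])
})

test_that("identical epochs give means equal to the single-trial value", {
  s <- mep_session(array(rep(sin(1:50), 8), dim = c(50, 1, 8)),
    sampling_rate_hz = 1000, stim_intensities = 1:2, trials_per_stim = c(4, 4)
  )
  q <- quantify_session(s, epoch_spec(0, 49), metric = "rms")
  expect_equal(q$per_intensity$mean_value, rep(q$per_trial$value[1], 2))
})

test_that("latency sessions aggregate onset times per intensity", {
  sweeps <- array(0, dim = c(40, 1, 4))
  sweeps[21:40, 1, 1:2] <- 3 # onset at 20 ms
  sweeps[31:40, 1, 3:4] <- 3 # onset at 30 ms
  s <- mep_session(sweeps,
    sampling_rate_hz = 1000,
    stim_intensities = 1:2, trials_per_stim = c(2, 2)
  )
  q <- quantify_session(s, epoch_spec(0, 39),
    metric = "latency",
    latency_pct = 50, baseline_ms = 5
  )
  expect_equal(q$per_intensity$mean_value, c(20, 30))
  expect_equal(q$per_intensity$n_undefined, c(0L, 0L))
  expect_equal(glance(q)$n_undefined, 0L)
})
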