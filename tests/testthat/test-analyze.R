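baseline_curve <- function() make_curve(P = 0, M = 10, L = 0, K = 5, Q = 1, span = c(0, 10))

test_that("baseline compared with itself gives exactly 100 (and ratio 1)", {
  cs <- curve_set(baseline_curve(), list(baseline_curve(), baseline_curve()),
    labels = c("same1", "same2")
  )
  for (pct in c(20, 50, 80)) {
    expect_equal(mep_metric(cs, pct)$normalized, rep(100, 3))
    expect_equal(stim_metric(cs, pct)$normalized, rep(100, 3))
  }
  expect_equal(slope_metric(cs)$normalized, rep(1, 3))
})

test_that("MEP metric matches the closed-form shifted-curve example", {
  shifted <- make_curve(P = 0, M = 10, L = 0, K = 4, Q = 1, span = c(0, 10))
  cs <- curve_set(baseline_curve(), list(shifted), labels = "shift")
  res <- mep_metric(cs, 50)
  expect_equal(attr(res, "stim_ref"), 5)
  expect_equal(res$raw[2], 10 / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(res$normalized[2], 146.2, tolerance = 1e-3)
  expect_equal(res$normalized[1], 100)

  chg <- mep_metric(cs, 50, as_change = TRUE)
  expect_equal(chg$normalized[1], 0)
  expect_equal(chg$normalized[2], 46.2, tolerance = 1e-2)

  expect_error(mep_metric(cs, 100), "strictly between")
  expect_error(mep_metric(cs, 0), "strictly between")
})

test_that("stimulation metric matches the closed-form inversion example", {
  shifted <- make_curve(P = 0, M = 10, L = 0, K = 4, Q = 1, span = c(0, 10))
  cs <- curve_set(baseline_curve(), list(shifted), labels = "shift")
  res <- stim_metric(cs, 50)
  expect_equal(attr(res, "mep_ref"), 5)
  expect_equal(res$raw, c(5, 4))
  expect_equal(res$normalized, c(100, 80))
})

test_that("unattainable horizontal cuts produce NA markers with a warning", {
  weak <- make_curve(P = 0, M = 4, L = 0, K = 5, Q = 1, span = c(0, 10))
  cs <- curve_set(baseline_curve(), list(weak), labels = "weak")
  expect_warning(res <- stim_metric(cs, 50), class = "mepkit_unattainable")
  expect_true(is.na(res$normalized[2]))
  expect_equal(res$normalized[1], 100)
})

test_that("slope metric scales linearly with curve amplitude", {
  base <- make_curve(P = 0, M = 1, L = 0, K = 5, Q = 1, span = c(0, 10))
  double <- make_curve(P = 0, M = 2, L = 0, K = 5, Q = 1, span = c(0, 10))
  cs <- curve_set(base, list(double), labels = "double")
  res <- slope_metric(cs)
  expect_equal(res$normalized[2], 2, tolerance = 0.02)

  # raw slope approximates the analytic maximum derivative exp(L)(M-P)/4
  expect_equal(res$raw[1], 1 / 4, tolerance = 0.1)

  flat <- make_curve(P = 1, M = 1 + 1e-15, L = 0, K = 5, Q = 1, span = c(0, 10))
  cs2 <- curve_set(base, list(flat), labels = "flat")
  expect_lt(abs(slope_metric(cs2)$raw[2]), 1e-12)
  cs3 <- curve_set(flat, list(base), labels = "base")
  expect_error(slope_metric(cs3), "baseline slope")
  raw_only <- slope_metric(cs3, normalize = FALSE)
  expect_true(all(is.na(raw_only$normalized)))
})

test_that("rightward midpoint shifts move the two cut metrics in opposite directions", {
  set.seed(83)
  for (rep in 1:10) {
    shift <- runif(1, 0.3, 2)
    shifted <- make_curve(P = 0, M = 10, L = 0, K = 5 + shift, Q = 1, span = c(0, 14))
    cs <- curve_set(
      make_curve(P = 0, M = 10, L = 0, K = 5, Q = 1, span = c(0, 14)),
      list(shifted),
      labels = "right"
    )
    pct <- runif(1, 20, 80)
    expect_lt(mep_metric(cs, pct)$normalized[2], 100)
    expect_gt(stim_metric(cs, pct)$normalized[2], 100)
  }
})

test_that("group aggregation computes means and standard errors across records", {
  mk <- function(vals) {
    structure(
      tibble::tibble(
        condition = c("baseline", "a", "b"),
        raw = c(1, vals / 100), normalized = c(100, vals)
      ),
      metric_type = "MEP", cutoff_pct = 50,
      class = c("mep_metric_result", class(tibble::tibble()))
    )
  }
  g <- group_aggregate(list(mk(c(100, 100)), mk(c(110, 100)), mk(c(120, 100))))
  expect_equal(g$mean, c(100, 110, 100))
  expect_equal(g$se[2], 10 / sqrt(3))
  expect_equal(g$se[3], 0) # identical records
  expect_equal(g$n, rep(3L, 3))

  single <- group_aggregate(list(mk(c(105, 95))))
  expect_true(all(is.na(single$se)))
  expect_equal(single$mean, c(100, 105, 95))

  # NA markers excluded with reported counts
  withna <- mk(c(NA, 90))
  g2 <- group_aggregate(list(mk(c(110, 100)), withna))
  expect_equal(g2$n, c(2L, 1L, 2L))
  expect_equal(g2$n_undefined, c(0L, 1L, 0L))
  expect_equal(g2$mean[2], 110)

  bad <- structure(
    tibble::tibble(condition = c("baseline", "a"), raw = 1:2, normalized = c(100, 90)),
    metric_type = "MEP", cutoff_pct = 50,
    class = c("mep_metric_result", class(tibble::tibble()))
  )
  expect_error(group_aggregate(list(mk(c(1, 2)), bad)), "same conditions")
  expect_s3_class(autoplot(g), "ggplot")
})

test_that("direct mean-MEP comparison pools trials per condition", {
  mkq <- function(values) {
    s <- mep_session(
      array(rep(values, each = 20), dim = c(20, 1, length(values))),
      sampling_rate_hz = 1000, stim_intensities = 1,
      trials_per_stim = length(values)
    )
    quantify_session(s, epoch_spec(0, 19), metric = "p2p")
  }
  # constant sweeps have zero peak-to-peak; use rms instead for value control
  mkq2 <- function(values) {
    s <- mep_session(
      array(rep(values, each = 20), dim = c(20, 1, length(values))),
      sampling_rate_hz = 1000, stim_intensities = 1,
      trials_per_stim = length(values)
    )
    quantify_session(s, epoch_spec(0, 19), metric = "rms")
  }
  res <- direct_mep_comparison(list(mkq2(c(1, 2, 3)), mkq2(c(1, 2, 3))), c("a", "b"))
  expect_equal(res$mean, c(2, 2))
  expect_equal(res$se, rep(1 / sqrt(3), 2))
  expect_equal(res$n_trials, c(3L, 3L))

  expect_error(direct_mep_comparison(list(mkq2(1:3)), c("a", "b")), "one label")
})
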