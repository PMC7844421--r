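# Encounter segmentation, event detection, stall plateaus, and the
# distribution summaries.

test_that("flat and sub-threshold traces contain no encounters", {
  trap <- trap_config(noise_sd = 0)
  expect_equal(nrow(segment_encounters(mk_trace(rep(0, 5000), trap))), 0)
  expect_equal(nrow(segment_encounters(mk_trace(rep(0.2, 5000), trap))), 0)
})

test_that("a constructed sawtooth yields one event per tooth with its force", {
  fs <- 5000
  gap <- rep(0, round(0.05 * fs))
  force <- c(gap, mk_tooth(2.5), gap, mk_tooth(1.8), gap, mk_tooth(2.2), gap)
  tr <- mk_trace(force, trap_config(noise_sd = 0))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$detach_force, c(2.5, 1.8, 2.2), tolerance = 1e-6)
})

test_that("a monotone rise ending in a single drop is one event at the maximum", {
  fs <- 5000
  force <- c(rep(0, 200), seq(0, 3, length.out = 0.3 * fs),
             rep(3, 0.05 * fs), rep(0, 500))
  tr <- mk_trace(force, trap_config(noise_sd = 0))
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$detach_force, 3, tolerance = 1e-6)
})

test_that("drop window must span at least 3 samples", {
  tr <- mk_trace(rep(0, 1000))
  expect_error(detect_events(tr, drop_window = 1e-4), "3 samples")
})

test_that("low thresholds trigger a false-positive warning", {
  tr <- mk_trace(rep(0, 2000), trap_config(noise_sd = 0.15))
  expect_warning(segment_encounters(tr, threshold = 0.1), "noise")
})

test_that("a ramp has no stalls; a 50-ms plateau passes 10 ms but not 200 ms", {
  fs <- 5000
  ramp <- c(seq(0, 3, length.out = fs), rep(0, 300))
  tr <- mk_trace(ramp, trap_config(noise_sd = 0))
  ev <- detect_events(tr)
  expect_equal(nrow(detect_stalls(tr, ev, t_min = 0.1, band_sd = 0.15)), 0)

  set.seed(1)
  plateau <- c(seq(0, 3, length.out = 0.03 * fs), rep(3, 0.05 * fs),
               rep(0, 400))
  tr2 <- mk_trace(plateau + rnorm(length(plateau), 0, 0.1),
                  trap_config(noise_sd = 0.1))
  ev2 <- detect_events(tr2)
  s10 <- detect_stalls(tr2, ev2, t_min = 0.01)
  s200 <- detect_stalls(tr2, ev2, t_min = 0.2)
  expect_equal(nrow(s10), 1)
  expect_equal(nrow(s200), 0)
  expect_equal(s10$mean_force, 3, tolerance = 0.05)
})

test_that("stall criterion must span at least 5 samples", {
  tr <- mk_trace(rep(1, 1000))
  ev <- tibble::tibble(encounter = 1L, event = 1L, t_start = 0, t_end = 0.19,
                       detach_force = 1, peak_force = 1, censored = FALSE)
  expect_error(detect_stalls(tr, ev, t_min = 1e-4), "5 samples")
})

test_that("every encounter sample belongs to exactly one event or gap", {
  p <- kinesin_preset("KIF1A(1-393)")
  tr <- simulate_trap_trace(p, trap_config(k_land = 1), 20, seed = 12)
  enc <- segment_encounters(tr)
  ev <- detect_events(tr, enc)
  for (e in unique(ev$encounter)) {
    sub <- ev[ev$encounter == e, , drop = FALSE]
    sub <- sub[order(sub$t_start), , drop = FALSE]
    # events ordered and non-overlapping within the encounter
    expect_true(all(diff(as.vector(rbind(sub$t_start, sub$t_end))) >= 0))
    expect_gte(min(sub$t_start), enc$t_start[enc$encounter == e] - 1e-9)
    expect_lte(max(sub$t_end), enc$t_end[enc$encounter == e] + 0.01)
  }
  expect_true(all(ev$detach_force <= ev$peak_force + 3 * 0.15 |
                    ev$flagged, na.rm = TRUE))
})

test_that("stall-force median is non-decreasing in the stall criterion", {
  p <- kinesin_preset("KIF1A(1-393)")
  tr <- simulate_trap_trace(p, trap_config(k_land = 1), 60, seed = 13)
  ev <- detect_events(tr)
  meds <- vapply(c(0.01, 0.03, 0.05, 0.1), function(tm) {
    median(detect_stalls(tr, ev, t_min = tm)$mean_force)
  }, numeric(1))
  expect_true(all(diff(meds) >= -0.05))
})

test_that("exponential-CDF stall-time fit recovers exact quantile input", {
  Tm <- 0.010
  q <- -Tm * log(1 - (seq_len(200) - 0.5) / 200)
  fit <- fit_stall_time_cdf(q, criterion = 0)
  expect_equal(fit$T, Tm, tolerance = 1e-4)
  # scale equivariance
  fit2 <- fit_stall_time_cdf(2 * q, criterion = 0)
  expect_equal(fit2$T, 2 * fit$T, tolerance = 1e-6)
})

test_that("stall-time fit recovers the rate of censored exponential draws", {
  set.seed(7)
  x <- rexp(3000, 1 / 0.0223)
  x <- x[x >= 0.01]
  fit <- fit_stall_time_cdf(x, criterion = 0.01)
  expect_lt(abs(fit$T - 0.0223), 3 * fit$T_sem + 5e-4)
  expect_error(fit_stall_time_cdf(rep(0.02, 30)), "identical")
})

test_that("cluster metrics aggregate per-encounter event counts", {
  ev <- tibble::tibble(encounter = c(1, 2, 2, 3, 3, 3),
                       event = c(1, 1, 2, 1, 2, 3),
                       t_start = c(0, 1, 1.2, 2, 2.2, 2.4),
                       t_end = c(0.1, 1.1, 1.3, 2.1, 2.3, 2.5))
  cm <- cluster_metrics(ev)
  expect_equal(cm$events_per_encounter, 2)
  expect_equal(cm$n_encounters, 3)
})

test_that("summarize_forces reports the single-event trivial case", {
  fs <- 5000
  force <- c(rep(0, 500), mk_tooth(2.0), rep(0, 500))
  tr <- mk_trace(force, trap_config(noise_sd = 0))
  s <- summarize_forces(tr)
  expect_equal(s$detach_median, 2, tolerance = 1e-6)
  expect_equal(s$detach_q1, 2, tolerance = 1e-6)
  expect_equal(s$events_per_encounter, 1)
  expect_true(is.na(s$stall_time_T) || is.finite(s$stall_time_T))
})
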