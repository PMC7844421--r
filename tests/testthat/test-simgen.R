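# Synthetic-data generators: trap traces with ground truth, motility
# tracks, photobleaching, dilution series, ensemble pairs.

test_that("inert motor yields a flat zero-force trace and an empty log", {
  p <- motor_params(k_step0 = 0, k_det0 = 0, k_slip0 = 0, k_reattach = 0)
  tr <- simulate_trap_trace(p, trap_config(noise_sd = 0), duration = 2,
                            seed = 1)
  expect_true(all(tr$force == 0))
  expect_equal(nrow(ground_truth(tr)$attachments), 0)
  expect_equal(nrow(tr), 2 * 5000)
})

test_that("identical seeds give bit-identical traces and logs", {
  p <- kinesin_preset("KIF1A(1-393)")
  a <- simulate_trap_trace(p, trap_config(k_land = 1), 5, seed = 42)
  b <- simulate_trap_trace(p, trap_config(k_land = 1), 5, seed = 42)
  expect_identical(a$force, b$force)
  expect_identical(ground_truth(a), ground_truth(b))
  c_ <- simulate_trap_trace(p, trap_config(k_land = 1), 5, seed = 43)
  expect_false(identical(a$force, c_$force))
})

test_that("noise-free force equals stiffness x motor position while attached", {
  p <- kinesin_preset("KIF1A(1-393)")
  trap <- trap_config(noise_sd = 0, k_land = 1)
  tr <- simulate_trap_trace(p, trap, 10, seed = 3)
  gt <- ground_truth(tr)
  att <- gt$attachments[!is.na(gt$attachments$t_off), , drop = FALSE]
  # at the sample just before each release the force must equal the
  # logged detachment force (trap relaxation has not started)
  i <- pmax(1, floor(att$t_off * trap$sample_rate))
  expect_lt(max(abs(tr$force[i] - att$detach_force)), 1e-9)
})

test_that("sawtooth drops above the detection limit match logged detachments", {
  p <- kinesin_preset("KIF1A(1-393)")
  tr <- simulate_trap_trace(p, trap_config(noise_sd = 0, k_land = 1), 30,
                            seed = 8)
  gt <- ground_truth(tr)
  n_logged <- sum(gt$attachments$detach_force >= 0.5, na.rm = TRUE)
  ev <- detect_events(tr)
  # counts agree up to events sitting exactly at the 0.5-pN cut
  expect_lte(abs(sum(ev$detach_force >= 0.5, na.rm = TRUE) - n_logged), 1)
  m <- match_events(tr, ev, fmin = 0.5)
  expect_equal(nrow(m), n_logged)
  expect_lt(max(abs(m$detected - m$truth)), 1e-9)
})

test_that("detachment-force distribution matches an independent jump-chain oracle", {
  p <- motor_params(construct_label = "generic", step_size = 8.2,
                    k_step0 = 250, d_load = 1, k_det0 = 0.8, F_d = 1.5,
                    k_slip0 = 0.2, d_slip = 5, k_reattach = 10,
                    F_stall_cap = 3.2)
  trap <- trap_config(noise_sd = 0, k_land = 2)
  tr <- simulate_trap_trace(p, trap, 400, seed = 5)
  sim_f <- ground_truth(tr)$attachments$detach_force
  sim_f <- sim_f[!is.na(sim_f)]
  orc_f <- oracle_detach_forces(p, trap$stiffness, 2000, seed = 6)
  expect_gt(length(sim_f), 500)
  ks <- suppressWarnings(stats::ks.test(sim_f, orc_f))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(median(sim_f) - median(orc_f)),
            3 * mad(orc_f) / sqrt(min(length(sim_f), length(orc_f))) + 0.15)
})

test_that("WT preset median detachment force reproduces the observed ~2.7 pN", {
  p <- kinesin_preset("KIF1A(1-393)")
  tr <- simulate_trap_trace(p, trap_config(noise_sd = 0, k_land = 1), 150,
                            seed = 9)
  f <- ground_truth(tr)$attachments$detach_force
  f <- f[!is.na(f)]
  expect_gt(length(f), 1000)
  expect_lt(abs(median(f) - 2.7), 0.15)
})

# ---- motility generator ----------------------------------------------------

test_that("zero landing rate gives no tracks", {
  tk <- simulate_motility_tracks(landing_rate = 0, seed = 1)
  expect_equal(nrow(tk), 0)
})

test_that("processive runs are censored at the microtubule length", {
  tk <- simulate_motility_tracks(runlen_mean = 20, mt_lengths = rep(10, 10),
                                 diffusive_frac = 0, conc = 0.2, seed = 2)
  disp <- purrr::map_dbl(tk$data, ~ max(.x$position) - min(.x$position))
  expect_true(all(disp <= 10 + 1e-6))
  expect_gt(mean(tk$censored), 0.5)
})

test_that("uncensored run lengths recover the generator mean", {
  tk <- simulate_motility_tracks(runlen_mean = 16.7, vel_sd = 0.2,
                                 mt_lengths = rep(4000, 2), conc = 0.035,
                                 diffusive_frac = 0, loc_sd = 0, seed = 3)
  runs <- purrr::map_dbl(tk$data, ~ .x$position[nrow(.x)] - .x$position[1])
  expect_gt(length(runs), 2000)
  se <- sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - 16.7), 2 * se + 0.15)
})

test_that("frame interval must be positive", {
  expect_error(simulate_motility_tracks(frame_dt = 0, seed = 1), "frame_dt")
})

# ---- photobleaching --------------------------------------------------------

test_that("bleach trace trivial cases", {
  b0 <- simulate_bleach_trace(0, noise_sd = 5, seed = 1)
  expect_equal(attr(b0, "true_steps"), 0)
  expect_lt(max(abs(b0$intensity)), 30)
  b2 <- simulate_bleach_trace(2, p_label = 1, noise_sd = 0, duration = 60,
                              seed = 2)
  expect_equal(attr(b2, "true_steps"), 2)
  expect_equal(length(unique(round(b2$intensity, 6))), 3)
})

test_that("labelling statistics follow binomial(n, p_label)", {
  n_tr <- 3000
  counts <- vapply(seq_len(n_tr), function(s) {
    attr(simulate_bleach_trace(2, 0.7, seed = s, duration = 1e-3), "n_active0")
  }, numeric(1))
  p2 <- mean(counts == 2)
  expect_lt(abs(p2 - 0.49), 2 * sqrt(0.49 * 0.51 / n_tr))
})

# ---- dilution series -------------------------------------------------------

test_that("dilution fractions follow the Poisson binding models", {
  lo <- simulate_dilution_series(0.001, c(0.1, 0.2, 0.4, 0.8), 1000, seed = 1)
  expect_lt(max(lo$fraction), 0.01)
  hi <- simulate_dilution_series(50, c(1, 2, 4, 8), 1000, seed = 2)
  expect_gt(min(hi$fraction), 0.99)
  hin <- simulate_dilution_series(50, c(1, 2, 4, 8), 1000,
                                  model = "nonprocessive", seed = 3)
  expect_gt(min(hin$fraction), 0.99)
  pr <- simulate_dilution_series(1, 1, 1e6, seed = 4)
  expect_lt(abs(pr$fraction - (1 - exp(-1))),
            3 * sqrt(0.632 * 0.368 / 1e6))
  expect_error(simulate_dilution_series(1, 1, 10, model = "other", seed = 1))
})

# ---- ensemble pair ---------------------------------------------------------

test_that("noise-free injected shift changes that pair distance exactly", {
  ep <- simulate_ensemble_pair(n_res = 12, n_conf = 10,
                               shifts = data.frame(i = 3, j = 5, delta = 2),
                               fluct_sd = 0, seed = 4)
  da <- residue_distance_ensemble(ep$a)
  db <- residue_distance_ensemble(ep$b)
  k <- which(da$pair_index$i == 3 & da$pair_index$j == 5)
  expect_equal(unname(colMeans(db$distances)[k] - colMeans(da$distances)[k]),
               2, tolerance = 1e-10)
})

test_that("duplicate shift pairs are rejected", {
  expect_error(simulate_ensemble_pair(
    10, 20, shifts = data.frame(i = c(1, 2), j = c(2, 1), delta = c(1, 1)),
    seed = 1), "duplicate")
})

test_that("exchangeable null ensembles produce no significant pairs", {
  ep <- simulate_ensemble_pair(n_res = 12, n_conf = 400, fluct_sd = 0.3,
                               seed = 11)
  r <- eddm_compare(ep$a, ep$b)
  expect_equal(sum(r$significant), 0)
})
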