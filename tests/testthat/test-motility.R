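# Motility event classification, statistics and censoring diagnostics.

mk_track <- function(time, position, mt = 1, mt_length = 20, conc = 2,
                     movie_duration = 60, frame_dt = 0.1, track = 1) {
  out <- tibble::tibble(track = track, mt = mt, mt_length = mt_length,
                        conc = conc, movie_duration = movie_duration,
                        frame_dt = frame_dt, t_land = time[1],
                        true_class = NA_character_, censored = FALSE,
                        data = list(tibble::tibble(time = time,
                                                   position = position)))
  class(out) <- c("motility_tracks", class(out))
  attr(out, "mt_lengths") <- mt_length
  out
}

test_that("classification thresholds follow the kymograph rules", {
  tks <- dplyr::bind_rows(
    mk_track(seq(0, 2, by = 0.1), seq(0, 0.15, length.out = 21), track = 1),
    mk_track(seq(0, 2.5, by = 0.1), seq(0, 5, length.out = 26), track = 2),
    mk_track(c(0, 0.1), c(0, 1), track = 3))
  attr(tks, "mt_lengths") <- 20
  cl <- classify_tracks(tks)
  expect_equal(cl$class[cl$track == 1], "diffusive")     # 150 nm net
  expect_equal(cl$class[cl$track == 2], "processive")
  expect_equal(cl$velocity[cl$track == 2], 2, tolerance = 1e-9)
  expect_false(cl$retained[cl$track == 3])               # 2 frames only
  # partition: retained + discarded = input
  expect_equal(sum(cl$retained) + sum(!cl$retained) +
                 attr(cl, "n_discarded"), 3)
})

test_that("landing-rate arithmetic: 24 events, 60 s, 2 nM, 10 um -> 1.2", {
  tks <- dplyr::bind_rows(lapply(1:24, function(i) {
    mk_track(seq(0, 1, by = 0.1), seq(0, 1.5, length.out = 11),
             mt_length = 10, conc = 2, movie_duration = 60, track = i)
  }))
  attr(tks, "mt_lengths") <- 10
  cl <- classify_tracks(tks)
  ms <- motility_stats(cl)
  expect_equal(ms$landing_rate, 1.2, tolerance = 1e-9)
  expect_equal(ms$velocity_mean, 1.5, tolerance = 0.01)
})

test_that("landing rate scales linearly with each normaliser", {
  base <- dplyr::bind_rows(lapply(1:24, function(i) {
    mk_track(seq(0, 1, by = 0.1), seq(0, 1.5, length.out = 11),
             mt_length = 10, conc = 2, movie_duration = 60, track = i)
  }))
  attr(base, "mt_lengths") <- 10
  half_conc <- base
  half_conc$conc <- 1
  r1 <- motility_stats(classify_tracks(base))$landing_rate
  r2 <- motility_stats(classify_tracks(half_conc))$landing_rate
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
})

test_that("velocity and run-length recovery on simulated events", {
  tk <- simulate_motility_tracks(vel_mean = 2.1, vel_sd = 0.25,
                                 runlen_mean = 16.7,
                                 mt_lengths = rep(2000, 3), conc = 0.008,
                                 diffusive_frac = 0, loc_sd = 0.02, seed = 21)
  cl <- classify_tracks(tk)
  ms <- motility_stats(cl)
  expect_gt(ms$n_processive, 400)
  expect_lt(abs(ms$velocity_mean - 2.1), 2 * ms$velocity_sem + 0.02)
  # uncensored exponential with mean 16.7: median ln(2) * 16.7
  expect_lt(abs(ms$run_median - 16.7 * log(2)), 2 * ms$run_sem + 0.3)
  expect_equal(ms$run_fit$model, "exponential")
})

test_that("stepping-rate arithmetic matches the reporting convention", {
  expect_equal(stepping_rate_from_velocity(2.1, 8), 263)
  expect_equal(stepping_rate_from_velocity(1.3, 8), 163)
  expect_equal(stepping_rate_from_velocity(0, 8), 0)
  expect_error(stepping_rate_from_velocity(1, 0), "step")
})

test_that("censoring diagnostic: limits and ordering under shorter tracks", {
  tk_short <- simulate_motility_tracks(runlen_mean = 20,
                                       mt_lengths = rep(seq(5, 55, 10), 3),
                                       conc = 0.05, diffusive_frac = 0,
                                       seed = 31)
  tk_long <- simulate_motility_tracks(runlen_mean = 20,
                                      mt_lengths = rep(seq(35, 75, 10), 3),
                                      conc = 0.05, diffusive_frac = 0,
                                      seed = 32)
  cs <- censored_runlength_note(classify_tracks(tk_short))
  cl_ <- censored_runlength_note(classify_tracks(tk_long))
  expect_gt(cs$censored_fraction, cl_$censored_fraction)
  ms_s <- motility_stats(classify_tracks(tk_short))
  ms_l <- motility_stats(classify_tracks(tk_long))
  expect_lt(ms_s$run_median, ms_l$run_median)

  # runs far longer than every MT: censored fraction -> 1
  tk_cens <- simulate_motility_tracks(runlen_mean = 200,
                                      mt_lengths = rep(10, 5), conc = 0.2,
                                      diffusive_frac = 0, seed = 33)
  expect_gt(censored_runlength_note(classify_tracks(tk_cens))$censored_fraction,
            0.9)
})

test_that("diffusive landings are classified as diffusive", {
  tk <- simulate_motility_tracks(diffusive_frac = 1, mt_lengths = rep(20, 5),
                                 conc = 0.1, seed = 41)
  cl <- classify_tracks(tk)
  keep <- cl$retained
  expect_gt(sum(keep), 20)
  expect_gte(mean(cl$class[keep] == "diffusive"), 0.99)
})
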