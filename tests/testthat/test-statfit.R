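# Shared statistical machinery.

test_that("Gaussian fit recovers parameters of normal samples", {
  set.seed(1)
  x <- rnorm(10000, 3.1, 0.5)
  g <- fit_gaussian(x)
  expect_lt(abs(g$mean - 3.1), 2 * 0.5 / sqrt(10000) + 0.02)
  expect_lt(abs(g$cdf[["mean"]] - 3.1), 0.02)
  # shift equivariance
  g2 <- fit_gaussian(x + 5)
  expect_equal(g2$mean, g$mean + 5, tolerance = 1e-3)
  # symmetric two-point data
  g3 <- fit_gaussian(rep(c(2, 4), 20))
  expect_equal(g3$mean, 3, tolerance = 0.05)
  expect_error(fit_gaussian(rep(1, 50)), "degenerate")
  expect_error(fit_gaussian(1:5), "20")
})

test_that("median_quartiles uses type-7 interpolation", {
  mq <- median_quartiles(1:5)
  expect_equal(unlist(mq), c(median = 3, q1 = 2, q3 = 4))
  mq1 <- median_quartiles(7)
  expect_equal(unlist(mq1), c(median = 7, q1 = 7, q3 = 7))
  set.seed(2)
  x <- rexp(1e5)
  expect_lt(abs(median_quartiles(x)$median - log(2)) / log(2), 0.01)
  # monotone + affine equivariance with positive scale
  y <- 3 * x + 1
  expect_equal(unlist(median_quartiles(y)),
               3 * unlist(median_quartiles(x)) + 1, tolerance = 1e-12)
})

test_that("Welch's t matches a long-hand computation and separates groups", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5)
  # long-hand Welch: means, variances, t, Welch-Satterthwaite dof
  ma <- mean(a); mb <- mean(b); va <- var(a) / 15; vb <- var(b) / 14
  t_hand <- (ma - mb) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / 14 + vb^2 / 13)
  w <- welch_t(a, b)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$dof, df_hand, tolerance = 1e-12)
  expect_equal(w$p, 2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  same <- welch_t(rep(2, 5), rep(2, 5))
  expect_equal(same$p, 1)
  far <- welch_t(1:10, 1:10 + 100)
  expect_lt(far$p, 1e-6)
})

test_that("Welch p agrees with a permutation test on small samples", {
  set.seed(3)
  a <- rnorm(8, 0, 1); b <- rnorm(8, 0.8, 1)
  w <- welch_t(a, b)
  pooled <- c(a, b)
  t_obs <- abs(w$t)
  perm <- replicate(1e4, {
    i <- sample(16, 8)
    abs(welch_t(pooled[i], pooled[-i])$t)
  })
  expect_lt(abs(mean(perm >= t_obs) - w$p), 0.01 + 3 * sqrt(w$p * (1 - w$p) / 1e4))
})

test_that("Kruskal-Wallis wraps the standard test", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(10, 11, 12, 13))
  kw <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(kw$H, unname(ref$statistic))
  expect_equal(kw$p, ref$p.value)
})

test_that("binding models: limits, ordering and noiseless inversion", {
  expect_equal(binding_fraction(2, 1e-9), 0, tolerance = 1e-8)
  expect_equal(binding_fraction(2, 1e3), 1)
  expect_equal(binding_fraction(2, 1e3, "nonprocessive"), 1)
  C <- c(0.3, 0.7, 1.5, 3)
  expect_true(all(binding_fraction(1.2, C) >
                    binding_fraction(1.2, C, "nonprocessive")))
  series <- tibble::tibble(rel_concentration = C, n_beads = 100,
                           n_moving = NA,
                           fraction = binding_fraction(2, C),
                           se = 0.02)
  fit <- fit_binding_fraction(series)
  expect_equal(unname(fit$lam[["processive"]]), 2, tolerance = 1e-3)
  expect_gt(fit$r2[["processive"]], 0.9999)
  expect_equal(fit$best, "processive")
  expect_error(fit_binding_fraction(series[1:3, ]), "4")
  series0 <- series; series0$fraction <- 0
  expect_error(fit_binding_fraction(series0), "uninformative")
})

test_that("dispersion percentages match the printed convention", {
  tally <- tibble::tibble(
    condition = c("WT", "WT", "V8M", "V8M", "none", "none"),
    category = rep(c("peripheral", "partial"), 3),
    count = c(42, 4, 29, 24, 0, 10))
  pc <- dispersion_fractions(tally)
  expect_equal(pc$percent[pc$condition == "WT" & pc$category == "peripheral"], 91L)
  expect_equal(pc$percent[pc$condition == "V8M" & pc$category == "peripheral"], 54L)
  expect_equal(pc$percent[pc$condition == "none" & pc$category == "peripheral"], 0L)
  # sums within rounding of 100
  tot <- tapply(pc$percent, pc$condition, sum)
  expect_true(all(tot >= 98 & tot <= 100))
  expect_error(dispersion_fractions(dplyr::mutate(tally, count = -count)),
               "negative")
})
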