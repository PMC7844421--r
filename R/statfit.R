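# Shared statistical fits: Gaussian histogram/CDF fits, exponential CDF
# fits, Poisson bead-binding models, classical tests, quantile conventions.

#' Gaussian fit to a sample
#'
#' Fits a Gaussian to the binned histogram of `values` (Freedman--Diaconis
#' bin width) and, alternatively, to the empirical CDF; both fits are
#' reported and `method` selects which one populates the headline
#' `mean`/`sd`. The quoted SEM is `sd / sqrt(n)`, the convention used when
#' stall-force histograms are reported as "mean +- SEM from Gaussian fit".
#'
#' @param values numeric sample, length >= 20.
#' @param method `"histogram"` (default) or `"cdf"`.
#' @return a `gaussian_fit` object; see [tidy()].
#' @export
fit_gaussian <- function(values, method = c("histogram", "cdf")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20) abort("fit_gaussian() needs at least 20 values")
  if (sd(values) == 0) abort("fit_gaussian(): degenerate sample (zero variance)")

  m0 <- mean(values); s0 <- sd(values)

  # histogram fit
  bw <- 2 * stats::IQR(values) / n^(1 / 3)
  if (bw <= 0) bw <- s0 / 2
  breaks <- seq(min(values) - bw, max(values) + bw, by = bw)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  hd <- tibble(x = h$mids, y = h$counts)
  # start at the histogram mode so the fit locks onto the dominant peak
  # (step-size histograms carry a minority double-step satellite)
  m_start <- hd$x[which.max(hd$y)]
  s_start <- min(s0, 2 * bw)
  hist_fit <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ a * exp(-(x - m)^2 / (2 * s^2)), data = hd,
                             start = list(a = max(hd$y), m = m_start, s = s_start),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit); c(mean = unname(cf["m"]), sd = abs(unname(cf["s"])))
  }, error = function(e) c(mean = m0, sd = s0))
  # ill-posed histogram fits (e.g. widely separated spikes) fall back to
  # moments
  if (hist_fit[["mean"]] < min(values) || hist_fit[["mean"]] > max(values) ||
      hist_fit[["sd"]] > 3 * diff(range(values))) {
    hist_fit <- c(mean = m0, sd = s0)
  }

  # CDF fit
  xs <- sort(values)
  cd <- tibble(x = xs, y = (seq_len(n) - 0.5) / n)
  cdf_fit <- tryCatch({
    fit <- minpack.lm::nlsLM(y ~ pnorm(x, m, s), data = cd,
                             start = list(m = m0, s = s0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit); c(mean = unname(cf["m"]), sd = abs(unname(cf["s"])))
  }, error = function(e) c(mean = m0, sd = s0))

  pick <- if (method == "histogram") hist_fit else cdf_fit
  structure(list(mean = pick[["mean"]], sd = pick[["sd"]],
                 sem = pick[["sd"]] / sqrt(n), n = n, method = method,
                 histogram = hist_fit, cdf = cdf_fit),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mean %.4g +- %.2g (SEM), sd %.4g, n = %d (%s fit)\n",
              x$mean, x$sem, x$sd, x$n, x$method))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gaussian_fit <- function(x, ...) {
  tibble(method = c("histogram", "cdf"),
         mean = c(x$histogram[["mean"]], x$cdf[["mean"]]),
         sd = c(x$histogram[["sd"]], x$cdf[["sd"]]),
         sem = c(x$histogram[["sd"]], x$cdf[["sd"]]) / sqrt(x$n),
         n = x$n)
}

#' Median and quartiles (type-7 interpolation)
#'
#' The reporting convention used for detachment forces and run lengths:
#' median with interpolated (type 7) quartiles.
#'
#' @param values nonempty numeric vector.
#' @return one-row tibble with `median`, `q1`, `q3`.
#' @export
median_quartiles <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("median_quartiles() needs a nonempty vector")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(median = q[2], q1 = q[1], q3 = q[3])
}

#' Welch's two-sample t test
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return one-row tibble with `t`, `dof`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("welch_t() needs >= 2 values per group")
  if (sd(a) == 0 && sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(t = if (same) 0 else Inf,
                  dof = length(a) + length(b) - 2,
                  p = if (same) 1 else 0))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), dof = unname(tt$parameter), p = tt$p.value)
}

#' Kruskal-Wallis rank test
#'
#' @param groups a list of numeric vectors.
#' @return one-row tibble with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("kruskal_wallis() needs a list of >= 2 groups")
  }
  kt <- kruskal.test(groups)
  tibble(H = unname(kt$statistic), p = kt$p.value)
}

#' Poisson bead-binding models
#'
#' Expected moving-bead fraction at relative motor concentration `C` under
#' the Poisson motor-loading models: `"processive"`, where one or more
#' motors suffice, `f = 1 - exp(-lambda C)`; and `"nonprocessive"`, where
#' two or more are needed, `f = 1 - exp(-lambda C) - (lambda C) exp(-lambda C)`.
#'
#' @param lam dimensionless lambda.
#' @param C relative concentration(s).
#' @param model `"processive"` or `"nonprocessive"`.
#' @export
binding_fraction <- function(lam, C, model = c("processive", "nonprocessive")) {
  model <- match.arg(model)
  x <- lam * C
  if (model == "processive") 1 - exp(-x) else 1 - exp(-x) - x * exp(-x)
}

#' Fit Poisson bead-binding models to a dilution series
#'
#' Weighted least squares (weights `1/se^2`, binomial standard errors) of
#' the processive and nonprocessive models of [binding_fraction()] to the
#' moving-bead fractions of a dilution series; the model with the higher
#' weighted R-squared is reported as `best`.
#'
#' @param series a tibble as produced by [simulate_dilution_series()], with
#'   columns `rel_concentration`, `n_beads`, `fraction`, `se`.
#' @return a `binding_fit` object.
#' @export
fit_binding_fraction <- function(series) {
  need <- c("rel_concentration", "n_beads", "fraction", "se")
  if (!all(need %in% names(series))) {
    abort(paste("`series` must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(series) < 4) abort("fit_binding_fraction() needs >= 4 concentration points")
  f <- series$fraction
  if (all(f <= 0) || all(f >= 1)) {
    abort("uninformative series: all fractions are 0 or all are 1")
  }
  se <- pmax(series$se, sqrt(0.25 / series$n_beads) / 10)
  w <- 1 / se^2
  C <- series$rel_concentration

  fit_one <- function(model) {
    sse <- function(loglam) {
      sum(w * (f - binding_fraction(exp(loglam), C, model))^2)
    }
    op <- optimize(sse, c(log(1e-6), log(1e4)))
    lam <- exp(op$minimum)
    ss_res <- op$objective
    ss_tot <- sum(w * (f - sum(w * f) / sum(w))^2)
    list(lam = lam, r2 = 1 - ss_res / ss_tot)
  }
  pr <- fit_one("processive")
  np <- fit_one("nonprocessive")
  structure(list(lam = c(processive = pr$lam, nonprocessive = np$lam),
                 r2 = c(processive = pr$r2, nonprocessive = np$r2),
                 best = if (pr$r2 >= np$r2) "processive" else "nonprocessive",
                 series = as_tibble(series)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> best: %s | processive lambda %.3g (R2 %.4f), nonprocessive lambda %.3g (R2 %.4f)\n",
              x$best, x$lam[["processive"]], x$r2[["processive"]],
              x$lam[["nonprocessive"]], x$r2[["nonprocessive"]]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) {
  tibble(model = names(x$lam), lam = unname(x$lam), r2 = unname(x$r2),
         best = names(x$lam) == x$best)
}

#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble(best = x$best, lam = unname(x$lam[x$best]), r2 = unname(x$r2[x$best]),
         n = nrow(x$series))
}

#' Cargo-dispersion phenotype percentages
#'
#' Converts category counts of the inducible cargo (peroxisome) dispersion
#' assay -- cells scored as clustered, partial, diffuse or peripheral
#' dispersion per condition and time point -- into integer percentages.
#' Percentages are truncated to whole percent, matching the printed
#' convention of the source counts (e.g. 29/53 -> 54%).
#'
#' @param tally a data frame with a `category` column, a `count` column and
#'   any number of grouping columns (condition, time point, ...).
#' @return the tally with an added `percent` column (integer).
#' @export
dispersion_fractions <- function(tally) {
  tally <- as_tibble(tally)
  if (!all(c("category", "count") %in% names(tally))) {
    abort("`tally` must have `category` and `count` columns")
  }
  if (any(tally$count < 0)) abort("negative counts are not allowed")
  grp <- setdiff(names(tally), c("category", "count", "percent"))
  out <- tally |>
    group_by(across(dplyr::all_of(grp))) |>
    mutate(total = sum(.data$count)) |>
    ungroup()
  if (any(out$total <= 0)) abort("each condition must have a positive total count")
  out |>
    mutate(percent = as.integer(floor(100 * .data$count / .data$total))) |>
    select(-"total")
}
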