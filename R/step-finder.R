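# Iterative chi-squared step fitting (Kerssemakers-style): greedy placement
# of the single best step per plateau, model size chosen where the
# counter-fit quality ratio peaks.

# best single split of y[a..b] with both sides >= min_plateau samples;
# returns c(reduction, split_index) or NULL
.best_split <- function(cs, cs2, a, b, min_plateau) {
  m <- b - a + 1L
  if (m < 2L * min_plateau) return(NULL)
  sum_ab <- cs[b + 1L] - cs[a]
  ss_ab <- cs2[b + 1L] - cs2[a]
  sse0 <- ss_ab - sum_ab^2 / m
  cc <- (a + min_plateau - 1L):(b - min_plateau)
  nl <- cc - a + 1L
  sl <- cs[cc + 1L] - cs[a]
  sr <- sum_ab - sl
  sse <- (ss_ab) - sl^2 / nl - sr^2 / (m - nl)
  i <- which.min(sse)
  c(reduction = sse0 - sse[i], split = cc[i])
}

# coordinate-descent refinement: re-place each change point optimally
# between its neighbours until stable (greedy placement then refinement
# reaches the exhaustive chi-squared optimum in practice)
.refine_cps <- function(cs, cs2, n, cps, min_plateau) {
  if (length(cps) == 0) return(cps)
  for (pass in 1:10) {
    changed <- FALSE
    for (q in seq_along(cps)) {
      a <- if (q == 1L) 1L else cps[q - 1L] + 1L
      b <- if (q == length(cps)) n else cps[q + 1L]
      sp <- .best_split(cs, cs2, a, b, min_plateau)
      if (!is.null(sp) && sp[2] != cps[q]) {
        cps[q] <- as.integer(sp[2]); changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(cps)
}

# piecewise-mean SSE for a given set of breakpoints (last index per plateau)
.pw_sse <- function(cs, cs2, n, cps) {
  bounds <- c(0L, cps, n)
  tot <- 0
  for (q in seq_len(length(bounds) - 1L)) {
    a <- bounds[q] + 1L; b <- bounds[q + 1L]
    m <- b - a + 1L
    s <- cs[b + 1L] - cs[a]
    tot <- tot + (cs2[b + 1L] - cs2[a]) - s^2 / m
  }
  tot
}

#' Step detection by iterative chi-squared fitting
#'
#' Fits a staircase (piecewise-constant signal) to a position or intensity
#' series by greedy recursive placement of the single best chi-squared step
#' per plateau. The number of steps is selected where the counter-fit
#' quality ratio -- the chi-squared of an anti-phase fit with steps at the
#' plateau midpoints divided by the chi-squared of the best fit -- peaks;
#' ratios below `min_quality` are never accepted, so featureless inputs
#' (e.g. a monotone ramp) return zero steps.
#'
#' @param positions numeric series (nm for bead records, a.u. for
#'   intensity traces); length >= `3 * min_plateau`.
#' @param min_plateau minimum plateau length, samples.
#' @param max_steps cap on the number of fitted steps; if the quality peak
#'   has not been passed when the cap is reached the fit is flagged.
#' @param min_quality minimum accepted counter-fit quality ratio.
#' @return a `step_fit` object with `change_points` (index of the last
#'   sample of each plateau), `levels` (plateau means), `sizes` (signed
#'   differences), `quality` (ratio at the accepted size) and the full
#'   `quality_path`.
#' @export
fit_steps <- function(positions, min_plateau = 10, max_steps = NULL,
                      min_quality = 1.2) {
  y <- as.numeric(positions)
  n <- length(y)
  min_plateau <- max(2L, as.integer(min_plateau))
  if (n < 3L * min_plateau) {
    abort("`positions` must be at least 3 x min_plateau samples long")
  }
  max_steps <- max_steps %||% max(1L, n %/% (2L * min_plateau))
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))

  cps <- integer()       # change points: last index of each plateau
  chi2 <- .pw_sse(cs, cs2, n, cps)
  path_k <- 0L; path_chi2 <- chi2; path_counter <- NA_real_; path_ratio <- NA_real_
  fits <- list(integer())
  hit_cap <- FALSE

  repeat {
    if (length(cps) >= max_steps) { hit_cap <- TRUE; break }
    bounds <- c(0L, cps, n)
    best <- NULL
    for (q in seq_len(length(bounds) - 1L)) {
      sp <- .best_split(cs, cs2, bounds[q] + 1L, bounds[q + 1L], min_plateau)
      if (!is.null(sp) && (is.null(best) || sp[1] > best[1])) best <- sp
    }
    tol <- 1e-9 * max(cs2[n + 1L] / n, 1e-12)
    if (is.null(best) || best[1] <= tol) break
    cps <- .refine_cps(cs, cs2, n, sort(c(cps, as.integer(best[2]))),
                       min_plateau)
    k <- length(cps)
    fit_sse <- .pw_sse(cs, cs2, n, cps)
    # counter-fit: steps at the midpoints of the fitted plateaus
    bounds <- c(0L, cps, n)
    mids <- integer()
    for (q in seq_len(length(bounds) - 1L)) {
      a <- bounds[q] + 1L; b <- bounds[q + 1L]
      if (b - a >= 1L) mids <- c(mids, as.integer(floor((a + b) / 2)))
    }
    mids <- sort(unique(mids[mids >= 1L & mids < n]))
    ctr_sse <- .pw_sse(cs, cs2, n, mids)
    path_k <- c(path_k, k)
    path_chi2 <- c(path_chi2, fit_sse)
    path_counter <- c(path_counter, ctr_sse)
    path_ratio <- c(path_ratio, if (fit_sse > 0) ctr_sse / fit_sse else Inf)
    fits[[k + 1L]] <- cps
    if (fit_sse <= tol) break   # exact fit reached; further splits are noise
  }

  ratio <- path_ratio
  ok <- which(!is.na(ratio) & ratio >= min_quality)
  k_star <- if (length(ok)) path_k[ok[which.max(ratio[ok])]] else 0L
  cps_star <- fits[[k_star + 1L]]
  bounds <- c(0L, cps_star, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(q) {
    (cs[bounds[q + 1L] + 1L] - cs[bounds[q] + 1L - 1L + 1L]) /
      (bounds[q + 1L] - bounds[q])
  }, numeric(1))
  structure(list(change_points = cps_star, levels = levels,
                 sizes = diff(levels),
                 quality = if (k_star > 0) max(ratio[ok]) else NA_real_,
                 n_steps = k_star,
                 quality_path = tibble(k = path_k, chi2 = path_chi2,
                                       counter = path_counter, ratio = ratio),
                 hit_max_steps = hit_cap && k_star == max_steps,
                 n = n, data = y),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d steps over %d samples (quality %.3g%s)\n",
              x$n_steps, x$n, x$quality,
              if (isTRUE(x$hit_max_steps)) ", max_steps reached" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.step_fit <- function(x, ...) {
  if (x$n_steps == 0) {
    return(tibble(index = integer(), size = numeric(),
                  level_before = numeric(), level_after = numeric()))
  }
  tibble(index = x$change_points, size = x$sizes,
         level_before = x$levels[-length(x$levels)],
         level_after = x$levels[-1])
}

#' Fitted staircase of a step fit
#'
#' @param x a `step_fit`.
#' @return numeric vector of the fitted piecewise-constant signal.
#' @export
step_signal <- function(x) {
  bounds <- c(0L, x$change_points, x$n)
  rep(x$levels, diff(bounds))
}

#' Step-size statistics under load
#'
#' Pools detected steps from one or more [fit_steps()] results, keeps the
#' steps whose local force lies within `force_window`, and reports the
#' Gaussian-fit mean size and the forward-step fraction. Positive sizes
#' point away from the trap center (toward the microtubule plus end).
#'
#' @param fits a `step_fit`, a list of them, or a steps tibble with `size`
#'   and `force` columns (as from [find_trap_steps()]).
#' @param trace_forces for `step_fit` input: a numeric force series (or
#'   list of them) aligned with the fitted positions, pN.
#' @param force_window length-2 numeric window (pN); `NULL` keeps all.
#' @return a `step_stats` object with `mean_size`, `sem`,
#'   `forward_fraction`, `n`, and the selected `steps` tibble.
#' @export
step_size_stats <- function(fits, trace_forces = NULL, force_window = NULL) {
  if (inherits(fits, "step_fit")) {
    fits <- list(fits)
    if (!is.null(trace_forces) && !is.list(trace_forces)) {
      trace_forces <- list(trace_forces)
    }
  }
  if (is.data.frame(fits)) {
    steps <- as_tibble(fits)
    if (!"force" %in% names(steps)) steps$force <- NA_real_
  } else {
    steps <- purrr::imap(fits, function(f, i) {
      td <- tidy(f)
      td$force <- if (!is.null(trace_forces)) {
        trace_forces[[i]][td$index]
      } else NA_real_
      td
    }) |> bind_rows()
  }
  if (!is.null(force_window)) {
    steps <- steps[!is.na(steps$force) & steps$force >= force_window[1] &
                     steps$force <= force_window[2], , drop = FALSE]
  }
  if (nrow(steps) == 0) {
    return(structure(list(mean_size = NA_real_, sem = NA_real_,
                          forward_fraction = NA_real_, n = 0L,
                          steps = steps), class = "step_stats"))
  }
  if (nrow(steps) < 30) abort("step_size_stats() needs >= 30 steps in the window")
  gf <- fit_gaussian(steps$size)
  structure(list(mean_size = gf$mean, sem = gf$sem,
                 forward_fraction = mean(steps$size > 0), n = nrow(steps),
                 steps = as_tibble(steps)), class = "step_stats")
}

#' @export
print.step_stats <- function(x, ...) {
  cat(sprintf("<step_stats> %.3g +- %.2g nm (Gaussian fit, n = %d), forward fraction %.3f\n",
              x$mean_size, x$sem, x$n, x$forward_fraction))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.step_stats <- function(x, ...) {
  tibble(mean_size = x$mean_size, sem = x$sem,
         forward_fraction = x$forward_fraction, n = x$n)
}

#' Detect motor steps within trap force-generation events
#'
#' Converts each event's force record to bead displacement
#' (`position = force / stiffness`), runs [fit_steps()] on the unfiltered
#' record, and pools the detected steps with the local (1-kHz filtered)
#' force at each step.
#'
#' @param trace a `trap_trace`.
#' @param events output of [detect_events()]; computed if `NULL`.
#' @param min_plateau minimum plateau, samples.
#' @param min_samples events shorter than this are skipped.
#' @param window analysis window, s. Events are fitted in windows of this
#'   length (the way stepwise segments of bead records are analysed), so
#'   that model-size selection is local and slowly and rapidly stepping
#'   stretches of a record do not compete.
#' @return tibble with `encounter`, `event`, `time`, `size` (nm), `force`
#'   (pN at the step).
#' @export
find_trap_steps <- function(trace, events = NULL, min_plateau = 10,
                            min_samples = 60, window = 0.02) {
  trap <- .trace_meta(trace)
  fs <- trap$sample_rate
  if (is.null(events)) events <- detect_events(trace)
  f_ev <- .boxcar(trace$force, round(fs / 1000))
  wlen <- max(round(window * fs), 6L * min_plateau)
  out <- list()
  for (r in seq_len(nrow(events))) {
    a0 <- .t2i(events$t_start[r], fs)
    b0 <- min(nrow(trace), .t2i(events$t_end[r], fs))
    if (b0 - a0 + 1L < max(min_samples, 3L * min_plateau)) next
    starts <- seq(a0, b0, by = wlen)
    for (a in starts) {
      b <- min(b0, a + wlen - 1L)
      if (b - a + 1L < max(min_samples, 3L * min_plateau)) next
      pos <- trace$force[a:b] / trap$stiffness
      sf <- fit_steps(pos, min_plateau = min_plateau)
      if (sf$n_steps == 0) next
      out[[length(out) + 1L]] <- tibble(
        encounter = events$encounter[r], event = events$event[r],
        time = trace$time[a + sf$change_points],
        size = sf$sizes, force = f_ev[a + sf$change_points])
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(encounter = integer(), event = integer(), time = numeric(),
                  size = numeric(), force = numeric())
  }
  res
}

#' Count photobleaching steps in an intensity trace
#'
#' Applies the step finder to a fluorescence intensity record and counts
#' the significant downward steps, the fluorophore-stoichiometry readout
#' of stepwise photobleaching.
#'
#' @param intensity intensity series, a.u.
#' @param min_plateau minimum plateau, samples (bleach traces are analysed
#'   at the native camera rate).
#' @param unit optional single-fluorophore intensity, a.u. When given,
#'   each downward step counts as `round(-size / unit)` bleach events, so
#'   two fluorophores bleaching within one plateau are still counted as
#'   two steps (amplitude-based stoichiometry).
#' @return integer step count.
#' @export
count_bleach_steps <- function(intensity, min_plateau = 10, unit = NULL) {
  y <- as.numeric(intensity)
  if (length(y) == 0) abort("empty intensity trace")
  if (length(y) < 3L * max(2L, as.integer(min_plateau))) return(0L)
  third <- max(1L, length(y) %/% 3L)
  if (mean(tail(y, third)) > mean(head(y, third))) {
    warn("intensity trends upward; not a photobleaching trace?")
  }
  sf <- fit_steps(y, min_plateau = min_plateau)
  down <- sf$sizes[sf$sizes < 0]
  if (is.null(unit)) sum(sf$sizes < 0)
  else as.integer(sum(pmax(1L, .round_half_up(-down / unit))))
}
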