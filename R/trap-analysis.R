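# Segmentation of force-time records into microtubule encounters,
# force-generation events and stall plateaus; distribution summaries.

.trace_meta <- function(trace) {
  trap <- attr(trace, "trap")
  if (is.null(trap)) {
    abort("`trace` must be a trap_trace (or carry a trap_config attribute)")
  }
  trap
}

# time -> sample index (1-based) on the trace grid
.t2i <- function(t, fs) pmax(1L, floor(t * fs + 1e-9) + 1L)

#' Segment a force trace into microtubule encounters
#'
#' An encounter is a maximal period during which the bead is held away from
#' the trap center: the 500-Hz low-pass-filtered force exceeds `threshold`,
#' with sub-`min_gap` dips (the rapid detach/reattach gaps within a cluster
#' of force-generation events) merged.
#'
#' @param trace a `trap_trace`.
#' @param threshold detection threshold, pN; defaults to the trap's
#'   detection limit (~0.3 pN).
#' @param min_gap gaps below threshold shorter than this (s) are bridged.
#' @return tibble with `encounter`, `t_start`, `t_end`, `cluster_duration`.
#' @export
segment_encounters <- function(trace, threshold = NULL, min_gap = 0.5) {
  trap <- .trace_meta(trace)
  if (nrow(trace) == 0) abort("empty trace")
  threshold <- threshold %||% trap$detection_limit
  if (threshold < 2 * trap$noise_sd) {
    warn("encounter threshold below 2x the noise SD; expect false positives")
  }
  fs <- trap$sample_rate
  f_lp <- .boxcar(trace$force, round(fs / 500))
  runs <- .runs(f_lp > threshold)
  above <- runs[runs$value, , drop = FALSE]
  if (nrow(above) == 0) {
    return(structure(tibble(encounter = integer(), t_start = numeric(),
                            t_end = numeric(), cluster_duration = numeric()),
                     threshold = threshold))
  }
  # merge encounters separated by sub-min_gap dips
  gap_s <- (above$start[-1] - above$end[-nrow(above)] - 1L) / fs
  grp <- cumsum(c(1L, as.integer(gap_s >= min_gap)))
  enc <- tibble(grp = grp, start = above$start, end = above$end) |>
    group_by(.data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  # discard blips shorter than 5 ms
  enc <- enc[(enc$end - enc$start + 1L) / fs >= 0.005, , drop = FALSE]
  out <- tibble(encounter = seq_len(nrow(enc)),
                t_start = trace$time[enc$start],
                t_end = trace$time[enc$end])
  out$cluster_duration <- out$t_end - out$t_start
  structure(out, threshold = threshold)
}

#' Detect force-generation events within encounters
#'
#' Within each encounter, force-generation events are the detach/reattach
#' cycles of the sawtooth record: maximal stretches where the 1-kHz
#' filtered force stays above threshold. A detachment is a force drop of at
#' least `drop_frac` of the pre-drop force within `drop_window`; the
#' detachment force is read from the unfiltered record in the 2 ms
#' immediately preceding the drop onset (the trap relaxes essentially
#' instantly at these stiffnesses).
#'
#' @param trace a `trap_trace`.
#' @param encounters output of [segment_encounters()]; computed if `NULL`.
#' @param drop_frac fractional force decrease that defines a detachment.
#' @param drop_window time window of the drop criterion, s.
#' @param threshold event threshold, pN; defaults to the segmentation
#'   threshold.
#' @return tibble with one row per event: `encounter`, `event`, `t_start`,
#'   `t_end`, `detach_force`, `peak_force`, `censored`, `flagged`.
#' @export
detect_events <- function(trace, encounters = NULL, drop_frac = 0.75,
                          drop_window = 0.005, threshold = NULL) {
  trap <- .trace_meta(trace)
  fs <- trap$sample_rate
  if (drop_window * fs < 3) abort("`drop_window` must span at least 3 samples")
  if (is.null(encounters)) encounters <- segment_encounters(trace, threshold)
  threshold <- threshold %||% attr(encounters, "threshold") %||% trap$detection_limit

  f_ev <- .boxcar(trace$force, round(fs / 1000))
  f_raw <- trace$force
  n <- length(f_raw)
  cm0 <- c(0, cumsum(f_raw))              # cm0[i + 1] = sum(f_raw[1:i])
  w_pre <- max(3L, round(0.002 * fs))     # pre-drop read-out window
  res <- vector("list", nrow(encounters))

  for (e in seq_len(nrow(encounters))) {
    i0 <- .t2i(encounters$t_start[e], fs)
    i1 <- min(n, .t2i(encounters$t_end[e], fs))
    seg <- f_ev[i0:i1]
    bound <- seg > threshold
    # bridge sub-millisecond dips (noise)
    runs <- .runs(bound)
    short_gap <- !runs$value & (runs$end - runs$start + 1L) < max(3L, round(0.001 * fs)) &
      runs$start > 1L & runs$end < length(bound)
    for (g in which(short_gap)) bound[runs$start[g]:runs$end[g]] <- TRUE
    runs <- .runs(bound)
    ev_runs <- runs[runs$value, , drop = FALSE]
    if (nrow(ev_runs) == 0) next
    ev <- vector("list", nrow(ev_runs))
    for (j in seq_len(nrow(ev_runs))) {
      a <- i0 + ev_runs$start[j] - 1L
      b <- i0 + ev_runs$end[j] - 1L
      censored <- b >= n - 1L
      cross <- NA_integer_
      if (!censored) {
        # locate the release: raw force falls below (1 - drop_frac) of the
        # trailing 2-ms plateau average near the run end
        lo <- max(a + w_pre + 1L, b - round(0.004 * fs))
        hi <- min(n - 1L, b + round(0.003 * fs))
        if (lo <= hi) {
          idx <- lo:hi
          plat <- (cm0[idx] - cm0[idx - w_pre]) / w_pre  # trailing 2-ms mean
          hitidx <- which(f_raw[idx] < (1 - drop_frac) * plat & plat > threshold)
          cross <- if (length(hitidx)) idx[hitidx[1L]] else b
        } else cross <- b
      }
      onset <- if (is.na(cross)) b else cross
      pre_hi <- max(a, onset - 5L)      # clear of the first decay samples
      pre_lo <- max(a, pre_hi - round(1.2 * w_pre) + 1L)
      detach <- if (censored) NA_real_ else mean(f_raw[pre_lo:pre_hi])
      peak <- max(f_ev[a:b])
      ev[[j]] <- tibble(encounter = encounters$encounter[e], event = j,
                        t_start = trace$time[a],
                        t_end = trace$time[min(onset, n)],
                        detach_force = detach, peak_force = peak,
                        censored = censored)
    }
    res[[e]] <- bind_rows(ev)
  }
  out <- bind_rows(res)
  if (nrow(out)) {
    # discard threshold-grazing noise blips: a genuine force-generation
    # event must clear the detection limit and outlast the drop window
    keep <- out$peak_force >= threshold + 0.15 &
      (out$t_end - out$t_start) >= max(0.003, 3 / fs)
    out <- out[keep, , drop = FALSE]
    out <- out |>
      group_by(.data$encounter) |>
      mutate(event = dplyr::row_number()) |>
      ungroup()
  }
  if (nrow(out) == 0) {
    out <- tibble(encounter = integer(), event = integer(), t_start = numeric(),
                  t_end = numeric(), detach_force = numeric(),
                  peak_force = numeric(), censored = logical())
  }
  out$flagged <- !out$censored & !is.na(out$detach_force) &
    out$detach_force > out$peak_force + 3 * trap$noise_sd
  structure(out, threshold = threshold, drop_frac = drop_frac,
            drop_window = drop_window)
}

#' Detect stall plateaus within force-generation events
#'
#' A stall plateau is a maximal stretch of at least `t_min` seconds with no
#' embedded step or drop, filtered-force standard deviation at most
#' `band_sd`, and mean force at least `f_min`, that either terminates the
#' event or abuts a downward step (a back-slip). Pauses that end with a
#' further forward step are not stalls. The stall force is the mean
#' unfiltered force over the plateau.
#'
#' @param trace a `trap_trace`.
#' @param events output of [detect_events()].
#' @param t_min stall criterion (minimum plateau duration), s.
#' @param band_sd maximum filtered-force SD within a plateau, pN.
#' @param f_min minimum mean plateau force, pN.
#' @return tibble with `encounter`, `event`, `t_start`, `duration`,
#'   `mean_force`.
#' @export
detect_stalls <- function(trace, events, t_min = 0.01, band_sd = 0.15,
                          f_min = 1) {
  trap <- .trace_meta(trace)
  fs <- trap$sample_rate
  if (t_min * fs < 5) abort("`t_min` must span at least 5 samples")
  params <- attr(trace, "params")
  step_pn <- trap$stiffness * (params$step_size %||% 8.2)
  w2 <- max(3L, round(0.002 * fs))
  # step-edge threshold: at least half a step, and >= 4 sigma of the
  # local-mean difference noise so plateaus are not split by noise
  jump_thr <- max(0.55 * step_pn, 4 * trap$noise_sd * sqrt(2 / w2))
  f_ev <- .boxcar(trace$force, round(fs / 1000))
  f_raw <- trace$force
  n <- length(f_raw)
  cm <- c(0, cumsum(f_raw))
  win_mean <- function(a, b) (cm[b + 1L] - cm[a]) / (b - a + 1L)
  E1 <- c(0, cumsum(f_ev)); E2 <- c(0, cumsum(f_ev^2))

  out <- list()
  for (r in seq_len(nrow(events))) {
    if (isTRUE(events$censored[r])) next
    a <- .t2i(events$t_start[r], fs)
    b <- min(n, .t2i(events$t_end[r], fs))
    if (b - a < 3L * w2) next
    idx <- a:b
    m <- length(idx)
    # two-sided local mean difference marks step transitions
    lead_m <- (cm[pmin(idx + w2, b) + 1L] - cm[idx + 1L]) /
      pmax(1L, pmin(idx + w2, b) - idx)
    lag_m <- (cm[idx] - cm[pmax(idx - w2, a)]) / pmax(1L, idx - pmax(idx - w2, a))
    jump <- abs(lead_m - lag_m) > jump_thr
    jump[c(seq_len(w2), (m - w2 + 1L):m)] <- FALSE
    zr <- .runs(jump)
    zones <- zr[zr$value, , drop = FALSE]
    centers <- if (nrow(zones)) round((zones$start + zones$end) / 2) else integer()
    bounds <- c(1L, centers, m)   # plateau boundaries in local coordinates
    for (q in seq_len(length(bounds) - 1L)) {
      lo <- bounds[q]; hi <- bounds[q + 1L]
      if ((hi - lo) / fs < t_min) next
      a1 <- idx[min(lo + w2, hi)]; b1 <- idx[max(hi - w2, lo)]
      if (b1 <= a1) next
      # longest band-limited stretch ending at the plateau end (stalls
      # abut the terminating drop); handles both stepped arrivals and
      # smooth force ramps into a plateau
      len_min <- max(2L, ceiling(t_min * fs) - 2L * w2)
      if (b1 - a1 + 1L < len_min) next
      cand <- a1:(b1 - len_min + 1L)
      mlen <- b1 - cand + 1L
      mu <- (E1[b1 + 1L] - E1[cand]) / mlen
      vv <- (E2[b1 + 1L] - E2[cand]) / mlen - mu^2
      okv <- vv <= band_sd^2
      if (!any(okv)) next
      a2 <- cand[which(okv)[1L]]
      # no residual trend: the two half means must agree within the band
      mid <- (a2 + b1) %/% 2L
      if (abs(win_mean(a2, mid) - win_mean(mid + 1L, b1)) > band_sd) next
      mf <- win_mean(a2, b1)
      if (mf < f_min) next
      # must terminate the event or abut a downward step (slip/backstep)
      terminal <- q == length(bounds) - 1L
      if (!terminal) {
        nxt_lo <- idx[min(hi + w2, m)]
        nxt_hi <- idx[min(hi + 3L * w2, m)]
        down <- win_mean(nxt_lo, max(nxt_lo, nxt_hi)) < mf - 0.5 * jump_thr
        if (!down) next
      }
      dur <- (b1 - a2 + 1L + 2L * w2) / fs
      if (dur < t_min) next
      out[[length(out) + 1L]] <- tibble(
        encounter = events$encounter[r], event = events$event[r],
        t_start = trace$time[a2], duration = dur, mean_force = mf)
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(encounter = integer(), event = integer(),
                  t_start = numeric(), duration = numeric(),
                  mean_force = numeric())
  }
  structure(res, t_min = t_min, band_sd = band_sd, f_min = f_min)
}

#' Exponential fit to stall-duration cumulative distribution
#'
#' Least-squares fit of the empirical CDF of stall durations to
#' `1 - exp(-t / T)`, censored below the stall criterion (durations shorter
#' than the criterion are unobservable; by memorylessness the conditional
#' CDF is `1 - exp(-(t - criterion) / T)`). The SEM of the characteristic
#' time `T` is obtained from 200 bootstrap resamples.
#'
#' @param durations stall durations, s (>= 20 values).
#' @param criterion censoring point, s; defaults to `min(durations)`.
#' @param n_boot bootstrap resamples for the SEM.
#' @param seed seed for the bootstrap.
#' @return a `stall_time_fit` object with elements `T`, `T_sem`, `n`,
#'   `criterion`.
#' @export
fit_stall_time_cdf <- function(durations, criterion = NULL, n_boot = 200,
                               seed = 1) {
  durations <- durations[is.finite(durations)]
  if (length(durations) < 20) abort("fit_stall_time_cdf() needs >= 20 durations")
  if (diff(range(durations)) == 0) abort("degenerate input: all durations identical")
  criterion <- criterion %||% min(durations)
  x <- sort(durations[durations >= criterion])

  fit_T <- function(x) {
    nn <- length(x)
    Fe <- (seq_len(nn) - 0.5) / nn
    sse <- function(logT) {
      Tm <- exp(logT)
      sum((Fe - (1 - exp(-(x - criterion) / Tm)))^2)
    }
    mu <- max(mean(x - criterion), 1e-8)
    exp(optimize(sse, log(c(mu / 50, mu * 50)))$minimum)
  }
  Tm <- fit_T(x)
  set.seed(seed)
  bt <- replicate(n_boot, fit_T(sort(sample(x, replace = TRUE))))
  structure(list(T = Tm, T_sem = sd(bt), n = length(x), criterion = criterion),
            class = "stall_time_fit")
}

#' @export
print.stall_time_fit <- function(x, ...) {
  cat(sprintf("<stall_time_fit> T = %.4g +- %.2g s (n = %d, censored < %.3g s)\n",
              x$T, x$T_sem, x$n, x$criterion))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stall_time_fit <- function(x, ...) {
  tibble(term = "T", estimate = x$T, std.error = x$T_sem, n = x$n,
         criterion = x$criterion)
}

#' Clustering metrics of force-generation events
#'
#' Number of engagement events per microtubule encounter (mean +- SEM) and
#' the distribution of cluster durations (median with quartiles).
#'
#' @param events output of [detect_events()] (possibly row-bound over
#'   traces, keeping `encounter` unique per trace via [analyze_trap()]).
#' @return a `cluster_metrics` object.
#' @export
cluster_metrics <- function(events) {
  if (nrow(events) == 0) abort("no events")
  key <- if ("trace" %in% names(events)) c("trace", "encounter") else "encounter"
  per <- events |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(n_events = dplyr::n(),
              duration = max(.data$t_end) - min(.data$t_start),
              .groups = "drop")
  mq <- median_quartiles(per$duration)
  structure(list(
    events_per_encounter = mean(per$n_events),
    events_per_encounter_sem = sd(per$n_events) / sqrt(nrow(per)),
    n_encounters = nrow(per),
    cluster_duration_median = mq$median,
    cluster_duration_q1 = mq$q1, cluster_duration_q3 = mq$q3,
    per_encounter = per), class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf("<cluster_metrics> %.3g +- %.2g events/encounter (n = %d); cluster duration %.3g (%.3g, %.3g) s\n",
              x$events_per_encounter, x$events_per_encounter_sem,
              x$n_encounters, x$cluster_duration_median,
              x$cluster_duration_q1, x$cluster_duration_q3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_metrics <- function(x, ...) x$per_encounter

#' Run the full trap analysis on one or more traces
#'
#' Convenience wrapper: encounters, events and stalls for each trace, with
#' a `trace` id column so event tables can be pooled.
#'
#' @param traces a `trap_trace` or list of them.
#' @param threshold,min_gap passed to [segment_encounters()].
#' @param stall_criterion,band_sd,f_min passed to [detect_stalls()].
#' @return list with `events` and `stalls` tibbles.
#' @export
analyze_trap <- function(traces, threshold = NULL, min_gap = 0.5,
                         stall_criterion = 0.01, band_sd = 0.15, f_min = 1) {
  if (inherits(traces, "trap_trace")) traces <- list(traces)
  ev <- list(); stl <- list()
  for (i in seq_along(traces)) {
    enc <- segment_encounters(traces[[i]], threshold, min_gap)
    e <- detect_events(traces[[i]], enc, threshold = threshold)
    s <- detect_stalls(traces[[i]], e, t_min = stall_criterion,
                       band_sd = band_sd, f_min = f_min)
    if (nrow(e)) ev[[length(ev) + 1L]] <- mutate(e, trace = i, .before = 1L)
    if (nrow(s)) stl[[length(stl) + 1L]] <- mutate(s, trace = i, .before = 1L)
  }
  list(events = bind_rows(ev), stalls = bind_rows(stl))
}

#' Summary statistics of trap force generation
#'
#' Runs the complete pipeline (encounter segmentation, event detection,
#' stall detection at the requested criterion) and reports the observables
#' used throughout: detachment-force median with quartiles, stall-force
#' mean +- SEM from a Gaussian fit, characteristic stalling time from the
#' exponential CDF fit, and events per encounter, each with its n.
#'
#' @param traces a `trap_trace` or list of traces.
#' @param stall_criterion minimum stall-plateau duration, s.
#' @param threshold detection threshold, pN.
#' @param ... further arguments to [analyze_trap()].
#' @return a `force_summary` object; `tidy()` gives the statistics as a
#'   tibble, `glance()` a one-row summary.
#' @export
summarize_forces <- function(traces, stall_criterion = 0.01, threshold = NULL,
                             ...) {
  an <- analyze_trap(traces, threshold = threshold,
                     stall_criterion = stall_criterion, ...)
  ev <- an$events
  if (nrow(ev) == 0) abort("no force-generation events detected")
  det <- ev$detach_force[!ev$censored & is.finite(ev$detach_force)]
  mq <- median_quartiles(det)
  cm <- cluster_metrics(ev)
  stalls <- an$stalls
  if (nrow(stalls) >= 20) {
    gf <- fit_gaussian(stalls$mean_force)
    st_fit <- fit_stall_time_cdf(stalls$duration, criterion = stall_criterion)
    stall_mean <- gf$mean; stall_sem <- gf$sem
    Tm <- st_fit$T; T_sem <- st_fit$T_sem
  } else if (nrow(stalls) > 0) {
    stall_mean <- mean(stalls$mean_force)
    stall_sem <- sd(stalls$mean_force) / sqrt(nrow(stalls))
    Tm <- NA_real_; T_sem <- NA_real_
  } else {
    stall_mean <- NA_real_; stall_sem <- NA_real_
    Tm <- NA_real_; T_sem <- NA_real_
  }
  structure(list(
    detach_median = mq$median, detach_q1 = mq$q1, detach_q3 = mq$q3,
    n_events = length(det),
    stall_mean = stall_mean, stall_sem = stall_sem,
    n_stalls = nrow(stalls), stall_criterion = stall_criterion,
    stall_time_T = Tm, stall_time_T_sem = T_sem,
    events_per_encounter = cm$events_per_encounter,
    events_per_encounter_sem = cm$events_per_encounter_sem,
    n_encounters = cm$n_encounters,
    events = ev, stalls = stalls), class = "force_summary")
}

#' @export
print.force_summary <- function(x, ...) {
  cat("<force_summary>\n")
  cat(sprintf("  detachment force: %.3g (%.3g, %.3g) pN, n = %d\n",
              x$detach_median, x$detach_q1, x$detach_q3, x$n_events))
  cat(sprintf("  stall force (>= %.0f ms): %.3g +- %.2g pN, n = %d\n",
              1000 * x$stall_criterion, x$stall_mean, x$stall_sem, x$n_stalls))
  cat(sprintf("  characteristic stall time: %.3g +- %.2g ms\n",
              1000 * x$stall_time_T, 1000 * x$stall_time_T_sem))
  cat(sprintf("  events per encounter: %.3g +- %.2g (n = %d)\n",
              x$events_per_encounter, x$events_per_encounter_sem,
              x$n_encounters))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.force_summary <- function(x, ...) {
  tibble(statistic = c("detach_median", "detach_q1", "detach_q3", "stall_mean",
                       "stall_time_T", "events_per_encounter"),
         value = c(x$detach_median, x$detach_q1, x$detach_q3, x$stall_mean,
                   x$stall_time_T, x$events_per_encounter),
         sem = c(NA, NA, NA, x$stall_sem, x$stall_time_T_sem,
                 x$events_per_encounter_sem),
         n = c(x$n_events, x$n_events, x$n_events, x$n_stalls, x$n_stalls,
               x$n_encounters))
}

#' @exportS3Method generics::glance
glance.force_summary <- function(x, ...) {
  tibble(detach_median = x$detach_median, stall_mean = x$stall_mean,
         stall_time_T = x$stall_time_T,
         events_per_encounter = x$events_per_encounter,
         n_events = x$n_events, n_stalls = x$n_stalls,
         n_encounters = x$n_encounters)
}
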