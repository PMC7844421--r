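# Continuous-time (Gillespie) simulation of a bead-motor-trap system.
#
# The motor state alternates between: waiting for a microtubule encounter
# (rate k_land), strongly bound and stepping against the trap, a brief
# weakly bound slip transit, and a detached-but-captured state from which
# it either rebinds (k_reattach) or the encounter ends (k_escape). The bead
# is slaved quasi-statically to the motor while bound and relaxes
# exponentially to the trap center when released.

# internal engine; uses the RNG state of the caller
.gillespie_trap <- function(p, trap, duration) {
  k <- trap$stiffness
  delta <- p$step_size
  inert <- p$k_step0 <= 0 && p$k_det0 <= 0 && p$k_slip0 <= 0 &&
    p$k_reattach <= 0

  cap_n <- 4096L
  seg_t0 <- numeric(cap_n); seg_x <- numeric(cap_n); seg_decay <- logical(cap_n)
  n_seg <- 0L
  add_seg <- function(t0, x, decay) {
    n_seg <<- n_seg + 1L
    if (n_seg > length(seg_t0)) {
      seg_t0 <<- c(seg_t0, numeric(length(seg_t0)))
      seg_x <<- c(seg_x, numeric(length(seg_x)))
      seg_decay <<- c(seg_decay, logical(length(seg_decay)))
    }
    seg_t0[n_seg] <<- t0; seg_x[n_seg] <<- x; seg_decay[n_seg] <<- decay
  }

  att_on <- c(); att_off <- c(); att_F <- c(); att_enc <- c(); att_end <- c()
  st_t <- c(); st_s <- c(); st_kind <- c()
  enc_t0 <- c(); enc_t1 <- c(); enc_censored <- c()

  t <- 0
  add_seg(0, 0, FALSE)
  enc_id <- 0L

  if (!inert && trap$k_land > 0) {
    repeat {
      # free bead waiting for an encounter
      t_att <- t + rexp(1L, trap$k_land)
      if (t_att >= duration) break
      enc_id <- enc_id + 1L
      enc_start <- t_att
      t <- t_att
      x <- runif(1L, 0, delta)      # engagement offset on the 8-nm lattice
      t_on <- t
      attached <- TRUE
      last_off <- NA_real_
      ended <- FALSE
      censored <- FALSE

      while (attached) {
        add_seg(t, x, FALSE)
        F <- k * x
        pb <- .p_back(F, p)
        ks <- .rate_step(F, p)
        kf <- (1 - pb) * ks
        kb <- pb * ks
        kd <- .rate_detach(F, p)
        ksl <- .rate_slip(F, p)
        R <- kf + kb + kd + ksl
        dt <- if (R > 0) rexp(1L, R) else Inf
        if (t + dt >= duration) { # trace ends while bound
          t <- duration; censored <- TRUE
          att_on <- c(att_on, t_on); att_off <- c(att_off, NA_real_)
          att_F <- c(att_F, NA_real_); att_enc <- c(att_enc, enc_id)
          att_end <- c(att_end, "censored")
          break
        }
        t <- t + dt
        u <- runif(1L) * R
        if (u < kf) {
          st_t <- c(st_t, t); st_s <- c(st_s, delta); st_kind <- c(st_kind, "step")
          x <- x + delta
        } else if (u < kf + kb) {
          st_t <- c(st_t, t); st_s <- c(st_s, -delta); st_kind <- c(st_kind, "step")
          x <- x - delta
        } else if (u < kf + kb + kd) {
          # direct release from the strongly bound state
          att_on <- c(att_on, t_on); att_off <- c(att_off, t)
          att_F <- c(att_F, k * x); att_enc <- c(att_enc, enc_id)
          att_end <- c(att_end, "detach")
          last_off <- t
          attached <- FALSE
        } else {
          # slip: back one site, weakly bound transit, then release or
          # re-engagement
          st_t <- c(st_t, t); st_s <- c(st_s, -delta); st_kind <- c(st_kind, "slip")
          x <- x - delta
          add_seg(t, x, FALSE)
          if (t + p$t_slip >= duration) {
            t <- duration; censored <- TRUE
            att_on <- c(att_on, t_on); att_off <- c(att_off, NA_real_)
            att_F <- c(att_F, NA_real_); att_enc <- c(att_enc, enc_id)
            att_end <- c(att_end, "censored")
            break
          }
          t <- t + p$t_slip
          if (runif(1L) < p$p_slip_detach) {
            att_on <- c(att_on, t_on); att_off <- c(att_off, t)
            att_F <- c(att_F, k * x); att_enc <- c(att_enc, enc_id)
            att_end <- c(att_end, "slip_release")
            last_off <- t
            attached <- FALSE
          }
        }

        if (!attached && !censored) {
          # bead relaxing; after the dead time it competes rebind vs escape
          add_seg(t, x, TRUE)
          rates <- p$k_reattach + trap$k_escape
          dt2 <- trap$rebind_dead + if (rates > 0) rexp(1L, rates) else Inf
          if (t + dt2 >= duration) { t <- duration; censored <- TRUE; break }
          t <- t + dt2
          if (rates > 0 && runif(1L) < p$k_reattach / rates) {
            x <- runif(1L, 0, delta)
            t_on <- t
            attached <- TRUE
          } else {
            ended <- TRUE
          }
        }
        if (censored || ended) break
      }

      enc_t0 <- c(enc_t0, enc_start)
      enc_t1 <- c(enc_t1, if (is.na(last_off)) t else last_off)
      enc_censored <- c(enc_censored, censored)
      if (censored || t >= duration) break
      add_seg(t, 0, FALSE)  # bead free at trap center until next landing
    }
  }

  list(
    segments = list(t0 = seg_t0[seq_len(n_seg)], x = seg_x[seq_len(n_seg)],
                    decay = seg_decay[seq_len(n_seg)]),
    attachments = tibble(encounter = as.integer(att_enc %||% integer()),
                         t_on = as.numeric(att_on %||% numeric()),
                         t_off = as.numeric(att_off %||% numeric()),
                         detach_force = as.numeric(att_F %||% numeric()),
                         end = as.character(att_end %||% character())),
    steps = tibble(time = as.numeric(st_t %||% numeric()),
                   size = as.numeric(st_s %||% numeric()),
                   kind = as.character(st_kind %||% character())),
    encounters = tibble(encounter = seq_along(enc_t0 %||% numeric()),
                        t_start = as.numeric(enc_t0 %||% numeric()),
                        t_end = as.numeric(enc_t1 %||% numeric()),
                        censored = as.logical(enc_censored %||% logical()))
  )
}

#' Simulate an optical-trap force record with ground truth
#'
#' Runs a continuous-time stochastic simulation of a single motor working
#' against a fixed optical trap (see [motor_params()] for the kinetic
#' scheme), samples the bead force on a uniform grid with additive Gaussian
#' measurement noise, and returns the trace together with an exact event
#' log (attachments, steps, per-attachment detachment forces, encounter
#' bounds) for use as an analysis oracle.
#'
#' @param params a [motor_params()] object (or [kinesin_preset()] result).
#' @param trap a [trap_config()] object.
#' @param duration record length, s.
#' @param seed integer seed; required, recorded in the trace metadata.
#' @return a `trap_trace` tibble with columns `time` (s) and `force` (pN);
#'   the trap configuration, motor parameters and the ground-truth log are
#'   attached as attributes (see [ground_truth()]).
#' @examples
#' tr <- simulate_trap_trace(kinesin_preset("KIF1A(1-393)"),
#'                           trap_config(k_land = 1), duration = 5, seed = 1)
#' ground_truth(tr)$attachments
#' @export
simulate_trap_trace <- function(params, trap = trap_config(), duration, seed) {
  if (!inherits(params, "motor_params")) abort("`params` must be a motor_params object")
  if (!inherits(trap, "trap_config")) abort("`trap` must be a trap_config object")
  .check_scalar(duration, "duration", min = 0, allow_min = FALSE)
  seed <- .assert_seed(seed)
  set.seed(seed)

  sim <- .gillespie_trap(params, trap, duration)

  fs <- trap$sample_rate
  n <- floor(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  seg <- sim$segments
  pos <- seg$x[findInterval(tt, seg$t0)]
  # overwrite decaying (bead-relaxation) stretches with the exponential
  dec <- which(seg$decay)
  for (j in dec) {
    t0 <- seg$t0[j]
    t1 <- if (j < length(seg$t0)) seg$t0[j + 1L] else duration
    i0 <- ceiling(t0 * fs - 1e-9) + 1L
    i1 <- min(n, ceiling(t1 * fs - 1e-9))
    if (i1 >= i0) {
      idx <- i0:i1
      pos[idx] <- seg$x[j] * exp(-(tt[idx] - t0) / trap$tau_relax)
    }
  }
  force <- trap$stiffness * pos
  if (trap$noise_sd > 0) force <- force + rnorm(n, 0, trap$noise_sd)

  out <- tibble(time = tt, force = force)
  class(out) <- c("trap_trace", class(out))
  attr(out, "trap") <- trap
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  attr(out, "truth") <- structure(sim[c("attachments", "steps", "encounters")],
                                  class = "truth_log")
  out
}

#' Ground-truth event log of a simulated trace
#'
#' @param trace a `trap_trace` from [simulate_trap_trace()].
#' @return a list of tibbles: `attachments` (with per-attachment detachment
#'   forces in pN), `steps` (signed sizes, nm, `kind` is `"step"` or
#'   `"slip"`), and `encounters` (bounds in s).
#' @export
ground_truth <- function(trace) {
  tl <- attr(trace, "truth")
  if (is.null(tl)) abort("`trace` carries no ground-truth log")
  tl
}

#' @export
print.truth_log <- function(x, ...) {
  cat("<truth_log> ", nrow(x$attachments), " attachments, ",
      nrow(x$steps), " steps, ", nrow(x$encounters), " encounters\n", sep = "")
  invisible(x)
}

#' @export
print.trap_trace <- function(x, ...) {
  trap <- attr(x, "trap")
  cat("<trap_trace> ", nrow(x), " samples @ ", trap$sample_rate, " Hz, k = ",
      trap$stiffness, " pN/nm, construct ",
      attr(x, "params")$construct_label, "\n", sep = "")
  NextMethod()
}
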