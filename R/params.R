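#' Motor kinetic parameter set
#'
#' Bundles the mechanochemical parameters of a single dimeric kinesin motor
#' as used by [simulate_trap_trace()]. The stepping/detachment scheme is:
#'
#' * forward stepping at `k_step0 * exp(-F * d_load / kBT)`, clipped to zero
#'   once the trap force reaches `F_stall_cap` (the stall ceiling);
#' * a backstep fraction rising linearly from `p_back0` at zero load to 2%
#'   at 1.5 pN (motors take ~98% forward steps under 1--2 pN load);
#' * direct (Bell-law) release from the strongly bound state at
#'   `k_det0 * exp(F / F_d)`;
#' * a force-promoted slip: at `k_slip0 * exp(F * d_slip / kBT)` the motor
#'   loses grip, slides back one site into a weakly bound state lasting
#'   `t_slip` seconds, from which it releases with probability
#'   `p_slip_detach` and otherwise re-engages. Kinesin-3 motors, which
#'   release almost exclusively below their stall plateau, are modelled with
#'   `k_det0 = 0` so that every release passes through the slip state;
#' * while the bead is back in the trap capture window the motor rebinds at
#'   `k_reattach`, producing the clustered sawtooth pattern characteristic
#'   of KIF1A.
#'
#' @param construct_label construct name, e.g. `"KIF1A(1-393)"`.
#' @param step_size step amplitude seen by the bead, nm.
#' @param k_step0 unloaded stepping rate, 1/s.
#' @param d_load load-sensitivity distance of the stepping rate, nm.
#' @param p_back0 unloaded backstep probability.
#' @param k_det0 unloaded direct detachment rate, 1/s (Bell law).
#' @param F_d detachment force scale of the Bell law, pN.
#' @param k_slip0 unloaded slip rate, 1/s.
#' @param d_slip slip load-sensitivity distance, nm.
#' @param t_slip duration of the weakly bound slip transit, s.
#' @param p_slip_detach probability that a slip ends in release rather than
#'   re-engagement.
#' @param k_reattach rebinding rate while the bead is within the capture
#'   window, 1/s.
#' @param F_stall_cap force at which forward stepping ceases, pN.
#' @return an object of class `motor_params`.
#' @seealso [kinesin_preset()] for calibrated per-construct parameter sets.
#' @export
motor_params <- function(construct_label = "custom",
                         step_size = 8.2,
                         k_step0 = 250,
                         d_load = 0.5,
                         p_back0 = 0.002,
                         k_det0 = 1,
                         F_d = 2,
                         k_slip0 = 0,
                         d_slip = 4,
                         t_slip = 0.004,
                         p_slip_detach = 0.85,
                         k_reattach = 5,
                         F_stall_cap = 3) {
  vals <- list(construct_label = as.character(construct_label)[1],
               step_size = step_size, k_step0 = k_step0, d_load = d_load,
               p_back0 = p_back0, k_det0 = k_det0, F_d = F_d,
               k_slip0 = k_slip0, d_slip = d_slip, t_slip = t_slip,
               p_slip_detach = p_slip_detach, k_reattach = k_reattach,
               F_stall_cap = F_stall_cap)
  for (nm in setdiff(names(vals), "construct_label")) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L ||
        !is.finite(vals[[nm]])) {
      abort(paste0("motor parameter `", nm, "` must be a single finite number"))
    }
  }
  .check_scalar(vals$step_size, "step_size", min = 0, allow_min = FALSE)
  .check_scalar(vals$F_d, "F_d", min = 0, allow_min = FALSE)
  .check_scalar(vals$p_back0, "p_back0", min = 0, max = 1)
  .check_scalar(vals$p_slip_detach, "p_slip_detach", min = 0, max = 1)
  for (nm in c("k_step0", "k_det0", "k_slip0", "k_reattach", "d_load",
               "d_slip", "t_slip", "F_stall_cap")) {
    .check_scalar(vals[[nm]], nm, min = 0)
  }
  structure(vals, class = "motor_params")
}

#' @export
print.motor_params <- function(x, ...) {
  cat("<motor_params> ", x$construct_label, "\n", sep = "")
  num <- unlist(x[setdiff(names(x), "construct_label")])
  print(round(num, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.motor_params <- function(x, ...) {
  tibble(parameter = setdiff(names(x), "construct_label"),
         value = unlist(x[setdiff(names(x), "construct_label")], use.names = FALSE))
}

#' Optical trap / assay configuration
#'
#' @param stiffness trap stiffness k, pN/nm (force = k x bead displacement).
#' @param sample_rate acquisition rate, Hz.
#' @param noise_sd additive Gaussian measurement noise on the force, pN.
#' @param detection_limit smallest resolvable force, pN.
#' @param tau_relax bead relaxation time constant to the trap center after
#'   motor release, s.
#' @param rebind_dead dead time after release before the bead re-enters the
#'   capture window and rebinding can occur, s.
#' @param k_escape rate at which a detached bead leaves the capture window,
#'   ending the microtubule encounter, 1/s.
#' @param k_land rate of new microtubule encounters while the bead is free,
#'   1/s.
#' @return an object of class `trap_config`.
#' @export
trap_config <- function(stiffness = 0.055,
                        sample_rate = 5000,
                        noise_sd = 0.15,
                        detection_limit = 0.3,
                        tau_relax = 3e-4,
                        rebind_dead = 2e-3,
                        k_escape = 2,
                        k_land = 0.1) {
  .check_scalar(stiffness, "stiffness", min = 0.001, max = 1)
  .check_scalar(sample_rate, "sample_rate", min = 0, allow_min = FALSE)
  .check_scalar(noise_sd, "noise_sd", min = 0)
  .check_scalar(detection_limit, "detection_limit", min = 0)
  .check_scalar(tau_relax, "tau_relax", min = 0, allow_min = FALSE)
  .check_scalar(rebind_dead, "rebind_dead", min = 0)
  .check_scalar(k_escape, "k_escape", min = 0)
  .check_scalar(k_land, "k_land", min = 0)
  structure(list(stiffness = stiffness, sample_rate = sample_rate,
                 noise_sd = noise_sd, detection_limit = detection_limit,
                 tau_relax = tau_relax, rebind_dead = rebind_dead,
                 k_escape = k_escape, k_land = k_land),
            class = "trap_config")
}

#' @export
print.trap_config <- function(x, ...) {
  cat("<trap_config>\n"); print(unlist(x)); invisible(x)
}

# --- force-dependent rate laws (shared by simulator and calibration) -------

.p_back <- function(F, p) {
  pmin(0.25, p$p_back0 + (0.02 - p$p_back0) * pmax(F, 0) / 1.5)
}

.rate_step <- function(F, p) {
  ifelse(F >= p$F_stall_cap, 0, p$k_step0 * exp(-pmax(F, 0) * p$d_load / kBT))
}

.rate_detach <- function(F, p) p$k_det0 * exp(pmax(F, 0) / p$F_d)

# slip rate saturates at the stall ceiling: once stepping has stalled the
# release propensity no longer grows with load, so stall durations are
# force-independent within the stall band
.rate_slip <- function(F, p) {
  p$k_slip0 * exp(pmin(pmax(F, 0), p$F_stall_cap) * p$d_slip / kBT)
}

# --- calibrated construct presets ------------------------------------------

# Values produced by calibrate_preset() against the observables used
# throughout the package (detachment-force median, stall-force mean at the
# stated plateau criterion, characteristic stall time, events per MT
# encounter) and then frozen here.
.preset_table <- function() {
  list(
    "KIF1A(1-393)" = motor_params(
      construct_label = "KIF1A(1-393)",
      step_size = 7.7, k_step0 = 273, d_load = 0.3, p_back0 = 0.002,
      k_det0 = 0, F_d = 2, k_slip0 = 0.503, d_slip = 6.2, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 48, F_stall_cap = 2.913),
    "KIF1A(FLact)" = motor_params(
      construct_label = "KIF1A(FLact)",
      step_size = 7.7, k_step0 = 247, d_load = 0.3, p_back0 = 0.002,
      k_det0 = 4.1, F_d = 2.2, k_slip0 = 0.12, d_slip = 6.2, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 114, F_stall_cap = 2.83),
    "KIF5C(1-560)" = motor_params(
      construct_label = "KIF5C(1-560)",
      step_size = 8.2, k_step0 = 100, d_load = 2.5, p_back0 = 0.002,
      k_det0 = 0.0127, F_d = 0.9, k_slip0 = 0.008, d_slip = 4, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 0.42, F_stall_cap = 4.465),
    "UNC-104(1-389)" = motor_params(
      construct_label = "UNC-104(1-389)",
      step_size = 7.9, k_step0 = 230, d_load = 0.3, p_back0 = 0.002,
      k_det0 = 0.61, F_d = 0.7, k_slip0 = 0.55, d_slip = 6.2, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 4.0, F_stall_cap = 2.42),
    "KIF1A(1-393)-V8M" = motor_params(
      construct_label = "KIF1A(1-393)-V8M",
      step_size = 7.7, k_step0 = 169, d_load = 0.3, p_back0 = 0.002,
      k_det0 = 0, F_d = 2, k_slip0 = 2.4, d_slip = 6.2, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 60, F_stall_cap = 2.94),
    "KIF1A(1-393)-Y89D" = motor_params(
      construct_label = "KIF1A(1-393)-Y89D",
      step_size = 7.7, k_step0 = 221, d_load = 0.3, p_back0 = 0.002,
      k_det0 = 0, F_d = 2, k_slip0 = 18, d_slip = 6.2, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 60, F_stall_cap = 2.94),
    "KIF1A(1-393)-SW" = motor_params(
      construct_label = "KIF1A(1-393)-SW",
      step_size = 7.7, k_step0 = 273, d_load = 0.3, p_back0 = 0.002,
      k_det0 = 0, F_d = 2, k_slip0 = 3.1, d_slip = 6.2, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 5.2, F_stall_cap = 2.94),
    "KIF1A(1-393)-SWA" = motor_params(
      construct_label = "KIF1A(1-393)-SWA",
      step_size = 7.7, k_step0 = 273, d_load = 0.3, p_back0 = 0.002,
      k_det0 = 0, F_d = 2, k_slip0 = 4.3, d_slip = 6.2, t_slip = 0.004,
      p_slip_detach = 0.85, k_reattach = 4.8, F_stall_cap = 2.94)
  )
}

#' Calibrated motor presets
#'
#' Returns the shipped, calibrated [motor_params()] set for a kinesin
#' construct. Presets were produced with [calibrate_preset()] so that
#' simulating with them and analysing the traces with the package's own
#' pipeline reproduces the construct's observed detachment-force median,
#' stall-force mean, characteristic stall time and events per encounter.
#'
#' @param construct one of `names(kinesin_presets())`; matching is
#'   case-insensitive and ignores spaces.
#' @return a `motor_params` object.
#' @export
kinesin_preset <- function(construct = "KIF1A(1-393)") {
  tab <- .preset_table()
  key <- gsub("[ ]", "", tolower(construct))
  hit <- match(key, gsub("[ ]", "", tolower(names(tab))))
  if (is.na(hit)) {
    abort(paste0("unknown construct '", construct, "'; available: ",
                 paste(names(tab), collapse = ", ")))
  }
  tab[[hit]]
}

#' @rdname kinesin_preset
#' @export
kinesin_presets <- function() .preset_table()
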