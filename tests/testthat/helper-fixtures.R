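# Shared fixtures: hand-built traces and event/truth matching.

# wrap a force vector as a trap_trace
mk_trace <- function(force, trap = trap_config(noise_sd = 0)) {
  n <- length(force)
  out <- tibble::tibble(time = (seq_len(n) - 1) / trap$sample_rate,
                        force = force)
  class(out) <- c("trap_trace", class(out))
  attr(out, "trap") <- trap
  attr(out, "params") <- motor_params()
  out
}

# a sawtooth tooth: linear ramp to `peak` then a flat top, then release
# (force falls to zero); `fs` samples/s
mk_tooth <- function(peak, ramp_s = 0.05, top_s = 0.02, fs = 5000) {
  c(seq(0, peak, length.out = round(ramp_s * fs)),
    rep(peak, round(top_s * fs)))
}

# match detected events to logged attachments by release time; returns a
# data frame with truth and detected forces for events above `fmin`
match_events <- function(trace, events, fmin = 0.5, tol_t = 0.005) {
  att <- ground_truth(trace)$attachments
  att <- att[!is.na(att$detach_force) & att$detach_force >= fmin, , drop = FALSE]
  if (nrow(att) == 0 || nrow(events) == 0) {
    return(data.frame(truth = numeric(), detected = numeric(),
                      dt = numeric()))
  }
  hit <- vapply(att$t_off, function(t) {
    i <- which.min(abs(events$t_end - t))
    c(i, abs(events$t_end[i] - t))
  }, numeric(2))
  data.frame(truth = att$detach_force,
             detected = events$detach_force[hit[1, ]],
             dt = hit[2, ])
}
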