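# Independent oracles, coded from the model definitions rather than the
# package internals.

# Embedded-jump-chain simulation of the attached motor: returns the
# release force of each force-generation event. The distribution of
# release forces depends only on the transition probabilities, so bead
# dynamics and waiting times can be ignored here.
oracle_detach_forces <- function(p, stiffness, n_events, seed) {
  set.seed(seed)
  kBT <- 4.11
  out <- numeric(n_events)
  for (e in seq_len(n_events)) {
    x <- runif(1, 0, p$step_size)
    repeat {
      F <- stiffness * x
      Fp <- max(F, 0)
      pb <- min(0.25, p$p_back0 + (0.02 - p$p_back0) * Fp / 1.5)
      ks <- if (F >= p$F_stall_cap) 0 else p$k_step0 * exp(-Fp * p$d_load / kBT)
      rates <- c(fwd = (1 - pb) * ks, back = pb * ks,
                 det = p$k_det0 * exp(Fp / p$F_d),
                 slip = p$k_slip0 * exp(min(Fp, p$F_stall_cap) * p$d_slip / kBT))
      if (sum(rates) <= 0) { out[e] <- NA_real_; break }
      ev <- sample(names(rates), 1, prob = rates)
      if (ev == "fwd") x <- x + p$step_size
      else if (ev == "back") x <- x - p$step_size
      else if (ev == "det") { out[e] <- stiffness * x; break }
      else {
        x <- x - p$step_size
        if (runif(1) < p$p_slip_detach) { out[e] <- stiffness * x; break }
      }
    }
  }
  out[!is.na(out)]
}

# Exhaustive search for the best k-step piecewise-constant fit
# (minimum SSE over all change-point placements with min_plateau spacing).
oracle_best_steps <- function(y, k, min_plateau) {
  n <- length(y)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  sse_seg <- function(a, b) {
    m <- b - a + 1
    (cs2[b + 1] - cs2[a]) - (cs[b + 1] - cs[a])^2 / m
  }
  best <- list(sse = Inf, cps = NULL)
  recurse <- function(start, left, cps, acc) {
    if (acc >= best$sse) return()
    if (left == 0) {
      tot <- acc + sse_seg(start, n)
      if (tot < best$sse) best <<- list(sse = tot, cps = cps)
      return()
    }
    for (c_ in (start + min_plateau - 1):(n - left * min_plateau)) {
      recurse(c_ + 1, left - 1, c(cps, c_), acc + sse_seg(start, c_))
    }
  }
  recurse(1, k, integer(), 0)
  best
}
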