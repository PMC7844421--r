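# Synthetic generators for the unloaded-assay inputs: kymograph-derived
# motility tracks, stepwise photobleaching traces, bead dilution series and
# paired conformational ensembles.

#' Simulate unloaded single-molecule motility tracks
#'
#' Landings on each microtubule are a Poisson process with intensity
#' `landing_rate * conc * mt_length`. A landing is diffusive (bounded
#' random walk with sub-threshold net displacement) with probability
#' `diffusive_frac`, otherwise processive with Gaussian velocity and an
#' exponential run length truncated at the remaining microtubule length
#' (runs reaching the MT end are censored, the central caveat for
#' run-length comparisons).
#'
#' @param vel_mean,vel_sd processive velocity distribution, um/s.
#' @param runlen_mean mean of the exponential run-length distribution, um.
#' @param diffusive_frac probability that a landing is diffusive.
#' @param mt_lengths microtubule lengths, um (one track set per MT).
#' @param frame_dt frame interval, s.
#' @param landing_rate events per min per nM per um of MT.
#' @param conc motor concentration, nM.
#' @param movie_duration movie length, s.
#' @param seed integer seed.
#' @param loc_sd localisation noise on positions, um.
#' @param diff_dwell_mean mean duration of diffusive events, s.
#' @return a `motility_tracks` tibble, one row per track, with the
#'   time--position data as a list column `data` and per-track metadata
#'   (`mt`, `mt_length`, `conc`, `movie_duration`, `frame_dt`, ground-truth
#'   `true_class` and `censored`).
#' @export
simulate_motility_tracks <- function(vel_mean = 2.1, vel_sd = 0.3,
                                     runlen_mean = 16.7,
                                     diffusive_frac = 0.044,
                                     mt_lengths = rep(c(35, 45, 55, 65, 75), 4),
                                     frame_dt = 0.1,
                                     landing_rate = 10.7, conc = 1,
                                     movie_duration = 60, seed,
                                     loc_sd = 0.02,
                                     diff_dwell_mean = 1.5) {
  for (nm in c("vel_mean", "vel_sd", "runlen_mean", "frame_dt",
               "landing_rate", "conc", "movie_duration", "loc_sd")) {
    .check_scalar(get(nm), nm, min = 0)
  }
  if (frame_dt <= 0) abort("`frame_dt` must be > 0")
  .check_scalar(diffusive_frac, "diffusive_frac", min = 0, max = 1)
  if (length(mt_lengths) == 0) abort("`mt_lengths` must be nonempty")
  seed <- .assert_seed(seed)
  set.seed(seed)

  # diffusive step SD chosen so 1-s net displacement has SD 120 nm,
  # safely below the 200-nm classifier threshold
  diff_step_sd <- 0.120 * sqrt(frame_dt)
  reflect_at <- 0.150   # walk bound; leaves margin for localisation noise

  rows <- list()
  tid <- 0L
  for (mi in seq_along(mt_lengths)) {
    L <- mt_lengths[mi]
    n_land <- rpois(1L, landing_rate / 60 * conc * L * movie_duration)
    if (n_land == 0) next
    for (j in seq_len(n_land)) {
      t0 <- runif(1L, 0, movie_duration)
      x0 <- runif(1L, 0, L)
      if (runif(1L) < diffusive_frac) {
        dwell <- 0.35 + rexp(1L, 1 / diff_dwell_mean)
        nf <- max(2L, floor(dwell / frame_dt))
        walk <- cumsum(rnorm(nf - 1L, 0, diff_step_sd))
        # fold the walk into [-reflect_at, reflect_at] (reflecting bounds)
        z <- (walk + reflect_at) %% (4 * reflect_at)
        dx <- ifelse(z < 2 * reflect_at, z - reflect_at, 3 * reflect_at - z)
        pos <- pmin(pmax(x0 + c(0, dx), 0), L)
        cls <- "diffusive"; cens <- FALSE
      } else {
        v <- max(0.05, rnorm(1L, vel_mean, vel_sd))
        run <- rexp(1L, 1 / runlen_mean)
        cens <- run > (L - x0)
        run <- min(run, L - x0)
        dwell <- run / v
        nf <- max(2L, floor(dwell / frame_dt) + 1L)
        pos <- pmin(x0 + v * (seq_len(nf) - 1L) * frame_dt, L)
        cls <- "processive"
      }
      nf <- length(pos)
      if (loc_sd > 0) pos <- pmin(pmax(pos + rnorm(nf, 0, loc_sd), 0), L)
      tid <- tid + 1L
      rows[[tid]] <- tibble(
        track = tid, mt = mi, mt_length = L, conc = conc,
        movie_duration = movie_duration, frame_dt = frame_dt,
        t_land = t0, true_class = cls, censored = cens,
        data = list(tibble(time = t0 + (seq_len(nf) - 1L) * frame_dt,
                           position = pos)))
    }
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(track = integer(), mt = integer(), mt_length = numeric(),
           conc = numeric(), movie_duration = numeric(), frame_dt = numeric(),
           t_land = numeric(), true_class = character(), censored = logical(),
           data = list())
  class(out) <- c("motility_tracks", class(out))
  attr(out, "mt_lengths") <- mt_lengths
  attr(out, "seed") <- seed
  out
}

#' Simulate a stepwise photobleaching intensity trace
#'
#' The initially active fluorophore count is binomial(`n_fluors`,
#' `p_label`); each active fluorophore bleaches independently at
#' `bleach_rate`. Intensity is `count * unit_intensity` plus Gaussian
#' noise. The true number of bleach steps within the recording is attached
#' as the `true_steps` attribute.
#'
#' @param n_fluors number of fluorophore sites (2 for a dimer).
#' @param p_label labelling probability per site.
#' @param bleach_rate bleaching rate, 1/s.
#' @param unit_intensity single-fluorophore intensity, a.u.
#' @param noise_sd intensity noise SD, a.u.
#' @param duration recording length, s.
#' @param frame_dt frame interval, s.
#' @param seed integer seed.
#' @return tibble with `time` and `intensity`; attributes `true_steps`
#'   and `n_active0`.
#' @export
simulate_bleach_trace <- function(n_fluors = 2, p_label = 0.7,
                                  bleach_rate = 0.2, unit_intensity = 100,
                                  noise_sd = 8, duration = 30,
                                  frame_dt = 0.05, seed) {
  if (!is.numeric(n_fluors) || n_fluors < 0) abort("`n_fluors` must be >= 0")
  .check_scalar(p_label, "p_label", min = 0, max = 1)
  .check_scalar(bleach_rate, "bleach_rate", min = 0)
  seed <- .assert_seed(seed)
  set.seed(seed)
  n0 <- rbinom(1L, as.integer(n_fluors), p_label)
  tt <- seq(0, duration, by = frame_dt)
  bleach_t <- if (n0 > 0 && bleach_rate > 0) sort(rexp(n0, bleach_rate)) else numeric()
  count <- vapply(tt, function(t) n0 - sum(bleach_t <= t), numeric(1))
  intensity <- count * unit_intensity
  if (noise_sd > 0) intensity <- intensity + rnorm(length(tt), 0, noise_sd)
  out <- tibble(time = tt, intensity = intensity)
  attr(out, "true_steps") <- sum(bleach_t <= duration)
  attr(out, "n_active0") <- n0
  attr(out, "unit_intensity") <- unit_intensity
  out
}

#' Simulate a bead-dilution moving-fraction series
#'
#' At each relative concentration the number of moving beads is binomial
#' with success probability given by the chosen Poisson motor-loading
#' model ([binding_fraction()]). Standard errors follow the binomial
#' convention `sqrt(f (1 - f) / n)`.
#'
#' @param lam dimensionless lambda of the Poisson model.
#' @param concentrations relative motor concentrations (strictly positive).
#' @param n_beads_per_point beads tested per concentration.
#' @param model `"processive"` or `"nonprocessive"`.
#' @param seed integer seed.
#' @return a tibble with `rel_concentration`, `n_beads`, `n_moving`,
#'   `fraction`, `se`.
#' @export
simulate_dilution_series <- function(lam, concentrations,
                                     n_beads_per_point = 80,
                                     model = c("processive", "nonprocessive"),
                                     seed) {
  model <- match.arg(model)
  .check_scalar(lam, "lam", min = 0, allow_min = FALSE)
  if (any(concentrations <= 0)) abort("`concentrations` must be > 0")
  seed <- .assert_seed(seed)
  set.seed(seed)
  C <- sort(concentrations)
  p <- binding_fraction(lam, C, model)
  n <- rep_len(n_beads_per_point, length(C))
  mv <- rbinom(length(C), n, p)
  f <- mv / n
  tibble(rel_concentration = C, n_beads = n, n_moving = mv, fraction = f,
         se = sqrt(f * (1 - f) / n))
}

#' Simulate a pair of conformational ensembles with localized shifts
#'
#' Generates a shared base geometry (a random open C-alpha chain), then
#' draws two ensembles of jittered conformations. In state B the listed
#' residue pairs have their mean separation displaced by `delta` Angstrom
#' along the pair axis (residue `j` is moved), emulating localized
#' conformational differences between two simulation ensembles.
#'
#' @param n_res number of residues.
#' @param n_conf conformations per ensemble (>= 10; 400 matches four
#'   replicate trajectories sampled at 100 frames each).
#' @param shifts data frame with columns `i`, `j`, `delta` (Angstrom); may
#'   be empty.
#' @param fluct_sd isotropic Gaussian fluctuation per coordinate, Angstrom.
#' @param seed integer seed.
#' @return list with elements `a` and `b`, each an `ensemble` object
#'   (array `n_conf x n_res x 3` with residue labels and a state label).
#' @export
simulate_ensemble_pair <- function(n_res = 30, n_conf = 400,
                                   shifts = NULL, fluct_sd = 0.3, seed) {
  if (n_conf < 10) abort("`n_conf` must be >= 10")
  .check_scalar(fluct_sd, "fluct_sd", min = 0)
  seed <- .assert_seed(seed)
  if (is.null(shifts)) {
    shifts <- tibble(i = integer(), j = integer(), delta = numeric())
  }
  shifts <- as_tibble(shifts)
  if (nrow(shifts)) {
    if (any(shifts$i < 1 | shifts$j < 1 | shifts$i > n_res | shifts$j > n_res |
              shifts$i == shifts$j)) {
      abort("shift residue indices out of range")
    }
    key <- paste(pmin(shifts$i, shifts$j), pmax(shifts$i, shifts$j))
    if (anyDuplicated(key)) abort("duplicate residue pair in `shifts`")
  }
  set.seed(seed)

  # base geometry: persistent random chain, 3.8-A virtual bonds
  dirs <- matrix(rnorm(3L * n_res), ncol = 3L)
  for (r in 2:n_res) {
    dirs[r, ] <- 0.75 * dirs[r - 1L, ] + 0.25 * dirs[r, ]
  }
  dirs <- dirs / sqrt(rowSums(dirs^2))
  base <- apply(dirs * 3.8, 2L, cumsum)

  base_b <- base
  if (nrow(shifts)) {
    for (s in seq_len(nrow(shifts))) {
      u <- base[shifts$j[s], ] - base[shifts$i[s], ]
      u <- u / sqrt(sum(u^2))
      base_b[shifts$j[s], ] <- base_b[shifts$j[s], ] + shifts$delta[s] * u
    }
  }

  draw <- function(b, label) {
    coords <- array(rep(b, each = n_conf), dim = c(n_conf, n_res, 3L))
    coords <- coords + array(rnorm(length(coords), 0, fluct_sd), dim = dim(coords))
    structure(list(coords = coords,
                   residue_labels = paste0("R", seq_len(n_res)),
                   state_label = label),
              class = "ensemble")
  }
  list(a = draw(base, "A"), b = draw(base_b, "B"))
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("<ensemble> state ", x$state_label, ": ", d[1], " conformations x ",
      d[2], " residues\n", sep = "")
  invisible(x)
}
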