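---
title: "Analysing kinesin-3 force generation with kinforce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing kinesin-3 force generation with kinforce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3)
library(kinforce)
```

## Scope

kinforce quantifies single-molecule optical-tweezers force records and
unloaded motility data for kinesin motors, with kinesin-3 (KIF1A and its
*C. elegans* homologue UNC-104) as the reference system. Kinesin-3 motors
stall near 3 pN but typically release from the microtubule below stall and
rebind within tens of milliseconds through their class-specific K-loop, so
a single microtubule encounter contains a cluster of rapid sawtooth
force-generation events. The package provides both the analyses (encounter
segmentation, event and stall detection, distribution fits, step finding,
motility statistics, Poisson bead-binding models, ensemble difference
distance matrices) and a stochastic simulator whose exact event log makes
every analysis stage testable against ground truth.

## The bead–motor–trap model

While bound, the motor holds the bead at displacement $x$ from the trap
centre and experiences a hindering force $F = kx$ with trap stiffness $k$
(default 0.055 pN/nm, acquisition 5 kHz, additive Gaussian force noise
0.15 pN). The bead is slaved quasi-statically to the motor: the analyses
operate at millisecond resolution, where full bead hydrodynamics is
irrelevant, so on release the bead simply relaxes exponentially to the
trap centre (time constant 0.3 ms — essentially instantaneous at these
stiffnesses, and short enough that every detach/reattach cycle leaves a
resolvable dip in the sampled record).

Bound-state kinetics (all rates per second, forces in pN, distances nm,
$k_BT = 4.11$ pN·nm):

* **Forward stepping** $k_\mathrm{step}(F) = k_\mathrm{step,0}
  e^{-F d_\mathrm{load}/k_BT}$, set to zero once $F \ge F_\mathrm{cap}$
  (the stall ceiling). The unloaded rate is tied to the measured unloaded
  velocity (2.1 µm/s at a 7.7-nm bead step gives 273/s for KIF1A).
  $d_\mathrm{load}$ is small for KIF1A (0.3 nm): stepping stays fast
  nearly to stall, which is what makes the observed force-generation
  cycles as short as ~50 ms, and larger for kinesin-1 (2.5 nm), whose
  velocity falls substantially under load.
* **Backsteps** occur with a probability rising linearly from
  $p_\mathrm{back,0}$ (0.002) to 2% at 1.5 pN, honouring the observation
  that these motors take ~98% forward steps under 1–2 pN load.
* **Direct release** follows a Bell law
  $k_\mathrm{det}(F) = k_{\mathrm{det},0} e^{F/F_d}$.
* **Slip release.** A direct Bell release alone cannot reproduce the
  kinesin-3 data: the measured stall force (3.12 pN, Gaussian-fit mean at
  the 10-ms plateau criterion) sits about one lattice step *above* the
  measured detachment-force median (2.65 pN), and nearly every analysed
  event contains a stall. If the motor released from the stall level the
  two numbers would coincide. The motor must descend before releasing, so
  the model includes a force-promoted slip: at
  $k_\mathrm{slip}(F) = k_{\mathrm{slip},0}
  e^{\min(F, F_\mathrm{cap}) d_\mathrm{slip}/k_BT}$ the motor loses grip,
  slides back one site into a weakly bound state of fixed 4-ms duration,
  and then releases with probability 0.85 or re-engages. For the
  kinesin-3 presets all release goes through this pathway
  ($k_{\mathrm{det},0} = 0$); kinesin-1 keeps the classic direct release.
  The slip rate saturates at the stall ceiling: once stepping has
  stalled, the release propensity no longer grows with load. This makes
  stall durations force-independent inside the ~0.4-pN-wide stall band,
  which is why the stall-force median is flat-to-slightly-increasing as
  the plateau criterion is lengthened from 10 to 100 ms (as observed);
  an unsaturated slip law would instead select low-force stalls at long
  criteria.
* **Clustering.** After release the bead re-enters the capture window
  (2-ms dead time) and the motor rebinds at $k_\mathrm{reattach}$,
  competing with loss of the encounter at $k_\mathrm{escape}$ (2/s). The
  number of events per encounter is therefore geometric with mean
  $1 + k_\mathrm{reattach}/k_\mathrm{escape}$. Rebinding engages the
  8-nm lattice at a uniformly distributed offset, which is what gives the
  stall- and detachment-force distributions their continuous spread at a
  fixed trap stiffness.

Every transition is written to a ground-truth log (attachments with
release forces, signed steps and slips, encounter bounds), which the test
suite uses as an oracle: on noise-free records the event detector must
recover every release above the detection limit with its exact force, and
a second, independently coded jump-chain simulation of the same rate laws
must reproduce the detachment-force distribution (two-sample
Kolmogorov–Smirnov).

## Preset calibration

`calibrate_preset()` adjusts the release-rate scale, release force
sensitivity, stepping rate and reattachment rate (Nelder–Mead on log
parameters, common random numbers so the objective is deterministic)
until the *analysed* observables of fresh simulations match a target set.
The shipped presets were produced this way against each construct's
published observables — e.g. KIF1A(1-393): detachment median 2.65 pN,
stall force 3.12 pN (10-ms criterion), characteristic stalling time
22.3 ms, 27 events per encounter; KIF5C(1-560): 4.64-pN stall at the
200-ms criterion — and the stall ceiling $F_\mathrm{cap}$ was set
directly from the stall-force level (it is deliberately not part of the
four-parameter optimisation). Mutant presets differ from wild type only
in their release and reattachment parameters plus the stepping rate
implied by their unloaded velocity.

Because calibration targets the full pipeline output, the presets absorb
detection-level conventions (filter bandwidths, the 0.5-s encounter
merging gap, the sparse landing rate used for clustering batches) along
with the physics.

## Analysis conventions

* **Filtering.** Event logic runs on boxcar-filtered force (500 Hz for
  encounter segmentation, 1 kHz for event bounds); the unfiltered record
  is kept for step finding and for force read-out.
* **Encounters** are maximal stretches of filtered force above the
  detection limit (~0.3 pN), with sub-0.5-s dips merged — the rapid
  detach/reattach gaps within a cluster.
* **Detachments.** A release is a force drop of ≥ 75% of the pre-drop
  force within 5 ms; the detachment force is the mean unfiltered force in
  the ~2.5 ms immediately before the drop onset, backed off far enough
  that bead-relaxation samples never contaminate it. Events that fail to
  clear the detection limit by a 0.15-pN margin or last under 3 ms are
  discarded as threshold-grazing noise.
* **Stalls.** A stall plateau must last at least the criterion (10 or
  200 ms), keep its filtered-force SD within 0.15 pN, show no residual
  trend (its two half-means must agree within the band — this is what
  rejects smooth force ramps), exceed 1 pN, and either terminate the
  event or abut a downward step. Pauses ending in a further forward step
  are not stalls. The stall force is the mean unfiltered force over the
  plateau; durations feed the censored exponential CDF fit
  $1 - e^{-(t - t_\mathrm{min})/T}$, with bootstrap SEMs (200 resamples).
* **Step finding** is iterative chi-squared fitting: the single best step
  per plateau is placed greedily, each placement is refined by
  coordinate descent (which restores the exhaustive-enumeration optimum),
  and the model size is chosen where the counter-fit quality ratio
  (counter-fit chi-squared over fit chi-squared, counter steps at plateau
  midpoints) peaks, with a minimum accepted ratio of 1.2 so featureless
  records return zero steps. Bead records are analysed in ~20-ms windows
  so that slowly and rapidly stepping stretches of a record do not
  compete for model size, and stepping records are simulated at 20 kHz —
  the bandwidth at which individual 8-nm steps with ~4-ms exponential
  dwells are resolvable at the default 2.7-nm position noise. Even so,
  ~15% of dwells are too brief to resolve and merge into double steps;
  the Gaussian histogram fit is therefore initialised at the histogram
  mode, which locks it onto the dominant single-step peak (7.7 nm for
  KIF1A). Detected forward fractions at 1–2 pN come out at 0.93–0.95
  against a generator truth of ~0.97: detection artifacts add a few
  percent of apparent backsteps, so the ~98% forward-step figure is
  reproduced only approximately.
* **Motility.** Events lasting ≤ 0.3 s are discarded; diffusive means
  < 200 nm net displacement. Velocities are per-event net displacement
  over duration with a Gaussian-CDF population fit; run lengths are
  medians with type-7 quartiles plus an exponential-vs-Gaussian CDF fit
  chosen by residual; landing rates are events per minute per nM per µm
  of microtubule, with processive-only (default), all-events, and
  dwell-time-cut definitions all available because the conventions in
  use disagree. `censored_runlength_note()` reports the fraction of runs
  ending at a microtubule end, since measured run lengths depend on the
  available track-length distribution.
* **EDDM.** Cα–Cα distances per conformation, hard-capped at 10 Å before
  differencing (short distances kept intact, long ones reduced), compared
  pair-wise with a two-sample Wilcoxon rank-sum test (normal
  approximation with tie correction for the 400-conformation default,
  exact below 50), and flagged significant only under the dual threshold
  p < 1e-5 and |mean masked difference| > 1 Å. Conformations are pooled
  across replicates; no further multiplicity correction is applied.
  Masking means a shift injected on a pair whose separation exceeds the
  cap is invisible by construction.

## What the generators do and do not emulate

The synthetic data reproduce the *structure* of the real assays: sawtooth
clustering with realistic cycle times, exponential stall durations,
construct-specific detachment-force distributions, ~8-nm stepping
staircases, censored run lengths on finite microtubules, binomial
labelling and stepwise bleaching, Poisson bead loading, and localized
distance shifts between conformational ensembles. They do not emulate
instrument drift, bead-size or stiffness variation between experiments
(simulated force distributions are therefore somewhat narrower than
measured ones — compare the detachment quartiles), vertical force
components from bead–motor geometry (invoked qualitatively to explain why
the full-length motor stalls longer than the minimal dimer; the presets
encode those differences phenomenologically), motor-to-motor
heterogeneity, or kymograph tracing errors. Passing tests therefore
validate the analysis chain and the internal consistency of the model,
not the microscopic truth of the rate laws.

## Numerical choices and degenerate inputs

Quantiles are type-7 throughout, so medians and quartiles are
bit-reproducible. Percentages of cargo-dispersion phenotypes are
truncated to whole percent, matching the printed convention of the
source counts (42/46 → 91%, 29/53 → 54%). Apparent stepping rates from
velocities round half away from zero (2.1 µm/s at 8 nm → 263/s). All
stochastic entry points require an explicit seed and record it; bootstrap
SEMs use 200 resamples with a seed from the analysis configuration.
Degenerate inputs are rejected rather than silently handled: zero-variance
samples for Gaussian fits, identical stall durations, all-zero or
all-saturated dilution series, duplicate ensemble shift pairs, mismatched
residue sets. The weighted R² of the bead-binding fits is
$1 - SS_\mathrm{res}/SS_\mathrm{tot}$ with binomial weights; a dilution
design spanning the sub-saturating regime (λC ≲ 2) is what gives the
processive/nonprocessive comparison its discriminating power, since both
models coincide at saturation.

## A short tour

```{r trap, eval = FALSE}
trace <- simulate_trap_trace(kinesin_preset("KIF1A(1-393)"),
                             trap_config(k_land = 0.5),
                             duration = 120, seed = 42)
autoplot(trace, truth = TRUE)
fs <- summarize_forces(trace, stall_criterion = 0.01)
tidy(fs)
plot_stall_histogram(fs$stalls)
```

```{r steps, eval = FALSE}
hi <- simulate_trap_trace(kinesin_preset("KIF1A(1-393)"),
                          trap_config(sample_rate = 20000, k_land = 1),
                          duration = 30, seed = 7)
steps <- find_trap_steps(hi, min_plateau = 15)
step_size_stats(steps, force_window = c(1, 2))
```

```{r eddm, eval = FALSE}
ens <- simulate_ensemble_pair(n_res = 30, n_conf = 400,
                              shifts = data.frame(i = 10, j = 13,
                                                  delta = 1.5),
                              fluct_sd = 0.3, seed = 3)
res <- eddm_compare(ens$a, ens$b)
autoplot(res)
```

## Known limitations

* The detachment-force quartile spread is narrower than measured because
  inter-experiment stiffness and linkage variation are not simulated.
* The full-length activated motor's small stall/detachment offset
  (~0.2 pN) is only approximated: with a single slip step the offset is
  quantised near one lattice step, and the preset compromises via a
  mixture of direct and slip release.
* The forward-step fraction at 1–2 pN is detected at 0.93–0.95 rather
  than ~0.98 (see above).
* Replicate structure of simulation ensembles is pooled in the EDDM
  Wilcoxon test; a hierarchical test is future work.
* `calibrate_preset()` optimises four parameters at fixed stall ceiling
  and slip sensitivity; calibrating those too would need a richer target
  set (e.g. the full stall-force histogram).
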