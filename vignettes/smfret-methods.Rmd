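---
title: "Methods: smFRET trace analysis, mixture decomposition and distance modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFRET trace analysis, mixture decomposition and distance modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smfretr)
```

# Scope and model

Single-molecule FRET (smFRET) reports the distance between a donor and
an acceptor dye attached to specific residues of a protein — here,
cysteine pairs on the two subunits of a membrane-protein dimer imaged by
TIRF microscopy at 100-ms frames over 80-s records.  The package covers
the complete numerical chain from two-channel intensity traces to
inter-dye distances:

1. **trace simulation** with known ground truth (`sim_params()`,
   `simulate_ensemble()`),
2. **photobleaching QC** — change-point detection, selection of
   molecules with a single acceptor bleach before a single donor bleach,
   per-molecule γ estimation (`detect_steps()`, `select_trace()`,
   `estimate_gamma()`),
3. **efficiency computation and histogramming** — per-frame
   `E = I_A / (I_A + γ I_D)`, 40-bin summed trace-normalized histograms,
   Gaussian mixture decomposition (`compute_fret()`,
   `build_histogram()`, `fit_mixture()`),
4. **distance modelling** — the Förster relation
   `E = 1 / (1 + (R/R0)^6)` and R₀ calibration (`fret_to_distance()`,
   `calibrate_R0()`),
5. **accessible-volume dye simulation** on atomic structures
   (`sample_dye_positions()`, `mean_dye_distance()`),
6. **auxiliary quantifications** — puncta-intensity time courses and
   crosslink efficiencies (`puncta_timecourse()`,
   `crosslink_efficiency()`).

The `analysis/` scripts chain these stages into a reproducible workflow
over synthetic data; `run_pipeline()` does the same programmatically
from a single seeded configuration.

# The trace generator and what it does (not) emulate

`simulate_trace()` produces a two-channel photon series for one molecule
in a fixed FRET state `E` with per-molecule correction factor γ.  Before
acceptor bleach the acceptor emits `T·E` and the donor `T·(1−E)/γ`
photons/frame on top of a shared constant background; at acceptor bleach
the donor recovers to the full γ-scaled total `T/γ` (standard FRET
photophysics — the energy-transfer pathway disappears); after donor
bleach both channels fall to background.  Bleach times are exponential
with per-dye rates, discretized to frames; if the donor dies first the
acceptor never bleaches within the FRET record, since it is excited via
transfer.

Parameter defaults are chosen once as realistic EMCCD-scale acquisition
values: 800 frames of 100 ms, total intensity 500 photons/frame,
additive Gaussian channel noise of 25 photons/frame (5%), background 20,
acceptor bleach rate 0.04 s⁻¹, donor 0.015 s⁻¹, and γ drawn from
N(1, 0.1) truncated positive.  The source experiments do not publish
photon budgets or noise magnitudes, so these are the package's own study
conditions, not reproductions.

Deliberate simplifications: noise is additive Gaussian
(detector-dominated) rather than Poisson; there is no spectral
crosstalk, no direct acceptor excitation, no blinking, and no
within-trace state switching (the histograms under study are treated as
static mixtures of molecules).  Passing recovery tests on these
ensembles therefore validates the *estimators* — not the photophysical
completeness of the generator, and not performance on real data with
dynamics or correlated noise.  Per-molecule seeds are derived from
`(master seed, molecule_id)`, making ensembles order-independent.

# Photobleaching QC

`detect_steps()` fits a piecewise-constant model by penalized binary
segmentation: recursive best-split on residual sum of squares, a split
kept only when its SSE reduction exceeds a penalty.  The default penalty
is `2·σ²·log n` with σ estimated robustly from successive differences
(`mad(diff(x))/√2`) — a BIC-style rule that returns nothing on constant
noise and localizes large steps to the frame.  `step_frame` is the
1-based index of the first frame *at* the new level.  Minimum segment
length defaults to 5 frames; series shorter than twice that are rejected
as `too_short`.

`select_trace()` accepts a molecule iff the acceptor shows exactly one
downward step, the donor exactly one downward step, and the acceptor
step comes first.  The donor's *upward* recovery step at acceptor bleach
is expected and not counted.  Two physical consistency checks guard
against spurious marginal change points: after a genuine donor bleach
both channels must sit at the same baseline (|donor − acceptor|
after-bleach means within 25% of the donor step size), and between
acceptor and donor bleach the acceptor must already sit at that baseline
(within 25% of the acceptor step size).  Without these, a noise-level
false "donor bleach" on a trace whose donor survives the record poisons
the baseline estimate and with it every downstream efficiency.

The per-trace background is the mean of both channels after donor
bleach and is subtracted before computing E.  γ is the ratio of the two
intensity jumps at acceptor bleach,
`γ = (Ā_pre − Ā_post)/(D̄_post − D̄_pre)`, with 20-frame windows and one
guard frame on each side of the step; constant offsets cancel in both
differences.  γ outside [0.2, 5] rejects the molecule (`gamma_invalid`)
— such values only arise from pathological traces and would turn into
distance artifacts.

# Histogram and mixture decomposition

Efficiencies are computed frame-by-frame over the region strictly before
the acceptor bleach and are *not* clipped to [0, 1]; the histogram range
−0.25 to 1.25 (40 equal bins) is wide enough to hold noise excursions.
Frames with non-positive denominator are dropped and counted; a trace
losing more than 20% of frames is rejected.  Traces with more than 20
points enter the histogram, each with total weight 1: per-bin counts are
divided by the trace's number of in-range points.  (Normalizing by
in-range rather than total points keeps weight conservation — Σ weights
= number of retained molecules — exact even when a few excursions fall
outside the range; the two denominators coincide for all but
pathological traces.)  Bins are half-open `[left, right)` with the last
bin closed.

`fit_mixture()` decomposes the histogram by nonlinear least squares of
`Σ A_i exp(−(x−μ_i)²/2σ_i²)` against bin centers vs weights
(Levenberg–Marquardt with box bounds: μ within the histogram range, σ
bounded below by half a bin width — a component pinned there is flagged
— amplitudes non-negative).  The reported *fractional area* of component
i is its analytic area share `A_i σ_i / Σ_j A_j σ_j`, the convention
under which published decompositions sum to ~100%.  Fits are unweighted
(no published weighting scheme exists for this analysis).  The number of
components is user-chosen per dataset, as in the source figures; a
BIC-style score is reported for guidance but never overrides the user.

Initialization: with explicit `init` means the fit is a single
deterministic refinement of the user's component hypothesis.  Without
`init`, means start at the weighted quantiles of the histogram and five
deterministically jittered restarts protect against local minima, with
best-SSE selection.  Restarting is confined to the no-`init` case on
purpose — when the user asserts components, jumping to a
marginally-lower-SSE merged solution would silently discard that
hypothesis.

**Shared widths.** With `shared_sd = TRUE` all components are
constrained to one common σ.  For strongly overlapping components (e.g.
peaks ~2σ apart with unequal areas) the unconstrained fit is close to
non-identifiable: across random samples of n = 5000 from a fixed
three-component mixture, the highest-component mean scatters by ±0.06
as one broad component intermittently swallows its neighbour.  Linking
widths — justified here because the decompositions being emulated report
near-equal widths per histogram, and because the synthetic reference
mixtures are generated with a common σ = 0.08 — removes that failure
mode while leaving well-separated fits unchanged.  The per-component-σ
fit remains the default.

# Förster model and calibration

Distances follow `R = R0·((1−E)/E)^{1/6}`, strictly decreasing in E,
with the working value R₀ = 5.8 nm (per-pair calibrations of the dye
pair bracket it at 5.80–5.85 nm).  Distances are reported to 0.1 nm with
half-up rounding (`format_distance()`); the raw value is always
retained.  Note that a peak efficiency that is itself printed rounded to
two decimals can round-trip to a distance 0.1 nm away from one computed
from the unrounded fit mean — e.g. E = 0.97 gives 3.25 nm, which reports
as 3.2, while an unrounded fit mean of ~0.965 reports as 3.3.

Fit means occasionally land at or outside the physical range (E ≤ 0 or
≥ 1); for distance *reporting* these are clamped to [0.01, 0.99] and
flagged (`clamp = TRUE`), otherwise they raise a domain error.

`calibrate_R0()` inverts a single reference pair in closed form,
`R0 = R_ref·(E/(1−E))^{1/6}`; multiple pairs are pooled by least squares
on predicted vs measured efficiency, solved as the root of the
objective's gradient bracketed by the per-pair closed forms (the
gradient is negative below every per-pair root and positive above, so
the bracket is guaranteed).  On noiseless pairs the generating radius is
recovered to 10⁻⁹ nm; per-pair estimates and residuals are always
reported alongside the pooled value.

# Accessible-volume dye simulation

Published dye-position modelling for this system used constrained
molecular dynamics of explicit dye/linker atoms.  This package instead
implements a deterministic single-sphere accessible-volume (AV) model:
dye centers are sampled uniformly within a sphere of radius
`linker_length` (default 21 Å, generic maleimide-linked cyanine/AF dye)
around the attachment atom (Cβ; Cα + 1.5 Å of extra reach for glycine),
rejecting positions within `dye_radius + 2 Å` (default 5 + 2) of *any*
protein atom — including the attachment residue's own atoms, so the
clash rule is uniform and exactly shared with the dense-grid reference
implementation `av_grid_reference()`.  The mean inter-dye distance
averages over all cross pairs of the two sites' samples (the samples are
independent, so every A×B pair is a valid draw).  Sampling happens in a
local orthonormal frame anchored on the attachment atom and its nearest
non-collinear neighbours, so a seeded sample is exactly equivariant
under rigid motion of the structure.  An acceptance rate below 1% at the
attempt cap raises a buried-site error.

Because the AV model replaces dye MD, absolute predicted distances are
approximations: linker length, dye radius and clash probe are
conventional values, not fitted ones, and orientation effects (κ²) are
outside the model.  The AV machinery is validated against the grid
oracle, not against published per-pair distances.

# Auxiliary quantifications

`puncta_timecourse()` computes, per frame, the mean background-corrected
intensity over the cell-footprint mask and divides the series by its
first element, which is therefore exactly 1 — multiplicative
expression-level differences cancel by construction.  The footprint mask
is user-supplied or Otsu-thresholded from the temporal-mean image;
background is user-supplied (scalar or per-frame) or estimated as the
per-frame 5th-percentile pixel value outside the mask.  The estimation
choices are recorded on the output.  `aggregate_cells()` returns
pointwise mean and SEM (`sd/√n`).  `crosslink_efficiency()` is
`dimer/(monomer + dimer)` per gel lane, reported as integer percent.

# Numerical choices and degenerate inputs

* Half-up decimal rounding (`round_half_up()`) for all reported
  distances and percentages; `base::round()`'s banker's rounding would
  disagree with printed tables at ties.
* Step detection penalty floor of 10⁻¹⁶-scale σ² lets noiseless
  constructed fixtures segment exactly.
* Mixture fits with σ collapsing to the half-bin-width bound are
  constrained there and flagged rather than failing.
* `detect_steps` requires `2·min_segment` frames; `estimate_gamma`
  requires at least one usable frame on each side of the guard region,
  else the molecule is rejected, not errored.
* All stochastic stages (simulation, mixture sampling, AV sampling)
  save and restore the caller's RNG state, so library calls never
  perturb a user's random stream.

# Problem sizes

The bundled tests and analysis scripts run ensembles of 300–1500
molecules of 800 frames, mixture refits on 5000-point samples, and AV
cross-checks on a few thousand grid points — sizes at which every
recovery statistic is well inside its tolerance band while a complete
run of the suite plus all analysis stages finishes in a few minutes on a
single CPU.

# Known limitations

* The selection stage assumes intensity levels are piecewise constant;
  real traces with slow drift or blinking will inflate the reject rate.
* γ estimation needs both a pre- and post-bleach window; molecules whose
  acceptor bleaches in the first or last ~20 frames are lost.
* The two-sided 25% consistency thresholds in `select_trace()` are
  heuristics tuned for step-like traces; they are parameters of the QC,
  not physical constants.
* The AV model's absolute distances inherit its conventional geometry
  defaults; treat cross-structure *differences* as the robust output.
* Histogram fits quantify a static mixture; exchange dynamics between
  states are invisible to this analysis.
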