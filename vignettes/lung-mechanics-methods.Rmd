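---
title: "Models and methods: occlusion elastance, AFM microrheology and alveolar morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: occlusion elastance, AFM microrheology and alveolar morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmomech)
```

pulmomech implements three measurement pipelines that together
characterize lung mechanics from the whole organ down to the
extracellular matrix, plus the statistics used to compare experimental
groups. This vignette is the package's own account of the underlying
models, the tunable parameters, the numerical choices, and what the
synthetic-data module does and does not emulate.

## 1. Whole-lung elastance by end-inspiratory occlusion

### Forward model

The simulator uses the minimal lumped model that reproduces the
characteristic two-phase pressure decay after an airway occlusion: a
single compartment with static elastance `Est` (cmH2O/ml), Newtonian
airway resistance `Raw` (cmH2O·s/ml), and one Maxwell body (elastance
`E2`, resistance `R2`) in parallel:

$$P_{tr} = PEEP + R_{aw}\dot V + E_{st} V + P_{ve}, \qquad
\frac{dP_{ve}}{dt} = E_2 \dot V - \frac{P_{ve}}{\tau}, \quad
\tau = R_2/E_2.$$

At occlusion (flow clamped to zero at end-inspiration, volume held at
`VT`) the resistive term vanishes within one sample — the fast drop ΔP1 —
and the Maxwell pressure decays exponentially — the slow drop ΔP2 — to
the plateau `Pel = PEEP + Est·VT`. The Maxwell update is exact per sample
for piecewise-constant flow, so the occluded decay and the plateau are
exact, not integrator approximations. The emitted tracheal pressure also
contains the nonlinear cannula drop `k1·V' + k2·V'·|V'|` so that the
correction stage of the analysis is genuinely exercised, plus optional
additive Gaussian pressure noise.

Ventilation is volume-controlled: constant inspiratory flow over a third
of the cycle, passive first-order expiration with time constant
`Raw/Est`. The instrument's inspiratory flow shape and I:E ratio are not
part of the model's claims — they are conventions, and the analysis does
not depend on them beyond reaching `VT` at end-inspiration. The
anti-aliasing analog filter of a real acquisition chain is not emulated;
the analysis assumes pre-filtered signals.

### Analysis choices

* **Cannula correction** subtracts `k1·V' + k2·V'|V'|` using the
  metadata coefficients; on synthetic data this inverts the generator
  exactly, and static elastance is invariant to the coefficients used
  (round-trip identity, tested).
* **Volume** is the trapezoidal cumulative integral of flow, re-zeroed
  at each detected inspiration onset. Re-zeroing (rather than high-pass
  filtering) keeps the tidal excursion exact while suppressing drift.
* **Occlusion detection**: maximal runs with |flow| below 2% of peak
  inspiratory flow lasting at least 1 s. The 1 s floor is deliberately
  longer than the near-zero-flow tail of a passive murine expiration
  (tens of milliseconds time constant), so expiratory pauses are never
  mistaken for occlusions. Windows must start at end-inspiration
  (integrated volume ≈ VT); others are flagged, not silently dropped.
* **Inflection point**: the occlusion trace from the last pre-occlusion
  sample through 0.5 s after onset is fitted by a continuous two-segment
  piecewise-linear least-squares model; the breakpoint locates the
  inflection, and `Pi` is the *recorded* pressure at the breakpoint
  sample. Using the fitted chord value instead would bias `Pi` low,
  because a straight segment under-reads a convex exponential decay at
  its left end; on noiseless data the located breakpoint is the first
  occluded sample and the residual bias in `Edyn/Est` is below 0.01.
  This operational definition of the "fast drop endpoint" is a package
  choice — 100 Hz data do not uniquely define it — and is the reason the
  dynamic-to-static ratio carries a small systematic error while `Est`
  is exact.
* **Plateau**: mean pressure over the last 0.2 s before the 5 s mark.
  `PEEP` is taken from metadata (0 closed-chest, 2 cmH2O open-chest by
  the study convention), never estimated from the trace.
* Per-animal `Est`/`Edyn` are means over the (typically two) detected
  occlusions; chest wall = total − lung, element-wise.

`calibrate_viscoelastance()` chooses `E2` at fixed τ so that the Maxwell
pressure at occlusion onset equals `(ratio − 1)·Est·VT`; since that
pressure is linear in `E2` at fixed τ, one noiseless probe simulation
determines the scale. This is how the package constructs generators whose
analyzed `Edyn/Est` approaches a prescribed ratio such as 1.15.

## 2. AFM nanomechanics

### Pyramidal contact model

For a four-sided pyramidal tip of half-angle θ indenting an
incompressible sample (ν = 0.5) to depth δ, the contact force is
`F = 3 E tanθ / (4(1−ν²)) · δ²` with `F = k·d`. The fit works in the
deflection form, `d = d0 + (C/k)((z−z0)−(d−d0))²`, whose forward
prediction has a closed-form solution of the quadratic in `d−d0` — no
inner iteration is needed. Parameters are `(E, z0, d0)`, with `E`
parameterized on the log scale to stay positive.

Numerical choices:

* **Fit window**: indentations up to 500 nm, re-selected on every pass
  because δ depends on the current contact point; pre-contact baseline
  points are kept to pin `d0`. A config option excludes δ < 300 nm,
  reflecting the validity limit of the ideal-pyramid form on blunted
  real tips; the default keeps the full range because the synthetic
  curves are ideal pyramids.
* **Restarts**: three (contact point at the maximum-curvature sample of
  a lightly smoothed d(z) or at a small threshold crossing; E at 1, 10
  and 20 kPa), best converged residual wins — contact-point local minima
  are the dominant failure mode of Hertz fits.
* **Degeneracy guard**: the fitted model must raise the deflection above
  the residual noise floor at the deepest used indentation, otherwise
  the curve carries no contact information (e.g. a pre-contact-only
  sweep) and the fit fails loudly rather than returning a meaningless
  modulus.
* The fit is invariant to a joint shift of `z` and `d` (contact-point
  reparameterization), which is tested. A hypothetical invariance to
  rescaling `d` while counter-scaling `k` does *not* hold in the
  deflection form — indentation itself depends on `d` — and is not
  claimed.

Curve moduli aggregate by nested arithmetic means: curves → point,
points → site, sites → region (the 5-curve × 5-point × 3-site design).
Failed fits are dropped with a count; a point with no surviving curve is
flagged and the flag propagates upward.

Photodiode calibration fits a two-segment line to a bare-glass curve;
the contact slope is the sensitivity, and contact-region linearity
(R² ≥ 0.999) flags a clean tip.

### Complex shear modulus and the two power-law fit

Force and indentation phasors at each stimulus frequency are estimated by
least-squares sinusoidal regression (intercept + linear drift + one
cosine/sine pair per frequency, fitted jointly over the whole record).
Regression was chosen over raw discrete-transform bins because the
record length is not an integer number of periods of 0.35 Hz — regression
is leakage-free at the known stimulus frequencies, and single-frequency
estimates are invariant to record length beyond a few periods (tested).
The modulus follows from the pyramidal transduction factor at operating
indentation δ0:

$$G^*(f) = \frac{1-\nu}{3\,\delta_0 \tan\theta}
\left[\frac{F(f)}{\delta(f)} - i f\, b(h)\right],$$

where `b(h)` is the cantilever drag coefficient at the working gap —
a required metadata input in the same units the generator uses
(nN·s/nm); the generator injects exactly the `i f b(h)` term, so the
correction cancels it exactly (tested to 1e-10). A stimulus frequency
whose indentation phasor is indistinguishable from the regression noise
floor (5 standard errors) is flagged degenerate; an entirely unexcited
record is an error.

The two power-law model `G* = A(if)^α + B(if)^{3/4}` (f normalized to
1 Hz, `(ix)^p` expanded on the principal branch) is fitted in the complex
plane. For fixed α the problem is linear in (A, B), so α is profiled:
a grid from 0.01 to 0.5 (plus a coarse extension to 0.95) followed by
local refinement, with boundary solutions (B = 0, or A at a small
positive floor) considered at every α. At α = 3/4 the two basis
functions are colinear and only A + B is identifiable — the fit then
returns a boundary representative whose predicted moduli are still
correct, and the tests assert exactly that.

## 3. Mean linear intercept morphometry

Pipeline: Otsu global threshold on the (luminance of the) image with a
polarity flag for light- vs dark-tissue stains; removal of large vessels;
speck removal; Zhang–Suen thinning of the septal walls to a one-pixel
skeleton (topology-preserving — the enclosed-face count is tested via an
Euler-characteristic oracle); a deterministic grid of 11 vertical and 9
horizontal probe lines inset by a 2% margin per side; intercept counting
as maximal connected skeleton runs along each probe, so an oblique wall
counts once and probe-parallel runs (longer than 10 px) are flagged and
counted once.

Two definitions deserve justification:

* **Vessel removal.** Real analyses remove vessels manually; an
  automated rule must not delete the wall network, which is one large
  connected component. A morphological opening with a disc larger than
  the septal half-thickness erases walls while vessel cores survive;
  surviving components above the area threshold (default 5000 µm²),
  dilated back, form the vessel mask. A manual exclusion mask can
  override or supplement this. On fixtures where vessels are
  tissue-filled discs, removal can only increase the measured airspace
  (tested).
* **The Lm quotient.** The mean linear intercept is reported as the
  airspace probe length *between the outermost intercepts of each line*
  divided by the number of inter-septal intervals (intercepts − 1 per
  line), skipping zero-airspace intervals (a probe running lengthwise
  inside a wall measures no chord). This estimator equals the mean
  airspace chord exactly: on a square lattice of pitch p and wall
  thickness w it returns p − w with no bias, whereas dividing the full
  geometric probe length by the raw intercept count is inflated by the
  truncated chords at the probe ends (a p/L-order bias, several percent
  at realistic fields of view). The closed form `Lm = pitch − wall` of
  the synthetic lattice is the package's reference invariant, verified
  independently by brute-force chord enumeration on the rendered image.

Lm is reported per image; per-animal Lm is the mean over that animal's
images. Pixel size is always a required input.

The synthetic lattice reproduces the features the estimator relies on —
closed airspaces bounded by thin walls, vessels, gray noise, contrast
polarity — but not stain texture, wall-thickness heterogeneity, broken
septa or oblique sectioning artifacts. Passing on the lattice therefore
validates the geometry and counting logic, not stain-specific
segmentation robustness. Airspaces must also be resolvable: once wall
thickness approaches the pitch, the skeleton of near-solid tissue no
longer follows wall centerlines and Lm degrades to a few pixels.

## 4. Statistics

* Two-group comparisons use an explicit normality gate — Shapiro–Wilk at
  α = 0.05 per group — selecting the pooled-variance t-test or the
  Mann–Whitney test; the gate decision is always part of the result.
  The gate criterion itself is a package convention (the choice "when
  required" is otherwise undefined), and the type-I error of the gated
  procedure is calibrated at 0.05 ± 0.01 over 5000 null replicates in
  the test suite.
* Two-way ANOVA uses Type II sums of squares by default (the study's
  designs are near-balanced, where Type II is both efficient and equal
  to the sequential decomposition); a Type III override exists. The
  repeated-measures variant uses univariate within-subject error
  partitioning (`aov` with an `Error(subject/within)` stratum) — enough
  for a frequency-by-group design; sphericity corrections and
  mixed-effects models are out of scope. An all-constant response
  returns F = 0, p = 1 rather than a 0/0.
* Holm–Šidák: step-down `1 − (1 − p_(i))^(m−i+1)` with running-maximum
  monotonicity and capping at 1.

## 5. Cohorts, orchestration and problem sizes

Between-animal variation is lognormal (parameters stay positive) with a
stated CV; the viscoelastic parameters scale with the animal's `Est` so
the dynamic-to-static ratio is a group property. The default
demonstration study uses 6 animals per group, two occlusions per animal,
a 3-site × 5-point × 5-curve stiffness design per region, one
multifrequency record and one 600 × 600 px lattice image per animal —
sizes chosen so a full `run_study()` completes in minutes on a laptop
while keeping group-level sampling error a few percent. The acceptance
script uses n = 7 per group (the adult cohort size) and a 1200 × 1200 px
reference lattice. At a between-animal CV of 0.05 and n = 7, the
percent-difference estimate between two cohorts carries a sampling
standard deviation of about 1.7 percentage points; that spread is a
property of the simulated study design, not of the pipeline.

Every generator takes a mandatory seed and uses exactly one seeded
stream per call, restoring the caller's RNG state, so noiseless outputs
are bit-reproducible and stochastic ones reproducible given the seed.
Study reports echo seeds, configuration and package version; per-sample
CSVs back every reported mean.

## Known limitations

* The occlusion analysis assumes a linear single-compartment lung;
  frequency dependence beyond one Maxwell body, airway-tree
  heterogeneity and gas exchange are not modeled, and `Edyn` inherits a
  small operational bias from the inflection-point definition.
* The Hertz model assumes an ideal pyramid and sample-thickness effects
  are avoided only by the 500 nm cap, not modeled.
* The hydrodynamic drag correction for static force curves is linear in
  tip velocity and only active when velocity metadata are present.
* The morphometry estimator requires resolvable airspaces and is not a
  stain-normalization or whole-slide tool.
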