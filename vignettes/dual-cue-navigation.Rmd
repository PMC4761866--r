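---
title: "Methods: geomagnetic isoline drift, odor-plume dispersal, and the dual-cue homing model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geomagnetic isoline drift, odor-plume dispersal, and the dual-cue homing model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`magplume` asks a quantitative question about natal homing to a remote
island: if an animal memorizes the local geomagnetic intensity and returns
years later, how far has that magnetic signature drifted, and can an
island-sourced odor plume bridge the remaining gap? This vignette records
the models, the defaults and why they were chosen, the numerical choices,
and what the synthetic test beds do and do not demonstrate.

## 1. Geomagnetic field model

The internal field is the gradient of a scalar potential expanded in
spherical harmonics with Schmidt quasi-normalized associated Legendre
functions, truncated at the degree of the supplied coefficient table. All
evaluation is on a geocentric sphere of radius a = 6371.2 km. The ~0.2%
geodetic-geocentric correction is deliberately omitted: the analysis
compares positions of isolines with one another, and the ellipticity
correction shifts both states of an isoline nearly identically at the
latitudes involved, far below the tens-to-hundreds of km signal of
interest. This is a documented limitation, not an oversight; absolute
element values near the poles are the place it would matter most.

Legendre functions and their colatitude derivatives use the standard
stable upward recurrence for Schmidt quasi-normalization. Latitudes are
clamped to ±89.9999° internally so the 1/sin θ term in the east component
stays finite; coefficients between tabulated epochs are interpolated
linearly in time (the convention of reference field models), and dates up
to 5 years beyond the last epoch use the predictive secular-variation
column. A sweep over start years therefore computes 5-year look-aheads
from every epoch but refuses 25-year intervals that would lean on the
predictive column.

The package bundles a transcription of the published IGRF-13 Gauss
coefficients, 1900.0–2010.0 at 5-year intervals, truncated at degree 10
(higher-degree terms contribute ~1 nT, irrelevant to isoline geometry at
corridor scale). The transcription could not be re-verified against the
official distribution when the package was assembled; the test suite
instead validates the combination of table and synthesis against an
independent oracle (below) and against well-known features of the field —
the location and depth of the South Atlantic intensity minimum, polar
intensities — which it reproduces closely.

Two test beds guard the synthesis. Degree-1 closed forms: an axial dipole
must satisfy F(λ) = |g₁⁰|·√(1+3 sin²λ) and tan I = 2 tan λ to 1e-9
relative. And an independent brute-force oracle: the potential is
re-assembled term by term with Legendre functions built from the Rodrigues
formula (a different construction than the recurrence), and the field
components are obtained by Richardson-extrapolated central differences of
V in r, θ, φ. Agreement to 1e-8 relative at random degree-3 coefficient
sets is required. This oracle caught a real defect during development — a
recurrence that produced Gauss- rather than Schmidt-normalized functions,
invisible to every degree-1 test — which is why it exists as a separate
code path and must stay one.

## 2. Isolines and drift

Isolines of total intensity F are extracted from a regular lat/lon grid by
marching squares with linear interpolation along cell edges
(`grDevices::contourLines`). The drift of a remembered signature is
operationalized as the **minimum great-circle distance from the reference
point to the contour, Δt years later, of the intensity the point had at
t₀**. The original isoline passes through the point, so this measures
exactly the displacement a navigator holding the old value would
experience; among the metrics one could define on a moving curve (nearest
approach, displacement along a fixed bearing, area swept) the nearest
approach is the one with navigational meaning, and it is the assumption
recorded for the drift figures. When a level has several contour
components, the component nearest the reference point is used, ties broken
by the longest component.

Point-to-polyline distances are exact spherical point-to-arc computations
(cross-track distance where the great-circle foot falls inside the arc,
nearer-vertex distance otherwise) on R = 6371 km, vectorized in 3-D
Cartesian form; tests compare them against a dense-sampling oracle to
0.1 km. The default corridor window, lat [−25, 10] × lon [−45, 5] at 0.1°,
covers the Brazil-to-Ascension region; halving the step must change drift
by less than one coarse grid step (a convergence test), and a static field
must give drift below one grid step (~11 km), which bounds the
discretization error of everything built on top.

## 3. Synthetic forcing fields

The generators exist so that every downstream stage has inputs with known
ground truth; their defaults are the study conditions, not tuning knobs.

**Ocean.** A streamfunction ψ = (mean-flow term) + Σ signed Gaussian
eddies, differentiated by central differences on the grid, gives u = −∂ψ/∂y,
v = ∂ψ/∂x. Because the same discrete operator is used twice, the discrete
divergence vanishes identically — passive plumes cannot artificially pile
up or thin out, mirroring the near-incompressibility of mesoscale surface
flow. Defaults: 0.08° grid (the resolution of the global ocean hindcasts
this stands in for) on a ~900 × 900 km box around Ascension, five depth
layers (0–50 m) with independently seeded eddy phases under a shared mean
flow (vertical shear without 3-D machinery), daily velocity snapshots,
eddy radius 60 km and streamfunction amplitude giving ~0.03–0.08 m/s swirl
— mesoscale values for the tropical Atlantic. What this emulates is the
*kinematics* of meandering currents and eddies; what it does not emulate
is data-assimilative realism, fronts with sharp density structure, tides,
or vertical velocities, so a passing intersection test says the method
behaves correctly under plausible kinematics, not that any specific year's
ocean produced a specific rate.

**Wind.** Spatially uniform flow toward a fixed bearing (default 292.5°,
the WNW trade-wind direction at Ascension) plus an AR(1) gust component
with a 6-h decorrelation time.

**Magnetic.** A dipole whose moment vector is rigidly rotated about a
horizontal axis: the intensity pattern then translates at exactly the
configured speed at the reference point, giving an exact ground truth for
drift-recovery tests (a 10 km/yr series must yield 250 km at Δt = 25 to
5%). The axis pole can be placed off the rotation axis; the standard
homing scenario uses a pole at (55° N, 60° W) so that intensity isolines
cross the corridor obliquely, which is how real South Atlantic isolines
run — a centered axial dipole would make them geographic parallels and
hide a whole class of navigation errors. Static low-degree anomaly terms
can be added, in which case the translation ground truth is only
first-order and the exactness tests use the anomaly-free configuration.

## 4. Lagrangian dispersal

Particles advance by classical RK4 on d(lat)/dt = v/R·(180/π),
d(lon)/dt = u/(R cos lat)·(180/π), sampling velocities bilinearly in
space, linearly in time (or frozen at each day's 00:00 snapshot when the
daily-frozen mode is chosen; both modes exist because archived model
output is often consumed either way) and nearest in depth layer. RK4 is
exact for constant fields — the 10-day uniform-flow test requires the
259.2-km displacement to better than 1 m — and fourth-order otherwise,
checked by radius conservation in a solid-body rotation field to 1e-6
over 100 steps. A particle whose sub-step sampling leaves the domain is
frozen and flagged `exited` rather than reflected; frozen particles no
longer count as plume members, which is conservative for open boundaries.

Horizontal dispersion is an uncorrelated Gaussian random walk, independent
per axis, σ = √(2 K_h Δt), applied after each RK4 step. The formulation
of sub-gridscale mixing in the reference particle-tracking literature is
not specified numerically, so the diffusivity is an assumption exposed as
a parameter; K_h = 10 m²/s is a typical sub-gridscale value for ~8-km
grids. The 2-D diffusion law (mean-square displacement 4 K_h Δt) is
verified at 10⁵ samples within 3 standard errors.

Release schedules follow the island-source protocol: particles seeded
uniformly over a 10 × 10 km zone centered on the island, 100 per layer at
five depth layers every day across the December 15 – April 29 nesting
season (135 days, 136 in leap years; releases at 00:00), with odorant
lifetimes of 15, 30, or 45 days; airborne runs reuse the engine with one
0-m layer, hourly releases, and a 48-h lifetime. Because a particle's
trajectory does not depend on when it will expire, a single run at the
longest lifetime contains every shorter-lifetime run as an age filter:
snapshots filtered to lifetime L₁ < L₂ are exact subsets of the L₂
snapshots. The lifetime-sensitivity analysis exploits this, which makes
the monotonicity of intersection rates in lifetime an exact property of
the construction rather than a statistical observation — that is the
qualitative mechanism behind the duration effect, testable without any
real ocean data.

## 5. Intersection statistics

A snapshot intersects an isoline when any living particle lies within a
buffer (default 10 km, about one ocean-model grid cell) of the polyline;
the criterion is exposed and reported because map-overlay analyses never
define one explicitly. Snapshots are taken at k evenly spaced instants per
season (10 waterborne, 5 airborne; endpoints included, k = 1 degenerating
to the midpoint), and proportions carry 95% Wilson score intervals —
appropriate at n = 40 or 15, where Wald intervals misbehave; the interval
construction is cross-checked against `prop.test(correct = FALSE)`.
Per-year rates use only that year's snapshots; multi-year summaries
average the yearly rates and pool counts for the interval. Snapshot
counting (rather than continuous time integration) is the chosen reading
of "proportion of time"; with evenly spaced snapshots the two coincide in
expectation.

## 6. The agent model

Agents move at a constant swim speed (default 0.6 m/s, a sustained green
turtle cruising speed) in one of three strategies. **Isoline following**:
heading along the local isoline tangent (perpendicular to ∇F, estimated
by central differences over 0.05°), signed to preserve the direction of
progress, plus a cross-track correction along ±∇F proportional to the
signed offset (target − F)/|∇F| — the local linear estimate of the
distance to the isoline in km — scaled by a dimensionless gain, saturated
at 2:1 against the tangent component so corrections cannot reverse
progress. Below |∇F| = 1e-3 nT/km (a magnetic plateau) the previous
heading is held. A contraction test verifies |F − target| decreases for
gains in the working range. **Plume following**: up-flow (particles
stream downstream from the source, so swimming against the local current
leads to it) blended with a unit pull toward the centroid of the
currently detected particles. The centering term is essential, not
cosmetic: pure up-flow parallels a streamline at whatever lateral offset
first contact happened to occur, and agents then ride past the island at
that offset; the blend pulls them into the plume core, and inside the
release zone the centroid converges on the source. With no resolvable
flow the centroid pull acts alone. **Search**: an Archimedean spiral
around the point of lost contact with pitch 2 × detection radius, so
successive passes leave no gap wider than the detection diameter. Mode
transitions are monotone (isoline/transit → plume ↔ search → arrived/
failed); odor detection is binary proximity to any particle (default
15 km), with no concentration model, matching the presence/absence
treatment of plumes throughout. Agents are not advected by the current
while homing: the question is the strategy logic, and drift would
confound the paired comparison; superposition is a straightforward
extension.

No quantitative strategy parameter here is an observed value; swim speed,
detection radius, gain, search pitch and the 2.5-km arrival radius
(island of 5 km diameter) are stated assumptions exposed in
`agent_params()`.

## 7. The standard homing scenario

The strategy comparison needs a configuration in which the hypothesis is
actually at stake: the remembered isoline must miss the island (so
magnetic guidance alone fails), the plume must cross the drifted isoline
(so the sequence can work), and unguided travel must be genuinely worse
than guided travel. `standard_scenario()` builds it: tilted dipole (axis
pole 55° N, 60° W) translated south for 25 years so the remembered
isoline passes ~100 km from the island and runs obliquely (≈ 0.45
lat/lon slope) across the corridor; a SSW mean current (−0.15, −0.2 m/s)
with six 60-km eddies carrying a 15-day plume across the isoline a
couple of hundred km downstream; 200 agents per strategy placed on the
drifted isoline 300–600 km from the island. Odor-only agents hold their
initial eastward course (they have no field to follow); because the
corridor is oblique, a straight run diverges from it by more than the
plume's living extent for many start positions, while dual agents follow
the curve to the guaranteed crossing. The paired design (identical seeds,
fields, plume and starts across strategies) makes the comparison exact
rather than statistical; the required outcome — dual strictly better
than both single-cue controls, magnetic-only at exactly zero — is
asserted at 200 agents with a fixed seed and holds across the seeds
exercised in the tests.

## 8. Problem sizes and reproducibility

All generators and simulations are pure functions of their parameters and
an integer seed; reruns are bit-identical, pipeline outputs are stamped
with a configuration hash and written at fixed precision. The test suite
and the acceptance script use deliberately scaled runs — single-layer
plumes of a few hundred to ~2500 particles over 45–60 days at 1–2 h
steps, 0.05–0.15° isoline grids over the corridor, two flow realizations
for the lifetime analysis, 200 agents per strategy — sizes chosen so the
full suite exercises every claim in a few minutes while keeping each
check's discriminating power (grid-convergence, 3-SE statistical bands,
exact paired properties). The full paper-scale protocol (five layers ×
100 particles × 135 daily releases × four seasons) runs through exactly
the same code paths via `magplume_config()`.

## 9. Known limitations

- Geocentric sphere, no geodetic conversion (see §1).
- The bundled coefficient table is a transcription; see §1 for how it is
  validated. Isoline drift at Ascension is ill-conditioned for short
  intervals: |∇F| ≈ 1.4 nT/km there, so every nT of coefficient or epoch
  error moves the 5-year answer by ~0.7 km.
- Odorant chemistry is reduced to a lifetime; no degradation kinetics,
  no concentration field.
- The synthetic ocean is kinematic (streamfunction flow), not dynamical.
- Agents sense instantaneous, noise-free field values; magnetoreception
  noise would widen the effective corridor and is not modelled.
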