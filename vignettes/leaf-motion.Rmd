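---
title: "Leaf sequencing and bank-offset optimization for a two-dimensional dynamic MLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaf sequencing and bank-offset optimization for a two-dimensional dynamic MLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmlc2d)
```

## The problem

In sliding-window IMRT a multileaf collimator (MLC) delivers a planned 2-D
intensity map (the *optimal fluence map*) by sweeping an open gap between a
leading and a trailing leaf across the field while the beam is on. The leaf
width (5 mm for the central pairs of a Millennium-120-class MLC) quantizes
the field in the direction perpendicular to leaf travel: wherever the target
border falls inside a leaf's span, the whole leaf must open, and a band of
up to half a leaf width of normal tissue is irradiated at the superior and
inferior target margins.

A two-dimensional dynamic MLC (2DDMLC) adds one degree of freedom: the whole
bank can translate rigidly along y (the leaf-stacking axis) by up to half a
leaf width, in 0.25 mm steps. Choosing that offset per *sector* of the sweep
re-phases the leaf boundaries against the local target border and removes
most of the quantization band. This package implements the complete
leaf-motion calculator for that technique: sequencing, per-sector offset
optimization, reconstruction of the deliverable ("actual") fluence, and the
evaluation metrics.

## The sequencing model

Each leaf pair receives a 1-D target profile $\Phi$ in monitor units (MU)
per beamlet. Sweeping left to right, the exposure of a point equals the MU
elapsed between the leading (right) leaf uncovering it and the trailing
(left) leaf covering it, so the pair is described by two arrival-MU
sequences at the beamlet centers. With $\Delta = \Phi_{i+1} - \Phi_i$ and
the minimum beamlet-crossing MU $\tau = dx / v_{MU}$ (where
$v_{MU} = v_{max} \cdot 60 / \dot{D}$ is the leaf speed in mm/MU at dose
rate $\dot{D}$):

* rising or flat fluence ($\Delta \ge 0$): the leading leaf moves first,
  $r_{i+1} = r_i + \tau$, $l_{i+1} = r_{i+1} + \Phi_{i+1}$;
* falling fluence ($\Delta < 0$): the trailing leaf moves first,
  $l_{i+1} = l_i + \tau$, $r_{i+1} = l_{i+1} - \Phi_{i+1}$;

initialized with $r_1 = 0$, $l_1 = \Phi_1$. By construction
$l_i - r_i = \Phi_i$ at every beamlet — the delivered profile is *exact* —
and both sequences advance by at least $\tau$ per beamlet, so the leaf-speed
bound is respected; the extra MU spent when a leaf must travel farther than
the fluence gradient requires is exactly the "extra time to reach the
destination" a physical sweep needs. `sequence_pair_profile()` implements
the recurrence (in closed form, $r_i = (i-1)\tau + \sum_{j<i}
\max(0, \Phi_j - \Phi_{j+1})$), and a property test asserts exactness to
$10^{-9}$ MU on random profiles.

All pairs share one MU clock (`synchronize_pairs()`): the field total is the
largest trailing-leaf finish, early finishers hold closed at their final
position, and control points are emitted at every distinct arrival MU with
positions interpolated linearly in MU — the standard constant-speed contract
of dynamic delivery. An alternative would be to dilate each pair's time axis
to a common total; we keep the single shared clock because a LINAC has one
MU counter, and we flag the choice here because delivery logs from other
calculators may differ.

Ties $\Delta = 0$ take the $\Delta \ge 0$ branch, the sweep direction is
fixed $-x \to +x$, and pairs with an all-zero profile are parked closed at
`x_travel_min`; under the zero-transmission leaf model (leakage is out of
scope) the parking position is dosimetrically irrelevant but deterministic.

## Sectors and the bank-offset search

The map's x-range is partitioned into `n_sectors = 8` equal-width sectors
(the bank holds one offset at a time, and during a monotone sweep the x-axis
and the time axis induce the same partition). For each sector,
`optimize_sectors()` evaluates every candidate offset in
$\{-w/2, \dots, +w/2\}$ in 0.25 mm steps ($w$ = smallest engaged leaf
width; 21 candidates for 5 mm leaves, always including 0) and keeps the
minimizer of a normalized mean absolute difference between the deliverable
and the optimal fluence (`score_offset()`), evaluated on a 0.25 mm y-grid
over the sector plus a one-leaf-width guard band above and below its nonzero
rows — the over-coverage to be removed lives *outside* the target, so the
guard band must be scored. We use the difference rather than the conformity
index as the objective because the CI is piecewise constant in the offset
(threshold-based areas jump by whole bands) while the difference is smooth
and gives a deterministic argmin; both are reported.

Because the sequencer is exact per pair, the deliverable fluence of a sector
equals its aggregated per-pair profiles, and the score is computed from
those profiles directly rather than re-sequencing all 21 candidates; the
full sequence-then-reconstruct path is exercised end to end by
`compare_techniques()` and its tests, which confirm the identity.

Ties are broken by the smallest |offset| (prefer not moving), then by the
positive sign. The sign rule matters only for exactly tied candidates —
e.g. a uniform rectangle misaligned by exactly half a leaf width is fixed
equally well by $+2.5$ and $-2.5$ mm, which produce congruent leaf
partitions — and the positive convention (translate toward $+y$) makes the
choice reproducible.

Since offset 0 is always among the candidates, the chosen offset never
scores worse than holding the bank still; this is the non-worsening
guarantee the acceptance suite checks map by map.

## Row aggregation: how 1 mm fluence rows become 5 mm leaf profiles

A pair overlapping several fluence rows needs one profile. Two reductions
are provided (`aggregate_pair_profiles()`):

* `max` (default): any row overlapping the pair by at least 10 % of the row
  height counts fully, and the profile is the row-wise maximum. This is the
  "open whenever any covered row demands fluence" behavior that produces
  the over-coverage (CI > 1) observed for rigid-bank delivery — precisely
  the effect the 2DDMLC corrects — so it is the default for studying that
  effect.
* `coverage_weighted_mean`: rows weighted by overlap fraction; conserves
  integrated fluence across the reduction (a tested invariant) at the cost
  of under-dosing partially covered border rows.

The choice is recorded in every plan and report.

## Delivery reconstruction and the oracle

`reconstruct_fluence()` computes, for every cell of a delivery grid (y
refined to the 0.25 mm offset step so every admissible offset lands on grid
lines), the exact beam-on time during which the cell center lies inside the
open aperture of the pair covering its y at the prevailing bank offset,
integrating crossing times over control-point intervals. Cell-center
containment (not area-weighted partial coverage) decides exposure in x;
at 1 mm beamlets and a 0.25 mm y-grid the partial-coverage correction is
second-order, and the convention is stated in the reports.

`simulate_delivery_oracle()` is an intentionally brute-force cross-check:
it marches the MU clock in fixed increments and scores each cell open or
closed at the step midpoint. Its worst-case per-cell deviation from the
analytic reconstruction is bounded by $2\,\Delta_{MU}$ (each of the two
crossing times is resolved to within a step), so the certified envelope
halves when the step halves; the realized maximum decays at first order
with a fluctuating constant, which is why the tests assert the envelope at
both steps plus strict decrease rather than an exact factor of two. Bank
moves between sectors happen during a beam hold — a pair of control points
at the same cumulative MU — so they contribute no exposure and no fluence
smearing; consequently the control-point MU column is non-decreasing rather
than strictly increasing, with ties only at sector transitions.

## Metrics

All metrics are computed on the 0.25 mm y-grid, with the planned map
row-replicated; comparing on the coarse planning grid would alias the
sub-leaf effect under study.

* Conformity index `CI = actual irradiated area / planned irradiated area`,
  areas thresholded at `tau` (default 0.1) of the *planned* maximum. The
  threshold is configurable because "irradiated area" has no universal
  definition; every report records `tau`.
* Mean intensity over the union of planned and actual nonzero supports
  (symmetric between the two techniques being compared).
* Mean absolute difference, as a percentage of the mean planned intensity
  over the planned support.
* Out-of-field area: cells above threshold whose planned fluence is at or
  below threshold.
* Paired two-sided t-tests over case suites, with the two degenerate
  branches (all-zero differences, constant nonzero differences) handled
  explicitly.

## The synthetic suites

No clinical fluence maps ship with the package, so `generate_suite()`
emulates the two regimes that matter for the physics: *small* targets
(vertical extents 20–30 mm — the scale at which a 2.5 mm band is a tenth of
the target) and *large* targets (60–80 mm, where it is marginal). Shapes
are drawn uniformly from rectangles, ellipses and two-lobe compounds;
intensities are textured with smoothed multiplicative noise of depth 0.3 to
emulate modulated clinical maps (binary maps would make the
mean-difference metric trivially edge-dominated); x-extents are 30–60 mm
(small) and 50–90 mm (large); and — the key randomized parameter — the
lower target edge is placed uniformly over one 5 mm leaf period, so the
suite visits every misalignment phase. Maps are generated on 1 mm beamlet
grids with 10 mm margins and are bit-reproducible from their seed.

What the suites do *not* emulate: TPS-optimized fluence textures, leakage
and transmission, rounded leaf ends, tongue-and-groove, scatter, or any
in-patient dose. Passing tests therefore demonstrate the geometric and
sequencing claims (exact profile delivery, conformity improvement from
re-phasing the leaf boundaries, insensitivity for tall targets), not
absolute clinical dosimetry.

At study scale (50 maps per regime, the default machine: 600 MU/min,
25 mm/s leaves, 500 MU per map, Millennium-120 geometry) the suites
reproduce the qualitative published behavior of the technique: small-target
conformity indices around 1.2 falling to ~1.1 with the bank translation
(paired p well below 0.05), per-map mean intensities preserved within 2 %,
mean absolute differences reduced by roughly a third, and a large-target
conformity gain less than a third of the small-target gain. The acceptance
script recomputes all of these from scratch; the vignette intentionally
states no number the tests or the script do not themselves compute.

## Numerical choices and limitations

* Control points are merged within $10^{-6}$ MU; reconstruction treats a
  pair as closed when its gap is below $10^{-9}$ mm.
* Fluence files are plain ASCII (self-describing header plus rows) printed
  at 17 significant digits, so write/read round trips are bit-lossless;
  intensities below $10^{-9}$ of the map maximum are clamped to zero on
  read to protect the sequencer from numerical dust.
* The maximum leaf speed is not part of the clinical record this models;
  25 mm/s is the Millennium-class specification figure and is configurable
  via `machine_config()` or the YAML setup file. Optimal fluence maps may
  arrive normalized or in absolute MU; both are supported through the
  `units` flag, with `scale_to_mu()` anchoring the map maximum at the
  prescribed total MU.
* Interdigitation and minimum-gap constraints, carriage limits, dose-rate
  modulation, step-and-shoot sequencing, DICOM I/O and VMAT are out of
  scope; the serialized control-point table plus JSON sidecar is the
  exchange format.
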