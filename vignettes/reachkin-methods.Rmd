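---
title: "Methods: kinematic landmarks, planned comparisons and 1D SPM for pointing movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic landmarks, planned comparisons and 1D SPM for pointing movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reachkin` analyses point-to-point reaching movements recorded as 3D
fingertip marker trajectories, in factorial designs crossing posture
(upright, lying), visual environment (virtual, physical) and allocentric
movement direction (up, down, left, right). This vignette documents the
model and the numerical decisions behind each stage, including the places
where the protocol leaves genuine freedom and what the package chose.

## Preprocessing and landmark extraction

Positions are low-pass filtered with a third-order Butterworth filter at a
5 Hz cutoff, applied forward and backward for zero phase lag (squared
magnitude response). The zero-phase pass is implemented in the package:
the input is extended by odd reflection (pad length `3 * (order + 1)`) and
the filter state is initialised at its steady state, so a constant series
passes through exactly and no start-up transient leaks into the data. The
`signal` package supplies only the coefficients; its own `filtfilt` leaves
large edge transients that would corrupt the quiescent baselines the
segmentation relies on.

Velocity and acceleration come from three-point numerical differentiation
(central differences, one-sided at the endpoints; exact for affine
signals). The analysed speed is the **tangential speed**, the Euclidean
norm of the 3D velocity of the fingertip: a threshold on "velocity" is
only meaningful as a magnitude. Scalar acceleration is the derivative of
speed — not the norm of the acceleration vector — so deceleration is a
well-defined negative phase; the peak deceleration PD is reported as a
magnitude. One consequence worth knowing: for curved paths at constant
speed the scalar acceleration is ~0 even though the vector acceleration is
not.

Movement onset and offset are the first and last samples at which speed
strictly exceeds 10% of its peak. Onset/offset are kept at sample
resolution (no sub-sample interpolation): at 120 Hz the quantization is at
most 8.3 ms, below the effects of interest, and the rule stays trivially
reproducible. The seven landmarks are MD, PV, PA, PD and the relative
times rDPV, rDPA, rDPD, each relative time computed as
`100 * (index(extremum) - onset) / (offset - onset)`. PA is searched
before the speed peak and PD after it, as unimodal-profile logic dictates;
ties at an extremum break to the earliest sample and are flagged.

Degenerate inputs are contracts, not silent repairs: series with missing
samples are rejected by the filter and the differentiator (exclusion, not
interpolation, is the remedy), an all-zero speed series is a segmentation
error, and a threshold crossing that touches the series boundary (no
quiescent baseline) flags the trial.

### Trial exclusion

Two rules: trials with any missing motion samples are removed first; then
trials whose MD strictly exceeds the pool mean by more than three pool
standard deviations are removed. The protocol does not specify the pool
over which mean and SD are computed; the package uses the **grand pool**
(all valid trials of all participants, in a single pass, with the
candidate outliers included in the pool statistics), which is the most
conservative reading of "exceeded the mean". A trial exactly at
mean + 3 SD is retained — the rule is strictly "exceeded" — and the test
suite pins that boundary.

## The synthetic-trajectory generator

The generator exists so that every downstream stage can be tested against
known ground truth. It emulates the reference design: 27 participants,
2 postures × 2 environments × 4 directions, 4 blocks of 3 trials per
direction, 30 cm amplitude, 120 Hz sampling — 5184 trials.

The speed profile of each trial is a beta-shaped curve
`v(τ) ∝ τ^(a−1) (1−τ)^(b−1)` with `a + b = 6`, so a single parameter — the
generative rDPV — places the mode at `rdpv/100` of the movement duration;
`rdpv = 50` gives `a = b = 3`, exactly the minimum-jerk speed curve
`30 τ²(1−τ)²`. Default targets are 45% (up), 51% (down) and 48% (left and
right) in every posture and environment: an up/down gap of the size
reported for vertical arm movements, symmetric laterals, and no
environment effect. Paths are straight lines along the allocentric
direction vectors; since all landmarks derive from tangential speed, which
is path-shape invariant, straight paths lose no generality and keep the
oracles analytic (the 1-degree-of-freedom arm constraint of the real task
matters physiologically, not computationally).

Per-trial movement durations are drawn from a normal distribution with
mean 0.5 s and SD 0.05 s — plausible values for fast 30 cm pointing; the
protocol's summary tables are not available as machine-readable input, so
these defaults are stated as placeholders, not measured values — truncated
at ±2.5 SD. The truncation is deliberately tighter than the 3-SD exclusion
rule: truncation at ±3 SD would shrink the empirical SD to ≈0.973 of the
nominal one, putting legitimate extreme draws at ≈+3.08 empirical SDs and
causing occasional false exclusions; at ±2.5 SD a clean trial cannot cross
the empirical threshold, so the injected corruptions are provably the only
exclusions. Duration outliers are regenerated at 4–5 nominal SDs above the
mean; missing-data trials have a contiguous 0.1 s span blanked. Marker
jitter is i.i.d. Gaussian positional noise (default SD 0.5 mm) added
before filtering. An optional per-participant rDPV offset
(`rdpv_participant_sd`, default 0) adds between-participant variability
for statistics-level demonstrations.

What the generator does *not* emulate: corrective submovements, curved
shoulder-rotation paths, autocorrelated marker noise, endpoint variability
scaling with speed, or any feedback-dependent structure. Passing tests
therefore certify the computational chain, not the behaviour of human
data.

### What recovery tests can resolve

rDPV measured from a segmented trial is quantized in steps of one sample —
about 2 percentage points for a ~0.4 s segmented movement at 120 Hz. The
recovery tests compare measured rDPV against the analytic
segmentation-adjusted value of the generating curve (its rDPV after
truncation at the 10% threshold, evaluated on a dense grid) at the
design's mean duration, where the quantization stays under 1 point.
Separately, the 5 Hz filter symmetrizes fast asymmetric profiles slightly:
on 0.5 s movements the measured rDPV moves toward 50 by up to ~1.6 points
at generative targets of 40 or 60 (verified against an independent filter
implementation; it is the filter's physics, not an implementation
artefact). The suite bounds this bias at 2 points and checks its
direction. For the same quantization reason, double-filtering a trial can
move rDPV by one sample's worth; idempotence is asserted at that
granularity.

## Condition-level inference

Retained trials are averaged to participant × cell means (16 cells per
participant), the analysis unit of all inference. For each of the seven
parameters a Shapiro–Wilk test runs per cell across participants; the
branch is non-parametric as soon as any of the 16 cells rejects at 0.05.
With all cells Gaussian this family gate passes parametrically in about
`0.95^16 ≈ 44%` of datasets — a property the tests verify by simulation —
so the gate is deliberately conservative about normality.

The parametric branch is a fully within-participant three-way ANOVA on the
balanced 2×2×4 table, each effect tested against its own
effect-by-participant interaction (sums of squares via the standard
marginal-means decomposition; partial eta squared as
`SS_effect/(SS_effect + SS_error)`). For effects with more than one
numerator df, Mauchly's test runs on the orthonormalized contrast scores
(with the second-order Box correction term, matching the reference
implementations), and when it rejects at 0.05 the Greenhouse–Geisser
epsilon multiplies both degrees of freedom. Epsilon is exactly 1 for
two-level factors and lies in `[1/(k−1), 1]` otherwise. The implementation
is pinned, effect by effect, against `aov` error strata and against
`car::Anova` for the sphericity machinery.

The non-parametric branch runs a Friedman test across all 16 cells at
once — the planned-comparison list spans both postures, so a single
16-condition test is the coherent omnibus — followed by Wilcoxon
signed-rank tests. Zero differences are dropped (Wilcoxon's original
treatment; implementations differ, so this is stated explicitly). For 25
or fewer non-zero pairs the two-sided p is exact, from the full null
distribution of the signed-rank statistic computed by convolution (which
also handles average ranks under ties); beyond that, the normal
approximation with tie correction applies — so a 27-participant study uses
the approximation, and the switch is recorded in the result. The exact
path is verified against complete 2^n enumeration; note that the
signed-rank statistic ranks pair *differences*, so it is invariant under
increasing affine transforms of the data but not under arbitrary monotone
ones (the Friedman statistic is).

Sixteen planned comparisons are fixed a priori: eight virtual-vs-physical
contrasts (one per posture × direction) and eight direction contrasts
(up-vs-down and right-vs-left per posture × environment). Vertical-vs-
lateral contrasts are never produced. The per-test threshold is
`0.05/16 = 0.003125`. On the parametric branch the pairs are tested as
paired contrasts on the cell means (equivalent to paired t tests):
sphericity across heterogeneous cells is untestable for specific pairs, so
per-pair error terms are the defensible choice; the protocol names only
"post hoc comparisons", leaving the form open. Follow-up simple main
effects of direction within posture use the same machinery with a
Bonferroni family of four.

## Time-resolved SPM{t}

Speed and acceleration are linearly interpolated onto 101 nodes spanning
onset to offset (0–100% of movement time in 1% steps, the field-standard
grid; only time is normalized, amplitudes are untouched since raw
velocity magnitudes are compared). Trials are averaged within participant
and cell, and each planned comparison is a paired, node-wise t statistic
across participants — the figure-level unit of movement-SPM practice.
Inference is two-tailed with the family-wise alpha split per tail.

The critical threshold comes from random-field theory for a 1D t field:
`t*` solves `P(T > t) + resels · EC1(t) = α/2` per tail, with
`resels = (nodes − 1)/FWHM` and `EC1` the 1D Euler-characteristic density
of the t field; the root is found by monotone bisection to 1e-6. As
smoothness grows the threshold approaches the pointwise t quantile, and it
always dominates it. Field smoothness is estimated from the residual
curves by the normalized-gradient estimator:
`FWHM = sqrt(4 ln 2) / RMS` of the node-wise variance-normalized residual
gradients, clamped to `[1, nodes]`. Suprathreshold clusters are maximal
runs of `|t| > t*`, reported as start/end percentages with the sign of the
dominant excursion; a node set is partitioned exactly (conservation is
tested). Zero variance at a node is an error naming the node, never a
silent infinity.

The calibration that anchors the whole stage: under a smooth Gaussian null
(27 participants, 101 nodes, ~20-node-FWHM curves), the fraction of
replicates showing any suprathreshold cluster must stay at or below the
nominal 0.05 plus Monte-Carlo noise. `scripts/acceptance.R` recomputes
this rate over 2000 replicates; the test suite runs the same check. The
smoothness estimator itself is validated against known-kernel simulations
(recovering the kernel FWHM within 15%) and its node-unit scaling
property.

## Problem sizes used by the test suite

The suite exercises the full 5184-trial design once (exclusion
arithmetic), and otherwise scales simulations to the smallest sizes that
make the statistical assertions sharp: 2000 replicates for the SPM
family-wise calibration, 10000 for the Wilcoxon threshold calibration, 400
for the normality-gate rates, 200 for smoothness-estimator recovery, 50
for the planned-comparison power pattern, and 4–8 participants for the
oracle-equivalence fixtures.

## Known limitations

- Landmarks are sample-resolution; sub-sample interpolation would reduce
  the ~2-point rDPV quantization of fast movements but is deliberately
  avoided (see above).
- The parametric post-hoc form and the exclusion pool are documented
  choices among defensible alternatives, selectable where it matters.
- The SPM stage implements suprathreshold presence only — no cluster-
  extent or cluster-mass p-values, no permutation variant, no 2D fields.
- The generator's duration and noise defaults are plausible placeholders,
  not fitted values; conclusions about real data require real data.
- The coordinate frame is assumed room-fixed (allocentric) with direction
  labels independent of posture; marker axes of a given capture system may
  need remapping before import.
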