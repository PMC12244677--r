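---
title: "Methods: a closed-loop MIMO model of upper-limb afferent feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a closed-loop MIMO model of upper-limb afferent feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbloop)
```

## The model

`limbloop` implements a linear time-invariant, multiple-input
multiple-output model of the human upper limb around a static posture
(arm hanging, elbow flexed 90 degrees, forearm pronated 90 degrees).
The forward path is a cascade of three submodels:

1. **Muscle activation/contraction.** Each of the 15 plant muscles
   (the grouped biceps and triceps are split into their heads) turns
   descending drive `u` (MVC fraction) into force through two
   first-order lags with unity DC gain scaled by the maximum voluntary
   force: `f_i(s)/u_i(s) = C_i / ((T1_i s + 1)(T2_i s + 1))`. This
   two-lag form is the unique structure consistent with naming only
   `T1`, `T2`, `C` and with an open-loop pole census of two real poles
   per muscle; we therefore adopt it as the activation model, with no
   feedthrough.
2. **Musculoskeletal geometry.** Joint torques are `tau = M f`, where
   the 7-by-15 moment-arm matrix `M` is the transpose of the
   muscle-to-joint Jacobian. The same geometry maps joint rotation back
   to muscle elongation, `dlam = -M' q`: a rotation in the direction of
   a muscle's moment arm shortens that muscle. This sign convention is
   centralized in `assemble_forward_path()` and
   `build_closed_loop()`.
3. **Joint impedance.** `I qdd + D qd + K q = tau + tau_ext` over the
   7 DOF from shoulder to wrist, with coupled (full) symmetric
   matrices, so torque about one DOF moves all others.

Two feedback paths close the loop:

* **Muscle spindles (type Ia)** act as proportional-derivative
  feedback on elongation, `u_MS = L dlam + V d(dlam)/dt`, applied with
  positive sign at the muscle input. `L` and `V` share the structure of
  one relative gain matrix `G`: `V = c G` and `L = (c/r) G`. The ratio
  `r` (seconds) is constrained to [0.06, 0.14] with default 0.1, the
  range over which joint damping behaves realistically in single-muscle
  models; `c` is set by stability (below).
* **Golgi tendon organs** act as negative force feedback with
  homonymous gain `k / C_i` (`k` in (0, 2.7), default 1.27). The rule
  makes the drive-to-feedback transformation independent of muscle
  size: `gain_i * C_i = k` exactly, which the tests assert identically.

Both feedback signals of muscle `i` pass through one lumped
transmission delay `d_i = a_i + 1 ms + e_i` (afferent + central +
efferent), realized as a third-order diagonal Pade block per channel.
The published closed-loop order (89 = 44 + 3 x 15) implies exactly one
third-order block per muscle channel, not separate afferent and
efferent blocks; heteronymous delay differences are therefore ignored,
which we flag as an approximation of the delay placement.

## Parameter provenance

The packaged tables under `inst/extdata/` are transcriptions of the
published parameter compilation: the 13-by-13 relative spindle gain
matrix (68 of 169 cells measured; missing cells are first-class mask
entries, never zeros), the per-muscle maximum forces, solved delays and
the printed force-feedback gain column, and the 11-by-11 excess central
delay matrix (43 measured pairs, deltoid heads collapsed). Two printed
inconsistencies are preserved rather than silently fixed: the
force-feedback gains printed for ECR/FCR and for ECU/FCU are swapped
relative to `k/C` computed from the printed forces (the recomputed
column is authoritative, the printed one ships as reference), and the
printed mean force-feedback gain (2.85e-3 MVC/N) matches neither
column (both give 2.71e-3).

The forward-path matrices (`M`, `I`, `D`, `K`, `T1`, `T2`) of the
reference implementation live in supplementary material that is not
redistributed here. `generate_fixture()` therefore produces a
deterministic synthetic plant with the same structure: moment arms
with proximal-distal block sparsity (each muscle spans 1-3 DOF at
physiological magnitudes, 1-6 cm), symmetric positive-definite
impedance whose modal frequencies rise from about 1.8 Hz at the
shoulder to about 5 Hz at the wrist, modal damping ratio 0.25, and
Hill time constants `T1 ~ 35 ms`, `T2 ~ 150 ms` with 10 percent
seed-controlled jitter. These values were chosen once as physiological
midpoints; all analyses that depend on the supplementary plant (the
absolute gain margin 0.572, the closed-loop pole census 21 + 68, the
stretch-response percentages) are consequently checked as structural
and qualitative properties on the fixture, not as absolute numbers.
What passing tests show is that the machinery reproduces every exact
law and census that is plant-independent; what they cannot show is
agreement with the published absolute margin, which requires the
original plant values.

## The estimation pipeline

Relative spindle gains are compiled in three steps.

*Step 1 - per-study gains.* Post-stimulus-histogram observations give
`(n+ - n-)/n_tot`, bounded by [-1, 1]; EMG-averaging observations give
`p b / s`, unbounded. When a nerve innervating several muscles was
stimulated proximal to them, the observed strength is split:
subtraction when one component is known, equal division otherwise
(`split_nerve_stimulus()`).

*Step 2 - cross-method scaling.* Methods are assumed to differ by a
scalar; a through-origin regression of the reference method on each
other method (slope `sum(a*ref)/sum(a^2)`) rescales every table, first
onto the bridge scale, then onto the reference scale, after which
cells measured by several methods are averaged without weights (the
source text does not state a weighting, so the unweighted mean is
used). The study-level precursor tables are supplementary material;
`synthetic_precursor_tables()` generates a consistent synthetic
stand-in with known scales so the pipeline can be tested for exact
reconstruction of the packaged matrix.

*Step 3 - absolute scaling.* `system_gain_margin()` finds the largest
`c` for which the full closed loop (force feedback and delays
included) is stable. The state matrix is affine in `c`, so the
authoritative method is bisection on the maximum eigenvalue real part
to relative tolerance 1e-4. A second, frequency-domain bound in the
style of a multiloop disk margin is computed from positive-real-axis
crossings of the characteristic loci of the broken spindle-loop
transfer matrix; the two methods agree within 5 percent on all tested
plants, and any discrepancy is reported, not hidden. The printed
per-loop criterion `real(1 - c S_i P_k) < 0` cannot hold at `c = 0`,
so it is exposed as the boundary diagnostic `loop_at_a_time_check()`
rather than a stability certificate.

Before closing the loop, the unidentified lateral-deltoid homonymous
gain is filled with the mean of the other two heads' homonymous gains
and the remaining missing cells with zero - both as explicit steps
(`fill_gain_matrix()`), and deliberately not inside
`compile_gain_matrix()`, whose output mirrors the measured table. The
13-to-15 head expansion replicates target rows; source contributions
replicate by default, with an equal-split mode (`source_mode =
"split"`) that conserves grouped-level loop gain.

## Delay decomposition

Measured round-trip delays satisfy `T_ij = a_i + c_ij + e_j`.
Homonymous central delays are the single-synapse 1 ms; heteronymous
ones are the measured excess central delay plus 1 ms, and unmeasured
pairs are imputed with the mean central delay of their excitatory or
inhibitory class, classified by the sign of the corresponding spindle
gain with a 0.5 ms excess-central-delay threshold as fallback
(excitatory connections sit near 0 ms excess, inhibitory near 1-2 ms).
One equation per measured pair yields a sparse 0/1 system `A x = b`
solved with minimum-norm pseudo-inverse semantics (`MASS::ginv`).
Because every equation couples one afferent and one efferent unknown,
the direction (+1 on afferent, -1 on efferent columns) always lies in
the null space: the decomposition is determined only up to a common
shift. The solver reports whether this indeterminacy is active, and an
optional anchor pins one afferent delay for synthetic recovery tests,
which demand exact recovery (< 1e-9 ms) on noise-free full grids. The
published round-trip table is not printed in the available text, so
`synthetic_roundtrip_delays()` reconstructs a synthetic one from the
packaged per-muscle delays; solving it reproduces those delays to
machine precision, which validates the solver against the published
solutions without the unpublished inputs. Conduction-velocity
regressions (velocity = 1000/slope for delays in ms against lengths in
m) degrade gracefully when no innervation-length table is supplied.

## Response analyses

`step_response_grid()` simulates every channel pair of a chosen
input/output kind with the exact zero-order-hold discretization
(`Matrix::expm` on the augmented system), which has no integration
error for step inputs; `frequency_response_grid()` evaluates the
resolvent on a 0-20 Hz grid. Because the state vector mixes units
spanning roughly eight orders of magnitude (wrist inertia of
8e-4 kg m^2 against muscle forces of 1.5e3 N), all resolvent and DC
solves first apply an Osborne diagonal balancing similarity; without
it the raw state matrix is numerically singular in the 1-norm even
though its eigenvalues are well separated from the origin.

`classify_stretch_response()` applies a 1 N m torque step per DOF and
labels each of the 105 (DOF, muscle) cases by sign consistency:
elongation over the first 25 ms after perturbation onset (lengthening
is instantaneous through the geometry), muscle activity over the 25 ms
window starting after that muscle's own lumped delay ("excluding
delay"). A sign change within the window labels the case ambiguous.
The concordance fraction (lengthened-and-excited or
shortened-and-inhibited) carries a nonparametric bootstrap 95 percent
interval over cases (10,000 resamples, seeded); the source text does
not state its interval method, so the bootstrap is our choice.
`random_gain_experiment()` redraws the proportional gains uniformly
under the single global bound max|L| (per-element bounds are not
supported by the text), either preserving the estimated signs on
measured cells or shuffling sign and value densely, keeps `V = r L`
and the force-feedback gains fixed, and enforces stability by
rejection.

## Numerical choices and degenerate inputs

* Bisection tolerance 1e-4 (relative) on `c`; the sensitivity tests
  tighten it to 1e-5 so the exact quadratic-in-`M` and linear-in-`C`
  laws can be asserted at 1e-3. These two laws are exact because `M`
  enters both paths and `C` only the forward path (its appearance in
  the force-feedback rule cancels); all other parameters act through
  the dynamics, and their sensitivity is plant-dependent - sub-linear
  for the published values, close to linear for `T2` on some synthetic
  plants - so the tests assert only that they stay strictly below the
  quadratic law.
* Pade blocks use the diagonal (order, order) approximant in
  controllable canonical form with a pole-magnitude state rescaling;
  zero delay returns a zero-state identity block.
* A measured gain of exactly 0 is present but sign-neutral: it joins
  the bidirectional-pair count yet can never be sign-discordant or
  enter the sign-validation overlap.
* Degenerate inputs fail loudly: non-square or unlabeled gain tables,
  non-numeric cells (reported with row and column), unstable
  configurations passed to simulators, empty measurement sets, and
  constant innervation lengths are all errors, not warnings.

## Problem sizes

The test suite and the acceptance script run the full 89-state model:
stability searches take about 40 eigendecompositions each,
classification simulates 7 torque steps at 0.5 ms resolution for about
0.1 s of model time, and the random-gain experiments use a handful of
draws with a few hundred bootstrap resamples. The complete suite runs
in well under a minute on one core; these sizes are the package's
defaults because the analyses are exact or structural rather than
Monte-Carlo-limited.

## Known limitations

* No force-length/force-velocity muscle nonlinearity, no type II
  afferents, no gamma modulation or gain scheduling, no heteronymous
  force feedback - all deliberately outside the linear time-invariant
  scope.
* Posture is fixed; `M` and `I` are not recomputed for other postures.
* The synthetic plant reproduces structure, not the published absolute
  gain margin; conclusions about absolute feedback strength require
  the original forward-path tables.
* The lumped per-channel delay ignores heteronymous afferent/efferent
  asymmetries (see above).
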