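---
title: "From contour overlap to plan quality: the contourdose methods"
author: "contourdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From contour overlap to plan quality: the contourdose methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

Automatic segmentation of radiotherapy structures is usually validated
geometrically: the Dice similarity coefficient (DSC) measures volumetric
overlap between the auto-segmented (AS) and manually segmented (MS) contour,
and the Hausdorff distance (HD) measures worst-case boundary disagreement.
Neither metric is defined with reference to the treatment plan, yet the
clinical consequence of a contour error is entirely mediated by the plan:
the same geometric error can be harmless or decisive depending on where the
structure sits in the dose distribution and how steep the local dose
gradient is. `contourdose` provides a controlled environment for studying
that mediation — synthetic cohorts with known contour discrepancies, a dose
model whose gradient is a single explicit parameter, and the three-way
plan/contour cross-evaluation that separates "the plan looks fine on its own
contours" from "the plan is fine on the true anatomy".

## Geometric metrics

For masks with occupied-voxel sets $V_{AS}$ and $V_{MS}$,

$$\mathrm{DSC} = \frac{2\,|V_{AS} \cap V_{MS}|}{|V_{AS}| + |V_{MS}|},$$

computed over voxel counts on the shared grid. The Hausdorff distance is the
symmetric version of the directed worst-case nearest-point distance over
boundary point sets $A$ and $B$:

$$\mathrm{dHD}(A,B) = \max_{a \in A} \min_{b \in B} \lVert a-b \rVert, \qquad
  \mathrm{HD} = \max\{\mathrm{dHD}(A,B),\, \mathrm{dHD}(B,A)\}.$$

Three conventions are deliberate and applied uniformly:

- **Boundary points, not volume points.** Contours are surfaces, so HD is
  evaluated on the physical centers of boundary voxels — occupied voxels
  with at least one unoccupied 6-neighbour (the grid edge counts as
  unoccupied). Using all occupied voxels would only ever lower dHD from the
  full set toward the same boundary extremes while blurring its meaning.
- **3D, not per-slice.** A single mm value is reported per structure pair;
  the 3D distance is the stricter reading.
- **Exact distances in physical mm.** Indices are converted to mm with the
  (possibly anisotropic) spacing before any distance is taken, and nearest
  distances are computed exactly — the implementation is required by test to
  be bit-identical to an all-pairs brute-force oracle.

Degenerate inputs: DSC of two empty masks is undefined (error); one empty
mask gives DSC 0 by definition but has no HD (the distance has no value for
an empty point set, so it is an error rather than a sentinel).

## The phantom generator

Structure sets are built from shape templates (sphere, ellipsoid, tube —
spanning the compact, flattened and elongated regimes in which segmentation
quality is known to vary) placed on a default grid of 96³ voxels at 2 mm
spacing: a desk-scale volume of 19.2 cm per side that still leaves ≥ 10
voxels across every default structure. Occupancy follows the
voxel-center-in-shape rule — unambiguous and exactly countable, at the cost
of partial-volume fidelity. Per-subject realism comes from seeded jitter of
template centers (± 2 mm uniform per axis) and sizes (± 5% uniform),
chosen as a mild inter-patient variation that never moves structures across
each other. Subject $i$ of a cohort draws its random stream from
`seed + i`, so subjects are independent yet individually reproducible, and
every operation restores the caller's RNG state.

The AS set applies one perturbation per structure to the MS "truth":

| kind             | magnitude unit | models |
|------------------|----------------|--------|
| `translate`      | mm (rounded to whole voxels per axis) | systematic placement error |
| `dilate`/`erode` | mm (morphological ball radius)        | over/under-segmentation |
| `truncate_axial` | mm removed from the superior extent   | inconsistent superior–inferior range of elongated organs |
| `surface_noise`  | fraction of boundary voxels toggled, in [0, 1] | boundary raggedness |

`surface_noise` is defined as a toggle *fraction* because a mm magnitude has
no natural meaning for independent voxel flips; both the occupied boundary
shell and its unoccupied 6-neighbour shell are candidates, so the expected
volume is approximately preserved. Translation rounds to whole-voxel
offsets (recorded in the mask's metadata) to keep masks binary without
resampling.

What the phantom does *not* emulate: CT intensities, anatomically realistic
organ shapes, inter-observer MS variability, or the atlas-selection failure
modes of any particular segmentation tool. Passing tests on the phantom
therefore demonstrate correctness of the metrics and of the
geometric-to-dosimetric propagation machinery — not the accuracy of any
segmentation algorithm on real anatomy.

## The dose surrogate

Commercial inverse optimization is irreproducible (institutional objectives,
proprietary optimizers), so plans are synthesized by a declared closed form.
Each prescribed target $T$ with prescription $Rx_T$ contributes

$$f_T(x) = \begin{cases} Rx_T & x \in T \\
  Rx_T \cdot 2^{-d(x,T)/h} & \text{otherwise,} \end{cases}$$

where $d(x,T)$ is the exact Euclidean distance from the voxel center to the
nearest occupied voxel center of $T$ (computed by a separable
lower-envelope distance transform in compiled code) and $h$ is the **falloff
half-distance**: the dose halves every $h$ mm outside the target. The raw
dose is the voxelwise maximum over targets, which composes simultaneous
integrated boost prescriptions naturally; voxels inside a spared OAR and
outside all targets are multiplied by $(1-w)$; the result is floored at a
background dose (default 0 Gy).

The surrogate is *not* a model of VMAT delivery — no beams, no fluence, no
optimizer. It is chosen so that (a) the plan genuinely depends on which
contour set it is built from, through both the target field and the sparing
regions, and (b) the dose gradient is one tunable number, since gradient is
precisely the quantity that couples geometric error to dosimetric error.
Presets: $h = 5$ mm emulates a steep stereotactic-body-style falloff,
$h = 10$ mm a conventional one. Sparing is a hard in-mask multiplier with no
feathering so that the dependence of dose on contours stays exactly
interpretable in tests.

## DVH and constraint conventions

- Cumulative DVH bins run $0, w, 2w, \dots$ ($w = 0.1$ Gy default) up to the
  first edge strictly above the in-mask maximum; the value at edge $e$ is
  the percentage of occupied voxels with dose $\ge e$ (closed superlevel
  convention, the standard TPS reading of VxGy). The curve starts at 100%,
  is non-increasing, ends at 0%, and its trapezoid integral reproduces the
  voxel mean dose to within one bin width.
- Constraints are always evaluated **bin-free**, directly on voxel doses, so
  binning can never change a pass/fail decision; superlevel counts are
  integer-exact.
- `Max` is the single hottest voxel (no volume-qualified maximum), `Mean`
  the arithmetic voxel mean; volumes are relative (%), with absolute cc
  available from `mask_volume()`.
- The constraint grammar accepts `V<d>Gy`, `Max`, `Mean` with relations
  `<`, `≤`/`<=`, `≥`/`>=`; mixed typography (`<` vs `≤`) is normalized but
  strictness is preserved exactly as parsed, and a strict `<` is evaluated
  strictly.

## The three-mode cross-evaluation

For each subject, two plans are synthesized — one from the AS contours, one
from the MS contours — and constraints are evaluated in three combinations:

| mode | plan from | evaluated on | reads as |
|------|-----------|--------------|----------|
| PlanAEvalA | AS | AS | the AS workflow's self-assessment |
| PlanMEvalM | MS | MS | the clinical reference plan |
| PlanAEvalM | AS | MS | the controlled observation: AS plan on the true anatomy |

The fourth combination (MS plan on AS contours) answers no clinical question
and is intentionally never produced. Two target policies mirror the two
planning styles: `same_source` takes targets and OARs from the planning
source (prostate-style), `always_MS_target` pins targets to the clinical MS
contours and varies only the OARs (head-and-neck-style).

Per-constraint comparisons between modes use the classical paired t-test
($t = \bar d / (s_d/\sqrt n)$, sample SD, two-sided $p$ from Student's $t$
with $n-1$ df) at $\alpha = 0.05$, per constraint across subjects, with no
multiple-testing correction by default (a Holm option exists but is off, to
keep per-endpoint readings directly interpretable). Zero-variance
differences — which a zero-perturbation cohort produces by construction —
are flagged degenerate instead of yielding an infinite statistic: $p = 1$
(not significant) when the mean difference is also zero, $p = 0$ with a
degeneracy flag otherwise.

## The discordance experiment

`discrepancy_experiment()` sweeps a spherical OAR over surface-to-surface
distances {10, 25, 40} mm from a 40 Gy spherical target under rigid AS
shifts of {2, 4, 6} mm at $h = 5$ mm, five subjects per cell on the default
96³ grid. Because the shift (hence DSC and HD) is independent of placement
while the local dose level decays as $2^{-d/h}$, cells with
indistinguishable geometric agreement differ many-fold in mean-dose impact,
and the mean $|\Delta\,\text{mean dose}|$ decreases monotonically with
distance at fixed shift. This is the package's quantitative exhibit that
geometric metrics do not rank dosimetric impact; the acceptance tests assert
both properties, and `scripts/acceptance.R` reports the near/far deltas and
their ratio.

```{r discordance}
sw <- discrepancy_experiment(seed = 17)
aggregate(cbind(abs_delta = abs(delta_aa_mm), dsc) ~ distance_mm + magnitude_mm,
          sw, mean)
```

## Problem sizes and numerical choices

The shipped studies use five subjects per cohort — the scale at which paired
per-constraint testing is still meaningful while keeping a full study (two
plans per subject on 96³ grids) in the tens of seconds. The test suite's
oracle comparisons use random blob masks with ≤ 500 boundary points, where
the $O(n^2)$ all-pairs Hausdorff reference is instant; the distance-ordered
properties of the dose model are asserted on 48³–64³ grids. Distance
transforms are exact (no sampling approximations); Hausdorff reductions are
blocked at 2048 points to bound memory but change no value. Ties in the
dose-decay monotonicity checks are tolerated at $10^{-12}$ to absorb
floating-point reordering only.

## Known limitations

- The DICOM-RT import path (RTSTRUCT/RTDOSE) is not implemented; volumes
  move through NIfTI with spacing and origin in the header plus a JSON
  manifest per structure set. Grid congruence is checked on read and
  mismatches are refused rather than silently resampled.
- The dose surrogate's falloff is isotropic and target-centric; it cannot
  represent beam-direction effects, heterogeneity corrections, or the
  constraint-driven local shaping of a real optimizer.
- DVHs count whole voxels; no sub-voxel contour integration is attempted, so
  very small structures (few voxels) carry discretization noise in their
  endpoints — visible in the head-and-neck phantom's chiasm and optic
  nerves, as it is in practice at coarse dose-grid resolutions.
- Geometric metrics beyond DSC and HD (mean surface distance, Jaccard,
  added-path-length) are out of scope, as are biological indices (EUD,
  NTCP/TCP) and statistical procedures beyond the paired t-test.
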