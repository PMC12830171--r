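---
title: "Multi-course dose accumulation and reirradiation planning with redose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-course dose accumulation and reirradiation planning with redose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redose)
```

## The problem

A patient returning for radiotherapy in a region that overlaps a previous
treatment cannot be planned course-by-course: normal-tissue toxicity is
driven by the *cumulative* biological dose.  Because courses differ in
fractionation, the physical doses are not additive; the standard currency
is the equieffective dose in 2 Gy fractions (EQD2) under the
linear-quadratic (LQ) model.  `redose` implements the full evaluation
chain — spatial mapping, EQD2 conversion, recovery scaling, summation,
constraint evaluation, and the construction of planning aids for the new
course — independent of any one treatment planning system.

## Model and assumptions

For a course of total dose $D$ in $n$ fractions and tissue ratio
$\alpha/\beta$ (Gy),

$$\mathrm{EQD2} = D \cdot \frac{D/n + \alpha/\beta}{2 + \alpha/\beta}.$$

Assumptions the package inherits from this model:

* **Uniform fractionation per voxel.** Dose per fraction at a voxel is its
  total course dose divided by the course's fraction number.  This is the
  universal convention for EQD2 grids; it ignores the fact that a voxel on
  a steep gradient may have received its dose non-uniformly over the
  course (e.g. from a re-plan mid-course).
* **LQ validity.** No high-dose-per-fraction correction (no LQ-L) and no
  time factor; EQD2 only.  Tissue recovery over the interval between
  courses is modelled, if at all, by a static dose scaling factor
  (DSF, a multiplier in $(0,1]$ applied to the converted EQD2).
* **Registration is an input.** The spatial transform per prior course —
  rigid affine or a displacement field — is the *result* of a registration
  the user performed and reviewed elsewhere.  The package only applies it.
  The transform maps points of the current planning frame to the prior
  frame (pull-back convention), so resampling requires no inversion; this
  direction is stated in the type contract because conventions differ
  between systems.
* **Current-plan contours only.** EQD2 conversion assigns each voxel the
  $\alpha/\beta$ of the highest-priority current-plan structure containing
  it (explicit priority ranks; ties are rejected), falling back to a
  configurable default.  Prior-course contours are never needed, which is
  what makes the workflow practical — historical structure sets do not
  require curation.

## Key parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `alpha_beta` | Gy | 3 | LQ fractionation sensitivity; ~3 for late-responding normal tissue, ~10 for most tumors.  Institutional tables vary, so the default is deliberately neutral and every analysis accepts an explicit map. |
| `dsf` | — | 1 | dose scaling factor; fraction of prior EQD2 still "remembered" by the tissue.  1 = no recovery credit. |
| `near_margin_mm` | mm | 20 | expansion of the target defining the "region near the target" within which the prior OAR maximum P is taken.  "Near" is not standardized; 20 mm covers the distance over which a modern plan can realistically drop its dose. |
| `N` | — | 3 | number of nested optimization structures; more structures give a smoother gradient. |
| `dvh_bin_width` | Gy | 0.1 | cumulative DVH resolution. |

## The accumulation pipeline

`accumulate()` runs, per prior course: **resample** (trilinear, physical
dose, out-of-extent voxels set to 0 Gy *and counted* in provenance so
inadequate prior grid coverage is visible), then **convert** to EQD2, then
**scale** by the course's DSF; finally all courses are **summed**
voxel-wise.  Physical doses are mapped before conversion because
interpolation is only meaningful on the physical grid the TPS computed;
converting first and resampling after would interpolate a nonlinear
function of dose.

Trilinear interpolation was chosen over nearest-neighbour (blocky
gradients) and cubic (overshoot): it is bounded by the eight surrounding
voxels and monotone, which the test suite asserts as an invariant.

## Point-dose feasibility

With cumulative constraint $A$ and accumulated prior point dose $P$ (both
EQD2 Gy, the point being the OAR's near-maximum D0.01cc), the remaining
budget is $B = \max(A - P, 0)$ and the allowed physical dose for the new
scheme solves the LQ quadratic:

$$D = \frac{n}{2}\left(-\frac{\alpha}{\beta} +
\sqrt{\left(\frac{\alpha}{\beta}\right)^2 +
\frac{4B(2+\alpha/\beta)}{n}}\right).$$

```{r}
point_dose_feasibility(A = 60, P = 35, fractionation(5), alpha_beta = 3)
```

This is conservative by construction: it assumes the new maximum lands
exactly on the prior maximum.  `pointdose_worksheet()` applies it row-wise
to a CSV, mirroring the spreadsheet practice it replaces.

## Nested optimization structures

When $P + R > A$ (prescription $R$), full prescription dose would exceed
the constraint somewhere, and the planner needs a gradient.  The
construction partitions the OAR by prior-dose isodose levels
$D_i = P - i\,d$, $d = ((P+R)-A)/N$, into shells
$S_i = \{\mathrm{OAR}: \mathrm{EQD2} \ge D_i\} \setminus \bigcup_{j<i} S_j$,
assumes every voxel of $S_i$ received $D_{i-1}$ (with $D_0 = P$), and
limits it to $A - D_{i-1}$ — converted to physical dose for the prescribed
scheme with the OAR's $\alpha/\beta$.  The assumption errs high for every
voxel (each shell's actual prior dose is below its assumed prior except at
the shell boundary), so the construction is conservative; the test suite
checks this voxel-by-voxel.  Remaining OAR voxels below all thresholds can
be planned without regard to the prior treatment.

```{r}
case <- make_fig4_case()
res <- accumulate(case$courses, case$geometry, case$structures,
                  alpha_beta_map())
P <- compute_near_target_dmax(res$summed_eqd2, case$structures[[2]],
                              case$structures[[1]], 20)
generate_opt_structures(P, R = 60, A = 60, N = 3, res$summed_eqd2,
                        case$structures[[2]], fractionation(30), 3)
```

Design choices that were genuinely open:

* **Equality case.** $P + R = A$ yields an empty set: $d$ would be 0 and
  all $N$ levels would coincide degenerately, and at equality the full
  prescription is still deliverable.
* **Shell domain.** Shells are cropped to the OAR by default (the limits
  protect the OAR, and the remaining-voxels rule is OAR-scoped); a flag
  produces whole-grid shells for visual review.
* **Negative levels.** If $A < R$, low thresholds are clamped at 0, which
  simply means "all remaining OAR voxels".  If $P > A$ (prior dose already
  over constraint), a shell's EQD2 budget is negative and its physical
  limit is 0 — the deficit is reported, not hidden.
* **Per-OAR processing.** P is recomputed for each OAR processed, since
  the near-target maximum is organ-specific.

## Dose metrics and the scorecard

`metric_d_cc()` (e.g. D0.01cc) sorts masked voxel doses descending and
accumulates whole voxel volumes until the requested volume is reached — no
sub-voxel interpolation, which keeps the estimator conservative and
exactly reproducible; the suite pins it to an independent full-sort
oracle.  Structures smaller than the requested volume return their minimum
dose with a warning.  Scorecard semantics: PASS iff achieved ≤ limit, so
exact equality passes (a limit is a "≤" constraint).

## Synthetic cases: what they emulate and what they do not

The generator builds prior dose as a flat high-dose core with a Gaussian
shoulder, $D(r) = D_\mathrm{peak}\exp(-\max(0, r - r_\mathrm{core})^2 /
2\sigma^2)$, plus spherical/cuboid OAR and target masks.  This captures
what the algorithms consume — a smooth distribution with a hot plateau and
realistic falloff overlapping an OAR — and makes isodose shells
analytically checkable.  It does **not** emulate CT anatomy, heterogeneity
corrections, multi-focal plans, or registration error; passing tests
demonstrate algorithmic correctness, not clinical robustness to imaging
artefacts.  `make_fig4_case()` calibrates two courses (40 EQD2 Gy in 25
fractions + 17 EQD2 Gy in 10, $\alpha/\beta$ = 3, peaks set through the
inverse LQ conversion) so the accumulated near-target OAR maximum is
exactly P = 57 EQD2 Gy, matching the worked example's printed inputs
(R = 60, A = 60) end-to-end.

Default problem sizes: the worked-example grid is 48×48×24 voxels at
2.5 mm isotropic — coarse enough that every property check (including
1000-case parameter sweeps and 100-grid metric-oracle comparisons) runs in
seconds, fine enough that shells span several voxels.

## Numerical choices

* Thresholds and budgets are exact floating-point arithmetic; no rounding
  of allowed doses to deliverable increments (deliberately — rounding
  policy is institutional).
* Feasibility flags use safe boundaries: prior = limit counts as
  INFEASIBLE; prior + prescription = limit still counts as ACHIEVABLE
  (consistent with the empty-set rule at $P + R = A$).
* RT Dose files store 32-bit unsigned integers with a dose-grid scaling
  chosen as the smallest 16-character decimal at or above
  max/(2³²−1), so the stored string is exactly the quantization factor;
  round-trip error is bounded by half a step.
* Masks rasterize by voxel-centre-in-polygon (even-odd rule) with
  nearest-slice assignment within half a slice spacing; mask export traces
  marching-squares contours at level 0.5, so a mask→contours→mask round
  trip can differ only in the one-voxel boundary layer.
* The near-target region uses an exact Euclidean distance dilation on
  voxel centres, honouring anisotropic spacing.

## Known limitations

* Axis-aligned grids only for masks and DICOM I/O; oblique geometries must
  be resampled to an axis-aligned target first.
* EQD2 only; no BED, LQ-L, or time-dependent recovery kinetics.
* The DICOM codec covers the common axis-aligned Explicit-VR-Little-Endian
  dialect and rejects everything else explicitly rather than guessing.
* No registration, no inverse planning: the package prepares inputs for a
  TPS and evaluates its outputs, nothing in between.
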