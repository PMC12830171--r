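# redose — reirradiation dose accumulation and EQD2 planning

`redose` is an R toolkit for the medical-physics workflow around
**reirradiation** (reRT): treating a patient whose target region overlaps
tissue irradiated in one or more earlier courses.  Deciding whether a new
course is safe — and shaping it so that it is — requires accumulating dose
across courses on a common geometry and in a common radiobiological
currency.  The package is aimed at physicists and dosimetrists who need a
treatment-planning-system-neutral way to do that, and at researchers who
want a reproducible, scriptable implementation of the standard method.

## What it computes

**EQD2 conversion.** Physical dose D delivered in n fractions is expressed
as the equieffective dose in 2 Gy fractions under the linear-quadratic
model:

    EQD2 = D · (d + α/β) / (2 + α/β),   d = D/n

with a tissue-specific α/β ratio (Gy).  The inverse — the physical dose
that spends a given EQD2 budget in n fractions — is the non-negative root
of `D²/n + (α/β)·D − EQD2·(2 + α/β) = 0`.

**Accumulation.** Each prior course's physical dose grid is resampled onto
the current planning geometry through a user-supplied rigid or deformable
transform (registration itself is an input, never computed here),
converted voxel-wise to EQD2 using the *current* plan's structures and α/β
map, optionally multiplied by a dose scaling factor (DSF ≤ 1, modelling
tissue recovery), and summed.

**Point-dose feasibility.** For a cumulative OAR constraint A (EQD2 Gy)
and prior accumulated point dose P, the remaining budget is
B = max(A − P, 0); inverting the LQ conversion gives the physical dose per
fraction and in total that the new course may deliver at that point.

**Optimization structures.** When the near-target prior maximum P plus the
new prescription R exceeds the constraint A, the OAR is partitioned into N
nested shells by prior-EQD2 isodose levels `D_i = P − i·d` with step
`d = ((P + R) − A)/N`.  Every voxel of shell S_i is conservatively assumed
to have received `D_{i−1}` (with `D_0 = P`), so S_i gets the planning
limit `A − D_{i−1}`, also expressed in physical dose for the prescribed
fractionation.  If P + R ≤ A no structures are needed.

**Reporting.** Cumulative DVH curves, dose metrics (Dmax, Dmean, D0.01cc,
Dx%, VxGy), a pass/fail constraint scorecard, and a deterministic
JSON/markdown report with per-course provenance; plus an append-only
machine-readable case log.

I/O covers DICOM RT Dose / RT Structure Set / RT Plan (axis-aligned
Explicit-VR-Little-Endian dialect, written and read by the package's own
codec), NIfTI volumes, JSON transform files, and a `case.json` bundle
format tying a case together.

## Worked example

The built-in synthetic case generator produces a two-course, two-structure
case calibrated so the accumulated near-target OAR maximum is 57 EQD2 Gy:

```r
library(redose)

case <- make_fig4_case()
res  <- accumulate(case$courses, case$geometry, case$structures,
                   alpha_beta_map())   # default alpha/beta 3 Gy
res
#> accumulation_result: 2 course(s), summed EQD2 max 57.000 Gy
#>   C1: identity transform, dsf 1.00, 25 fx, 0 voxels out of extent
#>   C2: identity transform, dsf 1.00, 10 fx, 0 voxels out of extent

oar <- case$structures[[2]]; target <- case$structures[[1]]
P <- compute_near_target_dmax(res$summed_eqd2, oar, target, near_margin_mm = 20)
generate_opt_structures(P, R = 60, A = 60, N = 3, res$summed_eqd2, oar,
                        fractionation(30), alpha_beta = 3)
#> opt_structure_set: P = 57.00, R = 60.00, A = 60.00 EQD2 Gy, N = 3, step d = 19.000
#>  structure threshold_eqd2 assumed_prior_eqd2 limit_eqd2 limit_physical voxels
#>         S1             38                 57          3        4.74937    548
#>         S2             19                 38         22       27.97260    291
#>         S3              0                 19         41       45.41571     86
```

Reading the table: voxels that previously received ≥ 38 EQD2 Gy (S1) may
take at most 3 EQD2 Gy more, i.e. 4.75 Gy physical over 30 fractions;
the 19–38 Gy shell (S2) may take 22 EQD2 Gy; the remaining OAR (S3) may
take 41 EQD2 Gy.  The assumed prior dose plus the limit always equals the
constraint A = 60.

The point-dose method, as used in the worksheet fallback:

```r
point_dose_feasibility(A = 60, P = 35, fractionation(5), alpha_beta = 3)
#> point-dose feasibility: A = 60.000, P = 35.000 -> budget 25.000 EQD2 Gy
#>   allowed: 3.7202 Gy/fx x 5 fx = 18.6008 Gy (alpha/beta 3.0)
```

A scorecard against cumulative limits:

```r
evaluate_scorecard(res$summed_eqd2, case$structures,
                   list(constraint("OAR", "DMAX", 60),
                        constraint("OAR", "D0.01cc", 55)))
#>   structure  metric achieved limit margin status
#> 1       OAR    Dmax       57    60      3   PASS
#> 2       OAR D0.01cc       57    55     -2   FAIL
```

## Command line

`inst/cli/redose` wraps the same functions as shell subcommands:

```sh
redose synth --out case_dir --preset fig4
redose accumulate --bundle case_dir
redose optstructs --bundle case_dir --oar OAR --target PTV -R 60 -A 60 -N 3 --fractions 30
redose report --bundle case_dir
redose pointdose --worksheet points.csv
```

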