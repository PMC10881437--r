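---
title: "Spatially resolved re-irradiation planning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially resolved re-irradiation planning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `dartplan`: the radiobiological
model and its assumptions, the geometry conventions, the parameters that
matter (with units and defaults), what the synthetic phantom does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## 1. Radiobiological model

### EQD2 and dose accumulation

Doses from courses with different fractionation are accumulated after
conversion to the equivalent dose in 2 Gy fractions. For a total dose $D$
delivered in $n$ equal fractions to a tissue with linear-quadratic ratio
$\alpha/\beta$,

$$\mathrm{EQD2} = D \cdot \frac{D/n + \alpha/\beta}{2 + \alpha/\beta}.$$

The 2 Gy in the denominator is the reference fraction size that *defines*
EQD2 and is deliberately not configurable. Per-voxel conversion of a plan's
dose distribution assumes each voxel's total dose is delivered in the plan's
$n$ equal fractions — the standard single-plan assumption. Cumulative dose
is the voxelwise sum of the two courses' EQD2 images, each converted with
the organ's own $\alpha/\beta$ (2 Gy spinal cord, 3 Gy esophagus). No
time-dependent recovery factor is applied; the cumulative tolerance is taken
as given in the organ specification.

### Remaining-budget inversion

Given an organ's cumulative maximum-dose tolerance $\mathrm{EQD2}_{max}$ and
the maximum mapped prior EQD2 of a structure, $\mathrm{EQD2}^{pRT}_i$, the
physical dose limit for the new course of $n$ fractions solves
$\mathrm{EQD2}(D_i) = b$ with budget
$b = \mathrm{EQD2}_{max} - \mathrm{EQD2}^{pRT}_i$, i.e. the positive root of
$D^2/n + D\,(\alpha/\beta) = b\,(2+\alpha/\beta)$:

$$D_i = n\left(\sqrt{\left(\tfrac{\alpha/\beta}{2}\right)^2 +
\frac{b\,(2+\alpha/\beta)}{n}} - \frac{\alpha/\beta}{2}\right).$$

The forward map of the returned limit reproduces the budget to $10^{-9}$
(property-tested over 1000 random cases). Budgets $\le 0$ clamp to a 0 Gy
limit with an explicit infeasibility flag rather than raising, so a
clinically impossible case flows through the pipeline and is surfaced in the
reports instead of crashing it.

Default tolerances (`default_oars()`): spinal cord 70 GyEQD2 — a
thecal-sac maximum-dose figure discussed in the re-irradiation literature —
and esophagus 84 GyEQD2, a documented placeholder. Both are configuration,
not recommendations; the published range for cord alone spans roughly
70–100 GyEQD2, which is why the package treats tolerance strictly as input.

## 2. Geometry and volume conventions

All volumes live on axis-aligned regular grids in physical millimetres;
voxel $(0,0,0)$'s centre is the grid origin, indices are 0-based, and
oblique orientations are rejected at the I/O boundary rather than silently
reinterpreted. Mask membership and distances are evaluated at voxel centres
with no partial-volume weighting. Dose samples outside the prior grid return
0 Gy — prior dose outside the scanned volume is unknown and zero is the only
non-inflating choice. Volumes used together must share a grid; resampling
(trilinear for dose, nearest-neighbour for masks) is an explicit step so an
accidental grid mismatch errors instead of interpolating silently.

## 3. Conservative dose mapping

For each planning-grid voxel centre $x$, the homologous prior-frame point is
$p = x + v(x)$ with $v$ the displacement field (stored in mm, planning frame
to prior frame). The mapped dose is

$$\max\Big(\text{trilinear}(p),\;
\max\{\,D(c) : \lVert c - p\rVert \le r,\; c \in \text{organ}\,\}\Big)$$

over prior-grid voxel centres $c$, with smearing radius $r = 2$ mm by
default. Design choices, each made once:

* the spherical neighbourhood is evaluated in the **prior** frame around
  $p$, because the registration uncertainty is in where $p$ truly is;
* the restriction mask is the organ contour on the **prior** anatomy — the
  frame in which the neighbourhood search happens. The alternative
  (current-frame restriction) is defensible; the choice is a config switch
  away (`restrict_to_structure`, plus which mask is passed);
* the direct trilinear sample is always included in the maximum, so the
  estimator is continuous at $r \to 0$, never below the unsmeared value,
  and falls back gracefully when restriction empties the neighbourhood;
* no energy/mass-conserving resampling is attempted; interpolation plus a
  local maximum *is* the method, and its conservatism is the point.

Monotonicity in $r$ (more smearing never lowers any voxel) is
property-tested and is the structural reason the cumulative-dose robustness
sweep is non-decreasing.

## 4. Optimization structures and the constraint table

Isodose levels start at exactly one step (10 GyEQD2) and rise in 10 GyEQD2
steps to the organ's mapped maximum; thresholding uses a closed $\ge L$
bound so the shell segregation is an exact partition. Each shell's recorded
prior maximum is the actual voxelwise maximum over its segregated core — not
the bin's upper edge (tighter, still safe) — and is kept from the
pre-expansion core, because the small-structure expansion exists to make the
optimization robust, not to change dose bookkeeping.

One deliberate deviation from a straightforward reading of "the organ
outside all shells gets the full-tolerance budget": the organ remainder
holds prior dose anywhere in $[0, 10)$ GyEQD2, so giving it the full
tolerance would allow cumulative dose up to tolerance + one step at its
hottest voxel. The package instead treats the remainder as the level-0
shell: its budget is the tolerance minus the maximum mapped prior EQD2 over
the remainder itself. This makes the end-to-end guarantee exact — every
organ voxel belongs to exactly one structure whose recorded prior maximum
bounds its own prior dose, hence cumulative dose $\le$ tolerance wherever
the physical limits are honoured. A configured per-organ template limit
(default 30 Gy cord / 35 Gy esophagus for 5 fractions) additionally caps
every entry.

The binary baseline comparator reproduces current practice: the organ
segment within the superior–inferior extent of the prior treatment field
(dose footprint above 1 Gy as the observable proxy for the projected field
edge, since beam geometry is not available on phantoms), expanded by a
safety margin (default 7.5 mm, the midpoint of the clinical 5–10 mm range),
gets the template limit minus a fixed reduction — 12 Gy cord and 25 Gy
esophagus, stated for 5-fraction courses only; other fractionations must
configure their own.

## 5. The stand-in fluence optimizer

The clinical hierarchical solver is external and proprietary; the package
ships a deterministic convex stand-in implementing exactly the property the
constraint-generation method needs: per-structure maximum-dose limits are
*hard*. The dose engine is a parallel-ray pencil-beam kernel
$e^{-\mu_{\mathrm{eff}}\,\mathrm{depth}}\cdot
e^{-r_\perp^2/2\sigma^2}$ with $\mu_{\mathrm{eff}} = 0.005$/mm and
$\sigma = 3$ mm on 5 mm beamlets — invented, documented, config-exposed —
over nine posterior coplanar beams spanning 160°. Optimization is
projected-gradient (FISTA) over non-negative fluence:

* **Phase 1 (feasibility):** with the mean PTV dose pinned to prescription,
  minimize the quadratic constraint violation; a residual above 0.1 Gy
  marks the plan infeasible (pure upper bounds are trivially satisfiable by
  zero fluence, so feasibility is only meaningful at prescription scale).
* **Phase 2 (coverage):** minimize squared PTV underdose below a 3%
  headroom above prescription plus a weak penalty (weight 0.2) on dose
  above 105% of prescription outside the PTV, with a ramped quadratic
  penalty ($\rho$ from 30 to $3\times10^4$) on the hard constraints.
* **Exact feasibility:** a final conservative rescale shrinks the fluence by
  the worst limit ratio, so every returned feasible plan satisfies all hard
  limits exactly; structures with a 0 Gy limit that still receive dose are
  reported infeasible instead.

There is no randomness anywhere in the solver (fixed iteration counts,
deterministic initialization), so identical inputs reproduce identical
plans bit for bit. Because the objective only penalizes underdose below the
headroom level, the optimum is non-unique above prescription; empirical
comparisons of coverage between runs are therefore made at the prescription
level.

## 6. Plan evaluation

$D_{x\%}$ is the minimum dose to the hottest $x\%$ of the structure volume,
linearly interpolated on the sorted voxel-dose curve (so $D_{99\%}$ is a
near-minimum dose); $D_{y\,\mathrm{cm}^3}$ is the absolute-volume analogue
and $V_d$ the percentage of the structure at or above $d$. The Paddick
conformity index is $(TV \cap PIV)^2/(TV \cdot PIV)$; the homogeneity index
is the ICRU 83 form $(D_{2\%}-D_{98\%})/D_{50\%}$; the gradient index is the
ratio of the half-prescription to full-prescription isodose volumes,
computed over the whole dose grid (configurable in principle, whole-grid by
default, and documented as an assumption since several variants circulate).
Cumulative validation accepts a 1 GyEQD2 exceedance above tolerance — the
slack clinically granted for final-dose-calculation discrepancies that the
stand-in optimizer does not model but whose acceptance semantics are kept.
The robustness sweep holds the plan fixed and recomputes only the mapped
prior EQD2 at each smearing radius, mirroring how the uncertainty analysis
is applied to finished plans.

## 7. The synthetic phantom: what it emulates, what it does not

The generator builds a 120 × 100 × 160 mm elliptical "body" with six 25 mm
vertebral levels, a 4 mm-radius cord cylinder in the canal and a
5 mm-radius esophagus 36 mm anterior of it. The PTV is a 2 mm expansion of
the CTV (the target vertebral bodies) that crops out a 2 mm cord-avoidance
margin, so cord and PTV never intersect. Prior and re-irradiation target
level sets realize the three clinical overlap classes: partial
(neighbouring vertebrae), large (re-irradiation contains the prior target)
and complete (same levels). Default schedules are the cohort-typical
9 Gy × 3 prior and 8 Gy × 5 re-irradiation courses.

The prior dose is closed-form — prescription inside the prior target box
with exponential falloff of scale 6 mm — and is stored both sampled and as
parameters, so the mapping has an analytic end-to-end oracle. The 6 mm
scale was chosen once so that the cord's mapped prior EQD2 crosses several
10 GyEQD2 levels in the partial-overlap case (a test-design choice, on the
steep side of clinical falloffs, which only makes the mapping tests
harder). The displacement field is a rigid shift (1.5, −1, 4) mm plus a
1.5 mm sinusoid of 80 mm wavelength — smooth and trivially invertible at
these amplitudes — plus a 1.2 mm systematic bias that the prior-frame
anatomy does *not* follow: the field is imperfect by construction, at the
millimetre scale the 2 mm dose smearing is designed to absorb, which is
what makes the robustness sweep informative rather than degenerate.

What the phantom does not emulate: CT intensities and tissue heterogeneity,
curved spines, realistic beam spectra or deliverability, organ motion, and
discontinuous or folding deformations. Passing tests therefore demonstrate
the correctness of the mapping, structure-generation, budgeting and
constraint-enforcement machinery under controlled geometry — not clinical
dosimetric accuracy on real anatomy.

## 8. Problem sizes and numerical tolerances

Three grid presets cover the same physical extent: `full` (1 mm voxels,
~1.9 M) for geometry and mapping-oracle work, `small` (2.5 mm, ~123 k) for
planning runs, and `tiny` (4 mm, ~30 k) for smoke tests. These sizes were
chosen so a complete three-scenario planning study runs in a couple of
minutes on one core; they are package defaults, not limits. Key tolerances:
budget-inversion round trip $10^{-9}$; DVH/metric oracles $10^{-9}$;
solver hard-constraint tolerance 0.1 Gy physical (well under the 1 GyEQD2
cumulative slack after conversion); trilinear mapping error bounded by
$3\,(h/4\cdot R_x/s + h^2/8\cdot R_x/s^2)$ — the piecewise bound that
accounts for the gradient discontinuity at the prior target surface, where
the pure curvature bound does not apply.

## 9. Known limitations

* Maximum-dose constraints only: volumetric cumulative constraints
  (e.g. a cumulative $D_{5\,\mathrm{cm}^3}$) cannot be expressed as
  per-voxel hard limits in this framework.
* The stand-in optimizer demonstrates constraint enforcement, not clinical
  plan quality; no leaf sequencing, deliverability or final dose engine.
* The displacement field is an input; no registration is performed and no
  inverse-consistency checking of supplied fields.
* Isodose step size is configurable but fixed per run; spatially variable
  steps and smearing radii are natural extensions.
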