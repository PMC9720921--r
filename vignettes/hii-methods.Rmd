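---
title: "Measuring hematoma irregularity from CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hematoma irregularity from CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hii)
```

## The index

Among all solids of a given volume the ball has the smallest surface area
(the isoperimetric inequality, $S^3 \ge 36\pi V^2$). The hematoma
irregularity index exploits this: from the measured surface area $S$
(mm²) and volume $V$ (mm³) of a segmented hematoma, two equivalent sphere
radii are formed,

$$R_1 = \frac{\sqrt{S/\pi}}{2}, \qquad R_2 = \sqrt[3]{3V/4\pi},$$

and the index is $\mathrm{HII} = 100\, R_1 / R_2$. $R_1$ is the radius of
the sphere *with surface area* $S$, $R_2$ the radius of the sphere *with
volume* $V$. For a perfect ball $R_1 = R_2$ and HII $= 100$; any deviation
from sphericity increases $S$ at fixed $V$, hence $R_1$ and the index. The
index is dimensionless and scale invariant ($S \to k^2 S$, $V \to k^3 V$
leaves it unchanged), so it isolates *shape* from *size* — unlike raw
surface area, which grows with the hematoma. Useful reference values, all
exactly computable:

* ball: 100 (the lower bound);
* cube: $\approx 111.39$;
* $n$ disjoint congruent balls: $100\, n^{1/6}$ (112.25 for two) — the
  index also penalises fragmentation;
* prolate spheroids with aspect ratio 2 and 4: $\approx 103.77$ and
  $\approx 113.09$ from the closed-form spheroid area.

In the clinical study this package operationalises, the index is measured
on baseline non-contrast head CT and used to predict hematoma expansion,
defined as volume growth $> 33\%$ relative or $> 12.5$ mL absolute on the
follow-up scan (strict inequalities; `classify_expansion()` guards the
boundary against floating-point noise so exactly 33% is "no expansion").

## From CT to a number

The measurement chain is `read_nifti()`/`read_dicom_series()` →
`segment_hematoma()` → optional `apply_exclusion_mask()` →
`compute_hii_for_mask()`:

1. **Input.** Volumes carry Hounsfield units and physical voxel spacing in
   internal axis order (slice, row, column). DICOM stored values are
   rescaled with the slope/intercept tags; missing rescale tags are an
   error because a silently assumed intercept would shift the whole HU
   window. Orientation matrices are deliberately not applied: the index
   needs spacing, not pose.
2. **Segmentation.** Acute clot is hyperdense; voxels inside the closed HU
   window $[40, 100]$ are candidates, and one 26-connected component is
   kept (the largest, or a seeded one). The interactive slice-by-slice
   editing of the original workflow is represented by the seed rule and by
   user-supplied exclusion masks (e.g. intraventricular blood), keeping
   the pipeline scriptable. Window endpoints are inclusive; no
   morphological cleanup is applied by default because hole-filling and
   smoothing change $S$ and therefore the index.
3. **Surface reconstruction.** The mask's 0.5 level set is triangulated
   with a tetrahedral marching-cubes variant (each voxel cell is split
   into six tetrahedra sharing a body diagonal, consistently across
   cells). This decomposition has no ambiguous configurations, so the
   surface is watertight by construction — every edge is shared by exactly
   two faces, which `mesh_volume()` verifies before applying the
   divergence theorem. The mask is zero-padded first so surfaces close at
   the array boundary, and vertices live in physical millimetres, so
   anisotropic voxels (e.g. 5 mm slices) need no resampling.
4. **Metrics.** $S$ is the summed triangle area, $V$ the signed-tetrahedron
   sum over the same closed mesh. Using one mesh for both matters: mixing
   a mesh area with a voxel-count volume would bias $R_1/R_2$. The
   voxel-count volume is reported alongside as a cross-check; the two
   agree within 2% on phantoms at 0.5 mm isotropic sampling.

### Why the binary field is anti-aliased before isosurfacing

On a raw {0,1} field every isosurface vertex sits at an edge midpoint, and
the resulting faceting *overestimates surface area by roughly 8–9%
regardless of grid resolution* — the error does not converge, in the same
way the staircase length of a diagonal never approaches the diagonal. A
digitized ball would score HII $\approx 104$ forever. `compute_hii_for_mask()`
therefore blurs the binary field with a Gaussian of $\sigma = 1.5$ voxels
(per axis) before taking the 0.5 level set. This is the mesh-generation
analogue of the smoothing every practical model-maker applies, and it
restores convergence: on a 20 mm ball at 0.5 mm spacing the area error is
$-0.20\%$, the volume error $-0.45\%$, and HII $= 100.05$, with the
deviation from 100 shrinking monotonically as the grid is refined (2 → 1 →
0.5 mm). The width was fixed by a grid search over $\sigma \in \{0.8, 1,
1.5, 2\}$ before the test suite was written: 1.5 is the smallest value
with comfortably monotone convergence; smaller widths leave residual
faceting, larger ones erode thin structures. `extract_surface()` itself
defaults to the raw field ($\sigma = 0$) so the literal voxel model
remains available, and the sigma in force is embedded in every report.

Taubin $\lambda|\mu$ mesh smoothing (`smooth_mesh()`, default **off**) is a
separate, explicit knob. The original desktop workflow smooths its models
by default but does not report its settings; since smoothing lowers $S$
and hence the index, the honest default here is the unsmoothed
measurement plus a documented option whose setting is echoed into the
report. On a sphere mesh 20 Taubin iterations change the area by well
under 2% (shrinkage-compensated); on a cube they strictly shrink it
(corners round off).

## Parameters that matter

| parameter | where | default | units | why |
|---|---|---|---|---|
| `hu_low`, `hu_high` | `segmentation_config()` | 40, 100 | HU | acute-clot window; inclusive ends |
| `component_rule` | `segmentation_config()` | largest | — | stand-in for manual component choice |
| `antialias_sigma` | `compute_hii_for_mask()` | 1.5 | voxels | area/volume convergence (above) |
| `smoothing` | `compute_hii_for_mask()` | off | — | unreported upstream; explicit knob |
| `relative_threshold` | `expansion_rule()` | 0.33 | fraction | expansion definition |
| `absolute_threshold_mL` | `expansion_rule()` | 12.5 | mL | expansion definition |
| isosurface level | fixed | 0.5 | — | unbiased midpoint of {0,1} |

## Phantoms and what they do (and do not) show

Every measurement operation is validated against synthetic CT phantoms
with known truth, generated in code (`make_sphere_phantom()`,
`make_ellipsoid_phantom()`, `make_lobulated_phantom()`,
`resample_to_slices()`). Foreground is 70 HU and background 30 HU —
either side of the 40 HU threshold, mimicking clot against parenchyma —
with optional seeded Gaussian noise. Rasterization is voxel-center-inside,
chosen because it is unbiased at fine spacing and trivial to re-implement
as an oracle. Truth comes from closed forms (sphere, spheroids), numerical
integration (triaxial ellipsoids; Simpson grid, relative error below
$10^{-6}$), or a brute-force oracle (lobulated shapes re-rasterized at 4×
finer spacing; the oracle grid is measured with $\sigma = 0.75$ voxels,
which keeps 4× and 8× refinements within 1% of each other). The
thick-slice resampler slab-averages a fine phantom down to clinical 5 mm
slices to probe anisotropy: a ball then reads HII $\approx 100.8$ instead
of 100.05, a fair picture of thick-slice degradation.

What passing phantom tests do **not** show: phantoms have no skull,
ventricles, partial-volume edema, beam hardening, or rater variability, so
they validate the *geometry and statistics machinery*, not clinical
segmentation difficulty. In the original study inter-rater agreement (ICC
0.936) absorbs boundary ambiguity that these phantoms cannot exhibit.

## The cohort simulator and the statistical chain

`simulate_cohort()` is a first-class, seeded generator standing in for the
93-patient study cohort, which is not public. Marginals are calibrated to
the published baseline table: age $\mathcal N(64.2, 14.0^2)$; binary
history flags Bernoulli with the reported prevalences; onset-to-CT and
baseline volume log-normal matched to the reported medians and IQRs
(volume: median 10.8 mL, IQR 4.1–20.6); GCS a rounded, clamped normal on
3–15; and HII $= 100 + \mathrm{lognormal}$ matched to the overall median
121.4 (IQR 116.7–130.1) — the shift enforces the theoretical floor of
100. Expansion is drawn from a logistic model whose default coefficients
give HII $\beta = 0.18$ (an adjusted odds ratio of $e^{0.18} \approx 1.20$
per index point, the magnitude reported in the study), volume and GCS
small effects in the reported directions, and an intercept fixed by a
one-off numerical solve so the expansion prevalence is near 36/93. No
claim is made of matching the unpublished per-patient data; the simulator
exists so the full chain — baseline table with its Shapiro–Wilk gate
(α = 0.05, applied per group), univariate logistic screen, $p < 0.1$
selection, adjusted model, Hosmer–Lemeshow, ROC with the Youden cutoff —
runs end to end and recovers its own generating parameters.

Statistical design choices, each made where the upstream description was
silent or ambiguous:

* **ICC form**: "one-way ANOVA" determines ICC(1,1) — the one-way
  random-effects, single-rater, absolute-agreement form — uniquely; that
  is what `icc_oneway()` computes, with the F test of between-subject
  variance for its p-value.
* **AUC interval**: DeLong's placement-variance method — deterministic, no
  resampling seed; cross-checked in the tests against pROC.
* **Youden ties**: the lowest qualifying cutoff wins, which is
  deterministic and conservative toward sensitivity.
* **Logistic CIs**: Wald on the coefficient scale, exponentiated (the
  convention of the SPSS workflow being mirrored). Separation is detected
  by coefficient/standard-error blow-up and raised as an error rather
  than reported as an inflated odds ratio.
* **Rater comparison**: the upstream reliability table's "Wilcoxon
  Rank-Sum" is ambiguous between paired and unpaired; `summarize_baseline()`
  implements the unpaired comparison.

## Numerical and degenerate-input conventions

* Isosurface level 0.5 with zero padding of $\max(1, \lceil 3\sigma\rceil + 1)$
  voxels; interpolation parameters are clamped to $[0,1]$.
* Empty segmentations raise a structured error carrying the HU quantiles
  of the volume (so a mis-windowed scan is diagnosable from the message);
  the CLI maps this to exit code 3.
* Constant rating grids make ICC undefined → error, as does a
  single-class outcome for ROC or logistic fits (exit code 4 via the CLI).
* Hosmer–Lemeshow groups with zero expected counts are merged into a
  neighbour and flagged; degrees of freedom follow the merged count.
* Groups too small for Shapiro–Wilk (n < 3) or with zero variance are
  treated as non-normal; zero-variance comparisons are flagged with an NA
  p-value instead of a fabricated one.

## Problem sizes used by the test and acceptance runs

The default validation runs measure a 20 mm ball at 2, 1 and 0.5 mm
isotropic spacing (about 270k foreground voxels at the finest grid),
prolate spheroids with 10 mm minor axes at 0.5 mm, a five-lobe phantom at
1 mm, and simulated cohorts of 93 (study-sized descriptive statistics),
500–2000 (parameter recovery; 100 seeds) and 2000 (calibration; 200
seeds). These sizes were chosen so each property is measured well inside
its tolerance while the whole suite stays quick to run.

## Known limitations

* Gantry tilt and oblique acquisitions are not corrected; only axis-aligned
  spacing is honoured.
* The anti-aliased reconstruction is a documented analogue, not a
  bit-for-bit reproduction, of the desktop model-maker the clinical study
  used; absolute index values depend on reconstruction settings, which is
  precisely why every report embeds them.
* Automatic ventricle detection is out of scope; intraventricular blood is
  excluded only via a user-supplied mask.
* The simulator draws covariates independently (no age–GCS–volume
  correlation structure), which is adequate for parameter-recovery and
  calibration checks but not for studying confounding patterns.
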