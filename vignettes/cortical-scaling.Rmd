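---
title: "Within-cortex scaling of cortical folding: model, correction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-cortex scaling of cortical folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscale)
```

## The model

Cortical folding follows an allometric law linking the total (pial) area
$A_t$, the exposed (envelope) area $A_e$ and the average cortical
thickness $T$ of a hemisphere:

$$A_t \sqrt{T} = k\,A_e^{\alpha}, \qquad \alpha = 5/4 \text{ predicted},$$

which in the coordinates $x = \log_{10} A_e$, $y = \log_{10}(A_t\sqrt T)$
is a straight line with slope $\alpha$ and offset $K = \log_{10} k$. The
prediction $\alpha = 5/4$ comes from treating the cortex as a
self-avoiding surface folded by a pressure-like term; the offset absorbs
the balance of tension and pressure and is the quantity that moves with
age and disease. **All logarithms in this package are base 10** (offsets
are in dex); slope estimates are invariant to that choice, offsets are
not.

### Why partitions need a correction

For a partition $P$ of one cortex (a lobe, a parcel), the raw pair
$(x, y)$ is displaced from the whole-hemisphere point roughly along a line
of slope 1 — the contour of constant gyrification index
$g = A_t/A_e$ — by an amount set by the partition's size. Raw partitions
therefore line up with slope 1 regardless of the folding law; no scaling
exponent can be read off them directly.

The correction uses the Gauss–Bonnet theorem: the integrated Gaussian
curvature of any closed surface is $\oint G\,dA = 4\pi$, independent of
shape, size or discretisation. On a triangulated surface the curvature
concentrates at vertices as angle deficits ($2\pi$ minus the incident
corner angles), and the deficit carried by a partition of the smooth
exposed envelope, $I_G^P$, is a topological measure of the partition's
relative size. Requiring that a reconstructed full cortex preserve the
partition's thickness, gyrification index and mean curvatures
$I_G^P/A_e^P$, $I_G^P/A_t^P$ forces

$$A_e'^P = \frac{4\pi}{I_G^P} A_e^P, \qquad
  A_t'^P = \frac{4\pi}{I_G^P} A_t^P .$$

Two exact invariants follow, and are asserted in the test suite:
$g'^P = g^P$, and $(x' - x, y' - y) = (\log_{10} c, \log_{10} c)$ with
$c = 4\pi/I_G^P$ — the correction moves points along the slope-1 contour,
nothing else.

### Estimators

* `fit_hemisphere(..., method = "ols")` regresses $y'$ on $x'$ across the
  (typically four) corrected lobes of one hemisphere, giving a lobe-based
  exponent for that single cortex.
* `fit_hemisphere(..., method = "corrected")` applies the
  errors-in-variables form
  $\alpha = 1/(\gamma + \sqrt{1+\gamma^2})$,
  $\gamma = (\sigma_{11}^2 - \sigma_{22}^2) /
  (2\sigma_{12}^2 - \sigma^2_{\log I_G})$,
  which removes the systematic dispersion that the shared correction term
  $\log I_G^P$ injects into both coordinates. With
  $\sigma^2_{\log I_G} = 0$ this is a standardised-major-axis-style
  estimator and is exact on collinear data (verified in closed form for
  slopes 0.5, 1, 1.25, 2). Whether published lobe-based slopes used OLS or
  this correction is not documented for the per-hemisphere fits, so both
  are provided; OLS is the default because it is what the per-hemisphere
  regression figure describes. The estimator's behaviour for
  anti-correlated lobes ($\sigma_{12}^2 < 0$) is not covered by its
  derivation; the formula is applied as printed and a sign change of the
  $\gamma$ denominator is flagged in the fit diagnostics.
* `fit_group` regresses raw whole-hemisphere $(x, y)$ across subjects —
  the group-based exponent, for comparison.
* `offset_k` always uses the fixed slope $5/4$, never a fitted exponent,
  so that offsets are comparable across subjects and studies.
* `implied_fractal_dimension` returns $2\alpha$: at fixed $T$ the law
  gives $A_t \propto A_e^{\alpha} \propto L^{2\alpha}$ for linear scale
  $L$ (since $A_e \propto L^2$), i.e. a self-similar surface of dimension
  $2\alpha$ — 2.5 at the predicted exponent.

## Parameters that matter

| parameter | where | default | rationale |
|---|---|---|---|
| `epsilon` | `validity_filter` | $0.01 \cdot 4\pi$ sr | partitions whose exposed-surface curvature is below 1% of the closed-surface total (medial-wall remnants, tiny parcels) get unstable corrections $4\pi/I_G$; 1% removes those degenerate cases while keeping all four lobes in practice. Retention is strict: $I_G > \epsilon$. |
| `sigma2_logIG` | corrected estimator | 0 | the variance of the log correction term is unknown without replicate measurements; `estimate_sigma2_logIG` computes it from replicates when available. |
| `weighted_thickness` | `aggregate_partitions` | TRUE | per-partition thickness is the barycentric-vertex-area-weighted mean on the pial surface; the unweighted mean is available for sensitivity checks. |
| `renormalize_curvature` | `aggregate_partitions` | FALSE | for almost-closed hemispheres (cut by the corpus callosum) boundary-vertex deficits are zeroed, so $\sum_P I_G^P < 4\pi$; the flag rescales partition curvatures to sum exactly to $4\pi$. Default keeps the literal correction; the deviation is always reported. |
| bin width | `age_bin` | 10 years | wide-age-range cohorts; densely sampled young cohorts support 4-year bins. Bins are half-open, left-closed, anchored at the cohort minimum unless overridden. |
| `n_boot` | `bootstrap_mean_ci` | 1000 | percentile method; the seed is a required argument — no silent default entropy. |

## Numerical choices

* Corner angles use `atan2(|u×v|, u·v)`, stable near degenerate corners;
  triangles with area below $10^{-12}$ mm$^2$ are rejected at
  construction, never silently skipped.
* Boundary vertices (meshes with open edges) get deficit 0 and are
  reported via attributes; non-manifold edges (more than two incident
  triangles) are an error naming the edge.
* Vertices exactly on a partition boundary (a zero coordinate for octant
  labels, equidistant nearest neighbours in label transfer, three-way
  face-label ties) always resolve to the lowest label id — a deterministic
  tie-break, chosen because no convention is documented for how faces
  straddling parcel boundaries were assigned in published analyses.
* Conservation identities (areas, curvature additivity, barycentric
  vertex areas) hold to within accumulated rounding ($10^{-12}$ relative
  in the tests); the Gauss–Bonnet identity is asserted at $10^{-9}$
  relative.
* The convex hull (fallback exposed surface) is an incremental
  construction with a visibility tolerance of $10^{-10}$ times the
  bounding-box scale; coplanar inputs are an error rather than a guess.
* The Desikan–Killiany-to-lobe table ships as an editable CSV because the
  upstream lobe assignment is referenced, not printed, in the literature;
  the packaged copy follows FreeSurfer's `--lobesStrict` division with the
  anterior cingulate assigned frontally, posterior/isthmus cingulate
  parietally, and the insula excluded.

## What the synthetic generators emulate — and what they do not

`make_gyrified_sphere` produces closed genus-0 surfaces with sinusoidal
radial folding: enough to exercise every geometric primitive (curvature
concentration, partition aggregation, hull computation) with analytic
ground truth, but its folds are regular and shallow compared with real
gyri, and it has no medial wall, so the validity filter's target case is
only reachable through constructed tables.

`simulate_lobe_table` generates per-lobe tables by *inverting* the
correction: corrected areas are drawn first (subject size jitter of 0.04
dex around a 40 000 mm$^2$ mean exposed area, per-lobe multipliers 1.25 /
1.0 / 0.95 / 0.70 spreading lobe sizes and hence gyrification indices),
$A_t'$ is set from the law at the generating exponent, and raw rows are
emitted as fractions $f_P$ of each quantity with $I_G^P = f_P \cdot 4\pi$
(curvature fractions 0.35/0.25/0.25/0.15 for frontal/parietal/temporal/
occipital — size-ordered like real lobes, otherwise arbitrary). The
pipeline's correction therefore restores the generating values exactly at
zero noise, which is what makes machine-precision recovery tests possible.
Noise is applied in $y$ only (default 0.01 dex), matching the regression's
error model; `noise_sd_logIG` optionally perturbs the curvature split to
exercise the corrected estimator. Offsets follow
$K = K_0 + s_{\mathrm{age}}\,\mathrm{age}$ with $K_0 = -0.56$ dex and
$s_{\mathrm{age}} = -0.001$ dex/year — the level consistent with human
hemispheres ($A_t \approx 9\times10^4$ mm$^2$, $A_e \approx 4\times10^4$
mm$^2$, $T \approx 2.5$ mm) and a slow lifetime drift of a few hundredths
of a dex.

`simulate_ad_cohort` (ages 60–90, K noise 0.02 dex) gives controls the
ageing drift and gives the AD group a constant level of $-0.655$ dex plus
per-lobe shifts $(-0.018, -0.016, -0.030, -0.004)$ dex for
frontal/parietal/temporal/occipital — encoding "premature ageing" with the
temporal lobe most affected and the occipital least. Cohort records are
produced by running the generated raw tables through the package's own
correction and fitting code, not by shortcutting to the truth values.

Because the generators satisfy the law by construction, passing tests
demonstrate that the estimators are *consistent and correctly
implemented* — exact inversion, unbiased recovery under the stated noise
model, the constructed clinical orderings — not that real cortices obey
the law; that evidence must come from real surface data, for which the
mesh pipeline (`read_surface` → `transfer_labels` →
`aggregate_partitions` → `group_to_lobes` → `correct_areas` →
`fit_hemisphere`) or precomputed partition CSVs are the entry points. One
property of the AD generator worth knowing: because its per-lobe shifts
correlate with lobe size, AD hemispheres fit systematically slightly
shallower slopes (about 1.19 at the defaults) — a deliberate echo of the
subtle slope flattening reported in patients.

## Problem sizes used in validation

Test meshes run up to icosphere subdivision 5 (10 242 vertices) and
gyrified spheres at subdivision 4 (2 562 vertices); synthetic cohorts use
50–100 subjects, with 200 independent seeds for the noise-recovery check
and 40 seeded runs for the trend-coverage property. These sizes give
stable statistics (standard error of the mean slope well below the 0.01
acceptance band) while keeping the full suite under a minute of compute.

## Known limitations

* The exposed-surface fallback is the convex hull; real morphometric
  pipelines use a tighter smooth envelope, and hull-based exposed areas
  are slight underestimates of a shrink-wrapped envelope's.
* FreeSurfer `annot` parcellation files are not parsed; labels enter as
  the documented CSV schema (or any per-vertex integer field).
* The linear mixed-effects joint-slope formulation across subjects and
  slope–offset correlation analyses are out of scope; `fit_group` provides
  the plain pooled regression only.
* Curvature is the angle-deficit (intrinsic, discrete) definition
  throughout; no smooth-surface curvature estimation by local fitting is
  attempted, so results on very coarse meshes inherit the triangulation.
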