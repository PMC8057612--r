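---
title: "A multi-physical model of plaque progression: methods and numerical choices"
author: "plaquesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-physical model of plaque progression: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquesim)
```

## The model

`plaquesim` simulates the microenvironment of an atherosclerotic plaque on a
labeled 2D cross-section of a coronary artery, the kind of tissue map a
segmented VH-IVUS frame provides: a lumen, a thickening intima, a media ring
bounded by the external elastic membrane (EEM), and exterior background.
Twelve coupled fields live on the wall (intima + media):

* **Lipid axis** — plasma LDL enters through the endothelium at a rate damped
  by wall shear stress (WSS), is cleared from the wall, and is partly
  oxidized; ox-LDL is phagocytosed by macrophages and triggers SMC
  apoptosis.
* **Inflammation axis** — plasma monocytes extravasate under the same
  WSS-damped influx, chemotax toward ox-LDL, differentiate into macrophages,
  which chemotax toward MCP-1; MCP-1 is produced by endothelial cells
  (saturating in ox-LDL) and SMCs. Foam cells form where macrophages meet
  ox-LDL.
* **SMC/matrix axis** — SMCs migrate up MCP-1 and macrophage-derived PDGF
  gradients and along the ECM (haptotaxis); ECM is produced by SMCs and
  degraded by MMPs, which ECs and SMCs secrete.
* **Angiogenesis axis** — microvascular endothelial cells seeded at the EEM
  rim (vasa vasorum) chemotax up a VEGF gradient that rises toward the
  hypoxic intima; extravascular plasma (the intraplaque-haemorrhage proxy)
  accumulates in proportion to local EC density and leaks LDL and monocytes
  into the deep wall.

Each field obeys a reaction–diffusion–taxis balance

$$\partial_t C_i \;=\; D_i \nabla^2 C_i \;-\; \nabla\!\cdot\!\big(\lambda\, C_i \nabla C_j\big) \;+\; R_i(C),$$

with zero normal flux at every tissue interface (lumen border for the
excluded species, EEM on the outside). Endothelial exchange enters only as
the flux sources
$J_\mathrm{LDL} = L_{cr} C_\mathrm{LDL} / (1 + \mathrm{WSS}/\mathrm{WSS}_0)$ and
$J_\mathrm{Mo} = Mo_{cr} C_\mathrm{Mo} / (1 + \mathrm{WSS}/\mathrm{WSS}_0)$
($\mathrm{WSS}_0 = 100$ dyn/cm², $L_{cr} = 2\times10^{-5}$ m/s,
$Mo_{cr} = 4\times10^{-5}$ m/s) applied at the intima cells adjacent to the
lumen. A claim of a fixed-value outer boundary can also be found in this
model family; we read the governing statement — no mass transport at the
outer boundary — as zero flux, and provide `dirichlet_outer = TRUE` in
`solver_config()` for the literal clamped alternative.

The three-grade plasma monocyte level (mild/moderate/severe = 4, 8, 16
×10⁵ cells/cm³) and the three-grade microvessel density (low/mid/high
scaling of the initial EEM-rim EC density) are the two initial conditions
imaging cannot measure; the calibration workflow selects them.

## Nondimensionalization

Fields are evolved dimensionless: each species is divided by a reference
concentration (`reference_scales()`), one time unit is one month, one length
unit is one grid cell. Species that start at a working level (LDL, SMC,
ECM, MMP) use their initial magnitude as reference, so they start at 1;
trace species (ox-LDL, MCP-1, VEGF) use a plausible maximum so they remain
order one as they grow. `nondimensionalize()`/`redimensionalize()` are exact
inverses. Rate constants are therefore specified directly in nondimensional
units (per month, cell² per month); the few published physical constants
(the influx block) keep their units and are scaled inside the influx-source
conversion.

## Parameters and provenance

Every constant in `default_parameters()` carries a provenance tag:

* `paper` — printed in the source study (influx constants, monocyte levels,
  grid geometry, initial concentrations);
* `prior-model-literature` — the kind of diffusivity/rate used in earlier
  continuum plaque and angiogenesis models;
* `gap-filled` — needed by the model but printed nowhere (foam-cell rates,
  plasma extravasation gain, influx-to-source gains, taxis capacity).

The full coupled system's published description does not include numeric
values for most rates, so the defaults here were calibrated **once** against
the magnitudes the study reports — necrotic-core growth of order 1.3–2 at a
5–13-month follow-up, order 4–9 at three years, stable plaques below
unstable ones — and against the qualitative biology (low WSS promotes lipid
influx; inflammation promotes NC expansion). Two defaults deserve comment:

* LDL wall clearance is fast (`lambda_L = 3`/month) relative to oxidation
  (`lambda_LoxL = 0.05`/month). If most of the uniform initial LDL load were
  oxidized in place, ox-LDL would accumulate uniformly and the 50% SMC
  threshold would tip the whole intima into necrosis almost simultaneously —
  a knife edge, not a progression. Fast clearance plus a sustained
  endothelial influx keeps ox-LDL a decelerating front that starts at the
  lumen, which is also where imaging sees early lipid.
* The volume-filling capacity `taxis_cmax = 6` bounds every taxis flux by a
  factor $(1 - C/C_\mathrm{max})_+$. Without it the SMC → MCP-1 → SMC
  attraction loop is a Keller–Segel system that can aggregate into
  finite-time collapse; with a generous capacity the linear flux law is
  unchanged in the physiological range but collapse is impossible.

All constants are overridable via `default_parameters(...)` or a YAML file
(`write_parameters()`/`read_parameters()`), and each Table-row constant can
be zeroed to switch off exactly its pathway (this is tested).

## Discretization

The grid is the published 200 × 200 discretization of a 4 mm × 4 mm frame
(`h = 20` µm); coarser grids keep the physical domain by setting
`h = 4000/n`. Diffusion uses the 5-point stencil with mirror closure at
inactive neighbours. Taxis terms use a conservative face-flux form: the face
velocity is `coeff × (Δattractant)/h`, and the transported density is taken
from the **donor (upwind) cell**. We chose upwinding over the
arithmetic-mean face density deliberately: the averaged form moves mass out
of empty cells, so it violates positivity at any time step wherever a sharp
front exists (the seeded EC rim is one from step one), and it allows
chemotactic collapse. Donor-cell fluxes are positivity-preserving under the
advective CFL bound and identically conservative (face fluxes cancel in the
interior sum; this is tested to machine precision).

Time stepping is explicit Euler — the scheme stated for this model family —
with the bound
`dt = safety × h²/(4 D_max)` further limited by `safety × h/(4 v_max)`,
where `v_max` is the largest face taxis speed (factor 4 because a cell can
drain through four faces at once). Because taxis gradients steepen as the
simulation develops, `run_simulation()` re-evaluates the bound every ten
steps and only ever decreases `dt`; an explicitly configured `dt` is used as
given. Negative values produced by the update are clipped to zero with a
logged count and per-species pre-clip minima. Clipping is a health metric,
not a crutch: for every species whose sinks are proportional to its own
density it stays at zero under the stability bound (tested). The one
exception is VEGF, whose published uptake term (−λ·E) is a zeroth-order
drain; we keep the published form and let the clip log absorb it.

With the default diffusivities (`D_max = 6` cell²/month) the bound gives
`dt ≈ 0.033` months, so the three-year horizon takes roughly 1100 steps —
about a minute at 200 × 200 on one core, a few seconds at 60 × 60.

## The calibrate-then-predict workflow

Baseline (T1) imaging fixes the geometry; the patient record fixes plasma
LDL/HDL and WSS (held at its baseline value, since reported follow-up WSS
changes in this setting are small). The necrotic core (NC) is the intima
area where SMC density fell **more than 50% below** its initial value
(strictly; exact halving does not count), and the trajectory's NC series is
the baseline core area `N0` — an image-derived input — plus the newly
apoptotic area, so the growth ratio `N(t)/N0` starts at 1.

`calibrate_t2()` simulates all nine (inflammation × microvessel) candidate
pairs to the follow-up time T2 and selects the pair whose NC growth is
closest to the observed growth; exact residual ties go to the milder pair
(smaller combined level, then lower inflammation). `predict_t3()` re-runs
the chosen pair to 36 months. With the default parameters the nine candidate
growths at a 12-month interval are strictly monotone in both levels and all
distinct, which is what makes noise-free recovery exact; this is the
package's analogue of selecting initial inflammation/neovascularization
levels by comparison with follow-up images.

## Scoring and cohort statistics

The severity scale grades eight factors 1–3: plaque burden
(`plaque area/(plaque area + lumen area)`; plaque area includes the media by
default, with an intima-only flag), eccentricity index
(`1 − WT_min/WT_max`, wall thickness by 360 equiangular rays from the lumen
centroid — the measurement protocol is our choice, since none is published),
LDL, HDL and WSS from the record, and the simulated macrophage, SMC and
ox-LDL levels at T3. Grading is comparative: the cohort min–max range is
split into equal thirds, the worst third scores 3 (direction per factor:
higher LDL worse, lower HDL/WSS worse, lower SMC worse), boundary values go
to the milder grade, and an all-equal cohort grades 2 everywhere. This rule
reproduces the published LDL and WSS grade columns exactly for the published
four-patient values; like the original scale it is only meaningful within
the cohort that defines the range. One published grade (an HDL column entry)
is not consistent with any single threshold rule that fits the other
columns; we do not special-case it. Totals of 18 or more are labelled
vulnerable — the published totals are 15 and 20 with only the 20s called
vulnerable, so we cut at the midpoint.

`group_ttest()` compares stable-like and unstable-like groups per factor by
Welch's t-test on monthly spatial means pooled within group (the original
sampling is unstated; monthly means are our choice), significance at 0.01.
`spearman_nc_correlation()` rank-correlates factor trajectories with the NC
series using average ranks for ties.

## The synthetic cohort

No imaging data accompany the model, so `generate_cohort()` manufactures a
four-patient cohort: eccentric annular geometries (lumen radius 800–1000 µm,
intima 300–400 µm with a 40–150 µm cosine eccentricity, media 250 µm — a
worst case of 1800 µm outer radius that always fits the 4 mm frame) and
records drawn from brackets spanning the published demographics (LDL 70–160,
HDL 19–38 mg/dL, WSS 77–141 dyn/cm², intervals 5–13 months). Two patients
are truly mild-inflammation ("stable-like"), two severe ("unstable-like"),
mirroring the 2/2 grouping of the original study.
`generate_observed_followup()` plays the role of the T2 image measurement by
simulating the truth and optionally adding multiplicative noise; the
baseline core `N0` is set to 12% of the intima area, standing in for the
image-derived baseline core.

What the generator deliberately does **not** emulate: VH-IVUS pixel
statistics, calcification, M1/M2 macrophage phenotypes, discrete microvessel
networks, 3D anatomy, or co-registration error between time points. Passing
tests on this cohort therefore demonstrate internal consistency of the
method — recovery of known truths, orderings, conservation — not clinical
accuracy on real patients.

## Problem sizes used by tests and the acceptance script

Unit tests run on 32–48-cell grids. Calibration recovery runs at the
published 200 × 200 resolution with a 12-month follow-up: the NC area is
quantized at one cell (`h²`), and at the published 20 µm cell the nine
candidate growths are all distinct, whereas coarser grids can merge the
weaker microvessel-level differences into ties. The cohort workflow runs at
100 × 100 with the 36-month horizon, grid-refinement checks compare
100 × 100 against 200 × 200, and the shipped demo runs the whole workflow at
60 × 60. These sizes exercise every stage, including the published
resolution, in a few minutes on one core.

## Known limitations

* Explicit Euler is first-order; the time-step refinement check bounds the
  discretization error on summaries at about the percent level, not below.
* The NC area is a thresholded cell count, so it is quantized at `h²`;
  coarse grids make small growth differences indistinguishable (ties resolve
  to the milder calibration pair).
* Extravascular plasma has no published sink and accumulates monotonically;
  over horizons much longer than three years the leaky-microvessel source
  would eventually dominate.
* The severity scale is comparative and cohort-relative by construction; its
  grades are not transferable between cohorts.
* Published per-patient correlation tables and significance patterns depend
  on the original patients' imaging and the unpublished parameter values,
  and are out of reach by design; the package reproduces the scale
  arithmetic, the grading rule and the method's internal properties instead.
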