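---
title: "Wall-shear metrics, reduced pulsatile flow models and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wall-shear metrics, reduced pulsatile flow models and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wssmetrics)
```

## The metrics and how they are integrated

Disturbed near-wall flow is summarized per surface node from the wall shear
stress (WSS) vector history $\tau_\omega(t)$ over one cardiac cycle $T$:

$$\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\tau_\omega|\,dt, \qquad
\mathrm{OSI} = \frac{1}{2}\left(1 -
  \frac{\left|\int_0^T \tau_\omega\,dt\right|}{\int_0^T |\tau_\omega|\,dt}\right), \qquad
\mathrm{RRT} = \frac{1}{(1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}}.$$

Numerical conventions, chosen once and applied everywhere:

- **Vector numerator.** The OSI numerator integrates the *vector*
  componentwise and then takes the magnitude — not a componentwise or
  magnitude-of-parts variant. Printed forms of the formula are often
  ambiguous about this; the vector form is the standard definition and the
  one implemented.
- **Periodic trapezoid.** All cycle integrals use the trapezoidal rule with
  periodic closure: if the sampled series stops short of $t = T$, a closing
  sample equal to the $t = 0$ value is synthesized first. For smooth
  periodic integrands this rule is spectrally accurate; where $|\tau|$ has
  kinks (sign reversals) it is second order, which the refinement tests
  confirm (error ratios ≈ 4 per halving of the step).
- **Clamping and degeneracy.** OSI is clamped to $[0, 0.5]$ against
  floating-point drift. A node whose cycle-integrated magnitude falls below
  $10^{-12}$ Pa·s (zero WSS all cycle) gets OSI 0 plus a degenerate flag
  rather than NaN, so area statistics stay defined; flagged counts are
  reported in pipeline logs. Where $(1-2\,\mathrm{OSI})\,\mathrm{TAWSS} <
  10^{-12}$, RRT receives a $+\infty$ sentinel and a flag; sentinels count
  as "above" any finite threshold in area fractions and are excluded (with
  a warning) from regional means.
- **Strict thresholds.** Area-ratio predicates are strict inequalities —
  TAWSS $< 20$ Pa, OSI $> 0.2$, RRT $> 0.5$ Pa⁻¹ — and ties fall on the
  non-qualifying side. The TAWSS histogram uses fixed 20 Pa bins,
  $[0,20), [20,40), \dots, [120,\infty)$, seven in all.

### Areas: node lumping

Area weighting uses barycentric lumping: each triangle assigns one third of
its area to each of its vertices. Compared with Voronoi-type lumping this
is simpler, always positive, and makes area ratios reproducible
bit-for-bit; node areas are invariant to triangle re-ordering and vertex
relabelling, and disjoint region masks partition the total wall area
exactly. Whether published area ratios were face- or node-based is usually
unstated in the literature; node-lumped areas are this package's documented
choice. Geometry is stored in millimetres (areas in mm²); the flow models
work in SI internally; metric maps are in Pa and Pa⁻¹. Plain STL and
legacy-VTK files carry no cap labels, so meshes loaded from disk treat
every node as wall; a `wall_mask` can be supplied in code to exclude
inlet/outlet cap nodes. Node indices are 1-based throughout the R API;
VTK connectivity is translated to the format's 0-based convention on I/O.

### A unit note on RRT

RRT is reported in Pa⁻¹ with no rescaling. At rodent-scale WSS (tens of
Pa), $(1-2\,\mathrm{OSI})\,\mathrm{TAWSS}$ is tens of Pa wherever the
steady component survives, so RRT sits near $0.05$ Pa⁻¹ and the area with
RRT $> 0.5$ Pa⁻¹ is essentially zero unless the steady shear locally
collapses. Published rodent studies that report RRT values of order 1
are implicitly using a different normalization; keeping honest Pa⁻¹ units
means the default synthetic study yields a zero RRT-threshold area for
every animal, and the pipeline therefore skips (and logs) group tests on
variables that come out constant.

## Reduced-order pulsatile flow models

The package deliberately contains no 3-D Navier–Stokes solver (and no
fluid–structure interaction; walls are rigid, blood is Newtonian with
density 1060 kg/m³ and dynamic viscosity 3.5 mPa·s by default). Transient
laminar pipe flow stands in for the full CFD stage in two forms:

1. **Analytic Womersley solution** (`womersley_wss`): a flow-rate waveform
   is decomposed into $H$ complex harmonics by least squares
   (`fourier_decompose`; the fit reproduces DFT coefficients on uniform
   grids, and $c_0$ is the cycle mean). The steady part contributes
   Poiseuille wall shear $4\mu Q/(\pi R^3)$; each harmonic $n$ uses the
   classical Bessel-function solution at Womersley number
   $\alpha_n = R\sqrt{n\omega\rho/\mu}$. $J_0$ and $J_1$ of the complex
   argument are evaluated by their power series, which is accurate to
   machine precision for $|z| \lesssim 25$ — comfortably covering rat- and
   human-scale $\alpha$ with the default $H = 8$ harmonics ($H = 8$
   captures waveforms sampled at ≥ 20 points/cycle without ringing).
2. **Crank–Nicolson finite-difference solver** (`fd_pipe_solver`): the
   axisymmetric axial momentum equation on $[0, R]$ with no-slip at the
   wall, symmetry at the axis (the $1/r$ term regularized by L'Hôpital's
   rule at $r = 0$), 100 time steps per cycle by default, an exact number
   of cycles (default 3) with the final cycle returned. Wall shear uses a
   one-sided second-order difference. Crank–Nicolson is second order and
   unconditionally stable, so 100 steps/cycle is safe at rat heart rates.
   The returned `cycle_delta` (relative change of the wall-shear series
   between the last two cycles) is the periodicity diagnostic: at rat
   scale the start-up transient decays by roughly $e^{-4}$ per cycle, so
   3 cycles leaves a ~1% residual (ample for 1–2% accuracy against the
   analytic solution) and 8 cycles drives it below $10^{-6}$.

Branch flow splitting is time-invariant: cycle-volume ratios (e.g.
innominate : left carotid : left subclavian of 10:7:8 or 9:6:10) are
applied instant by instant, a documented simplification of outlet boundary
conditions that conserves volume exactly; an optional residual branch
models a descending aorta taking the remainder. `reynolds_number` reports
$\rho v d / \mu$ and warns past 2000, the edge of the laminar assumption
all these models rest on.

## What the synthetic generator emulates — and what it does not

The generator provides every input the pipeline needs, with one explicit
seed per call and no global RNG state.

- **Geometry** (`make_arch_mesh`): a torus-segment tube — default
  centerline radius 3 mm, lumen radius 1 mm, half-torus sweep — standing
  in for an aortic arch. The tube-circumference angle $\phi$ is $\pi$ on
  the inner (lesser) curvature; `inner_arch` is the $60°$ window around
  that line, `outer_arch` its mirror. The mesh area converges to the
  analytic $\theta_{\mathrm{arch}} \cdot 2\pi r R_c$ under refinement.
  Dimensions are rat-scale literature values and fully config-overridable.
- **Waveforms** (`make_waveform`): only the heart rate (period $60/HR$ s)
  and the systolic peak are treated as known; the shape is a raised-cosine
  systolic pulse over ~35% of the cycle on a small (3% of peak) diastolic
  baseline, with seeded jitter of the systolic fraction for
  animal-to-animal variety. Real rat waveforms have dicrotic features this
  shape does not attempt.
- **WSS fields** (`make_wss_field`): per node
  $\tau(t) = (a + b\sin(2\pi t/T))\,\hat d$ along the local axial tangent,
  steady magnitude $a$ near `baseline_wss` (default 20 Pa, the scale at
  which a 20 Pa low-TAWSS threshold is meaningful) with 5% multiplicative
  noise, and oscillatory amplitude ratio $\gamma = b/a_{\mathrm{ref}}$
  maximal on the inner-arch line (default 8, driving inner OSI toward
  ~0.4) decaying as $e^{-\Delta\phi/0.2}$ away from it. Because the
  oscillation has a fixed axis, the ground-truth OSI has the closed form
  implemented in `osi_offset_sine` (cycle mean of $|a + b\sin|$ is
  $(2b/\pi)(s\,\mathrm{asin}\,s + \sqrt{1-s^2})$, $s = a/b$, when
  $b > a$), and recovery of the planted structure can be checked exactly.
  Multi-directional oscillation is a possible extension, not the default.
  A consequence worth knowing: for this field family
  $(1-2\,\mathrm{OSI})\,\mathrm{TAWSS} = a$ identically, so planted RRT
  carries no oscillation signal — remodelling measurements are planted
  against regional OSI, and RRT correlations in the synthetic study are
  incidental rather than planted.
- **Study tables** (`make_study_table`): four groups (WKY/SHR strains ×
  saline/nifedipine), six animals each. Wall thickness (mm) is
  `intercept + slope × metric + N(0, sd)`; the noise SD is either given or
  derived from a target Pearson correlation (default 0.62 for wall
  thickness, 0.672 for the elastin layer) via
  `sd = |slope| sd_x sqrt(1/r² − 1)`. Slope/intercept defaults (3.3, −1.0)
  map inner-arch OSI of 0.39–0.42 onto wall thickness of ~0.26–0.36 mm.

Passing tests on these fields demonstrate that the metric implementations,
area bookkeeping and statistics recover planted structure under controlled
conditions; they do not show that any particular biological effect size is
reproduced, because the fields are statistical stand-ins, not measured
rat geometries or flows.

## The pipeline and the statistics stage

`run_pipeline` derives every per-animal seed deterministically from the
master seed, simulates 24 animals (group heart rates 271/378/319/379
beats/min, peaks 1521/2047/1846/2239 mm/s, branch splits 9:6:10 for WKY
and 10:7:8 for SHR, inner amplitude ratios 6.5/9.0/7.0/8.8 with SD 0.6
between animals so the hypertensive and treated-hypertensive groups stay
more oscillatory), computes maps, area fractions and regional means,
plants the remodelling table, and runs the statistics. Identical config
and seed give byte-identical CSV/JSON outputs. The default mesh is
40 × 96 (axial × circumferential): circumferential resolution is what
resolves the narrow high-OSI band whose boundary moves by ~0.02 rad
between animals, and this size keeps the 24-animal run at a few seconds
on one CPU.

Statistics are intentionally plain: group mean ± sample SD; one-way ANOVA
and Kruskal–Wallis both offered, with the method an explicit argument
(normality is not auto-tested); pairwise comparisons Bonferroni-corrected
(a deliberate choice among equally defensible corrections, switchable via
the returned p-value machinery); Pearson r with the t-transform p-value on
n − 2 degrees of freedom and the least-squares line. The test suite checks
calibration, not just formulas: the ANOVA omnibus rejects at 5.0 ± 2% over
1000 seeded null replicates of the 4 × 6 design, and a planted r = 0.62 at
n = 24 falls inside the fixed Fisher-z 95% interval of the population
value in ≥ 90% of 500 replicates.

## Problem sizes and tolerances used by the checks

Chosen to make every property sharp yet quick: metric oracle comparisons
use ≤ 10-node meshes with 12–24 samples against an independently coded
per-interval integrator (agreement to 1e-6 relative); solver validation
runs 3 cycles × 100 steps at $R = 1$ mm and rat period (Poiseuille within
1%, analytic pulsatile solution within 2%, $\alpha > 1$); spatial order is
measured at $N_r \in \{25, 50, 100\}$ with 1600 steps/cycle so temporal
error cannot mask it (observed order ≈ 2.0); planted-structure recovery
uses the default 40 × 96 arch (area fraction within 2 percentage points of
the planted share — in practice the discrepancy is at the 1e-4 level
because only hairline nodes can ever be misclassified).

## Known limitations

- Pipe models are axisymmetric stand-ins; no secondary flow, curvature or
  branch geometry enters the computed shear — the arch geometry only
  carries the planted fields.
- RRT is the algebraic surrogate above, not a Lagrangian residence time;
  no particle tracking is performed, and no OSI variants (transverse WSS,
  WSS divergence) are provided.
- The synthetic oscillation axis is fixed per node; rotating-direction
  disturbed flow would need the multi-directional extension.
- STL/VTK I/O covers triangulated surfaces only (no volumetric meshes, no
  image segmentation upstream).
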