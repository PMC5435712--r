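# wssmetrics

Disturbed blood flow — slow, oscillatory, stagnating near the vessel wall —
marks arterial regions prone to remodelling, plaque formation and endothelial
dysfunction, and is a hallmark of hypertension. The standard way to quantify
it is to post-process the wall shear stress (WSS) vector field of a pulsatile
flow simulation into a small set of per-node metrics over one cardiac cycle
of duration `T`:

- **TAWSS** (Pa) — time-averaged WSS magnitude:
  `TAWSS = (1/T) ∫₀ᵀ |τ_ω| dt`
- **OSI** (dimensionless, 0–0.5) — oscillatory shear index, the cyclic
  departure of the WSS vector from its dominant direction:
  `OSI = ½ (1 − |∫₀ᵀ τ_ω dt| / ∫₀ᵀ |τ_ω| dt)`
  (0 = unidirectional, 0.5 = complete flow reversal)
- **RRT** (Pa⁻¹) — relative residence time, a surrogate for near-wall
  particle stagnation: `RRT = 1 / ((1 − 2·OSI) · TAWSS)`

`wssmetrics` implements these metrics on triangulated vessel surfaces
(area-weighted by barycentric node lumping), the thresholded area-ratio
statistics used to compare animals (area with TAWSS < 20 Pa, OSI > 0.2,
RRT > 0.5; 7-bin 20 Pa TAWSS histograms), regional means over named masks
such as the inner wall of an aortic arch, reduced-order pulsatile pipe-flow
models (analytic Womersley solution and a Crank–Nicolson finite-difference
solver, branch flow splitting, Reynolds-number reporting), and the study
statistics stage (group mean ± SD, ANOVA / Kruskal–Wallis with Bonferroni
pairwise comparisons, Pearson correlation with regression). A synthetic-data
module generates everything needed to exercise the pipeline end to end —
curved-arch surface meshes, rat-like cardiac waveforms, WSS fields with a
planted oscillatory band on the inner curvature and known closed-form
ground-truth OSI, and per-animal study tables with planted metric–remodelling
correlations. It is aimed at cardiovascular biomechanics work at the rodent
scale, where WSS runs to tens of pascals.

## Worked example

```r
library(wssmetrics)

arch <- make_arch_mesh(arch_spec())   # rat-scale half-torus arch
spec <- planted_field_spec(baseline_wss = 20, inner_amp_ratio = 8,
                           period = 60 / 378, seed = 42)
planted <- make_wss_field(arch, spec)

tawss <- compute_tawss(planted$field)
osi   <- compute_osi(planted$field)
rrt   <- compute_rrt(tawss, osi)

ww <- arch$masks$whole_wall
cat("area with OSI > 0.2:",
    round(100 * area_fraction(osi, ww, 0.2, "above"), 2), "%\n")
cat("area with TAWSS < 20 Pa:",
    round(100 * area_fraction(tawss, ww, 20, "below"), 2), "%\n")
cat("inner-arch mean OSI:",
    round(regional_mean(osi, arch$masks$inner_arch), 3),
    "| outer-arch:", round(regional_mean(osi, arch$masks$outer_arch), 3), "\n")
cat("max |OSI - planted truth|:",
    signif(max(abs(osi$values - planted$truth$osi_true)), 3), "\n")
```

prints

```
area with OSI > 0.2: 6.31 %
area with TAWSS < 20 Pa: 46.26 %
inner-arch mean OSI: 0.185 | outer-arch: 0
max |OSI - planted truth|: 6.63e-05
```

The planted oscillation is concentrated on the inner curvature, so the
disturbed-flow area (OSI > 0.2) is a narrow band — here 6.3% of the wall —
and the inner-arch regional mean OSI far exceeds the outer-arch one. The
computed OSI map agrees with the generator's closed-form ground truth to
better than 1e-4 at 100 time steps per cycle.

The full synthetic study (4 groups × 6 animals, per-animal fields, metric
maps, area fractions, planted remodelling measurements and the statistics
stage) runs in a few seconds:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "out"))
res$correlations          # metric vs wall/elastin thickness, r + p + fit
```

or from a shell: `Rscript scripts/run_pipeline.R --seed 1 --out out`
(optionally `--config cfg.yaml`; see `?read_pipeline_config`).

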