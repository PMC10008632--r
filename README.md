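# DewetDynamics

Smooth muscle cells cultured past confluence spontaneously reorganize from a
flat multilayered sheet into three-dimensional clusters. The process runs
through a reproducible sequence of physical events — a contractility-induced
hole opens in the sheet, the retracting tissue tears off as an oblong
aggregate, the aggregate rounds up into a hemispherical cluster, and
neighboring clusters fuse — each of which behaves like the mechanics of an
active liquid. **DewetDynamics** implements the complete analysis pipeline
for quantifying these dynamics from time-lapse masks and morphometric time
series, for cell biologists and biophysicists studying tissue-scale active
matter.

The four kinetic laws at the package's core:

- **Hole opening** (viscoelastic fracture): width
  `a(t) = a_max [1 − exp(−C t)]`, where elastic recoil `~E·h·(R_c − a)` is
  resisted by cell–substrate friction `k·R_c²·da/dt`, so
  `C ~ E·h/(k·R_c²)`. Fitting `a(t)` yields the friction coefficient
  `k = E·h/(C·R_c²)`; the near-tip edge profile `y = A·√x` with
  `A ~ √(G/E)` yields the adhesion energy `G`.
- **Cluster rounding** (active dewetting): for a volume-conserving spheroid
  with anisotropy `ε = (c − a)/(c + a)` and mean radius `r = (2a + c)/3`,
  `ln(ε/ε₀) = −(15/56)·(γ/η)·∫dt/r`. The slope gives the capillary velocity
  `γ/η` (surface tension over viscosity, m/s).
- **Cluster fusion** (Frenkel viscous sintering): neck radius
  `ρ²/R₀ = (γ/η)·t` with `R₀ = √((A₁+A₂)/2π)`, until the neck saturates at
  the cluster radius.
- **Population dynamics**: total cluster count
  `dN/dt = p₁ − min(t/t_s, 1)·p₂·N`, rising to a single maximum and
  settling at the plateau `p₁/p₂`.

Around them: mask morphometry (8-connected labeling, subpixel contour
perimeters, moments-based ellipse metrics, nearest-centroid tracking, hole
width and fusion-neck measurement), the nematic order parameter
`Q = √(⟨cos2θ⟩² + ⟨sin2θ⟩²)` of stress-fiber angles with a
structure-tensor extractor, a minimal three-pass cross-correlation PIV with
the 3-SD spurious-vector filter, and a synthetic-data generator that emits
every input modality with known ground truth.

## Worked example

Generate a noisy synthetic hole-width series at the observed scales
(saturation 200 µm, rate 2×10⁻³ s⁻¹, 5 µm measurement noise), fit the
opening law, and derive the friction coefficient:

```r
library(DewetDynamics)

hole <- simulateHoleSeries(noiseSD_um = 5, seed = 42)
fit <- fitHoleWidth(hole, nBoot = 200, seed = 42)
fit
#> HoleFit: a_max = 196.7 um (SE 1.4), C = 0.0021 /s (SE 4.6e-05)
#>   stretching time 1/C = 476 s, residual SD 5.21 um

deriveConstants(fit, E_Pa = 2000, h_m = 30e-6, Rc_m = 200e-6)$k_Pa_s_m
#> [1] 7.1e+08
```

The fitted saturation width and rate recover the generator's ground truth
(200 µm, 2×10⁻³ s⁻¹) within the 5 µm noise; the stretching time ~500 s sets
the pace of each opening phase, and `k ≈ 10⁹ Pa·s/m` is the cell–substrate
friction implied by a 2 kPa, 30 µm sheet with 200 µm cells.

Rounding and fusion both estimate the capillary velocity `γ/η`:

```r
tracks <- lapply(1:7, function(i)
  simulateRoundingTrack(axisNoiseSD_um = 2, seed = 100 + i, objectId = i))
fitRounding(tracks)
#> RoundingFit: gamma/eta = 9.94e-09 m/s (SE 1.5e-10), 7 cluster(s)

pairs <- lapply(1:3, function(i)
  simulateFusionSeries(noiseSD_um = 2, seed = 200 + i))
pool <- poolFrenkel(pairs)
sprintf("fusion gamma/eta = %.3g +- %.2g m/s (N = %d)",
        pool$mean_m_s, pool$sd_m_s, pool$n)
#> "fusion gamma/eta = 2.9e-09 +- 1.4e-11 m/s (N = 3)"
```

Rounding proceeds at `γ/η ≈ 10⁻⁸ m/s`; fusion is an order of magnitude
slower (`2.9×10⁻⁹ m/s`), consistent with extracellular matrix at the
cluster rim slowing neck remodeling. `runRecoverySuite(outDir, seed)` chains
every stage on default synthetic datasets and writes CSV/JSON results plus
a summary table of recovered versus ground-truth parameters.

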