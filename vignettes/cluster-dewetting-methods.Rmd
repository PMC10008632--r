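---
title: "Models and methods: cell-sheet dewetting and cluster dynamics"
author: "DewetDynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cell-sheet dewetting and cluster dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DewetDynamics)
```

# The physical picture

Cultured smooth muscle cells at high density spontaneously reorganize from a
flat multilayered sheet into three-dimensional clusters. The package models
the four kinetic stages of that process as the mechanics of an active
liquid:

1. **Hole opening.** A contractility-induced breach in the sheet widens like
   a crack in a brittle viscoelastic material. Treating the sheet as an
   elastic layer of modulus $E$ and thickness $h$ whose recoil (scaling as
   $Eh(R_c - a)$, with $R_c$ a cell size) is resisted by cell–substrate
   friction $k R_c^2\, da/dt$, the width obeys
   $$a(t) = a_{\max}\left[1 - e^{-Ct}\right], \qquad
     C \sim \frac{Eh}{kR_c^2},$$
   so $1/C$ is the *stretching time* of hole opening and the fitted $C$
   yields the friction coefficient $k = Eh/(CR_c^2)$. Near the advancing
   edge the hole profile is the parabola $y = A\sqrt{x}$ of viscoelastic
   fracture, with $A \sim \sqrt{G/E}$ linking the fitted coefficient to the
   adhesion energy $G$.

2. **Cluster rounding (active dewetting).** A freshly torn-off cluster is an
   oblong spheroid that rounds up under its effective surface tension
   $\gamma$ against bulk viscous dissipation $\eta$. For a volume-conserving
   spheroid near a sphere the anisotropy $\epsilon = (c-a)/(c+a)$ (major
   semi-axis $a$, minor $c$) decays as
   $$\ln\frac{\epsilon}{\epsilon_0} =
     -\frac{15}{56}\,\frac{\gamma}{\eta}\,\int_0^t \frac{dt'}{r(t')},
     \qquad r = \frac{2a+c}{3},$$
   so the log-anisotropy regressed on the running $\int dt/r$ has slope
   $-(15/56)(\gamma/\eta)$: the *capillary velocity* $\gamma/\eta$ (m/s) is
   the single material parameter.

3. **Cluster fusion (viscous sintering).** Two touching clusters grow a
   contact neck of radius $\rho$ following Frenkel's law
   $$\frac{\rho^2}{R_0} = \frac{\gamma}{\eta}\, t, \qquad
     R_0 = \sqrt{\frac{A_1 + A_2}{2\pi}},$$
   until geometric saturation; the through-origin slope of $\rho^2/R_0$
   versus time since first contact estimates $\gamma/\eta$ for fusion.

4. **Population dynamics.** The total cluster count obeys
   $$\frac{dN}{dt} = p_1 - \alpha(t)\, p_2 N, \qquad
     \alpha(t) = \min(t/t_s, 1), \quad N(0) = 0,$$
   where $p_1$ is the formation rate (clusters/day), $p_2$ the relative
   reduction rate from fusion (1/day), and the ramp $\alpha$ accounts for
   the time clusters need to meet; the long-time plateau is $p_1/p_2$.

Two supporting measurements close the loop: the nematic order parameter of
actin stress fibers,
$Q = \sqrt{\langle\cos 2\theta\rangle^2 + \langle\sin 2\theta\rangle^2}$,
which quantifies the pre-cluster alignment state of the sheet, and a
multi-pass cross-correlation PIV that measures sheet velocity fields around
opening holes.

# What the synthetic generator emulates — and what it does not

Every analysis stage has a matching generator with known ground truth:
exponential hole-width saturation (plus the $y=A\sqrt{x}$ tip profile),
anisotropy decay on a volume-conserving spheroid rendered as projected
ellipse masks, $\sqrt{t}$ neck growth rendered as disc doublets with a
tangent-capped bridge, rise–peak–plateau count series with Poisson noise and
a configurable onset delay, von Mises-concentrated nematic angles (doubled
angles von Mises, so $E[Q] = I_1(\kappa)/I_0(\kappa)$), and speckle image
pairs advected by an exact displacement field.

The generators emit the *fitted laws plus measurement noise*; they are not
mechanistic simulations. No cell agents, no stochastic hole nucleation, no
contractility field. Consequently, passing round trips demonstrate that the
measurement and fitting stages are unbiased and correctly scaled on data
obeying the models — they cannot tell whether real tissue obeys the models.
Features of real movies that the fixtures deliberately lack include:
segmentation errors and uneven illumination, cluster migration during
rounding, neighboring objects that merge or occlude, and non-Gaussian
measurement error.

Noise magnitudes are fixture choices, not claims about the study's data
(none are printed there): axis measurement SD 2 µm, hole-width SD 5 µm,
Poisson count noise. Frame intervals follow the imaging protocol (5 min for
hole scenarios, 20 min for cluster scenarios); the hole generator defaults
to 60 frames over 2000 s — about four stretching times at the reported
$C = 2\times10^{-3}\,\mathrm{s^{-1}}$ — because shorter spans leave $C$
poorly constrained.

# Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `aMax_um`, `C_per_s` | µm, 1/s | 200, 2e-3 | reported hole saturation and rate |
| `gammaOverEta_m_s` (rounding) | m/s | 1e-8 | reported capillary velocity |
| `gammaOverEta_m_s` (fusion) | m/s | 2.9e-9 | reported fusion value (slower: ECM at the cluster rim) |
| `eps0`, `r0_um` | —, µm | -0.4, 100 | oblong cluster of circularity ≈0.78, diameter ≈200 µm |
| `p1, p2, ts_day` | /day, /day, day | 50, 1.5, 8 | reported population fit |
| `epsMin` | — | 0.01 | below this, log-anisotropy is noise-dominated |
| `growthCutoff` | — | 0.9 | Frenkel's law holds before geometric saturation |
| `minArea_um2` | µm² | 100 | drops sub-cellular debris from tracking |
| PIV `passes`, `finalWindow`, `overlap` | —, px, — | 3, 32, 0.5 | the study's stated PIV settings |
| `pixel_size` | µm/px | 0.65 | from the stated window size (32 px = 20.8 µm) |

# Numerical choices

**Perimeter.** Circularity $4\pi A/P^2$ is exquisitely sensitive to the
perimeter estimator: counting pixel edges biases a disc's circularity low by
tens of percent, which would corrupt the 0.75→1 rounding signature. The
package extracts the subpixel marching-squares contour
(`grDevices::contourLines` at level 0.5) and smooths the closed polygon with
a circular moving average (half-window 5 vertices) before measuring arc
length. On rendered discs this is accurate to <0.6% down to R = 20 px; on
squares the corner rounding biases the perimeter low by a fixed
per-corner length, so the $\pi/4$ circularity limit is approached from above
as the side grows.

**Ellipse metrics.** Semi-axes come from the second central moments of the
pixel set (+1/12 unit-square correction): semi-axis $= 2\sqrt{\lambda}$,
exact for ideal ellipses. The stored anisotropy uses the $a$ = major
convention, so $\epsilon \le 0$ for measured shapes; fits consume the
normalized ratio $\epsilon/\epsilon_0$, which is positive.

**Connectivity.** Components are 8-connected. `EBImage::bwlabel` is
4-connected, so diagonal-adjacent labels are merged afterwards with a small
union–find pass.

**Anisotropy regression.** The decay law is fitted per cluster as
$\ln(\epsilon/\epsilon_0)$ against the cumulative trapezoidal
$\int dt/r$ using the per-frame radius (set `assumeConstantR = TRUE` for the
constant-radius reading; at small $|\epsilon_0|$ the two agree). The
regression includes an intercept: measurement noise in $\epsilon_0$ enters
every response value as a common offset, which an intercept absorbs and a
through-origin fit would convert into slope bias. A track is truncated at
its first anisotropy sign change (the log law is undefined past it) and
excluded when fewer than 5 usable frames remain; frames with
$|\epsilon| <$ `epsMin` are dropped. Per-cluster slopes are pooled by
inverse variance; exact (zero-SE) tracks share equal weight.

**Hole and fusion time origins.** Both laws presume a zero initial value, so
the origin is re-detected from the data: the frame before the first nonzero
width (hole) or the frame before the first neck wider than one pixel
(fusion). This makes both fits invariant to uniform time shifts.

**Onset alignment for counts.** The onset is the last zero-count day before
the first positive count, so a series that is zero through day 3 is shifted
by exactly 3 days and the $N(0)=0$ anchor of the ODE is preserved. Mapping
the first *positive* day to the origin instead offsets the whole master
curve by one sampling day and visibly degrades the joint fit.

**Population fitting.** The forward model is classical fixed-step RK4
(default reference step $10^{-3}$ day; $10^{-2}$ day inside the objective,
where the fourth-order error is far below count noise). Optimization runs
Nelder–Mead on log-parameters from a 3×3×3 multi-start grid spanning
$p_1 \in [5, 150]$, $p_2 \in [0.2, 4]$, $t_s \in [2, 16]$, polishing the
best starts. The loss is unweighted SSE pooled across all aligned series
(one master curve). The test suite checks RK4 against the exact solution of
the ramped ODE, which is available in closed form through the imaginary
error function on $t \le t_s$ and a constant-coefficient relaxation beyond.

**Frenkel fit.** Plateau = median of the last quartile of $\rho$; growth
phase = frames below `growthCutoff` × plateau; regression through the
origin (the law has no intercept). Multiple pairs are fitted separately and
summarized as mean ± SD, mirroring a mean-over-pairs report.

**Neck measurement.** How the study read $\rho$ off the images is not
stated; the operationalization here is: half the minimal cross-width of the
object along scan lines perpendicular to the lobe centroid axis, restricted
to strictly between the centroids. Rendered doublets place the discs with a
3 px gap so pre-contact frames rasterize as detached lobes (tangent discs
would show a spurious minimal chord of order $\sqrt{R}$).

**Structure tensor.** The image is pre-smoothed at an inner scale
(default σ = 1.5 px) — without it the staircase edges of binarized fibers
produce axis-aligned gradients and a biased tensor — and differentiated
with the Farid–Simoncelli 5-tap pair, whose rotation-invariance keeps the
angle bias below ~0.5° where plain central differences pull the estimate
toward the diagonals by about a degree. Products are smoothed at the outer
scale σ = window/4; each window reports the eigenvector of the smaller
eigenvalue (the fiber direction) weighted by the normalized eigenvalue gap.

**PIV.** Window sizes halve per pass down to the final window; later passes
shift the search window by the previous pass's rounded displacement.
Correlation peaks are localized with the three-point Gaussian estimator
(parabolic fallback for non-positive neighbors). The spurious-vector rule
invalidates vectors exceeding their 3×3 neighborhood mean (center excluded)
by three times the *field-wide* SD of magnitudes: a neighborhood SD would
let adjacent spurious vectors shield each other (each inflates the other's
threshold), and with ~5% outliers a third of them sit next to another one.
The field-wide spread exposes clustered outliers in one pass while removing
well under 2% of clean vectors.

**Dissipation diagnostic.** `dissipationCheck` evaluates both sides of the
energy balance $\gamma\dot S = -\eta\int_V \nabla u\!:\!\nabla u\, dV$ on a
volume-conserving spheroid for a pluggable interior-flow ansatz
(Gauss–Legendre product quadrature on the mapped unit ball; exact
prolate/oblate area formulas for $\dot S$) and reports the implied
relaxation prefactor. The velocity field that yields the 15/56 prefactor is
defined in supplementary material that is not available here, and the naive
affine incompressible ansatz implies a different constant — the diagnostic
therefore *reports* the prefactor and never asserts it; 15/56 is taken as
authoritative for fitting.

# Problem sizes used by the tests and the acceptance script

Recovery checks run at the study's scales: hole fits on 60 frames with 5 µm
noise (medians over 100 seeds), rounding on 7 clusters × 72 frames with
2 µm axis noise (100 seeds), fusion on 3 pairs (100 seeds), population fits
on 3 Poisson replicates × 15 days, order parameters on 10^3–10^5 angles,
PIV on 256² speckle images. Mask round trips use radii of 50–150 px, where
rasterization error is comfortably below the stated tolerances.

# Known limitations

- The rounding law is a near-sphere approximation; tracks are generated and
  fitted within $|\epsilon| \le 0.4$, and the 15/56 prefactor is trusted
  rather than re-derived.
- `measureHole` assumes one dominant enclosed hole per frame; multiple
  holes are resolved by size, not tracked individually.
- `measureNeck` handles exactly two lobes; triple fusions raise an error.
- The population model has no developing→developed compartment structure;
  all tracked objects count as clusters.
- PIV performs integer window shifting only (no window deformation), so
  strong shear inside one window degrades the correlation peak.
- Tip-profile extraction reads the contour of a rasterized hole; its
  parabola coefficient inherits rasterization noise of order one pixel and
  is accurate to ~10% on elliptical test holes.
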