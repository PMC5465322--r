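---
title: "A three-force model of deep-cell-layer spreading on the killifish egg"
author: "epiboly package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-force model of deep-cell-layer spreading on the killifish egg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiboly)
```

## The biological system and the model

During epiboly of annual killifish, the embryonic deep cell layer (DCL) --
on the order of a hundred mesenchymal-like cells -- disperses from the
animal pole over the egg surface underneath the extra-embryonic enveloping
cell layer (EVL), a squamous epithelium of 50--60 polygonal cells whose
free (vegetal) margin advances toward the vegetal pole. The DCL is sparse,
moves on the EVL basal surface, and its dispersal couples three
ingredients: autonomous random motility, passive dragging by the expanding
EVL, and short-range attraction toward EVL cell borders.

`epiboly` represents both tissues as interacting point particles confined
to a sphere of radius $R$ (default 592 µm, the fitted egg radius):

* **EVL**: the polygon vertices are particles connected by harmonic
  springs along cell edges and across each cell between (near-)opposite
  vertices, all with elastic constant $U_0$; the opposite-vertex springs
  prevent runaway expansion of single cells. Vertices on the epibolic
  margin are a kinematic boundary condition: they move at constant speed
  $V_0$ along their meridian toward the vegetal pole.
* **DCL**: particles of radius $r$ obeying overdamped dynamics with four
  terms per step -- (i) a soft-sphere repulsion of amplitude $U_1$, acting
  when two particles overlap, with force $U_1 (r_i + r_j - d)$ along the
  centre line; (ii) an attraction to the nearest EVL cell border described
  by a Gaussian potential of amplitude $U_2$ and length $a_2$ in the
  geodesic distance $d$ to the border,
  $U(d) = -U_2\,c_a \exp(-d^2 / 2 a_2^2)$; (iii) a drag term equal to
  `drag` times the local EVL velocity, interpolated with barycentric
  weights of the three nearest EVL vertices; and (iv) zero-mean Gaussian
  noise in the two tangent directions with per-component variance
  $2 D_n\,\mathrm{d}t$.

Dynamics are overdamped with unit mobility (velocity equals force), the
appropriate regime for cells at negligible Reynolds number, and are
integrated with a forward-Euler step followed by re-projection to the
sphere. Cell divisions are scheduled events: each initial DCL cell divides
at most once, at a time drawn uniformly over a window, and is replaced by
two daughters of radius $(1/2)^{1/3}$ times its own (volume halving),
separated by one parent radius along a random tangent direction.

## Parameters, units and the two declared conversion constants

| parameter | meaning | unit | default |
|---|---|---|---|
| `U0` | EVL spring constant | 1/min | 0.05 |
| `V0` | margin speed | µm/min | 0.3 |
| `U1` | DCL--DCL repulsion | 1/min | 0.2 |
| `U2` | border-attraction amplitude | dimensionless | 0.3 |
| `a2` | border-attraction length | µm | 15 |
| `sigma` | noise amplitude | dimensionless | 2e4 |
| `drag` | EVL--DCL coupling | in [0, 1] | 1 |
| `dt` | integration step | min | 0.5 |
| `R` | egg radius | µm | 592 |
| `frameInterval` | recording cadence | min | 10 |

The fitted optimum of the free parameters is `drag = 1`, `sigma = 2e4`,
`U2 = 0.3`; those are the package defaults. The literature values of
`sigma` and `U2` come without stated units, so the package declares two
conversion constants, chosen once for physiological plausibility at this
scale and not revisited:

* `sigmaDiffusionScale = 1e-4` µm²/min per unit of `sigma`, so
  `sigma = 2e4` gives an effective step-noise diffusion of
  $D_n = 2$ µm²/min -- realistic cell-scale motility over a 17-h recording
  (RMS excursion of roughly 90 µm);
* an attraction scale $c_a = 20$ µm²/min per unit of `U2`
  (`borderAttractionScale`), so at the optimum the potential depth is
  $0.3 \times 20 = 6$ µm²/min, i.e. three times $D_n$. That ratio sets the
  Boltzmann-like stationary enhancement $\exp(U/D_n) \approx 20$ at the
  border, which produces the strongly border-concentrated distance
  distribution seen in the data while leaving cells able to escape and
  re-approach borders.

`V0 = 0.3` µm/min makes the margin advance about 430 µm over 24 h,
matching the progression from late blastula (~25% epiboly) to ~60%
epiboly. `U0 = 0.05`/min keeps the explicit Euler scheme stable at
`dt = 0.5` (stability requires `dt * U0 * connectivity << 2`) while
letting the spring network relax within tens of minutes. `a2 = 15` µm
places essentially all of the attraction force inside the ±40-µm
preferential zone reported around borders.

## Geometry

All analytics run in exact spherical geometry: geodesic distances use
`atan2(|p × q|, p · q)` (stable near 0 and π); spherical polygon areas use
a signed solid-angle fan (Van Oosterom--Strackee), a discrete form of the
Green's-theorem line integral; point-to-border distances find the exact
foot of the great-circle perpendicular on each border arc. The algebraic
sphere fit solves the linear least-squares problem of
$x^2+y^2+z^2+ax+by+cz+d=0$. Rotational drift of the egg inside the chorion
is removed by rotation-only orthogonal Procrustes (Kabsch) on radially
normalized points: epibolic growth is radial/tangential scaling on the
unit sphere, so normalization isolates the rigid rotation exactly under
isotropic growth -- the calibration scenario the method is validated on.

Two-dimensional steps (Delaunay triangulation for the deformation models,
Lloyd relaxation for the tessellation, convex hulls for covered area) run
in the azimuthal-equidistant projection about the animal pole, which
preserves geodesic distances from the pole and keeps distortion small in
the analysis cap.

## The synthetic tessellation

`makeEvlTessellation()` builds the substrate: seeds are Lloyd-relaxed in
the projected cap disc, with mirror "ghost" seeds across the margin circle
so every real Voronoi cell is finite and margin edges fall on the circle;
cells are read off `deldir`, merged into a shared-vertex mesh, margin
chords are subdivided along the circle, and everything is lifted to the
sphere. The cells partition the spherical cap to a few parts in $10^5$,
which the tests assert against the closed form $2\pi R^2(1-\cos\theta)$.
A deliberate radial jitter of relative size $10^{-7}$ is applied to margin
vertices: exactly cocircular points are a degenerate input for Delaunay
codes, and the jitter is far below every analysis tolerance.

## Drag interpolation versus the deformation models

The simulator's drag term uses barycentric weights of the *three nearest*
EVL vertices, recomputed every step -- cheap, robust, and exact for
uniform fields. The trajectory-analysis side implements three geometric
models of the EVL deformation field (`advectedDisplacement`): barycentric
interpolation over the enclosing Delaunay triangle (weights recomputed per
frame), the two closest vertices (inverse-distance weighted by default),
and the containing cell's vertex centroid. On both isotropic and
anisotropic synthetic scenarios with analytically known fields, the
Delaunay model has the lowest mean error of the three; being piecewise
linear, it slightly underestimates smooth deformation between vertices,
which is visible as a small residual when decomposing perfectly advected
tracks.

## Track analytics conventions

* **MSD**: sliding windows of 1--25 frames, squared 3D Euclidean
  displacement, pooled over windows and tracks by default (per-track
  averaging is available via `pooled = FALSE`).
* **Diffusion**: $D = \mathrm{slope}/4$. Motion is confined to the locally
  flat two-dimensional egg surface, so the 2-D convention applies;
  `fitDiffusion(..., dims = 3)` switches to slope/6 for users preferring
  the volumetric convention.
* **Neighbour distances** are geodesic; `k` is a required argument since
  both $k=3$ and $k=6$ are in use (close-neighbour statistic vs.
  dispersion statistic).
* **Distance-to-border distributions** use 5-µm bins by default and ship
  with the analytic uniform-in-disc baseline
  $p(d) = 2(R_c - d)/R_c^2$ for an equivalent cell radius $R_c$ (120 µm by
  default). Note the baseline itself is maximal at $d = 0$; border
  preference means exceeding it there, not merely peaking there.
* **Epiboly index** (a figure-level definition in the source literature)
  is taken as the axial fraction $100\,(R - \bar z_{\rm margin})/(2R)$:
  0% at the animal pole, 50% at the equator, 100% at the vegetal pole,
  consistent with the usual 30--35% / 60--65% / 85--90% staging
  vocabulary.
* **Linking** is greedy nearest-centroid -- deliberately so, to match the
  tracking actually used for this kind of data -- with quality-control
  flags (area change above 200% for EVL / 50% for DCL, displacement above
  35 µm/frame, appearances, disappearances) rather than silent
  corrections; an optimal-assignment linker appears only as a test oracle.

## Morphometrics

Shape indices derive from the spacing-aware second-moment tensor of a
label's voxels; the reported $\lambda_i$ are square roots of the
eigenvalues (lengths, not variances), so elongation $1-\lambda_2/\lambda_1$
and flatness $1-\lambda_3/\lambda_2$ stay in $[0,1]$. Entropy
$-\sum \lambda_i' \log \lambda_i'$ is maximal for isotropic objects;
eccentricity is that of the ellipse with the same second moments. The
protrusion detector takes body and membrane masks directly (the upstream
pixel segmentation is out of scope), labels membrane-minus-body components
at 8-connectivity, keeps those larger than 1.1 µm² that touch the body,
and classifies by the fixed cascade: eccentricity > 0.97 → elongated;
else solidity > 0.65 → round; else multiple elongated. Solidity is area
over convex-hull area (the standard definition; the source text does not
define it), with the hull taken over pixel corners so solidity never
exceeds 1. The protrusion base is the centroid of the pixels in contact
with the body, and orientation is the angle of base minus cell centre of
mass.

## Model fitting

The EVL target compares matched per-cell areas (normalized squared
differences). The DCL target is an equally weighted sum of normalized L2
discrepancies of four statistics: mean distance to the six nearest DCL
neighbours per frame, the border-distance probability density, the MSD
curve, and the per-frame step-displacement density. Weights are
configurable; equal weights after per-statistic scale normalization are
the default since no other weighting is documented. Optimization is
Nelder--Mead with box clamping plus a quadratic out-of-bounds penalty
(keeping on-boundary optima such as `drag = 1` reachable) and optional
restarts from the incumbent. Simulation stochasticity inside the objective
is handled with common random numbers: a fixed per-evaluation seed,
distinct from the reference's seed, makes the objective deterministic for
the optimizer while keeping the recovery test honest. `sampleLandscape()`
reproduces the min--max-normalized objective maps over (drag, sigma, U2)
grids.

## Numerical choices and degenerate inputs

Explicit Euler with per-step re-projection keeps all particles on the
sphere to machine precision; halving `dt` changes deterministic runs at
first order, as the tests verify. A per-step displacement above $0.1R$
aborts the run as an integration instability. Border vertices reaching the
vegetal pole are clamped there (the meridian tangent is undefined).
Coincident spring endpoints, degenerate triangles, coplanar sphere-fit
inputs, empty margins and too-small labels raise errors rather than
returning garbage; points outside the Delaunay triangulation fall back to
the nearest triangle and are flagged. In the simulator the attraction
force is truncated beyond $6 a_2$ (where it is below $10^{-6}$ of its
peak) with an exact lower-bound test, so the truncation is a pure
optimization.

## What the synthetic data do and do not emulate

The generators reproduce the study conditions: 50--60 polygonal EVL cells
on a 592-µm sphere, 100--120 DCL cells doubling once through asynchronous
divisions, a margin advancing at constant speed, and DCL motion combining
advection, border attraction and diffusion. They do not emulate EVL cell
fusion, failed cytokinesis, apical extrusion, image noise, segmentation
errors, or biological heterogeneity in cell size and motility. Passing
tests therefore demonstrate internal consistency of model, analytics and
fitting under the stated generative assumptions -- not that real embryos
satisfy those assumptions.

## Problem sizes used by the test suite

The suite favours scaled configurations chosen as the smallest that leave
the statistics stable: 30-cell meshes for geometric properties, the full
55/110-cell condition for spreading checks, 100 recorded frames for the
area-linearity and border-preference analyses, 300--500 random-walk tracks
for diffusion recovery (sampled at 1-s intervals so that 25-lag excursions
at $D = 31.2$ µm²/s stay small against the egg radius), and a 40-frame
reference at 1-min steps for the two-parameter simplex recovery. The
division window defaults to the middle half of the simulated interval,
emulating one asynchronous round.

## Known limitations

* The EVL margin is kinematic, not force-balanced; margin tension
  anisotropy is outside the model.
* The nearest-3-vertex drag interpolation is not continuous across
  triangle changes; the effect is far below the noise scale at the
  default parameters.
* The tessellation is a Voronoi partition in the projected chart, not an
  exact spherical Voronoi diagram; cells near the margin are mildly
  distorted.
* Parameter units for `sigma` and `U2` rest on the two declared
  conversion constants; refitting them against other data sets will
  rescale the optima accordingly.
* `detectProtrusions()` is 2D, matching the projection-based protrusion
  analysis it reimplements; `shapeIndices()` handles 2D and 3D masks.
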