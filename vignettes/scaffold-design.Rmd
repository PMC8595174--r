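---
title: "Multiscale design of TPMS bone-growth scaffolds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale design of TPMS bone-growth scaffolds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`scaffopt` selects a bone tissue-engineering scaffold — a triply periodic
minimal surface (TPMS) lattice type and a volume fraction — that maximises
the predicted pre-osteoblast growth rate while keeping the scaffold's pores
wide enough for capillary supply and its axial stiffness inside the window
that promotes bony healing of a critical femoral defect. This vignette
explains the models behind each stage, the numerical choices, and what the
test suite does and does not demonstrate.

## Scaffold geometry

Six sheet-TPMS families are supported: Primitive, Gyroid, Split P, Diamond,
Lidinoid and Neovius. Each is defined by a trigonometric field
$f(\mathbf{x})$ with period equal to the unit-cell edge (1 mm by default);
the solid is the *sheet* phase $|f| \le t$ between the two offset
isosurfaces $f = \pm t$, written in thresholded form $U = f^2 - t^2 \le 0$.
The threshold $t$ is dimensionless and controls the volume fraction
$\rho^*$. `calibrate_t()` bisects $t$ against the volume fraction measured
on the voxelised cell — the measured $VF(t)$ is non-decreasing in $t$, so
bisection is guaranteed to converge — at the same resolution later used for
analysis, so calibration and analysis agree by construction (tolerance
$10^{-3}$).

Voxelisation classifies a voxel as solid when $U \le 0$ at its centre
(boundary voxels count as solid, for determinacy). Grids built by
`voxelize()` and `make_fixture()` also carry a smooth *level-set seed* —
the implicit field $t - |f|$, or the analytic signed distance for fixtures —
whose sub-voxel zero crossings recover the true smooth surface. Interface
analyses (growth initialisation, surface export) use the seed; purely
volumetric analyses (volume fraction, pore sizes, FE) use the boolean
occupancy.

Surface export triangulates the zero level of the signed distance field by
marching tetrahedra (each grid cube split into six tetrahedra sharing the
main diagonal). This variant needs no case tables, interpolates shared edges
identically in adjacent tetrahedra (watertight meshes), and reproduces the
area of an analytic sphere to within a few percent at 100 voxels per
diameter-ish resolutions.

## Pore-size constraint

Capillaries must thread the pore network to supply oxygen and nutrients:
pores narrower than 100 µm block capillary ingrowth, and because the
diffusion range of oxygen from a capillary is roughly 200 µm, pores wider
than 400 µm leave scaffold surface beyond reach. The package measures both
extremes as the diameters of the smallest and largest virtual spheres
centred on the medial axis of the void and inscribed in it.

The medial skeleton is computed by homotopic thinning of the void phase
(26-connectivity for the void, 6 for the solid): simple points are removed
in order of increasing Euclidean distance to the solid, preserving curve
endpoints. Plateau-inclusive local maxima of the distance transform are
anchored first — without them, topologically trivial channels erode from
their open ends and can vanish entirely; void loops need no anchors because
homotopy preservation already protects them. Degenerate grid alignments
leave two-voxel-thick medial plateaus, which a final pass removes by
deleting simple voxels that participate in fully occupied 2×2×2 blocks.
Before taking diameters, skeleton voxels within 2 voxels of the domain
boundary are excluded and terminal branches shorter than 3 voxels are
pruned; raw thinning otherwise produces boundary and spur artefacts that
drive the minimum pore size to spurious near-zero values. Distances are
measured to the nearest solid voxel centre and reduced by half a spacing to
approximate the solid surface (configurable off). Only the largest connected
void component is analysed by default — a capillary cannot reach sealed
voids — with the component count reported.

Scaffolds are analysed as 3×3×3 tilings at 60 voxels per cell so that the
largest and smallest voids of the periodic network are represented. Sweeping
volume fraction from 0.2 to 0.9 in steps of 0.05 and interpolating the
crossings of the 400 µm (largest pore) and 100 µm (smallest pore) limits
yields the admissible volume-fraction window per type; both pore diameters
shrink as material is added, so the 400 µm crossing is the window's lower
edge and the 100 µm crossing its upper edge. Because the largest pores of
the Primitive and Neovius types exceed 400 µm at *every* volume fraction
(they concentrate their void in compact pockets), those types are discarded
outright — and since pore sizes shrink monotonically with volume fraction,
the implementation short-circuits the sweep by checking the densest point
first.

## Axial stiffness constraint

A scaffold bridging a 30 mm critical femoral defect, fixed with a fracture
plate, should present an axial stiffness between 1000 and 2700 N/mm: softer
scaffolds risk refracture, stiffer ones suppress the interfragmentary
movement that stimulates bone formation and shield the healing bone from
load. For a cylindrical scaffold of diameter $D$ and length $L$,

$$k_{\mathrm{scaff}} = E^* E \, \frac{\pi D^2}{4L},$$

with $E$ the material modulus (1.8 GPa, additively manufactured Nylon,
converted to N/mm² internally so that $k$ comes out in N/mm) and $E^*$ the
relative modulus of the lattice. $E^*$ follows a Gibson–Ashby law
$E^*(\rho^*) = C_1 \rho^{*n} + E_0$ per lattice type; the shipped constants
cover Gyroid, Split P, Diamond and Lidinoid over the fit range
$\rho^* \in [0.2, 0.9]$. The stiffness window inverts the law in closed form
at the two stiffness bounds. `fit_scaling_law()` (Levenberg–Marquardt,
started at $(1, 2, 0)$, $n$ bounded in $(1,5)$ — the range observed for
sheet lattices) refits constants from any modulus data.

The voxel FE homogeniser regenerates such constants from scratch: trilinear
hexahedral elements on the solid voxels of one unit cell, bottom face fixed
in the loading direction, a uniform compressive displacement on the top
face, lateral faces traction-free. Poisson's ratio defaults to 0.3.
Solid clusters not connected to both loading faces carry no load and are
removed before assembly; in-plane rigid-body modes (this is a
displacement-controlled test with free lateral faces) are suppressed by a
diagonal regularisation eight orders of magnitude below the stiffness scale.
$E^* = F /(A\,\varepsilon\, E)$ uses the full bounding cross-section $A$, so
it is the effective modulus of the homogenised block: a homogeneous block
returns $E^* = 1$ and walls aligned with the load attain the Voigt bound
$E^* = \rho$ to three digits. At 32 voxels per cell the Gyroid sweep
(VF 0.2–0.9) refits an exponent within about 1% of the shipped 2.68,
although the boundary conditions of the original fits are not documented,
so regenerated constants are treated as approximations, never silently
swapped for the shipped defaults.

### An unresolved inconsistency in the published design windows

Applying the stiffness formula with the printed defaults ($E = 1.8$ GPa,
$D = L = 30$ mm) to the shipped scaling laws yields admissible windows near
$\rho^* \in [0.23, 0.33]$ for all four types — far below the published
final windows (minima 0.44–0.49). The published minima correspond, across
all four types, to a nearly constant relative modulus
$E^* \approx 0.171 \pm 0.004$, i.e. to the 1000 N/mm bound applied with an
effective prefactor $E\pi D^2/4L \approx 5850$ N/mm rather than the
42 412 N/mm the printed constants give; the published maxima fit no single
prefactor and are presumably pore-driven. Neither reading can be derived
from the printed constants alone. The package therefore always reports the
pore window, the stiffness window and their intersection separately, so the
provenance of every edge is visible, and offers a `manual` window source
(e.g. `reference_vf_windows()`) for reproduction runs against the published
windows. Our own pore analysis, for what it is worth, also does not place
the 400 µm crossings at the published minima — with our skeleton
conventions the Gyroid's largest pore is already below 400 µm at
$\rho^* = 0.2$.

## Curvature-driven growth model

Pre-osteoblast tissue is modelled as an interface advancing from the
scaffold surface into the void. The interface is the zero level of a signed
distance field $\varphi$ (positive in solid + tissue), advected by

$$\frac{\partial \varphi}{\partial t} + \mathbf{u} \cdot \nabla \varphi = 0,
\qquad
\mathbf{u} = \begin{cases} -k\,\mathbf{n} & k > 0 \\ 0 & k \le 0 \end{cases},
\qquad
k = \nabla \cdot \mathbf{n}, \quad
\mathbf{n} = \frac{\nabla \varphi}{|\nabla \varphi|}.$$

With $\mathbf{n}$ pointing into the solid, $k$ is positive on surfaces
concave as seen from the void — the inside of a pore — so pores fill while
flat and convex surfaces are inert, matching the experimental observation
that cells proliferate on concave substrates. A spherical pore of radius
$r$ has $k = 2/r$ and obeys $\dot r = -2\lambda/r$, i.e. it fills at
$\tau = r_0^2/4\lambda$; a cylindrical channel at $r_0^2/2\lambda$. These
closed forms are the correctness oracles of the test suite (both pass
within 10% at 10–15 voxels per radius).

**Time units and the velocity–curvature coefficient.** The advection law
fixes only the *shape* of the dynamics; converting to physical time needs a
dimensional coefficient $\lambda$ (mm²/day) multiplying the curvature. The
solver therefore integrates the dimensionless flow (unit coefficient) and
reports days as $\tau/\lambda$; the printed time step $10^{-4}$ is read as
the dimensionless step. Consequences: growth-rate *ratios* between scaffold
designs are exactly $\lambda$-free, rescaling $\lambda$ rescales every curve
exactly linearly (an exact invariant in the tests), and one calibration
point — here the Split P optimum at 0.082 mm³/day — fixes absolute rates
for every other design as genuine cross-validation predictions.

**Numerics.** First-order Godunov upwinding advances $\varphi$, with the
upwind side chosen for growth of the positive phase (characteristics arrive
from the tissue side). Curvature uses central differences of the normalised
gradient, evaluated only within a narrow band of ±6 spacings around the
interface and only where the central gradient magnitude is at least 0.5
(distance-field ridges make the curvature stencil singular; such cells carry
no interface information). Three further safeguards were each found
necessary for a *rectified* curvature velocity, which converts any
grid-scale surface noise into systematic spurious growth:

* the speed tapers smoothly to zero over the outer half of the band — a
  hard cut-off leaves a kink whose curvature noise cascades back to the
  interface;
* stepping respects the *parabolic* stability bound
  $\Delta\tau \le 0.1\,h^2$ in addition to the advective CFL condition —
  curvature-driven speed is diffusive, and the nominal $10^{-4}$ step
  violates the parabolic limit on grids finer than about $48^3$, which
  manifests as the interface racing at the curvature-clamp speed;
* reinitialisation (every 10 steps, 12 pseudo-time iterations) pins
  interface-adjacent cells to the sub-cell normal distance
  $\varphi/|\nabla\varphi|$ — bounded by the nearest axial crossing of the
  linear interpolant, which takes over where the gradient estimate
  degenerates on single-cell pockets — before relaxing the far field with
  the usual upwind iterations. Plain reinitialisation displaces the zero
  level by $O(h)$, which the rectifier again turns into spurious growth.

Curvatures are additionally clamped at $0.5/h$ (radii below two voxels are
not resolvable), and the initial field is built from the smooth level-set
seed rather than the boolean occupancy: the ±half-voxel staircase of a
binary surface carries $O(1/h)$ curvature noise.

With these choices the solver is resolution-stable: unit-cell growth rates
at 64³ and 100³ voxels differ by about 1% for the lattices studied, and the
analytic pore-fill clocks hold within 10% from 24³ to 96³.

**Volumes and termination.** Tissue volume is measured by a smoothed
Heaviside of $\varphi$ (half-width 1.5 spacings), so growth curves are not
staircase-quantised. A cell is *filled* when the remaining void drops below
0.5% of the initial void volume; the average growth rate is the initial
void volume divided by the fill time, and is undefined for unfilled runs. A
plateau detector stops runs whose residual surfaces are flat or convex
(zero speed) rather than burning the full horizon. Scaffold cells use
periodic boundaries (one period of an infinite lattice); bounded fixtures
use clamped boundaries. The interface starts exactly on the scaffold
surface, with no initial cell layer: seeding thickness is not documented
for the reference experiments, and a bare surface is the cleanest
convention, though it does delay growth on the nearly minimal (near-zero
mean curvature) surfaces of low-volume-fraction sheets.

## The optimisation pipeline

`optimise_scaffold()` intersects the pore and stiffness windows per type
(or substitutes manual windows), sweeps the growth rate across each
admissible window at 0.05 spacing with the window edges always included,
and selects the volume fraction with the maximal average rate (ties resolve
toward less material). Excluded types carry machine-readable reasons.
Growth simulations and pore sweeps are memoised by a content key over all
inputs (optionally on disk via `options(scaffopt.cache_dir = ...)`), since
the growth sweep dominates the pipeline cost. `report()` writes the
scaling-constant, window, growth-curve and optimal-design tables as CSV
(6 significant digits, so reruns are byte-identical), diagnostic plots, and
a manifest with the configuration, package version and seed.

Within our model the published ranking reproduces cleanly — the Lidinoid
type yields the highest average growth rate at every volume fraction
examined, with Split P second — but two quantitative behaviours differ from
the published study, and the package reports them as computed rather than
adjusting parameters toward the published values. First, the average rate
is not monotone decreasing in volume fraction here: low-volume-fraction
sheets spend long on their nearly minimal initial surfaces before curvature
builds, which depresses their average rate. Second, within the published
admissible windows the rate profile is nearly flat (1–7% spread) but tilts
*upward*, so the computed optima sit at the window maxima (Lidinoid 0.59,
Split P 0.54) rather than the published minima (0.49, 0.44), and the
computed Lidinoid-over-Split-P margin at the optima is 11–16% rather than
the published 6%. Both behaviours are stable from 64³ to 100³ voxels, so
they are properties of this model variant (finite differences, bare-surface
initialisation, 99.5% fill criterion) rather than discretisation artefacts.

## Problem sizes

Default study scales, chosen to keep a full desk run in tens of minutes:
pore analysis on 3×3×3 cells at 60 voxels/cell; growth on one periodic cell
at 64 voxels/cell (100 voxels/cell changes rates by about 1%); FE
homogenisation at 32 voxels/cell. The memory guard in `voxelize()` refuses
grids above 1.6×10⁸ voxels unless raised deliberately.

## Known limitations

* The stiffness window from the printed constants and the published design
  windows cannot both be right; see above. Reproduction runs should use
  explicit manual windows.
* The growth model is geometry-only: no nutrient transport, fluid shear,
  scaffold degradation or cell-density effects; rates are relative until
  $\lambda$ is calibrated against one observed rate.
* First-order accuracy in space and time; curvature radii under two voxel
  spacings are clamped.
* Pore metrics depend on skeleton conventions (pruning, boundary margins,
  surface correction) that published pore curves rarely document; windows
  should be compared in trend and crossing location, not point-by-point.
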