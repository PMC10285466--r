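---
title: "Methods: phase-field modelling of chemotactic sprouting through a porous ECM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-field modelling of chemotactic sprouting through a porous ECM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`sproutfield` simulates collective endothelial cell migration as a moving
boundary problem. A conserved order parameter $\phi(x, y, t)$ takes the value
$+1$ in the cell phase and $-1$ in the medium, joined by a diffuse interface
whose one-dimensional equilibrium profile is $\tanh\!\big(y / (\sqrt{2}\,
\varepsilon)\big)$. The free energy is the dimensionless Ginzburg–Landau
double well $\int (-\phi^2/2 + \phi^4/4 + (\varepsilon^2/2) |\nabla\phi|^2)$,
and the dynamics is a Cahn–Hilliard flow extended by a single environment
coupling:

$$
\partial_t \phi \;=\; M \nabla^2\!\Big(
  \underbrace{-\phi + \phi^3 - \varepsilon^2 \nabla^2 \phi}_{\text{Cahn–Hilliard}}
  \;+\;
  \underbrace{2\phi\,\varepsilon C_0 B_\phi - \varepsilon^2 \nabla^2 B_\phi}_{\text{environment}}
\Big),
\qquad
B_\phi = \varepsilon\, C_0\, (\phi^2 - 1).
$$

$B_\phi$ vanishes identically in both bulks, so the environment acts only at
the diffuse interface: the continuum counterpart of tip cells reading their
microenvironment through surface receptors and filopodia. All environmental
information enters through one scalar field, the total angiogenic factor

$$
C_0 = \max(\nu_c - \gamma h,\ \text{floor}),
$$

the sum of the chemoattractant distribution $\nu_c$ and the ECM contribution
$\nu_{ECM} = -\gamma h$, where $h \in [0, 1]$ is hydrogel density. Cells
advance where $C_0$ is positive; where it is (close to) zero they are
immobile. Three bands classify the landscape and are used throughout:
$[0, 0.1)$ hydrogel, $[0.1, 0.2)$ hydrogel–pore interface, $[0.2, 0.5]$
pore with chemotactic factors. Band boundaries are half-open with the final
band closed at $0.5$ (the printed band limits overlap at 0.1 and 0.2; a
convention had to be fixed).

Assumptions inherited from the modelled assay: the chemoattractant gradient
is quasi-static (no diffusion PDE is solved); a single cell type; no
proliferation (the endothelium is an unlimited Dirichlet reservoir instead);
no mechanics, haptotaxis, durotaxis, flow or 3-D effects. The ECM is static
in the fundamental model and mutated only by the explicit degradation rule
in the extended model.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `nx`, `ny` | 200 | grid points | domain (770 µm at the canonical pixel size) |
| `dx_um` | 3.85 | µm/px | physical pixel size |
| `time_unit_h` | 2.75e-3 | h | physical duration of one in-silico time unit |
| `dt` | 1e-3 | in-silico units | Euler step (2.75e-6 h) |
| `M` | 1 | — | phase-field mobility |
| `eps` | 1 | grid units | interfacial length scale |
| `gamma` | 0.5 | — | ECM coupling, $\nu_{ECM} = -\gamma h$ |
| `floor` | 0 | — | lower clamp of $C_0$ |
| `alpha`, `beta` | 0.1, 0.3 | — | linear gradient $\nu_c = \alpha y + \beta$ |
| `sensing_radius_px` | 10 | px | tip look-ahead (~2 cell diameters, ~40 µm) |
| `power` | 0.2 | — | degradative power $d$ of one MMP deposit |
| `sigma_px` | 5 | px | MMP Gaussian footprint scale (~19 µm) |
| cadence | 0.275 h | — | simulated time between sensing/degradation events |

The time calibration follows from the printed equivalence $\Delta t = 10^{-3}
\leftrightarrow 2.75\times10^{-6}$ h and is consistent with the canonical
snapshot times (2.75, 27.5, 55, 96.25 h); a body-text value of
$3.0\times10^{-3}$ h per unit is treated as rounding.

**Gradient normalization.** The printed gradient "$0.1y + 0.3$" cannot use
per-pixel $y$ (it would leave the admissible $C_0 \le 0.5$ range within two
pixels). `make_gradient()` measures $y$ from the cell-side edge in units of
$n_y/2$ grid points, the unique normalization under which the profile spans
exactly the printed $[0.3, 0.5]$ band across the domain. Mid-domain evaluates
to exactly 0.4; the far-edge *site* (199 px out of 200) evaluates to 0.499,
i.e. the printed 0.5 at printed precision.

**$\nu_{ECM}$ sign and scale.** Only the composite $C_0$ bands are specified,
not $\nu_{ECM}$ itself. With $\gamma = 0.5$ and floor 0, dense hydrogel under
the $[0.3, 0.5]$ gradient lands in the immobilizing band and open pore in the
chemoattractant band, reproducing the published classification; this is the
package's choice, made once.

## Term grouping: why "conserved" is the default

The environment terms can be grouped two ways: *additive* (outside the outer
Laplacian, as the governing equation is typographically printed) or
*conserved* (inside it, as part of a generalized chemical potential). Both
are implemented (`model_params(env_grouping = ...)`) and both are verified
against an independent nested-loop oracle.

Linearizing the additive dynamics about the bulk medium $\phi = -1$ under
constant $C_0$ gives the growth rate

$$
\lambda(k) = 4\varepsilon^2 C_0^2 \;-\; 2\varepsilon^3 C_0 k^2
             \;-\; M k^2 (2 + \varepsilon^2 k^2),
$$

which is positive at small $k$ whenever $C_0 > 0$: every chemoattractant-
filled pore is linearly unstable, nucleates spontaneously once seeded by the
interface's exponential tail, and (because $\phi < -1$ has no restoring
force) diverges below $-1$. Over the simulated horizons ($10^3$–$10^4$ time
units) this contradicts the defining behaviours of the model: a pore distant
from the cells must stay quiescent, and total cell volume must change only
through the reservoir ("the model conserves the number of cells"). Under the
conserved grouping $\lambda(k) = -Mk^2(2 + \varepsilon^2 k^2 +
4\varepsilon^2 C_0^2 + 2\varepsilon^3 C_0 k^2) \le 0$: the bulk is
unconditionally stable, interior dynamics conserve $\sum\phi$ exactly (the
five-point stencil with mirror closure is a discrete flux divergence), and
all volume injection is attributable to the Dirichlet reservoirs — which is
what the volume-flux metric measures. The conserved grouping is therefore
the default; the additive grouping remains available for study and is
exercised by the unit tests.

## Numerical choices

- **Stencil and closure.** Five-point Laplacian; mirror (ghost = edge)
  closure at non-reservoir boundaries, making $\sum \mathrm{lap}(f) = 0$ to
  rounding and hence mass conservation exact up to accumulation error
  (verified to relative drift $\le 10^{-9}$ over $10^4$ steps).
- **Stability guard.** Explicit Euler on the biharmonic term requires
  $dt \lesssim \Delta x^4 / (32 M \varepsilon^2)$; `run_simulation()` refuses
  `dt` above 0.8x that bound. The canonical `dt = 1e-3` passes with an
  order-of-magnitude margin.
- **Initial interfaces** are seeded with the $\tanh$ profile of width
  $\sqrt{2}\varepsilon$, avoiding spurious transients from step initial data.
- **Overshoot diagnostic.** $|\phi| > 1.1$ aborts with the step index and
  magnitude: benign Cahn–Hilliard overshoot stays well below this, blow-up
  crosses it within a few hundred steps.
- **Interface resolution.** At the canonical $\varepsilon = \Delta x = 1$ the
  discrete equilibrium interface is lattice-narrowed (fitted width ~1.32
  versus $\sqrt{2}$; maximum deviation from the continuum kink ~0.035 in
  $\phi$). Comparisons against the continuum $\tanh$ profile at the 0.02
  tolerance are therefore made with the interface resolved
  ($\varepsilon / \Delta x \ge 2$, deviation ~0.007). This is a resolution
  requirement of the comparison, not a tuning of the model.
- **Reduced-grid scaling.** The behavioural tests run the simplified-pore
  system on a 100 x 100 grid. Tip velocity in px per in-silico unit is
  grid-size independent, so preserving the µm/h calibration requires scaling
  `dx_um` and `time_unit_h` together (7.7 µm and 5.5e-3 h). Those runs use
  `dt = 5e-3`, four times under the guard, chosen once for the test budget.
- **Deterministic tie-breaks.** Tip detection resolves equally advanced
  columns by distance to the cell-mask centroid, then by the smaller index;
  sensing resolves equal scores toward straight chemoattractant ascent. Runs
  are bit-reproducible from (config, seed).

## The degradation rule

The extended model's sensing/degradation step, applied every cadence
interval (default one event per 0.275 h of simulated time, an event-indexed
rather than integration-step-indexed cadence):

1. `locate_tip()`: the most advanced $\phi \ge 0$ site.
2. `sense_environment()`: candidate headings within ±60° of the local
   $\nu_c$ ascent, each scored by mean hydrogel density over a look-ahead
   disc of radius `sigma_px` centred `sensing_radius_px` away; the minimal
   score wins. The disc score is this package's concrete realization of
   "find the path of lower ECM toward increasing chemoattractant" — the
   original implementation details are not public.
3. `deposit_mmp()`: $h' = \max(h - d\, G, 0)$ with $G$ a unit-peak Gaussian
   of scale `sigma_px` (truncated at $4\sigma$), then $C_0$ is recomposed
   with the same $\gamma$ and floor.

$\sigma = 5$ px (~19 µm) clears a pore of the ~40 µm scale after a few
events. One deposit per event is used (continuous production along the tip
trajectory would be an alternative reading); degraded matrix is removed, not
converted into additional chemoattractant — the biological
"re-biosynthesis into pro-migratory agents" has no published magnitudes and
is out of scope. Degradative power 0 reproduces the fundamental model
bit-for-bit, hydrogel mass is pointwise non-increasing, and the clamp keeps
density non-negative.

## Synthetic ECM: what it emulates and what it does not

`generate_synthetic_ecm()` stands in for a confocal image of a large-pore,
low-concentration fibrin hydrogel: Gaussian-smoothed white noise thresholded
at the quantile matching the target porosity (default 0.5, a realistic
pore-area fraction for such gels; the source assay reports only the 40 µm
mean pore size). The smoothing scale is calibrated by bisection against the
pore-size morphometric, exploiting that mean pore size grows monotonically
with correlation length at fixed porosity. Identical spec + seed gives
identical fields.

The generator reproduces the two features the model consumes — pore-scale
(40 µm mean inscribed-disc diameter) and a binary dense/open structure — but
not fibre anisotropy, strand connectivity, imaging noise, or 3-D pore
topology. A green test against synthetic ECM therefore establishes the
solver/degradation/metrics pipeline on a landscape with realistic pore
geometry statistics; it does not validate against any particular imaged gel.
Real images enter through `load_hydrogel_image()` (luminance, min-max
normalization, exact area-average resampling), which in this build reads
text netpbm (P1/P2/P3) and CSV/TSV matrices.

**Pore-size morphometric.** `measure_mean_pore_size()` binarizes pore space
at $h < 0.5$ and computes local thickness — for each pore pixel, the
diameter of the largest pore-inscribed disc covering it, from an exact
Euclidean distance transform followed by disc dilation — averaged over pore
pixels. Chosen over chord-length sampling for rotation invariance; on slab
and disc geometries it recovers the analytic inscribed diameter within one
pixel. The experimental measurement protocol is not public; this is a
standard morphometric stand-in.

## Scenario geometry (chosen where the source is silent)

- Simplified-pore system: pocket of 0.25 $n_x$ x 0.2 $n_y$ in solid matrix;
  in contact with the cell front, or separated by a 0.3 $n_y$ dense band for
  the distant case (the separation guarantees no positive-$C_0$ site is
  within reach of the cells or their interface tail, which is the meaning of
  "distant"). Peaked chemoattractant: 0.1 at the cells, 0.5 at the pocket
  centre, decaying to 0 at the far edge, one-dimensional along the
  advancement axis.
- Open-path landscape: spherical-cap endothelium of radius 0.15 $n_y$ on the
  high-y edge, whole edge pinned as the reservoir, corridor width
  0.05 $n_y$ along a three-segment meander.
- Spherical-reservoir variants: sphere radius 0.075 $n_y$ centred on the
  corridor axis 0.12 $n_y$ from the edge; the Dirichlet mask is the initial
  sphere itself.
- No-chemoattractant control: uniform baseline $\nu_c = 0.3$ restricted to
  pore space — bands exist but no directional cue, the minimal construction
  under which cells fill nearby pores without long-range migration.

## Known limitations

- Full-scale summary metrics (mean tip velocity ~-6 µm/h over ~96 h of
  simulated time, volume fluxes ~0.7e-3 /h) require 1.7–3.5 x 10^7 Euler
  steps on the 200 x 200 grid — hours of single-CPU time. The test suite
  and acceptance script verify the model at reduced scale (the worked
  example reaches -5.6 µm/h over 27.5 h); full-scale runs are a CLI
  invocation away but are not part of the default checks.
- Explicit Euler only; no adaptive stepping or implicit/spectral solvers.
- 2-D; conclusions about 3-D pore topology or sprout lumenization are out of
  scope.
- The additive term grouping is retained for completeness but is bulk-
  unstable (see above); long simulations should use the conserved default.
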