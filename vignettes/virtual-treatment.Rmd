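---
title: "Virtual treatment of bifurcation aneurysms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual treatment of bifurcation aneurysms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aneutreat` compares two endovascular treatments of middle-cerebral-artery
(MCA) bifurcation aneurysms in silico: a conventional braided
flow-diverting stent placed in the parent lumen across the aneurysm neck
(jailing one daughter branch), and an intrasaccular flow disruptor — a
dual-layer braided bowl placed inside the sac at the neck. The pipeline
is generate → measure → size → deploy → solve → report, and every stage
is an exported function. This vignette explains the models behind each
stage, the parameters that matter, and what the desk-scale defaults can
and cannot show.

## Synthetic vasculature

Patient imaging is deliberately out of scope; the computational domain is
a parametric idealization built from implicit surfaces
(`generateBifurcationAneurysm()`):

* a straight parent vessel along +x;
* a spheroidal dome centred on the continuation of the parent axis, so
  the parent jet empties towards the sac — the *terminal bifurcation*
  topology in which essentially the whole parent flow transits the neck
  region. This choice is load-bearing: with a side-wall dome the braid
  cannot scaffold the orifice and neither device reproduces the
  clinical flow pattern;
* two daughter branches leaving just proximal of the neck plane at
  configurable angles, dipping slightly out of plane away from the dome.
  A daughter may branch further proximally (negative `daughter_offsets`
  entry), in which case its ostium lies under the body of a deployed
  stent — the classic picture of a jailed side branch.

The sac is the part of the spheroid beyond a neck plane perpendicular to
the parent axis, positioned so the spheroid's cross-section there has
exactly the requested neck width `d_n`; the maximum width `d_a` is twice
the equatorial semi-axis. The surface is triangulated by marching
tetrahedra on a uniform grid (default target edge length 0.2 mm, which
puts more than 15 edges across the smallest catalogued neck of 3.11 mm);
the same Kuhn tetrahedral split in every cell makes the mesh watertight
by construction. All dimensions are millimetres.

`measureAneurysm()` reads the construction back off the surface, the way
a user-supplied mesh would be measured: the neck contour is the largest
boundary loop of the dome-surface triangle set, refined by Newton
projection onto the intersection of the dome surface and the neck
envelope; `d_n` is the maximum 3D chord of that contour, `d_a` the
maximum chord parallel to the least-squares neck plane. The printed
measurement convention of the source cases is two-dimensional and not
operationally defined; the 3D max-chord reading adopted here recovers
the generator's parameters within 2% and is exact on analytic test sacs
(a sphere cut at its equator, a hemisphere on the neck plane).

## Devices

The Contour-style intrasaccular device is selected from a five-row
catalogue by `d_n` (hard criterion) and `d_a` (advisory): the published
selections themselves violate strict `d_a` containment (a 5.56 mm-wide
aneurysm receives a device whose advisory range tops at 5.5 mm), so
`selectContour()` warns rather than errors on `d_a`. Braided stents are
sized by slight oversizing of the landing vessel.

`buildBraidedStent()` realizes two counter-rotating helix families on a
cylinder (default 48 wires, braid angle 45° from the axis). The wire
radius is not published; the default (22 µm) was calibrated once so that
the deployed-cylinder porosity of the default braid is ≈60%, the
published deployed porosity, and is exposed as a parameter.
`buildContour()` realizes a dual-layer braided bowl — a truncated
spherical cap with its largest diameter at the open rim — from spherical
spirals (2 × 72 wires, layer gap 2.5 wire radii, inert marker node at
the pole). Porosity is computed by rasterizing the strut footprint on
the carrier surface at sub-wire resolution (`computePorosity()`), which
counts overlapping wires at crossings once; the intrasaccular device has
no published porosity, so its screen strength is always derived from its
built wireframe.

## Virtual deployment

Deployment is quasi-static dynamic relaxation (`crimpWireframe()`,
`releaseWireframe()`):

* **Crimp.** Struts keep their rest lengths while the radius shrinks, so
  each strut's axial advance becomes `sqrt(L^2 - chord^2)` — the braid
  elongates exactly as braid kinematics dictates, and crimping a stent
  to its own nominal radius is the identity.
* **Release.** Nodes are unpinned progressively from the distal to the
  proximal end of the delivery path (default 48 equal increments, the
  same order as clinical unsheathing), relaxing between increments.
* **Relaxation.** Damped gradient descent on an elastic energy with two
  terms: linear stretch springs along struts, and a stress-free-shape
  restoring term that maps the reference shape onto the delivery path by
  parallel transport (this is the bending/torsion surrogate — it makes
  the free-space equilibrium exactly the nominal shape). The vessel wall
  is rigid and frictionless: any node outside the lumen is projected
  back onto the surface each iteration.

Convergence is a maximum node displacement below 1 mm/1000 per
iteration with penetration below 0.01 mm; both are package choices (no
published values exist) and both are verified properties, not just
stopping rules: free expansion recovers the nominal diameter to <1%, and
in an undersized rigid tube the equilibrium matches an independent
penalty minimization of the same energy.

## Steady hemodynamics

Blood is an incompressible Newtonian fluid (density 1000 kg/m³, dynamic
viscosity 0.004 Pa·s); walls and struts are rigid and no-slip; the inlet
is a parabolic (radially symmetric) profile scaled to the configured
flow; both outlets carry the same fixed gauge pressure. The solver
(`solveSteady()`) is a pseudo-time projection method on a uniform
staggered Cartesian grid with immersed boundaries:

* wall positions between fluid and solid face centres are located by
  linear interpolation of the signed distance, and enter the diffusion
  stencils as shortened arms — shear is resolved to sub-cell accuracy on
  the stair-step grid;
* advection is first-order upwind and explicit; diffusion is explicit
  too (at these resolutions and Reynolds numbers ~100–300 the advective
  Courant limit binds first); the time step adapts if the developing
  flow outruns its initial velocity-scale estimate;
* the pressure correction is a sparse Cholesky solve factorized once,
  giving a discretely divergence-free field on every interior cell at
  every iteration — global mass balance holds independently of the
  convergence level;
* branch caps are extended by straight buffers: the inlet ends in a
  Dirichlet-velocity slab, outlets are fixed-pressure cell regions.

Convergence follows the published bookkeeping: relative residual
reduction below 1e-5 or absolute residual below 1e-8 (the residual is
the per-iteration velocity change scaled to a per-domain-transit rate,
so it is time-step independent). Verification is by closed forms: on a
straight tube at the reference test density of 300 elements/mm³ the
centreline velocity is within 3%, the pressure drop within 5% and the
wall shear stress within 5% of Hagen–Poiseuille values, and a symmetric
bifurcation splits flow 50/50 within 1%.

### Device coupling

The default coupling is a homogenized porous screen
(`applyDeviceScreen()`): faces within one grid spacing of the deployed
strut cloud receive an anisotropic Brinkman drag
`c (n n' + beta (I - n n'))`, where `n` is the local braid-surface
normal estimated by principal-component analysis of the strut points.
Only through-screen flow feels the full resistance; flow along a
wall-apposed braid is unimpeded (`beta = 0` by default) — penalizing the
tangential component inside the smeared layer would otherwise act like a
grossly thickened screen and choke the stented branch. The resistance
follows a Kozeny–Carman-type screen law on the wire diameter and the
computed porosity, scaled so the integrated trans-screen pressure drop
matches a physical screen one wire-diameter thick. The drag is implicit
in its diagonal and capped in its explicit cross-coupling, which keeps
the iteration stable for arbitrarily strong screens; porosity 1 leaves
the discrete model bit-identical to the untreated one, and porosity 0
seals the marked faces exactly. Resolved-strut no-slip coupling exists
(`device_coupling = "resolved"`) but needs grids fine enough to resolve
44 µm wires and is not a desk-scale default.

### Measurement planes

Aneurysm inflow `Q_in` is the directional influx (positive part of
`u · n`, switchable to signed net flux) through a neck plane; the
daughter-vessel inflow `Q_in-DV` is the influx through a plane three
local diameters down the monitored (non-stented) daughter,
perpendicular to its axis. The neck plane is placed just sac-side of the
deployed device crowns and shared by all arms of a case: the device
surface is the boundary of the treated sac, and a plane below the braid
crown would count flow that bulges upward inside the stent without ever
entering the isolated sac. Wall shear stress is viscosity times the
tangential velocity-gradient magnitude, evaluated by a two-point
quadratic fit along the inward normal at probe depths of 2.5 and 5 grid
spacings (clear of the immersed-boundary interpolation layer); the
regional maximum is the literal field maximum, with a 99th-percentile
variant reported alongside but never substituted.

## Study conditions and what the tests show

Two reference cases fix the study conditions (`caseConfig()`):

* **Case I-like** — wide-neck giant aneurysm, `d_n` 8.58 / `d_a`
  9.37 mm, parent 2.4 mm, daughters 2.1/2.2 mm at 70°/80° (the
  non-stented daughter steeper and branching 1.5 mm proximally, i.e.
  jailed under the stent body; non-stented-to-parent diameter ratio
  0.92), untreated parent inflow 126.4 ml/min. Auto-sizing selects the
  14 mm intrasaccular device and a 2.25 × 15 mm stent.
* **Case II-like** — narrow neck, `d_n` 3.11 / `d_a` 5.56 mm, parent
  2.8 mm, daughters 2.8/1.9 mm at 55°/65°, parent inflow 74.4 ml/min —
  the value implied by the published untreated sac inflow of
  51.8 ml/min being 69.63% of the parent flow. Auto-sizing selects the
  7 mm device — with the advisory `d_a` warning the published selection
  also implies — and a 3 × 15 mm stent.

The comparison runs all three arms (untreated, stent, intrasaccular) on
one mesh at 27 elements/mm³ (cell size 1/3 mm). That is three orders of
magnitude coarser than the >4000 elements/mm³ the full-resolution
reference setup used, which is why the package's acceptance checks on
these cases are *directional properties*, not numeric matches: both
devices must cut neck influx by more than half (full-resolution
behaviour: ≥85%), the stent must reduce and the intrasaccular device
must not reduce the non-stented daughter's flow. At these conditions the
pipeline reproduces the full qualitative pattern, and the magnitudes
land close to the published ones (Case I-like: reductions 94%/86%,
daughter changes −15%/+14%).

What the synthetic cases do *not* emulate: patient-specific lumen
irregularity and neck morphology, vessel curvature and tapering,
pulsatility (steady flow only), vessel-wall and device mechanics beyond
rigid contact, and thrombosis biology. Passing the directional checks
says the modelling chain behaves physically; it does not validate
patient-specific predictions.

## Numerical choices and limitations

* Tie-breaks and degeneracies: exact zeros of the level set are
  perturbed by 1e-12 mm before isosurfacing; wall distances are clamped
  to at least 0.15 cells in the stencils; devices crimped onto a path
  shorter than their elongated length raise an error rather than fold.
* Determinism: every stage is deterministic for fixed inputs; the only
  randomness is the optional seeded dome perturbation of the generator.
* The first-order upwind scheme is diffusive; at 27 elements/mm³
  secondary vortices in the sac are under-resolved, which is the main
  reason treated-arm inflow reductions sit below the full-resolution
  reference values.
* The screen model homogenizes the braid; strut-scale jetting and
  pore-scale transport are invisible to it. The resolved mode removes
  this limit in principle but not at desk-scale budgets.
* Iteration counts of the deployment relaxation are
  implementation-dependent and are deliberately not a reported quantity.
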