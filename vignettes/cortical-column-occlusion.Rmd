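---
title: "Micro-occlusion and oxygen transport in synthetic cortical columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-occlusion and oxygen transport in synthetic cortical columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`arteriox` simulates what happens to brain tissue oxygenation when a single
25 µm microsphere lodges in a cerebral penetrating arteriole, and quantifies
the spatial relationship between the occlusion site and the resulting
hypoxic tissue with two distance statistics that can be applied identically
to simulated columns and to segmented experimental image stacks. This
vignette is the package's own account of the models, the numerical choices,
and what the synthetic data do and do not represent.

## The cortical column model

The tissue unit is a 375 × 375 × 1500 µm³ cortical column supplied by one
penetrating arteriole entering at the centre of the cortical surface. A
column is assembled from two generated networks:

* **Capillary bed** — `generate_capillary_cube()` builds a periodic
  375 µm cube: nodes on a jittered cubic lattice (62.5 µm pitch), each
  joined to its six periodic neighbours, then edges deleted at random —
  never a bridge — until the requested segment count is met exactly.
  Four copies are stacked in z; segments wrapping across the outer faces are
  cut at the face and become pressure-boundary stubs. Capillary diameters
  follow a truncated normal law, `N(6.8, 0.8)` µm on `[4, 10]`.
* **Penetrating arteriole** — `generate_arteriole_tree()` grows a trunk
  that tapers geometrically from 30 µm at the surface to 20 µm at 1400 µm
  depth, with 9–12 side offshoots whose root diameters are 0.75–0.95 of the
  local trunk diameter and whose subtrees bifurcate with Murray-law
  daughters (cube-law exponent). Because the roots straddle the 25 µm bead
  size, a bead can lodge at an offshoot root, inside an offshoot at a
  first-generation branch, or at the mid-depth trunk segment where the
  taper crosses 25 µm — occlusion sites spread over generations and
  depths, which mirrors where microspheres are found in vivo.

`assemble_column()` trims the tree at the column faces, joins every
arteriole terminal to the nearest interior capillary node with a connector
segment, and narrows the boundary stubs to 0.7× their capillary diameter.
That last step represents the resistance of the capillary–venule
transition at the column boundary. It matters: with free-draining
boundaries the network shunts (the 95th/5th percentile ratio of capillary
flows is ~240), large tissue regions receive only slow, fully desaturated
blood, and a quarter of the healthy column is spuriously hypoxic. With the
outflow resistance in place the ratio falls to ~50 and healthy columns show
only scattered hypoxic voxels, as they should.

The free generator constants (cube segment density 9290 /mm³, capillary
diameter law, outflow factor) were calibrated once so that ten default
columns reproduce the reference column geometry — vessel density
10 846 ± 163 /mm³ and vascular volume fraction 2.82 ± 0.22 % — and then
frozen. The measured means are 10 843 /mm³ and 2.97 %. The volume fraction
is deliberately left slightly above centre: re-centring it requires
thinning the capillaries, which destabilises healthy oxygenation for some
seeds.

## Blood flow

Flow is steady Hagen–Poiseuille flow on the graph: segment conductance
`π r⁴ / (8 µ L)`, apparent viscosity from the in-vitro empirical law in
diameter and discharge haematocrit (haematocrit 0.45, plasma viscosity
1.2 mPa·s), mass conservation at interior nodes, all boundary nodes at one
reference pressure and the inlet at a calibrated pressure. Because the
viscosity law does not depend on flow, the network is linear and
`calibrate_perfusion()` rescales a unit-pressure solve so that inlet flow
per column volume equals 55 mL/100 mL/min exactly. The sparse
Cholesky path is verified against a dense solve on small fixtures to
10⁻¹⁰.

## Oxygen transport

Oxygen follows the Green's function method: vessels are discrete source
elements (segments split to ≤ `max_element_um`), tissue voxels are
Michaelis–Menten sinks, and the tissue PO₂ field is the superposition

P(x) = Σₛ G(x, xₛ) qₛ − Σₖ G(x, xₖ) mₖ + c,

with the free-space diffusion kernel `G = 1/(4π Dₜ αₜ |x − x*|)`. The
singular kernel is regularised with finite self-coefficients: a source
element's own potential is the average of a uniform line source over the
element evaluated at its radius, and a voxel's is the average over the
equal-volume sphere. The uniform offset `c` is an unknown of the system,
paired with the solvability constraint Σq = Σm; this keeps global oxygen
balance exact and replaces boundary-image corrections (a pure free-space
superposition with the field pinned at infinity would leak an O(10%)
monopole).

Blood-side physics: content `C_b = α_b P + C_Hb H S(P)` with the Hill
saturation `S = Pᴺ/(P₅₀ᴺ + Pᴺ)`; along each flowing segment the content
drops by `q/Q` per element, with flow-weighted mixing at converging nodes
and the inlet at 90 mmHg. Tissue consumption is `M = M₀ P/(P + P₀)` with
`M₀ = 6.72 × 10⁻⁴ cm³O₂ cm⁻³ s⁻¹` (human grey matter). The remaining
constants are the standard set of the Green's function literature
(N = 3, P₅₀ = 38 mmHg, C_Hb = 0.5, α_b = 3.1 × 10⁻⁵,
αₜ = 3.89 × 10⁻⁵ cm³O₂ cm⁻³ mmHg⁻¹, Dₜ = 2.41 × 10⁻⁵ cm² s⁻¹,
P₀ = 1 mmHg); they are configuration defaults, not fitted values. An
optional intravascular resistance term (blood-to-wall PO₂ drop) exists and
is off by default.

### Numerics

The coupled system is stiff: an element's wall PO₂ responds to upstream
sources through `1/(Q c′)`, which for capillaries exceeds the diffusive
kernel diagonal by an order of magnitude, and the kernel matrix is strongly
non-diagonally-dominant (row sums ≈ 100 × diagonal), so naive lagged or
Gauss–Seidel iterations diverge. `solve_oxygen()` therefore uses:

* an **inner damped Newton** solve of the vessel system (wall conditions +
  balance constraint) with the *exact* convection Jacobian, assembled in
  compiled code by marching sensitivities along the flow with
  flow-weighted mixing; the blood-content clamp at zero is smoothed over
  10⁻³ of the arterial content so the system is C¹; the factorised
  operator (dense LU) is reused until a backtracking line search fails;
  near-stagnant elements (flow below 3 × 10⁻⁵ of the maximum) are excluded
  as sources, and convergence is judged by the oxygen-flux step size, not
  the mmHg residual, which stiffness inflates at the remaining
  slowest-flow elements;
* an **outer quasi-Newton tissue update** solving `(I + C D) δ = r`, where
  `C` is the voxel–voxel kernel applied by FFT convolution and `D` the
  local metabolic slope, via the symmetrised conjugate-gradient form —
  this damps the strong negative feedback of large hypoxic regions
  (local gain 10–40) that defeats plain relaxation;
* **Anderson(5) acceleration** with a fall-back safeguard, a six-step ramp
  of the metabolic demand on cold starts (scenario solves warm-start from
  the healthy solution), and a hard-damped fall-back when a localised
  hypoxia-front mode keeps a small residual oscillating.

Convergence is declared when the tissue field changes by less than
0.1 mmHg, demand is at full strength, and global balance holds to 1%;
non-convergence is an explicit warning carrying the residual history.
Negative PO₂ is clamped only inside the iteration; the reported field is
the raw converged superposition. A closed-form check — a single straight
vessel through a tissue block with constant consumption, compared against
the analytic line-source plus box-sink potential — agrees to within 2% at
2–10 vessel radii.

## Occlusion scenarios

A bead entering the inlet travels with the flow and lodges at the inlet of
the first vessel narrower than 25 µm. `enumerate_trapping_sites()` returns
every arteriole segment below the bead size whose upstream node is
reachable through ≥ 25 µm segments along flow directions; all sites carry
equal probability (no transport model weights them), and capillaries are
excluded (they are shadowed by the first arteriole trap). Blocking keeps
the segment's geometry but zeroes its conductance; flow is re-solved at
the *healthy* calibrated inlet pressure, so the reported relative
perfusion drop is meaningful, and oxygen is re-solved warm-started from
the healthy state. Default columns provide 6–10 sites each (75 over ten
columns).

## Distance statistics

* **Pixel-based Gx** — the empirical CDF `P(δ < d)` of distances from
  every in-domain hypoxic voxel centre to its nearest microsphere, with
  voxels hypoxic under the healthy baseline excluded; distances use voxel
  centres and physical (possibly anisotropic) spacing. Reported on a
  0–1000 µm grid in 10 µm bins by default (the binning is a package
  choice; crossings are located as the first bin at or above the level).
* **Hypoxic intensity** — the hypoxic volume fraction inside spheres of
  radius 50–500 µm (step 50) around a microsphere; out-of-domain voxels
  are excluded from numerator and denominator; a radius with no in-domain
  voxel is missing, not zero. Curves are classified type A (fraction falls
  from 50 to 100 µm, or fully hypoxic within 100 µm) versus type B
  (rises, or no hypoxia within 100 µm); a flat curve with partial hypoxia
  is B, the residual class. The subtype is *local* iff any hypoxic voxel
  lies within 100 µm.
* **Aggregation** — within a column, intensity curves are averaged
  unweighted over scenarios (equal blockage probability) and Gx distances
  are pooled before forming the CDF; across columns, the per-column Gx
  curves are averaged. Monte-Carlo control points, uniform over the tissue
  domain at matched density, provide the chance baseline for intensity.

The same functions ingest experimental-style data: binary section stacks
(3.033 µm pixels, 50 µm slabs, content at slab centres) are downsampled
5 × 5 to 15.165 × 15.165 × 50 µm³ voxels by majority pooling over
in-tissue pixels (ties count as hypoxic; an "any-pixel" rule is available),
and bead centres come from CSV exports validated against the tissue mask.

## What the synthetic data are, and are not

The generators emulate the *statistics* the column model is specified by —
Table-1-style densities, single-arteriole topology, 6–15 trapping sites,
physiological healthy oxygenation — not any particular reconstructed
network. Consequences worth knowing:

* Capillaries form a jittered lattice with uniform connectivity. Real (and
  the reference study's data-derived) capillary networks share its density
  but not its regularity.
* **Collateral rescue right-shifts the Gx curve.** At the reference vessel
  density, the boundary of a ~150 µm blocked territory is crossed by ~70
  capillary links, so a blocked branch's own territory is partly rescued
  and occlusion-induced hypoxia concentrates in the column's marginal
  shell (lateral boundary, depth extremes). The simulated mean Gx
  therefore reaches 50% near 500–600 µm rather than ~300 µm, while the
  90% crossing lands near 800 µm as expected. Structural variants (flat
  offshoot discs, fewer/more offshoots, sealed bottom face, thinner
  capillaries) either did not move the 50% crossing or broke healthy
  oxygenation; the discrepancy is reported as computed.
* Instance-specific numbers (per-scenario perfusion drops, RMS field
  differences between particular columns) depend on the particular
  networks and are not reproducible by a statistical stand-in.
* The synthetic *experimental* fixtures plant hypoxic blobs at recorded
  displacements from beads inside an elliptical tissue mask, which lets
  the analysis arm be tested for exact recovery (planted 300 µm median
  displacement is recovered by the Gx 50% crossing to one 10 µm bin); they
  contain none of the segmentation noise, tearing, or multi-occlusion
  superposition of real material.

## Problem sizes and runtimes

Full-fidelity columns use 15 µm tissue voxels and ≤ 30 µm source elements
(~62 500 voxels, ~7000 elements). The test-suite and batch analyses run at
the coarse desk scale — 30 µm voxels, ≤ 100 µm elements, three to four
columns (~30 scenarios) — where a healthy solve takes seconds to a couple
of minutes and a warm-started scenario solve less than a minute on one
core. The solver tolerance (0.1 mmHg on the tissue field) is kept at desk
scale; the few hardest scenarios that stop at a slightly larger residual
are flagged `converged = FALSE` and carried with that flag.

## Worked example

```{r}
library(arteriox)

cfg <- default_config(seed = 1)
cfg$oxy <- list(voxel_um = 30, max_element_um = 100, max_iter = 60)

col <- generate_column(cfg, 1)
network_stats(col)

cal <- calibrate_perfusion(col)
cal$flow

sites <- enumerate_trapping_sites(col, cal$flow)
nrow(sites)

batch <- run_scenarios(col, oxy = do.call(oxy_params, cfg$oxy))
gx <- pixel_gx(batch$scenarios[[1]]$mask,
               matrix(batch$scenarios[[1]]$bead, 1),
               batch$scenarios[[1]]$oxygen$grid,
               baseline_mask = batch$healthy$mask)
gx_crossing(gx, 0.5)
```
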