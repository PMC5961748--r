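---
title: "vaspol: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vaspol: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaspol)
```

This vignette is the package's own account of its science: what each stage
computes, which assumptions it makes, which parameters matter, and where a
design choice was genuinely open. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## 1. From lumen mask to vessel graph

The input is a single-plane binary mask of the vessel lumen, typically a
thresholded maximal-intensity z-projection of a luminal immunostaining.
Working in a projection carries a strong assumption: **all vessels must be
coplanar**. Vessels passing at different depths appear merged, and the
telltale signature is a junction with four or more incident segments —
`diagnose_overlaps()` reports exactly those nodes, and the pipeline turns
them into prominent warnings rather than errors, because the rest of the
network is still usable.

* *Skeletonization* uses iterative Zhang–Suen thinning: topology-preserving,
  8-connected, one pixel wide. Any medial-axis-class algorithm would do;
  the tests pin down behaviour (component preservation, centerline of an
  ideal strip) rather than the algorithm. Components so small that thinning
  consumes them are restored as their distance-transform maximum pixel.
* *Graph extraction* places nodes at skeleton pixels with ≠ 2 neighbours;
  mutually adjacent node pixels are merged into a single junction (so a
  genuine crossing yields one degree-4 node, not two adjacent degree-3
  ones). Redundant diagonal adjacencies (where an orthogonal two-step path
  exists) are dropped first; diagonal steps count √2 px towards length.
  A cyclic component with no branch point is kept as a self-loop edge with
  a warning — it can carry no flow but should not silently vanish.
* *Radii* come from the exact Euclidean distance transform: per edge, the
  median along the centerline of (EDT − 0.5 px) × pixel size, clamped to
  ≥ 0.5 px. The median (not the mean) resists inflation near junctions,
  where the EDT sees the junction blob rather than the vessel. The −0.5 px
  term is the pixel-centre correction: the EDT measures to the centre of
  the first background pixel, half a pixel beyond the wall. A circular
  cross-section is assumed throughout.
* *Pruning* removes terminal edges shorter than `min_spur_factor` (default
  2) × their own radius — the hair-like artefacts thinning produces at
  boundary bumps — then re-merges degree-2 chains, iterating to a fixed
  point so the operation is idempotent. The factor is a free parameter; 2
  radii is roughly the scale below which a "branch" is indistinguishable
  from a boundary perturbation. Pruning that would empty the network is an
  error, not a silent no-op.

One discretization honesty note: a skeleton of *n* pixels spans *n − 1*
steps, so even a zero-erosion centerline of a tube ℓ px long has polyline
length ℓ − 1. Length-recovery tests use the bound ℓ − w − 1 ≤ L ≤ ℓ
(w = tube width) for this reason.

## 2. The 1-D hemodynamic model

Each edge is treated as a straight cylindrical tube in fully developed
laminar (Poiseuille) flow:

* conductance `g = π r⁴ / (8 μ_eff L)`,
* node pressures solve the Kirchhoff balance `Σ Q = 0` with Dirichlet
  (pressure) boundary conditions at user-chosen degree-1 terminals,
* wall shear rate `γ̇ = 4 |Q| / (π r³)`, WSS `τ = μ_eff γ̇`,
* the WSS *vector* at a centerline point is the unit path tangent oriented
  by the sign of Q and scaled by τ.

This is a deliberate reduced stand-in for a resolved 3-D CFD solver. It
preserves what the downstream polarity analyses consume — WSS magnitude
and flow direction — and the boundary-condition design (pressure at inlets
and outlets, which keeps capillary-bed errors bounded when absolute flow
measurements are unavailable). It cannot represent secondary flows,
junction losses, plasma skimming or the Fåhræus–Lindqvist effect; in
vessels narrower than a red blood cell (~8 μm) the homogeneous rheology is
itself questionable. Velocities and WSS should be read as network-scale
patterns, not point predictions.

**Rheology.** Two models: newtonian (`μ` constant; default 3.5 mPa·s, a
standard high-shear blood value, and the right choice for every analytic
test) and Carreau–Yasuda,
`μ(γ̇) = μ∞ + (μ0 − μ∞)[1 + (λγ̇)ᵃ]^((n−1)/a)`. The shipped parameter set
(μ0 = 0.16 Pa·s, μ∞ = 3.5 mPa·s, λ = 8.2 s, a = 0.64, n = 0.2128,
`inst/extdata/rheology_carreau_yasuda.json`) is a standard literature
whole-blood fit — it is a configuration default, **not** a value taken
from the study whose workflow this package re-implements (that study cites
an external reference for its rheology and prints no parameters).

**Fixed-point solve.** μ_eff per edge starts at μ(0) = μ0, each outer
iteration solves the linear network and re-evaluates μ at the new shear
rates with under-relaxation 0.5; convergence is max relative change in Q
below `tol` (default 10⁻⁶), with a hard cap of `max_iter` (default 100,
exceeding it is an error reporting the residual). Zero-flow edges keep
μ_eff = μ0 by construction. The V-A-V fixture converges in ~31 iterations.

**A degenerate bracketing property, kept red.** One acceptance criterion
asserts that the shear-thinning per-edge τ lies between the two newtonian
solutions at μ0 and μ∞. Under *pressure* boundary conditions this bracket
has zero width: scaling a uniform viscosity scales all conductances
equally, leaving the pressure field — and hence
`τ = r Δp_edge / (2 L)` — unchanged, so τ(μ0) ≡ τ(μ∞) edge by edge (the
test suite confirms agreement to ~10⁻¹³). Any viscosity *heterogeneity*
then necessarily falls outside the bracket; on the V-A-V fixture μ_eff
spans 0.004–0.13 Pa·s and τ deviates up to ~2× on low-shear edges. The
criterion is implemented exactly as stated and intentionally left failing;
the meaningful analogue — per-edge |Q| bracketed by the two newtonian
flows, and μ_eff ∈ [μ∞, μ0] — is asserted (and passes) as a module
property test.

**Unperfused structure.** Components without an inlet/outlet pair are
marked unperfused (zero flow, undefined pressure) with a warning rather
than an error; `identify_unperfused()` additionally strips dead-end
subtrees hanging off non-boundary terminals, the structures behind
inaccurate hemodynamics in masks with missing connections.

## 3. Polarity vectors and matching

A cell's polarity vector **p** runs from the nucleus centre to the Golgi
centre (the front–rear axis proxy); cells with coincident points are
flagged, never silently kept. The signed angle θ from the local WSS vector
**t** to **p** is `atan2(t×p, t·p)` in degrees, counterclockwise positive
in image coordinates, with exact antiparallel mapped to +180. The polar
histograms of the source workflow state no sign convention; this one is
fixed and documented, and every statistic downstream depends only on |θ|
or on full rotations, so the choice is inert.

Cells are matched to the *nearest centerline WSS sample* of a
flow-carrying edge, anchored at the nucleus (the cell-position reference
of the delineation protocol). Matching beyond `max_distance_um` (default
25 μm, a few capillary radii) flags the cell unmatched instead of raising
an error; ties break towards the lower edge id. Sampling WSS at the
nearest *surface* point would be the main alternative; at capillary scale
the difference is below the delineation error, and the centerline is where
the 1-D model is defined.

Region labels come from user polygons (even-odd rule, boundary counts as
inside, first label wins on overlap with a warning, self-intersection is
an error).

## 4. The four analyses

1. **Directionality table** — a cell is "against flow" iff
   |θ| ≥ 180° − tolerance (default tolerance 45°, boundary inclusive, so
   the window is exactly a quarter of the circle and a uniform null gives
   ratio 0.25). Empty groups report `NA`, not 0.
2. **Polar histogram + Kuiper tests** — 24 sectors of 15° by default;
   both signed (primary) and folded |θ| variants are emitted. The
   randomness test is Kuiper-vs-uniform: V = D⁺ + D⁻ on
   u = (θ+180)/360, invariant under rotation of all angles — the property
   that makes it the correct circular test (a Rayleigh test is provided as
   a labelled secondary; it only sees unimodal departures). P-values use
   the asymptotic series with Stephens' finite-n correction
   (λ = V(√n + 0.155 + 0.24/√n)); below n = 8, or on request, a seeded
   Monte-Carlo null replaces it. The two-sample version evaluates both
   right-continuous ECDFs at the sorted pooled points (the implicit
   baseline 0 is included, which preserves rotation invariance; identical
   samples give V = 0), uses effective size nm/(n+m) asymptotically, and
   offers a seeded pooled-permutation p-value. Calibration under the
   uniform null (n = 50, 2000 reps) is pinned to a 3.5–6.5 % rejection
   rate at α = 0.05 by the acceptance suite.
3. **WSS sensor curve** — matched cells are binned by ‖t‖
   (*equal-count/quantile* bins by default, n = 8: stable binomial
   proportions at the cost of uneven widths; equal-width and log-width are
   flags), the against-flow fraction is computed per bin, and the
   threshold τ\* is the first crossing of 0.60, linearly interpolated
   between consecutive bin medians (the alternative "first bin at/above
   threshold" is a flag; the source workflow states no crossing rule). A
   curve that never crosses yields `NA` plus a reason, never a fabricated
   threshold.
4. **Scalar-product slopes** — `s = p·t` is regressed on ‖t‖ by OLS
   separately for s > 0 and s < 0 (s = 0 counted apart); slope, intercept,
   Pearson r and n are reported, and subgroups under 3 cells are skipped
   explicitly. The slope estimates ‖p‖cos θ: a larger negative slope means
   stronger against-flow polarization per unit WSS.

## 5. What the synthetic fixtures emulate — and what they do not

`make_tube_mask`, `make_crossing_mask` and `make_vav_plexus` generate
ideal binary masks: exact widths, no imaging noise, no point-spread
function, no segmentation artefacts. The V-A-V fixture reproduces the
*configuration* of a retinal wedge — a central artery (radius 9 μm at the
default 2 μm/px) feeding a staggered capillary lattice (radius 5 μm,
row spacing 88 μm) drained by two lateral veins (radius 11 μm) — with
every junction three-way by construction. Defaults were chosen once, for
realism at desk scale: a 150 Pa inlet–outlet drop lands capillary WSS near
the ~1 Pa literature value for microvessels, and vein > artery > capillary
calibre matches retinal morphology. The absolute pressures are gauge
values, not measurements; the source workflow used adult-mouse central
retinal values it does not print.

`sample_cells` places cells on perfused centerlines (uniform over evenly
spaced samples ≈ length-weighted) and draws θ from a von Mises
distribution with mean 180° — the canonical circular noise model, which
the source workflow implies but never names — with concentration
κ(τ) = κ_max τ/(τ_half + τ). The saturating (Michaelis) form exercises
both the uniform-like low-WSS regime and the strongly polarized high-WSS
regime; defaults κ_max = 6, τ_half = 0.5 Pa put the half-saturation inside
the fixture's capillary WSS range so the demo sensor curve crosses 60 %.
A second response type ("window") makes P(against | τ) exactly linear,
giving the analytically known 60 %-crossing used by the acceptance suite
(`simulate_polarity_pairs` builds such pair tables directly). Generators
are seed-deterministic: same seed, byte-identical cells.

A green end-to-end test therefore establishes that the *computational*
chain is correct on ideal geometry with a stated noise model — not that
the package is robust to real segmentation quality, anisotropic PSFs,
delineation error, or 3-D plexuses (explicitly out of scope).

## 6. Numerical and interface choices

* Pixel coordinates are 0-based, x = column, y = row, origin top-left;
  all physical quantities convert via `pixel_size` at graph construction.
  Flow sign is positive along the stored path orientation (first → second
  node).
* The Kirchhoff system is solved sparsely (Matrix); an independent dense
  solve oracle in the tests agrees to 10⁻¹² on small networks, and
  interior-node imbalance stays below 10⁻¹⁰ of total inflow on the
  plexus.
* Masks travel as ASCII PBM or 0/1 CSV — there is deliberately no binary
  image I/O; networks as GraphML plus flat CSV; configs/results/manifests
  as JSON. Figures are PDF (deterministic headless rendering); because PDF
  embeds a creation timestamp, reproducibility is asserted — and
  guaranteed — over the CSV/JSON outputs, which re-runs from a manifest
  reproduce hash-identically.
* All Monte-Carlo procedures take an explicit seed and restore the
  caller's RNG state.

## 7. Known limitations

* Coplanarity: degree-4 junctions are only *diagnosed*; flow through them
  is still computed as if the vessels truly connected.
* Constant radius per edge (the median): real vessels taper; per-sample
  radii along an edge are retained internally but not used by the solver.
* The Poiseuille model's quantitative WSS in vessels ≲ 8 μm diameter
  inherits all caveats of homogeneous blood rheology.
* The sensor threshold depends on the binning rule when the curve is flat
  near 0.60; both the binning and the crossing rule are explicit
  parameters for that reason.
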