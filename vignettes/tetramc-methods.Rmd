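---
title: "Photon transport and iPDT planning in tetramc: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon transport and iPDT planning in tetramc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the transport model
and its assumptions, the planning formulation, the tunable parameters with
their defaults and units, what the synthetic phantoms do and do not emulate,
and the numerical choices a maintainer would want to know about.

## 1. The transport model

Tissue is a conforming tetrahedral mesh. Every tetrahedron carries an
integer region label, and every region a material record
(`μa`, `μs` in mm⁻¹, anisotropy `g ∈ (−1, 1)`, refractive index `n ≥ 1`).
All geometry is held internally in millimetres; meshes declared in
centimetres are multiplied by 10 once at read time, so the kernels never see
mixed units. Fluence rates are reported in mW cm⁻² (the natural clinical
unit), with the mm→cm conversion applied exactly once in the estimators.

Photon packets follow the standard hop/drop/spin scheme:

* **Hop.** A dimensionless optical step `s = −ln u` is drawn once per
  flight and consumed across tetrahedra as `s −= d·μt`, where `d` is the
  geometric distance to the next event. In a region with `μt = 0`
  (transparent inclusions such as a fluid-filled void) the packet streams
  geometrically and the leftover `s` survives to the next scattering
  region — this is why the track-length estimator (below) is the default.
* **Drop.** At an interaction the packet deposits `w·μa/μt` in the current
  tetrahedron; the new weight is computed as `w − deposit` (not `w·albedo`)
  so the ledger closes to machine precision.
* **Spin.** The scattering cosine is drawn from the Henyey–Greenstein
  inverse CDF. For `|g| < 10⁻⁶` the isotropic branch `2u − 1` is used to
  avoid catastrophic cancellation, and the endpoints `u = 0, 1` are mapped
  to exactly ∓1 (they are analytically forced, since
  `(1−g²)/(1−g) = 1+g`).
* **Interfaces.** When the face ahead separates regions of different
  refractive index, a single RNG draw against the unpolarized Fresnel
  reflectance decides specular reflection versus Snell refraction (packet
  splitting is not used; the single-draw scheme is unbiased and keeps
  weights intact). Total internal reflection falls out of `R = 1` beyond
  the critical angle. Faces between regions with equal `n` are transparent
  to the physics, which is what makes the "matched boundary invisibility"
  test exact. The external mesh boundary is treated as matched: exiting
  energy is scored per boundary face and the packet terminates.
* **Roulette.** Below weight 10⁻⁵ a packet survives with probability 0.1
  (weight ÷ 0.1) or dies; both sides are logged so the expected net effect
  is zero. These are the MCML conventions; they are package defaults,
  exposed in `sim_config()`.

**Conservation ledger.** Every run records emitted, absorbed, exited and
net-roulette energy in extended precision; the residual is a pure
floating-point bookkeeping quantity and is asserted below 10⁻⁹ of the
emitted energy in the test suite (50 randomized configurations).

**Geometry traversal.** Face planes (outward unit normals) are precomputed
per tetrahedron; the exit face is the minimum positive plane intersection.
Intersections within 10⁻⁹ mm are snapped to zero, and after each face
crossing the packet is nudged 10⁻⁷ mm along its direction so that it is
strictly inside the next tetrahedron. Packets that still wedge on a shared
edge or vertex (the failure mode of plane-based traversal) are re-seated by
walking the adjacency graph toward a slightly advanced probe point; a walk
that leaves the mesh scores the packet as a boundary exit. Emission
positions are likewise nudged 10⁻⁶ mm along the initial direction before
point location, so sources placed exactly on mesh vertices (a natural thing
to do with lattice-aligned phantoms) seat correctly. Tetrahedra with volume
below 10⁻¹² mm³ are rejected at construction: they would break the
per-volume fluence estimators.

**Reproducibility.** Emission sampling uses R's RNG under `set.seed(seed)`;
transport uses a xoshiro256++ stream seeded per packet from
(seed, packet index) via splitmix64. Runs are therefore bitwise
reproducible for a fixed seed. `sim_config()` accepts a `threads` field for
interface compatibility, but the kernel is single-threaded; the
deterministic contract is documented as `threads = 1`.

## 2. Fluence estimation

Two estimators are scored in the same pass:

* **Absorption**: `Φᵢ = P·Aᵢ/(μa,ᵢ·Vᵢ)` — exact in expectation, undefined
  where `μa = 0` (flagged `NA` with a warning).
* **Track length**: `Φᵢ = P·Lᵢ/Vᵢ` with `Lᵢ` the weighted path length —
  defined everywhere, lower variance in weakly absorbing regions; the
  package default.

The two agree within Monte Carlo error on homogeneous phantoms (tested), and
the absorption estimator satisfies the exact identity
`Σ μa,ᵢ Φᵢ Vᵢ = absorbed power`.

Dose-volume histograms are survival curves of `Φᵢ/T_region` on a uniform
grid (default 1000 bins), volume-weighted, piecewise-constant per element —
matching the scoring granularity, with no intra-element interpolation.
Threshold comparisons use `≥`; the boundary set has measure zero for real
fields. Fluence (J cm⁻²) versus fluence rate (mW cm⁻²): the engine produces
rate for powers in mW; integrating over exposure time is a workflow-level
multiplication and deliberately not baked into the estimators.

## 3. Planning formulation

Plan evaluation is linear in source powers, so per-source unit-power dose
matrices (`build_dose_matrix()`, one simulation per source with
deterministic sub-seeds `seed + j`) reduce optimization to linear algebra.

The power allocation solves

```
minimize   Σ_{i∈OAR} w_r(i)·Vᵢ·max(0, φᵢ·p − Tᵢ)
         + w_t·Σ_{i∈tumor} Vᵢ·max(0, Tᵢ − φᵢ·p)
subject to 0 ≤ p ≤ p_max
```

a hinge-loss LP. The published planning literature states the coverage goal
(tumor destruction well above 98%) and a tumor-weight input without printing
the exact program, so this concrete formulation is this package's own
interpretation, with the coverage constraint met operationally: if the
solution covers less than `coverage_target` (default 0.98) of the tumor
volume, `w_t` is doubled and the LP re-solved; once bracketed, a
geometric-mean bisection (default 6 steps) finds a near-minimal weight that
meets the target. An unreachable target (at the power bounds, or when some
tumor element received no sampled fluence) is reported explicitly with an
`infeasible` flag — never silently.

**Solver.** There is no large-scale LP library in the package's dependency
footprint, and the per-element slack formulation would be needlessly large
anyway, so the LP is solved exactly in power space by Kelley cutting planes:
the objective is piecewise-linear convex in the few powers, each iteration
adds the supporting hyperplane at the current point and re-solves a tiny
master LP (`boot::simplex`). Two normalizations make this robust at
clinical scales: powers are expressed in units of the median power that
lifts a tumor element to threshold, and the objective in units of its value
at zero power. Convergence is declared at a 10⁻⁹ relative gap between the
best value and the cutting-plane lower bound. A second phase minimizes the
total power among (near-)optimal vectors, which is what makes degenerate
cases deterministic (a single source covering one element returns exactly
`p = T/φ`). Returned powers carry a relative bump of 10⁻⁷ — inside the
solver tolerance — because the LP parks marginal elements exactly on their
thresholds and the `≥` coverage count would otherwise flip on rounding
dust. OAR weights default to 1 per thresholded region; a
`pruning_normalization` factor can scale all thresholds.

**Placement annealing.** `anneal_placement()` perturbs one source position
per iteration with Gaussian jitter (σ defaults to about two mesh cells),
clipped to the tumor region, re-optimizes powers on a reduced-packet dose
matrix, and accepts by Metropolis on the LP objective with geometric
cooling `T_k = T₀·0.95^k` (`T₀` from the initial objective scale). The
best-seen plan is returned; the trace is nonincreasing by construction.
Reduced-packet proposals trade per-proposal accuracy for more proposals;
a final `evaluate_plan()` at full packets gives the honest numbers.

**Surface cap.** `enforce_surface_limit()` scales all powers by
`limit/max` when the composed fluence rate on a designated surface exceeds
the limit; global scaling preserves the relative allocation. The
dose-escalation workflow applies this with the vessel-wall (intima) surface,
defined as the wall-region tetrahedra sharing a face with the lumen, and a
default cap of 300 mW cm⁻² (the thermal-damage limit for vessel walls);
it reports the maximum permissible power per diffuser, the fluence profile
between diffuser midpoints, and the peak-to-midpoint attenuation factor.

## 4. Sources

Six emitter models: point, pencil, cut-end cone fiber (uniform in solid
angle within the half-angle), cylindrical diffuser, ball, surface and
volume-region emitters. Packets are allocated across sources proportionally
to power (stratified, remainders resolved by the seeded RNG — lower variance
than multinomial sampling, still reproducible).

The angular law of "radially emitting" diffusers is not standardized in the
literature; the package default is cosine-weighted (Lambertian) emission
about the outward surface normal, with an isotropic-shell alternative behind
the `emission` flag. Diffuser emission positions honour the physical radius
(lateral surface); the diffuser interior is not carved out as a mesh region
by default, but the nested-cylinder phantom can represent it when wanted.
`discretize_diffuser()` splits a diffuser into equal-length segments with
powers proportional to segment weights; with uniform weights the union of
segments emits identically to the parent (verified distributionally by a
χ² test).

## 5. Phantoms and what the tests do (and do not) show

All test geometries are generated: boxes, slab stacks, spheres, nested
cylinders (lumen + wall) and a tumor+OAR-shell phantom, built from a
hexahedral grid split 6 tetrahedra per cell (Freudenthal decomposition,
conforming across cells) with regions assigned by tetrahedron-centroid
membership. This is deliberate desk-scale fidelity: region boundaries are
staircase approximations (a 20³-cell sphere's volume is correct to ~15%),
there is no mesh grading, no anatomical realism, and no imaging-derived
geometry. Passing tests therefore demonstrate the correctness of the
transport, dosimetry and optimization machinery — conservation, agreement
with closed forms, oracle equality — not the clinical accuracy of any
specific organ model. Real meshes enter through the VTK reader
(legacy ASCII unstructured grids, cell type 10, region labels in a
`CELL_DATA` array whose name is configurable with default `"region"`).

Study conditions used by the bundled analyses and the acceptance script:

* Planning phantom: 60 mm box, sphere tumor radius 10 mm, OAR shell 3 mm,
  15³ cells (20 250 tets; the reduced in-suite variant uses 12³), three
  100 mW interstitial point sources, uniform soft-tissue optics
  `μa = 0.03 mm⁻¹`, `μs′ = 1 mm⁻¹`, `g = 0.9`, `n = 1.4`, fluence-rate
  thresholds 20 mW cm⁻² for tumor and OAR, dose matrices at 2×10⁵ packets
  per source. Per-tissue threshold doses are not standardized in the
  source literature, so they are always explicit user inputs here; the
  values above were chosen once as plausible PDT-scale numbers and the
  coverage result is insensitive to the common scale (powers scale
  linearly).
* Vessel phantom: 30 mm box, lumen radius 2.5 mm, wall to 4.5 mm, one
  10 mm × 1 mm-radius diffuser at a requested 1000 mW, cap 300 mW cm⁻²,
  10⁵ packets. The request is deliberately above the cap so the scaling
  step binds and the reported maximum sits at the cap; the scaled power is
  the "maximum permissible power" of the escalation study.
* Lookup sweep: liver-cube 60×120×60 mm (coarse 6×12×6 cells so elements
  are 10 mm), 2-cm diffuser at 100 mW cm⁻¹, 11 × 11 grid over
  `μa ∈ [0.0005, 0.0631] mm⁻¹`, `μs′ ∈ [6, 11] mm⁻¹` (`g = 0` for the
  sweep material so `μs = μs′`), three interstitial detectors, 10³ packets
  per grid point in the acceptance script and 2×10³ in the in-suite
  recovery experiment (a 40×60×40 mm box with detectors 4.6–6.8 mm from
  the diffuser axis, close enough that every grid point yields a positive
  detector signal at these packet counts). Detector readout is the
  containing element's fluence rate (piecewise constant); a sensor-area
  average would be a straightforward alternative. Inversion minimizes the
  summed squared log-ratio between measured and tabulated signals and
  reports single-detector degeneracy instead of guessing.

Problem sizes in the test suite (diffusion validation at 10⁶ packets on a
27³-cell 80 mm box; Beer–Lambert at 10⁵; HG moments at 10⁶ draws; the rest
at a few × 10³) were chosen so the whole suite completes in minutes while
every statistical assertion keeps ≥3σ headroom.

## 6. Numerical choices, degenerate inputs, limitations

* Face-crossing tolerance 10⁻⁹ mm, crossing nudge 10⁻⁷ mm, emission nudge
  10⁻⁶ mm, degenerate-volume cutoff 10⁻¹² mm³ — all fixed, not exposed:
  they are traversal plumbing, not physics.
* `locate_tetra` uses closed barycentric containment: points on shared
  faces belong to whichever incident tetrahedron the walk reaches first.
* LP determinism: identical dose matrix and configuration give identical
  powers (pure R + deterministic pivoting); tolerance 10⁻⁹ relative.
* Transparent regions flag the absorption estimator as undefined rather
  than returning 0/0.
* Sweep runs abort identifying the failing grid coordinate; a sweep's
  sub-seeds are `seed + run index`, so any single grid point can be
  reproduced standalone.
* Out of scope by design: GPU/FPGA kernels, time-resolved and fluorescence
  transport, polarization, alternative phase functions,
  reinforcement-learning placement, photosensitizer/oxygen kinetics, mesh
  generation from imaging, and any web/cloud layer. The CLI is a thin
  wrapper over the exported functions.

## 7. Validation summary

The test suite asserts: adjacency symmetry and volume closure on generated
meshes; VTK round-trips; locate/exit-face equality with brute-force
oracles; HG moments and χ² distributional agreement plus exact endpoint
mapping; Fresnel energy closure and Snell ratios; conservation (<10⁻⁹
relative) on randomized configurations; Beer–Lambert within 3 binomial
standard errors; diffusion-theory agreement within 10% for r ∈ [5, 20] mm;
estimator cross-agreement; DVH/coverage equality with exhaustive counting;
LP equality with analytic one-source cases, symmetry, and refined grid
search within 1%; 11×11 lookup recovery from noiseless and 1%-noise
signals; dose-escalation cap enforcement; and byte-identical reruns at
fixed seeds throughout.
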