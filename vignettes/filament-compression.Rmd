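---
title: "Two-resolution Brownian dynamics of actin filament compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-resolution Brownian dynamics of actin filament compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filacomp)
```

## The scientific question

Actin filaments bend and twist as cells push and pull on them, and the two
deformations are not independent: because the filament is a helical polymer,
bending it induces axial rotation (twist-bend coupling), which under
compression can express itself as *supertwist* — large-scale helical coiling
of the filament axis, distinct from the internal monomer-lattice twist.
Coarse-grained simulation engines differ in whether they can express this at
all. A fiber-scale model that represents the filament as an achiral chain of
segments has no helical degrees of freedom, so any out-of-plane excursion it
shows is thermal and directionless. A monomer-scale model that encodes the
helical lattice in its bonded interactions can transmit lattice chirality to
the filament's large-scale shape.

`filacomp` implements both resolutions inside one Brownian-dynamics engine,
drives them with the same anchored-end compression protocol, and measures
their shapes with simulator-independent metrics, so the two model classes can
be compared quantitatively — and so that externally produced filament
centerlines (e.g. segmented from tomograms) can be dropped into the same
metric and shape-space machinery through the plain-text trajectory format.

## The two chain models

Both models are bead chains with bonded-only interactions; forces are exact
negative gradients of the total energy.

**Monomer-scale (chiral).** Beads sit on the ideal actin helix: rise 2.74 nm
per subunit, twist −166.7° per subunit (the canonical left-handed short-pitch
lattice), bead track radius 1 nm. The structure is enforced by

* harmonic bonds, $U = \tfrac12 k_b (r - r_0)^2$, between each bead and its
  first and second neighbour in each direction,
* harmonic angles, $U = \tfrac12 k_\theta (\theta - \theta_0)^2$, on
  consecutive triples,
* cosine dihedrals, $U = k_\phi\,(1 + \cos(\phi - \phi_0 - \pi))$, on
  consecutive quadruples. This convention has its minimum at
  $\phi = \phi_0$; we state it explicitly because "cosine dihedral" is
  convention-dependent.

All equilibrium targets ($r_0, \theta_0, \phi_0$) are measured from the ideal
helix, so the ideal structure is a zero-force configuration by construction
(`derive_topology_targets()`). The dihedral targets are what make the chain
chiral: mirroring the reference structure flips their sign and nothing else.

**Fiber-scale (achiral).** A straight chain of 10 nm segments — a discrete
worm-like chain. Stretching bonds (first neighbours only) and harmonic
angles with $\theta_0 = \pi$ and $k_\theta = \kappa/\ell$, so the chain's
persistence length is $L_p = \kappa/k_BT$ exactly in the worm-like-chain
sense. No dihedrals exist, so the chain cannot store or transmit chirality.

## Force-constant calibration

The monomer-scale stiffnesses are not observable one at a time; what is
observable is the filament's persistence length. We calibrated the defaults
($k_b = 100$ pN/nm, $k_\theta = 12{,}000$ pN nm/rad², $k_\phi = 6{,}000$
pN nm) so that the free chain's tangent-correlation persistence length falls
in the 10–25 µm band at $k_BT = 4.1$ pN nm, bracketing the experimental
9–11 µm of ADP-actin. The calibration procedure is reproducible with package
functions:

```{r calibration, eval = FALSE}
gam <- stokes_drag(2, scale = 10)
ch <- build_monomer_chain(length_nm = 120)
th <- thermal_model(4.1, gam, seed = 1)
tr <- simulate_relaxation(ch$ff, th, ch$frame, t_total_s = 1.2e-4,
                          timestep_s = 5e-11, n_frames_out = 60)
persistence_length(list(tr$frames[tr$times > 4e-5]), smooth_window = 13)
```

A structural fact worth recording: in this single-bead-per-monomer zigzag,
bending compliance is dominated by the *dihedral* stiffness, not the angle
stiffness. The zigzag bends by rotating its dihedrals — a discrete version of
twist-bend coupling — so $L_p$ responds nearly linearly to $k_\phi$ and only
weakly to $k_\theta$ or to the order-2 bond stiffness. The flip side is that
bend and twist compliance cannot be set independently in this representation;
their ratio is fixed by the lattice geometry.

## Integrator

Overdamped Euler–Maruyama: each free bead moves by
$\frac{F}{\gamma}\Delta t + \sqrt{2 k_BT \Delta t/\gamma}\,\xi$ with
$\xi \sim \mathcal N(0,1)$ per coordinate. Noise comes from a package-owned
counter-based generator (xoshiro256++ with a ziggurat normal sampler), so a
seed determines a trajectory bitwise regardless of R's RNG state.

Three numerical choices deserve explanation:

* **Protocol substeps.** The fiber-scale protocol timestep is 5×10⁻⁷ s, the
  value used for the translate/relax displacement arithmetic. An explicit
  integrator is unstable at that step for any realistic stiffness (the
  stability bound is $\Delta t \lesssim \gamma/2k$, here ~5×10⁻¹⁰ s), so each
  protocol step is integrated with `n_sub` equal substeps (default 2500).
  The protocol bookkeeping — one translate step, nine relax steps, the
  per-cycle displacement — is untouched by this choice.
* **Monomer timestep.** The monomer chain uses its integration step directly
  as the protocol step. The default 5×10⁻¹¹ s is the largest value found
  stable in a sweep (energy per degree of freedom bounded near equipartition;
  at 1×10⁻¹⁰ s the chain heats catastrophically). At the default step the
  stiffest local modes run slightly hot (~40% excess energy in the bonded
  terms); the long-wavelength shape statistics that the metrics read are
  insensitive to this — the calibrated persistence length is unchanged within
  replicate scatter when the step is halved.
* **Rescaled monomer drag.** Bead drag is Stokes $6\pi\eta r$ with
  $r = 2$ nm, scaled ×10 (`stokes_drag(2, scale = 10)`). The stable timestep
  scales with $\gamma$, and compression at the simulated velocities is deeply
  quasi-static (the bending relaxation time of a 120 nm chain is two orders
  of magnitude shorter than the fastest compression), so inflating the drag
  slows the internal dynamics without moving the quasi-static shape
  statistics, while buying a ×10 larger stable step. Equilibrium ensembles do
  not depend on $\gamma$ at all.

## The compression protocol

The chain lies along +x. The first beads (3 for the monomer chain, 2 spaced
10 nm for the fiber chain — the barbed end) are held fixed; the same count at
the pointed end is translated along −x for one protocol step and then held
while the chain relaxes for nine. The translation distance is
$v\,\Delta t \times 10$, so the moved end advances at the nominal velocity on
average: 7.5×10⁻⁵ µm per cycle at 15 µm/s with the 5×10⁻⁷ s step. The run
stops at the first cycle where the x-projected end-to-end distance reaches
`compression_fraction` × its initial value (70% by default; 500 nm → 350 nm).
Because both anchor groups move deterministically, the stop time is
deterministic and the end-to-end distance decays piecewise-linearly at
exactly the protocol velocity in a zero-temperature run.

## Shape metrics

All metrics accept any ordered point chain (`filament_frame`), resampled
internally at equal arc length.

* **Compression ratio**: $1 - d/d_0$ with $d$ the end-to-end distance —
  normalized by the initial *end-to-end* distance, not contour length.
* **Peak asymmetry**: $|2s^* - 1|$, where $s^*$ is the arc-length fraction at
  the maximum perpendicular distance from the end-to-end chord. 0 for a
  symmetric buckle; defined as 0 (not missing) for a straight chain so time
  series start complete.
* **Non-coplanarity**: $\lambda_3/(\lambda_1+\lambda_2+\lambda_3)$ of the
  3×3 covariance of the points — exactly 0 for planar shapes, at most 1/3.
  Reported raw, without rescaling.
* **Supertwist angle**: the signed angle from the first to the last segment
  tangent, both projected onto the plane perpendicular to the compression
  axis (+x), measured right-handed about the axis; a right-handed coil is
  positive. When a projected tangent is below 10⁻⁶ of the tangent norm
  (straight filament) the metric is undefined and reported `NA`, never 0.
  Per-frame values live in (−180°, 180°]; across a trajectory
  `unwrap_angles()` applies nearest-branch continuity so accumulated coiling
  beyond half a turn is tracked.
* **Persistence length**: least-squares fit of
  $\langle t(s)\!\cdot\!t(s+\Delta s)\rangle = e^{-\Delta s/L_p}$ on the log
  of pooled, binned tangent correlations; per-replicate estimates are
  averaged. A chain whose correlations never decay is flagged rigid
  ($L_p = \infty$), not given a number.

Three practical notes. Monomer-bead chains are smoothed with a centered
13-subunit sliding mean (`monomers_to_axis()`, one helical crossover) before
the shape metrics are taken, which collapses the lattice zigzag onto the
filament axis to within 0.2 nm for the ideal helix. The fiber chain's
outermost anchor bead pins its end segment exactly onto the compression
axis, which would make the supertwist projection identically zero at all
times; the pipeline therefore drops one bead per end (`trim_ends = 1`) so
the first thermally fluctuating segment carries the tangent. End-to-end
distance and compression ratio, by contrast, are always measured between the
*raw* chain's end points — the distance between the filament's ends is the
defining quantity of the compression protocol, and smoothing or trimming
would shift its normalization.

**The ±180° branch point.** A chord-closed *planar* buckle has antiparallel
end-tangent projections: its supertwist sits exactly at the branch point of
the signed angle, and tiny out-of-plane components decide between values near
+180° and −180°. Deeply buckled, nearly planar filaments therefore show
late-time supertwist magnitudes near 180°, and the sign — not the magnitude —
carries the chirality information. This is a property of the
projection-angle definition itself, not of any particular simulator.

## Alignment and the shape space

For shape-space analysis each frame is translated so its fixed end sits at
the origin and rotated about the x-axis only, bringing the point furthest
from the origin in the yz-plane onto the positive y-axis. The rotation is
proper, so chirality is preserved, and x-coordinates, lengths and all metrics
above are unchanged (|supertwist| exactly; its sign too, since the rotation
is about the compression axis).

Aligned shapes are resampled to 50 points — matching a 10 nm segmentation of
a 500 nm filament — flattened to 150 coordinates, and pooled across
simulators, velocities, replicates and time points into one PCA
(`fit_shape_space()`), on centered, unscaled coordinates (they share nm
units). PCA components are sign-ambiguous, so signs are fixed
deterministically: PC1 to correlate positively with compression ratio, PC2
with the chiral model's supertwist; components without a sign feature get
their largest-magnitude loading made positive. `latent_walk()`
inverse-transforms mean ± scores along one component back into 3D chains —
the direct visualisation of what each component encodes.

## The parametric shape generator

`generate_parametric_shape()` produces analytic polylines with ground-truth
metrics attached: straight rods (all deformation metrics zero, supertwist
undefined), planar arcs with an adjustable apex position (known peak
asymmetry, zero non-coplanarity, supertwist at the +180° branch), and
constant-radius helical coils whose end-tangent winding — hence supertwist —
is exact by construction and flips sign under mirroring. These are the
oracles for the metric tests and the fixtures written by
`generate_fixtures()`. They emulate the *geometry* of compressed filaments,
not their statistics: passing metric tests on them validates the measurement
code, not the simulator.

## Study sizes and what the desk-scale comparison can show

The `desk` preset compresses a 120 nm filament (mid-range of 100–150 nm) at
the two fastest protocol velocities (47 and 150 µm/s), five replicates per
condition and model — about 2×10⁷ monomer-scale integration steps per
replicate, minutes on one CPU. The `paper` preset (500 nm, four velocities
4.7/15/47/150 µm/s, five replicates) runs the full-scale protocol
geometry exactly and is available behind `preset = "paper"`; its
monomer-scale runs are hours-long and are not exercised by the test suite.

Scale matters physically, not just computationally. Elastica shapes are
scale-free, but the chirality expression is not: a 120 nm chain holds ~3
helical crossovers against ~13 in a 500 nm filament, and its elastic energies
are ~4× larger relative to $k_BT$, so desk-scale buckling stays close to the
planar branch and the supertwist hugs the ±180° branch point, whereas longer
runs develop genuinely non-planar coiling. The desk-scale comparison is
therefore read through signs and contrasts — directional versus directionless
supertwist, higher versus lower non-coplanarity, late-time PC2 separation —
rather than through coil magnitudes.

On direction: with the canonical left-handed (−166.7°/subunit) lattice, the
chain's emergent coiling is consistently *left*-handed (negative supertwist)
under the package's conventions — +x compression axis, points ordered from
fixed to moved end, right-handed positive angles. The mirrored lattice coils
the other way, as the chirality invariant demands. The absolute sign reported
by any pipeline is convention-bound (flipping the axis orientation flips it);
the reproducible physical statement is that the chiral model picks a
deterministic handedness where the achiral model picks none.

## What the models deliberately leave out

No monomer binding or unbinding, no crosslinkers or motors, no excluded
volume, no hydrodynamic coupling between beads, no reaction chemistry, and no
double-stranded representation of the filament — the helical lattice enters
only through the bonded targets of a single bead chain. Agreement between the
two resolutions here says nothing about regimes those ingredients dominate.

## Degenerate inputs and tie-breaks

Collinear reference structures have undefined dihedrals: deriving a chiral
force field from one is an error, an achiral one is fine (angle targets π).
Coincident consecutive points are rejected with the offending index. A
blow-up (non-finite coordinate) aborts with the cycle index rather than
writing garbage. Straight filaments return supertwist `NA` and peak asymmetry
0. Constant metric columns yield `NA` correlations, never 0. Resampling an
already-uniform chain is exact; endpoints are always preserved bit-for-bit.
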