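---
title: "Partition functions and equilibrium yields for rigid self-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition functions and equilibrium yields for rigid self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the statistical
mechanics it implements, the conventions it fixes where several are
possible, the numerics, and the limits of what its validation can show.

## The model

A **building block** is a rigid body: spheres (the excluded volume) plus
point patches (the specific interaction sites), given in a body frame. A
block has three translational degrees of freedom and, unless it is
*isotropic*, three rotational ones. A **cluster** is a set of blocks at a
local minimum of the total energy

* matching patch types on *different* blocks attract through a smoothed
  Morse well
  `E(r) = E_b (exp(-2 a (r - r0)) - 2 exp(-a (r - r0))) S(r - r0)`,
  with `S` a polynomial switch that is 1 below `r_on`, 0 above `r_cut`, and
  C^1 at both junctions; the minimum value is `-E_b` at `r = r0`;
* sphere centers on different blocks repel softly,
  `H(r) = A/(2.5 d) (d - r)^{2.5}` for `r < d`, with `d` the mean of the
  two diameters. The 2.5 power makes the value and slope (and, at contact,
  the curvature) vanish at `r = d`, so touching spheres contribute nothing
  to ground-state energies or Hessians.

Energies are in units of `kB T` (so `beta` multiplies them), lengths in the
sphere diameter `d` for toy/protein systems or the cage radius `R`.
Defaults follow the reference systems: `A = 500`, `r_on = 0`,
`r_cut = 8/alpha`; `alpha = 5/d` for the toy system (interaction range
`8d/5`), `alpha = 2/d` for protein models (range `4d`), `alpha = 5/R` for
cages. All of these are arguments, not constants.

The cluster's configurational partition function factorizes at the minimum
(Laplace's approximation for the vibrations) into

```
Z_s = exp(-beta E0) * V * (Jtilde / sigma_s) * prod_i sqrt(2 pi / (beta w_i^2))
```

`w_i^2` are the nonzero eigenvalues of the energy Hessian; `Jtilde` is the
orientation integral of the Jacobian of the change of variables from
per-block poses to (center of mass, global rotation, vibrational
coordinates); `sigma_s` counts the rotation/permutation combinations that
map the cluster onto itself.

### Assumptions

1. **Rigidity.** Clusters have no internal zero modes beyond the six global
   ones (`hessian_spectrum()` raises `FloppyCluster` otherwise). The one
   deliberate extension — quartically confined *soft modes* of shell-like
   clusters — is described below and is opt-in.
2. **Harmonic vibrations.** Thermal energy is small against the well depth.
   The exactly solvable dimer quantifies the error (see "Validation").
3. **Ideal solution.** The mass-action system treats clusters as
   non-interacting at their equilibrium concentrations; it is reliable in
   the dilute regime.

## Conventions the package fixes

Several bookkeeping choices are not dictated by the physics (they cancel
from every observable) but must be made *consistently*. The package's
contracts are chart-invariance and agreement with the closed-form anchors;
these pin the following conventions.

**Orientation measure.** All orientation integrals use the
rotation-invariant (Haar) measure with total volume `8 pi^2` per body.
Orientations are sampled as Haar-uniform quaternions (4D Gaussian,
normalized); Euler angles in the fixed-axis x,y,z convention are provided
for interoperability, with a canonical `phi = 0` branch at gimbal lock.
Where the Jacobian is evaluated, exponential-map charts centered at the
evaluation point are used on both sides of the map; at their origin the
Haar density is exactly 1, which is what makes `ln Z` independent of how
the input structure was positioned (tested to MC precision, and to 1e-9
for isotropic clusters).

**The center-of-mass factor.** The Jacobian of the coordinate change
includes the factor `N^{3/2}` from the translation block (its Gram matrix
is `N I`), in both the Monte Carlo route and the inertia closed form
`8 pi^2 sqrt(det I) N^{3/2}`. This is required for the two routes to agree
with each other and with the exactly solvable dimers: the planar benchmark
J = 2 sqrt(2) a cos(phi) contains exactly this `sqrt(N^d)` factor, and the
separated isotropic dimer's assembled `Z` reproduces the one-dimensional
radial Laplace integral only with the `2^{3/2}` included. Linear clusters
use the `4 pi I_perp` branch (five zero modes); point-like clusters
(coincident centers) have no rotational volume at all.

**Free spins.** Isotropic blocks carry no orientation coordinates; their
`8 pi^2` spin volumes are appended uniformly to every structure's
`Jtilde`, so they cancel from yields but keep monomer partition functions
equal between oriented and isotropic conventions.

**Hessian charts.** The default chart is per-block: translation increments
plus left rotation-vector increments. For two-body systems a
`"relative"` chart (unit-Jacobian center-of-mass split) is also provided:
the overlapping isotropic dimer has all three eigenvalues `2 E0 alpha^2`
there, versus `4 E0 alpha^2` with a compensating `2^{3/2}` Jacobian in the
block chart — the assembled `Z` is identical, which the tests assert. This
is worth spelling out because the eigenvalues themselves are
chart-dependent; only the product `Jtilde * prod sqrt(2 pi / beta w^2)` is
physical.

**Symmetry numbers.** For clusters of isotropic blocks, `sigma` is counted
by brute force: candidate rotations are constructed from images of a
reference point pair and accepted if they map the whole (species-labeled)
coordinate set onto itself as proper rotations. Homonuclear dimers give 2,
equilateral triangles 6, tetrahedra 12, the complete icosahedral cage 60.
For oriented blocks the user-supplied value is used (default 1, with a
warning): patch decorations usually destroy geometric symmetries, and a
wrong default would silently bias `Z` by an integer factor.

**Exact derivatives.** Gradients and Hessians of the energy are closed-form
(the chain rule through the rigid-body kinematics: site positions are
`q + R b`, with first and second derivatives of `R` in the rotation-vector
chart written out analytically). Finite differences appear only as test
oracles. Two oracle subtleties the tests document: at a minimum with
coincident patches the pair energy has an `|u|^3` term, so second
differences converge only linearly (the oracle Richardson-extrapolates);
and the `(d - r)^{2.5}` repulsion has a half-power kink at contact that
pollutes finite differences while contributing exactly zero to the true
Hessian.

## Ensembles

**Grand-canonical.** Unknowns are log free-monomer concentrations,
initialized at the totals. The conservation residuals are evaluated with
log-sum-exp; the Newton matrix `J_ab = sum_s N_sa N_sb c_s / sum_s N_sa c_s`
degenerates when a single structure dominates every conservation law, so
the step is Levenberg-regularized and backtracked until the residual norm
decreases. Convergence demands residuals below 1e-8 (typically 1e-12);
yields sum to 1 by construction. Factors of `V` — and any per-length
normalization `lambda` of the partition functions — cancel identically, and
a test asserts bit-identical yields under `Z_s -> kappa^{N_s} Z_s`.

**Canonical.** For closed systems (guarded at 30 particles total) every
cluster multiset satisfying the per-species counts is enumerated; each is
weighted by `M * prod_a Z_a^{N_a}` in the log domain, with the integer
multiplicity `M = prod_i n_i! / (prod_a N_a! prod_{a,i} (N_{a,i}!)^{N_a})`.
The general formula is a package extension of the printed two-species dimer
case `choose(Nb,Nd) choose(Nw,Nd) Nd!`; it is gated behind tests against
that case for all `Nb, Nw <= 9` and against genuinely brute-force labeled
enumeration for small systems. The grand-canonical error for finite systems
decays as a power law in particle number (tested at constant volume and
constant density).

## The reference systems

**Chiral three-sphere monomers.** Two mirror-image species, each three unit
spheres in an equilateral triangle with three uniquely colored patches on
one face. The unique bound dimer has all three patch pairs coincident
(`E0 = -3 E_b`) and exactly six zero modes; with a single patch pair a
seventh (rotation about the patch axis) appears, which the tests use to
exercise the floppy-cluster guard. The finite-size scenario (9 + 9
monomers, `V = 18000 d^3`, range `8d/5`) is the generator default. The
package emits both the exact canonical yield curve and the energy-only
curve `exp(3 beta E_b) / (1 + exp(3 beta E_b))`; their gap is the entropic
cost the package exists to compute.

**The exactly solvable spherical dimer.** Isotropic black/white spheres
binding at zero separation. Its `Z`-ratio is a one-dimensional integral
(`4 pi int r^2 exp(-beta U) dr / V`), so the Laplace error is measurable
exactly: at `beta E0 = 30` the second-order value is low by about 40%, the
radial quartic correction (whose quartic coefficient is the exact rational
`7177/12288 alpha^4` at `r_cut = 8/alpha`, recomputed symbolically for
other cutoffs) lands between the two, and the error in the half-yield well
depth grows with the interaction range. The integral is taken over
`[0, r0 + r_cut]`: the potential's own cutoff is the natural boundary of
the bound region, and without it the integral would diverge for weak
binding.

**Protein complexes.** `coarse_grain_pdb()` makes one sphere per residue at
the unweighted mean of its atom positions (first model,
highest-occupancy alternate locations, hydrogens included when present);
each chain is one rigid block, with coordinates in units of the
residue-sphere diameter `d` (user-supplied; the Angstrom value of `d` is
deliberately left to the user because no physical value is implied by the
model). `place_contact_patches()` puts a uniquely typed patch pair at the
midpoint of each contacting residue pair with strength
`epsilon * p_contact`, so the supplied complex *is* the ground state. Real
contact tables are external inputs; the tests use synthetic complexes whose
interface totals match the reference three-protein system (15.7, 6.7, 1.9),
and the scans reproduce its qualitative three-regime behavior
(monomers, then one dominant dimer, then the trimer, as the energy scale
grows). `interface_rebalance()` implements the constant-total-energy
reweighting of two interfaces.

## The icosahedral cage, and soft modes

Sixty identical isotropic spheres on a shell with icosahedral symmetry. Any
such set is one free orbit of the icosahedral rotation group (orbits with
stabilizers have 12, 20 or 30 points; free-orbit points all share one
radius), and the package generates the orbit that maximizes the minimum
pairwise distance: the snub-dodecahedral arrangement, with bond length
0.4639 R — the printed "0.46 R" — five bonds per sphere, and the next
distance shell (the pentagon diagonals) at 0.7506 R, just outside the
cutoff `r_cut = 0.75 R`. The Morse minimum is set at the bond length, so
*every* pair within the cutoff of *every* nested fragment sits exactly at
its minimum: fragments are exact stationary points with positive
semidefinite Hessians, with zero gradient to machine precision.

That choice has a consequence the package treats head-on: with 150 equal
bonds and 174 internal degrees of freedom, the full shell (and its larger
fragments) keeps zero modes beyond the six global ones — collective flexes
of the non-triangulated faces, plus hinge modes of spheres attached by two
bonds during growth. These are not harmonic vibrations (their stiffness is
quartic or flat), and a strictly harmonic pipeline would have to reject the
system outright. We verified that the alternatives are worse: bracing the
shell by pulling the diagonals inside the cutoff puts them on the concave
tail of the switched Morse well, where the second-order length changes of
the flexes couple to the attractive slope and the shell is not even
metastable (numerically, relaxation collapses it to a saddle). Short-ranged
pair attraction simply does not make a one-shell icosahedral cage
mechanically rigid.

The package's treatment: a **soft mode** is integrated explicitly over the
interval of mode displacements within which the cluster keeps its bond
topology — the same region that defines the cluster in the first place
(fluctuations that change which pairs are bonded belong to a different
cluster). Pair distances are exact quadratics in the mode coordinate, so
the window boundaries are closed-form roots; within the window the energy
profile is evaluated on a grid and `int exp(-beta dE) dt` replaces the
divergent harmonic factor, mode by mode. Three approximations are
documented rather than hidden:

* modes are treated independently in an orthonormal basis of the soft
  subspace (the basis inside a degenerate kernel is arbitrary; the
  independent-mode volumes are basis-dependent at the percent level in
  `ln Z`, which the tests assert explicitly);
* displacement is along straight chart lines, not the curved mechanism
  path, which biases hinge volumes slightly low;
* couplings between soft modes are neglected.

`FloppyCluster` remains the default contract everywhere;
`soft_modes = "integrate"` is opt-in and is what the cage drivers use.

**Growth and scenario.** The nested growth path adds one random sphere with
at least two bonds to the current fragment (the dimer being the flagged
linear exception); with the soft-mode treatment no extra rigidity filter is
needed and the rule is implemented verbatim. The scan grids default to
well depths 2–20 kT — which brackets the monomer-to-cage transition for
every default concentration — and totals `1e-7, 1e-6, 1e-5 R^-3`. The
dilute range is where the ideal-solution mass-action treatment is reliable,
and it is the regime consistent with the reference observation that no
intermediate ever becomes prevalent; at substantially higher totals
(`1e-4 R^-3` and above) this package's soft-mode entropics let small
oligomers reach percent-level yields near the transition, which we report
as a model property rather than tuning away. Within the defaults the
maximum intermediate yield comes out at a few 1e-3, dominated by dimers at
the transition — the reference order of magnitude.

Depth scaling is used to make scans cheap: the cage has no repulsion and
one interaction type, so `E0`, the stiff eigenvalues and the soft-mode
profiles all scale linearly in the well depth and are precomputed once
(`cage_partition_parts()`), after which any `(epsilon, c)` grid point costs
one scalar root-find.

## Numerical choices

* Zero-mode threshold: `|w^2| < 1e-8 * max |w^2|`, configurable; the stiff
  spectra here separate zeros from the softest genuine modes by >10 orders.
* Minimization (`minimize_and_check()`): damped Newton with retraction
  (poses are updated and the chart re-centered each step), Levenberg
  fallback when the Hessian is indefinite, gradient tolerance 1e-8, basin
  guard on the accumulated step; a vanishing Hessian at convergence (no
  binding) is reported as not-a-minimum.
* Monte Carlo orientation integrals: default `1e5` samples (standard errors
  are reported and propagate into the test tolerances: cross-route and
  invariance checks pass at 3 combined standard errors); the seed is
  mandatory, every output row carries it, and sampling restores the
  caller's RNG state.
* Quadratures (`integrate()`): relative tolerance 1e-10; large well depths
  are handled in the log domain with the depth factored out of the
  integrand.
* The mass-action solver is deterministic given inputs; its residuals are
  returned with every solution.
* Geometry searches (the snub orbit) use a fixed internal seed unrelated to
  any physics seed, are cached per session, and reproduce the same
  coordinates for every growth seed.

## What the generators do and do not emulate

The built-in systems are *models of models*: they reproduce the geometry,
energetics and ensembles of the reference systems exactly as specified, and
the validation shows the statistical mechanics is implemented correctly
(closed forms, cross-route agreement, ensemble consistency). They do not
contain conformational flexibility, solvent, electrostatics, polydispersity
or kinetics; passing tests say nothing about whether a rigid
pairwise-additive model describes any particular experimental system. For
proteins in particular, contact tables and the residue-sphere diameter are
inputs, and the absolute energy scale `epsilon` is a free parameter to be
swept, not predicted.

## Known limitations

* Floppy clusters with extended zero-mode manifolds are out of scope; the
  soft-mode quadrature covers bounded flexes/hinges only, with the
  approximations listed above.
* Anharmonic corrections beyond the radial quartic special case are not
  implemented (the machinery to do so per mode exists but the general
  fourth-order Laplace correction with Hessian inverses does not).
* Structure lists are inputs: the package does not enumerate all complexes
  a set of species could form.
* Mixed oriented/isotropic clusters take the Monte Carlo rotational route
  only; linear clusters of oriented blocks are unsupported.
* Canonical enumeration is exhaustive and guarded at 30 particles.
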