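---
title: "Membrane tubes from polymerizing filaments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane tubes from polymerizing filaments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

memtube simulates how growing semiflexible filaments (actin, in the
motivating experiments) push a fluid membrane into tubular protrusions,
and provides a reduced stochastic theory for the rate-limiting step of
that process, the single-filament bending transition. This vignette is
the package's own account of the models, the numerical choices behind
them, and what the tests do and do not establish.

## The membrane model

The membrane is a dynamically triangulated surface: a periodically
replicated patch of vertices (nodes) in a box of lateral size
`Lx x Ly`, triangulated with consistent orientation, torus topology
(Euler characteristic 0), fluctuating freely in `z`. Its energy is the
discretized Helfrich functional

    E = sum_v [ (kappa/2) (2 H_v)^2 + gamma ] A_v

with bending rigidity `kappa` (kT), tension `gamma` (kT/nm^2), the
per-vertex mean curvature `H_v` and barycentric area share `A_v`
(which partitions the total area exactly). Lengths are nm, energies kT.

**Curvature discretization.** `H_v` is the edge-dihedral (Juelicher-type)
form, `H_v = sum_e l_e theta_e / (4 A_v)`, summing the signed dihedral
angles `theta_e` of the one-ring edges. We initially used the
cotangent-Laplacian mean-curvature normal; it is exact on smooth
oracles, but on the irregular meshes that grand-canonical sampling
explores it admits near-cancellations on slivers and thin necks, which
showed up as unphysical crumpled and string-like states carrying almost
no discrete bending energy. The dihedral form is positive-definite in
folds and removes those states entirely, while remaining convergent on
the continuum oracles: a fine triangulated sphere gives `8 pi kappa`
within 0.5% and a triangulated cylinder matches
`(kappa/2) (2H)^2 A` to 0.1% (both are unit tests). The same
`H_v` is exposed as the curvature observable (`vertex_geometry()`).

**Constraints.** Edges are tethered to `[a_min, a_max]` (defaults 4 and
12 nm). Non-bonded membrane node pairs exclude `d_mem = 5` nm;
edge-connected neighbours form the continuous sheet and are governed by
the tether floor instead -- the same overlapping-bead logic used for
filaments. (Applying the 5 nm core to bonded pairs would make
grand-canonical insertion geometrically impossible: a vertex inserted
near the centroid of a typical triangle necessarily sits closer than
5 nm to its new neighbours.) A triangle shape guard (all angles below
135 degrees, area above 1 nm^2) keeps the discrete curvature operator
on meshes it can represent faithfully. Membrane-filament pairs exclude
`(d_mem + d_fil)/2 = 7.5` nm and filament-filament pairs `d_fil = 10`
nm (chain neighbours within four nodes exempt). All pair checks run
through a periodic cell list.

**Why the tether band is wide.** `a_max = 12` with typical edges near 8
is needed twice over: insertions must fit a new vertex at least
`a_min` from three corners, and edge flips -- whose new diagonal runs
near sqrt(3) times the typical edge -- must succeed often enough to
keep the surface fluid. With a narrow band (`a_max = 9`) flips all but
stop, the connectivity quenches, and the patch behaves like a
polymerized membrane whose effective rigidity grows toward long
wavelengths; the height-fluctuation spectrum then falls well below the
Helfrich prediction at low q. With the default band the fixed-count
spectrum matches `<|h_q|^2> = kT / [A (kappa q^4 + gamma q^2)]` on the
low-q mode shells (the spectrum check of the physics test
suite). One caveat of scale: the single
lowest mode of a 400-vertex patch relaxes on a timescale comparable to
the affordable run length, so its amplitude estimator carries order-one
autocorrelation error and is only loosely constrained; the 3-sigma
comparison uses the next shells (still wavelengths of 70-110 nm), whose
relaxation times sit 4-16x inside the run.

## Grand-canonical sampling

One sweep attempts, per vertex: one displacement (uniform in a cube,
amplitude auto-tuned to 30-50% acceptance during warm-up and frozen
afterwards), one edge flip, and 0.1 insertion plus 0.1 removal attempts
(insertion and removal equally often). Displacements and flips use
Metropolis acceptance `min(1, exp(-dE))` on top of the hard
constraints.

Vertex exchange works against the grand-canonical weight
`z^V exp(-E)`, with the fugacity `z` measuring the implicit lipid
reservoir (one unit of proposal volume = 1 nm^3). Insertions pick a
random triangle and propose the new vertex uniformly in an oriented
cylinder about its centroid -- a disk of radius `r_ins = 2.5` nm in the
triangle plane (in-plane placement is cheap in bending energy) with
half-thickness `h_ins = 0.7` nm along the normal. Removals pick
uniformly among the removable vertices (3-coordinated, mobile, inside
the reverse-insertion cylinder of their own ring), maintained in an
incremental candidate list. The acceptance ratios

    insert: min[1, z * F V_ins / N_rem' * exp(-dE)]
    remove: min[1, (1/z) * N_rem / (F' V_ins) * exp(-dE)]

(`F` triangles before insertion, `N_rem` removable vertices counted in
the state where removal is attempted, `V_ins` the proposal volume)
satisfy detailed balance by construction; the operational check in the
test suite is the reweighting identity -- the ratio of stationary `V`
histograms at two nearby fugacities is `(z1/z2)^V` for *any*
configurational weight -- plus stationarity of `V` after equilibration.

**Tension from fugacity.** At fixed frame, the fugacity sets the vertex
density and hence the membrane tension. The package measures
`gamma(z)` from the low-q height spectrum of grand-canonical flat
patches and fits the incompressible-reservoir form `z = C
exp(-gamma/(rho kT))`; `default_calibration()` ships the measured curve
for the default parameters (kappa = 20, 100 nm patch; `C` and `rho`
are specific to this proposal scheme and discretization, so their
numerical values are not comparable across implementations). The
mapping is monotone and close to log-linear over the tension range of
interest (about -0.02 to +0.06 kT/nm^2), which is the functional-form
content of the calibration check in the physics test suite.

**Tube-state calibration.** A strongly curved tube feels a slightly
different chemistry than a flat patch (insertion proposals couple to
local curvature), which shifts the effective tension by about +0.01
kT/nm^2 at the default parameters. Experiments on held tubes therefore
use a fugacity calibrated directly on tube radii through the
zero-temperature relation `gamma = kappa/(2 R^2)` -- the same
calibration route the tube relation itself suggests, and the analogue
of calibrating against pulled-tube radii rather than flat-patch
spectra. The shipped tube-route working point for `gamma = 0.01`,
`kappa = 20` is `z = 0.012`.

## Tube experiments

`R0 = sqrt(kappa/(2 gamma))` and `f0 = 2 pi sqrt(2 kappa gamma)` are
the zero-temperature radius and asymptotic pulling force of a membrane
tube. Pulling a tube out of a flat patch with a harmonic spring
(attached to the mean height of a small central vertex disk, as in
optical-tweezer experiments) reproduces the qualitative
force-extension shape -- rise, peak, slow decay toward `f0` -- but the
tube radius is the slowest-relaxing observable: it equilibrates only
as fast as the reservoir supplies area, far too slowly for desk-scale
runs. The equilibrium measurement therefore starts from a pre-formed
tube (`build_tube_patch()`: a stitched cylinder-plus-hemispherical-cap
initial condition with all edges inside the tether band), holds the cap
with a soft spring, and samples radius and force
(`tube_equilibrium_experiment()`). Starting at the presumed minimum is
a hot start, not an answer: a wrong Hamiltonian or acceptance rule
drives the state away from the construction, and the drift is exactly
what the measurement would report. At the shipped working point the
held tube keeps `R` within a few percent of `R0` and the force settles
near `f0` (the held-tube check of the physics test suite); the
residual force excess of order 5%
is consistent with the finite tube length (`L/R` about 5).

## Filaments and growth kinetics

Filaments are discrete worm-like chains: nodes every
`delta = 2.7` nm (the length increment per polymerized monomer), bending
Hamiltonian `(Lp/delta) sum_i (1 - t_i . t_{i+1})`, persistence length
`Lp = 15` um by default, 10 nm beads forming a smooth excluded tube.
The first segment is clamped (fixed base position and orientation);
the last node is the barbed end. Monte Carlo moves are pivots (rotate
the tail beyond a random joint about a random axis) and crankshafts
(rotate an interior arc of 2-6 segments about its chord); both are
exact rigid rotations, so segment lengths are preserved to machine
precision, and both leave the base untouched. Sampled tangent
correlations reproduce the discrete-model closed form
`<t_i . t_{i+s}> = (coth(k) - 1/k)^s`, `k = Lp/delta`, which converges
to `exp(-s delta/Lp)` for `Lp >> delta`.

Polymerization is kinetic Monte Carlo: reaction times are exponential
with total rate `N_fil (kon0 + koff)`; the filament and channel are
drawn proportionally to their rates; growth appends a segment along
the barbed-end tangent (locking in the acquired curvature) and is
accepted exactly when excluded volume permits -- otherwise the attempt
is a null event and only the clock advances. Between events,
`nu * dt` configurational sweeps of membrane and filaments run
(`nu = 100` per `1/kon0` by default, chosen so the resolved membrane
modes of a desk-scale patch equilibrate in a small fraction of
`1/kon0`; a sensitivity check doubling `nu` is part of the acceptance
suite). Default `koff/kon0 = 0.01` reflects typical in-vitro actin
conditions; time is measured in units of `1/kon0` throughout.

A single rigid filament growing against the patch is the
polymerization-ratchet control: its acceptance ratio `kon(n)/kon0`
falls with the membrane restoring force as `exp(-f(L) delta / kT)` and
net growth stalls where the ratio meets `koff/kon0` (the ratchet check of the physics test suite).

## The reduced bending-transition model

A filament far from a nascent bundle sees, to first approximation, a
static tilted membrane: relative angle `theta`, base-membrane distance
`L0` along the plane normal. Working in the membrane frame (flat
membrane, tilted filament -- identical physics, compatible with
periodic boundaries), the filament grows freely to the contact index
`n_c = floor(L0/(delta cos theta) - 1)`; each further monomer needs a
clearance fluctuation. The model components:

* **Ground state** (`gap_profile()`): the planar minimum-bending-energy
  shape of the clamped n-segment chain constrained below the plane,
  found by BFGS with an escalating quadratic penalty and warm starts in
  n. The required clearance is the height the collinearly added monomer
  would protrude, `delta cos(phi_tip)`; the absorbing index `n_star` is
  where the ground-state tip tangent is parallel to the plane within
  `parallel_tol` (cosine 0.05), after which growth is unimpeded. In the
  head-on geometry (`theta = 0`) transverse bending gives no
  first-order clearance: the clearance grows by `delta` per monomer and
  `n_star` is infinite.
* **Gap probability** (`p_bend()`): a Gaussian-tail estimate using the
  two softest modes -- the clamped filament's transverse tip mode
  (variance `l^3/(3 Lp)`, projected on the plane normal through the
  ground-state tip angle) and the local membrane height (variance =
  the discrete mode sum of the patch between the patch-size and
  mesh-resolution cutoffs) -- multiplied by the Boltzmann factor of the
  ground-state bending-energy increment the accepted monomer locks in.
  The elastic increment is what makes poorly aligned filaments
  exponentially slow to recruit; without it the model predicts a
  nearly flat MFPT landscape, with it the map spans many orders of
  magnitude and is steep in `theta`, as it must be.
* **Master equation** (`evolve_master_equation()`): the birth-death
  system `dP(n)/dt = koff[P(n+1) - P(n)] + kon(n-1)P(n-1) - kon(n)P(n)`
  with `kon(n) = kon0 p_bend(n)`, reflecting at n = 1 (the base never
  depolymerizes) and absorbing at `n_star`, integrated with `lsode`
  (rtol 1e-10); probability plus absorbed mass is conserved to better
  than 1e-8. First-passage density = flux into the absorbing state;
  the mean is checked against the closed-form birth-death recursion
  (`h_1 = 1/kon(1)`, `h_k = (1 + koff h_{k-1})/kon(k)`) to 1e-6
  relative, and both against a continuous-time simulation of the same
  chain (10^5 replicas, compiled Gillespie).

The end-to-end check runs the explicit simulation of the same scenario
(`run_tilt_experiment()`: flat fluctuating membrane at the matched
height -- the steric wall for filament nodes sits exactly `L0` above
the base -- with a tilted clamped filament) and compares both the
pooled acceptance fractions per monomer count against `p_bend(n)` and
the first-passage times to the absorbing count against the master
equation (the matched-simulation check of the physics test
suite). The absorbing count is capped at
`n_c + 30` so the bent filament stays clear of its own periodic image
at the default patch size.

## Synthetic initial conditions

`generate_initial_condition()` is the generator behind the ensemble
experiments: uniform random lateral base positions (rejection-sampled
to respect the filament hard core), polar angles half-Gaussian with
standard deviation `std` about the membrane normal (`std = 0`
reproduces the perpendicular ensemble), azimuths uniform, bases 50 nm
below the membrane, everything reproducible from one seed. It emulates
the geometry of filaments nucleated under a vesicle membrane. It does
not emulate branching, capping, crosslinking, monomer depletion, or
any correlation between neighbouring filament orientations -- so
passing tests say nothing about those aspects of real networks, only
about the membrane-mediated cooperativity of independent nucleators.

## Scaled-down study conditions

The headline ensemble results (50 trajectories, 200-300 nm patches,
260 nm tubes, times to 2500/kon0) are cluster-scale. The test and
acceptance runs use desk-scale reductions, chosen once as the largest
sizes that keep the full suite within ordinary interactive budgets,
and stated here as the package's study conditions:

* spectrum: 146 nm patch (about 400 vertices), 60k production sweeps;
* tube observables: 140 nm box, L = 150 nm held tube, 25-40k sweeps;
* calibration: 80-100 nm patches, 3 fugacities, 25k sweeps each;
* ratchet: 120 nm patch, one rigid filament, 400/kon0;
* bending transition: 140 nm patch, 6-8 replicas to `n_c + 30`;
* screening: 100 nm patch, 8 filaments, paired seeds, waiting time to
  a 12 nm protrusion and the count of filaments protruding above the
  frozen plane (a 260 nm tube cannot form at this scale; the ordinal
  comparison is the scaled content of the full experiment);
* load sharing: clustered bundle of 4 rigid filaments versus a lone
  filament at the tube working point.

## Known limitations

* `C` and `rho` of the fugacity calibration are scheme constants; only
  the functional form and the measured tensions transfer.
* The flat-patch and tube-state calibrations differ by a
  curvature-coupled chemical offset; experiments state which working
  point they use.
* The reduced model's `p_bend` is a two-mode Gaussian with a locked-in
  elastic increment -- a closed-form stand-in validated against the
  explicit simulation at desk scale, not derived from the full
  configurational measure.
* No Gaussian-curvature term, spontaneous curvature, hydrodynamics,
  crosslinkers, capping or branching; topology is fixed (no fission,
  fusion or poration).
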