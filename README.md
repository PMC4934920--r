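# memtube

Monte Carlo simulation and stochastic theory for membrane tubes built by
polymerizing filaments.

Cells grow tubular membrane protrusions (filopodia) by polymerizing stiff
actin filaments against a comparatively soft membrane, and reconstituted
systems show that tubes can emerge without any bundling proteins: the
membrane itself mediates an effective attraction that collects individually
polymerizing filaments into a cooperative bundle. memtube provides the
computational pieces needed to study that mechanism quantitatively at
desk scale:

* a **dynamically triangulated membrane** patch (periodic, fluid,
  self-avoiding) with the discretized Helfrich energy
  `E = sum_v [ (kappa/2)(2 H_v)^2 + gamma ] A_v`, sampled by
  Metropolis Monte Carlo (vertex displacements, edge flips);
* a **grand-canonical vertex exchange** that couples the patch to an
  implicit lipid reservoir: insertions/removals accepted against the
  weight `z^V e^{-E}`, with the fugacity mapping to surface tension via
  `z = C exp(-gamma/(rho kT))`;
* **worm-like-chain filaments** (segment length `delta = 2.7 nm`,
  persistence length 15 um, clamped bases, crankshaft/pivot moves) with
  sterically gated **kinetic Monte Carlo** (de)polymerization - a
  polymerization attempt succeeds exactly when the fluctuating membrane
  can accommodate the new monomer, which yields the Brownian-ratchet
  rate reduction `kon(n)/kon0 ~ exp(-f(L) delta / kT)`;
* the **reduced bending-transition model**: a birth-death master
  equation `dP(n)/dt = koff[P(n+1)-P(n)] + kon(n-1)P(n-1) - kon(n)P(n)`
  whose rate ladder `kon(n) = kon0 P_bend(n -> n+1)` comes from the
  equilibrium probability of gap-opening fluctuations under a tilted
  membrane, with first-passage densities, closed-form mean first
  passage times, and the MFPT landscape over tilt angle and distance;
* observables and experiment drivers: tube radius/force
  (`R0 = sqrt(kappa/(2 gamma))`, `f0 = 2 pi sqrt(2 kappa gamma)`),
  height-fluctuation spectra, fugacity calibration, filament bundle
  classification and alignment profiles, frozen-node screening and
  load-sharing experiments, OFF/PLY/VTK mesh output, and a `memtube`
  command-line front end (`inst/cli/memtube`) driven by YAML configs
  (`inst/examples/`).

Units throughout: lengths in nm, energies in kT, forces in kT/nm
(1 kT/nm is about 4.1 pN), times in units of the bare polymerization
attempt time 1/k_on0.

## Worked example: how long until a misaligned filament joins a bundle?

A filament anchored 60 nm beneath the membrane at 45 degrees to its
normal grows freely, stalls when its straight path meets the membrane,
and must wait for bending fluctuations to carry it into the tangential,
freely-growing state. The reduced model computes the waiting-time
statistics directly:

```r
library(memtube)

s <- tilt_scenario(theta = 45, L0 = 60)    # kappa = 20, gamma = 0.01, Lp = 15 um
lad <- rate_ladder(s, kon0 = 1, koff = 0.01)
c(contact = lad$n_c, absorbing = lad$n_star)
#>   contact absorbing
#>        30        78

fp <- first_passage_stats(lad)
round(c(mfpt = fp$mfpt, closed_form = fp$mfpt_closed), 2)
#>        mfpt closed_form
#>      137.26      137.26

M <- mfpt_map(theta_range = c(15, 30, 45), L0_range = c(40, 60),
              base = s)
signif(M, 3)
#>     theta
#> L0         15       30  45
#>   40 1.12e+49 4.78e+14 291
#>   60 3.18e+19 1.46e+03 137
```

Reading: growth is free up to 30 monomers; the bent escape state is
reached at 78 monomers; the mean waiting time is about 137 attempt
times, and both routes to it (integrating the first-passage density and
the closed-form birth-death sum) agree. The map shows why network
architecture matters: tilting the same filament from 45 to 15 degrees
slows its recruitment by tens of orders of magnitude - bundling
effectively selects filaments whose orientation is compatible.

The same scenario can be simulated explicitly
(`run_tilt_experiment()`): six desk-scale replicas of the fluctuating
membrane + filament simulation gave first passage times to the
60-monomer mark of 80-122 attempt times (mean 100 +- 7) against a
master-equation value of 115 for the same target - the agreement
behind the reduced model.

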