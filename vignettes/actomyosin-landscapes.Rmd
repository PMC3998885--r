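---
title: "Coarse-grained actomyosin landscapes and stepping dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained actomyosin landscapes and stepping dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`motorscape` models the motion of a myosin II head (S1) on an actin
filament at two coupled levels: a residue-level structure-based model whose
Langevin dynamics, umbrella sampling and WHAM produce state-dependent
free-energy landscapes of the motor-domain position, and a kinetic Monte
Carlo walker that diffuses on those landscapes while hopping among the
actomyosin chemical states. This vignette documents the model, its
parameters and defaults, the numerical choices, what the synthetic
generators emulate, and the known limitations.

## The molecular model

Each polypeptide chain is a string of beads at the C-alpha positions;
bound ligands (Mg + ADP, and Pi in the pre-hydrolysis states) are kept as
all non-hydrogen atoms. The actin filament is generated from one subunit
by the screw operation of 166.4 degrees and 2.759 nm per subunit, so the
13-subunit repeat is 35.867 nm long with a 3.2 degree net twist. The
filament axis is z (plus end toward +z) and the azimuth theta is measured
about it.

The potential separates into intra-molecular structure-based terms (the
reference structure is the exact minimum of each), interface terms, and
restraints:

* bond angles `k_a (theta - theta0)^2`, `k_a = 6.67` kcal/mol/rad^2;
* dihedrals `k1 [1 - cos(phi - phi0)] + k3 [1 - cos 3(phi - phi0)]`;
* native 12-10 contact wells `eps [5 (r0/r)^12 - 6 (r0/r)^10]` for residue
  pairs with at least one heavy-atom pair within 4.5 A in the reference
  structure (intra-chain pairs additionally need sequence separation >= 4,
  a conventional value since the printed rule does not state it);
* nonnative `(C/r)^12` repulsion, `C = 4.0` A, truncated at 10 A;
* ligand springs `k (r - r0)^2` (`k = 6.67` kcal/mol/A^2) for ligand-ligand
  and residue-ligand pairs within 4.5 A;
* interface Debye-Hueckel electrostatics with residue charges -1 (Asp,
  Glu), +1 (Lys, Arg), +0.5 (His; configurable, the printed value is not
  legible), -1 per charged phosphate oxygen and +2 for Mg, truncated at
  59.3 A, which we interpret as the electrostatic cutoff radius;
* interface 12-6 Lennard-Jones wells of depth 0.015 kcal/mol at 8.0 A;
* the curtain rail: each lever-arm-tip residue is tied (k = 0.2
  kcal/mol/A^2, half-k-x^2 convention) to the helical line through its own
  reference position, twisting 3.2 degrees per 35.867 nm so that the
  restrained system retains the filament's screw symmetry, with zero force
  along the rail;
* harmonic anchors on every actin residue (k = 1.33 kcal/mol/A^2 by
  default; the printed value is masked).

The dihedral amplitudes and contact depths follow the canonical Go-model
ratios angle : dihedral-1 : dihedral-3 : contact = 20 : 1 : 0.5 : 1 scaled
to `k_a = 6.67` (the printed magnitudes are not legible); every constant is
a `forcefield_params()` field and the resolved values are stored in run
metadata.

**Spring continuations.** To keep the Langevin integration stable, the
steep cores of the 12-10 and 12-6 terms are replaced below a switch
distance by a spring of stiffness 1.33 kcal/mol/A^2 that matches the pair
potential in value and slope; the switch sits where the pair force equals
the force of that spring anchored at the pair minimum. The purely
repulsive nonnative term has no minimum to anchor such a spring, so its
continuation engages at 0.8 of the excluded-volume diameter. Both rules
make the potential C1; the energy tests verify value and one-sided
derivative continuity at the switch.

**Electrostatics calibration.** The Debye length of a 1:1 electrolyte is
`sqrt(eps_r eps0 kB T / (2 NA e^2 c))`. We calibrate the relative
permittivity once so that 25 mM at 300 K gives exactly 1.9 nm (the
calibrated value, 76.1, is close to water at 300 K); the inverse square
root law then gives 0.95 nm at 100 mM. The Coulomb prefactor is
332.06/eps_r kcal A/mol.

**Flexibility.** Residues flagged flexible (disordered loops such as
loop 1 205-215, loop 2 627-646, loop 3 572-574 of the heavy chain, and the
actin N-terminus) keep their bond constraints and excluded volume but are
excluded from angle, dihedral and native-contact terms, so they fluctuate
without the guidance of the structure-based potential. Salt concentration
and the flexible-region lists are plain configuration, which is how the
flexibility and ionic-strength perturbation studies are set up.

## Langevin sampler

The integrator is velocity-Verlet Langevin (BBK discretization) with mass
1.0, time step 0.0175 and friction 0.005 in reduced units at 300 K.
Virtual bonds are constrained to their reference lengths by RATTLE
(relative tolerance 1e-12 on the squared lengths, i.e. well below 1e-6 A);
velocities are initialized from the Maxwell-Boltzmann distribution and
projected onto the constraint manifold. The mapping from reduced to
physical time is left symbolic; physical time enters only through the
Monte Carlo timescale estimate below.

Umbrella windows bias the motor-domain centroid with
`1/2 k_z (z - z_c)^2 + 1/2 k_th wrap(theta - theta_c)^2`
(`k_th = 10` kcal/mol/rad^2; `k_z` is not printed, the package default
0.01 kcal/mol/A^2 gives window widths comparable to the 60-window spacing
of one repeat split 20 x 3). Each window runs 12 independent replicas and
discards the first half of every series, both configurable.

## WHAM with helical replication

Window histograms on the `(z, theta)` grid (default bins 0.1 nm and
2 pi/72; the printed bin sizes are masked) are combined by the standard
WHAM equations. The window constants are obtained by damped Newton
minimization of the (convex) WHAM negative log-likelihood, followed by the
classical self-consistent iteration, which supplies the convergence
criterion (maximum change of the window free energies below `tol` kT) and
a monotone convergence diagnostic. Bins never sampled are reported missing
rather than extrapolated, and the landscape gauge puts the global minimum
at zero.

Sampling a single repeat leaves the landscape aperiodic through boundary
effects. Following the helical-replication idea, the window data are
replicated as `(z + nL, theta + n tau)`, `n = -2..2` (five data sets in
total, `L = 35.867` nm, `tau = 3.2` degrees). The package ties the five
copies of each window together by giving the window the log-mixture bias
of its five helical images: this is exactly the statement that a window
and its screw-translated image are the same thermodynamic state, it makes
the solved landscape periodic by construction in the covered interior,
and it removes the slow relative drift of weakly coupled copies that a
naive 5K-window solution exhibits. `periodicity_residual()` quantifies
the remaining violation; on sampled bins (>= 50 counts) of the synthetic
oracle problems it is below 0.1 kT.

## The kinetic network and Monte Carlo stepping

The eight actomyosin states are A.Mpre.ADP.Pi, A.Mpost.ADP.Pi, A.Mpre.ADP,
A.Mpost.ADP, A.Mclosed.ADP, A.Mpost, A.Mclosed and the absorbing A.Mrigor.
Directed edges are the conformational exchanges within each nucleotide
state (pre <-> post for ADP.Pi and ADP; post <-> closed for ADP and the
nucleotide-free state), the irreversible Pi and ADP releases that preserve
the conformation, and the rigor entry from A.Mclosed. Each of the twelve
rate constants is either fast (1e-4 per MCS) or slow (1e-6 per MCS), and
rigor entry uses k_w = 1e-3 per MCS; with an MCS on the nanosecond scale
these correspond to the millisecond lifetimes of the chemical steps. The
main preset makes A.Mpre.ADP.Pi long-lived (both exits slow, the return
fast); the alternative presets lengthen A.Mpre.ADP or A.Mpost.ADP.Pi
instead, and a fourth variant admits rigor entry from the two lowest
valleys. The exact fast/slow assignment per preset is a design choice of
this package (only the qualitative fast/slow structure is published);
changing it within reason does not alter the two-part displacement
distribution, which is what the robustness tests assert.

One MCS attempts, in order: (i) a state switch with the configured
probability (the walker keeps its position; rigor entry is attempted only
within 0.5 nm of the strong-binding valley minimum of the A.Mclosed
landscape); otherwise (ii) an axis choice, z with probability
`p_z = s^2/(dz^2 + s^2)` where `s = r_arc d_theta` is the arc step; (iii)
a direction with probability 1/2; and (iv) Metropolis acceptance on the
free-energy difference, with moves into unsampled bins rejected. The
lattice mesh defaults are `dz = 0.1` nm and `d_theta = 2 pi/360` (masked
in print), with `r_arc = 4.5` nm the motor-domain centroid radius. The
isotropy of the resulting walk, exact Boltzmann occupancy on enumerable
landscapes, downhill drift monotone in the slope, and edge-soundness of
the network are all property-tested.

The per-trajectory displacement is `D = z(rigor) - z(first entry into
A.Mclosed)` on the unwrapped axis, which distinguishes the periodic
strong-binding sites. The default trajectory budget is 5e6 MCS: with the
slow rates at 1e-6 per MCS the long-lived weak state alone persists for
about 5e5 MCS, so a 1e5-step budget would leave most trajectories
unfinished; under the default budget more than 99% complete.

**Physical timescale.** Treating the free head as a prolate ellipsoid
(semi-axes 8 and 2.5 nm) translating sidewise in water (0.89 pN ns/nm^2),
the Perrin friction factor gives D_free = 0.055 nm^2/ns, and equating the
lattice mean-square displacement per MCS with `4 D tau` yields
`tau = 0.035` ns per MCS. Because it assumes free diffusion, this is a
lower limit; trajectories of ~1e6 MCS then span at least tens of
microseconds, and hindered diffusion near the filament surface pushes the
real scale toward milliseconds.

## Synthetic landscapes

The desk-scale generator (`synthetic_landscape_spec()`,
`make_landscape_set()`) builds analytic landscapes with the qualitative
structure of the computed ones; its defaults are the package's study
conditions and were fixed on the following physical grounds.

* **Wells on the subunit helix.** Binding wells sit at `(k * 2.759 nm,
  k * 166.4 deg)` for all integers k, so helical periodicity is exact by
  construction. An azimuthal confinement band of width 0.6 rad about the
  slowly twisting rail — the restraint is a property of the assay, so the
  band is state-independent — makes only the strand facing the myosin
  accessible: the effective basins along the band are spaced by two
  subunit rises, 5.52 nm, the actin-subunit diameter. A wider band would
  expose both strands and halve the step; that is a geometric fact, not a
  tuning knob.
* **Open-cleft states** (pre/post with ADP.Pi or ADP, and nucleotide-free
  post): well depth 1.5 kT (the printed barriers are 1-2 kT), broad
  angular wells (0.8 rad), and a weak tent ramp (0.8 kT per basin) toward
  the weak-binding site one basin minus-end-ward of the strong site, which
  concentrates the weak-state occupancy on one strand segment.
  Post-stroke states are z-shifted by 1.5 nm.
* **Closed-cleft states**: deep wells (4 kT; strong binding must pin the
  walker so stepping proceeds by resolvable well-to-well hops rather than
  smooth drift), narrower angular wells (0.6 rad), and the global gradient
  of 2 kT per basin descending into the strong-binding site at the repeat
  origin. The screened electrostatics that generate the gradient have a
  1.9 nm range, so the descent spans 2.5 basins and the ramp plateaus in
  between; the barrier separating periodic strong-site basins is then
  finite (5 kT), which is what allows the small minor part of the
  displacement distribution at the adjacent periodic site. The rise back
  to the plateau occupies 0.2 of a repeat plus-end-ward of the site, so
  walkers landing just beyond a site step backward to it.

What the generator does **not** emulate: real actin/myosin sequence and
geometry, the coupling of the landscape shape to salt and flexibility
(those enter the molecular tier instead), load dependence, and any
absolute free-energy scale beyond the stated well/gradient magnitudes.
Passing the stepping tests on these landscapes validates the Monte Carlo
machinery and the qualitative stepping mechanism, not the quantitative
landscapes of the full-size system, which require cluster-scale umbrella
sampling of the real S1/filament models.

The mini actomyosin system (`make_mini_system()`) is a 40-bead motor
chain facing a small helical filament (6 subunits of 9 beads by default),
with an acidic patch per subunit and a basic flexible loop on the motor
emulating loop 2, clash-free by construction (no nonbonded pair under
3.8 A, regenerated with the next sub-seed otherwise). Its WHAM periodicity
is the two-subunit repeat (5.518 nm, -27.2 deg). The end-to-end smoke test
samples 8 windows across that repeat with 6 replicas of 30,000 steps each
on a 10-subunit filament — long enough that the sampled region plus the
5.9 nm electrostatic reach stays clear of the filament ends — and requires
the WHAM landscape to be periodic within 0.3 kT on well-sampled bins.

## Numerical choices and degenerate inputs

Collinear bond angles are handled by clamping the cosine; a degenerate
dihedral (three collinear beads) is an error. Landscape lookup is bilinear,
periodic in theta and helically periodic in z; the incommensurate last
grid cell interpolates against the twisted image of the first column.
Verlet neighbor lists (2 A skin) accelerate the cutoff terms and are
tested to reproduce brute force exactly. The Monte Carlo and Langevin
engines use a counter-based xoshiro256** generator seeded per trajectory
from `(seed, index)`, so runs are reproducible to the byte for a given
seed on any platform.

Problem sizes used by the shipped tests (chosen to exercise every code
path at desk scale): 8,000 stepping trajectories for the displacement
distribution; 400 per alternative preset for robustness; 1e5-step
constraint and umbrella runs of the mini system; 4e5-step oscillator runs
for equipartition; 20-40 thousand draws per window for the WHAM oracles.

## Known limitations

* The two tiers are decoupled: state switches teleport the walker between
  landscapes at fixed position; dynamic coupling of conformational change
  and diffusion is out of scope.
* Landscapes for the Monte Carlo tier must cover one full repeat; WHAM
  landscapes from partial sampling carry missing bins that reject moves.
* The Debye-Hueckel + 12-6 interface is an implicit-solvent approximation;
  no hydrodynamics, no explicit ions.
* The mini system stands in for the real S1/filament structures; its
  landscapes are not those of myosin II, and quantities derived from the
  full-size models (lever-arm versus Brownian decomposition magnitudes,
  absolute basin depths) are outside what the desk-scale artifacts can
  reproduce.
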