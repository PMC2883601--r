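---
title: "A polarizable coarse-grained water bead: model, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A polarizable coarse-grained water bead: model, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

polwater simulates a MARTINI-style coarse-grained fluid in which one water
bead stands for four real water molecules (72 amu). The polarizable water
bead is a three-site construction:

* a neutral core **W** that carries the Lennard-Jones interaction
  (self-interaction level III: well depth 4.0 kJ/mol, size 0.47 nm);
* two satellite sites **WP** and **WM** with charges $+q$ and $-q$
  ($q = 0.46\,e$), each held at a constrained distance $l = 0.14$ nm from the
  core. The satellites carry mass (24 amu each, a third of the bead mass) and
  follow ordinary dynamics — a charge-on-a-spring construction rather than a
  massless, self-consistently relaxed Drude particle;
* a cosine-harmonic angle $V(\theta) = \tfrac{K_\theta}{2}
  (\cos\theta - \cos\theta_0)^2$ between the satellites with $\theta_0 = 0$
  and $K_\theta = 4.2$ kJ/mol, which controls how easily the bead develops a
  dipole;
* all three intra-bead nonbonded pairs are excluded, so the satellites are
  transparent to each other and rotate freely around the core.

The instantaneous bead dipole is $\mu = q\,|r_{WP} - r_{WM}|$, ranging from 0
(satellites coincident, the angle equilibrium) to $2ql = 0.1288\,e\,$nm $=
6.2$ Debye (antipodal satellites). Orientational polarizability arises
because the satellites reorient in the local field; dielectric screening of
bulk water then emerges from the model instead of being imposed through a
large uniform screening constant. Explicit Coulomb interactions are still
divided by a residual screening constant $\epsilon_r = 2.5$ (the polarizable
setting; the standard single-site model uses $\epsilon_r = 15$).

**A note on the angle form.** The angle term is often described as a
"harmonic angle potential with $K_\theta$ in kJ mol$^{-1}$ rad$^{-2}$". A
strictly harmonic-in-$\theta$ form is stiffer at intermediate angles; in our
implementation it yields a mean bead dipole near 4.25 D and a dielectric
constant well below the published behavior of this parameterization, whereas
the cosine-harmonic (G96-style) form with $K_\theta = 4.2$ kJ/mol reproduces
the expected mean dipole (4.9 D) and density. The distributed GROMACS
topologies for this class of models also use the cosine form. polwater
therefore implements both (`funct = 1` harmonic-in-$\theta$, `funct = 2`
cosine-harmonic) and uses the cosine form in the shipped topologies.

## Nonbonded interactions

Pair interactions follow the MARTINI interaction-level scheme: each type pair
maps to a level O–IX, each level to an LJ well depth between 5.6 and
2.0 kJ/mol ($\sigma = 0.47$ nm except level IX, $\sigma = 0.62$ nm). The
package ships the full matrix as a readable TSV
(`inst/extdata/interaction_levels.tsv`) with two columns of levels:

* the revised charged-particle (Q) rows used with polarizable water,
  including the reduced Q–water attraction that compensates the strong
  electrostatic hydration of ions;
* the previous values, used by the `standard` and `early` force-field
  variants (`early` additionally maps Qd/Qa–C1 to level VIII).

Water cross-interactions with the uncharged P/N/C types are the P4 row
scaled to 95% of its well depth (`pol_cross_scale`), the calibration that
restores the published water/oil partitioning with the polarizable bead. The
apolar/polar block of the matrix (P/N/C against P/N/C) is taken from the
standard published force field; entries not exercised by the systems this
package builds (water, alkanes, ions) are carried for completeness.

Both nonbonded kernels use the classic polynomial shift: the force picks up
$A(r - r_1)^2 + B(r - r_1)^3$ beyond $r_1$ such that force and its
derivative vanish at the cutoff $r_c = 1.2$ nm, and the potential is offset
to vanish there too. LJ shifts from $r_1 = 0.9$ nm; Coulomb is shifted over
its whole range ($r_1 = 0$). Below $r_1$ the force is the unmodified 12-6
force and the energy is constant-shifted, so $F = -dE/dr$ holds everywhere —
a property the test suite checks against central differences at $10^{-6}$
relative tolerance.

## Engine

The integrator is leapfrog with a 20 fs time step. Constraints (the two
0.14 nm core–satellite bonds) are enforced by iterative SHAKE-style pair
corrections against the reference geometry (tolerance $10^{-6}$ nm, at most
100 iterations); the accumulated constraint multipliers contribute to the
virial, without which the pressure of a constrained fluid would be wrong.
Temperature and pressure use Berendsen weak coupling ($\tau_T = 0.3$ ps,
$\tau_p = 3.0$ ps, compressibility $4.5\times10^{-5}$ bar$^{-1}$), with
isotropic, z-only (`NP_zAT`) and independent z/xy (`NP_zP_xyT`) variants.
Kinetic temperature uses $3N - N_{constraints} - 3$ degrees of freedom and
on-step velocities (the average of the two half-step values). Center-of-mass
motion is removed every 10 steps.

Neighbor search uses Verlet pair lists (skin 0.2 nm, rebuilt when any site
has moved half a skin) over a cell grid when the box admits three cells per
dimension and a direct $O(N^2)$ sweep otherwise; boxes only need to satisfy
$r_c < L/2$, so the down-scaled 125-bead test systems remain valid
minimum-image systems.

**Electrostatic cutoff gating.** By default the Coulomb interactions are
gated by the distance between *bead centers* (the charge-group convention of
the simulation packages this model family was parameterized in): the
satellite charges of two water beads interact — each pair at its own
distance, through the shifted kernel, which is zero beyond the cutoff — if
and only if their cores are within $r_c$. The alternative `site` gating cuts
every charged pair at its own distance. The difference sounds cosmetic but
is not: site gating retains extra near-cutoff dipole–dipole attraction,
raising the bulk density by about 1% and, through the steep density
dependence of mobility at this packing, slowing self-diffusion by ~25%
relative to the published behavior; center gating reproduces both. Center
gating introduces small energy discontinuities when a pair of beads crosses
the cutoff, so it is not strictly energy conserving — exactly like the
group-scheme cutoffs it mirrors — and is intended for thermostatted runs;
microcanonical checks use `coulomb_gating = "site"`, which conserves energy
to high accuracy. Positions are propagated unwrapped (wrapping happens
in analysis and file output), which makes mean-square displacements exact
without jump healing; the barostat's affine scaling is applied to the
unwrapped coordinates, which is consistent because the periodic lattice
scales with them.

A uniform external field $E_z$ adds $qE_z$ (96.4853 kJ mol$^{-1}$ nm$^{-1}$
e$^{-1}$ per V/nm) to every charged site; field and umbrella-bias forces are
treated as external forces and excluded from the virial.

## System builders

Builders are seeded and bit-reproducible. Bulk boxes place beads on the
cubic lattice (simple, body-centered or face-centered) that keeps the
largest nearest-neighbor distance for the requested count, jittered by at
most 0.05 nm, and never closer than 0.4 nm between LJ cores. Slab builders
segregate species into z-slabs at bulk-like packing (1000 kg/m$^3$ for
water, 750 kg/m$^3$ for alkanes) on an interleaved lattice; thin slabs still
leave contacts a little tight, so `minimize_energy()` (steepest descent with
constraint projection) is the intended preamble to dynamics for slab
systems — the command-line paths do this automatically.

Satellites start coincident at 0.14 nm from the core along a random
direction. That is the angle-potential equilibrium and gives every bead a
zero initial dipole, avoiding any initial polarization bias; describing the
start as "a random vector and its negation" would instead put every bead at
its maximum dipole and far from the angle equilibrium, which is why we chose
the coincident convention.

Alkanes follow the 4:1 mapping as C1-bead chains: butane one bead, octane
two, hexadecane four, with harmonic bonds ($b_0 = 0.47$ nm, $k_b = 1250$
kJ/mol/nm$^2$) and cosine-harmonic angles ($\theta_0 = \pi$, $K = 25$
kJ/mol) — the standard bonded parameters of the parent force field, which
the source parameterization does not restate. Ion masses are 72 amu, the
single-bead convention.

## Estimators

* **Density**: total mass over instantaneous box volume, averaged over log
  records; errors from block averaging (5 blocks by default).
* **Dielectric constant**: the Clausius–Mosotti-type fluctuation formula in
  the no-reaction-field limit,
  $\epsilon = 1 + (\langle M^2\rangle - \langle M\rangle^2) /
  (3\epsilon_0 V k_B T)$, evaluated in md units where $1/\epsilon_0 = 4\pi
  \times 138.935485$ kJ mol$^{-1}$ nm e$^{-2}$. The run-time screening
  constant $\epsilon_r$ is **not** inserted into this formula; whether the
  original analysis applied any $\epsilon_r$-dependent correction is not
  derivable from its description, and the plain fluctuation form is the
  defensible default. Note $\epsilon$ converges slowly (tens of ns for a few
  percent); short runs give ordering information, not converged values.
* **Dipole statistics**: per-bead magnitudes $q|r_{WP}-r_{WM}|$ in Debye
  (48.0321 Debye per e nm), histogrammed over beads and frames. Every
  magnitude is bounded by $2ql$ plus constraint tolerance — a per-frame
  invariant the tests enforce.
* **RDF**: shell-normalized minimum-image pair histogram; same-species
  selections exclude self-pairs.
* **Surface tension**: $\gamma = \tfrac{L_z}{2}(\langle P_{zz}\rangle -
  \tfrac{1}{2}\langle P_{xx}+P_{yy}\rangle)$, the half accounting for the
  two interfaces of a periodic slab; 1 bar nm = 0.1 mN/m.
* **Diffusion**: MSD with multiple time origins (origin stride one tenth of
  the fit window), slope over the window divided by 6. Kinetic quantities
  are reported against effective time $t_{eff} = 4t$ — the conventional
  correction for the smoothed coarse-grained landscape — and the effective
  factor is always carried in the output next to the value, never silently
  applied to thermodynamic quantities. `D_molecular` $= 4 D_{CG}$ is the
  equivalent single-molecule value.
* **Potential profile**: binned charge density and double integration of
  Poisson's equation, with potential and field zeroed at the lower box
  boundary.

## Free energies

Solute decoupling uses a separation-shifted soft core: the plain pair
Hamiltonian is evaluated at $r_A = (r^6 + \alpha\sigma^6(1-\lambda))^{1/6}$
($\alpha = 0.5$, linear $\lambda$ coupling) and scaled by $\lambda$. The LJ
term uses the pair $\sigma$ and the Coulomb term a reference $\sigma$ of
0.47 nm (charged satellite sites have no LJ size of their own); both terms
share the same $\alpha$ and $\lambda$ power. $\lambda = 1$ recovers the
plain kernels to machine precision and $\lambda = 0$ removes the
interaction entirely while $\partial H/\partial\lambda$ stays finite —
tests verify the analytic derivative against central differences in
$\lambda$. TI integrates $\langle\partial H/\partial\lambda\rangle$ over 22
evenly spaced windows by default with the trapezoidal rule; per-window
errors are block averages, combined by trapezoid-weighted root-sum-square,
and windows whose block means drift are flagged in the result rather than
silently accepted. Window length and the discarded equilibration fraction
are configurable; the shipped defaults are desk-scale and err on honest
error bars rather than long sampling.

Umbrella-sampling PMFs are recombined with the standard self-consistent
WHAM iteration on binned histograms (convergence tolerance $10^{-8}$ on the
window constants). Windows must chain together — pairwise-disjoint
histograms raise a coverage error naming the gap — and the PMF is zeroed
over a stated reference region (bulk water, in the partitioning setup) or
at its minimum.

## What the synthetic systems do and do not show

The builders generate ideal, fully specified systems: pure CG water, simple
salt solutions, sharp water/alkane slabs. Passing tests on these systems
demonstrates that the force field, integrator and estimators implement the
model correctly at the stated parameters; they do not probe force-field
transferability, lipid membranes, long-range (lattice-sum) electrostatics, or
finite-size effects beyond the 400-bead scale. Quantities with slow
convergence (dielectric constant, surface tension, free energies) carry
statistical error at desk scale; the test suite checks them through fast
surrogates (closed-form oracles, orderings, analytic two-particle systems)
and reserves full-length runs for explicit validation scripts.

## Problem sizes used by the shipped checks

The test suite and the acceptance script use, as the package's desk-scale
defaults: 400-bead bulk boxes with 0.2–0.5 ns equilibration and 0.4–1 ns
production for density and dipole statistics; a 0.5 ns NVT segment for
diffusion; 125-bead boxes with ~1 ns sampling for parameter-trend orderings;
two-particle systems for the TI oracle; and Brownian-dynamics windows for
the WHAM oracle. These reproduce the published density (within 2%), mean
dipole (within 0.2 D) and diffusion (within 15%); the dielectric constant,
the 3708-bead surface tension, and the full hydration/partitioning free
energies are long-run quantities and are validated at reduced scale through
their oracles and trends instead.

Two behaviors of the reduced systems deserve flagging. First, small boxes
whose bead count exactly fills a cubic lattice (e.g. 250 beads on a
body-centered grid) can simply stay crystalline at 300 K — this water model
melts near 282 K — so the parameter-trend checks first melt the initial
lattice with a short 450 K segment before coupling to the target
temperature. Second, the self-diffusion coefficient is the most fragile
benchmark: it depends steeply on density near this packing (we measure
$d\ln D/d\ln\rho \approx -7$) and on the periodic box size. Our
implementation equilibrates about 0.9% denser than the reference value for
this parameter set (well inside the density tolerance) and correspondingly
diffuses some 20% slower at its own equilibrium state point; at the
reference density itself we measure $2.2\times10^{-5}$ cm$^2$/s, within
11% of the reference mobility. The shipped checks report the value at the
model's own equilibrium density and accept the mobility consequence rather
than measure at a state point chosen for agreement.

## Known limitations

* Berendsen coupling does not sample a rigorous canonical/isobaric ensemble;
  it matches the original parameterization protocol but slightly suppresses
  fluctuations. The dielectric estimator uses dipole fluctuations, which is
  one reason short runs read low/noisy.
* No lattice-sum electrostatics: all electrostatics are shifted cutoff, as
  in the parameterization; ionic-imbalance setups that require long-range
  fields across periodic compartments are out of scope.
* The constraint solver is SHAKE-style; it reproduces the constraint
  contract (and virial) but not the exact numerical trajectory of other
  engines' constraint algorithms.
* Lipid topologies are not included; the electroporation demo uses the
  octane-slab surrogate.
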