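---
title: "Grand canonical and nonequilibrium candidate Monte Carlo in grandmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grand canonical and nonequilibrium candidate Monte Carlo in grandmc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The sampling problem

Buried solvent molecules exchange with bulk on time scales far beyond what
plain molecular dynamics can reach: a water occluded in a protein cavity may
stay put for the entire trajectory simply because no diffusion pathway is
sampled. Grand canonical Monte Carlo (GCMC) sidesteps the kinetic barrier by
proposing the *insertion* or *deletion* of a solvent molecule inside a region
of interest, accepting or rejecting with probabilities that preserve the
grand canonical (constant chemical potential, volume, temperature) ensemble.
The practical obstacle is that abrupt insertions into condensed phases
almost always clash sterically, so acceptance rates are tiny — on the order
of one accepted move in several thousand.

`grandmc` implements both the classical instantaneous scheme and its
nonequilibrium enhancement, in which an insertion or deletion is carried out
*gradually*: the molecule's nonbonded interactions are scaled by an
alchemical coupling parameter $\lambda$ through a sequence of small
perturbations, each followed by a burst of Langevin relaxation that lets the
environment get out of the way. The decision is then based on the
accumulated nonequilibrium work rather than a single energy difference. We
refer to the combined method as grand canonical nonequilibrium candidate
Monte Carlo (GCNCMC).

## Acceptance probabilities

In the Adams formulation the instantaneous probabilities are

$$P_\text{ins} = \min\!\left(1, \frac{e^{B}\,e^{-\beta\,\Delta U}}{N+1}\right), \qquad
  P_\text{del} = \min\!\left(1, N\,e^{-B}\,e^{-\beta\,\Delta U}\right),$$

where $\Delta U$ is the potential-energy change of the proposed move, $N$
the number of movable molecules in the region before it, and $B$ the Adams
parameter. When the region is to be in equilibrium with bulk solvent,

$$B_\text{equil} = \beta\,\mu'_\text{ex} + \ln\frac{V_\text{region}}{V^\circ},$$

with $\mu'_\text{ex}$ the excess chemical potential of the solvent model
(for TIP3P water, $-6.09$ kcal/mol, its hydration free energy) and
$V^\circ = 30.345$ Å$^3$ the standard-state volume per molecule. `grandmc`
always works with $B$ directly; the thermal wavelength never needs to be
evaluated. $B$ is computed once from the *nominal* region volume and held
fixed for the whole run.

For nonequilibrium moves $\Delta U$ is replaced by the protocol work $W$
(the sum of the potential-energy changes caused by the $\lambda$
perturbation steps, evaluated at fixed coordinates) and the counts by the
sphere occupancies that account for diffusion during the protocol: the
insertion test divides by $N_T$, the occupancy of the *proposed* (final)
state including the inserted molecule, and the deletion test multiplies by
$N_0$, the occupancy of the initial state. With no diffusion, $N_T = N + 1$
and $N_0 = N$, and the instantaneous forms are recovered exactly — a
property the test suite checks move for move. The shadow work accumulated
by the integrator during relaxation is neglected throughout; the BAOAB
discretization is accurate enough at a 2 fs step that this is the standard
approximation, and the package never even accumulates it.

Two subtleties of sphere-restricted moves are handled explicitly. First, an
inserted molecule that has diffused out of the sphere by the end of the
protocol makes the move non-reversible, so it is rejected automatically
regardless of the work. Second, a rejected move must restore the system
*exactly*: `grandmc` snapshots coordinates, velocities, the ghost registry
and the random-number stream before the switch and restores all of them on
rejection. Because the proposal draws (move kind, pose, velocities, and the
acceptance uniform) happen before the snapshot, a rejected move rewinds only
its propagation noise; this makes the degenerate one-perturbation protocol
reproduce the instantaneous engine decision-for-decision on a shared stream,
which is the cross-validation the acceptance suite relies on.

## The switching protocol

A protocol is described by its switching time $\tau$ (the total length of
MD relaxation in one move), the number of MD steps between perturbations
$n_\text{prop}$, and the number of perturbation steps $n_\text{pert}$. A
move is one propagation segment followed by $n_\text{pert}$ (perturbation,
propagation) pairs, so

$$\tau = (n_\text{pert} + 1)\; n_\text{prop}\; \delta t .$$

This is the relation that reproduces both worked protocol sizes used in the
package's checks (a 10 ps switch at $n_\text{prop} = 10$, $\delta t = 2$ fs
gives $n_\text{pert} = 499$; 15 ps at $n_\text{prop} = 50$ gives 149). The
$\lambda$ schedule is the list of $n_\text{pert} + 1$ equally spaced values
from 0 to 1 inclusive, traversed in reverse for deletions.
$n_\text{prop} = 0$ is permitted only as the instantaneous-limit testing
degenerate, not for production.

## Interactions and the alchemical pathway

The model is deliberately self-contained: rigid molecules with per-site
Lennard-Jones parameters and point charges in an orthorhombic periodic box
under the minimum-image convention (half-edge ties resolved toward the
negative image, so membership tests are deterministic).

* **Soft-core van der Waals.** Partially coupled LJ interactions use a
  Beutler-style soft core,
  $U = 4\epsilon\lambda\,[(\sigma/r_\text{eff})^{12} -
  (\sigma/r_\text{eff})^{6}]$ with
  $r_\text{eff} = (\tfrac12 \sigma^6 (1-\lambda) + r^6)^{1/6}$ and a
  soft-core constant of $\tfrac12$. The energy is finite everywhere for
  $\lambda < 1$ (at $r = 0$ it evaluates to $24\epsilon\lambda\cdot$const),
  identically zero at $\lambda = 0$, and *exactly* the 12-6 potential at
  $\lambda = 1$ — endpoint identities enforced by property tests.
* **Split coupling.** $\lambda_\text{vdw} = \min(2\lambda, 1)$ and
  $\lambda_\text{elec} = \max(2\lambda - 1, 0)$: repulsion grows first so
  charges are never bare. The ranges are fixed by the method; linear
  interpolation within them is the simplest monotone choice and is the one
  implemented.
* **Electrostatics.** Coulomb interactions are cut off with an energy shift
  to zero at the cutoff, scaled linearly by $\lambda_\text{elec}$, with
  $k_e = 332.0636$ kcal·Å/(mol·e²). This is a deliberate, documented
  deviation from the Ewald treatment used for the full-scale systems this
  package emulates: lattice sums are out of scope at desk scale, and the
  acceptance statistics under study are dominated by short-range
  interactions. Quantitative bulk-water acceptance rates will differ from
  Ewald-based values for this reason.
* **LJ switching.** Lennard-Jones terms are smoothly switched to zero
  between a switch-start distance and the cutoff (quintic smoothstep), the
  desk-scale analog of the 1.0–1.2 nm switching used at full scale.
  Fixtures use proportionally smaller boxes and cutoffs; the box must
  exceed twice the cutoff.

Internal units are Å, ps, amu, kcal/mol, K and elementary charge, with
$k_B = 0.0019872041$ kcal/(mol·K).

## Dynamics

Propagation uses the BAOAB splitting of Langevin dynamics (default 2 fs
step, 1.0 ps$^{-1}$ friction, 298 K) with the exact Ornstein–Uhlenbeck
velocity update in the O step. Rigid molecules (e.g. 3-site water) are
maintained by iterative SHAKE/RATTLE-style distance-constraint projection:
after each position half-step the constrained distances are restored to the
template values to a relative tolerance of $10^{-8}$ (the solver iterates
to $10^{-10}$) and the position corrections are folded back into the
velocities; velocity components along constrained bonds are removed after
velocity updates. The projection is mass-weighted, so molecular linear
momentum is conserved. An analytic rigid-water solver would give the same
contract; the iterative projector was chosen because its guarantee (the
residual bound) is directly testable. Ghost molecules and fixed scaffold
sites are never propagated.

## Drivers, counters and reproducibility

A campaign alternates move blocks with MD: batches of instantaneous moves
(default 20 per batch) for GCMC/MD, or a single gradual move per iteration
for GCNCMC/MD. One analysis frame is captured at the end of *every*
iteration, whether or not a move was accepted (rejected-move iterations
therefore repeat configurations; the occupancy statistics require this).
Computational cost is reported in force evaluations: one per MD step
(plain or propagation, retained or rejected), one per instantaneous move,
and one per perturbation energy evaluation — the perturbation counting is a
package choice flagged in the summary report, since conventions differ on
whether those belong in the tally. MD retained from accepted gradual moves
is counted toward sampled MD, in keeping with how the full-scale method
reports its sampling.

The staged equilibration protocol is: 10,000 GCMC moves; 100 iterations of
(1,000 moves + 10 fs MD); 500 ps of NPT sampling implemented as Langevin MD
with isotropic Monte Carlo volume moves at 1 bar (skippable, and skipped
for fixtures with static scaffolds); then 500 iterations of (1 ps MD + 200
moves). Every count scales with a single reduction factor so desk-scale
fixtures can run the same schedule in miniature.

Everything is reproducible from a single integer seed: fixtures, proposals,
thermostat noise, and campaign restarts (a rejected nonequilibrium move
restores the stream, so downstream draws are unaffected by discarded
propagation).

## Analysis

Hydration sites are identified by average-linkage hierarchical clustering
of the pooled region positions (via `stats::hclust`), with the dendrogram
cut at 2.4 Å. Frames are first superposed on designated static reference
sites (least-squares/Kabsch) when at least three are available; whole-box
campaigns skip alignment. Cluster occupancy is reported as the fraction of
frames contributing at least one member — the mean member count per frame
is reported alongside, since either convention is defensible — and each
cluster is matched to at most one reference coordinate by greedy ascending
distance under a 1.4 Å threshold (the van der Waals radius of water). The
assignment rule is a package choice; on the well-separated sites the method
produces, greedy and optimal assignment coincide, which the oracle tests
exercise on small point sets. Bulk density is mass over volume averaged
over frames.

## What the fixtures emulate — and what they do not

The synthetic fixtures stand in for the full-scale test systems:

* `make_ideal_gas()` — a non-interacting species for which the grand
  canonical chain is exactly solvable: the stationary occupancy is
  Poisson($e^B$), giving a parameter-free correctness oracle for both move
  engines.
* `make_lj_fluid()` — a 20 Å box of single-site LJ particles
  ($\epsilon = 0.2$ kcal/mol, $\sigma = 3$ Å), the smallest condensed-ish
  phase on which instantaneous and gradual sampling can be compared.
* `make_water_box()` — rigid TIP3P waters (parameters in a versioned
  side-car file, `inst/extdata/tip3p.yaml`) for constraint, I/O and density
  checks.
* `make_toy_pocket()` — the desk-scale analog of a protein binding site: a
  static scaffold whose tetrahedral cages of attractive sites create deep
  point minima (about $-8$ kcal/mol for the default parameters) inside a
  6 Å spherical move region, with mobile solvent outside. The reference
  "crystal" coordinates are the numerically refined minima of the scaffold
  potential, so ground truth is exact by construction. The fixture declares
  a solvent excess chemical potential of $-3.5$ kcal/mol, chosen so that
  wells are strongly occupied at equilibrium while the background of the
  sphere stays dilute.

What passing these tests shows is that the move engines sample the grand
canonical ensemble they claim to, that the gradual engine is exactly
consistent with the instantaneous one, and that the analysis recovers
planted ground truth. What they cannot show is fidelity to real solvated
proteins: there is no Ewald electrostatics, no protein force field, no
ligand, and system sizes are orders of magnitude smaller. The full-scale
bulk-water acceptance rates (0.028% instantaneous; up to ~40% for gradual
moves) require days of compute and Ewald sums, and are therefore carried
only as documented long-run expectations
(`bulk_water_reference_config()`), not as desk-scale assertions.

## Numerical choices and problem sizes

Tolerances: constraint residuals $10^{-8}$ relative (solver target
$10^{-10}$); work re-summation agreement $10^{-10}$ kcal/mol; energy
bookkeeping recomputation agreement $10^{-8}$ kcal/mol; soft-core endpoint
identity $10^{-12}$ relative. Degenerate inputs are legislated, not left to
chance: deletions proposed on an empty region are recorded as auto-rejected
attempts, a membership test exactly on the sphere boundary is outside, and
a switching time not divisible by $n_\text{prop}\,\delta t$ is a
configuration error that reports the nearest valid $\tau$.

The statistical checks run at sizes chosen for a single CPU: $2\times10^5$
moves per ideal-gas chain (three $B$ values, both engines), $10^4$ paired
moves for the degenerate-protocol equivalence on a 30-particle fluid,
400–800 iterations for the two-engine occupancy comparison (agreement
within three combined batch-mean standard errors), 512 oscillators ×
30,000 steps for the thermostat variance check (2% tolerance), and a
40,000-move hydration stage before the toy-pocket recovery campaign. These
sizes are the package's study conditions; the seeds are fixed in the test
suite.
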