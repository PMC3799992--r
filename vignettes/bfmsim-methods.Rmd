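---
title: "Coarse-grained lattice Monte Carlo of a protein in an effective solvent: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained lattice Monte Carlo of a protein in an effective solvent: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`bfmsim` simulates a protein as a bond-fluctuation chain on a periodic cubic
lattice. Each residue is one chain node (or two/three consecutive nodes in
the fine-grain representations); a node occupies the eight vertices of the
unit cube anchored at its lattice coordinate. Two constraints define the
geometry:

* **Excluded volume.** No two cubes may share a vertex; equivalently, anchor
  coordinates of any two nodes differ by at least 2 in the Chebyshev
  (max-norm) distance.
* **Bond window.** Consecutive nodes are covalently bonded with fluctuating
  bond vectors whose squared length lies in {4, 5, 6, 9, 10} — lengths
  between 2 and sqrt(10), excluding sqrt(8). Together with cube occupancy
  this is exactly the classic three-dimensional bond-fluctuation move set,
  which makes chain crossing impossible.

Empty lattice sites act as an effective solvent medium. Every interaction —
residue–residue and residue–solvent — uses one truncated generalized
Lennard-Jones kernel with `sigma = 1`, cutoff `r_c = sqrt(8)`:

$$U(r) = |\epsilon|\left(\frac{\sigma}{r}\right)^{12} +
          \epsilon\left(\frac{\sigma}{r}\right)^{6}, \qquad r \le r_c .$$

The hard core is repulsive for either sign of the coupling; the sign of
$\epsilon$ controls the tail. This specific functional form is one of the
package's declared modelling choices (see *Design choices* below).

**Residue–residue couplings** $\epsilon_{ij}$ come from the bundled
Miyazawa–Jernigan (1996) knowledge-based contact matrix (20×20, symmetric,
all attractive, RT units in the source table). Pairs of covalently bonded
neighbours are excluded from this sum — the bond already constrains them.
Non-bonded anchors can only sit at squared distances {4, 5, 6, 8} inside the
cutoff.

**Residue–solvent couplings** are $f_s\,\epsilon_i$, where the solvent
strength $f_s \ge 0$ is the model's solvent-quality knob and $\epsilon_i$ is
a per-residue coupling built from the Kyte–Doolittle hydropathy index
divided by its maximum magnitude (4.5), so $\epsilon_i \in [-1, 1]$.
Hydrophobic residues (class H) have $\epsilon_i > 0$ (solvent-repulsive);
polar (P) and charged (E) residues have $\epsilon_i < 0$
(solvent-attractive). A residue's solvent energy sums the kernel over every
*empty* lattice site among the 92 offsets with $0 < |o|^2 \le 8$ around its
anchor.

The reference input is the canonical 136-residue human histone H3.1
sequence, shipped as a FASTA fixture (`h31_sequence()`); any sequence of the
20 standard one-letter codes can be simulated.

## Units, and the contact-energy normalization

All quantities are in reduced units: lengths in lattice constants, time in
Monte Carlo steps (1 MCS = N attempted single-node moves), temperature with
the Boltzmann constant equal to one, energies in units of the
*characteristic residue–residue interaction energy*. Concretely,
`interaction_model()` divides the contact table by its mean magnitude
(≈ 3.17 for the bundled table) by default, so a typical tight contact is
worth about 0.016–0.03 in model units. This convention matters: it places
the coil–globule crossover of a mixed-composition chain such as H3.1 inside
the working temperature window ($T \approx 0.01$–$0.04$) — at $T = 0.010$
the unsolvated chain compacts toward a globule, by $T = 0.025$ it is a
self-avoiding coil. Using the raw RT-unit table instead
(`normalize_contact = FALSE`) makes every contact worth several $k_BT$
across that whole window; the chain is then kinetically arrested at all
temperatures of interest and no transition is observable. No mapping to
laboratory units is attempted.

## Dynamics

Single-node Metropolis kinetics: an attempted move picks a uniform random
node and one of the six unit directions, checks the bond window and the
excluded volume first, and then accepts with probability
$\min(1, e^{-\Delta E/T})$. Node selection is with replacement; one MCS is
defined as N attempts. There are no cluster moves or tempering.

$\Delta E$ is computed incrementally. Writing the solvent indicator as
1 − (occupied) turns the solvent sum into a per-residue-type constant minus
short-ranged anchor–anchor "blocking" terms (the part of one node's cube
footprint that intrudes into another node's solvent shell). A move therefore
only needs a scan over a precomputed offset list (66 offsets unsolvated, 256
solvated) around the old and new positions, with all kernel values looked up
from tables. The running total energy is re-derived from scratch at a
configurable audit cadence; the maximum drift is reported with every run and
is typically below $10^{-12}$, and the same audit re-verifies every bond,
the excluded volume and the occupancy grid. Ensembles use one base seed;
replica $i$ runs on seed + i − 1, and initialization and dynamics use
separate streams of a counter-based generator, so every result is exactly
reproducible from the logged configuration.

Initial states come from random self-avoiding growth: bonds drawn uniformly
from the 108 admissible vectors under the excluded-volume constraint, with
the whole chain restarted on dead ends (bounded retries). This produces
swollen, coil-like starting configurations.

## Observables

* **Radius of gyration** $R_g$: RMS node distance from the centroid, on
  unwrapped coordinates (periodic wrapping would corrupt it).
* **Per-residue energy profile** $\langle E_n \rangle$: each node's pair +
  solvent-shell energy, averaged over the equilibrium window (the later half
  of each run by default) and over replicas; at fine grain, a residue's
  nodes are averaged. Summing $E_n$ over nodes counts each pair interaction
  twice and each solvent term once — an identity the tests verify.
* **Mobility profile**: accepted moves per attempt per node over the
  equilibrium window; chain ends are always the most mobile.
* **Center-of-mass displacement** $R_c(t)$: from unwrapped COM trajectories.
  By default the estimator averages over all time origins (increments are
  stationary), which is a variance-reduced version of the fixed-origin
  definition; the asymptotic exponent comes from a log-log fit (0.5 =
  diffusion).
* **Structure factor**
  $S(q) = \langle |\sum_j e^{i q\cdot r_j}|^2 \rangle / N$, spherically
  averaged over 64 random unit directions per magnitude (seeded) on a
  32-point log-spaced grid in $[2\pi/L, \pi]$, averaged over
  equilibrium-window frames of all replicas.
* **Effective dimension** $D_e$: $|$slope$|$ of $\log S$ vs $\log q$ over a
  fit window, $D_e \approx 1/\nu$ — about 1.76 for a self-avoiding coil, 2
  for an ideal chain, 3 for a compact globule.
* **Solvent scan**: equilibrium $\langle R_g\rangle(f_s)$ over a grid, with
  the peak location $f_{sc}$ by grid arg-max plus 3-point parabolic
  refinement, flagged when the maximum sits on the grid boundary.

### Structure-factor fit windows

The default window covers the spread of the radius of gyration: length
scales from $\lambda_{\min} = 10$ lattice constants (about four bond
lengths) up to $2 R_g$, i.e. $q \in [\pi/R_g,\, 2\pi/10]$. Below
$\lambda \approx 10$ the discrete chain's correlation hole and finite node
size flatten and then upturn $S(q)$, contaminating any power law; windows
are configurable and are always reported alongside the fitted value. For
blob-chain states a two-window mode fits high-q (local, below the blob
scale) and low-q (chain morphology) ranges separately. The estimator was
validated on synthetic geometries with known dimensions — a rod, an ideal
Gaussian chain and a uniform sphere cloud (fixtures carry their analytic
windows) — recovering $D_e = 1, 2, 3$ within ±0.2.

A related numerical point: the coherent limit $S(q \to 0) = N$ is only
reached well below the Guinier knee; at $q = 2\pi/(10 R_g)$ the Guinier
factor $e^{-(qR_g)^2/3}$ still removes ~12%, so the small-q identity is
checked at $q = 2\pi/(100 R_g)$.

## What the simulations show, and known limitations

At desk scale (ensembles of 5–10 replicas, $10^5$–$10^6$ MCS; the package's
tests and the acceptance script use exactly these sizes, stated in each
call) the model reproduces the expected phenomenology of the unsolvated
chain: a self-avoiding coil at $T = 0.025$ and compaction toward a globular
state at $T = 0.010$, with the $D_e$ values rising from ≈1.76 to ≈3
accordingly, and diffusive COM motion ($R_c \sim t^{1/2}$) at high
temperature.

Two caveats are inherent to the model as parameterized:

* **Low-temperature kinetics.** At $T = 0.010$ compaction is a strong
  quench; individual replicas can linger in pearl-necklace intermediates for
  $10^6$ MCS or more, so small ensembles mix globules with partially
  collapsed states and the fitted $D_e$ carries corresponding spread.
* **Strong solvent coupling freezes the dynamics.** With
  $\epsilon_i \in [-1,1]$ the solvent energy of moving an exposed residue at
  $f_s \gtrsim 5$ is tens of $k_BT$ for $T \le 0.03$: at $f_s = 20$ the
  acceptance rate drops to ~$10^{-3}$ and the chain is effectively frozen
  near its initial configuration at every temperature in the working range.
  Structural measures at strong solvent coupling therefore mostly reflect
  arrested, growth-generated configurations (coil-like statistics,
  $D_e \approx 1.8$–2.1); slow local self-assembly into compact blobs is
  beyond desk-scale runs. The exact per-residue solvent couplings behind the
  published behaviour are not recoverable, and the bundled
  hydropathy-derived table is an explicit stand-in.

The solvated model also has a deliberate geometric quirk: the solvent shell
is anchored at a cube *corner* (the node's lattice coordinate). The
unsolvated energy is invariant under the full 48-element cubic point group,
but the solvated energy is invariant only under the six axis permutations
plus translations — reflections relocate the anchor to a different corner of
the footprint. The tests assert exactly these invariances.

Finally, the synthetic sequences and point-set fixtures used by the test
suite emulate geometry and statistics (bond sets, known $R_g$, known $S(q)$
slopes, enumerable two-node Boltzmann distributions), not the biology of any
real protein; passing tests validate the machinery and the model's internal
consistency, not agreement with experiments on H3.1.

## Design choices made where the source model was open

* **LJ form.** $U = |\epsilon|(\sigma/r)^{12} + \epsilon(\sigma/r)^6$: a
  always-repulsive core with a sign-controlled tail, the natural choice when
  couplings carry either sign.
* **Node footprint and move set.** Cube-vertex occupancy and six
  nearest-neighbour unit moves — the canonical bond-fluctuation kinetics
  implied by the bond window above.
* **Boundaries.** Periodic with minimum image, lattice edges 64/100/210 for
  grain 1/2/3, large relative to $R_g$.
* **Bonded pairs** do not contribute contact energy (the covalent bond
  already constrains them); they do participate in solvent-shell blocking,
  as any occupied site does.
* **Fine grain** assigns every node of a residue the parent residue's full
  contact-matrix row and solvent coupling, without rescaling: the fine-grain
  representations add degrees of freedom, not renormalized couplings.
* **Equilibrium window.** The later half of each run, configurable.
* **No tail corrections or potential shifts** at the cutoff: a lattice
  model in arbitrary units gains nothing from them.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run scaled-down ensembles chosen
as the package's own working sizes: 5–10 replicas, $5\times10^4$–$10^6$ MCS
per condition on the 64³ lattice (100³/210³ for fine grain), with the
equilibrium window always the later half. Each call states its sizes
explicitly, and every random quantity is derived from the single seed
passed in.
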