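---
title: "Methods: asynchronous island-model docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asynchronous island-model docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isledock` predicts the bound pose of a flexible small molecule in a rigid
receptor by minimizing an empirical interaction energy with an island-model
Lamarckian genetic algorithm whose islands run *asynchronously*: they exchange
elite chromosomes whenever their completion times happen to align, instead of
stalling at a global barrier every migration interval. This vignette explains
the model, the operators, the parameters that matter, and the design choices
made where more than one reasonable realization existed.

## The candidate solution

A pose is the vector

\[ X = (t_x, t_y, t_z,\; q_w, q_x, q_y, q_z,\; \theta_1, \ldots, \theta_n), \]

three translation coordinates (Angstrom) of the ligand centroid, a unit
quaternion for the rigid-body orientation, and one torsion angle per rotatable
bond. All optimizers act on this flattened vector. Three repairs follow every
variation: translations are clamped to the docking box, the quaternion is
renormalized (an exactly zero quaternion resets to the identity), and torsions
are wrapped to \((-\pi, \pi]\).

Choices that had to be pinned down:

* The four orientation parameters are read as a unit quaternion, not
  axis-angle: it has no gimbal degeneracies and matches the Lamarckian-GA
  lineage of docking codes.
* The rotation pivot is the ligand centroid (the mean atom position after the
  torsions are applied); "ligand center point" is otherwise undefined.
* Torsions apply innermost-first along the torsion tree (leaves before
  parents). Either order is self-consistent; one must be fixed for
  reproducibility.
* Atom indices are 1-based throughout, the natural convention in R; PDBQT
  serial numbers are preserved for output.

## The energy model

The score of a pose is

\[ E_{\mathrm{total}}(X) = E_v + E_h + E_e + E_i + E_d , \]

evaluated on explicit atom pairs (no grid maps), with a hard nonbonded cutoff
of 8 Angstrom (configurable, `Inf` allowed):

* \(E_v\): 12-6 van der Waals, \(A/r^{12} - B/r^6\), with \(A, B\) chosen so
  the minimum is \(-\varepsilon_{ij}\) at \(r_{ij}\) (arithmetic-mean radii,
  geometric-mean well depths).
* \(E_h\): 12-10 hydrogen bond for donor-hydrogen/acceptor pairs, parameters
  from the acceptor's table row; it *replaces* the 12-6 term for that pair, so
  every pair contributes to exactly one of \(E_v\), \(E_h\). No angular
  weighting is applied.
* \(E_e\): Coulomb term \(332.06\, q_i q_j / (\epsilon(r)\, r)\) with the
  sigmoidal distance-dependent dielectric
  \(\epsilon(r) = A + B/(1 + k e^{-\lambda B r})\),
  \(A = -8.5525\), \(B = 78.4 - A\), \(k = 7.7839\),
  \(\lambda = 0.003627\).
* \(E_d\): desolvation, a volume-weighted Gaussian contact term
  \(w\,(S_i V_j + S_j V_i)\, e^{-r^2 / 2\sigma^2}\) with \(\sigma = 3.5\)
  Angstrom and weight \(w = 0.1465\).
* \(E_i\): the ligand intramolecular energy — the same pairwise forms summed
  over ligand atom pairs that are in different rigid groups *and* at least
  three bonds apart. With a rigid receptor the protein internal energy is a
  constant and is omitted. PDBQT carries no bond records, so covalent bonds
  are inferred from the input geometry (interatomic distance at most 1.9
  Angstrom) plus the declared rotatable bonds; 1-2 and 1-3 pairs are excluded
  because under any standard force field they sit on the repulsive wall by
  construction and carry no pose information.

No torsional-entropy constant is added; it shifts every pose equally and
cannot change the argmin. Per-type parameters (radii, well depths, solvation
volumes and weights, hydrogen-bond classes) live in a plain tab-separated
table (`inst/extdata/atom_params.tsv`) with AD4-like default values; any
column can be overridden by passing an edited copy. Bit-compatibility with any
particular docking engine is explicitly not a goal.

The hot path (pose-to-coordinates and the pairwise sums over precomputed
per-pair coefficient tables) is compiled (Rcpp); the scalar R term functions
(`vdw_energy()`, `hbond_energy()`, `electrostatic_energy()`,
`desolvation_energy()`) are the reference implementation, and the test suite
holds the compiled path to a brute-force double loop built from them at
relative error \(10^{-9}\).

## Per-island optimizers

**Genetic generation.** Fitness-proportional selection on shifted scores
\((\max E - E)\) (uniform if the population is energy-degenerate), two-point
crossover on the flattened gene vector at rate 0.9, additive Cauchy mutation
per gene at rate 0.08 (scales: 2 Angstrom translation, 0.2 per quaternion
component before renormalization, 15 degrees per torsion — heavy tails help
escape local minima), then gene repair, evaluation, and elitist replacement of
the worst offspring by the best parents (1 elite by default). Ties in elite
and worst identification break toward the lower index.

**Solis-Wets with Lamarckian write-back.** A derivative-free adaptive random
search: each iteration draws a Gaussian step \(\rho \cdot \text{scales} \cdot
N(0,1)\), tries the step and its reverse, and accepts an improvement; four
consecutive successes double \(\rho\), four failures halve it; the search
stops after the iteration budget or when \(\rho\) falls below 0.01. The
refined genotype *replaces* the individual's genotype, so acquired traits are
inherited. Defaults: \(\rho_0 = 1\), 300 iterations, selection probability
0.06 per individual per generation. The compiled and R implementations draw
identical random numbers and are trajectory-identical (tested).

**Baselines.** Differential evolution (rand/1/bin with greedy replacement,
\(F = 0.8\), \(CR = 0.9\); no forced crossover index, so \(F = CR = 0\) is
exactly the identity) and an inertia-weight particle swarm
(\(w = 0.729, c_1 = c_2 = 1.49445\)) run on the same gene vector with the
same repairs, and — matching the accounting used for the comparison tables —
the same Lamarckian local-search sweep after each generation.

## The asynchronous migration policy

Each island `i` keeps a window iteration counter \(T_i\), a migration-done
flag \(F_i\), and sees a master signal \(M_i\) (true when another island is
already waiting to exchange). After every island iteration the policy

\[
\psi(T_i, F_i, M_i) =
\begin{cases}
2 & T_i = T_H,\ F_i = \text{false},\ M_i = \text{true} \\
1 & T_i = T_H,\ F_i = \text{false},\ M_i = \text{false} \\
0 & \text{otherwise}
\end{cases}
\]

is evaluated (code 1: post the elite and wait for a partner; code 2: the
master directs an exchange now). The two non-zero cases overlap in their
written preconditions; the only self-consistent reading gives the
\(M_i = \text{true}\) case precedence, and that is how `migration_decision()`
is defined — the function is pure and its truth table is tested exhaustively.
\(T_H = 5\) and the synchronization interval \(M_T = 25\) are the defaults.

Eligible islands are paired greedily by *closest completion time* (ties toward
lower island indices; an odd island waits for the next candidate). A paired
exchange sends a copy of each island's elite to replace the partner's worst
individual — copies, so the source keeps its elite, elitism is preserved, and
subpopulation sizes never change. Once every island has run \(M_T\) window
iterations, the islands are grouped by the connected components of the
window's exchange graph and every island receives one uniformly drawn
chromosome from the other groups (donors snapshot before any replacement, so
the semantics are simultaneous); then all counters and flags reset. With a
single group (for example, two islands that already exchanged) the
cross-group step is skipped but the window still resets.

**Asynchrony model.** Rather than real network transport, a deterministic
discrete-event scheduler assigns each island iteration a cost assembled from
per-operation unit costs, multiplied by a per-island speed factor (linear
spread of 15% across islands, emulating heterogeneous workers) and a
seeded multiplicative jitter of 5%. The island with the smallest completion
time runs next (ties toward the lower id). Every island owns an independent
random stream derived from the master seed and its id, so trajectories do not
depend on scheduling order, identical seeds reproduce the event log exactly,
and a single-island run is bit-identical to the plain serial Lamarckian GA
(both are tested).

**Cost model defaults** (dimensionless units): evaluation 1, local search 1
per energy call, selection 0.05, crossover 0.05, mutation 0.02 per operation,
initialization 1 per individual, send-and-receive 5 per migrant — a
communication-heavy regime in which waiting would be expensive, which is the
regime the asynchronous policy addresses. `timing_profile()` reprices the
logged operation counts under any cost model and normalizes to the standard
seven reporting categories.

## Pattern reduction

The pattern-reduction operator removes converged search directions: every
`t_h` generations it inspects the best half of the subpopulation and freezes
any locus whose value range over that elite subset is at most a tolerance
(0.25 Angstrom translation, 0.05 quaternion, 5 degrees torsion by default;
torsions use the periodic range and the circular mean). Frozen loci are set to
the elite consensus in every individual and are skipped by mutation and
Solis-Wets, so the effective search dimensionality drops. Two safeguards keep
the operator reversible and safe:

* the quaternion freezes only as a whole 4-component block (freezing a subset
  and renormalizing per individual would silently reintroduce variance at the
  "frozen" loci); the consensus quaternion is sign-aligned (q and -q encode
  the same rotation), averaged and normalized once;
* if the island's best energy stagnates for `3 * t_h` generations the mask is
  cleared, so a premature freeze cannot trap the island permanently.

The operator's internals are under-documented in the line of work it comes
from; this realization (elite-range detection, freeze-and-skip, stagnation
release) is the package's documented interpretation, chosen for
reversibility. Freezing-decision audit rows are kept on the run object
(`$pr_log`). Disabling the operator is bit-identical to a run in which it
never fires (tested).

## The toy-system generator

`make_toy_system()` builds desk-scale docking problems with a *planted*
optimum. The ligand is a short zigzag chain (4 atoms, 1 rotatable bond by
default; bond length 1.5 Angstrom) with aperiodic, strongly charged centres
(\(|q| \in [0.3, 0.6]\), mixed signs — an irregular pattern avoids degenerate
register-shifted matches). The receptor is a pocket of 12 atoms on a bowl (a
spherical cap) around the ligand at a random reference pose: each pocket atom
sits at its pairwise equilibrium distance from a target ligand atom with an
opposite partial charge, and acceptors receive hydrogen-bond donors. The bowl
is concave enough that the planted pose collects many simultaneous contacts
and open enough that a downhill approach path exists — a fully enclosing cage
makes the optimum physically unreachable by rigid-body moves.

The planted pose is then refined to its exact local minimum and the system is
*certified* by rejection sampling: the reference must be deep
(below \(-8\) kcal/mol), must beat the minimum of 1000 random poses, and a
decoy sweep (Solis-Wets refinement of the 200 best of 8000 random poses) must
not uncover a competing basin within 3 kcal/mol of the reference at RMSD
greater than 2 Angstrom. Systems failing any check are regenerated from a
derived seed. `standard_toy_system()` (generator seed 1) is the fixed system
used by the pose-recovery benchmark.

What the generator emulates: a concave, chemically complementary binding site
with a funnel-shaped energy landscape and a unique deep minimum. What it does
not: real protein chemistry — no full bond graph, no protonation states, no
structural water, no receptor flexibility, and far fewer atoms than any real
pocket. Passing the recovery benchmark therefore demonstrates that the
optimizer machinery works end to end on a landscape of the right *shape*, not
that the energy function reproduces experimental binding modes.

## Problem sizes and the desk-scale preset

The full-scale preset (`config_preset("reference-2013")`) exposes the
canonical conditions: population 256 split as \(N/I_n\), crossover 0.9,
mutation 0.08, 10000 generations, \(T_H = 5\), \(M_T = 25\). The test suite
and the benchmark run the desk-scale preset (`config_preset("toy")`):
population 64 on 4 islands, 200 generations per island. Because a 200-
generation run has fifty times fewer generations for the genetic operators to
mix, the toy preset rebalances towards the Lamarckian side: local-search
probability 0.25 with a 100-iteration budget instead of 0.06 with 300. The
global/local budget per generation is comparable; refinement simply reaches
more individuals per generation, which is the standard way to make a
Lamarckian GA effective when the generation budget, not the evaluation
budget, is the binding constraint. The pose-recovery benchmark (20 seeded
runs on the standard system) passes at well above the 80% bar under these
conditions.

## Numerical choices and degenerate inputs

* Torsion wrapping uses \(x - 2\pi \lceil (x - \pi)/2\pi \rceil\), which maps
  exactly onto \((-\pi, \pi]\) including the boundary.
* A quaternion of norm below \(10^{-12}\) resets to the identity rotation.
* Energies at \(r \le 0\) are errors, never silently clamped.
* Elite/worst selection ties break toward the lower index everywhere, making
  every operator deterministic given the random stream.
* `n_torsions` in the generator is capped at `n_atoms - 3` so every rotatable
  bond moves at least one atom off its own axis (a chain-end "torsion" would
  be a no-op).
* An empty frozen mask is the identity; applying a mask that changed any
  genotype invalidates (or, given the objective, refreshes) the stored
  energies, preserving the invariant that stored energies always match stored
  genotypes.

## Known limitations

* The hydrogen-bond term has no angular dependence, so donor stacking is not
  penalized; the toy generator's certification step compensates at desk
  scale.
* The intramolecular pair list depends on distance-based bond perception;
  exotic input geometries with non-covalent contacts under 1.9 Angstrom would
  mis-classify pairs.
* Only the simulated-time scheduler is implemented; wall-clock multiprocess
  execution is out of scope, and simulated cost units are not seconds.
* Success rates and timing shares on the bundled toy systems characterize the
  algorithms' relative behaviour; they are not comparable to numbers measured
  on real protein-ligand complexes under other docking stacks.
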