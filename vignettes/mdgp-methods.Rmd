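---
title: "Solving distance geometry problems with sparse interval bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solving distance geometry problems with sparse interval bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsbuild)
```

## The problem

NMR experiments yield, for a subset $E$ of atom pairs of a molecule, interval
bounds on inter-atomic distances:
$$ l_{ij} \le \lVert x_i - x_j \rVert \le u_{ij}, \qquad (i,j) \in E . $$
The molecular distance geometry problem (MDGP) asks for coordinates
$x_1,\dots,x_n \in \mathbb{R}^3$ satisfying all bounds. With exact, complete
distances the problem is solved by one eigendecomposition; with sparse,
inaccurate data it is NP-hard and, in practice, dominated by two failure
modes: error accumulation in incremental (buildup-style) construction, and
local minima in penalty-based optimisation. The `lsbuild` solver combines
the two ideas and adds safeguards against both failure modes.

## The lsbuild pipeline

1. **Base selection.** The constraint set is a graph on the atoms; the
   maximum clique is the largest atom set whose pairwise distances are all
   constrained. It is found by an exact branch-and-bound in the
   Carraghan–Pardalos/Östergård style (vertices ordered by degree once, a
   memo $c(i)$ of the best clique in each suffix, pruning on both the
   candidate count and $c(i)$, early exit on a new record). A configurable
   time limit (default 60 s, far above what the sparse graphs here need)
   falls back to a deterministic greedy maximal clique, and the report
   records which path was taken.
2. **Distance sampling.** Interval bounds are collapsed to working
   distances $d_{ij}(t) = (1-t_{ij})\,l_{ij} + t_{ij}\,u_{ij}$ with one
   i.i.d. $t_{ij} \sim U[0,1]$ per edge, drawn once per run from the run
   seed (a deterministic midpoint policy is available). Repeat runs
   re-randomise; both solvers in a comparison share the same sample so the
   comparison isolates the algorithms.
3. **Base embedding.** With a designated base member translated to the
   origin, squared distances become inner products,
   $ \langle x_i, x_j\rangle = (d_{io}^2 + d_{jo}^2 - d_{ij}^2)/2 $,
   giving a Gram matrix whose best rank-3 factorization (top three
   eigenvalues, negatives clamped to zero — the classical-scaling
   treatment of non-Euclidean input) yields base coordinates; by
   Eckart–Young this is the optimal rank-3 fit.
4. **Refinement.** Coordinates are polished by minimising a hyperbolic
   smooth penalty (below) with limited-memory BFGS
   (`stats::optim(method = "L-BFGS-B")`, analytic gradient).
5. **Placement loop.** The unplaced atom with the most constraints into the
   current base (ties by index, at least 4 required) is positioned by the
   same linearised system, solved least-squares over *all* its anchored
   neighbours, then refined, then adopted into the base. Atoms that never
   reach 4 anchored constraints are positioned by the minimum-norm solution
   of their rank-deficient system, corrected along a deterministic
   null-space direction so the distance to the reference anchor is met
   exactly, and flagged low-confidence. Disconnected atoms are reported
   unplaced.

The geometric-buildup baseline (`solve_buildup()`) shares steps 1–2 and the
priority rule but re-solves, at each insertion, the whole substructure made
of the new atom and its anchored neighbours (unconstrained internal pairs
pinned to current distances), maps it back by an optimal orthogonal
superposition, and adopts the new atom's position. It never refines against
the bounds — that is precisely what it is a baseline for.

## The smooth penalty

For an edge with bounds $(l, u)$ at current distance $d$, the exact
violation is $e = \max\{l - d,\, d - u,\, 0\}$; the solution-quality metric
LDME is the root mean square of $e$ over all edges. The refinement
minimises the smooth surrogate
$$ \phi_{ij} = \tfrac{\lambda}{2}(l - u) + \theta(d, l) + \theta(d, u),
   \qquad \theta(d, c) = \tfrac{\lambda}{2}\sqrt{(c - d)^2 + \tau^2}, $$
summed over the active edges. Two properties pin this form down. First,
$\theta$ is the hyperbolic smoothing of $\tfrac{\lambda}{2}\lvert c - d\rvert$, so as
$\tau \to 0$ the edge term converges to $\lambda\,e$ exactly — the test
suite verifies $|\phi - \lambda \sum e_{ij}| \le C\,\tau\,|E|$ for
$\tau \in \{10^{-2}, 10^{-4}, 10^{-6}\}$. Second, the constant must be
$\tfrac{\lambda}{2}(l-u)$, not $\lambda(l-u)$: with the latter the value on
satisfied edges tends to $-\tfrac{\lambda}{2}(u-l) < 0$, which contradicts
a penalty's role. $\lambda$ (default 1.0) scales the penalty; $\tau$
(default 0.01 Å) controls the smoothing radius. Both defaults are the
values used in all reference experiments of the package.

Numerical details: the gradient is analytic and vectorised; a coincident
constrained pair (distance $< 10^{-12}$) gets a deterministic $10^{-9}$ Å
jitter instead of an error, keeping the optimiser total. Each
`minimize_phi()` call is guarded to never return a point with larger
penalty than its input. Anchor systems whose smallest singular value is
below $10^{-6}$ of the largest are flagged degenerate (near-coplanar
anchors leave a reflection ambiguity); the pseudo-inverse solve still
returns a finite answer and the flag is surfaced to the caller. The
reference anchor for each placement is the anchored neighbour sharing the
most constraints with the other anchors (ties by index) — a deterministic
choice that improves conditioning.

## Refinement scope: the one genuinely open design point

After each insertion the penalty is minimised "over the new atom and the
base". Two readings exist: move only the new atom against its base edges,
or let the base move too. Moving only the atom is cheap but lets placement
errors accumulate silently: on interval instances
($\varepsilon = 0.08$) it leaves residual violations (LDME of order
$10^{-3}$–$10^{-2}$) in roughly a third of runs. The package therefore
defaults to `refine = "cumulative"`: the new atom is refined alone first,
and whenever it cannot satisfy its own bounds the entire current base is
re-refined (warm-started from the current coordinates, so the cost stays
near the cheap reading in practice), with a final sweep at the end. The
literal atom-only behaviour remains available as `refine = "atom"`.

Rarely, a local minimum of the penalty survives refinement (an atom
trapped on the wrong side of a near-coplanar anchor set, or a mis-threaded
loop). When a refined scope still violates a bound, the solver escalates
through a short smoothing continuation of its own penalty — re-minimise at
$10\tau$, then $\tau$; if needed $100\tau \to 10\tau \to \tau$ — which
flattens the barrier and then re-sharpens. With this ladder, all measured
interval runs at the package's study sizes reach LDME $= 0$; a small
fraction of runs on 200-atom real-protein fragments still end at LDME
$\sim 10^{-3}$, which is the documented local-minimum behaviour of the
method, not a convergence bug. Global optimality is never claimed.

## The instance generators and what they emulate

`build_morewu_instance()` constrains every atom pair within one residue or
two consecutive residues, with symmetric relative bounds
$(1\pm\varepsilon)\hat d$. With $\varepsilon = 0$ it is an exact-distance
benchmark; $\varepsilon = 0.08$ is the standard mildly-inaccurate setting.
`build_biswas_instance()` emulates NOE-like data: pairs under
$R = 6$ Å are observable, a uniformly random 70 % of them is kept, and each
kept pair gets multiplicative noise $l = d^*\max(0, 1-\bar\varepsilon)$,
$u = d^*(1+\tilde\varepsilon)$. The noise draws are
$|N(0, \sigma^2)|$ with $\sigma = 0.05$ by default: the absolute value
guarantees $l \le d^* \le u$, so the true structure is always feasible and
LDME$(x^*) = 0$ is a testable invariant; $\sigma$ itself is a package
choice of plausible NMR-scale relative noise. Subsampling is drawn once
per instance seed, without replacement.

`generate_synthetic_structure()` supplies ground truth without any
download: a self-avoiding random walk (step 1.5 Å, the typical covalent
bond length; minimum separation 1 Å) confined to a cubic box of 20 Å$^3$
per heavy atom, the packing density of a folded protein, with residues
assigned in blocks of 8 atoms (the average heavy-atom count of an amino
acid residue). This emulates what matters to both protocols — compact
6 Å neighbourhoods and residue-local constraint windows. It does *not*
emulate real covalent geometry, secondary structure, or chirality, so
passing tests demonstrate correct behaviour of the solver machinery on
protein-like constraint graphs, not biological accuracy on real NMR data.
A real structure (hen egg lysozyme, shipped with the bio3d package) is
used in the tests wherever true protein geometry matters.

## Distance sampling and the buildup baseline

Under per-edge uniform sampling the matrix $D(t)$ is generally not a
Euclidean distance matrix, so the buildup baseline — which fits the sampled
distances and never consults the bounds again — carries a fit residual on
every insertion, and any residual crosses a bound with positive
probability (the sampled distance is uniform in the interval, so it can be
arbitrarily close to either end). Exact feasibility of buildup on interval
data should therefore not be expected under this sampling; the package's
acceptance script shows exactly this contrast (buildup LDME of order
$10^{-1}$ where lsbuild reaches 0). A per-run-*consistent* sample (one
shared $t$ for all edges of a symmetric relative-bound instance is a
uniform scaling of the truth) would make buildup trivially feasible; the
package keeps the per-edge reading as the default because it is the
stated sampling model, and notes the alternative here rather than
silently switching.

## Metrics

LDME is rigid-motion invariant and measures constraint satisfaction only.
RMSD is the per-atom root-mean-square deviation after optimal
superposition, $\mathrm{RMSD} = n^{-1/2}\min_{Q,h}\lVert x^* - Q(x-h)\rVert_F$,
with $Q$ ranging over the *full* orthogonal group: distance data cannot
determine handedness, so reflections must be allowed (a mirrored solution
is a perfect solution). The minimiser is the SVD Procrustes solution
without the determinant correction; the tests verify it beats randomly
sampled orthogonal candidates on every toy set.

## Problem sizes and determinism

The shipped tests and the acceptance script run synthetic chains of
50–280 atoms and real-protein fragments of 100–200 atoms, with 30 repeat
runs where run-to-run variability matters — sizes the package chose so a
full check stays interactive on one CPU. Every source of randomness
(structure generation, subsampling, noise, distance sampling) flows from
explicit integer seeds; identical (instance, configuration, seed) yield
identical placement order and base composition. Bit-identical coordinates
are *not* promised across platforms (the optimiser's floating-point path
may differ), but all reported metrics are stable well below the tolerances
used in the tests.

## Known limitations

- Refinement is local; no global-optimality or approximation guarantee.
- Very sparse graphs (no 4-clique) are rejected rather than solved;
  disconnected components beyond the base's reach are reported unplaced.
- The bounds-file format is package-specific plain text (there is no
  community standard for MDGP bounds); PDB is read, mmCIF is not.
- Underdetermined placements are a deterministic choice from a continuum
  of solutions; they anchor later atoms but should be treated as
  low-confidence, as flagged in the per-atom roles.
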