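# lsbuild

Solves the **molecular distance geometry problem** (MDGP): given sparse,
inaccurate interval bounds on some inter-atomic distances — the kind of data
NMR experiments produce — find 3-D coordinates `x_1, ..., x_n` with

```
l_ij <= || x_i - x_j || <= u_ij   for all (i, j) in E.
```

It is written for structural-bioinformatics practitioners and method
developers who need a transparent, fully scriptable MDGP solver with
reproducible benchmarks, rather than a black-box structure-calculation
pipeline.

## What it implements

**The `lsbuild` algorithm** — an iterative solver built from four pieces:

1. an exact maximum-clique search (Östergård-style branch and bound) on the
   constraint graph picks the initial *base*: the largest atom set whose
   pairwise distances are all bounded;
2. a working distance matrix is sampled inside the bounds,
   `d_ij(t) = (1 - t_ij) l_ij + t_ij u_ij`, `t_ij ~ U[0,1]`, once per run;
3. the base is embedded by the classic squared-distance trick
   `<x_i, x_j> = (d_io^2 + d_jo^2 - d_ij^2) / 2` followed by the best
   rank-3 Gram factorization (Eckart–Young), and each remaining atom is
   placed by the same linear system, least-squares over *all* its anchored
   neighbours (minimum-norm when it has fewer than four);
4. after every placement the coordinates are refined by limited-memory BFGS
   on a hyperbolic smooth penalty
   `phi_ij = (lambda/2)(l - u) + theta(d, l) + theta(d, u)`,
   `theta(d, c) = (lambda/2) sqrt((c - d)^2 + tau^2)`,
   whose `tau -> 0` limit is exactly `lambda * max(l - d, d - u, 0)`.
   Defaults `lambda = 1`, `tau = 0.01`.

**The geometric-buildup baseline** (`solve_buildup()`) — the classic
substructure-solving variant, for comparison. **Instance generators** for
two experimental protocols (residue-neighbourhood bounds `(1±eps)·d`; 6 Å
cutoff, 70 % retention, `|N(0, sigma^2)|` multiplicative noise), a compact
synthetic-structure generator, and **quality metrics**: LDME (root-mean-square
interval violation) and RMSD after optimal superposition over the full
orthogonal group (reflections allowed — distance data cannot fix chirality).

## A worked example

```r
library(lsbuild)

s    <- generate_synthetic_structure(100, seed = 7)   # ground truth, 100 atoms
inst <- build_morewu_instance(s, epsilon = 0.08)      # ±8 % interval bounds
inst
#> MDGP instance: 100 atoms, 1078 distance bounds
#> provenance: {"protocol":"morewu","epsilon":0.08}

sol <- solve_lsbuild(inst, seed = 1, truth = s)
sol
#> MDGP solution (lsbuild): 100 atoms
#>   LDME 0.000e+00 A   RMSD 3.027e-03 A
#>   base 16 | fully anchored 84 | underdetermined 0 | unplaced 0
```

LDME `0` means every one of the 1078 interval bounds is satisfied; RMSD
`3.0e-03` Å says the recovered fold matches the (blinded) ground truth to
three thousandths of an Ångström after optimal superposition. The 16-atom
base is the maximum clique of the constraint graph (two consecutive
8-atom residues are fully constrained under this protocol); the other 84
atoms were placed fully anchored, none needed the underdetermined fallback.

Results are tibbles all the way down:

```r
glance(sol)      # one-row summary: ldme, rmsd, base_size, seed, runtime, ...
tidy(sol)        # per-atom coordinates with the role each atom played
autoplot(sol, inst)  # realised distance per edge vs its bound interval
```

A thin command-line interface covers the same ground from a shell
(`inst/cli/mdgp generate|solve|evaluate`), writing plain-text bounds files,
XYZ coordinates and JSON-lines run reports.

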