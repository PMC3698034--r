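# Shared fixtures built in code.

# a tiny 3-atom PDB text fixture
toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "HEADER    TOY",
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   2       3.000   3.250   3.500  1.00  0.00           C",
    "HETATM    4  O   HOH A   9       9.000   9.000   9.000  1.00  0.00           O",
    "END"
  ), path)
  path
}

# structure from an explicit coordinate matrix, one residue per `block` atoms
structure_from_coords <- function(m, block = 4) {
  as_structure(tibble::tibble(
    atom_id = seq_len(nrow(m)), name = "CA",
    residue_index = as.integer((seq_len(nrow(m)) - 1) %/% block + 1),
    chain_id = "A", x = m[, 1], y = m[, 2], z = m[, 3]
  ))
}

# exact-distance instance over ALL pairs of a point set
complete_exact_instance <- function(m) {
  n <- nrow(m)
  pr <- t(utils::combn(n, 2))
  d <- sqrt(rowSums((m[pr[, 1], , drop = FALSE] - m[pr[, 2], , drop = FALSE])^2))
  mdgp_instance(n, tibble::tibble(i = pr[, 1], j = pr[, 2], l = d, u = d))
}

# Erdos-Renyi G(n, p) as an mdgp_graph, seeded
random_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    pr <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pr)) < p
    pr <- pr[keep, , drop = FALSE]
  })
  constraint_graph(tibble::tibble(i = pr[, 1], j = pr[, 2]), n_vertices = n)
}

# brute-force maximum-clique oracle: enumerate vertex subsets by
# descending size and return the first that is a clique (n <= 15 only)
brute_force_max_clique_size <- function(g) {
  n <- g$n
  adj <- g$adj
  for (k in n:1) {
    combos <- utils::combn(n, k)
    for (c in seq_len(ncol(combos))) {
      v <- combos[, c]
      sub <- adj[v, v, drop = FALSE]
      if (all(sub[upper.tri(sub)])) return(k)
    }
  }
  0L
}

# random rotation matrix (det +1), seeded by the caller
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
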