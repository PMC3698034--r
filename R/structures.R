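#' Molecular structures as tibbles
#'
#' A structure is a tibble with one row per atom and columns `atom_id`
#' (consecutive 1..n), `name` (atom name), `residue_index`, `chain_id`,
#' and Cartesian coordinates `x`, `y`, `z` in Angstrom. It is the ground
#' truth against which generated distance-bound instances are measured.
#'
#' @param df a data frame with the columns above.
#' @return a tibble of class `mdgp_structure`.
#' @export
as_structure <- function(df) {
  required <- c("atom_id", "name", "residue_index", "chain_id", "x", "y", "z")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("structure is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)[required]
  out$atom_id <- as.integer(out$atom_id)
  out$residue_index <- as.integer(out$residue_index)
  n <- nrow(out)
  if (n == 0) rlang::abort("structure has no atoms")
  if (!identical(out$atom_id, seq_len(n))) {
    rlang::abort("atom_id must be consecutive 1..n")
  }
  if (!all(is.finite(c(out$x, out$y, out$z)))) {
    rlang::abort("structure coordinates must be finite")
  }
  for (ch in unique(out$chain_id)) {
    res <- out$residue_index[out$chain_id == ch]
    if (is.unsorted(res)) {
      rlang::abort(paste0("residue_index must be non-decreasing within chain ", ch))
    }
  }
  class(out) <- c("mdgp_structure", class(tibble::tibble()))
  out
}

#' Extract the n x 3 coordinate matrix of a structure
#'
#' @param s an `mdgp_structure`.
#' @return a numeric matrix with one row per atom, columns x, y, z.
#' @export
coords <- function(s) {
  m <- cbind(x = s$x, y = s$y, z = s$z)
  rownames(m) <- s$atom_id
  m
}

#' Read atoms of one chain from a PDB file
#'
#' Parses `ATOM` records only (HETATM ignored); for alternate-location
#' duplicates the first occurrence is kept. Atoms are renumbered
#' consecutively 1..n in file order; residue numbering from the file is
#' preserved.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier to extract (single letter).
#' @param first_n optionally keep only the first `first_n` atoms of the chain.
#' @return an [as_structure()] tibble.
#' @export
read_pdb <- function(path, chain, first_n = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  atom_lines <- which(startsWith(lines, "ATOM"))
  for (k in atom_lines) {
    ln <- lines[k]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok) rlang::abort(paste0("malformed ATOM record at line ", k, ": ", ln))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) rlang::abort(paste0("chain '", chain, "' not found in ", path))
  # altloc: keep the first occurrence of each (residue, atom-name) pair
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety)), , drop = FALSE]
  if (!is.null(first_n)) {
    if (first_n > nrow(at)) {
      rlang::abort(paste0("first_n = ", first_n, " exceeds chain length ", nrow(at)))
    }
    at <- at[seq_len(first_n), , drop = FALSE]
  }
  as_structure(tibble::tibble(
    atom_id = seq_len(nrow(at)),
    name = at$elety,
    residue_index = as.integer(at$resno),
    chain_id = at$chain,
    x = at$x, y = at$y, z = at$z
  ))
}

#' Generate a synthetic chain-like structure
#'
#' Builds a self-avoiding random walk confined to a cubic box, emulating the
#' compactness of a folded protein: consecutive-atom spacing `bond_length`
#' (default 1.5 Angstrom, a typical covalent bond), steps rejected when they
#' approach any earlier atom closer than `min_separation` or leave the box.
#' The box volume is `volume_per_atom * n_atoms` (default 20 cubic Angstrom
#' per heavy atom, a typical protein packing density), which gives the
#' short-range constraint protocols realistic 6-Angstrom neighbourhoods.
#' Residue indices are assigned in consecutive blocks of
#' `atoms_per_residue` (default 8, the average heavy-atom count of an amino
#' acid residue), so the structure can feed both instance-generation
#' protocols. Deterministic for a given seed.
#'
#' @param n_atoms number of atoms (at least 4).
#' @param seed integer seed; the same seed always yields the same structure.
#' @param atoms_per_residue block size for synthetic residue numbering.
#' @param bond_length consecutive-atom spacing in Angstrom.
#' @param min_separation minimum distance allowed to any earlier atom.
#' @param volume_per_atom box volume per atom in cubic Angstrom.
#' @return an [as_structure()] tibble.
#' @export
generate_synthetic_structure <- function(n_atoms, seed = 1,
                                         atoms_per_residue = 8,
                                         bond_length = 1.5,
                                         min_separation = 1.0,
                                         volume_per_atom = 20) {
  if (n_atoms < 4) rlang::abort("n_atoms must be at least 4 (no base is possible below that)")
  half <- (volume_per_atom * n_atoms)^(1 / 3) / 2
  xyz <- withr::with_seed(seed, {
    repeat {
      m <- matrix(0, n_atoms, 3)
      ok <- TRUE
      for (i in 2:n_atoms) {
        placed <- FALSE
        for (try in 1:500) {
          dir <- stats::rnorm(3)
          cand <- m[i - 1, ] + bond_length * dir / sqrt(sum(dir^2))
          if (any(abs(cand) > half)) next
          prev <- m[seq_len(i - 2), , drop = FALSE]
          if (i == 2 || min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                                        byrow = TRUE))^2))) >= min_separation) {
            m[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      # reject degenerate (coplanar within tolerance) small walks
      if (ok && n_atoms >= 4) {
        sv <- svd(scale(m, scale = FALSE))$d
        if (sv[3] < 1e-8 * sv[1]) ok <- FALSE
      }
      if (ok) break
    }
    m
  })
  as_structure(tibble::tibble(
    atom_id = seq_len(n_atoms),
    name = "CA",
    residue_index = as.integer((seq_len(n_atoms) - 1) %/% atoms_per_residue + 1),
    chain_id = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ))
}

#' Write coordinates in XYZ format
#'
#' @param x an `mdgp_structure` or an n x 3 coordinate matrix.
#' @param path output file.
#' @param comment second-line comment.
#' @export
write_xyz <- function(x, path, comment = "") {
  m <- if (is.matrix(x)) x else coords(x)
  nm <- if (is.matrix(x)) rep("X", nrow(m)) else x$name
  lines <- c(nrow(m), comment,
             sprintf("%s %.6f %.6f %.6f", nm, m[, 1], m[, 2], m[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ coordinate file
#'
#' @param path the file to read.
#' @return an n x 3 coordinate matrix.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(lines[1])
  body <- lines[3:(2 + n)]
  parts <- strsplit(trimws(body), "\\s+")
  m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write a structure as minimal PDB ATOM records
#'
#' Emits fixed-width ATOM records carrying the structure's atom names,
#' residue indices and chain, with the supplied coordinates. Useful to
#' export solver output for visualisation.
#'
#' @param s an `mdgp_structure` providing names/residues/chain.
#' @param path output file.
#' @param xyz optional replacement n x 3 coordinate matrix (defaults to the
#'   structure's own coordinates).
#' @export
write_pdb <- function(s, path, xyz = NULL) {
  m <- if (is.null(xyz)) coords(s) else xyz
  stopifnot(nrow(m) == nrow(s))
  recs <- sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                  s$atom_id, substr(s$name, 1, 4), "GLY", s$chain_id,
                  s$residue_index, m[, 1], m[, 2], m[, 3])
  writeLines(c(recs, "END"), path)
  invisible(path)
}
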