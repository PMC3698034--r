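#' MDGP instances: interval distance bounds over atom pairs
#'
#' An instance is the central exchange object of the package: `n` atoms and
#' a set of edges `(i, j, l, u)` meaning `l <= ||x_i - x_j|| <= u` (Angstrom),
#' with `1 <= i < j <= n`, each unordered pair at most once, and `0 < l <= u`.
#' `provenance` records how the instance was generated (protocol, noise
#' level, cutoff, subsampling fraction, seed).
#'
#' @param n atom count.
#' @param edges a data frame with columns `i`, `j`, `l`, `u`.
#' @param provenance a named list of generator metadata.
#' @return an object of class `mdgp_instance`.
#' @export
mdgp_instance <- function(n, edges, provenance = list()) {
  e <- tibble::as_tibble(edges)[c("i", "j", "l", "u")]
  e$i <- unname(as.integer(e$i))
  e$j <- unname(as.integer(e$j))
  e$l <- unname(as.numeric(e$l))
  e$u <- unname(as.numeric(e$u))
  swap <- e$i > e$j
  if (any(swap)) {
    tmp <- e$i[swap]; e$i[swap] <- e$j[swap]; e$j[swap] <- tmp
  }
  if (any(e$i == e$j)) rlang::abort("self-edges are not allowed")
  if (any(e$j > n) || any(e$i < 1)) rlang::abort("edge indices out of 1..n")
  if (anyDuplicated(paste(e$i, e$j))) rlang::abort("duplicate atom pairs in edge set")
  if (any(e$l <= 0)) rlang::abort("lower bounds must be positive")
  if (any(e$l > e$u)) rlang::abort("every edge needs l <= u")
  e <- e[order(e$i, e$j), ]
  structure(list(n = as.integer(n), edges = e, provenance = provenance),
            class = "mdgp_instance")
}

#' @export
print.mdgp_instance <- function(x, ...) {
  cat("MDGP instance:", x$n, "atoms,", nrow(x$edges), "distance bounds\n")
  if (length(x$provenance) > 0) {
    cat("provenance:", jsonlite::toJSON(x$provenance, auto_unbox = TRUE), "\n")
  }
  print(x$edges, n = 5)
  invisible(x)
}

#' @method tidy mdgp_instance
#' @export
tidy.mdgp_instance <- function(x, ...) x$edges

#' Residue-neighbourhood instance (relative-error protocol)
#'
#' Emulates the classic exact-to-mildly-inaccurate benchmark protocol: the
#' edge set contains every atom pair within the same residue or in
#' consecutive residues of one chain, and the bounds are a symmetric
#' relative interval around the true distance,
#' `l = (1 - epsilon) * d`, `u = (1 + epsilon) * d`.
#' With `epsilon = 0` the instance has exact distances.
#'
#' @param s the source [as_structure()] ground truth.
#' @param epsilon relative half-width in `[0, 1)`.
#' @return an [mdgp_instance()]; the source structure satisfies every bound.
#' @export
build_morewu_instance <- function(s, epsilon = 0) {
  if (epsilon < 0 || epsilon >= 1) {
    rlang::abort("epsilon must be in [0, 1): epsilon >= 1 would give non-positive lower bounds")
  }
  m <- coords(s)
  n <- nrow(m)
  pairs <- list()
  for (a in seq_len(n - 1)) {
    nb <- which(s$chain_id == s$chain_id[a] &
                  abs(s$residue_index - s$residue_index[a]) <= 1)
    nb <- nb[nb > a]
    if (length(nb) > 0) pairs[[length(pairs) + 1]] <- cbind(a, nb)
  }
  pr <- do.call(rbind, pairs)
  d <- sqrt(rowSums((m[pr[, 1], , drop = FALSE] - m[pr[, 2], , drop = FALSE])^2))
  mdgp_instance(n,
                tibble::tibble(i = pr[, 1], j = pr[, 2],
                               l = (1 - epsilon) * d, u = (1 + epsilon) * d),
                provenance = list(protocol = "morewu", epsilon = epsilon))
}

#' Short-range subsampled instance (NMR-like protocol)
#'
#' Emulates realistic NMR-derived restraints: only pairs closer than
#' `cutoff_R` (default 6 Angstrom, the practical NOE range) are observable;
#' a uniformly random `keep_fraction` of those pairs (default 70%) is
#' retained; and each retained pair gets multiplicative noise
#' `l = d * max(0, 1 - e1)`, `u = d * (1 + e2)` with `e1`, `e2` drawn as
#' `|N(0, sigma^2)|`, so the true structure always remains feasible.
#'
#' @param s the source [as_structure()] ground truth.
#' @param sigma noise scale of the normal draws (relative units).
#' @param cutoff_R observability cutoff in Angstrom.
#' @param keep_fraction fraction of sub-cutoff pairs retained, in (0, 1].
#' @param seed integer seed controlling subsampling and noise.
#' @return an [mdgp_instance()]; the true structure satisfies `l <= d <= u`
#'   on every edge. If the constraint graph has no 4-atom clique a warning
#'   is recorded in the provenance (a solver cannot seed a base from it).
#' @export
build_biswas_instance <- function(s, sigma = 0.05, cutoff_R = 6.0,
                                  keep_fraction = 0.70, seed = 1) {
  stopifnot(sigma >= 0, cutoff_R > 0, keep_fraction > 0, keep_fraction <= 1)
  m <- coords(s)
  n <- nrow(m)
  dm <- as.matrix(stats::dist(m))
  idx <- which(upper.tri(dm) & dm < cutoff_R, arr.ind = TRUE)
  dstar <- dm[idx]
  res <- withr::with_seed(seed, {
    keep <- sort(sample.int(nrow(idx), size = round(keep_fraction * nrow(idx))))
    e1 <- abs(stats::rnorm(length(keep), 0, sigma))
    e2 <- abs(stats::rnorm(length(keep), 0, sigma))
    list(keep = keep, e1 = e1, e2 = e2)
  })
  d <- dstar[res$keep]
  prov <- list(protocol = "biswas", sigma = sigma, cutoff_R = cutoff_R,
               keep_fraction = keep_fraction, seed = seed)
  inst <- mdgp_instance(n,
                        tibble::tibble(i = idx[res$keep, 1], j = idx[res$keep, 2],
                                       l = d * pmax(0, 1 - res$e1),
                                       u = d * (1 + res$e2)),
                        provenance = prov)
  if (length(greedy_clique(constraint_graph(inst))) < 4) {
    inst$provenance$warning <- "constraint graph has no 4-clique; no base can be seeded"
    warning(inst$provenance$warning)
  }
  inst
}

#' Write an instance as a plain-text bounds file
#'
#' Format: header lines `# n <count>` and `# provenance <json>`, then one
#' whitespace-separated row `i j l u` per edge with 1-based indices and
#' distances in Angstrom to 6 decimals.
#'
#' @param inst an [mdgp_instance()].
#' @param path output file.
#' @export
write_instance <- function(inst, path) {
  hdr <- c(paste("# n", inst$n),
           paste("# provenance",
                 jsonlite::toJSON(inst$provenance, auto_unbox = TRUE, digits = NA)))
  rows <- sprintf("%d %d %.6f %.6f",
                  inst$edges$i, inst$edges$j, inst$edges$l, inst$edges$u)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a bounds file written by [write_instance()]
#'
#' @param path the file to read.
#' @return an [mdgp_instance()]; rows violating `l <= u` or duplicating a
#'   pair raise an error naming the offending row.
#' @export
read_instance <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  n_line <- grep("^# n ", hdr, value = TRUE)
  if (length(n_line) != 1) rlang::abort("bounds file lacks a '# n <count>' header")
  n <- as.integer(sub("^# n ", "", n_line))
  prov <- list()
  p_line <- grep("^# provenance ", hdr, value = TRUE)
  if (length(p_line) == 1) {
    prov <- jsonlite::fromJSON(sub("^# provenance ", "", p_line))
  }
  parts <- strsplit(trimws(body), "\\s+")
  bad_len <- which(vapply(parts, length, 1L) != 4)
  if (length(bad_len) > 0) {
    rlang::abort(paste0("malformed bounds row ", bad_len[1], ": ", body[bad_len[1]]))
  }
  tab <- matrix(as.numeric(unlist(parts)), ncol = 4, byrow = TRUE)
  bad <- which(tab[, 3] > tab[, 4])
  if (length(bad) > 0) {
    rlang::abort(paste0("row ", bad[1], " violates l <= u: ", body[bad[1]]))
  }
  dup <- which(duplicated(paste(pmin(tab[, 1], tab[, 2]), pmax(tab[, 1], tab[, 2]))))
  if (length(dup) > 0) {
    rlang::abort(paste0("row ", dup[1], " duplicates an atom pair: ", body[dup[1]]))
  }
  mdgp_instance(n, tibble::tibble(i = tab[, 1], j = tab[, 2],
                                  l = tab[, 3], u = tab[, 4]),
                provenance = prov)
}
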