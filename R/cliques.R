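#' Constraint graph of an instance
#'
#' The bounds of an instance induce a graph on the atoms: vertices are
#' atoms, edges are the pairs with known bounds. Its maximum clique is the
#' largest atom set whose pairwise distances are all constrained — the
#' natural initial base for buildup-style solvers.
#'
#' @param inst an [mdgp_instance()], or a data frame of `i`, `j` pairs plus
#'   `n_vertices`.
#' @param n_vertices vertex count when `inst` is a plain pair table.
#' @return an object of class `mdgp_graph` (symmetric logical adjacency).
#' @export
constraint_graph <- function(inst, n_vertices = NULL) {
  if (inherits(inst, "mdgp_instance")) {
    n <- inst$n
    e <- inst$edges
  } else {
    n <- n_vertices
    if (is.null(n)) rlang::abort("n_vertices is required for a plain pair table")
    e <- tibble::as_tibble(inst)
  }
  adj <- matrix(FALSE, n, n)
  adj[cbind(e$i, e$j)] <- TRUE
  adj[cbind(e$j, e$i)] <- TRUE
  structure(list(n = as.integer(n), adj = adj), class = "mdgp_graph")
}

#' @export
print.mdgp_graph <- function(x, ...) {
  cat("constraint graph:", x$n, "vertices,", sum(x$adj) / 2, "edges\n")
  invisible(x)
}

# degree-descending vertex order, ties broken by index (deterministic)
.clique_order <- function(adj) {
  deg <- rowSums(adj)
  order(-deg, seq_along(deg))
}

#' Maximum clique by branch and bound
#'
#' Exact maximum-clique search in the style of Ostergard's cliquer
#' (itself a refinement of the Carraghan--Pardalos algorithm): vertices are
#' ordered once (by decreasing degree, ties by index); the search runs over
#' suffixes of that order, memoising `c(i)` = the maximum clique size within
#' the suffix starting at `i`, and prunes a branch whenever the current
#' clique plus either the candidate count or `c(i)` cannot beat the best
#' clique found. The first new record at each size is kept, so ties resolve
#' to the lexicographically smallest clique under the search order, making
#' the result deterministic.
#'
#' @param g an `mdgp_graph`.
#' @param time_limit seconds before the search gives up and returns the
#'   best clique found so far (flagged incomplete).
#' @return integer vector of vertex indices (sorted), with attribute
#'   `complete` = `TRUE` if the search proved maximality.
#' @export
max_clique <- function(g, time_limit = 60) {
  n <- g$n
  if (n == 0) rlang::abort("empty graph")
  adj <- g$adj
  ord <- .clique_order(adj)
  a <- adj[ord, ord, drop = FALSE]   # permuted adjacency

  best_size <- 0L
  best <- integer(0)
  cbound <- integer(n)               # c(i): max clique size in suffix {i..n}
  deadline <- Sys.time() + time_limit
  timed_out <- FALSE
  found <- FALSE                     # Ostergard's new-record early exit
  stack <- integer(n)

  expand <- function(cand, size) {
    while (length(cand) > 0) {
      if (timed_out || Sys.time() > deadline) { timed_out <<- TRUE; return() }
      if (size + length(cand) <= best_size) return()
      v <- cand[1]
      if (size + cbound[v] <= best_size) return()
      stack[size + 1] <<- v
      newcand <- cand[a[v, cand]]
      if (length(newcand) == 0) {
        if (size + 1 > best_size) {
          best_size <<- size + 1L
          best <<- stack[seq_len(size + 1)]
          found <<- TRUE
        }
      } else {
        expand(newcand, size + 1L)
      }
      if (found) return()
      cand <- cand[-1]
    }
  }

  for (i in n:1) {
    if (timed_out) break
    found <- FALSE
    stack[1] <- i
    cand <- (i:n)[a[i, i:n]]
    if (length(cand) == 0) {
      if (best_size < 1) { best_size <- 1L; best <- i }
    } else {
      expand(cand, 1L)
    }
    cbound[i] <- best_size
  }

  if (timed_out) {
    # fall back to the greedy maximal clique if it beats the partial search
    grd <- greedy_clique(g)
    if (length(grd) > best_size) {
      out <- sort(grd)
      attr(out, "complete") <- FALSE
      return(out)
    }
  }
  out <- sort(ord[best])
  attr(out, "complete") <- !timed_out
  out
}

#' Greedy maximal clique
#'
#' Highest-degree-first greedy extension (ties by lowest index): start from
#' the full vertex set, repeatedly adopt the highest-degree candidate and
#' restrict candidates to its neighbours. The result is always maximal but
#' not necessarily maximum; it serves as the fallback when the exact search
#' hits its time limit.
#'
#' @param g an `mdgp_graph`.
#' @return integer vector of vertex indices (sorted).
#' @export
greedy_clique <- function(g) {
  if (g$n == 0) rlang::abort("empty graph")
  adj <- g$adj
  deg <- rowSums(adj)
  cand <- seq_len(g$n)
  clq <- integer(0)
  while (length(cand) > 0) {
    v <- cand[order(-deg[cand], cand)][1]
    clq <- c(clq, v)
    cand <- cand[adj[v, cand]]
  }
  sort(clq)
}

#' Check that a vertex set is a clique
#'
#' @param g an `mdgp_graph`.
#' @param vertices integer vertex subset.
#' @return `TRUE` iff all pairs are adjacent.
#' @export
verify_clique <- function(g, vertices) {
  v <- as.integer(vertices)
  if (length(v) <= 1) return(TRUE)
  sub <- g$adj[v, v, drop = FALSE]
  all(sub[upper.tri(sub)])
}

#' Write / read a graph in DIMACS ascii format
#'
#' Plain `p edge n m` / `e i j` format, for cross-checking against external
#' clique solvers.
#'
#' @param g an `mdgp_graph`.
#' @param path file path.
#' @export
write_dimacs <- function(g, path) {
  e <- which(upper.tri(g$adj) & g$adj, arr.ind = TRUE)
  writeLines(c(sprintf("p edge %d %d", g$n, nrow(e)),
               sprintf("e %d %d", e[, 1], e[, 2])), path)
  invisible(path)
}

#' @rdname write_dimacs
#' @export
read_dimacs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  p <- strsplit(grep("^p ", lines, value = TRUE)[1], "\\s+")[[1]]
  n <- as.integer(p[3])
  ee <- grep("^e ", lines, value = TRUE)
  parts <- do.call(rbind, strsplit(ee, "\\s+"))
  constraint_graph(tibble::tibble(i = as.integer(parts[, 2]),
                                  j = as.integer(parts[, 3])),
                   n_vertices = n)
}
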