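# Shared machinery for the two solvers: base-constraint bookkeeping,
# the solution object, and broom-style accessors.

# largest interval violation among a scope's edges
.scope_violation <- function(x, sc) {
  e <- sc$edges
  if (nrow(e) == 0) return(0)
  dij <- sqrt(rowSums((x[e$i, , drop = FALSE] - x[e$j, , drop = FALSE])^2))
  max(c(0, e$l - dij, dij - e$u))
}

# count, per atom, of sampled-edge neighbours currently in the base
.base_counts <- function(d, in_base) {
  vapply(seq_len(d$n), function(j) sum(in_base[d$nbr[[j]]]), integer(1))
}

.new_solution <- function(algorithm, coords, report, config) {
  structure(list(algorithm = algorithm, coords = coords,
                 report = report, config = config),
            class = "mdgp_solution")
}

#' @export
print.mdgp_solution <- function(x, ...) {
  r <- x$report
  cat("MDGP solution (", x$algorithm, "): ", nrow(x$coords), " atoms\n", sep = "")
  cat(sprintf("  LDME %.3e A", r$ldme))
  if (!is.null(r$rmsd)) cat(sprintf("   RMSD %.3e A", r$rmsd))
  cat("\n")
  cat("  base", r$base_size, "| fully anchored", r$n_fully_anchored,
      "| underdetermined", r$n_underdetermined, "| unplaced", r$n_unplaced, "\n")
  invisible(x)
}

#' Tidy a solution into a per-atom tibble
#'
#' @param x an `mdgp_solution`.
#' @param ... unused.
#' @return a tibble with `atom_id`, coordinates, and the `role` each atom
#'   played (`base`, `placed`, `underdetermined`, `unplaced`).
#' @method tidy mdgp_solution
#' @export
tidy.mdgp_solution <- function(x, ...) {
  co <- x$coords                 # pull out first: tibble() masks `x` below
  role <- x$report$role
  tibble::tibble(atom_id = seq_len(nrow(co)),
                 x = co[, 1], y = co[, 2], z = co[, 3],
                 role = role)
}

#' One-row summary of a solution
#'
#' @param x an `mdgp_solution`.
#' @param ... unused.
#' @return a one-row tibble: algorithm, LDME, RMSD (NA without ground
#'   truth), base size, placement counts, seed, runtime.
#' @method glance mdgp_solution
#' @export
glance.mdgp_solution <- function(x, ...) {
  r <- x$report
  tibble::tibble(algorithm = x$algorithm,
                 n = nrow(x$coords),
                 ldme = r$ldme,
                 rmsd = ifelse(is.null(r$rmsd), NA_real_, r$rmsd),
                 base_size = r$base_size,
                 n_fully_anchored = r$n_fully_anchored,
                 n_underdetermined = r$n_underdetermined,
                 n_unplaced = r$n_unplaced,
                 clique_complete = r$clique_complete,
                 seed = x$config$seed,
                 runtime = r$runtime)
}

#' Plot the per-edge violation profile of a solution
#'
#' @param object an `mdgp_solution`.
#' @param inst the instance it solved.
#' @param ... unused.
#' @return a ggplot: realised distance per edge against its bound interval.
#' @method autoplot mdgp_solution
#' @export
autoplot.mdgp_solution <- function(object, inst, ...) {
  placed <- which(object$report$role != "unplaced")
  e <- inst$edges[inst$edges$i %in% placed & inst$edges$j %in% placed, ]
  sub <- mdgp_instance(inst$n, e, inst$provenance)
  v <- edge_violations(object$coords, sub)
  v$edge <- seq_len(nrow(v))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$edge)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$l, ymax = .data$u),
                            colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$d, colour = .data$violation > 0),
                        size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 name = "violated") +
    ggplot2::labs(x = "edge", y = "distance (A)",
                  title = paste0(object$algorithm, ": realised distances vs bounds"))
}

# finalise a solve: metrics, accounting, report
.finish_solve <- function(algorithm, inst, x, role, placement_order,
                          clique_complete, optimizer_stats, config, truth,
                          t0) {
  placed <- which(role != "unplaced")
  if (length(placed) < inst$n) {
    keep <- inst$edges$i %in% placed & inst$edges$j %in% placed
    sub <- inst$edges[keep, , drop = FALSE]
    ld <- if (nrow(sub) > 0) {
      ldme(x, mdgp_instance(inst$n, sub, inst$provenance))
    } else NA_real_
  } else {
    ld <- ldme(x, inst)
  }
  rms <- NULL
  if (!is.null(truth)) {
    xt <- if (is.matrix(truth)) truth else coords(truth)
    rms <- if (length(placed) >= 3) {
      rmsd(x[placed, , drop = FALSE], xt[placed, , drop = FALSE])
    } else NA_real_
  }
  report <- list(
    ldme = ld, rmsd = rms,
    role = role,
    base_size = sum(role == "base"),
    n_fully_anchored = sum(role == "placed"),
    n_underdetermined = sum(role == "underdetermined"),
    n_unplaced = sum(role == "unplaced"),
    placement_order = placement_order,
    clique_complete = clique_complete,
    optimizer_stats = optimizer_stats,
    runtime = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  .new_solution(algorithm, x, report, config)
}

#' Dynamic placement priority
#'
#' Simulates the placement queue: repeatedly pick the unplaced atom with the
#' most sampled-edge constraints into the current base (ties broken by
#' lowest index), requiring at least `min_anchors`; each pick joins the base
#' before the next count. Returns the order in which fully-anchored atoms
#' would be placed; stops when no atom reaches `min_anchors` (the
#' underdetermined phase takes over there).
#'
#' @param d an `mdgp_distances` (or [mdgp_instance()], midpoint-sampled).
#' @param base integer vector of initial base members.
#' @param min_anchors minimum base-constraint count (default 4).
#' @return integer vector of atom indices in placement order.
#' @export
placement_order <- function(d, base, min_anchors = 4) {
  if (inherits(d, "mdgp_instance")) d <- sample_distances(d, policy = "midpoint")
  if (length(base) == 0) rlang::abort("base must be nonempty")
  in_base <- rep(FALSE, d$n)
  in_base[base] <- TRUE
  cnt <- .base_counts(d, in_base)
  out <- integer(0)
  repeat {
    cnt[in_base] <- -1L
    j <- which(cnt >= min_anchors)
    if (length(j) == 0) break
    j <- j[order(-cnt[j], j)][1]
    out <- c(out, j)
    in_base[j] <- TRUE
    cnt[d$nbr[[j]]] <- cnt[d$nbr[[j]]] + 1L
  }
  out
}

#' Solve an MDGP instance with the lsbuild algorithm
#'
#' The pipeline: (1) take the maximum clique of the constraint graph as the
#' initial base; (2) sample one working distance matrix `D(t)` inside the
#' bounds; (3) embed the base by the rank-3 Gram factorization; (4) refine
#' the base by minimising the hyperbolic penalty over its internal edges;
#' (5) repeatedly place the unplaced atom with the most constraints into the
#' current base (at least `min_anchors`) by the least-squares linear system,
#' refine, and adopt it into the base; (6) atoms that never reach
#' `min_anchors` base constraints are placed by the minimum-norm
#' underdetermined system and refined the same way; (7) optionally polish
#' all atoms jointly at the end.
#'
#' Each insertion is followed by a penalty refinement over the new atom and
#' the base (`refine = "cumulative"`, the default): the minimisation runs
#' over the coordinates of the enlarged base with all its internal edges
#' active, warm-started from the current partial solution, so placement
#' errors cannot accumulate silently. `refine = "atom"` instead moves only
#' the newly placed atom against its base edges — much cheaper, but
#' residual interval violations can survive in late-placed regions.
#'
#' @param inst an [mdgp_instance()].
#' @param params [penalty_params()] (defaults lambda = 1, tau = 0.01).
#' @param t_policy distance sampling policy, `"uniform"` or `"midpoint"`.
#' @param seed seed for the per-run distance sample.
#' @param clique_time_limit seconds for the exact maximum-clique search
#'   before falling back to the greedy clique.
#' @param min_anchors minimum anchors for a fully-determined placement.
#' @param refine refinement scope after each insertion: `"cumulative"`
#'   (new atom plus the whole base) or `"atom"` (new atom only).
#' @param final_global_refine polish all atoms jointly after placement.
#' @param max_iter,grad_tol optimiser controls per refinement.
#' @param truth optional ground-truth [as_structure()] or n x 3 matrix; when
#'   given, the report carries the superposition RMSD.
#' @return an `mdgp_solution`; see [tidy.mdgp_solution()] and
#'   [glance.mdgp_solution()].
#' @export
solve_lsbuild <- function(inst, params = penalty_params(),
                          t_policy = c("uniform", "midpoint"), seed = 1,
                          clique_time_limit = 60, min_anchors = 4,
                          refine = c("cumulative", "atom"),
                          final_global_refine = FALSE,
                          max_iter = 500, grad_tol = 1e-6, truth = NULL) {
  t_policy <- match.arg(t_policy)
  refine <- match.arg(refine)
  t0 <- Sys.time()
  config <- list(params = params, t_policy = t_policy, seed = seed,
                 clique_time_limit = clique_time_limit,
                 min_anchors = min_anchors, refine = refine,
                 final_global_refine = final_global_refine)
  g <- constraint_graph(inst)
  clq <- max_clique(g, time_limit = clique_time_limit)
  clique_complete <- attr(clq, "complete")
  if (length(clq) < 4) {
    rlang::abort(paste0("no valid base: maximum clique has only ",
                        length(clq), " atoms (need 4)"))
  }
  d <- sample_distances(inst, policy = t_policy, seed = seed)

  # embed and refine the base clique
  x <- matrix(NA_real_, inst$n, 3)
  x[clq, ] <- embed_clique(d, clq)
  role <- rep("unplaced", inst$n)
  role[clq] <- "base"
  base_scope <- refinement_scope(inst, clq,
                                 which(inst$edges$i %in% clq &
                                         inst$edges$j %in% clq))
  xw <- x
  xw[is.na(xw)] <- 0                   # placeholder; untouched by the scope
  ref <- minimize_phi(xw, base_scope, params, max_iter, grad_tol)
  x[clq, ] <- ref$x[clq, , drop = FALSE]
  opt_stats <- list(base = list(iterations = ref$iterations,
                                value = ref$value,
                                converged = ref$converged),
                    per_atom_iterations = 0L)

  in_base <- rep(FALSE, inst$n)
  in_base[clq] <- TRUE
  cnt <- .base_counts(d, in_base)
  order_placed <- integer(0)

  # refine the new atom against its base edges; under the cumulative policy
  # the whole base is re-refined (warm-started) whenever the atom alone
  # cannot satisfy its bounds, so placement errors cannot accumulate
  refine_step <- function(x, j) {
    atom_edges <- which((inst$edges$i == j & in_base[inst$edges$j]) |
                          (inst$edges$j == j & in_base[inst$edges$i]))
    sc <- refinement_scope(inst, j, atom_edges)
    xw <- x
    xw[is.na(xw)] <- 0
    ref <- minimize_phi(xw, sc, params, max_iter, grad_tol)
    opt_stats$per_atom_iterations <<- opt_stats$per_atom_iterations +
      ref$iterations
    if (refine == "cumulative" && .scope_violation(ref$x, sc) > 1e-9) {
      members <- c(which(in_base), j)
      edges <- which(inst$edges$i %in% members & inst$edges$j %in% members)
      scb <- refinement_scope(inst, members, edges)
      xw <- ref$x
      xw[is.na(xw)] <- 0
      xb <- refine_feasible(xw, scb)
      return(list(atoms = scb$variable_atoms,
                  coords = xb[scb$variable_atoms, , drop = FALSE]))
    }
    list(atoms = sc$variable_atoms,
         coords = ref$x[sc$variable_atoms, , drop = FALSE])
  }

  # refine a scope toward feasibility; if a local minimum of the penalty
  # still violates a bound, escalate through one smoothing-continuation
  # round (10x tau flattens the barrier, then the target tau re-sharpens)
  refine_feasible <- function(xw, sc) {
    ref <- minimize_phi(xw, sc, params, max_iter, grad_tol)
    opt_stats$per_atom_iterations <<- opt_stats$per_atom_iterations +
      ref$iterations
    x <- ref$x
    for (ladder in list(c(10, 1), c(100, 10, 1))) {
      if (.scope_violation(x, sc) <= 1e-9) break
      for (mult in ladder) {
        pp <- penalty_params(lam = params$lam, tau = params$tau * mult)
        ref <- minimize_phi(x, sc, pp, max_iter, grad_tol)
        x <- ref$x
        opt_stats$per_atom_iterations <<- opt_stats$per_atom_iterations +
          ref$iterations
      }
    }
    x
  }

  base_obj <- function() new_base(which(in_base), x[in_base, , drop = FALSE])

  repeat {
    cnt[in_base] <- -1L
    cand <- which(cnt >= min_anchors)
    if (length(cand) > 0) {
      j <- cand[order(-cnt[cand], cand)][1]
      x[j, ] <- place_point(j, base_obj(), d)$coords
      role[j] <- "placed"
    } else {
      cand <- which(cnt >= 1)
      if (length(cand) == 0) break
      j <- cand[order(-cnt[cand], cand)][1]
      x[j, ] <- place_underdetermined(j, base_obj(), d)$coords
      role[j] <- "underdetermined"
    }
    upd <- refine_step(x, j)
    x[upd$atoms, ] <- upd$coords
    order_placed <- c(order_placed, j)
    in_base[j] <- TRUE
    cnt[d$nbr[[j]]] <- cnt[d$nbr[[j]]] + 1L
  }

  # lazy-refinement completion: the per-insertion trigger watches only the
  # new atom, so a violation left behind by an earlier local minimum is
  # swept up here with the same cumulative machinery
  if (refine == "cumulative") {
    placed <- which(role != "unplaced")
    scp <- refinement_scope(inst, placed,
                            which(inst$edges$i %in% placed &
                                    inst$edges$j %in% placed))
    if (.scope_violation(x, scp) > 1e-9) {
      xw <- x
      xw[is.na(xw)] <- 0
      xb <- refine_feasible(xw, scp)
      x[placed, ] <- xb[placed, , drop = FALSE]
    }
  }

  if (final_global_refine) {
    placed <- which(role != "unplaced")
    sc <- refinement_scope(inst, placed,
                           which(inst$edges$i %in% placed &
                                   inst$edges$j %in% placed))
    xw <- x
    xw[is.na(xw)] <- 0
    ref <- minimize_phi(xw, sc, params, max_iter, grad_tol)
    x[placed, ] <- ref$x[placed, , drop = FALSE]
    opt_stats$global <- list(iterations = ref$iterations, value = ref$value)
  }

  .finish_solve("lsbuild", inst, x, role, order_placed, clique_complete,
                opt_stats, config, truth, t0)
}

# smallest lexicographic 4-clique by ascending-index depth-first extension
.first_4clique <- function(g) {
  n <- g$n
  adj <- g$adj
  for (a in seq_len(n - 3)) {
    na <- which(adj[a, ]); na <- na[na > a]
    for (b in na) {
      nb <- na[adj[b, na]]; nb <- nb[nb > b]
      for (cc in nb) {
        ncc <- nb[adj[cc, nb]]; ncc <- ncc[ncc > cc]
        if (length(ncc) > 0) return(c(a, b, cc, ncc[1]))
      }
    }
  }
  NULL
}

#' Solve an MDGP instance with the modified geometric buildup baseline
#'
#' The substructure-solving buildup variant: seed the base with the first
#' 4-clique (ascending-index search) embedded from the sampled distances;
#' then repeatedly take the unplaced atom `k` with at least four placed
#' neighbours, form the substructure `B = {k} + placed neighbours of k`,
#' complete its internal distances (sampled `d(t)` where bounds exist,
#' current inter-anchor distances otherwise), re-solve the whole
#' substructure in a local frame via the Gram/rank-3 system, superpose it
#' onto the current anchor coordinates by an optimal orthogonal map, and
#' adopt `k`'s mapped position. Atoms that never reach four placed
#' neighbours remain unplaced. No smoothing refinement is applied — this is
#' the comparison baseline.
#'
#' @inheritParams solve_lsbuild
#' @return an `mdgp_solution`.
#' @export
solve_buildup <- function(inst, params = penalty_params(),
                          t_policy = c("uniform", "midpoint"), seed = 1,
                          min_anchors = 4, truth = NULL) {
  t_policy <- match.arg(t_policy)
  t0 <- Sys.time()
  config <- list(params = params, t_policy = t_policy, seed = seed,
                 min_anchors = min_anchors)
  g <- constraint_graph(inst)
  seed_clique <- .first_4clique(g)
  if (is.null(seed_clique)) rlang::abort("no valid base: the constraint graph has no 4-clique")
  d <- sample_distances(inst, policy = t_policy, seed = seed)

  x <- matrix(NA_real_, inst$n, 3)
  x[seed_clique, ] <- embed_clique(d, seed_clique)
  role <- rep("unplaced", inst$n)
  role[seed_clique] <- "base"

  in_base <- rep(FALSE, inst$n)
  in_base[seed_clique] <- TRUE
  cnt <- .base_counts(d, in_base)
  order_placed <- integer(0)

  repeat {
    cnt[in_base] <- -1L
    cand <- which(cnt >= min_anchors)
    if (length(cand) == 0) break
    k <- cand[order(-cnt[cand], cand)][1]
    anchors <- intersect(which(in_base), neighbours_of(d, k))
    members <- c(anchors, k)
    # complete the substructure's internal distances
    dloc <- .substructure_distances(d, members, x)
    Xloc <- embed_clique(dloc, members)
    fit <- superpose_substructure(
      Xloc[seq_along(anchors), , drop = FALSE],
      x[anchors, , drop = FALSE])
    xk <- as.numeric(fit$Q %*% Xloc[length(members), ] + fit$translation)
    x[k, ] <- xk
    role[k] <- "placed"
    order_placed <- c(order_placed, k)
    in_base[k] <- TRUE
    cnt[d$nbr[[k]]] <- cnt[d$nbr[[k]]] + 1L
  }

  .finish_solve("buildup", inst, x, role, order_placed, TRUE, NULL,
                config, truth, t0)
}

# mdgp_distances-like lookup over a substructure: sampled d(t) where the
# pair is constrained, current coordinate distance otherwise
.substructure_distances <- function(d, members, x) {
  m <- length(members)
  nbr <- vector("list", max(members))
  dval <- vector("list", max(members))
  for (a in seq_len(m)) {
    ia <- members[a]
    nbr[[ia]] <- integer(0); dval[[ia]] <- numeric(0)
  }
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    ia <- members[a]; ib <- members[b]
    dd <- dist_between(d, ia, ib)
    if (is.na(dd)) {
      if (anyNA(x[ia, ]) || anyNA(x[ib, ])) next
      dd <- sqrt(sum((x[ia, ] - x[ib, ])^2))
    }
    nbr[[ia]] <- c(nbr[[ia]], ib); dval[[ia]] <- c(dval[[ia]], dd)
    nbr[[ib]] <- c(nbr[[ib]], ia); dval[[ib]] <- c(dval[[ib]], dd)
  }
  structure(list(n = max(members), nbr = nbr, dval = dval,
                 policy = d$policy, seed = d$seed),
            class = "mdgp_distances")
}
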