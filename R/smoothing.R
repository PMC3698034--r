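#' Penalty parameters
#'
#' `lam` (lambda) weights the penalty; `tau` controls how closely the smooth
#' surrogate hugs the piecewise-linear interval violation. Defaults
#' `lam = 1.0`, `tau = 0.01` are the values used throughout the package's
#' reference experiments.
#'
#' @param lam penalty weight, > 0.
#' @param tau smoothness, > 0.
#' @return a list of class `penalty_params`.
#' @export
penalty_params <- function(lam = 1.0, tau = 0.01) {
  stopifnot(lam > 0, tau > 0)
  structure(list(lam = lam, tau = tau), class = "penalty_params")
}

#' Refinement scope
#'
#' Restricts a refinement to a subset of movable atoms and a subset of
#' active edges (each active edge must touch at least one variable atom —
#' edges entirely between fixed atoms contribute a constant and are
#' rejected to keep scopes honest).
#'
#' @param inst an [mdgp_instance()].
#' @param variable_atoms atom indices whose coordinates may move.
#' @param active_edges integer rows of `inst$edges` to evaluate; default:
#'   all edges touching a variable atom.
#' @return a list of class `refinement_scope`.
#' @export
refinement_scope <- function(inst, variable_atoms,
                             active_edges = NULL) {
  variable_atoms <- sort(as.integer(variable_atoms))
  if (is.null(active_edges)) {
    active_edges <- which(inst$edges$i %in% variable_atoms |
                            inst$edges$j %in% variable_atoms)
  }
  e <- inst$edges[active_edges, , drop = FALSE]
  if (!all(e$i %in% variable_atoms | e$j %in% variable_atoms)) {
    rlang::abort("every active edge must touch at least one variable atom")
  }
  structure(list(variable_atoms = variable_atoms,
                 edges = e), class = "refinement_scope")
}

# pairwise distances over the scope's edges, with the deterministic jitter
# that keeps the gradient defined for coincident pairs
.scope_dists <- function(x, scope) {
  e <- scope$edges
  diff <- x[e$i, , drop = FALSE] - x[e$j, , drop = FALSE]
  dij <- sqrt(rowSums(diff^2))
  co <- dij < 1e-12
  if (any(co)) {
    diff[co, 1] <- diff[co, 1] + 1e-9
    dij[co] <- sqrt(rowSums(diff[co, , drop = FALSE]^2))
  }
  list(diff = diff, dij = dij)
}

#' Hyperbolic smooth interval-violation penalty
#'
#' For each active edge with bounds `(l, u)` and current distance `d`:
#' \deqn{\phi_{ij} = (\lambda/2)(l - u) + \theta(d, l) + \theta(d, u),\quad
#'       \theta(d, c) = (\lambda/2)\sqrt{(c - d)^2 + \tau^2}.}
#' This is the hyperbolic smoothing of the exact interval violation
#' `lambda * max(l - d, d - u, 0)`: as `tau -> 0` the two agree, and the
#' function is infinitely differentiable for any `tau > 0`, so quasi-Newton
#' methods apply. Up to an additive term of order `tau * |edges|` the value
#' is non-negative, vanishing exactly on satisfied edges in the `tau -> 0`
#' limit.
#'
#' @param x full n x 3 coordinate matrix.
#' @param scope a [refinement_scope()].
#' @param params [penalty_params()].
#' @return scalar penalty value.
#' @export
phi <- function(x, scope, params = penalty_params()) {
  e <- scope$edges
  if (nrow(e) == 0) return(0)
  dij <- .scope_dists(x, scope)$dij
  lam <- params$lam; tau <- params$tau
  sum((lam / 2) * (e$l - e$u) +
        (lam / 2) * sqrt((e$l - dij)^2 + tau^2) +
        (lam / 2) * sqrt((e$u - dij)^2 + tau^2))
}

#' Analytic gradient of [phi()]
#'
#' Gradient with respect to the variable atoms only; fixed atoms get zero
#' rows. Coincident constrained pairs are perturbed internally by a
#' deterministic 1e-9 jitter (the norm is not differentiable at zero), never
#' raised as an error.
#'
#' @inheritParams phi
#' @return an n x 3 matrix of partial derivatives (zero rows for atoms
#'   outside the scope).
#' @export
phi_gradient <- function(x, scope, params = penalty_params()) {
  e <- scope$edges
  g <- matrix(0, nrow(x), 3)
  if (nrow(e) == 0) return(g)
  sd <- .scope_dists(x, scope)
  dij <- sd$dij
  lam <- params$lam; tau <- params$tau
  # d phi / d dij
  dphi <- (lam / 2) * ((dij - e$l) / sqrt((e$l - dij)^2 + tau^2) +
                         (dij - e$u) / sqrt((e$u - dij)^2 + tau^2))
  w <- dphi / dij
  contrib <- sd$diff * w
  gi <- rowsum(contrib, e$i)
  gj <- rowsum(-contrib, e$j)
  g[as.integer(rownames(gi)), ] <- g[as.integer(rownames(gi)), ] + gi
  g[as.integer(rownames(gj)), ] <- g[as.integer(rownames(gj)), ] + gj
  fixed <- setdiff(seq_len(nrow(x)), scope$variable_atoms)
  g[fixed, ] <- 0
  g
}

#' Refine coordinates by limited-memory quasi-Newton descent of [phi()]
#'
#' Minimises the smooth penalty over the scope's variable atoms with
#' `stats::optim(method = "L-BFGS-B")` (limited-memory BFGS with a monotone
#' line search) using the analytic gradient. The returned coordinates never
#' have a larger penalty than the input.
#'
#' @param x0 starting n x 3 coordinate matrix (finite).
#' @param scope a [refinement_scope()].
#' @param params [penalty_params()].
#' @param max_iter iteration cap.
#' @param grad_tol projected-gradient tolerance.
#' @return a list with `x` (refined coordinates), `value`, `initial_value`,
#'   `iterations`, `converged`.
#' @export
minimize_phi <- function(x0, scope, params = penalty_params(),
                         max_iter = 500, grad_tol = 1e-6) {
  involved <- unique(c(scope$variable_atoms, scope$edges$i, scope$edges$j))
  if (!all(is.finite(x0[involved, ]))) {
    rlang::abort("phi is not finite at the starting point")
  }
  v0 <- phi(x0, scope, params)
  if (!is.finite(v0)) rlang::abort("phi is not finite at the starting point")
  va <- scope$variable_atoms
  x <- x0
  fn <- function(p) {
    x[va, ] <- matrix(p, length(va), 3)
    phi(x, scope, params)
  }
  gr <- function(p) {
    x[va, ] <- matrix(p, length(va), 3)
    as.vector(phi_gradient(x, scope, params)[va, , drop = FALSE])
  }
  opt <- stats::optim(as.vector(x0[va, , drop = FALSE]), fn, gr,
                      method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = grad_tol,
                                     factr = 10))
  if (opt$value <= v0) {
    x[va, ] <- matrix(opt$par, length(va), 3)
    value <- opt$value
  } else {
    x <- x0                      # monotonicity guard: never accept an increase
    value <- v0
  }
  list(x = x, value = value, initial_value = v0,
       iterations = opt$counts[["function"]],
       converged = opt$convergence == 0)
}
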