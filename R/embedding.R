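#' Sample a distance matrix inside the bounds
#'
#' Interval bounds are turned into a working distance for each edge by the
#' convex combination `d = (1 - t) * l + t * u`. Under the `"uniform"`
#' policy each edge draws an i.i.d. `t ~ U[0, 1]`; `"midpoint"` fixes
#' `t = 0.5` for deterministic runs. The sample always satisfies
#' `l <= d <= u`.
#'
#' @param inst an [mdgp_instance()].
#' @param policy `"uniform"` or `"midpoint"`.
#' @param seed integer seed (uniform policy).
#' @return an object of class `mdgp_distances`: the edge table with a `d`
#'   column plus per-atom neighbour lookup tables.
#' @export
sample_distances <- function(inst, policy = c("uniform", "midpoint"), seed = 1) {
  policy <- match.arg(policy)
  e <- inst$edges
  t <- if (policy == "uniform") {
    withr::with_seed(seed, stats::runif(nrow(e)))
  } else {
    rep(0.5, nrow(e))
  }
  e$d <- (1 - t) * e$l + t * e$u
  nbr <- vector("list", inst$n)
  dval <- vector("list", inst$n)
  for (k in seq_len(inst$n)) { nbr[[k]] <- integer(0); dval[[k]] <- numeric(0) }
  sp_i <- split(seq_len(nrow(e)), e$i)
  for (nm in names(sp_i)) {
    k <- as.integer(nm); rows <- sp_i[[nm]]
    nbr[[k]] <- c(nbr[[k]], e$j[rows]); dval[[k]] <- c(dval[[k]], e$d[rows])
  }
  sp_j <- split(seq_len(nrow(e)), e$j)
  for (nm in names(sp_j)) {
    k <- as.integer(nm); rows <- sp_j[[nm]]
    nbr[[k]] <- c(nbr[[k]], e$i[rows]); dval[[k]] <- c(dval[[k]], e$d[rows])
  }
  structure(list(n = inst$n, edges = e, nbr = nbr, dval = dval,
                 policy = policy, seed = seed),
            class = "mdgp_distances")
}

# sampled distance between atoms a and b; NA if the pair is unconstrained
dist_between <- function(d, a, b) {
  hit <- match(b, d$nbr[[a]])
  if (is.na(hit)) NA_real_ else d$dval[[a]][hit]
}

# neighbours of atom a in the sampled edge set
neighbours_of <- function(d, a) d$nbr[[a]]

#' Gram matrix of a clique from pairwise distances
#'
#' Translates the classic squared-distance identity into inner products:
#' with a designated origin member `o` translated to zero,
#' `<x_i, x_j> = (d_io^2 + d_jo^2 - d_ij^2) / 2` for all other members.
#' The members must be a clique of the sampled edge set (every pairwise
#' distance available).
#'
#' @param d an `mdgp_distances` object.
#' @param members atom indices forming a clique.
#' @param origin_member the member translated to the origin; its row and
#'   column are dropped.
#' @return a symmetric `(m-1) x (m-1)` matrix with rownames the non-origin
#'   members.
#' @export
gram_from_distances <- function(d, members, origin_member) {
  if (!(origin_member %in% members)) rlang::abort("origin_member must be one of the members")
  rest <- setdiff(members, origin_member)
  m <- length(rest)
  do <- vapply(rest, function(i) dist_between(d, i, origin_member), numeric(1))
  if (anyNA(do)) {
    rlang::abort(paste0("missing distance between origin and atom ",
                        rest[which(is.na(do))[1]], ": members are not a clique"))
  }
  G <- matrix(0, m, m, dimnames = list(rest, rest))
  for (a in seq_len(m)) {
    G[a, a] <- do[a]^2
    if (a < m) for (b in (a + 1):m) {
      dab <- dist_between(d, rest[a], rest[b])
      if (is.na(dab)) {
        rlang::abort(paste0("missing distance between atoms ", rest[a], " and ",
                            rest[b], ": members are not a clique"))
      }
      G[a, b] <- G[b, a] <- (do[a]^2 + do[b]^2 - dab^2) / 2
    }
  }
  G
}

#' Best rank-3 embedding of a Gram matrix
#'
#' Symmetric eigendecomposition of `G`; the three largest eigenvalues are
#' kept (negative kept eigenvalues clamped to zero, the standard
#' classical-scaling treatment of a non-Euclidean input) and coordinates are
#' `V * sqrt(lambda)`. By Eckart--Young this minimises the Frobenius error
#' among factorizations of rank at most 3. The origin member of the Gram
#' construction maps to the zero vector and is *not* part of the output.
#'
#' @param G symmetric matrix (asymmetry beyond 1e-8 is an error).
#' @return an `nrow(G) x 3` coordinate matrix (rownames preserved).
#' @export
rank3_embed <- function(G) {
  if (max(abs(G - t(G))) > 1e-8) rlang::abort("Gram matrix is not symmetric")
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  k <- min(3, ncol(G))
  lam <- pmax(eg$values[seq_len(k)], 0)
  X <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  if (k < 3) X <- cbind(X, matrix(0, nrow(G), 3 - k))
  rownames(X) <- rownames(G)
  X
}

# embed a clique: origin at zero, the rest via the rank-3 Gram factorization
embed_clique <- function(d, members, origin_member = members[1]) {
  X <- matrix(0, length(members), 3, dimnames = list(members, NULL))
  if (length(members) > 1) {
    G <- gram_from_distances(d, members, origin_member)
    X[rownames(G), ] <- rank3_embed(G)
  }
  X
}

#' The anchored base of a partial solution
#'
#' @param members atom indices already placed.
#' @param coords their coordinates (one row per member, in member order).
#' @param origin_member reference member used for Gram constructions.
#' @return an object of class `mdgp_base`.
#' @export
new_base <- function(members, coords, origin_member = members[1]) {
  stopifnot(length(members) == nrow(coords), !anyDuplicated(members),
            origin_member %in% members, all(is.finite(coords)))
  rownames(coords) <- members
  structure(list(members = as.integer(members), coords = coords,
                 origin_member = as.integer(origin_member)),
            class = "mdgp_base")
}

# base neighbour of j with most shared neighbours among j's anchors
# (improves conditioning of the linear system); ties by lowest index
.pick_reference <- function(d, j, anchors) {
  shared <- vapply(anchors, function(a) sum(anchors %in% d$nbr[[a]]), numeric(1))
  anchors[order(-shared, anchors)][1]
}

#' Place an atom from at least four anchored neighbours
#'
#' Linearises the distance equations against a reference anchor `o`: in the
#' frame translated so `x_o = 0`, every other anchored neighbour `i` of `j`
#' gives the linear equation `<x_i, x_j> = (d_io^2 + d_jo^2 - d_ij^2)/2`
#' (`d_io` taken from the anchors' actual coordinates, `d_jo`/`d_ij` from the
#' sampled distances). The overdetermined system is solved in the
#' least-squares sense.
#'
#' @param j the atom to place.
#' @param base an `mdgp_base`.
#' @param d an `mdgp_distances`.
#' @return a list with `coords` (3-vector), `condition` (condition number of
#'   the anchor system), `degenerate` (near-coplanar anchors flag),
#'   `residual` (least-squares residual norm).
#' @export
place_point <- function(j, base, d) {
  anchors <- intersect(base$members, neighbours_of(d, j))
  if (length(anchors) < 4) {
    rlang::abort(paste0("insufficient anchors for atom ", j, ": ",
                        length(anchors), " < 4"))
  }
  o <- .pick_reference(d, j, anchors)
  others <- setdiff(anchors, o)
  xo <- base$coords[as.character(o), ]
  A <- base$coords[as.character(others), , drop = FALSE] -
    matrix(xo, length(others), 3, byrow = TRUE)
  djo <- dist_between(d, j, o)
  dji <- vapply(others, function(i) dist_between(d, j, i), numeric(1))
  b <- (rowSums(A^2) + djo^2 - dji^2) / 2
  sv <- svd(A)
  condition <- sv$d[1] / sv$d[3]
  degenerate <- sv$d[3] < 1e-6 * sv$d[1]
  # pseudo-inverse solve: near-zero singular directions get no component,
  # so a degenerate anchor set still yields a finite (min-norm) answer
  dinv <- ifelse(sv$d > 1e-12 * sv$d[1], 1 / sv$d, 0)
  y <- sv$v %*% (crossprod(sv$u, b) * dinv)
  list(coords = as.numeric(xo + y),
       condition = condition,
       degenerate = degenerate,
       residual = sqrt(sum((A %*% y - b)^2)))
}

#' Place an atom from one to three anchored neighbours
#'
#' The same linear system as [place_point()] is rank-deficient with fewer
#' than four anchors. The minimum-norm (pseudo-inverse) solution is taken
#' and then shifted along a deterministic null-space direction so that the
#' distance to the reference anchor is met exactly — with one anchor this
#' yields *a* point at the sampled distance, with three consistent anchors a
#' point on the solution circle. The placement is flagged low-confidence.
#'
#' @inheritParams place_point
#' @return a list with `coords`, `n_anchors`, `low_confidence = TRUE`.
#' @export
place_underdetermined <- function(j, base, d) {
  anchors <- intersect(base$members, neighbours_of(d, j))
  if (length(anchors) == 0) {
    rlang::abort(paste0("disconnected atom ", j, ": no anchors in the base"))
  }
  if (length(anchors) > 3) {
    rlang::abort("use place_point for atoms with four or more anchors")
  }
  o <- .pick_reference(d, j, anchors)
  others <- setdiff(anchors, o)
  xo <- base$coords[as.character(o), ]
  djo <- dist_between(d, j, o)
  if (length(others) == 0) {
    y <- c(djo, 0, 0)
  } else {
    A <- base$coords[as.character(others), , drop = FALSE] -
      matrix(xo, length(others), 3, byrow = TRUE)
    dji <- vapply(others, function(i) dist_between(d, j, i), numeric(1))
    b <- (rowSums(A^2) + djo^2 - dji^2) / 2
    sv <- svd(A)
    tol <- max(sv$d) * 1e-10
    pos <- which(sv$d > tol)
    y <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], b) / sv$d[pos])
    # orthonormal basis of the null space of A (orthogonal complement of
    # its row space), via the complete QR of t(A)
    Q <- qr.Q(qr(t(A)), complete = TRUE)
    null_basis <- Q[, setdiff(seq_len(3), seq_len(length(pos))), drop = FALSE]
    if (ncol(null_basis) > 0) {
      nb <- null_basis[, 1]
      nz <- which(abs(nb) > 1e-12)[1]
      if (!is.na(nz) && nb[nz] < 0) nb <- -nb       # deterministic sign
      alpha <- sqrt(max(0, djo^2 - sum(y^2)))
      y <- as.numeric(y) + alpha * nb
    }
  }
  list(coords = as.numeric(xo + y), n_anchors = length(anchors),
       low_confidence = TRUE)
}
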