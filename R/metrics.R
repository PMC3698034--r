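#' Largest-distance-mean-error (root-mean-square interval violation)
#'
#' For every edge the violation is
#' `e_ij = max(l - ||x_i - x_j||, ||x_i - x_j|| - u, 0)`, zero when the
#' bound is satisfied; the LDME is the root mean square of the `e_ij` over
#' all edges. It measures solution quality against the constraints alone,
#' without reference to any ground truth, and is invariant under rigid
#' motions of `x`.
#'
#' @param x n x 3 coordinate matrix.
#' @param inst an [mdgp_instance()].
#' @return scalar LDME (Angstrom).
#' @seealso [edge_violations()] for the per-edge breakdown.
#' @export
ldme <- function(x, inst) {
  v <- edge_violations(x, inst)
  sqrt(mean(v$violation^2))
}

#' Per-edge interval violations
#'
#' @inheritParams ldme
#' @return the instance's edge table plus the realised distance `d` and the
#'   `violation` `e_ij` per edge.
#' @export
edge_violations <- function(x, inst) {
  e <- inst$edges
  if (nrow(e) == 0) rlang::abort("instance has no edges")
  d <- sqrt(rowSums((x[e$i, , drop = FALSE] - x[e$j, , drop = FALSE])^2))
  e$d <- d
  e$violation <- pmax(e$l - d, d - e$u, 0)
  e
}

#' Optimal rigid/mirror superposition of two point sets
#'
#' Least-squares Procrustes fit of `moving` onto `fixed` over the full
#' orthogonal group (reflections permitted — pairwise distances cannot fix
#' chirality) plus translation: centre both sets, take the SVD of the
#' cross-covariance, and compose. Returns the orthogonal matrix `Q`, the
#' translation, the per-point mapped coordinates and the residual RMS.
#'
#' @param moving m x 3 coordinates to be mapped.
#' @param fixed m x 3 target coordinates (same row correspondence).
#' @return a list with `Q` (3 x 3 orthogonal), `translation`, `mapped`,
#'   `rms`, `det_Q`, `degenerate` (collinear correspondence flag).
#' @export
superpose_substructure <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3, ncol(fixed) == 3)
  if (nrow(fixed) < 3) rlang::abort("at least 3 correspondence points are needed")
  cm_m <- colMeans(moving)
  cm_f <- colMeans(fixed)
  M <- sweep(moving, 2, cm_m)
  Fc <- sweep(fixed, 2, cm_f)
  sv <- svd(crossprod(M, Fc))         # 3x3 cross-covariance
  Q <- sv$v %*% t(sv$u)               # maps centred moving onto centred fixed
  svf <- svd(Fc)
  degenerate <- svf$d[2] < 1e-9 * max(svf$d[1], 1e-300)
  mapped <- M %*% t(Q) + matrix(cm_f, nrow(M), 3, byrow = TRUE)
  list(Q = Q,
       translation = as.numeric(cm_f - Q %*% cm_m),
       mapped = mapped,
       rms = sqrt(mean(rowSums((mapped - fixed)^2))),
       det_Q = det(Q),
       degenerate = degenerate)
}

#' Root-mean-square deviation after optimal superposition
#'
#' `RMSD = (1/sqrt(n)) * min over orthogonal Q and translation h of
#' ||truth - Q(x - h)||_F`; the minimum is attained by the Procrustes
#' solution of [superpose_substructure()]. Reflections are allowed, because
#' distance data cannot determine handedness. The value is the per-atom
#' root-mean-square deviation in Angstrom.
#'
#' @param x n x 3 solved coordinates.
#' @param truth n x 3 reference coordinates (same atom order).
#' @return scalar RMSD (Angstrom).
#' @export
rmsd <- function(x, truth) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.matrix(truth)) truth <- as.matrix(truth)
  if (nrow(x) != nrow(truth)) rlang::abort("coordinate sets must have equal atom counts")
  if (nrow(x) < 3) rlang::abort("RMSD needs at least 3 atoms")
  superpose_substructure(x, truth)$rms
}
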