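# tiny helper: sampled distances over a complete exact instance of a point set
exact_distances <- function(m) {
  sample_distances(complete_exact_instance(m), policy = "midpoint")
}

test_that("distance sampling stays inside the bounds and honours the policy", {
  s <- generate_synthetic_structure(20, seed = 1)
  inst <- build_morewu_instance(s, 0.1)
  mid <- sample_distances(inst, policy = "midpoint")
  expect_equal(mid$edges$d, (inst$edges$l + inst$edges$u) / 2)

  uni <- sample_distances(inst, policy = "uniform", seed = 3)
  expect_true(all(uni$edges$d >= inst$edges$l & uni$edges$d <= inst$edges$u))
  expect_identical(uni$edges$d,
                   sample_distances(inst, policy = "uniform", seed = 3)$edges$d)
  expect_false(identical(uni$edges$d,
                         sample_distances(inst, policy = "uniform", seed = 4)$edges$d))
})

test_that("the Gram construction reproduces hand algebra and true inner products", {
  # two points at distance 1: the single Gram entry is d^2
  m2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  G1 <- gram_from_distances(exact_distances(m2), members = c(1, 2),
                            origin_member = 1)
  expect_equal(unname(G1), matrix(1), tolerance = 1e-12)

  # unit right triangle: off-diagonal entry (1 + 1 - 2)/2 = 0
  G <- gram_from_distances(exact_distances(m2), members = 1:3, origin_member = 1)
  expect_equal(unname(G), diag(2), tolerance = 1e-12)

  # any exact point set: G equals the centred inner-product matrix
  withr::with_seed(11, {
    m <- matrix(rnorm(18), 6, 3)
  })
  G6 <- gram_from_distances(exact_distances(m), members = 1:6, origin_member = 3)
  rest <- setdiff(1:6, 3)
  centred <- m[rest, ] - matrix(m[3, ], 5, 3, byrow = TRUE)
  expect_equal(unname(G6), unname(tcrossprod(centred)), tolerance = 1e-9)

  # missing pair distance -> clique precondition error
  inst <- mdgp_instance(3, tibble::tibble(i = c(1, 1), j = c(2, 3), l = 1, u = 1))
  expect_error(gram_from_distances(sample_distances(inst, "midpoint"), 1:3, 1),
               "not a clique")
})

test_that("rank-3 embedding recovers exact and rank-deficient configurations", {
  withr::with_seed(21, m <- matrix(rnorm(24), 8, 3))
  d <- exact_distances(m)
  G <- gram_from_distances(d, 1:8, origin_member = 1)
  X <- rank3_embed(G)
  X_full <- rbind(0, X)
  expect_equal(as.matrix(dist(X_full)), as.matrix(dist(m)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # planar points: rank-2 Gram, planar output with exact distances
  withr::with_seed(22, mp <- cbind(matrix(rnorm(10, sd = 2), 5, 2), 0))
  dp <- exact_distances(mp)
  Gp <- gram_from_distances(dp, 1:5, origin_member = 1)
  Xp <- rank3_embed(Gp)
  expect_equal(as.matrix(dist(rbind(0, Xp))), as.matrix(dist(mp)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(svd(rbind(0, Xp))$d[3], 1e-6)

  expect_error(rank3_embed(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("rank-3 embedding is the Eckart-Young optimum under perturbation", {
  withr::with_seed(31, {
    m <- matrix(rnorm(21), 7, 3)
    P <- matrix(rnorm(36, sd = 1), 6, 6)
  })
  d <- exact_distances(m)
  G0 <- gram_from_distances(d, 1:7, origin_member = 1)
  errs <- vapply(c(0.5, 0.1, 0.01), function(eps) {
    G <- G0 + eps * (P + t(P)) / 2
    X <- rank3_embed(G)
    # compare against truncating the full eigendecomposition (oracle)
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0); lam[-(1:3)] <- 0
    Gbest <- eg$vectors %*% diag(lam) %*% t(eg$vectors)
    expect_equal(tcrossprod(X), Gbest, tolerance = 1e-7, ignore_attr = TRUE)
    norm(tcrossprod(X) - G0, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))   # error shrinks as the perturbation does
})

test_that("fully-anchored placement recovers exact positions", {
  withr::with_seed(41, m <- rbind(matrix(rnorm(30, sd = 3), 10, 3),
                                  c(1, 1, 1)))
  d <- exact_distances(m)
  base <- new_base(1:10, m[1:10, ])

  p <- place_point(11, base, d)
  expect_equal(p$coords, m[11, ], tolerance = 1e-8, ignore_attr = TRUE)
  expect_lt(p$residual, 1e-8)
  expect_false(p$degenerate)

  # 4 anchors only
  base4 <- new_base(1:4, m[1:4, ])
  p4 <- place_point(11, base4, d)
  expect_equal(p4$coords, m[11, ], tolerance = 1e-7, ignore_attr = TRUE)

  # coplanar anchors raise the degeneracy flag but still answer
  mc <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(0.3, 0.4, 2))
  dc <- exact_distances(mc)
  basec <- new_base(1:4, mc[1:4, ])
  pc <- place_point(5, basec, dc)
  expect_true(pc$degenerate)
  expect_true(all(is.finite(pc$coords)))

  expect_error(place_point(5, new_base(1:3, mc[1:3, ]), dc), "insufficient anchors")
})

test_that("underdetermined placement meets the distances it can", {
  m <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(1, 1, 1.2))
  d <- exact_distances(m)

  # one anchor: any point at the right distance is acceptable
  b1 <- new_base(1L, m[1, , drop = FALSE])
  p1 <- place_underdetermined(4, b1, d)
  expect_equal(sqrt(sum((p1$coords - m[1, ])^2)), sqrt(sum(m[4, ]^2)),
               tolerance = 1e-9)
  expect_true(p1$low_confidence)

  # three non-collinear anchors, consistent distances: all residuals ~ 0
  b3 <- new_base(1:3, m[1:3, ])
  p3 <- place_underdetermined(4, b3, d)
  for (a in 1:3) {
    expect_equal(sqrt(sum((p3$coords - m[a, ])^2)),
                 sqrt(sum((m[4, ] - m[a, ])^2)), tolerance = 1e-8)
  }

  # no anchors
  inst <- mdgp_instance(5, tibble::tibble(i = 1, j = 2, l = 1, u = 1))
  d0 <- sample_distances(inst, "midpoint")
  expect_error(place_underdetermined(5, b1, d0), "disconnected atom")
  m5 <- rbind(m, c(2, 2, 0.4))
  d5 <- exact_distances(m5)
  expect_error(place_underdetermined(5, new_base(1:4, m), d5), "place_point")
})

test_that("placement is invariant to the reference-anchor choice on exact data", {
  withr::with_seed(51, m <- rbind(matrix(rnorm(18, sd = 2), 6, 3), c(0.5, 0.5, 0.5)))
  # relabel the anchors so the tie-break designates a different physical
  # anchor as reference each time; the placed point must not move
  res <- vapply(1:6, function(o) {
    perm <- c(o, setdiff(1:6, o))
    mp <- rbind(m[perm, ], m[7, ])
    dp <- exact_distances(mp)
    place_point(7, new_base(1:6, mp[1:6, ]), dp)$coords
  }, numeric(3))
  expect_lt(max(apply(res, 1, function(r) diff(range(r)))), 1e-8)
})
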