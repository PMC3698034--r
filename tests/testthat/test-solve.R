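test_that("lsbuild recovers exact-distance instances to numerical precision", {
  s <- generate_synthetic_structure(50, seed = 20)
  inst <- build_morewu_instance(s, 0)
  sol <- solve_lsbuild(inst, seed = 1, truth = s)
  expect_lte(sol$report$ldme, 1e-8)
  expect_lte(sol$report$rmsd, 1e-4)
  expect_equal(sol$report$n_unplaced, 0)
})

test_that("lsbuild satisfies interval bounds on mildly inaccurate instances", {
  s <- generate_synthetic_structure(100, seed = 21)
  inst <- build_morewu_instance(s, 0.08)
  feasible <- vapply(1:5, function(r) {
    solve_lsbuild(inst, seed = r)$report$ldme == 0
  }, logical(1))
  expect_gte(sum(feasible), 4)
})

test_that("the solution report accounting always sums to n", {
  s <- generate_synthetic_structure(60, seed = 22)
  for (inst in list(build_morewu_instance(s, 0.05),
                    build_biswas_instance(s, seed = 1),
                    build_biswas_instance(s, keep_fraction = 0.35, seed = 2))) {
    sol <- solve_lsbuild(inst, seed = 3)
    r <- sol$report
    expect_equal(r$base_size + r$n_fully_anchored + r$n_underdetermined +
                   r$n_unplaced, inst$n)
    gl <- glance(sol)
    expect_s3_class(gl, "tbl_df")
    expect_equal(nrow(gl), 1)
  }
})

test_that("disconnected components are reported unplaced without crashing", {
  pr <- t(utils::combn(5, 2))
  edges <- rbind(tibble::tibble(i = pr[, 1], j = pr[, 2], l = 1, u = 2),
                 tibble::tibble(i = pr[, 1] + 5, j = pr[, 2] + 5, l = 1, u = 2))
  inst <- mdgp_instance(10, edges)
  sol <- solve_lsbuild(inst, seed = 1)
  expect_equal(sol$report$n_unplaced, 5)
  # exactly one of the two components is solved, the other left unplaced
  unplaced <- sort(which(sol$report$role == "unplaced"))
  expect_true(identical(unplaced, 1:5) || identical(unplaced, 6:10))
  td <- tidy(sol)
  expect_equal(sum(td$role == "unplaced"), 5)
})

test_that("a graph with no 4-clique is refused as a base", {
  inst <- mdgp_instance(5, tibble::tibble(i = 1:4, j = 2:5, l = 1, u = 1))
  expect_error(solve_lsbuild(inst), "no valid base")
  expect_error(solve_buildup(inst), "no valid base")
})

test_that("placement order follows the dynamic base-constraint priority", {
  # hand-checkable example: base {1,2,3,4}; atoms 5 and 6 both start with 4
  # base edges (tie broken by index), atom 7 becomes eligible only after
  # 5 and 6 have joined the base
  edges <- tibble::tibble(
    i = c(1, 1, 1, 2, 2, 3,                    # base clique 1-4
          1, 2, 3, 4,                          # atom 5: 4 base edges
          1, 2, 3, 4, 5,                       # atom 6: 5 base edges
          3, 4, 5, 6),                         # atom 7: 2 + 2 later
    j = c(2, 3, 4, 3, 4, 4,
          5, 5, 5, 5,
          6, 6, 6, 6, 6,
          7, 7, 7, 7),
    l = 1, u = 2)
  inst <- mdgp_instance(7, edges)
  d <- sample_distances(inst, "midpoint")
  got <- placement_order(d, base = 1:4)

  # independent simulation with a plain adjacency matrix
  adj <- matrix(FALSE, 7, 7)
  adj[cbind(edges$i, edges$j)] <- TRUE
  adj <- adj | t(adj)
  in_base <- c(rep(TRUE, 4), rep(FALSE, 3))
  expected <- integer(0)
  repeat {
    cnt <- vapply(1:7, function(a) if (in_base[a]) -1L else sum(adj[a, in_base]),
                  integer(1))
    if (max(cnt) < 4) break
    pick <- which(cnt == max(cnt))[1]
    expected <- c(expected, pick)
    in_base[pick] <- TRUE
  }
  expect_equal(got, expected)
  expect_equal(got, c(5L, 6L, 7L))   # frozen from the hand simulation

  # larger instance: property check against the same simulation
  s <- generate_synthetic_structure(48, seed = 23, atoms_per_residue = 4)
  inst2 <- build_morewu_instance(s, 0)
  d2 <- sample_distances(inst2, "midpoint")
  base2 <- max_clique(constraint_graph(inst2))
  ord <- placement_order(d2, base2)
  expect_true(!any(duplicated(ord)))
  expect_true(all(!(ord %in% base2)))
})

test_that("identical (instance, config, seed) reproduce the base and order", {
  s <- generate_synthetic_structure(70, seed = 24)
  inst <- build_biswas_instance(s, seed = 5)
  a <- solve_lsbuild(inst, seed = 11)
  b <- solve_lsbuild(inst, seed = 11)
  expect_identical(a$report$placement_order, b$report$placement_order)
  expect_identical(a$report$role, b$report$role)
  expect_identical(which(a$report$role == "base"), which(b$report$role == "base"))
})

test_that("buildup reconstructs exact data and mirrors the report schema", {
  withr::with_seed(61, m <- matrix(rnorm(30, sd = 3), 10, 3))
  inst <- complete_exact_instance(m)
  sol <- solve_buildup(inst, seed = 1, truth = structure_from_coords(m))
  expect_lte(sol$report$rmsd, 1e-6)

  s <- generate_synthetic_structure(100, seed = 25)
  inst2 <- build_morewu_instance(s, 0)
  sol2 <- solve_buildup(inst2, seed = 2, truth = s)
  expect_lte(sol2$report$ldme, 1e-8)
  expect_lte(sol2$report$rmsd, 1e-4)
  expect_equal(names(glance(sol2)), names(glance(solve_lsbuild(inst2, seed = 2))))
})

test_that("buildup leaves atoms with under four anchors unplaced", {
  # 4-clique plus an atom connected to only 3 of it
  edges <- tibble::tibble(i = c(1, 1, 1, 2, 2, 3, 1, 2, 3),
                          j = c(2, 3, 4, 3, 4, 4, 5, 5, 5),
                          l = c(rep(1.5, 6), rep(1.2, 3)),
                          u = c(rep(1.6, 6), rep(1.3, 3)))
  inst <- mdgp_instance(5, edges)
  sol <- solve_buildup(inst, seed = 1)
  expect_equal(sol$report$role[5], "unplaced")
  # lsbuild instead places it through the underdetermined system
  sol2 <- solve_lsbuild(inst, seed = 1)
  expect_equal(sol2$report$role[5], "underdetermined")
  expect_equal(sol2$report$n_unplaced, 0)
})

test_that("solutions expose tidy coordinates and a violation plot", {
  s <- generate_synthetic_structure(40, seed = 26)
  inst <- build_morewu_instance(s, 0.05)
  sol <- solve_lsbuild(inst, seed = 1, truth = s)
  td <- tidy(sol)
  expect_equal(nrow(td), 40)
  expect_named(td, c("atom_id", "x", "y", "z", "role"))
  p <- autoplot(sol, inst)
  expect_s3_class(p, "ggplot")
})
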