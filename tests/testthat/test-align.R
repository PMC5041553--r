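test_that("optimal rotation recovers a known rotation and is reflection-safe", {
  set.seed(61)
  Q1 <- random_srvf(12, dim = 5, k = 2L)
  expect_equal(optimal_rotation(Q1, Q1)$spatial, diag(3), tolerance = 1e-10)

  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)  # Rz(pi/2)
  Q2 <- Q1
  Q2$values[1:3, ] <- Rz %*% Q2$values[1:3, ]
  rec <- optimal_rotation(Q1, Q2)
  expect_equal(rec$spatial, t(Rz), tolerance = 1e-8)
  expect_equal(srvf_inner_product(Q1, apply_rotation(Q2, rec)),
               srvf_inner_product(Q1, Q1), tolerance = 1e-10)
  # auxiliary block is the identity
  expect_equal(rec$full[4:5, 4:5], diag(2))

  # planar curve vs its mirror image: proper rotation only, and at least as
  # good as a brute-force search over random rotations
  Qp <- random_srvf(10)
  Qp$values[3, ] <- 0
  Qm <- Qp
  Qm$values[1, ] <- -Qm$values[1, ]
  rot <- suppressWarnings(optimal_rotation(Qp, Qm))
  expect_equal(det(rot$spatial), 1, tolerance = 1e-10)
  kabsch <- srvf_inner_product(Qp, apply_rotation(Qm, rot))
  best_rand <- max(vapply(1:2000, function(i) {
    Rr <- random_rotation()
    srvf_inner_product(Qp, apply_rotation(Qm, Rr))
  }, numeric(1)))
  expect_gte(kabsch, best_rand - 1e-10)
})

test_that("applying a rotation preserves the inner product and composes", {
  set.seed(62)
  Q <- random_srvf(8)
  R <- random_rotation(3)
  expect_equal(apply_rotation(Q, diag(3))$values, Q$values)
  expect_equal(srvf_inner_product(apply_rotation(Q, R), apply_rotation(Q, R)),
               srvf_inner_product(Q, Q), tolerance = 1e-12)
  twice <- apply_rotation(apply_rotation(Q, R), R)
  once <- apply_rotation(Q, R %*% R)
  expect_equal(twice$values, once$values, tolerance = 1e-12)
})

test_that("segment matching cost agrees with hand quadrature and is non-negative", {
  # two-interval toy on grid (0, 0.4, 1), constant q1, q2
  Q1 <- structure(list(values = matrix(c(1, 0, 0), 3, 3), grid = c(0, 0.4, 1),
                       k = 0L), class = "esa_srvf")
  Q2 <- structure(list(values = matrix(c(0, 2, 0), 3, 3), grid = c(0, 0.4, 1),
                       k = 0L), class = "esa_srvf")
  expect_equal(matching_cost(Q1, Q1, 1, 3, 1, 3), 0, tolerance = 1e-14)
  # matching [0, 0.4] of Q1 to [0.4, 1] of Q2: slope 1.5, integrand
  # ||(1,0,0) - sqrt(1.5)(0,2,0)||^2 = 1 + 6 over width 0.4
  expect_equal(matching_cost(Q1, Q2, 1, 2, 2, 3), 0.4 * 7, tolerance = 1e-12)
  set.seed(63)
  for (r in 1:20) {
    Qa <- random_srvf(6)
    Qb <- Qa
    Qb$values <- matrix(rnorm(18), 3)
    expect_gte(matching_cost(Qa, Qb, 1, sample(2:6, 1), 1, sample(2:6, 1)), 0)
  }
  expect_error(matching_cost(Q1, Q2, 3, 1, 1, 3), "increasing")
})

test_that("dynamic programming equals exhaustive path enumeration on small grids", {
  set.seed(64)
  for (r in 1:25) {
    n <- sample(4:7, 1)
    Q1 <- random_srvf(n)
    Q2 <- Q1
    Q2$values <- matrix(rnorm(3 * n), 3)
    dp <- optimal_matching(Q1, Q2, window = 5)
    expect_equal(dp$matched_cost, enum_matching_cost(Q1, Q2, 5),
                 tolerance = 1e-12)
    # warp endpoints and monotonicity
    expect_equal(dp$gamma_values[1], 0)
    expect_equal(dp$gamma_values[length(dp$gamma_values)], 1)
    expect_true(all(diff(dp$gamma_values) > 0))
  }
})

test_that("matching an identical curve returns the identity warp at zero cost", {
  set.seed(65)
  Q <- random_srvf(20)
  m <- optimal_matching(Q, Q)
  expect_equal(m$matched_cost, 0, tolerance = 1e-12)
  expect_equal(m$gamma_values, m$change_points)
  expect_equal(m$warped$values, Q$values, tolerance = 1e-12)
})

test_that("optimal matching never exceeds the identity-warp cost", {
  set.seed(66)
  for (r in 1:5) {
    n <- 15
    Q1 <- random_srvf(n)
    Q2 <- Q1
    Q2$values <- Q2$values + matrix(rnorm(3 * n, sd = 0.3), 3)
    identity_cost <- sum(vapply(seq_len(n - 1), function(i)
      matching_cost(Q1, Q2, i, i + 1, i, i + 1), numeric(1)))
    expect_lte(optimal_matching(Q1, Q2)$matched_cost, identity_cost + 1e-12)
  }
})

test_that("geodesic distance behaves on identical, orthogonal and oracle cases", {
  mkc <- function(v) normalize_srvf(structure(
    list(values = matrix(v, 3, 4), grid = c(0, 0.2, 0.7, 1), k = 0L),
    class = "esa_srvf"))
  e1 <- mkc(c(1, 0, 0))
  e2 <- mkc(c(0, 1, 0))
  expect_equal(geodesic_distance(e1, e1)$theta, 0, tolerance = 1e-12)
  expect_equal(geodesic_distance(e1, e2)$theta, pi / 2, tolerance = 1e-12)
  set.seed(67)
  Qa <- normalize_srvf(random_srvf(7))
  Qb <- Qa
  Qb$values <- matrix(rnorm(21), 3)
  Qb <- normalize_srvf(Qb)
  d <- srvf_inner_product(Qa, Qb)
  expect_equal(geodesic_distance(Qa, Qb)$theta, acos(d), tolerance = 1e-12)
})

test_that("end-to-end comparison is reflexive and orders noise below fold change", {
  h <- make_chain(fixture_spec(50, "helix", seed = 1))
  expect_lt(quiet_compare(h, h)$theta, 1e-6)
  R <- random_rotation(17)
  expect_lt(quiet_compare(h, rigid_motion(h, R, c(3, -8, 12)))$theta, 1e-5)
  noisy <- make_chain(fixture_spec(50, "helix", noise_sigma = 0.1, seed = 23))
  strand <- make_chain(fixture_spec(50, "strand", seed = 24))
  th_noise <- quiet_compare(h, noisy)$theta
  th_fold <- quiet_compare(h, strand)$theta
  expect_gt(th_fold, th_noise)
})

test_that("the distance is near-symmetric and the result object is complete", {
  # exact symmetry is not guaranteed (the warp is applied to the second
  # curve only): tight for related shapes, looser for distant ones
  a1 <- make_chain(fixture_spec(30, "helix", noise_sigma = 0.3, seed = 31))
  a2 <- make_chain(fixture_spec(30, "helix", noise_sigma = 0.3, seed = 32))
  expect_lt(abs(quiet_compare(a1, a2)$theta - quiet_compare(a2, a1)$theta),
            0.02)
  a <- make_chain(fixture_spec(30, "helix", noise_sigma = 0.3, seed = 31))
  b <- make_chain(fixture_spec(34, "coil", seed = 32))
  ab <- quiet_compare(a, b)
  ba <- quiet_compare(b, a)
  expect_lt(abs(ab$theta - ba$theta), 0.05)
  expect_s3_class(ab, "esa_alignment")
  expect_equal(ab$theta, acos(ab$cosine), tolerance = 1e-12)
  expect_true(ab$theta >= 0 && ab$theta <= pi)
  expect_equal(ab$n_res, c(30, 34))
  expect_output(print(ab), "geodesic distance")
  rep <- jsonlite::fromJSON(esa_report(ab))
  expect_equal(rep$theta, ab$theta, tolerance = 1e-12)
})
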