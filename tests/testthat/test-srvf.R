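test_that("arc-length grid matches hand-computed values and spatial-only rule", {
  P <- t(matrix(c(0, 0, 0, 3, 0, 0, 6, 4, 0), 3, byrow = TRUE))
  g <- arc_length_param(P)$grid
  expect_equal(g, c(0, 0.375, 1))  # segments 3 and 5, cumulative (0,3,8)/8
  expect_equal(arc_length_param(cbind(c(0, 0, 0), c(1, 0, 0)))$grid, c(0, 1))
  # an auxiliary row must not change the grid
  Paux <- rbind(P, c(100, -50, 7))
  expect_equal(arc_length_param(Paux)$grid, g)
})

test_that("duplicate spatial points are collapsed; fully degenerate curves error", {
  P <- t(matrix(c(0, 0, 0, 0, 0, 0, 1, 0, 0, 2, 0, 0), 4, byrow = TRUE))
  expect_message(out <- arc_length_param(P), "duplicate")
  expect_equal(ncol(out$curve), 3)
  expect_equal(out$dropped, 2L)
  Pc <- matrix(1, 3, 4)
  expect_error(suppressMessages(arc_length_param(Pc)), "degenerate")
})

test_that("SRVF of a unit-speed line is constant (1,0,0)", {
  P <- rbind(seq(0, 1, length.out = 5), 0, 0)
  Q <- srvf_transform(arc_length_param(P))
  expect_equal(Q$values, matrix(rep(c(1, 0, 0), 5), 3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("spatial scaling leaves the grid unchanged and Q scales as sqrt(c)", {
  set.seed(21)
  P <- matrix(rnorm(3 * 8), 3)
  p1 <- arc_length_param(P)
  p4 <- arc_length_param(4 * P)
  expect_equal(p4$grid, p1$grid, tolerance = 1e-12)
  Q1 <- srvf_transform(p1)
  Q4 <- srvf_transform(p4)
  expect_equal(Q4$values, 2 * Q1$values, tolerance = 1e-9)
  expect_equal(normalize_srvf(Q4)$values, normalize_srvf(Q1)$values,
               tolerance = 1e-9)
})

test_that("translation of the spatial rows changes neither grid nor SRVF", {
  set.seed(22)
  P <- rbind(matrix(rnorm(3 * 10), 3), rnorm(10))
  Pt <- P
  Pt[1:3, ] <- Pt[1:3, ] + c(5, -3, 11)
  a <- arc_length_param(P)
  b <- arc_length_param(Pt)
  expect_equal(b$grid, a$grid, tolerance = 1e-12)
  expect_equal(srvf_transform(b)$values, srvf_transform(a)$values,
               tolerance = 1e-9)
})

test_that("grid merging keeps unique values and respects the length bound", {
  expect_equal(merge_grids(c(0, 0.5, 1), c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_equal(merge_grids(c(0, 0.3, 1), c(0, 0.7, 1)), c(0, 0.3, 0.7, 1))
  expect_equal(merge_grids(c(0, 1), c(0, 0.5, 1)), c(0, 0.5, 1))
  set.seed(31)
  for (r in 1:200) {
    n1 <- sample(2:30, 1)
    n2 <- sample(2:30, 1)
    g1 <- if (n1 > 2) sort(c(0, runif(n1 - 2), 1)) else c(0, 1)
    g2 <- if (n2 > 2) sort(c(0, runif(n2 - 2), 1)) else c(0, 1)
    n <- length(merge_grids(g1, g2))
    expect_gte(n, max(n1, n2))
    expect_lte(n, n1 + n2 - 2)
  }
})

test_that("resampling is the identity on the own grid and linear in between", {
  set.seed(41)
  Q <- random_srvf(6)
  expect_equal(resample_srvf(Q, Q$grid)$values, Q$values)
  # constant columns stay constant on any grid
  Qc <- Q
  Qc$values <- matrix(c(2, -1, 0.5), 3, 6)
  out <- resample_srvf(Qc, sort(c(0, runif(5), 1)))
  expect_equal(out$values, matrix(c(2, -1, 0.5), 3, 7), ignore_attr = TRUE)
  # midpoint of a linear-in-t row is the average of its neighbours
  Ql <- structure(list(values = rbind(c(0, 1), 0, 0), grid = c(0, 1), k = 0L),
                  class = "esa_srvf")
  expect_equal(resample_srvf(Ql, c(0, 0.5, 1))$values[1, 2], 0.5)
  # refinement consistency: resampling twice equals resampling once
  t1 <- sort(c(Q$grid, runif(4)))
  t2 <- sort(c(t1, runif(3)))
  expect_equal(resample_srvf(resample_srvf(Q, t1), t2)$values,
               resample_srvf(Q, t2)$values, tolerance = 1e-12)
  expect_error(resample_srvf(Q, c(-0.2, 0.5)), "outside")
})

test_that("inner product matches a direct quadrature oracle and normalization is projective", {
  c1 <- structure(list(values = matrix(c(1, 0, 0), 3, 2), grid = c(0, 1),
                       k = 0L), class = "esa_srvf")
  c2 <- structure(list(values = matrix(c(0, 1, 0), 3, 2), grid = c(0, 1),
                       k = 0L), class = "esa_srvf")
  expect_equal(srvf_inner_product(c1, c1), 1)
  expect_equal(srvf_inner_product(c1, c2), 0)
  set.seed(51)
  for (r in 1:10) {
    Q1 <- random_srvf(9, dim = 4, k = 1L)
    Q2 <- Q1
    Q2$values <- matrix(rnorm(4 * 9), 4)
    # interval-wise trapezoid oracle
    f <- colSums(Q1$values * Q2$values)
    oracle <- sum(0.5 * (f[-1] + f[-9]) * diff(Q1$grid))
    expect_equal(srvf_inner_product(Q1, Q2), oracle, tolerance = 1e-12)
    n1 <- normalize_srvf(Q1)
    expect_equal(srvf_inner_product(n1, n1), 1, tolerance = 1e-12)
    Q5 <- Q1
    Q5$values <- 5 * Q5$values
    expect_equal(normalize_srvf(Q5)$values, n1$values, tolerance = 1e-12)
  }
  expect_error(srvf_inner_product(c1, random_srvf(5)), "common grid")
})
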