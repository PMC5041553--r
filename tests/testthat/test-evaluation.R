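test_that("distance matrices are symmetric, zero-diagonal and match pairwise runs", {
  a <- make_chain(fixture_spec(20, "helix", seed = 1))
  b <- make_chain(fixture_spec(20, "strand", seed = 2))
  D <- suppressMessages(esa_distance_matrix(list(A = a, B = b)))
  expect_equal(dim(D$values), c(2, 2))
  expect_equal(diag(D$values), c(A = 0, B = 0))
  expect_equal(D$values[1, 2], quiet_compare(a, b)$theta)
  expect_equal(D$values, t(D$values))

  copies <- list(x = a, y = a, z = a)
  Dc <- suppressMessages(esa_distance_matrix(copies))
  expect_lt(max(Dc$values), 1e-6)

  f <- tempfile()
  on.exit(unlink(f))
  write_distance_matrix(D, f)
  back <- read_distance_matrix(f)
  expect_equal(back$values, D$values, ignore_attr = TRUE)
  expect_equal(back$labels, D$labels)
})

test_that("sigmoid similarity has the documented fixed points and monotonicity", {
  expect_equal(sigmoid_similarity(0), 1)
  expect_equal(sigmoid_similarity(1, 1), 0.537883, tolerance = 1e-6)
  x <- seq(0, 10, by = 0.5)
  expect_true(all(diff(sigmoid_similarity(x, 2)) < 0))
  expect_true(all(sigmoid_similarity(x, 0.5) > 0 &
                  sigmoid_similarity(x, 0.5) <= 1))
  expect_error(sigmoid_similarity(-1), "non-negative")
  expect_error(sigmoid_similarity(1, alpha = 0), "positive")
})

test_that("confusion metrics reproduce hand arithmetic", {
  perfect <- confusion_metrics(diag(c(5, 5)))
  expect_equal(perfect$per_class$precision, c(1, 1))
  expect_equal(perfect$per_class$recall, c(1, 1))
  expect_equal(perfect$per_class$f_measure, c(1, 1))
  expect_equal(perfect$RI, 1)
  expect_equal(perfect$rand_index, 1)

  m <- confusion_metrics(matrix(c(3, 2, 1, 4), 2))  # rows true, cols predicted
  expect_equal(m$per_class$precision[1], 0.6)
  expect_equal(m$per_class$recall[1], 0.75)
  expect_equal(m$per_class$f_measure[1], 2 * 0.6 * 0.75 / 1.35)
  expect_equal(m$RI, 0.7)
  # pair counting: C(10,2)=45, together-in-both=10, rows C(4,2)+C(6,2)=21,
  # cols C(5,2)+C(5,2)=20 -> (45 + 20 - 21 - 20)/45
  expect_equal(m$rand_index, 24 / 45)
})

test_that("macro metrics are invariant to consistent class relabeling", {
  M <- matrix(c(8, 1, 0, 2, 6, 1, 0, 3, 9), 3, byrow = TRUE)
  base <- confusion_metrics(M)
  for (p in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    perm <- confusion_metrics(M[p, p])
    expect_equal(perm$macro_precision, base$macro_precision)
    expect_equal(perm$macro_recall, base$macro_recall)
    expect_equal(perm$macro_f, base$macro_f)
    expect_equal(perm$RI, base$RI)
  }
})

test_that("empty classes are excluded from macro averages with a message", {
  M <- matrix(c(5, 0, 3, 0), 2, byrow = TRUE)  # no predictions in class 2
  expect_message(m <- confusion_metrics(M), "excluded")
  expect_true(is.na(m$per_class$precision[2]))
  expect_equal(m$macro_precision, 5 / 8)
})

test_that("clustering a separable two-family design recovers the classes", {
  specs <- list(helix = fixture_spec(25, "helix"),
                strand = fixture_spec(25, "strand"))
  ds <- make_dataset(specs, per_class = 3, noise_sigma = 0.05, seed = 4)
  D <- suppressMessages(esa_distance_matrix(ds$chains))
  for (meth in c("kmeans", "cmeans", "spectral")) {
    sc <- cluster_and_score(D, ds$labels, method = meth, seed = 1)
    expect_equal(sc$RI, 1)
    expect_equal(sc$rand_index, 1)
  }
  # determinism under a fixed seed
  s1 <- cluster_and_score(D, ds$labels, method = "kmeans", seed = 7)
  s2 <- cluster_and_score(D, ds$labels, method = "kmeans", seed = 7)
  expect_identical(s1$confusion, s2$confusion)
  # single-cluster edge case: everything recalled into one class
  one <- cluster_and_score(D, rep("all", 6), method = "kmeans",
                           n_clusters = 1, seed = 1)
  expect_equal(one$per_class$recall, 1)
})
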