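test_that("pairwise distances match closed forms for each metric", {
  d1 <- pairwise_distances(rbind(c(0, 0), c(1, 0)), metric = "sq_euclidean")
  expect_equal(d1$values[1, 2], 1)
  expect_equal(d1$mean_pairwise, 1)

  d2 <- pairwise_distances(rbind(c(0, 0), c(3, 4)), metric = "sq_euclidean")
  expect_equal(d2$values[1, 2], 25)
  expect_equal(pairwise_distances(rbind(c(0, 0), c(3, 4)))$values[1, 2], 5)

  # quarter great circle on the unit sphere
  d3 <- pairwise_distances(rbind(c(0, 0), c(90, 0)),
                           metric = "great_circle", radius = 1)
  expect_equal(d3$values[1, 2], pi / 2, tolerance = 1e-12)
})

test_that("distance matrices are symmetric with zero diagonal", {
  X <- rand_matrix(12, 2, seed = 9)
  for (m in c("euclidean", "sq_euclidean")) {
    D <- pairwise_distances(X, metric = m)$values
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 12))
    expect_true(all(D[upper.tri(D)] > 0))
  }
})

test_that("coordinate validation and tie handling follow the policy", {
  expect_error(pairwise_distances(rbind(c(200, 0), c(0, 0)),
                                  metric = "great_circle"), "longitude")
  X <- rbind(a = c(1, 1), b = c(1, 1), c = c(2, 2))
  expect_error(prepare_coordinates(X, jitter = FALSE), "a, b")
  expect_warning(P <- prepare_coordinates(X, jitter_seed = 7), "jittered")
  expect_true(P$jitter_applied)
  expect_equal(nrow(unique(P$points)), 3L)
  # only the tied points moved
  expect_equal(P$points["c", ], c(2, 2), ignore_attr = TRUE)
  # reproducible given the seed
  suppressWarnings(P2 <- prepare_coordinates(X, jitter_seed = 7))
  expect_identical(P$points, P2$points)
})

test_that("spatial covariance matches exp(-d/theta) with unit diagonal", {
  D <- pairwise_distances(line_coords(6))
  S <- spatial_covariance(D, theta = D$values[1, 2])
  expect_equal(S$values[1, 2], exp(-1))
  expect_equal(unname(diag(S$values)), rep(1, 6))
  expect_error(spatial_covariance(D, theta = 0), "positive")
  # theta -> 0 limit: numerically the identity
  S0 <- spatial_covariance(D, theta = 1e-12 * D$mean_pairwise)
  expect_lt(max(abs(S0$values - diag(6))), 1e-300)
  expect_gt(min(eigen(S$values, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("whitening operator satisfies its defining identities", {
  # 2x2 case checked against the dense inverse
  S2 <- structure(list(values = rbind(c(1, 0.5), c(0.5, 1)), theta = 1,
                       metric = "euclidean", jitter = 0,
                       chol_lower = t(chol(rbind(c(1, 0.5), c(0.5, 1))))),
                  class = "spfa_cov")
  W2 <- whitening_transform(S2)
  expect_lt(max(abs(crossprod(W2$C) %*% S2$values - diag(2))), 1e-10)
  expect_lt(max(abs(crossprod(W2$C) - solve(S2$values))), 1e-10)

  # collinear equispaced points at theta = d-bar, plus random layouts
  cases <- list(line_coords(5), rand_matrix(15, 2, seed = 2),
                rand_matrix(30, 2, seed = 4))
  for (X in cases) {
    D <- pairwise_distances(X)
    S <- spatial_covariance(D, theta = D$mean_pairwise)
    W <- whitening_transform(S)
    expect_lt(max(abs(W$C %*% S$values %*% t(W$C) - diag(nrow(X)))), 1e-8)
    expect_lt(max(abs(crossprod(W$C) %*% S$values - diag(nrow(X)))), 1e-8)
  }
})

test_that("identity covariance gives identity whitening", {
  D <- pairwise_distances(line_coords(4))
  S <- spatial_covariance(D, theta = 1e-14 * D$mean_pairwise)
  W <- whitening_transform(S)
  expect_equal(W$C, diag(4), tolerance = 1e-12)
})
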