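test_that("corrupt_expression is multiplicative, seeded, and mean-preserving", {
  set.seed(12)
  X <- matrix(rnorm(200, 5), 20, 10)
  ns <- noise_spec(mean = 1, sd = 0.1, seed = 3)
  X1 <- corrupt_expression(X, ns)
  X2 <- corrupt_expression(X, ns)
  expect_identical(X1, X2)
  expect_false(identical(X1, corrupt_expression(X, noise_spec(seed = 4))))

  # std -> 0 limit: X * 1 = X
  tiny <- corrupt_expression(X, noise_spec(mean = 1, sd = 1e-12, seed = 0))
  expect_equal(tiny, X, tolerance = 1e-9)

  # empirical ratio mean within 3 standard errors of the noise mean
  big <- matrix(1, 200, 200)
  ratios <- corrupt_expression(big, noise_spec(mean = 1, sd = 0.1, seed = 1))
  se <- 0.1 / sqrt(length(big))
  expect_lt(abs(mean(ratios) - 1), 3 * se)
  expect_error(noise_spec(sd = 0), "positive")
})

test_that("cross_view_similarity matches hand-computed cosines", {
  Z <- rbind(c(1, 0), c(0, 1))
  S <- cross_view_similarity(Z, Z)
  expect_equal(diag(S), c(1, 1))
  expect_equal(S[1, 2], 0)

  Z1 <- rbind(c(1, 0), c(0, 1))
  Z2 <- rbind(c(1, 0), c(1, 1))
  S <- cross_view_similarity(Z1, Z2)
  expect_equal(S[1, 2], 1 / sqrt(2), tolerance = 1e-12)
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))

  expect_warning(cross_view_similarity(rbind(c(0, 0), c(1, 0)), Z2),
                 "zero-norm")
  expect_error(cross_view_similarity(Z1, matrix(0, 3, 2)), "shapes")
})

test_that("space_contrastive_loss enumerates to hand values", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(space_contrastive_loss(A, A), 0)
  expect_equal(space_contrastive_loss(diag(2), A), 1, tolerance = 1e-12)

  # permutation invariance under a simultaneous relabeling
  set.seed(13)
  S <- matrix(runif(25), 5, 5); Af <- matrix(runif(25), 5, 5)
  p <- sample(5)
  expect_equal(space_contrastive_loss(S, Af),
               space_contrastive_loss(S[p, p], Af[p, p]))
})

test_that("assign_groups splits into near-equal seeded groups", {
  g <- assign_groups(4, 2, seed = 0)
  expect_equal(sort(tabulate(g$groups + 1L)), c(2, 2))
  g5 <- assign_groups(5, 2, seed = 0)
  expect_equal(sort(tabulate(g5$groups + 1L)), c(2, 3))
  expect_identical(assign_groups(100, 7, seed = 9)$groups,
                   assign_groups(100, 7, seed = 9)$groups)
  expect_error(assign_groups(3, 4), "exceed")
})

test_that("cluster_readout averages groups exactly", {
  Z <- matrix(rnorm(18), 6, 3)
  g1 <- assign_groups(6, 1, seed = 0)
  expect_equal(unname(cluster_readout(Z, g1)), t(colMeans(Z)),
               ignore_attr = TRUE)

  g2 <- assign_groups(6, 2, seed = 2)
  R <- cluster_readout(Z, g2)
  for (k in 0:1)
    expect_equal(unname(R[k + 1, ]), colMeans(Z[g2$groups == k, , drop = FALSE]),
                 tolerance = 1e-12)

  # identical rows reproduce the common row
  Zc <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  expect_true(all(abs(sweep(cluster_readout(Zc, g2), 2, c(1, 2, 3))) < 1e-12))
})

test_that("cluster_feature_loss matches enumerated small cases", {
  # cross-view feature cosine = identity -> 0
  R <- diag(2) * 3
  expect_equal(cluster_feature_loss(R, R), 0, tolerance = 1e-12)

  # d = 2, all-ones similarity: diagonal term 0, off-diagonal (1+1)/2 = 1
  R1 <- matrix(c(1, 1), 2, 2)   # both columns equal -> S all ones
  expect_equal(cluster_feature_loss(R1, R1), 1, tolerance = 1e-12)

  # cosine scale invariance under positive column scaling
  set.seed(14)
  Ra <- matrix(rnorm(12), 4, 3); Rb <- matrix(rnorm(12), 4, 3)
  sc <- diag(c(2, 0.5, 7))
  expect_equal(cluster_feature_loss(Ra, Rb),
               cluster_feature_loss(Ra %*% sc, Rb %*% sc), tolerance = 1e-12)

  # uniform normalization differs only in the off-diagonal weight
  d <- 3
  split <- cluster_feature_loss(Ra, Rb, "split")
  unif <- cluster_feature_loss(Ra, Rb, "uniform")
  S <- stdcl:::feature_cosine(Ra, Rb)
  off <- S; diag(off) <- 0
  expect_equal(split - unif, sum(off^2) * (1 / (d^2 - d) - 1 / d^2),
               tolerance = 1e-12)

  expect_error(cluster_feature_loss(matrix(1, 2, 1), matrix(1, 2, 1)),
               "at least 2")
})

test_that("total_loss is the documented weighted sum", {
  expect_equal(total_loss(0, 0, 0), 0)
  expect_equal(total_loss(1, 2, 5, loss_weights()), 15)
  expect_equal(total_loss(1, 1, 1, loss_weights(1, 2, 3)), 6)
})

test_that("losses are non-negative, finite, permutation-consistent", {
  set.seed(15)
  n <- 12; d <- 4
  Z <- matrix(rnorm(n * d), n, d)
  Zh <- matrix(rnorm(n * d), n, d)
  A <- knn_adjacency(matrix(rnorm(2 * n), n, 2), 3)
  S <- cross_view_similarity(Z, Zh)
  g <- assign_groups(n, 3, seed = 1)
  l1 <- space_contrastive_loss(S, A)
  l2 <- cluster_feature_loss(cluster_readout(Z, g), cluster_readout(Zh, g))
  expect_true(l1 >= 0 && is.finite(l1))
  expect_true(l2 >= 0 && is.finite(l2))

  p <- sample(n)
  gp <- g; gp$groups <- g$groups[p]
  Sp <- cross_view_similarity(Z[p, ], Zh[p, ])
  expect_equal(space_contrastive_loss(Sp, A[p, p]), l1, tolerance = 1e-12)
  expect_equal(cluster_feature_loss(cluster_readout(Z[p, ], gp),
                                    cluster_readout(Zh[p, ], gp)),
               l2, tolerance = 1e-12)
})

test_that("a gradient step on a free similarity matrix approaches A", {
  set.seed(16)
  S <- matrix(runif(16), 4, 4)
  A <- knn_adjacency(matrix(rnorm(8), 4, 2), 1)
  # d/dS of mean((S - A)^2) = 2 (S - A) / n^2
  step <- S - 0.5 * (2 / 16) * (S - A)
  expect_lt(norm(step - A, "F"), norm(S - A, "F"))
  expect_lt(space_contrastive_loss(step, A), space_contrastive_loss(S, A))
})
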