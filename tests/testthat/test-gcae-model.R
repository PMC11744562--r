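test_that("init_model is seeded, shaped, and seed-sensitive", {
  m1 <- init_model(30, d = 8, seed = 0)
  m2 <- init_model(30, d = 8, seed = 0)
  m3 <- init_model(30, d = 8, seed = 1)
  expect_identical(m1$W_e, m2$W_e)
  expect_identical(m1$W_d, m2$W_d)
  expect_false(identical(m1$W_e, m3$W_e))
  expect_equal(dim(m1$W_e), c(30, 8))
  expect_equal(dim(m1$W_d), c(8, 30))
  expect_error(init_model(30, d = 1), "at least 2")
})

test_that("encode collapses to x %*% W_e for a single spot", {
  m <- init_model(4, d = 3, seed = 2, activation = "identity")
  x <- matrix(rnorm(4), 1, 4)
  expect_equal(encode(x, matrix(1), m), x %*% m$W_e)

  m$W_e[] <- 0
  expect_equal(unname(encode(x, matrix(1), m)), matrix(0, 1, 3))
  expect_error(encode(matrix(Inf, 1, 4), matrix(1), m), "non-finite")
})

test_that("encode/decode agree with a dense oracle on random instances", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:50, 1); g <- sample(4:12, 1); d <- sample(2:6, 1)
    act <- sample(c("elu", "relu", "identity"), 1)
    X <- matrix(rnorm(n * g), n, g)
    P <- normalize_adjacency(knn_adjacency(matrix(rnorm(2 * n), n, 2),
                                           min(3, n - 1)))
    m <- init_model(g, d = d, seed = rep, activation = act)
    Zo <- oracle_gcn_layer(P, X, m$W_e, act)
    expect_equal(unname(encode(X, P, m)), Zo, tolerance = 1e-6)
    Ho <- oracle_gcn_layer(P, Zo, m$W_d, "identity")
    expect_equal(unname(decode(Zo, P, m)), Ho, tolerance = 1e-6)
  }
})

test_that("decode of a zero embedding is zero", {
  m <- init_model(5, d = 3, seed = 1)
  P <- diag(4)
  expect_equal(unname(decode(matrix(0, 4, 3), P, m)), matrix(0, 4, 5))
})

test_that("reconstruct_adjacency is a symmetric sigmoid inner product", {
  expect_equal(reconstruct_adjacency(matrix(0, 3, 2)), matrix(0.5, 3, 3))

  Z <- rbind(c(1, 0), c(1, 0))    # identical unit rows
  Ah <- reconstruct_adjacency(Z)
  expect_equal(Ah[1, 2], 1 / (1 + exp(-1)), tolerance = 1e-12)

  set.seed(10)
  Z <- matrix(rnorm(24), 8, 3)
  Ah <- reconstruct_adjacency(Z)
  expect_identical(Ah, t(Ah))
  expect_true(all(Ah > 0 & Ah < 1))
})

test_that("reconstruction_loss matches hand-enumerated values", {
  X <- matrix(1:4, 2, 2); A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(reconstruction_loss(X, X, A, A), 0)

  # n = 1, alpha1 = 1, alpha2 = 0.5, residual norms 1 and 0.25
  w <- loss_weights(alpha1 = 1, alpha2 = 0.5)
  X1 <- matrix(0, 1, 2); H1 <- matrix(c(1, 0), 1, 2)   # ||H-X||^2 = 1
  A1 <- matrix(0.5, 1, 1); Ah1 <- matrix(1, 1, 1)      # ||Ah-A||^2 = 0.25
  expect_equal(reconstruction_loss(X1, H1, A1, Ah1, w), 1.125, tolerance = 1e-12)
})

test_that("loss weights default to the tuned values and reject bad input", {
  w <- loss_weights()
  expect_equal(c(w$alpha1, w$alpha2), c(1.0, 0.5))
  expect_equal(c(w$gamma1, w$gamma2, w$gamma3), c(10, 0.5, 0.8))
  expect_error(loss_weights(gamma1 = -1), "non-negative")
  expect_error(loss_weights(0, 0, 0, 0, 0), "positive")
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  n <- 7; g <- 5; d <- 3
  X <- matrix(rnorm(n * g), n, g)
  Xhat <- X * matrix(rnorm(n * g, 1, 0.1), n, g)
  A <- knn_adjacency(matrix(rnorm(n * 2), n, 2), 2)
  P <- normalize_adjacency(A)
  G <- stdcl:::readout_operator(assign_groups(n, 2, seed = 1), n)
  model <- init_model(g, d = d, seed = 3)
  w <- loss_weights()

  loss_at <- function(m) stdcl:::stdcl_grads(m, X, Xhat, P, A, G, w)$total
  gr <- stdcl:::stdcl_grads(model, X, Xhat, P, A, G, w)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(3, 2), c(5, 3))) {
    mp <- model; mp$W_e[idx[1], idx[2]] <- mp$W_e[idx[1], idx[2]] + eps
    mm <- model; mm$W_e[idx[1], idx[2]] <- mm$W_e[idx[1], idx[2]] - eps
    expect_equal(gr$gW_e[idx[1], idx[2]],
                 (loss_at(mp) - loss_at(mm)) / (2 * eps), tolerance = 1e-5)
    mp <- model; mp$W_d[idx[2], idx[1]] <- mp$W_d[idx[2], idx[1]] + eps
    mm <- model; mm$W_d[idx[2], idx[1]] <- mm$W_d[idx[2], idx[1]] - eps
    expect_equal(gr$gW_d[idx[2], idx[1]],
                 (loss_at(mp) - loss_at(mm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("one gradient step on a linear toy instance reduces the loss", {
  set.seed(11)
  n <- 6; g <- 4
  X <- matrix(rnorm(n * g), n, g)
  A <- knn_adjacency(matrix(rnorm(n * 2), n, 2), 2)
  P <- normalize_adjacency(A)
  m <- init_model(g, d = 2, seed = 5, activation = "identity")
  w <- loss_weights()
  g0 <- stdcl:::stdcl_grads(m, X, NULL, P, A, NULL, w, with_contrastive = FALSE)
  m$W_e <- m$W_e - 1e-4 * g0$gW_e
  m$W_d <- m$W_d - 1e-4 * g0$gW_d
  g1 <- stdcl:::stdcl_grads(m, X, NULL, P, A, NULL, w, with_contrastive = FALSE)
  expect_lt(g1$l_rec, g0$l_rec)
})

test_that("model checkpoints round-trip exactly through plain text", {
  m <- init_model(12, d = 4, seed = 9)
  path <- withr::local_tempfile()
  write_model(m, path)
  m2 <- read_model(path)
  expect_identical(m2$W_e, unname(m$W_e))
  expect_identical(m2$W_d, unname(m$W_d))
  expect_equal(m2$d, m$d)
  expect_equal(m2$activation, m$activation)
  expect_equal(m2$rng_seed, m$rng_seed)
})
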