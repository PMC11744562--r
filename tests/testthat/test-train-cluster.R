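make_training_instance <- function(n = 60, g = 20, seed = 21) {
  ds <- generate_dataset(tissue_spec(n_spots = n, n_genes = g, n_domains = 2,
                                     n_markers_per_domain = 4, seed = seed))
  pe <- preprocess(ds, n_hvg = g)
  graph <- build_graph(ds$coords, pe)
  list(ds = ds, pe = pe, graph = graph)
}

test_that("train_config defaults follow the two-phase schedule", {
  cfg <- train_config()
  expect_equal(cfg$pretrain_epochs, 500L)
  expect_equal(cfg$train_epochs, 1000L)
  expect_equal(cfg$pretrain_lr, 0.001)
  expect_equal(cfg$train_lr, 0.005)
  expect_equal(cfg$optimizer, "adam")
})

test_that("pretrain reduces the reconstruction loss and is deterministic", {
  inst <- make_training_instance()
  m0 <- init_model(ncol(inst$pe$X), d = 8, seed = 0)
  cfg <- train_config(pretrain_epochs = 50, train_epochs = 1, seed = 0)
  m1 <- pretrain(m0, inst$pe, inst$graph, cfg)
  hist <- attr(m1, "loss_history")
  expect_lt(hist$l_rec[50], hist$l_rec[1])

  m2 <- pretrain(m0, inst$pe, inst$graph, cfg)
  expect_identical(m1$W_e, m2$W_e)

  # zero epochs: weights unchanged
  cfg0 <- train_config(pretrain_epochs = 0, train_epochs = 1)
  expect_identical(pretrain(m0, inst$pe, inst$graph, cfg0)$W_e, m0$W_e)
})

test_that("train lowers the total loss and yields bit-identical reruns", {
  inst <- make_training_instance()
  cfg <- train_config(pretrain_epochs = 20, train_epochs = 60, seed = 0)
  m0 <- init_model(ncol(inst$pe$X), d = 8, seed = 0)
  m0 <- pretrain(m0, inst$pe, inst$graph, cfg)
  tr1 <- train(m0, inst$pe, inst$graph, k = 2, cfg)
  tr2 <- train(m0, inst$pe, inst$graph, k = 2, cfg)
  expect_identical(tr1$history, tr2$history)
  expect_identical(tr1$model$W_e, tr2$model$W_e)
  expect_lt(tail(tr1$history$total, 1), tr1$history$total[1])
  expect_named(tr1$history, c("epoch", "l_rec", "l_con", "l_clu", "total"))
})

test_that("reduce_pca is an isometry at full rank with ordered variance", {
  set.seed(22)
  Z <- matrix(rnorm(200), 40, 5)
  full <- reduce_pca(Z, 5)
  expect_equal(as.numeric(dist(full)), as.numeric(dist(Z)), tolerance = 1e-9)
  v <- apply(reduce_pca(Z, 5), 2, var)
  expect_true(all(diff(v) <= 1e-10))
  expect_error(reduce_pca(Z, 6), "exceeds")

  # sign convention makes the output reproducible
  expect_identical(reduce_pca(Z, 3), reduce_pca(Z, 3))
})

test_that("cluster_embedding separates well-separated blobs perfectly", {
  set.seed(23)
  blobs <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 10), 30, 2))
  truth <- rep(0:1, each = 30)
  lab_gmm <- cluster_embedding(blobs, k = 2, method = "gmm", seed = 0)
  expect_equal(adjusted_rand_index(truth, lab_gmm), 1)
  lab_leiden <- cluster_embedding(blobs, method = "leiden", seed = 0,
                                  resolution = 0.1)
  expect_equal(adjusted_rand_index(truth, lab_leiden), 1)

  expect_identical(cluster_embedding(blobs, k = 2, seed = 5),
                   cluster_embedding(blobs, k = 2, seed = 5))
  # k = n: every spot its own cluster
  expect_equal(cluster_embedding(blobs[1:5, ], k = 5, seed = 0), 0:4)
  expect_error(cluster_embedding(blobs, k = 100), "exceed")
})

test_that("select_run_by_dbi returns the argmin with stable ties", {
  r1 <- list(dbi = 0.8, tag = "a")
  r2 <- list(dbi = 0.3, tag = "b")
  expect_identical(select_run_by_dbi(list(r1)), r1)
  expect_identical(select_run_by_dbi(list(r1, r2))$tag, "b")
  expect_identical(select_run_by_dbi(list(r2, list(dbi = 0.3, tag = "c")))$tag,
                   "b")
  expect_error(select_run_by_dbi(list()), "non-empty")

  # agrees with an explicit recomputed-DBI argmin
  set.seed(24)
  runs <- lapply(1:3, function(i) {
    emb <- matrix(rnorm(60, sd = i), 30, 2) + rep(0:1, each = 15) * 4
    lab <- rep(0:1, each = 15)
    list(emb = emb, labels = lab, dbi = davies_bouldin(emb, lab))
  })
  dbis <- vapply(runs, function(r) davies_bouldin(r$emb, r$labels), numeric(1))
  expect_identical(select_run_by_dbi(runs), runs[[which.min(dbis)]])
})

test_that("refine_labels reassigns by neighborhood majority", {
  # a mislabelled spot surrounded by 6 same-labelled neighbors
  coords <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(-1, -1))
  labels <- c(1L, rep(0L, 6))
  out <- refine_labels(labels, coords, radius = 2)
  expect_equal(out[1], 0L)

  # all same label: fixed point
  same <- rep(2L, 7)
  expect_equal(refine_labels(same, coords, radius = 2), same)

  # refinement never invents new labels
  set.seed(25)
  coords2 <- matrix(runif(80, 0, 10), 40, 2)
  labs2 <- sample(0:3, 40, replace = TRUE)
  out2 <- refine_labels(labs2, coords2, radius = 3)
  expect_true(all(out2 %in% labs2))
  expect_lte(length(unique(out2)), length(unique(labs2)))

  # empty neighborhood: label kept with a warning
  far <- rbind(c(0, 0), c(100, 100), c(101, 100), c(100, 101))
  expect_warning(kept <- refine_labels(c(3L, 0L, 0L, 0L), far, radius = 5),
                 "empty neighborhood")
  expect_equal(kept[1], 3L)
  expect_error(refine_labels(labels, coords, radius = -1), "positive")
})

test_that("refinement restores flipped labels on a stripe tissue", {
  ds <- generate_dataset(tissue_spec(n_spots = 200, n_genes = 30,
                                     n_domains = 4, n_markers_per_domain = 5,
                                     seed = 1))
  spec <- attr(ds, "spec")
  truth <- ds$labels
  set.seed(0)
  flip <- sample(length(truth), round(0.05 * length(truth)))
  noisy <- truth
  noisy[flip] <- (truth[flip] + 1L) %% 4L
  refined <- refine_labels(noisy, ds$coords, radius = spec$grid_step * 1.5)
  expect_gte(mean(refined[flip] == truth[flip]), 0.9)
})

test_that("the full pipeline object is consistent and deterministic", {
  ds <- generate_dataset(tissue_spec(n_spots = 80, n_genes = 30, n_domains = 2,
                                     n_markers_per_domain = 6, seed = 3))
  cfg <- train_config(pretrain_epochs = 20, train_epochs = 40, seed = 0)
  res <- stdcl_run(ds, k = 2, d = 8, cfg = cfg, refine_radius = 150)
  expect_s3_class(res, "stdcl_result")
  expect_length(res$labels_refined, 80)
  expect_true(all(res$labels_raw %in% 0:1))
  expect_equal(ncol(res$embedding_pca), 8)   # capped at latent dim

  res2 <- stdcl_run(ds, k = 2, d = 8, cfg = cfg, refine_radius = 150)
  expect_identical(res$labels_refined, res2$labels_refined)
  expect_identical(res$history, res2$history)

  td <- tidy(res)
  expect_equal(nrow(td), 80)
  expect_named(td, c("spot_id", "x", "y", "label_raw", "label_refined"))
  gl <- glance(res)
  expect_equal(gl$n_spots, 80L)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_loss_history(res), "ggplot")
})
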