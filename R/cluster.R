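#' PCA reduction of the latent embedding
#'
#' Projects onto the top `n_comp` principal components (centered, not
#' rescaled). For reproducibility each component's sign is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param Z latent matrix (spots x d).
#' @param n_comp number of components, at most `ncol(Z)`; default 20.
#' @return spots x n_comp score matrix.
#' @export
reduce_pca <- function(Z, n_comp = 20) {
  Z <- as.matrix(Z)
  if (n_comp > ncol(Z))
    stop(sprintf("n_comp = %d exceeds embedding dimension %d",
                 n_comp, ncol(Z)), call. = FALSE)
  p <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = n_comp)
  rot <- p$rotation
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(p$x, 2, flip, "*")
}

#' Cluster the reduced embedding
#'
#' `method = "gmm"` fits a Gaussian mixture with a shared covariance
#' structure across components (mclust, default model `"EEE"`), the choice
#' used when the number of annotated domains `k` is known.
#' `method = "leiden"` runs Leiden community detection on a 15-nearest-
#' neighbor graph of the embedding for the un-annotated case; `k` is then
#' ignored and `resolution` controls granularity.
#'
#' @param emb reduced embedding (spots x n_comp), e.g. from [reduce_pca()].
#' @param k number of clusters (required for `"gmm"`).
#' @param method `"gmm"` or `"leiden"`.
#' @param seed integer seed; labels are deterministic given it.
#' @param resolution Leiden resolution parameter (default 1).
#' @param model_name mclust covariance model (default `"EEE"`, shared full
#'   covariance; `"EII"`/`"VVV"` give diagonal-spherical/full).
#' @return integer label vector (0-based).
#' @export
cluster_embedding <- function(emb, k = NULL, method = c("gmm", "leiden"),
                              seed = 0, resolution = 1, model_name = "EEE") {
  method <- match.arg(method)
  emb <- as.matrix(emb)
  n <- nrow(emb)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (method == "gmm") {
    if (is.null(k)) stop("gmm clustering requires k", call. = FALSE)
    if (k > n) stop("k cannot exceed the number of spots", call. = FALSE)
    if (k == n) return(seq_len(n) - 1L)
    fit <- mclust::Mclust(emb, G = k, modelNames = model_name,
                          verbose = FALSE)
    if (is.null(fit))  # fall back to unconstrained covariance
      fit <- mclust::Mclust(emb, G = k, verbose = FALSE)
    as.integer(fit$classification) - 1L
  } else {
    kg <- min(15L, n - 1L)
    A <- knn_adjacency(emb, kg)
    gr <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    cl <- igraph::cluster_leiden(gr, resolution = resolution,
                                 objective_function = "modularity",
                                 n_iterations = 5)
    as.integer(igraph::membership(cl)) - 1L
  }
}

#' Select the training run with the lowest Davies-Bouldin index
#'
#' Training is run under two different corruption noise levels; the run
#' whose embedding/labels score the lower (better) DBI is kept. Ties keep
#' the earlier run.
#'
#' @param runs non-empty list of `stdcl_result` objects (or any lists with
#'   a numeric `dbi` element).
#' @return the selected element.
#' @export
select_run_by_dbi <- function(runs) {
  if (length(runs) == 0) stop("runs must be non-empty", call. = FALSE)
  dbis <- vapply(runs, function(r) r$dbi, numeric(1))
  runs[[which.min(dbis)]]
}

#' Majority-vote spatial label refinement
#'
#' For each spot, collects the labels of all other spots within Euclidean
#' distance `radius` (its circular spatial neighborhood) and reassigns the
#' spot to the most common label there. Ties, and spots with empty
#' neighborhoods, keep their original label. A single pass using the
#' pre-refinement labels throughout; set `iterations > 1` to repeat.
#'
#' @param labels integer label vector.
#' @param coords spots x 2 coordinate matrix, same units as `radius`.
#' @param radius neighborhood radius (default 50, the 10x Visium pixel
#'   spacing scale).
#' @param iterations number of refinement passes (default 1).
#' @return refined integer label vector.
#' @export
refine_labels <- function(labels, coords, radius = 50, iterations = 1) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  coords <- as.matrix(coords)
  n <- length(labels)
  if (nrow(coords) != n)
    stop("labels and coords have different lengths", call. = FALSE)
  labels <- as.integer(labels)
  D <- as.matrix(stats::dist(coords))
  empty <- 0L
  for (it in seq_len(iterations)) {
    new_labels <- labels
    for (i in seq_len(n)) {
      nb <- which(D[i, ] <= radius)
      nb <- nb[nb != i]
      if (length(nb) == 0) { empty <- empty + 1L; next }
      tab <- table(labels[nb])
      top <- as.integer(names(tab)[tab == max(tab)])
      if (length(top) == 1) new_labels[i] <- top
      else if (labels[i] %in% top) new_labels[i] <- labels[i]
      else new_labels[i] <- top[1]
    }
    labels <- new_labels
  }
  if (empty > 0)
    warning(sprintf("%d spot(s) had an empty neighborhood and kept their label",
                    empty), call. = FALSE)
  labels
}

#' Run the full spatial-domain identification pipeline
#'
#' End to end: preprocess counts, build the fused spatial/expression graph,
#' initialize and pre-train the graph convolutional autoencoder, train it
#' twice under two corruption noise levels, cluster each run's PCA-reduced
#' embedding, keep the run with the lower Davies-Bouldin index, and refine
#' the labels by spatial majority vote.
#'
#' @param ds a [spatial_dataset()].
#' @param k number of spatial domains.
#' @param n_hvg highly variable genes (default 3000; panels with fewer
#'   genes use all genes).
#' @param k1,k2,alpha graph parameters, see [build_graph()].
#' @param d latent dimension (default 64).
#' @param cfg a [train_config()].
#' @param w a [loss_weights()].
#' @param noise_sds standard deviations of the two corruption runs
#'   (default `c(0.1, 0.2)`, mean 1 both).
#' @param method clustering method, `"gmm"` (default) or `"leiden"`.
#' @param n_pca components for the pre-clustering PCA (default 20).
#' @param refine_radius spatial refinement radius (default 50).
#' @param graph_mode `"fused"` (default), `"spatial"` or `"gene"` — see
#'   [build_graph()]; `"gene"` removes the spatial graph (ablation).
#' @param seed master seed; every internal random draw derives from it.
#' @return An object of class `stdcl_result`: list with `labels_raw`,
#'   `labels_refined` (0-based integers), `embedding` (latent Z),
#'   `embedding_pca`, `dbi`, `noise_sd_used`, `k`, `model`, `graph`,
#'   `processed`, `history` (loss tibble), `spot_ids`, `coords`, `seed`.
#' @export
stdcl_run <- function(ds, k, n_hvg = 3000, k1 = 3, k2 = 3, alpha = 0.5,
                      d = 64, cfg = train_config(), w = loss_weights(),
                      noise_sds = c(0.1, 0.2), method = c("gmm", "leiden"),
                      n_pca = 20, refine_radius = 50,
                      graph_mode = c("fused", "spatial", "gene"),
                      seed = NULL) {
  method <- match.arg(method)
  graph_mode <- match.arg(graph_mode)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  pe <- preprocess(ds, n_hvg = n_hvg)
  graph <- build_graph(ds$coords, pe, k1 = k1, k2 = k2, alpha = alpha,
                       mode = graph_mode)
  model0 <- init_model(ncol(pe$X), d = d, seed = cfg$seed)
  model0 <- pretrain(model0, pe, graph, cfg, w)

  runs <- lapply(seq_along(noise_sds), function(i) {
    ns <- noise_spec(mean = 1, sd = noise_sds[i], seed = cfg$seed + i)
    tr <- train(model0, pe, graph, k, cfg, w, noise = ns)
    Z <- encode(pe$X, graph, tr$model)
    emb <- reduce_pca(Z, n_comp = min(n_pca, ncol(Z)))
    lab <- cluster_embedding(emb, k = k, method = method, seed = cfg$seed)
    dbi <- if (length(unique(lab)) >= 2) davies_bouldin(emb, lab) else Inf
    list(model = tr$model, history = tr$history, Z = Z, emb = emb,
         labels = lab, dbi = dbi, noise_sd = noise_sds[i])
  })
  best <- select_run_by_dbi(runs)

  refined <- refine_labels(best$labels, ds$coords, radius = refine_radius)
  structure(
    list(labels_raw = best$labels, labels_refined = refined,
         embedding = best$Z, embedding_pca = best$emb, dbi = best$dbi,
         noise_sd_used = best$noise_sd, k = as.integer(k),
         model = best$model, graph = graph, processed = pe,
         history = best$history, spot_ids = ds$spot_ids,
         coords = ds$coords, seed = cfg$seed),
    class = "stdcl_result"
  )
}

#' @export
print.stdcl_result <- function(x, ...) {
  cat(sprintf(
    "<stdcl_result> %d spots, k = %d domains, DBI = %.3f (noise sd %.2g)\n",
    length(x$labels_raw), x$k, x$dbi, x$noise_sd_used))
  invisible(x)
}
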