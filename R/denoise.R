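#' Latent-neighbor expression denoising
#'
#' For each spot, finds its `k` nearest neighbors by Euclidean distance in
#' the latent embedding and replaces the spot's expression with the mean
#' over the neighborhood (including the spot itself by default). Smoothing
#' in latent space aggregates signal across transcriptionally and spatially
#' coherent spots.
#'
#' @param X expression matrix to denoise (spots x genes); any matrix
#'   aligned with `Z` on rows (raw counts, normalized, or processed).
#' @param Z latent embedding (spots x d).
#' @param k number of latent neighbors (default 15), `k < n_spots`.
#' @param include_self include the spot's own row in the average
#'   (default `TRUE`).
#' @return list of class `denoised_expression` with `X_denoised`,
#'   `k_neighbors`, `include_self`.
#' @export
denoise_expression <- function(X, Z, k = 15, include_self = TRUE) {
  if (inherits(X, "processed_expression")) X <- X$X
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- nrow(X)
  if (nrow(Z) != n) stop("X and Z must have the same number of spots",
                         call. = FALSE)
  if (k >= n) stop(sprintf("k = %d must be smaller than n_spots = %d", k, n),
                   call. = FALSE)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  out <- matrix(0, n, ncol(X), dimnames = dimnames(X))
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    rows <- if (include_self) c(i, nb) else nb
    out[i, ] <- colMeans(X[rows, , drop = FALSE])
  }
  structure(list(X_denoised = out, k_neighbors = as.integer(k),
                 include_self = include_self),
            class = "denoised_expression")
}

#' Rank genes by encoder-weight dispersion
#'
#' Interpretable gene selection: each input gene owns one row of the
#' encoder weight matrix `W_e`; genes whose row has a large standard
#' deviation contribute unevenly across latent dimensions and are the ones
#' the embedding relies on. Returns the `top_m` gene indices by descending
#' weight standard deviation, with the per-gene mean expression reported
#' alongside when `X` is given.
#'
#' @param model a `stdcl_model`.
#' @param top_m how many genes to return (default 1000, capped at n_hvg).
#' @param gene_ids optional gene identifiers for the ranked table.
#' @param X optional expression matrix to report mean expression.
#' @return tibble with columns `rank`, `gene_index`, `gene_id` (if given),
#'   `weight_std`, `mean_expression` (if `X` given).
#' @export
interpretable_gene_ranking <- function(model, top_m = 1000, gene_ids = NULL,
                                       X = NULL) {
  if (!is.numeric(top_m) || top_m < 1)
    stop("top_m must be a positive integer", call. = FALSE)
  W <- model$W_e
  top_m <- min(as.integer(top_m), nrow(W))
  stds <- apply(W, 1, stats::sd)
  ord <- order(stds, decreasing = TRUE)[seq_len(top_m)]
  out <- tibble::tibble(rank = seq_len(top_m), gene_index = ord,
                        weight_std = stds[ord])
  if (!is.null(gene_ids)) out$gene_id <- gene_ids[ord]
  if (!is.null(X)) {
    if (inherits(X, "processed_expression")) X <- X$X
    out$mean_expression <- colMeans(X)[ord]
  }
  out
}

#' Imputation-space pairwise-distance agreement
#'
#' Projects the imputed expression matrix `H` to two dimensions (the
#' "imputation space"), computes all-pairs Euclidean distances there and in
#' the original expression space, and reports the agreement of the two
#' upper-triangular distance vectors as Pearson correlation, mean squared
#' error, Spearman correlation and cosine similarity.
#'
#' @param X_original processed expression matrix.
#' @param H imputed (reconstructed) expression matrix, same spots.
#' @param projector `"pca"` (default; deterministic 2-component PCA),
#'   `"identity"` (use `H` as is), or a function `H -> n x 2` matrix.
#' @return one-row tibble with `pcc`, `mse`, `srcc`, `cs`.
#' @export
imputation_space_correlation <- function(X_original, H,
                                         projector = "pca") {
  if (inherits(X_original, "processed_expression")) X_original <- X_original$X
  X_original <- as.matrix(X_original); H <- as.matrix(H)
  if (nrow(X_original) != nrow(H))
    stop("matrices are not aligned on spots", call. = FALSE)
  if (nrow(H) < 3) stop("need at least 3 spots", call. = FALSE)
  proj <- if (is.function(projector)) projector(H)
          else switch(projector,
                      pca = reduce_pca(H, n_comp = min(2, ncol(H))),
                      identity = H,
                      stop("unknown projector", call. = FALSE))
  d_orig <- as.numeric(stats::dist(X_original))
  d_imp <- as.numeric(stats::dist(proj))
  tibble::tibble(pcc = pearson(d_orig, d_imp),
                 mse = mean_squared_error_metric(d_orig, d_imp),
                 srcc = spearman(d_orig, d_imp),
                 cs = cosine_similarity_metric(d_orig, d_imp))
}
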