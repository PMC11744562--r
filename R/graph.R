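#' Symmetrized k-nearest-neighbor adjacency
#'
#' Builds the directed kNN relation on the rows of `points` under the chosen
#' metric, then symmetrizes by logical OR so the result is an undirected
#' graph. Ties in distance are broken by spot index (stable order). The
#' diagonal is zero.
#'
#' @param points numeric matrix, one row per spot (2-D coordinates for the
#'   spatial graph, expression profiles or PCs for the expression graph).
#' @param k number of neighbors per spot; must satisfy `k < nrow(points)`.
#' @param metric `"euclidean"` (default), `"cosine"` or `"manhattan"`.
#' @return binary symmetric matrix with zero diagonal; every row has at
#'   least `k` nonzero entries.
#' @export
knn_adjacency <- function(points, k,
                          metric = c("euclidean", "cosine", "manhattan")) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  n <- nrow(points)
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  if (k >= n)
    stop(sprintf("k = %d must be smaller than the number of spots (%d)",
                 k, n), call. = FALSE)

  D <- switch(metric,
    euclidean = as.matrix(stats::dist(points, method = "euclidean")),
    manhattan = as.matrix(stats::dist(points, method = "manhattan")),
    cosine = {
      nrm <- sqrt(rowSums(points^2))
      nrm[nrm == 0] <- 1
      S <- tcrossprod(points / nrm)
      1 - S
    })
  diag(D) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]  # order() is stable: index-order ties
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))   # OR-symmetrization
  diag(A) <- 0
  A
}

#' Fuse spatial and expression neighbor graphs
#'
#' Combines the two binary kNN adjacencies as
#' `A = min(A_spatial + alpha * A_gene, 1)`, so spatial edges carry weight 1,
#' expression-only edges weight `alpha`, and shared edges are clipped at 1.
#'
#' @param A_spatial,A_gene binary symmetric matrices with zero diagonal,
#'   same shape.
#' @param alpha expression-edge weight in (0, 1]; default 0.5.
#' @param k1,k2 optional records of the neighbor counts used (metadata only).
#' @return An object of class `neighbor_graph`: list with the fused `A`,
#'   the inputs `A_spatial`, `A_gene`, the parameters, and `A_norm`, the
#'   self-loop-augmented symmetric GCN propagation matrix from
#'   [normalize_adjacency()].
#' @export
combine_graphs <- function(A_spatial, A_gene, alpha = 0.5,
                           k1 = NA_integer_, k2 = NA_integer_) {
  if (!all(dim(A_spatial) == dim(A_gene)))
    stop("A_spatial and A_gene have different shapes", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]", call. = FALSE)
  A <- pmin(A_spatial + alpha * A_gene, 1)
  diag(A) <- 0
  structure(
    list(A = A, A_spatial = A_spatial, A_gene = A_gene,
         k1 = k1, k2 = k2, alpha = alpha,
         A_norm = normalize_adjacency(A)),
    class = "neighbor_graph"
  )
}

#' Symmetric GCN propagation matrix
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2)` with degree
#' `D = diag((I + A) 1_n)`, the self-loop-augmented symmetric normalization
#' used by graph convolutional layers. Every degree is at least 1 because of
#' the identity term, so the result is always finite; isolated spots get a
#' unit self-loop row.
#'
#' @param A symmetric weighted adjacency with zero diagonal, entries in
#'   `[0, 1]`.
#' @return symmetric propagation matrix of the same shape.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (!isSymmetric(unname(A), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  n <- nrow(A)
  Ai <- A + diag(n)
  d <- rowSums(Ai)
  dinv <- 1 / sqrt(d)
  P <- Ai * tcrossprod(dinv)   # D^-1/2 (A+I) D^-1/2
  (P + t(P)) / 2               # kill round-off asymmetry
}

#' Build the fused transcriptomics-profile-based spatial graph
#'
#' End-to-end graph construction: a spatial kNN graph on the coordinates, an
#' expression kNN graph on the processed expression (on its top `n_pcs`
#' principal components by default, for robustness), fused with weight
#' `alpha` and GCN-normalized.
#'
#' @param coords spots x 2 coordinate matrix.
#' @param X processed expression matrix (spots x genes), e.g. from
#'   [preprocess()].
#' @param k1 spatial neighbors (default 3).
#' @param k2 expression neighbors (default 3).
#' @param alpha expression-edge weight in (0, 1] (default 0.5).
#' @param metric distance metric for both kNN searches.
#' @param n_pcs number of principal components for the expression kNN;
#'   `NULL` uses the raw processed matrix.
#' @param mode `"fused"` (default) combines both graphs; `"spatial"` and
#'   `"gene"` use one source alone (ablations: the gene-only mode removes
#'   all spatial edges).
#' @return a `neighbor_graph` (see [combine_graphs()]).
#' @export
build_graph <- function(coords, X, k1 = 3, k2 = 3, alpha = 0.5,
                        metric = "euclidean", n_pcs = 50,
                        mode = c("fused", "spatial", "gene")) {
  mode <- match.arg(mode)
  if (inherits(X, "processed_expression")) X <- X$X
  Xg <- X
  if (!is.null(n_pcs) && n_pcs < ncol(X)) Xg <- reduce_pca(X, n_pcs)
  A_gene <- knn_adjacency(Xg, k2, metric = metric)
  A_spatial <- knn_adjacency(coords, k1, metric = metric)
  zero <- matrix(0, nrow(A_spatial), ncol(A_spatial))
  switch(mode,
    fused = combine_graphs(A_spatial, A_gene, alpha = alpha,
                           k1 = as.integer(k1), k2 = as.integer(k2)),
    spatial = combine_graphs(A_spatial, zero, alpha = alpha,
                             k1 = as.integer(k1), k2 = NA_integer_),
    gene = {
      g <- combine_graphs(A_gene, zero, alpha = alpha,
                          k1 = NA_integer_, k2 = as.integer(k2))
      g$A_spatial <- zero; g$A_gene <- A_gene
      g
    })
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf(
    "<neighbor_graph> %d spots, %d spatial + %d expression edges, alpha = %g\n",
    nrow(x$A), sum(x$A_spatial) / 2, sum(x$A_gene) / 2, x$alpha))
  invisible(x)
}

#' Export a graph as an edge-list tibble
#'
#' @param graph a `neighbor_graph`.
#' @return tibble with columns `i`, `j`, `weight` (upper triangle only).
#' @export
graph_edges <- function(graph) {
  A <- graph$A
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], weight = A[idx])
}
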