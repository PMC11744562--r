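#' Clustering and imputation evaluation metrics
#'
#' Formula-faithful implementations of the external clustering metrics
#' (adjusted Rand index, normalized mutual information, homogeneity score),
#' the internal Davies-Bouldin index, and the imputation-space agreement
#' metrics (Pearson, mean squared error, Spearman, cosine similarity), all
#' computed directly from their defining expressions on the contingency
#' table or raw vectors.
#'
#' @name stdcl-metrics
NULL

contingency <- function(true, pred) {
  if (length(true) != length(pred))
    stop("label vectors have different lengths", call. = FALSE)
  table(factor(true), factor(pred))
}

choose2 <- function(x) x * (x - 1) / 2

#' Adjusted Rand index
#'
#' Pair-counting agreement between two labelings, corrected for chance;
#' 1 for identical partitions (up to label names), ~0 for random ones.
#'
#' @param true,pred label vectors of equal length.
#' @return scalar in `[-1, 1]`.
#' @rdname stdcl-metrics
#' @export
adjusted_rand_index <- function(true, pred) {
  tab <- contingency(true, pred)
  n <- sum(tab)
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

entropy_counts <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Mutual information between the partitions normalized by the geometric
#' mean of their entropies; a single-cluster labeling has zero entropy, in
#' which case 0 is returned with a warning.
#'
#' @rdname stdcl-metrics
#' @export
normalized_mutual_information <- function(true, pred) {
  tab <- contingency(true, pred)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
  }
  ha <- entropy_counts(a, n); hb <- entropy_counts(b, n)
  if (ha == 0 || hb == 0) {
    warning("a labeling has a single cluster; NMI undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  val <- mi / sqrt(ha * hb)
  min(max(val, 0), 1)
}

#' Homogeneity score
#'
#' `1 - H(C|K)/H(C)`: 1 when every predicted cluster contains members of a
#' single true class (any refinement of the truth scores 1). Returns 1 by
#' convention when the true labeling has zero entropy.
#'
#' @rdname stdcl-metrics
#' @export
homogeneity_score <- function(true, pred) {
  tab <- contingency(true, pred)
  n <- sum(tab)
  hc <- entropy_counts(rowSums(tab), n)
  if (hc == 0) return(1)
  b <- colSums(tab)
  hck <- 0
  for (j in seq_along(b)) {
    if (b[j] > 0) {
      col <- tab[, j]
      p <- col[col > 0]
      hck <- hck - sum((p / n) * log(p / b[j]))
    }
  }
  1 - hck / hc
}

#' Davies-Bouldin index
#'
#' Average over clusters of the worst ratio of summed within-cluster
#' scatter (mean Euclidean distance to the centroid) to centroid
#' separation. Lower is better; 0 for point-mass clusters.
#'
#' @param points numeric matrix of observations.
#' @param labels cluster labels, at least 2 non-empty clusters.
#' @rdname stdcl-metrics
#' @export
davies_bouldin <- function(points, labels) {
  points <- as.matrix(points)
  labs <- unique(labels)
  k <- length(labs)
  if (k < 2) stop("need at least 2 clusters", call. = FALSE)
  centroids <- do.call(rbind, lapply(labs, function(l)
    colMeans(points[labels == l, , drop = FALSE])))
  scatter <- vapply(seq_len(k), function(i) {
    pts <- points[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, centroids[i, ])^2)))
  }, numeric(1))
  E <- as.matrix(stats::dist(centroids))
  zero_pairs <- which(E == 0 & upper.tri(E), arr.ind = TRUE)
  if (nrow(zero_pairs) > 0)
    stop(sprintf("coincident centroids for clusters %s and %s",
                 labs[zero_pairs[1, 1]], labs[zero_pairs[1, 2]]),
         call. = FALSE)
  diag(E) <- Inf
  mean(vapply(seq_len(k), function(i)
    max((scatter[i] + scatter[-i]) / E[i, -i]), numeric(1)))
}

#' Pearson correlation coefficient
#' @param x,y numeric vectors of equal length.
#' @rdname stdcl-metrics
#' @export
pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

#' Mean squared error
#' @rdname stdcl-metrics
#' @export
mean_squared_error_metric <- function(x, y) mean((x - y)^2)

#' Spearman rank correlation (mid-ranks for ties)
#' @rdname stdcl-metrics
#' @export
spearman <- function(x, y) {
  pearson(rank(x, ties.method = "average"),
          rank(y, ties.method = "average"))
}

#' Cosine similarity of two non-zero vectors
#' @rdname stdcl-metrics
#' @export
cosine_similarity_metric <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine similarity is undefined for a zero vector", call. = FALSE)
  sum(x * y) / (nx * ny)
}

#' Clustering evaluation report
#'
#' Convenience wrapper computing ARI, NMI and HS of predicted vs true
#' labels (plus DBI when an embedding is supplied) as a one-row tibble.
#'
#' @param true,pred label vectors.
#' @param embedding optional matrix for the DBI.
#' @return one-row tibble with columns `ari`, `nmi`, `hs` (and `dbi`).
#' @export
evaluate_clustering <- function(true, pred, embedding = NULL) {
  out <- tibble::tibble(
    ari = adjusted_rand_index(true, pred),
    nmi = normalized_mutual_information(true, pred),
    hs = homogeneity_score(true, pred))
  if (!is.null(embedding)) out$dbi <- davies_bouldin(embedding, pred)
  out
}
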