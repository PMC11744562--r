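#' Gaussian corruption noise specification
#'
#' The corrupted view is `X * N` elementwise (Hadamard product) with
#' `N ~ Normal(mean, sd^2)`. The default mean 1 keeps the expected
#' expression unchanged; `sd` controls corruption strength.
#'
#' @param mean noise mean (default 1).
#' @param sd noise standard deviation (default 0.1), must be positive.
#' @param seed integer seed for the noise draw.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(mean = 1, sd = 0.1, seed = 0) {
  if (!is.numeric(sd) || sd <= 0) stop("noise sd must be positive", call. = FALSE)
  structure(list(mean = mean, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt the expression matrix with multiplicative Gaussian noise
#'
#' @param X processed expression matrix.
#' @param noise a [noise_spec()]; the same seed gives an identical
#'   corrupted matrix.
#' @return corrupted matrix, same shape as `X`.
#' @export
corrupt_expression <- function(X, noise = noise_spec()) {
  if (inherits(X, "processed_expression")) X <- X$X
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  N <- matrix(stats::rnorm(length(X), noise$mean, noise$sd),
              nrow(X), ncol(X))
  X * N
}

# rows of M scaled to unit norm; zero rows stay zero (with optional warning)
row_normalize <- function(M, warn = FALSE) {
  nrm <- sqrt(rowSums(M^2))
  zero <- nrm == 0
  if (warn && any(zero))
    warning(sprintf("%d zero-norm row(s): their similarities are set to 0",
                    sum(zero)), call. = FALSE)
  nrm[zero] <- 1
  M / nrm
}

#' Cross-view cosine similarity of spot embeddings
#'
#' `S[i, j]` is the cosine similarity between spot `i`'s embedding in the
#' clean view and spot `j`'s embedding in the corrupted view. Zero-norm rows
#' yield similarity 0 with a warning.
#'
#' @param Z,Z_hat latent matrices of the two views, same shape.
#' @return spots x spots matrix with entries in `[-1, 1]`.
#' @export
cross_view_similarity <- function(Z, Z_hat) {
  if (!all(dim(Z) == dim(Z_hat)))
    stop("views have different shapes", call. = FALSE)
  tcrossprod(row_normalize(Z, warn = TRUE), row_normalize(Z_hat, warn = TRUE))
}

#' Space-aware contrastive loss
#'
#' Mean squared error between the cross-view spot similarity matrix and the
#' fused adjacency, over all n^2 entries: minimizing it pulls spatially
#' adjacent spots together (toward similarity ~ edge weight) and pushes
#' non-adjacent spots apart (toward 0).
#'
#' @param S cross-view cosine similarity matrix.
#' @param A fused adjacency of the same shape.
#' @return non-negative scalar.
#' @export
space_contrastive_loss <- function(S, A) {
  if (!all(dim(S) == dim(A))) stop("S and A have different shapes", call. = FALSE)
  mean((S - A)^2)
}

#' Random equal-size group assignment
#'
#' Partitions `n` spots into `k` nearly equal groups (sizes differ by at
#' most 1) by a seeded random permutation split into contiguous blocks.
#' Used as the grouping for the cluster-level readout during training.
#'
#' @param n number of spots.
#' @param k number of groups (the number of clusters), `k <= n`.
#' @param seed integer seed.
#' @return list of class `group_assignment` with `groups` (0-based integer
#'   vector length `n`) and `k`.
#' @export
assign_groups <- function(n, k, seed = 0) {
  if (k > n) stop("k cannot exceed the number of spots", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  groups <- integer(n)
  groups[perm] <- rep(seq_len(k) - 1L, times = sizes)
  structure(list(groups = groups, k = as.integer(k)),
            class = "group_assignment")
}

#' Group-mean readout of an embedding
#'
#' Row `i` of the result is the mean latent vector of the spots assigned to
#' group `i`; the k x d matrix of group averages is the cluster-level
#' representation contrasted across views.
#'
#' @param Z latent matrix (spots x d).
#' @param g a [assign_groups()] result consistent with `nrow(Z)`.
#' @return k x d matrix.
#' @export
cluster_readout <- function(Z, g) {
  if (length(g$groups) != nrow(Z))
    stop("group assignment does not match the number of spots", call. = FALSE)
  tab <- tabulate(g$groups + 1L, nbins = g$k)
  if (any(tab == 0)) stop("empty group in assignment", call. = FALSE)
  R <- rowsum(Z, group = g$groups, reorder = TRUE)
  R / tab
}

# readout as an averaging operator G (k x n), so R = G %*% Z and gradients
# flow back as t(G) %*% dR
readout_operator <- function(g, n) {
  G <- matrix(0, g$k, n)
  G[cbind(g$groups + 1L, seq_len(n))] <- 1
  G / rowSums(G)
}

# d x d cross-view feature cosine matrix: columns of the readouts are the
# feature vectors
feature_cosine <- function(R1, R2) {
  C1 <- t(row_normalize(t(R1)))
  C2 <- t(row_normalize(t(R2)))
  crossprod(C1, C2)
}

#' Cluster-level feature contrastive loss
#'
#' Computes the d x d cosine similarity matrix between the feature columns
#' of the two views' group readouts, then penalizes its distance from the
#' identity with split normalization: `(1/d^2) * sum_i (S[i,i] - 1)^2 +
#' (1/(d^2 - d)) * sum_{i != j} S[i,j]^2`. This decorrelates latent
#' dimensions across views while aligning each dimension with itself.
#' `normalization = "uniform"` uses `1/d^2` for both terms instead.
#'
#' @param R1,R2 k x d readout matrices of the two views
#'   (see [cluster_readout()]).
#' @param normalization `"split"` (default) or `"uniform"`.
#' @return non-negative scalar.
#' @export
cluster_feature_loss <- function(R1, R2,
                                 normalization = c("split", "uniform")) {
  normalization <- match.arg(normalization)
  d <- ncol(R1)
  if (d < 2) stop("latent dimension must be at least 2", call. = FALSE)
  S <- feature_cosine(R1, R2)
  diag_term <- sum((diag(S) - 1)^2)
  off <- S; diag(off) <- 0
  off_term <- sum(off^2)
  if (normalization == "split")
    diag_term / d^2 + off_term / (d^2 - d)
  else
    (diag_term + off_term) / d^2
}

#' Total training loss
#'
#' `gamma1 * L_rec + gamma2 * L_con + gamma3 * L_clu` with default weights
#' (10, 0.5, 0.8).
#'
#' @param l_rec,l_con,l_clu component losses.
#' @param w a [loss_weights()].
#' @return scalar.
#' @export
total_loss <- function(l_rec, l_con, l_clu, w = loss_weights()) {
  w$gamma1 * l_rec + w$gamma2 * l_con + w$gamma3 * l_clu
}
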