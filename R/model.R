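#' Initialize the graph convolutional autoencoder
#'
#' A single-hidden-layer GCN autoencoder: the encoder maps the processed
#' expression to a `d`-dimensional latent embedding through one graph
#' convolution, the decoder maps it back with a second graph convolution,
#' and an inner-product decoder reconstructs the adjacency. Weights use
#' Glorot-uniform initialization, drawn deterministically from `seed`.
#'
#' @param n_hvg number of input genes (columns of the processed matrix).
#' @param d latent dimension, at least 2; default 64.
#' @param seed integer RNG seed for the weight draw.
#' @param activation encoder activation: `"elu"` (default), `"relu"` or
#'   `"identity"`. The decoder is linear so the zero-mean scaled input can
#'   be reconstructed.
#' @return An object of class `stdcl_model`: list with `W_e` (n_hvg x d),
#'   `W_d` (d x n_hvg), `d`, `activation`, `rng_seed`.
#' @export
init_model <- function(n_hvg, d = 64, seed = 0,
                       activation = c("elu", "relu", "identity")) {
  activation <- match.arg(activation)
  if (!is.numeric(d) || length(d) != 1 || d < 2)
    stop("latent dimension d must be at least 2", call. = FALSE)
  d <- as.integer(d); n_hvg <- as.integer(n_hvg)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W_e <- glorot_uniform(n_hvg, d)
  W_d <- glorot_uniform(d, n_hvg)
  structure(
    list(W_e = W_e, W_d = W_d, d = d, activation = activation,
         rng_seed = as.integer(seed)),
    class = "stdcl_model"
  )
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# save/restore the global RNG state so seeded internals do not clobber it
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

activate <- function(U, activation) {
  switch(activation,
    elu = ifelse(U > 0, U, expm1(U)),
    relu = pmax(U, 0),
    identity = U)
}

activate_grad <- function(U, activation) {
  switch(activation,
    elu = ifelse(U > 0, 1, exp(U)),
    relu = (U > 0) * 1,
    identity = array(1, dim(U)))
}

#' Encode expression through the graph convolutional encoder
#'
#' `Z = activation(A_norm %*% X %*% W_e)`: one graph convolution that mixes
#' each spot's expression with its (weighted) neighborhood before the linear
#' projection to the latent space.
#'
#' @param X processed expression matrix (spots x n_hvg) or a
#'   `processed_expression` object.
#' @param A_norm GCN propagation matrix from [normalize_adjacency()] or a
#'   `neighbor_graph`.
#' @param model a `stdcl_model`.
#' @return latent matrix, spots x d.
#' @export
encode <- function(X, A_norm, model) {
  if (inherits(X, "processed_expression")) X <- X$X
  if (inherits(A_norm, "neighbor_graph")) A_norm <- A_norm$A_norm
  if (any(!is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  activate(A_norm %*% (X %*% model$W_e), model$activation)
}

#' Decode the latent embedding back to expression space
#'
#' `H = A_norm %*% Z %*% W_d`, the linear graph-convolutional decoder. `H`
#' is the imputed (reconstructed) expression matrix.
#'
#' @param Z latent matrix (spots x d).
#' @inheritParams encode
#' @return reconstructed expression, spots x n_hvg.
#' @export
decode <- function(Z, A_norm, model) {
  if (inherits(A_norm, "neighbor_graph")) A_norm <- A_norm$A_norm
  A_norm %*% (Z %*% model$W_d)
}

#' Inner-product adjacency reconstruction
#'
#' `A_hat = sigmoid(Z %*% t(Z))`: each entry is the sigmoid of the latent
#' inner product of a spot pair, a symmetric matrix with entries strictly in
#' (0, 1) compared against the fused adjacency in the reconstruction loss.
#'
#' @param Z latent matrix (spots x d).
#' @return spots x spots matrix.
#' @export
reconstruct_adjacency <- function(Z) {
  Q <- tcrossprod(Z)
  S <- 1 / (1 + exp(-Q))
  (S + t(S)) / 2
}

#' Reconstruction loss of expression and adjacency
#'
#' `(1/n) * sum_i [ alpha1 * ||H_i - X_i||^2 + alpha2 * ||A_hat_i - A_i||^2 ]`
#' where rows are per-spot vectors. Defaults `alpha1 = 1.0`, `alpha2 = 0.5`.
#'
#' @param X,H processed and reconstructed expression (spots x n_hvg).
#' @param A,A_hat fused and reconstructed adjacency (spots x spots).
#' @param w a [loss_weights()] object (only `alpha1`, `alpha2` are used).
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(X, H, A, A_hat, w = loss_weights()) {
  n <- nrow(X)
  (w$alpha1 * sum((H - X)^2) + w$alpha2 * sum((A_hat - A)^2)) / n
}

#' Loss weight configuration
#'
#' Bundles the five loss coefficients: `alpha1`, `alpha2` weight the
#' expression and adjacency terms inside the reconstruction loss;
#' `gamma1`, `gamma2`, `gamma3` weight reconstruction, space-aware
#' contrastive and cluster-level feature contrastive losses in the total.
#' Defaults are the tuned values (1.0, 0.5) and (10, 0.5, 0.8).
#'
#' @param gamma1,gamma2,gamma3,alpha1,alpha2 non-negative reals.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(gamma1 = 10, gamma2 = 0.5, gamma3 = 0.8,
                         alpha1 = 1.0, alpha2 = 0.5) {
  w <- list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
            alpha1 = alpha1, alpha2 = alpha2)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative", call. = FALSE)
  if (all(unlist(w) == 0)) stop("at least one loss weight must be positive",
                                call. = FALSE)
  structure(w, class = "loss_weights")
}
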