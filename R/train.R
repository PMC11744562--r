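#' Training configuration
#'
#' Two-phase schedule: pre-training optimizes the reconstruction loss alone
#' to warm-start the autoencoder, then full training optimizes the total
#' loss with both contrastive terms. Both phases use Adam. Defaults are the
#' tuned schedule: 500 pre-training epochs at learning rate 0.001 and 1000
#' training epochs at learning rate 0.005.
#'
#' @param pretrain_epochs,train_epochs positive epoch counts.
#' @param pretrain_lr,train_lr positive learning rates.
#' @param optimizer only `"adam"`.
#' @param seed integer seed controlling weight initialization and the
#'   grouping/corruption streams.
#' @return list of class `train_config`.
#' @export
train_config <- function(pretrain_epochs = 500, train_epochs = 1000,
                         pretrain_lr = 0.001, train_lr = 0.005,
                         optimizer = "adam", seed = 0) {
  stopifnot(pretrain_epochs >= 0, train_epochs >= 0,
            pretrain_lr > 0, train_lr > 0)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 train_epochs = as.integer(train_epochs),
                 pretrain_lr = pretrain_lr, train_lr = train_lr,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

# ---- forward + analytic gradients -----------------------------------------
#
# The model has two parameter matrices so backpropagation is written out
# explicitly. P is the symmetric propagation matrix, M = P X is precomputed.
# The corrupted view shares the encoder, so its gradient contributions
# accumulate into the same W_e.

# backprop through row normalization: given dL/d(row-normalized M),
# return dL/dM. nrm are the original row norms (zeros already replaced by 1).
rownorm_backprop <- function(dMn, Mn, nrm) {
  (dMn - Mn * rowSums(dMn * Mn)) / nrm
}

# full forward pass + gradients of the weighted loss terms.
# Returns loss components and gradients wrt W_e, W_d.
stdcl_grads <- function(model, X, Xhat, P, A, G, w,
                        with_contrastive = TRUE,
                        normalization = "split") {
  n <- nrow(X)
  W_e <- model$W_e; W_d <- model$W_d
  act <- model$activation

  M <- P %*% X
  U <- M %*% W_e
  Z <- activate(U, act)
  PZ <- P %*% Z
  H <- PZ %*% W_d
  Q <- tcrossprod(Z)
  Ahat <- 1 / (1 + exp(-Q))

  l_rec <- (w$alpha1 * sum((H - X)^2) + w$alpha2 * sum((Ahat - A)^2)) / n

  dZ <- matrix(0, n, ncol(Z))
  # expression reconstruction
  dH <- (w$gamma1 * 2 * w$alpha1 / n) * (H - X)
  dW_d <- crossprod(PZ, dH)
  dZ <- dZ + P %*% tcrossprod(dH, W_d)
  # adjacency reconstruction
  dAhat <- (w$gamma1 * 2 * w$alpha2 / n) * (Ahat - A)
  dQ <- dAhat * Ahat * (1 - Ahat)
  dZ <- dZ + (dQ + t(dQ)) %*% Z

  l_con <- 0; l_clu <- 0
  dZhat <- NULL; Uhat <- NULL
  if (with_contrastive) {
    Mhat <- P %*% Xhat
    Uhat <- Mhat %*% W_e
    Zhat <- activate(Uhat, act)
    dZhat <- matrix(0, n, ncol(Z))

    # space-aware contrastive: S = rownorm(Z) %*% t(rownorm(Zhat))
    nz <- sqrt(rowSums(Z^2));    nz[nz == 0] <- 1
    nzh <- sqrt(rowSums(Zhat^2)); nzh[nzh == 0] <- 1
    Zn <- Z / nz; Zhn <- Zhat / nzh
    S <- tcrossprod(Zn, Zhn)
    l_con <- mean((S - A)^2)
    dS <- (w$gamma2 * 2 / n^2) * (S - A)
    dZ <- dZ + rownorm_backprop(dS %*% Zhn, Zn, nz)
    dZhat <- dZhat + rownorm_backprop(crossprod(dS, Zn), Zhn, nzh)

    # cluster-level feature contrastive on readout columns
    R1 <- G %*% Z; R2 <- G %*% Zhat
    c1 <- sqrt(colSums(R1^2)); c1[c1 == 0] <- 1
    c2 <- sqrt(colSums(R2^2)); c2[c2 == 0] <- 1
    C1 <- sweep(R1, 2, c1, "/"); C2 <- sweep(R2, 2, c2, "/")
    St <- crossprod(C1, C2)
    d <- ncol(Z)
    diag_res <- diag(St) - 1
    off <- St; diag(off) <- 0
    if (normalization == "split") {
      l_clu <- sum(diag_res^2) / d^2 + sum(off^2) / (d^2 - d)
      dSt <- (2 / (d^2 - d)) * off
      diag(dSt) <- (2 / d^2) * diag_res
    } else {
      l_clu <- (sum(diag_res^2) + sum(off^2)) / d^2
      dSt <- (2 / d^2) * off
      diag(dSt) <- (2 / d^2) * diag_res
    }
    dSt <- w$gamma3 * dSt
    dC1 <- C2 %*% t(dSt)
    dC2 <- C1 %*% dSt
    # column-norm backprop (row-norm formula on transposed matrices)
    dR1 <- t(rownorm_backprop(t(dC1), t(C1), c1))
    dR2 <- t(rownorm_backprop(t(dC2), t(C2), c2))
    dZ <- dZ + crossprod(G, dR1)
    dZhat <- dZhat + crossprod(G, dR2)
  }

  dU <- dZ * activate_grad(U, act)
  gW_e <- crossprod(M, dU)
  if (with_contrastive) {
    dUhat <- dZhat * activate_grad(Uhat, act)
    gW_e <- gW_e + crossprod(Mhat, dUhat)
  }

  list(l_rec = l_rec, l_con = l_con, l_clu = l_clu,
       total = w$gamma1 * l_rec + w$gamma2 * l_con + w$gamma3 * l_clu,
       gW_e = gW_e, gW_d = dW_d)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(model) {
  list(m_e = model$W_e * 0, v_e = model$W_e * 0,
       m_d = model$W_d * 0, v_d = model$W_d * 0, t = 0L)
}

adam_step <- function(model, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m_e <- beta1 * state$m_e + (1 - beta1) * grads$gW_e
  state$v_e <- beta2 * state$v_e + (1 - beta2) * grads$gW_e^2
  model$W_e <- model$W_e - lr * (state$m_e / bc1) / (sqrt(state$v_e / bc2) + eps)
  state$m_d <- beta1 * state$m_d + (1 - beta1) * grads$gW_d
  state$v_d <- beta2 * state$v_d + (1 - beta2) * grads$gW_d^2
  model$W_d <- model$W_d - lr * (state$m_d / bc1) / (sqrt(state$v_d / bc2) + eps)
  list(model = model, state = state)
}

check_finite_loss <- function(grads, epoch) {
  if (!is.finite(grads$total))
    stop(sprintf(
      "non-finite loss at epoch %d (l_rec = %g, l_con = %g, l_clu = %g)",
      epoch, grads$l_rec, grads$l_con, grads$l_clu), call. = FALSE)
}

#' Pre-train the autoencoder on the reconstruction loss
#'
#' Runs `cfg$pretrain_epochs` full-batch Adam steps on
#' `gamma1 * L_rec` only (no corruption, no contrastive terms), returning
#' the warm-started model. Deterministic given the model and config.
#'
#' @param model a `stdcl_model` from [init_model()].
#' @param X processed expression (`processed_expression` or matrix).
#' @param graph a `neighbor_graph`.
#' @param cfg a [train_config()].
#' @param w a [loss_weights()].
#' @return the updated `stdcl_model`, with attribute `"loss_history"`
#'   (tibble: epoch, l_rec).
#' @export
pretrain <- function(model, X, graph, cfg = train_config(),
                     w = loss_weights()) {
  if (inherits(X, "processed_expression")) X <- X$X
  P <- graph$A_norm; A <- graph$A
  state <- adam_init(model)
  hist <- numeric(cfg$pretrain_epochs)
  for (e in seq_len(cfg$pretrain_epochs)) {
    g <- stdcl_grads(model, X, NULL, P, A, NULL, w, with_contrastive = FALSE)
    check_finite_loss(g, e)
    hist[e] <- g$l_rec
    st <- adam_step(model, g, state, cfg$pretrain_lr)
    model <- st$model; state <- st$state
  }
  attr(model, "loss_history") <-
    tibble::tibble(epoch = seq_len(cfg$pretrain_epochs), l_rec = hist)
  model
}

#' Train with the full dual contrastive objective
#'
#' Each epoch: redraw the multiplicative Gaussian corruption, encode both
#' views through the shared encoder, compute the reconstruction loss, the
#' space-aware contrastive loss and the cluster-level feature contrastive
#' loss, and take one full-batch Adam step on their weighted sum. The group
#' assignment for the cluster-level readout is a seeded equal-size random
#' partition into `k` groups, fixed for the run.
#'
#' @inheritParams pretrain
#' @param k number of clusters (groups for the cluster-level readout).
#' @param noise a [noise_spec()] for the corrupted view.
#' @param normalization off-diagonal normalization of the cluster-level
#'   loss: `"split"` (default) or `"uniform"`.
#' @return list with `model` (final `stdcl_model`) and `history` (tibble:
#'   epoch, l_rec, l_con, l_clu, total).
#' @export
train <- function(model, X, graph, k, cfg = train_config(),
                  w = loss_weights(), noise = noise_spec(),
                  normalization = c("split", "uniform")) {
  normalization <- match.arg(normalization)
  if (inherits(X, "processed_expression")) X <- X$X
  P <- graph$A_norm; A <- graph$A
  n <- nrow(X)
  ga <- assign_groups(n, k, seed = cfg$seed)
  G <- readout_operator(ga, n)
  state <- adam_init(model)
  hist <- matrix(0, cfg$train_epochs, 4,
                 dimnames = list(NULL, c("l_rec", "l_con", "l_clu", "total")))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  for (e in seq_len(cfg$train_epochs)) {
    N <- matrix(stats::rnorm(length(X), noise$mean, noise$sd),
                n, ncol(X))
    g <- stdcl_grads(model, X, X * N, P, A, G, w,
                     with_contrastive = TRUE, normalization = normalization)
    check_finite_loss(g, e)
    hist[e, ] <- c(g$l_rec, g$l_con, g$l_clu, g$total)
    st <- adam_step(model, g, state, cfg$train_lr)
    model <- st$model; state <- st$state
  }
  list(model = model,
       history = tibble::tibble(epoch = seq_len(cfg$train_epochs),
                                l_rec = hist[, 1], l_con = hist[, 2],
                                l_clu = hist[, 3], total = hist[, 4]))
}
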