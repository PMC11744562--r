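# Independent brute-force oracles for the clustering metrics, written from
# first principles (pair counting and direct entropy sums) so they share no
# code path with the package implementations.

# ARI by exhaustive pair counting: a = pairs co-clustered in both labelings,
# b/c = co-clustered in one only, d = separated in both.
oracle_ari <- function(true, pred) {
  n <- length(true)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- true[i] == true[j]
    sp <- pred[i] == pred[j]
    if (st && sp) a <- a + 1
    else if (st && !sp) b <- b + 1
    else if (!st && sp) cc <- cc + 1
    else d <- d + 1
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)
  2 * (a * d - b * cc) / denom
}

# entropy of a labeling from its empirical distribution
oracle_entropy <- function(l) {
  p <- as.numeric(table(l)) / length(l)
  -sum(p * log(p))
}

oracle_mutual_information <- function(true, pred) {
  n <- length(true)
  mi <- 0
  for (u in unique(true)) for (v in unique(pred)) {
    p_uv <- sum(true == u & pred == v) / n
    if (p_uv > 0) {
      p_u <- sum(true == u) / n
      p_v <- sum(pred == v) / n
      mi <- mi + p_uv * log(p_uv / (p_u * p_v))
    }
  }
  mi
}

oracle_nmi <- function(true, pred) {
  ht <- oracle_entropy(true)
  hp <- oracle_entropy(pred)
  if (ht == 0 || hp == 0) return(0)
  oracle_mutual_information(true, pred) / sqrt(ht * hp)
}

oracle_hs <- function(true, pred) {
  hc <- oracle_entropy(true)
  if (hc == 0) return(1)
  hck <- 0
  for (v in unique(pred)) {
    sel <- pred == v
    hck <- hck + sum(sel) / length(pred) * oracle_entropy(true[sel])
  }
  1 - hck / hc
}

# naive dense GCN-layer oracle: entry (i, j) computed as an explicit double
# sum over intermediate indices, no matrix products.
oracle_gcn_layer <- function(P, X, W, activation = "identity") {
  n <- nrow(P); d <- ncol(W)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) for (j in seq_len(d)) {
    acc <- 0
    for (l in seq_len(n)) acc <- acc + P[i, l] * sum(X[l, ] * W[, j])
    out[i, j] <- acc
  }
  switch(activation,
         elu = ifelse(out > 0, out, exp(out) - 1),
         relu = pmax(out, 0),
         identity = out)
}

# small random spatial dataset for unit tests
tiny_dataset <- function(n_spots = 30, n_genes = 12, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n_spots * n_genes, 5), n_spots, n_genes)
  counts[1, ] <- counts[1, ] + 1   # guard against an all-zero spot
  spatial_dataset(counts, cbind(runif(n_spots), runif(n_spots)))
}
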