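#' Synthetic tissue specification
#'
#' Parameters for the layered-tissue simulator used throughout the test
#' suite: spots on a jittered grid partitioned into contiguous spatial
#' domains (parallel stripes like cortical layers, Voronoi blobs, or
#' concentric rings), domain-specific marker-gene programs on a log-normal
#' baseline, negative-binomial counts with optional dropout, and optional
#' label noise.
#'
#' @param n_spots number of spots (default 800).
#' @param layout `"stripes"` (default), `"blobs"` or `"rings"`.
#' @param n_domains number of spatial domains (default 4, at least 2).
#' @param n_genes number of genes (default 200).
#' @param n_markers_per_domain marker genes per domain (default 10);
#'   `n_markers_per_domain * n_domains <= n_genes`.
#' @param marker_log_fc natural-log fold change of a domain's markers over
#'   baseline (default 1.5).
#' @param dispersion negative-binomial size (shape) parameter; larger is
#'   less overdispersed (default 2).
#' @param dropout_rate probability of zeroing an entry (default 0).
#' @param spatial_jitter sd of Gaussian coordinate jitter in grid-step
#'   units (default 0.1).
#' @param label_noise fraction of spots given a random wrong label
#'   (default 0).
#' @param grid_step spacing between grid points in coordinate units
#'   (default 100, a Visium-like pixel scale).
#' @param seed integer seed.
#' @return list of class `tissue_spec`.
#' @export
tissue_spec <- function(n_spots = 800, layout = c("stripes", "blobs", "rings"),
                        n_domains = 4, n_genes = 200,
                        n_markers_per_domain = 10, marker_log_fc = 1.5,
                        dispersion = 2, dropout_rate = 0,
                        spatial_jitter = 0.1, label_noise = 0,
                        grid_step = 100, seed = 0) {
  layout <- match.arg(layout)
  if (n_domains < 2) stop("n_domains must be at least 2", call. = FALSE)
  if (n_markers_per_domain * n_domains > n_genes)
    stop("too many marker genes for n_genes", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  structure(list(n_spots = as.integer(n_spots), layout = layout,
                 n_domains = as.integer(n_domains),
                 n_genes = as.integer(n_genes),
                 n_markers_per_domain = as.integer(n_markers_per_domain),
                 marker_log_fc = marker_log_fc, dispersion = dispersion,
                 dropout_rate = dropout_rate, spatial_jitter = spatial_jitter,
                 label_noise = label_noise, grid_step = grid_step,
                 seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Named simulator presets
#'
#' Three shipped configurations: `"easy"` (800 spots, 4 stripes, 200
#' genes, 10 markers/domain at log-FC 1.5, mild noise — recoverable to
#' near-perfect ARI), `"ambiguous"` (same geometry with log-FC 0.3, so
#' expression alone barely separates domains and the spatial graph must
#' carry the signal) and `"noisy-labels"` (easy plus 10% label noise, for
#' refinement experiments).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return a [tissue_spec()].
#' @export
tissue_preset <- function(preset = c("easy", "ambiguous", "noisy-labels"),
                          seed = 0) {
  preset <- match.arg(preset)
  switch(preset,
    easy = tissue_spec(seed = seed),
    ambiguous = tissue_spec(marker_log_fc = 0.3, seed = seed),
    `noisy-labels` = tissue_spec(label_noise = 0.1, seed = seed))
}

#' Generate spot coordinates and true domain labels
#'
#' Spots fill a near-square grid (jittered by `spatial_jitter` grid steps);
#' domains are parallel bands (`stripes`), Voronoi regions of random
#' centers (`blobs`) or concentric annuli around the grid center
#' (`rings`). All layouts give contiguous domains. Deterministic given the
#' spec seed.
#'
#' @param spec a [tissue_spec()].
#' @return list with `coords` (n x 2 matrix) and `labels` (0-based
#'   integers, before label noise).
#' @export
generate_domains <- function(spec) {
  if (spec$n_domains > spec$n_spots)
    stop("more domains than spots", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_spots
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  ix <- (seq_len(n) - 1) %% ncol_g
  iy <- (seq_len(n) - 1) %/% ncol_g
  coords <- cbind(x = ix * spec$grid_step, y = iy * spec$grid_step)
  grid_pos <- coords
  if (spec$spatial_jitter > 0)
    coords <- coords + matrix(
      stats::rnorm(2 * n, 0, spec$spatial_jitter * spec$grid_step), n, 2)

  labels <- switch(spec$layout,
    stripes = {
      # bands along y, equal spot counts per band via quantile cuts
      band <- floor(iy / nrow_g * spec$n_domains)
      pmin(band, spec$n_domains - 1L)
    },
    blobs = {
      centers <- cbind(stats::runif(spec$n_domains, 0, ncol_g * spec$grid_step),
                       stats::runif(spec$n_domains, 0, nrow_g * spec$grid_step))
      D <- outer(rowSums(grid_pos^2), rowSums(centers^2), "+") -
        2 * grid_pos %*% t(centers)
      max.col(-D) - 1L
    },
    rings = {
      ctr <- c(mean(grid_pos[, 1]), mean(grid_pos[, 2]))
      r <- sqrt((grid_pos[, 1] - ctr[1])^2 + (grid_pos[, 2] - ctr[2])^2)
      cuts <- stats::quantile(r, probs = seq_len(spec$n_domains - 1) /
                                spec$n_domains)
      findInterval(r, cuts)
    })
  list(coords = coords, labels = as.integer(labels))
}

#' Generate overdispersed counts with domain marker programs
#'
#' Baseline per-gene means are log-normal; each domain's marker block is
#' multiplied by `exp(marker_log_fc)` within that domain. Counts are
#' negative binomial with size `dispersion`, then zeroed independently
#' with probability `dropout_rate`. Deterministic given the spec seed.
#'
#' @param coords,labels from [generate_domains()] (coords unused, kept for
#'   interface symmetry).
#' @param spec a [tissue_spec()].
#' @return integer count matrix, spots x genes, with a `marker_genes`
#'   attribute: list of marker column indices per domain.
#' @export
generate_counts <- function(coords, labels, spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)
  n <- spec$n_spots; g <- spec$n_genes
  base_mu <- exp(stats::rnorm(g, log(2), 0.5))
  markers <- lapply(seq_len(spec$n_domains) - 1L, function(dm)
    (dm * spec$n_markers_per_domain + 1L):((dm + 1L) * spec$n_markers_per_domain))
  mu <- matrix(base_mu, n, g, byrow = TRUE)
  for (dm in seq_len(spec$n_domains) - 1L) {
    rows <- labels == dm
    mu[rows, markers[[dm + 1L]]] <- mu[rows, markers[[dm + 1L]]] *
      exp(spec$marker_log_fc)
  }
  counts <- matrix(stats::rnbinom(n * g, mu = mu, size = spec$dispersion),
                   n, g)
  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::runif(n * g) >= spec$dropout_rate, n, g)
    counts <- counts * keep
  }
  # guarantee no all-zero spot (the preprocessing precondition)
  zero_spots <- rowSums(counts) == 0
  if (any(zero_spots)) counts[zero_spots, 1] <- 1
  attr(counts, "marker_genes") <- markers
  counts
}

#' Generate a complete synthetic spatial dataset
#'
#' Composes [generate_domains()] and [generate_counts()], applies label
#' noise if requested, and returns a [spatial_dataset()] carrying the true
#' labels (post-noise) plus attributes `labels_clean` and `marker_genes`.
#'
#' @param spec a [tissue_spec()] or a preset name for [tissue_preset()].
#' @param seed optional seed overriding `spec$seed`.
#' @return a [spatial_dataset()].
#' @export
generate_dataset <- function(spec = tissue_spec(), seed = NULL) {
  if (is.character(spec)) spec <- tissue_preset(spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  dom <- generate_domains(spec)
  counts <- generate_counts(dom$coords, dom$labels, spec)
  labels <- dom$labels
  if (spec$label_noise > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(spec$seed + 2L)
    n_flip <- round(spec$label_noise * spec$n_spots)
    flip <- sample.int(spec$n_spots, n_flip)
    labels[flip] <- vapply(flip, function(i) {
      sample(setdiff(seq_len(spec$n_domains) - 1L, labels[i]), 1)
    }, integer(1))
  }
  ds <- spatial_dataset(counts, dom$coords, labels = labels)
  attr(ds, "labels_clean") <- dom$labels
  attr(ds, "marker_genes") <- attr(counts, "marker_genes")
  attr(ds, "spec") <- spec
  ds
}
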