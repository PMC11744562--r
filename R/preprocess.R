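#' Library-size normalize and log-transform counts
#'
#' Scales every spot to a common total (the median library size by default,
#' configurable via `target_sum`), then applies `log(1 + x)` elementwise.
#'
#' @param ds a [spatial_dataset()] or a bare non-negative counts matrix.
#' @param target_sum per-spot total after normalization; `NULL` (default)
#'   uses the median library size of the dataset.
#' @return numeric matrix, spots x genes, log-normalized.
#' @export
normalize_log <- function(ds, target_sum = NULL) {
  counts <- if (inherits(ds, "spatial_dataset")) ds$counts else as.matrix(ds)
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    bad <- rownames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop(sprintf("all-zero spot(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(target_sum)) target_sum <- stats::median(lib)
  log1p(counts * (target_sum / lib))
}

#' Select highly variable genes
#'
#' Ranks genes on the log-normalized matrix and returns the indices of the
#' `n_top` most variable. The default statistic is a Seurat-style dispersion
#' (variance / mean, with zero-mean genes given dispersion 0); plain variance
#' is available via `statistic = "variance"`. Datasets with at most `n_top`
#' genes (targeted panels such as STARmap, osmFISH or MERFISH) return all
#' gene indices unchanged.
#'
#' @param Xn log-normalized matrix from [normalize_log()].
#' @param n_top number of genes to keep; default 3000.
#' @param statistic `"dispersion"` (default) or `"variance"`.
#' @return integer vector of column indices into `Xn`, ordered by decreasing
#'   statistic.
#' @export
select_hvg <- function(Xn, n_top = 3000, statistic = c("dispersion", "variance")) {
  statistic <- match.arg(statistic)
  if (!is.numeric(n_top) || length(n_top) != 1 || n_top < 1)
    stop("n_top must be a positive integer", call. = FALSE)
  n_top <- as.integer(n_top)
  if (ncol(Xn) <= n_top) return(seq_len(ncol(Xn)))

  mu <- colMeans(Xn)
  v <- apply(Xn, 2, stats::var)
  stat <- if (statistic == "variance") v else ifelse(mu > 0, v / mu, 0)
  order(stat, decreasing = TRUE)[seq_len(n_top)]
}

#' Center and scale selected genes to zero mean and unit variance
#'
#' Subsets the normalized matrix to the highly variable genes and z-scores
#' each column. Constant columns become all-zero. No value clipping is
#' applied.
#'
#' @param Xn log-normalized matrix.
#' @param hvg integer vector of gene (column) indices to keep.
#' @return An object of class `processed_expression`: list with `X` (the
#'   scaled spots x n_hvg matrix), `hvg_indices`, and `scaling_stats`
#'   (per-gene `mean` and `sd` used).
#' @export
scale_features <- function(Xn, hvg = seq_len(ncol(Xn))) {
  if (length(hvg) < 1) stop("hvg must be non-empty", call. = FALSE)
  Xs <- Xn[, hvg, drop = FALSE]
  mu <- colMeans(Xs)
  sdev <- apply(Xs, 2, stats::sd)
  sd_safe <- ifelse(sdev > 0, sdev, 1)   # constant columns -> all zero
  X <- sweep(sweep(Xs, 2, mu, "-"), 2, sd_safe, "/")
  structure(
    list(X = X, hvg_indices = as.integer(hvg),
         scaling_stats = list(mean = mu, sd = sdev)),
    class = "processed_expression"
  )
}

#' Full preprocessing pipeline
#'
#' [normalize_log()], [select_hvg()] and [scale_features()] in one call:
#' library-size normalization to the median total, log1p, selection of the
#' top `n_hvg` variable genes, and z-scoring.
#'
#' @inheritParams normalize_log
#' @inheritParams select_hvg
#' @param n_hvg number of highly variable genes (default 3000).
#' @return A `processed_expression` object (see [scale_features()]).
#' @export
preprocess <- function(ds, n_hvg = 3000, target_sum = NULL,
                       statistic = c("dispersion", "variance")) {
  Xn <- normalize_log(ds, target_sum = target_sum)
  hvg <- select_hvg(Xn, n_top = n_hvg, statistic = match.arg(statistic))
  scale_features(Xn, hvg)
}

#' @export
print.processed_expression <- function(x, ...) {
  cat(sprintf("<processed_expression> %d spots x %d genes (scaled)\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}
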