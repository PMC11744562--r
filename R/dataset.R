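#' Construct a spatial transcriptomics dataset
#'
#' The universal input container: a spots-by-genes count matrix with per-spot
#' 2-D coordinates and optional ground-truth domain labels. All downstream
#' functions (preprocessing, graph construction, training, evaluation) accept
#' this object.
#'
#' @param counts numeric matrix, spots in rows, genes in columns. Must be
#'   non-negative and finite; a sparse `Matrix` is densified.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y), in arbitrary platform units.
#' @param spot_ids,gene_ids character vectors of unique identifiers; default
#'   to the dimnames of `counts` or generated `spot_i` / `gene_j` names.
#' @param labels optional integer vector of ground-truth domain labels,
#'   one per spot.
#' @return An object of class `spatial_dataset`: a list with elements
#'   `counts`, `coords`, `spot_ids`, `gene_ids`, `labels`.
#' @examples
#' ds <- spatial_dataset(matrix(rpois(12, 5), 4, 3), cbind(1:4, 0))
#' dim(ds$counts)
#' @export
spatial_dataset <- function(counts, coords, spot_ids = NULL, gene_ids = NULL,
                            labels = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  attributes(counts) <- attributes(counts)[c("dim", "dimnames")]
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"

  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts contains NA or non-finite entries", call. = FALSE)
  if (any(counts < 0))
    stop("counts contains negative entries", call. = FALSE)
  if (ncol(coords) != 2L)
    stop("coords must have exactly 2 columns (x, y)", call. = FALSE)
  if (nrow(coords) != nrow(counts))
    stop(sprintf("coords has %d rows but counts has %d spots",
                 nrow(coords), nrow(counts)), call. = FALSE)

  if (is.null(spot_ids)) spot_ids <- rownames(counts)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(counts)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)

  if (length(spot_ids) != nrow(counts))
    stop("spot_ids length does not match number of spots", call. = FALSE)
  if (length(gene_ids) != ncol(counts))
    stop("gene_ids length does not match number of genes", call. = FALSE)
  if (anyDuplicated(spot_ids))
    stop("spot_ids are not unique", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene_ids are not unique", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(counts))
      stop("labels length does not match number of spots", call. = FALSE)
  }

  dimnames(counts) <- list(spot_ids, gene_ids)
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")

  structure(
    list(counts = counts, coords = coords, spot_ids = spot_ids,
         gene_ids = gene_ids, labels = labels),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d spots x %d genes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$labels)) "" else
                sprintf(", %d labelled domains", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$counts)

#' Load a spatial transcriptomics dataset from disk
#'
#' Reads one of the supported on-disk layouts into a validated
#' [spatial_dataset()]. Counts are always returned spots-by-genes regardless
#' of on-disk orientation.
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx_dir`}{a directory with `matrix.mtx` (genes x spots, the
#'     CellRanger convention), `genes.tsv`, `barcodes.tsv` and
#'     `positions.csv` (columns `spot_id,x,y`), plus optional `truth.tsv`
#'     (columns `spot_id,label`).}
#'   \item{`csv`}{a directory with `counts.csv` (spots in rows, header =
#'     gene ids, first column = spot ids) and `positions.csv`; or a single
#'     counts CSV if `coords_path` is given.}
#'   \item{`h5ad`}{not supported in this build (no HDF5 reader); raises an
#'     error describing the limitation.}
#' }
#'
#' @param path file or directory path.
#' @param format one of `"mtx_dir"`, `"csv"`, `"h5ad"`.
#' @param coords_path optional explicit path to the coordinate CSV when
#'   `format = "csv"` and `path` is a single file.
#' @return A [spatial_dataset()].
#' @export
load_dataset <- function(path, format = c("mtx_dir", "csv", "h5ad"),
                         coords_path = NULL) {
  format <- match.arg(format)
  if (format == "h5ad")
    stop("h5ad input is not supported: no HDF5 reader is available to this ",
         "package. Export the matrix to an MTX directory or CSV instead.",
         call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("input path does not exist: %s", path), call. = FALSE)

  if (format == "mtx_dir") {
    need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "positions.csv")
    files <- file.path(path, need)
    missing <- need[!file.exists(files)]
    if (length(missing))
      stop(sprintf("mtx_dir is missing file(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    m <- Matrix::readMM(files[1])          # genes x spots on disk
    genes <- utils::read.delim(files[2], header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    spots <- utils::read.delim(files[3], header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    counts <- t(as.matrix(m))              # -> spots x genes
    pos <- utils::read.csv(files[4], stringsAsFactors = FALSE)
    labels <- NULL
    truth_file <- file.path(path, "truth.tsv")
    if (file.exists(truth_file)) {
      tr <- utils::read.delim(truth_file, stringsAsFactors = FALSE)
      labels <- tr$label[match(spots, tr$spot_id)]
    }
    coords <- reorder_coords(pos, spots, nrow(counts))
    return(spatial_dataset(counts, coords, spot_ids = spots,
                           gene_ids = genes, labels = labels))
  }

  # csv
  if (dir.exists(path)) {
    counts_file <- file.path(path, "counts.csv")
    pos_file <- file.path(path, "positions.csv")
    for (f in c(counts_file, pos_file))
      if (!file.exists(f))
        stop(sprintf("csv directory is missing file: %s", basename(f)),
             call. = FALSE)
  } else {
    counts_file <- path
    pos_file <- coords_path
    if (is.null(pos_file) || !file.exists(pos_file))
      stop("csv format needs a coordinate file: pass coords_path or use a ",
           "directory containing counts.csv and positions.csv", call. = FALSE)
  }
  tab <- utils::read.csv(counts_file, row.names = 1, check.names = FALSE)
  counts <- as.matrix(tab)
  pos <- utils::read.csv(pos_file, stringsAsFactors = FALSE)
  coords <- reorder_coords(pos, rownames(counts), nrow(counts))
  labels <- NULL
  if (dir.exists(path) && file.exists(file.path(path, "truth.tsv"))) {
    tr <- utils::read.delim(file.path(path, "truth.tsv"),
                            stringsAsFactors = FALSE)
    labels <- tr$label[match(rownames(counts), tr$spot_id)]
  }
  spatial_dataset(counts, coords, spot_ids = rownames(counts),
                  gene_ids = colnames(counts), labels = labels)
}

# align a positions table (spot_id, x, y) to the spot order of the matrix
reorder_coords <- function(pos, spot_ids, n_spots) {
  if (nrow(pos) != n_spots)
    stop(sprintf("coordinate file has %d rows but matrix has %d spots",
                 nrow(pos), n_spots), call. = FALSE)
  if (!is.null(spot_ids) && "spot_id" %in% names(pos)) {
    idx <- match(spot_ids, pos$spot_id)
    if (anyNA(idx))
      stop("coordinate file is missing entries for some spots", call. = FALSE)
    pos <- pos[idx, , drop = FALSE]
  }
  xy <- intersect(c("x", "y"), names(pos))
  if (length(xy) == 2) as.matrix(pos[, c("x", "y")])
  else as.matrix(pos[, setdiff(names(pos), "spot_id")[1:2]])
}

#' Write a dataset to disk
#'
#' Writes the MTX-directory or CSV layout that [load_dataset()] reads back,
#' giving exact round-trips for integer counts.
#'
#' @param ds a [spatial_dataset()].
#' @param path output directory (created if needed).
#' @param format `"mtx_dir"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(ds, "spatial_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  pos <- data.frame(spot_id = ds$spot_ids,
                    x = ds$coords[, 1], y = ds$coords[, 2])
  utils::write.csv(pos, file.path(path, "positions.csv"), row.names = FALSE)
  if (!is.null(ds$labels)) {
    utils::write.table(
      data.frame(spot_id = ds$spot_ids, label = ds$labels),
      file.path(path, "truth.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }

  if (format == "mtx_dir") {
    Matrix::writeMM(Matrix::Matrix(t(ds$counts), sparse = TRUE),
                    file.path(path, "matrix.mtx"))
    writeLines(ds$gene_ids, file.path(path, "genes.tsv"))
    writeLines(ds$spot_ids, file.path(path, "barcodes.tsv"))
  } else {
    utils::write.csv(as.data.frame(ds$counts),
                     file.path(path, "counts.csv"), row.names = TRUE)
  }
  invisible(path)
}
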