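#' Save and load model checkpoints
#'
#' Serializes a `stdcl_model` to a single self-describing plain-text
#' checkpoint (a header with dimensions, activation and seed, followed by
#' the two weight matrices at full double precision) and reads it back.
#' Round-trips are exact.
#'
#' @param model a `stdcl_model`.
#' @param path checkpoint file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the restored `stdcl_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "stdcl_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("n_hvg\t%d", nrow(model$W_e)),
    sprintf("d\t%d", model$d),
    sprintf("activation\t%s", model$activation),
    sprintf("rng_seed\t%d", model$rng_seed),
    "W_e"), con)
  utils::write.table(format(model$W_e, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines("W_d", con)
  utils::write.table(format(model$W_d, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:4], "\t")
  vals <- vapply(hdr, `[`, character(1), 2)
  names(vals) <- vapply(hdr, `[`, character(1), 1)
  n_hvg <- as.integer(vals[["n_hvg"]])
  d <- as.integer(vals[["d"]])
  stopifnot(lines[5] == "W_e")
  parse_block <- function(rows)
    do.call(rbind, lapply(rows, function(l) as.numeric(strsplit(l, "\t")[[1]])))
  W_e <- parse_block(lines[6:(5 + n_hvg)])
  stopifnot(lines[6 + n_hvg] == "W_d")
  W_d <- parse_block(lines[(7 + n_hvg):(6 + n_hvg + d)])
  structure(
    list(W_e = W_e, W_d = W_d, d = d,
         activation = vals[["activation"]],
         rng_seed = as.integer(vals[["rng_seed"]])),
    class = "stdcl_model"
  )
}
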