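#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a clustering result into a per-spot tibble
#'
#' @param x an `stdcl_result` from [stdcl_run()].
#' @param ... unused.
#' @return tibble with one row per spot: `spot_id`, `x`, `y`,
#'   `label_raw`, `label_refined`.
#' @export
tidy.stdcl_result <- function(x, ...) {
  out <- list(spot_id = x$spot_ids, x = x$coords[, 1], y = x$coords[, 2],
              label_raw = x$labels_raw, label_refined = x$labels_refined)
  tibble::as_tibble(out)
}

#' One-row summary of a clustering result
#'
#' @param x an `stdcl_result`.
#' @param ... unused.
#' @return tibble with `n_spots`, `k`, `n_domains_found`, `dbi`,
#'   `noise_sd_used`, `final_loss`, `seed`.
#' @export
glance.stdcl_result <- function(x, ...) {
  tibble::tibble(
    n_spots = length(x$labels_raw),
    k = x$k,
    n_domains_found = length(unique(x$labels_refined)),
    dbi = x$dbi,
    noise_sd_used = x$noise_sd_used,
    final_loss = utils::tail(x$history$total, 1),
    seed = x$seed)
}

#' Plot spatial domains
#'
#' Spots at their tissue coordinates colored by assigned domain.
#'
#' @param object an `stdcl_result`.
#' @param refined plot refined (default) or raw labels.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stdcl_result <- function(object, refined = TRUE, ...) {
  df <- tidy(object)
  df$domain <- factor(if (refined) df$label_refined else df$label_raw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$domain)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Spatial domains (%s labels)",
                                  if (refined) "refined" else "raw"),
                  colour = "domain") +
    ggplot2::theme_minimal()
}

#' Plot the training loss curves
#'
#' @param result an `stdcl_result` or a loss-history tibble from [train()].
#' @return a ggplot object with one line per loss component.
#' @export
plot_loss_history <- function(result) {
  hist <- if (inherits(result, "stdcl_result")) result$history else result
  long <- do.call(rbind, lapply(
    setdiff(names(hist), "epoch"),
    function(nm) data.frame(epoch = hist$epoch, component = nm,
                            value = hist[[nm]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "loss") +
    ggplot2::theme_minimal()
}

#' Default configuration snapshot
#'
#' Every tunable default in one flat tibble, for inspection and
#' configuration audits.
#'
#' @return two-column tibble (`parameter`, `value`).
#' @export
stdcl_defaults <- function() {
  cfg <- train_config()
  w <- loss_weights()
  tibble::tibble(
    parameter = c("n_hvg", "k1", "k2", "alpha", "latent_dim",
                  "alpha1", "alpha2", "gamma1", "gamma2", "gamma3",
                  "pretrain_epochs", "train_epochs",
                  "pretrain_lr", "train_lr",
                  "n_pca", "denoise_k", "refine_radius",
                  "noise_mean", "noise_sd_run1", "noise_sd_run2",
                  "top_genes"),
    value = c(3000, 3, 3, 0.5, 64,
              w$alpha1, w$alpha2, w$gamma1, w$gamma2, w$gamma3,
              cfg$pretrain_epochs, cfg$train_epochs,
              cfg$pretrain_lr, cfg$train_lr,
              20, 15, 50,
              1, 0.1, 0.2,
              1000))
}
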