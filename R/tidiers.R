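# broom-style accessors and ggplot2 autoplot methods for result objects.

#' Tidy per-gene correlations from a section evaluation
#'
#' @param x A `pcc_result` from [per_sample_pcc()].
#' @param ... Unused.
#' @return Tibble `gene`, `pcc`, `defined`.
#' @export
tidy.pcc_result <- function(x, ...) x$per_gene

#' @rdname tidy.pcc_result
#' @return For `glance()`, a one-row tibble with `mean_pcc`,
#'   `median_pcc`, `n_genes`, `n_undefined`, `n_spots`.
#' @export
glance.pcc_result <- function(x, ...) {
  tibble(mean_pcc = x$mean_pcc, median_pcc = x$median_pcc,
         n_genes = nrow(x$per_gene), n_undefined = x$n_undefined,
         n_spots = x$n_spots)
}

#' Tidy the training loss curve
#'
#' @param x A `scspot_fit` from [train_scspot()].
#' @param ... Unused.
#' @return Tibble `epoch`, `loss`.
#' @export
tidy.scspot_fit <- function(x, ...) x$history

#' @rdname tidy.scspot_fit
#' @export
glance.scspot_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         variant = x$model$config$variant,
         seed = x$model$config$seed)
}

#' Tidy leave-one-section-out results
#'
#' @param x A `scspot_loso` from [run_loso()].
#' @param ... Unused.
#' @return Per-section tibble (`section_id`, `mean_pcc`, `median_pcc`,
#'   `n_undefined`).
#' @export
tidy.scspot_loso <- function(x, ...) x$per_section

#' @rdname tidy.scspot_loso
#' @export
glance.scspot_loso <- function(x, ...) {
  tibble(variant = x$config$variant,
         mean_pcc = mean(x$per_section$mean_pcc),
         median_pcc = mean(x$per_section$median_pcc),
         n_sections = nrow(x$per_section))
}

#' Plot the per-gene PCC distribution of a section
#'
#' @param object A `pcc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcc_result <- function(object, ...) {
  df <- dplyr::filter(object$per_gene, .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pcc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$median_pcc, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "per-gene PCC", y = "genes",
                  title = sprintf("mean %.3f / median %.3f",
                                  object$mean_pcc, object$median_pcc)) +
    ggplot2::theme_minimal()
}

#' Plot a training loss curve
#'
#' @param object A `scspot_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scspot_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training MSE") +
    ggplot2::theme_minimal()
}

#' Plot held-out per-section performance
#'
#' @param object A `scspot_loso`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scspot_loso <- function(object, ...) {
  ggplot2::ggplot(object$per_section,
                  ggplot2::aes(x = .data$section_id, y = .data$mean_pcc)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "held-out mean PCC") +
    ggplot2::theme_minimal()
}

#' Plot a per-spot gene-set score map
#'
#' @param map_tbl Tibble from [geneset_spatial_map()].
#' @param meta Spot table with `spot_id`, `x`, `y`.
#' @return A ggplot.
#' @export
plot_spatial_map <- function(map_tbl, meta) {
  df <- left_join(map_tbl, meta, by = "spot_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -.data$y,
                                   colour = .data$score)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "mean expr") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
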