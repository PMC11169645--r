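#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x An `astnet_fit`.
#' @param ... Unused.
#' @return Long tibble with `epoch`, `loss` (component name) and `value`.
#' @export
tidy.astnet_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "loss",
                      values_to = "value")
}

#' One-row summary of a fitted model
#'
#' @param x An `astnet_fit`.
#' @param ... Unused.
#' @return Tibble with the variant, epochs run and final loss components.
#' @export
glance.astnet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    variant = x$model$variant,
    n_epochs = nrow(x$history),
    total_loss = last$total_loss,
    cross_entropy = last$cross_entropy,
    graph_loss = last$graph_loss,
    n_parameters = sum(vapply(x$model$params, length, integer(1)))
  )
}

#' Tidy group-difference maps into a long edge table
#'
#' @param x An `fc_diff` from [group_difference_maps()].
#' @param ... Unused.
#' @return Tibble with `segment` (integer, or `NA` for the static
#'   comparator), `roi_i`, `roi_j` (`i < j`), `p_value` and `significant`.
#' @export
tidy.fc_diff <- function(x, ...) {
  n <- x$n_rois
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  one <- function(map, seg) {
    tibble::tibble(
      segment = seg,
      roi_i = ij[, "row"], roi_j = ij[, "col"],
      p_value = map$p_values[ij],
      significant = map$p_values[ij] <= x$alpha
    )
  }
  dplyr::bind_rows(
    purrr::map2(x$maps, seq_along(x$maps),
                function(m, t) one(m, t)),
    one(x$static, NA_integer_)
  )
}

#' Plot training loss curves
#'
#' @param object An `astnet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.astnet_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = sprintf("%s training history",
                                  object$model$variant)) +
    ggplot2::theme_minimal()
}

#' Plot binarised group-difference maps
#'
#' One tile panel per window (plus the static comparator); significant
#' edges (`p <= alpha`) are the dark tiles.
#'
#' @param object An `fc_diff`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fc_diff <- function(object, ...) {
  td <- tidy(object)
  td$panel <- ifelse(is.na(td$segment), "static",
                     paste0("F", td$segment))
  td$panel <- factor(td$panel,
                     levels = c(paste0("F", seq_len(object$n_windows)),
                                "static"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                   fill = .data$significant)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#ffd92f",
                                          `TRUE` = "#1b7837")) +
    ggplot2::labs(x = "ROI", y = "ROI",
                  fill = sprintf("p <= %.2f", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a window-size sweep
#'
#' @param object An `astnet_sweep` from [window_sweep()].
#' @param ... Unused.
#' @return A ggplot of accuracy against window length.
#' @export
autoplot.astnet_sweep <- function(object, ...) {
  d <- dplyr::filter(object, !.data$skipped)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$window_length, y = .data$acc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "window length (timepoints)", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
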