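# Plot methods --------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.ssn_partition <- function(object, ...) {
  df <- object$clusters
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster_id),
                                   y = .data$size,
                                   fill = .data$convergence_ratio)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "convergence\nratio") +
    ggplot2::labs(x = "cluster (ranked by size)", y = "members",
                  title = "SSN cluster sizes",
                  subtitle = paste(length(object$singletons),
                                   "singletons not shown")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.plm_encoder <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Masked-LM pre-training loss", y = "cross-entropy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.plm_classifier <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$epoch, .data$train_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Task-training loss", y = "cross-entropy") +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2-D projection
#'
#' @param proj A [project_2d()] tibble.
#' @param labels Optional tibble (`id`, `cluster_id`) to colour points by.
#' @return A ggplot object.
#' @export
plot_projection <- function(proj, labels = NULL) {
  df <- proj
  if (!is.null(labels)) {
    df <- dplyr::left_join(proj, labels, by = "id")
    df$cluster <- factor(df$cluster_id)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = "2-D projection of sequence embeddings") +
    ggplot2::theme_minimal()
}
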