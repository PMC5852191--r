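#' Scatter plot of a 2-D embedding, one color per family
#'
#' Reproduces the standard presentation of these analyses: each sequence a
#' dot on the plane, colored by family label.  Axis scales are data-driven
#' and carry no physical meaning, so the theme drops axis units by default.
#'
#' @param emb An `embedding2d`.
#' @param title Optional plot title.
#' @param point_size Dot size.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
plot_embedding <- function(emb, title = NULL, point_size = 1.5) {
  stopifnot(is.data.frame(emb))
  df <- as.data.frame(emb)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = point_size, alpha = 0.8) +
    ggplot2::labs(title = title, x = NULL, y = NULL, colour = "family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
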