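# Plotting helpers (ggplot2 is suggested, not required).

#' Plot an attention heatmap over an image
#'
#' @param image `(S, S)` gray-value matrix.
#' @param map `(S, S)` heatmap from [attention_heatmap()].
#' @param title Optional title (e.g. the emitted word).
#' @return A ggplot object.
#' @export
plot_attention <- function(image, map, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_attention requires ggplot2")
  }
  S <- nrow(image)
  df <- data.frame(x = rep(seq_len(S), each = S),
                   y = rep(rev(seq_len(S)), times = S),
                   gray = as.vector(image),
                   att = as.vector(map))
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_raster(ggplot2::aes(alpha = att), fill = "red") +
    ggplot2::scale_alpha(range = c(0, 0.6), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::ggtitle(title)
}

utils::globalVariables(c("x", "y", "gray", "att"))
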