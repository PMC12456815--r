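# Convenience heatmaps for contact and smoothed matrices.

#' Heatmap of a contact or smoothed matrix
#'
#' ggplot2 raster heatmap with optional log1p transform (useful for raw
#' counts) and optional overlay of a domain partition's boundaries.
#'
#' @param M Symmetric numeric matrix.
#' @param log1p Transform values with `log1p()` before mapping to fill.
#' @param partition Optional [tad_partition] whose domain boundaries are
#'   drawn as boxes; defaults to `true_partition(M)` when present.
#' @param cap Optional upper cap applied to the (transformed) values.
#' @return A ggplot object.
#' @export
plot_contact_matrix <- function(M, log1p = FALSE, partition = true_partition(M),
                                cap = NULL) {
  stopifnot(is.matrix(M))
  N <- nrow(M)
  vals <- if (log1p) log1p(M) else M
  if (!is.null(cap)) vals <- pmin(vals, cap)
  dat <- tibble::tibble(
    i = rep(seq_len(N), times = N),
    j = rep(seq_len(N), each = N),
    value = as.vector(vals)
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$j, y = .data$i,
                                         fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3",
                                 name = if (log1p) "log1p" else NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "bin", y = "bin") +
    ggplot2::theme_minimal()
  if (!is.null(partition)) {
    dom <- partition[partition$kind == "domain", ]
    p <- p + ggplot2::annotate(
      "rect", xmin = dom$start + 0.5, xmax = dom$end + 0.5,
      ymin = dom$start + 0.5, ymax = dom$end + 0.5,
      fill = NA, colour = "blue", linewidth = 0.3
    )
  }
  p
}
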