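#' Plot a world snapshot
#'
#' Scatter of cell positions in their class colors (blue monolayer,
#' periwinkle daughters, green edge cohort, light-green edge daughters, red
#' crossed cells, orange crossed daughters), with ligand molecules as small
#' yellow points and the scratch line dashed.
#'
#' @param x A `scratch_world`.
#' @param show_ligands Draw ligand molecules (default TRUE).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.scratch_world <- function(x, show_ligands = TRUE, ...) {
  pal <- c("blue3", "slateblue1", "green4", "palegreen2", "red2", "orange")
  graphics::plot(NA, xlim = c(x$min_x - 0.5, x$max_x + 0.5),
                 ylim = c(x$min_y - 0.5, x$max_y + 0.5),
                 xlab = "x (patches)", ylab = "y (patches)", asp = 1,
                 main = sprintf("tick %d (%.1f h)", x$tick, x$tick / 60), ...)
  if (show_ligands && length(x$ligands$x) > 0) {
    graphics::points(x$ligands$x, x$ligands$y, pch = ".", col = "gold2")
  }
  if (.n_cells(x) > 0) {
    graphics::points(x$cells$x, x$cells$y, pch = 16, cex = 0.5,
                     col = pal[x$cells$color])
  }
  graphics::abline(v = x$params$scratch_line - 0.5, lty = 2, col = "grey40")
  invisible(x)
}
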