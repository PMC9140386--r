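#' Plot delta SNP index against position with the confidence band
#'
#' One file per chromosome: the window-mean delta SNP index curve (at window
#' midpoints) with the simulated null confidence band. The causal region
#' shows as a peak rising above the band.
#'
#' @param windows Per-window table with columns `chrom`, `start`, `end`,
#'   `mean_delta`, `lower`, `upper` (as in `map_dataset()$windows`).
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix (default `"mapping"`).
#' @return Character vector of files written (PDF, one per chromosome);
#'   empty, with a warning, when `windows` has no plottable rows.
#' @export
plot_mapping <- function(windows, out_dir, prefix = "mapping") {
  if (is.null(windows) || nrow(windows) == 0 || all(is.na(windows$mean_delta))) {
    warning("nothing to plot: empty window table")
    return(character(0))
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", out_dir)

  files <- character(0)
  for (chr in unique(windows$chrom)) {
    w <- windows[windows$chrom == chr & !is.na(windows$mean_delta), , drop = FALSE]
    if (nrow(w) == 0) next
    w$mid <- (w$start + w$end) / 2
    p <- ggplot2::ggplot(w, ggplot2::aes(x = .data$mid / 1e6)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           fill = "darkgreen", alpha = 0.2) +
      ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "darkgreen",
                         linewidth = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "darkgreen",
                         linewidth = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean_delta), colour = "firebrick") +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = sprintf("%s position (Mb)", chr),
                    y = expression(Delta * "(SNP index)"),
                    title = sprintf("Window-mean %s with 95%% null band", chr)) +
      ggplot2::coord_cartesian(ylim = c(-1, 1)) +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, sprintf("%s_%s.pdf", prefix, chr))
    grDevices::pdf(f, width = 8, height = 4)
    print(p)
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}
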