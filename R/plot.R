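#' Render the fusion plot
#'
#' Per-site mismatch rate along the reference paralog: discriminating sites
#' in red, ambiguous sites in grey; dashed horizontal lines at the background
#' (lower) and, when defined, the foreground (upper) level; the fitted
#' sigmoid overlaid when converged; and a triangle marking the crossover
#' interval for a fused call. The step pattern of the red points is the
#' visual signature of the chimera.
#'
#' Every plot also writes a machine-readable sidecar
#' (`<path>.plotdata.json`) with the exact plotted coordinates, the dashed
#' line levels and the triangle interval, so rendering is testable without
#' image comparison.
#'
#' @param profile a [build_mismatch_profile()] result.
#' @param call a [call_fusion()] result.
#' @param path output image path (`.png` or `.svg` decide the device).
#' @param width,height device size in inches.
#' @param show_fit overlay the fitted sigmoid?
#' @param show_triangle mark the crossover interval?
#' @param sample_id title annotation.
#' @return `path`, invisibly. Side effects: the image and its sidecar JSON.
#' @export
render_fusion_plot <- function(profile, call, path, width = 8, height = 4.5,
                               show_fit = TRUE, show_triangle = TRUE,
                               sample_id = "sample") {
  stopifnot(nrow(profile) > 0)
  fmt <- tolower(tools::file_ext(path))
  if (!fmt %in% c("png", "svg")) stop("unsupported plot format: ", fmt)
  pts <- profile[profile$used & !is.na(profile$rate), , drop = FALSE]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = position, y = rate,
                                         colour = kind)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(discriminating = "#d62728", ambiguous = "grey55")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("position on reference gene %s (bp)",
                  attr(profile, "reference_gene")),
      y = "mismatch rate",
      title = sprintf("%s - %s", sample_id,
                      if (call$status == "fused")
                        sprintf("fused (%s)", call$region_label)
                      else "no fusion observed")) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.title = ggplot2::element_blank())
  lines <- c(background = call$background)
  if (!is.na(call$foreground)) lines <- c(lines, foreground = call$foreground)
  p <- p + ggplot2::geom_hline(yintercept = unname(lines), linetype = "dashed",
                               colour = "grey30")
  fit <- call$fit
  curve_df <- NULL
  if (show_fit && fit$converged && !fit$degenerate) {
    xx <- seq(min(pts$position), max(pts$position), length.out = 400)
    yy <- fit$asym_right + (fit$asym_left - fit$asym_right) /
      (1 + exp(fit$slope * (xx - fit$inflection)))
    curve_df <- data.frame(position = xx, rate = yy)
    p <- p + ggplot2::geom_line(data = curve_df, colour = "#1f77b4",
                                inherit.aes = FALSE,
                                ggplot2::aes(x = position, y = rate))
  }
  triangle <- NULL
  if (show_triangle && call$status == "fused") {
    triangle <- unname(call$crossover_interval)
    tri_df <- data.frame(position = mean(triangle), rate = 1.02)
    p <- p + ggplot2::annotate("segment", x = triangle[1], xend = triangle[2],
                               y = 1.02, yend = 1.02, colour = "#e377c2",
                               linewidth = 2) +
      ggplot2::geom_point(data = tri_df, inherit.aes = FALSE,
                          ggplot2::aes(x = position, y = rate),
                          shape = 25, fill = "#e377c2", colour = "#e377c2",
                          size = 3)
  }
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  sidecar <- list(
    sample_id = sample_id, status = call$status,
    reference_gene = attr(profile, "reference_gene"),
    points = pts[, c("position", "kind", "n", "m", "rate")],
    dashed_lines = as.list(lines),
    triangle = triangle,
    fit = if (fit$converged) fit[c("asym_left", "asym_right", "slope",
                                   "inflection", "amplitude")] else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".plotdata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
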