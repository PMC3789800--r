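#' Plot sliding-window marker density along chromosomes
#'
#' Shaded density profiles (loci per window) along each chromosome, one
#' facet per chromosome — the standard way to show where a marker map is
#' dense (typically distal, gene-rich regions) and sparse (pericentromeric
#' regions).
#'
#' @param windows Window tibble from [window_density()] or a
#'   `wgmm_density_summary`.
#' @return A ggplot object.
#' @export
plot_marker_density <- function(windows) {
  if (inherits(windows, "wgmm_density_summary")) windows <- windows$windows
  ggplot2::ggplot(windows, ggplot2::aes(
    x = (.data$window_start + .data$window_end) / 2 / 1e6, y = .data$n_loci)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Marker loci per window") +
    ggplot2::theme_minimal()
}

#' Genetic-versus-physical dotplot
#'
#' Plots marker cM positions against physical bp positions, faceted by
#' (map chromosome, physical chromosome). Inversions appear as
#' negative-slope blocks, translocations as points in off-diagonal facets.
#' Detected rearrangement spans can be overlaid.
#'
#' @param dotpoints Tibble from [build_dotpoints()].
#' @param rearrangements Optional call tibble from [detect_inversions()] /
#'   [detect_translocations()]; highlighted as shaded rectangles.
#' @return A ggplot object.
#' @export
plot_dotplot <- function(dotpoints, rearrangements = NULL) {
  p <- ggplot2::ggplot(dotpoints, ggplot2::aes(x = .data$cM, y = .data$bp / 1e6)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.7) +
    ggplot2::facet_grid(phys_chrom ~ map_chrom, scales = "free") +
    ggplot2::labs(x = "Genetic position (cM)", y = "Physical position (Mb)") +
    ggplot2::theme_minimal()
  if (!is.null(rearrangements) && nrow(rearrangements) > 0) {
    p <- p + ggplot2::geom_rect(
      data = rearrangements,
      ggplot2::aes(xmin = pmin(.data$cM_lo, .data$cM_hi),
                   xmax = pmax(.data$cM_lo, .data$cM_hi),
                   ymin = pmin(.data$bp_start, .data$bp_end) / 1e6,
                   ymax = pmax(.data$bp_start, .data$bp_end) / 1e6,
                   fill = .data$kind),
      alpha = 0.2, inherit.aes = FALSE)
  }
  p
}

#' @rdname plot_marker_density
#' @param object A `wgmm_density_summary`.
#' @param ... Unused.
#' @export
autoplot.wgmm_density_summary <- function(object, ...) plot_marker_density(object)

#' @rdname plot_dotplot
#' @param object A `wgmm_report`.
#' @param ... Unused.
#' @export
autoplot.wgmm_report <- function(object, ...) {
  plot_dotplot(object$dotpoints, object$rearrangements)
}
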