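#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   facet_wrap labs theme_minimal geom_pointrange geom_col
#' @export
ggplot2::autoplot

#' Plot a windowed statistic along chromosomes
#'
#' Draws the raw window statistic per chromosome, highlighting flagged
#' windows (peaks/outliers) where present.
#'
#' @param object A `win_stat_tbl` (from [window_fst()], [fd_windows()],
#'   [pbs_windows()], possibly after peak/outlier calling).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.win_stat_tbl <- function(object, ...) {
  stat <- attr(object, "stat") %||% "value"
  d <- as_tibble(object)
  d$value <- d[[stat]]
  p <- ggplot(d, aes(x = .data$start / 1e6, y = .data$value)) +
    geom_line(na.rm = TRUE, linewidth = 0.3) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (Mb)", y = stat) +
    theme_minimal()
  if ("flag" %in% names(d) && any(d$flag, na.rm = TRUE)) {
    p <- p + geom_point(data = d[which(d$flag), ], colour = "firebrick",
                        size = 1, na.rm = TRUE)
  }
  p
}

#' Plot Z:A ratio estimates with confidence intervals
#'
#' @param ratios Tibble binding rows of [z_a_ratio()] /
#'   [harmonic_mean_ne_ratio()] results, optionally with a `species` column.
#' @return A ggplot object with a dashed reference line at 3/4.
#' @export
plot_za_ratios <- function(ratios) {
  d <- as_tibble(ratios)
  if (!"species" %in% names(d)) d$species <- "simulated"
  ggplot(d, aes(x = .data$method, y = .data$ratio, colour = .data$species)) +
    geom_pointrange(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                    position = ggplot2::position_dodge(width = 0.4),
                    na.rm = TRUE) +
    geom_hline(yintercept = 0.75, linetype = "dashed") +
    labs(x = NULL, y = "Z:A ratio of Ne") +
    theme_minimal()
}

#' Plot fixed-difference densities per functional category
#'
#' @param density_tbl Output of [functional_density()].
#' @return A ggplot object, faceted by chromosome class.
#' @export
plot_functional_density <- function(density_tbl) {
  ggplot(density_tbl,
         aes(x = .data$category, y = .data$density, fill = .data$category)) +
    geom_col(na.rm = TRUE) +
    facet_wrap(~class) +
    labs(x = NULL, y = "fixed differences per callable site") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   legend.position = "none")
}
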