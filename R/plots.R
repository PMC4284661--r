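# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_rect
#'   geom_step facet_wrap labs theme_minimal scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a window track statistic along the scaffolds
#'
#' @param object A `window_track`.
#' @param stat Column to plot (default `"te_bp"`).
#' @param ... Unused.
#' @return A ggplot object (one facet per scaffold, fraction of window on
#'   the y axis for bp statistics).
#' @export
autoplot.window_track <- function(object, stat = "te_bp", ...) {
  df <- as_tibble(object)
  df$value <- df[[stat]]
  if (stat %in% c("te_bp", "exon_bp")) {
    df$value <- df$value / df$effective_len
  }
  ggplot(df, aes(x = .data$start / 1e6, y = .data$value)) +
    geom_step(linewidth = 0.3) +
    facet_wrap(~scaffold, ncol = 1) +
    labs(x = "position (Mb)",
         y = if (stat %in% c("te_bp", "exon_bp")) {
           paste(sub("_bp", "", stat), "fraction")
         } else {
           stat
         }) +
    theme_minimal()
}

#' Plot island calls over the TE density track
#'
#' @param object A `region_partition`.
#' @param track Optional `window_track` to draw the TE density underneath.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_partition <- function(object, track = NULL, ...) {
  isl <- object$islands
  p <- if (!is.null(track)) {
    autoplot(track, stat = "te_bp")
  } else {
    ggplot() + facet_wrap(~scaffold, ncol = 1) + theme_minimal() +
      labs(x = "position (Mb)", y = NULL)
  }
  if (nrow(isl) > 0) {
    p <- p + geom_rect(
      data = isl,
      aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
          ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.3
    )
  }
  p
}

#' Volcano-style plot of enrichment results
#'
#' @param object A `te_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot of log2 odds ratio against -log10 q, one facet per
#'   analysis, significant units highlighted.
#' @export
autoplot.te_enrichment <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(is.finite(.data$odds_ratio), .data$odds_ratio > 0)
  ggplot(df, aes(x = log2(.data$odds_ratio), y = -log10(.data$q_value),
                 colour = .data$significant)) +
    geom_point() +
    facet_wrap(~analysis) +
    labs(x = "log2 odds ratio (island vs LDR)", y = "-log10 q") +
    theme_minimal()
}

#' Plot the CpG o/e versus expression-rank curve
#'
#' @param object A `rank_curve` from [expression_rank_curve()].
#' @param ... Unused.
#' @return A ggplot of per-bin median o/e against expression rank, one line
#'   per compartment.
#' @export
autoplot.rank_curve <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$rank_mid, y = .data$median_oe, colour = .data$region)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "expression rank (0 = least expressed)", y = "median CpG o/e") +
    theme_minimal()
}
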