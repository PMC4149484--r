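# ggplot2 displays for the tabular result objects; the genealogy itself is
# drawn with ape's tree plotting through plot.genealogy().

#' Plot node ages with confidence intervals
#'
#' @param object A `clock_dating` from [date_nodes()].
#' @param ... Unused.
#' @return A ggplot: nodes ordered by age, point estimate with CI bars, in
#'   thousands of years.
#' @method autoplot clock_dating
#' @export
autoplot.clock_dating <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$age_years) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_years / 1000, y = .data$rank)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low / 1000, xmax = .data$ci_high / 1000),
      height = 0.25, colour = "grey50"
    ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_tips), shape = 21,
                        fill = "steelblue") +
    ggplot2::scale_size_continuous(range = c(1.5, 4)) +
    ggplot2::labs(x = "node age (kyr before present)", y = "node (by age)",
                  size = "descendant tips") +
    ggplot2::theme_minimal()
}

#' Plot detected star-like expansions
#'
#' @param object A `star_report` from [detect_stars()].
#' @param ... Unused.
#' @return A ggplot of expansion ages (with CI) against lineage counts,
#'   labelled by assigned name.
#' @method autoplot star_report
#' @export
autoplot.star_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- ifelse(is.na(df$name), paste0("node ", df$node), df$name)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_years / 1000, y = .data$k)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low / 1000, xmax = .data$ci_high / 1000),
      height = 0.2, colour = "grey50"
    ) +
    ggplot2::geom_point(size = 3, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -1) +
    ggplot2::labs(x = "expansion age (kyr before present)",
                  y = "radiating lineages (k)") +
    ggplot2::theme_minimal()
}

#' Plot bait-region coverage along the target
#'
#' @param regions A `bait_regions` from [unique_regions()].
#' @param target_length Optional target length for the x axis.
#' @return A ggplot of retained merged intervals.
#' @export
plot_bait_regions <- function(regions, target_length = NULL) {
  df <- tibble::as_tibble(regions)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = 0, ymax = 1),
      fill = "darkgreen", alpha = 0.6
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = sprintf("%s position (bp)", attr(regions, "target")), y = NULL,
      title = sprintf("%d bait regions, %d bp covered",
                      nrow(df), attr(regions, "covered_bp"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(target_length)) {
    p <- p + ggplot2::xlim(0, target_length)
  }
  p
}

#' Draw a genealogy with branch lengths as substitution counts
#'
#' @param x A [genealogy()].
#' @param show_counts Annotate branches with their counts?
#' @param ... Passed to [ape::plot.phylo()].
#' @importFrom graphics plot
#' @export
plot.genealogy <- function(x, show_counts = TRUE, ...) {
  ape::plot.phylo(x$tree, ...)
  if (show_counts) {
    ape::edgelabels(round(x$tree$edge.length), frame = "none", cex = 0.7)
  }
  invisible(x)
}
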