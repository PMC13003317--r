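#' Plot simulation true-positive rates
#'
#' Two-stage true-positive rate per setting, bars by clause size L
#' within clause count K, methods side by side, faceted by subject
#' count (rows) and noise level (columns).
#'
#' @param object a [run_grid()] result (`sim_outcomes`).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sim_outcomes <- function(object, ...) {
  sm <- summarize_grid(object, by = c("K", "L", "M", "eps"))
  ggplot2::ggplot(sm, ggplot2::aes(
    x = factor(.data$L), y = .data$tpr_two_stage,
    fill = .data$method, group = interaction(.data$method, .data$K))) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(), colour = "black") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(paste0("M=", .data$M)),
      cols = ggplot2::vars(paste0("eps=", .data$eps))) +
    ggplot2::scale_fill_manual(values = c(cnf = "black", gwas = "white")) +
    ggplot2::labs(x = "phenotypes per clause (L), grouped by clause count (K)",
                  y = "two-stage true-positive rate", fill = "method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Plot a threshold boundary and its simplification
#'
#' Shows the level curve g(S), the pruned points, and the fitted
#' piecewise-linear separating boundary.
#'
#' @param curve a [threshold_curve()].
#' @param segments optional [simplify_boundary()] result to overlay.
#' @return a ggplot object.
#' @export
plot_boundary <- function(curve, segments = NULL) {
  df <- tibble::tibble(S = curve$S, g = curve$g) |> tidyr::drop_na()
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$S, .data$g)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::labs(x = "combined-phenotype count S",
                  y = "minimum co-occurrence count T") +
    ggplot2::theme_bw()
  R <- suppressWarnings(prune_boundary(curve))
  if (nrow(R))
    p <- p + ggplot2::geom_point(data = R, colour = "red", size = 1.6)
  if (!is.null(segments)) {
    seg <- segments$segments |>
      dplyr::mutate(y0 = .data$slope * .data$S_start + .data$intercept,
                    y1 = .data$slope * .data$S_end + .data$intercept)
    p <- p + ggplot2::geom_segment(
      data = seg, ggplot2::aes(x = .data$S_start, xend = .data$S_end,
                               y = .data$y0, yend = .data$y1),
      colour = "blue", inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
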