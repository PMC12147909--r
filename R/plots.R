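# ggplot2 views of the main result types. These render the per-figure
# tables computed elsewhere in the package; all statistics live in the
# analysis functions, not here.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Clone-size distribution plot, weighted by clone size
#'
#' Displays the cell-weighted log10 clone-size histogram from
#' [weighted_size_distribution()], with the hyper-expansion threshold
#' marked. A dominant hyper-expanded tail shows as a separated mode to the
#' right of the threshold.
#'
#' @param rep A `tcr_repertoire`.
#' @param n_bins Number of bins.
#' @param threshold Hyper-expansion threshold to mark (default 0.002).
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(rep, n_bins = 30, threshold = 0.002) {
  d <- weighted_size_distribution(rep, n_bins)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                  y = .data$mass)) +
    ggplot2::geom_col(width = d$upper[1] - d$lower[1], fill = "grey35") +
    ggplot2::geom_vline(xintercept = log10(threshold), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "log10 clone frequency", y = "fraction of cells") +
    ggplot2::theme_minimal()
}

#' @rdname plot_size_distribution
#' @param object A `tcr_repertoire`.
#' @param ... Passed to `plot_size_distribution()`.
#' @method autoplot tcr_repertoire
#' @export
autoplot.tcr_repertoire <- function(object, ...) {
  plot_size_distribution(object, ...)
}

#' Kaplan-Meier curve plot
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  d <- bind_rows(tibble(time = 0, surv = 1),
                 as_tibble(object)[, c("time", "surv")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Shared-clone percentage by clone-size bin
#'
#' @param sharing Output of [sharing_by_size_bin()].
#' @return A ggplot object.
#' @export
plot_sharing_by_size <- function(sharing) {
  d <- sharing[!is.na(sharing$pct_common), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$upper, y = .data$pct_common)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log10 clone frequency (bin end)", y = "% clones shared") +
    ggplot2::theme_minimal()
}

#' Group diversity trajectory plot
#'
#' Median normalized Shannon diversity per group over timepoints with the
#' interquartile range as a ribbon.
#'
#' @param traj Output of [diversity_trajectory()].
#' @return A ggplot object.
#' @export
plot_diversity_trajectory <- function(traj) {
  d <- traj$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint, y = .data$median,
                                  group = .data$group, colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "normalized Shannon diversity") +
    ggplot2::theme_minimal()
}

#' Shared-clone size correlation plot with enrichment coloring
#'
#' Log-log scatter of shared clone sizes with the one-to-one line (random
#' sharing expectation) and the linear fit, points colored by
#' enrichment/depletion call.
#'
#' @param object A `shared_size_cor` from [shared_size_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shared_size_cor
#' @export
autoplot.shared_size_cor <- function(object, ...) {
  d <- object$clones
  p <- ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$freq_a),
                                       y = log10(.data$freq_b),
                                       colour = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log10 frequency (baseline)",
                  y = "log10 frequency (paired)", colour = "call") +
    ggplot2::theme_minimal()
  if (is.finite(object$slope)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  colour = "darkorange")
  }
  p
}
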