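#' Plot cumulative response curves
#'
#' Draws the cumulative percentage of the cohort that has responded
#' against the treatment step for one or more cascade results — the
#' scenario panels of the model: x is the treatment number, y the percent
#' responded, with a horizontal guide at the coverage target.
#'
#' @param results A single [run_cascade()] result or a (optionally named)
#'   list of them; names label the curves. All results must be converged.
#' @param file Optional output path (`.png`, `.svg`, `.pdf`, ...); when
#'   given the figure is also written there via [ggplot2::ggsave()].
#' @param width,height Device size in inches when writing a file.
#' @return The ggplot object, invisibly when written to a file.
#' @export
plot_cumulative_response <- function(results, file = NULL,
                                     width = 7, height = 4.5) {
  if (inherits(results, "cascade_result")) results <- list(results)
  if (length(results) == 0) stop_invalid("no cascade results to plot")
  if (!all(vapply(results, inherits, TRUE, "cascade_result"))) {
    stop_invalid("results must be cascade_result objects")
  }
  if (!all(vapply(results, function(r) r$converged, TRUE))) {
    stop_invalid("all results must be converged")
  }
  labels <- names(results) %||% paste("scenario", seq_along(results))
  labels[labels == ""] <- paste("scenario", which(labels == ""))
  d <- do.call(rbind, Map(function(r, lab) {
    cbind(cumulative_response_curve(r), scenario = lab)
  }, results, labels))
  target <- 100 * results[[1]]$config$coverage_target

  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$pct_responded,
                                       colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_x_continuous(breaks = function(lim) {
      seq(0, ceiling(lim[2]), by = max(1, ceiling(lim[2] / 10)))
    }) +
    ggplot2::labs(x = "Treatment step", y = "Patients responded (%)",
                  colour = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
  if (length(results) == 1) p <- p + ggplot2::guides(colour = "none")

  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}
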