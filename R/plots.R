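#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-position base support for a consensus result
#'
#' Points show the top-base count at each base column as a fraction of the
#' maximum coverage, with the calling coverage floor as a dashed line;
#' coverage visibly decays across long homopolymer stretches because reads
#' under-report the run length. Plotting the reverse pass shows the same
#' region with the indel placement mirrored (right-aligned in the forward
#' frame), the convention that makes the decay run left-to-right.
#'
#' @param object A `consensus_result`.
#' @param from,to Optional 1-based base-column range to restrict the plot.
#' @param coverage_fraction The calling coverage floor to draw
#'   (default 0.10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, from = NULL, to = NULL,
                                      coverage_fraction = 0.10, ...) {
  calls <- object$calls[object$calls$kind == "base", ]
  if (!is.null(from)) calls <- calls[calls$ref_index >= from, ]
  if (!is.null(to)) calls <- calls[calls$ref_index <= to, ]
  calls$support <- calls$top_count / object$max_coverage
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$ref_index, y = .data$support)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$top_base), size = 0.8) +
    ggplot2::geom_hline(yintercept = coverage_fraction,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "draft position", y = "top-base coverage / max",
                  colour = "top base",
                  title = sprintf("Per-position base support (%s)",
                                  object$pass_label)) +
    ggplot2::theme_minimal()
}

#' Plot mixture-scan detection limits per mutation
#'
#' One point per mutation at its minimum detected variant-read fraction,
#' grouped by mutation class.
#'
#' @param object A `mixture_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixture_scan
#' @export
autoplot.mixture_scan <- function(object, ...) {
  s <- object$summary
  s$min_detected_fraction[is.na(s$min_detected_fraction)] <- Inf
  ggplot2::ggplot(s, ggplot2::aes(x = .data$min_detected_fraction,
                                  y = .data$kind)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kind), size = 3,
                        alpha = 0.8,
                        position = ggplot2::position_jitter(height = 0.1,
                                                            width = 0)) +
    ggplot2::scale_x_continuous(limits = c(0, 100),
                                breaks = seq(0, 100, 20)) +
    ggplot2::labs(x = "minimum variant-read fraction detected (%)",
                  y = NULL,
                  title = "Subclonal variant detection sensitivity") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
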