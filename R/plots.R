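#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot separation dynamics
#'
#' Lines of global and local separation over time.
#'
#' @param object A [separation_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.separation_series <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("d_global", "d_local"),
                            names_to = "measure", values_to = "metres")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$metres,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "separation (m)", colour = NULL)
}

#' Plot a binned rule curve
#'
#' Points with standard-error bars per bin; empty bins are dropped. For
#' `delta_separation` curves a dashed zero line marks the
#' repulsion/attraction boundary; for `alignment` curves the identity rule
#' is drawn.
#'
#' @param object A `rule_curve` (see [attraction_speed_curves()],
#'   [alignment_rule_curve()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rule_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  df <- dplyr::filter(tibble::as_tibble(object), !.data$empty)
  ylab <- switch(kind,
                 delta_separation = "change in neighbour separation (m/interval)",
                 speed = "speed (m/s)",
                 alignment = "heading at t+1 (rad)")
  xlab <- if (kind == "alignment") "neighbourhood heading at t (rad)"
          else "neighbour separation (m)"
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = ylab)
  if (kind == "delta_separation") {
    g <- g + ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  }
  if (kind == "alignment") {
    g <- g + ggplot2::geom_abline(slope = 1, intercept = 0,
                                  linetype = "dashed")
  }
  g
}

#' Plot agent paths
#'
#' Horizontal-plane paths of all agents, coloured by agent.
#'
#' @param object A [as_flock_traj()] trajectory.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flock_traj <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$agent, group = .data$agent)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
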