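# ggplot2 visualisations: pairwise efficiency frontiers, hotspot maps,
# trajectories and ordinations. Thin layers over the tidy outputs.

#' Plot a pairwise (2-D) efficiency frontier
#'
#' Scatter of all frontier entries' outcomes for two sectors, with the
#' non-dominated upper boundary traced.
#'
#' @param object An `msp_frontier`.
#' @param sector_x,sector_y Sector names for the axes (default the first
#'   aquaculture sector and the first existing sector).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msp_frontier <- function(object, sector_x = NULL, sector_y = NULL,
                                  ...) {
  sectors <- attr(object$scaled, "sectors")
  sector_x <- sector_x %||% sectors$sector[!is.na(sectors$option)][1]
  sector_y <- sector_y %||% sectors$sector[is.na(sectors$option)][1]
  e <- object$entries
  df <- tibble::tibble(x = e[[paste0("o_", sector_x)]],
                       y = e[[paste0("o_", sector_y)]])
  h <- upper_hull(df$x, df$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4, colour = "grey40") +
    ggplot2::geom_line(data = tibble::tibble(x = h$x, y = h$y),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = paste0(sector_x, " value (%)"),
                  y = paste0(sector_y, " value (%)"),
                  title = "Pairwise efficiency frontier") +
    ggplot2::theme_minimal()
}

#' Plot a hotspot map
#'
#' Tile map of per-site development frequency across plans.
#'
#' @param object An `msp_hotspots` tibble from [hotspot_map()].
#' @param option One of `"any"`, `"mussel"`, `"finfish"`, `"kelp"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msp_hotspots <- function(object, option = "any", ...) {
  col <- paste0("freq_", match.arg(option, c("any", "mussel", "finfish",
                                             "kelp")))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100),
                                  name = "% of plans") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km, offshore)",
                  title = paste0("Development frequency: ", option)) +
    ggplot2::theme_minimal()
}

#' Plot a conventional-planning trajectory
#'
#' Sector outcomes as development proceeds site by site.
#'
#' @param object An `msp_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msp_trajectory <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$outcome,
                                   colour = .data$sector)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sites developed", y = "sector value (%)",
                  title = paste0(attr(object, "mode"),
                                 " conventional planning")) +
    ggplot2::theme_minimal()
}

#' Plot the seed-plan ordination
#'
#' The 2-D nMDS embedding of plan dissimilarities, coloured by cluster,
#' with seed (representative) plans marked.
#'
#' @param object An `msp_seed_plans`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msp_seed_plans <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_point(data = df[df$is_representative, ],
                        shape = 8, size = 4, stroke = 1.2) +
    ggplot2::labs(x = "nMDS 1", y = "nMDS 2", colour = "cluster",
                  title = sprintf("Plan ordination (stress-1 = %.3f)",
                                  object$stress)) +
    ggplot2::theme_minimal()
}
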