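# autoplot methods: quick diagnostic figures for each result type.

#' Plot a slice of a synthetic landscape
#'
#' Energy heat map over the first two reduced coordinates, the remaining
#' coordinates held at the (lowest-depth) funnel center and `r` at its
#' reference distance. Funnel centers are overlaid.
#'
#' @param object A [funnel_landscape()].
#' @param xlim,ylim Slice extents (defaults span the funnel centers).
#' @param n Grid resolution per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot funnel_landscape
autoplot.funnel_landscape <- function(object, xlim = NULL, ylim = NULL,
                                      n = 101, ...) {
  centers <- do.call(rbind, lapply(object$funnels, `[[`, "center"))
  depths <- vapply(object$funnels, `[[`, 0, "depth")
  anchor <- object$funnels[[which.min(depths)]]
  pad <- 2.5 / sqrt(min(anchor$lambda))
  xlim <- xlim %||% (range(centers[, 1]) + c(-pad, pad))
  ylim <- ylim %||% (range(centers[, 2]) + c(-pad, pad))
  grid <- tidyr::expand_grid(a = seq(xlim[1], xlim[2], length.out = n),
                             b = seq(ylim[1], ylim[2], length.out = n))
  psi <- conformations(r = anchor$r0, a = grid$a, b = grid$b,
                       y1 = anchor$center[3], y2 = anchor$center[4],
                       y3 = anchor$center[5])
  grid$energy <- energy(object, psi)
  ggplot2::ggplot(grid, ggplot2::aes(.data$a, .data$b, fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = tibble::tibble(a = centers[, 1], b = centers[, 2]),
                        ggplot2::aes(.data$a, .data$b), inherit.aes = FALSE,
                        shape = 4, colour = "white", size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "a", y = "b", fill = "energy",
                  title = "Landscape slice (first two reduced coordinates)") +
    ggplot2::theme_minimal()
}

#' Plot a refinement run
#'
#' Overlaid energy distributions of the input and refined ensembles
#' (empirical CDFs), which directly visualizes the merge-and-filter
#' dominance of the refined energies.
#'
#' @param object An `ssdu_refined` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ssdu_refined
autoplot.ssdu_refined <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(energy = object$input$energy, set = "input"),
    tibble::tibble(energy = object$ensemble$energy, set = "refined"))
  ggplot2::ggplot(df, ggplot2::aes(.data$energy, colour = .data$set)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "energy", y = "empirical CDF",
                  title = "Ensemble energies before and after refinement") +
    ggplot2::theme_minimal()
}

#' Plot an experiment report
#'
#' Before/after counts of quality conformations per tier and replicate.
#'
#' @param object An `ssdu_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot ssdu_report
autoplot.ssdu_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$counts, c("before", "after"),
                            names_to = "stage", values_to = "count")
  df$stage <- factor(df$stage, levels = c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(.data$tier, .data$count, fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~replicate, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "quality tier (or better)", y = "conformations",
                  title = "Quality counts before and after refinement") +
    ggplot2::theme_minimal()
}

#' Plot top-k enrichment counts
#'
#' @param enrichment A [rank_and_enrich()] tibble (optionally row-bound over
#'   a `method` column).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  aes <- if ("method" %in% names(enrichment)) {
    ggplot2::aes(factor(.data$k), .data$count, fill = .data$method)
  } else {
    ggplot2::aes(factor(.data$k), .data$count)
  }
  ggplot2::ggplot(enrichment, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~tier) +
    ggplot2::labs(x = "top k clusters", y = "quality clusters",
                  title = "Quality solutions among top-ranked clusters") +
    ggplot2::theme_minimal()
}
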