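#' Plot per-species ELPD differences
#'
#' Dot-and-interval chart of species-specific ELPD differences (posterior
#' point estimates with +/- 2 standard errors), species ordered by decreasing
#' difference; positive values favor the first model.
#'
#' @param object a [elpd_compare()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bmsom_elpd_comparison <- function(object, ...) {
  d <- object$by_species |>
    dplyr::arrange(dplyr::desc(.data$elpd_diff)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$elpd_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(
      ymin = .data$elpd_diff - 2 * .data$se_diff,
      ymax = .data$elpd_diff + 2 * .data$se_diff), colour = "grey40") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = "species (ordered by ELPD difference)",
                  y = "ELPD difference (+/- 2 SE)") +
    ggplot2::theme_minimal()
}

#' Plot a richness profile along a site ordering
#'
#' Median richness with the credible ribbon, sites ordered by a covariate
#' (typically elevation).
#'
#' @param object a [richness_profile()] tibble.
#' @param sites site table supplying the ordering covariate.
#' @param order_by covariate column in `sites` (default `elev_m`).
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_richness_profile <- function(object, sites, order_by = "elev_m", ...) {
  qcols <- grep("^q[0-9.]+$", names(object), value = TRUE)
  d <- dplyr::left_join(object, sites, by = "site_id")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[order_by]]))
  if (length(qcols) >= 2) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data[[qcols[1]]], ymax = .data[[qcols[length(qcols)]]]),
      fill = "grey70", alpha = 0.5)
  }
  p + ggplot2::geom_line(ggplot2::aes(y = .data$richness_median)) +
    ggplot2::labs(x = order_by, y = "posterior point-scale richness") +
    ggplot2::theme_minimal()
}

#' Plot an occupancy surface for one species
#'
#' Scatter raster of posterior mean occupancy over prediction points.
#'
#' @param object an [occupancy_surface()] tibble.
#' @param sites site table with `x_km`, `y_km`.
#' @param species_id which species to draw.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_occupancy_surface <- function(object, sites, species_id, ...) {
  d <- object |>
    dplyr::filter(.data$species_id == !!species_id) |>
    dplyr::left_join(sites, by = "site_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_km, y = .data$y_km,
                                  colour = .data$psi_mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = "psi") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = species_id, x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot the linearization diagnostic
#'
#' Empirical logit of naive occupancy against the transformed bin midpoints
#' for every candidate scale; the selected scale should look most linear.
#'
#' @param object a [linearization_diagnostic()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bmsom_linearization <- function(object, ...) {
  d <- purrr::map_dfr(object$table$scale_km, function(s) {
    tibble(scale_km = s,
           x = scaled_inverse_logit(object$bins$mid_km, s),
           logit_prop = object$bins$logit_prop)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$logit_prop)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::facet_wrap(~scale_km, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "transformed distance (bin midpoint)",
                  y = "logit naive occupancy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
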