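# ggplot2 views of the analysis objects

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname energy_entropy_profile
#' @param object An `energy_entropy_profile`.
#' @export
autoplot.energy_entropy_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$bins, c("mean_entropy", "mean_code_energy"),
    names_to = "quantity", values_to = "bits")
  long$quantity <- dplyr::recode(long$quantity,
                                 mean_entropy = "conditional entropy H[h|v]",
                                 mean_code_energy = "codeword energy <E[h]>")
  ggplot2::ggplot(long, ggplot2::aes(.data$mean_E_v, .data$bits,
                                     colour = .data$quantity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "stimulus energy E[v] (bits)", y = "bits",
                  colour = NULL,
                  title = sprintf("Energy-entropy profile (%d hidden units)",
                                  object$n_hidden)) +
    ggplot2::theme_minimal()
}

#' @rdname spectrum_sweep
#' @param object A `spectrum_sweep`.
#' @param ... Unused.
#' @export
autoplot.spectrum_sweep <- function(object, ...) {
  ggplot2::ggplot(object$spectra,
                  ggplot2::aes(.data$beta, .data$eigenvalue,
                               group = .data$rank)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_line(data = object$summary,
                       ggplot2::aes(.data$beta, .data$lambda_max),
                       inherit.aes = FALSE, colour = "red") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(beta), y = "FIM eigenvalue",
                  title = "FIM spectrum over inverse temperature") +
    ggplot2::theme_minimal()
}

#' @rdname rank_frequency
#' @param object A `rank_frequency` object.
#' @export
autoplot.rank_frequency <- function(object, ...) {
  tab <- tidy.rank_frequency(object)
  ggplot2::ggplot(tab, ggplot2::aes(.data$rank, .data$frequency)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_abline(slope = -1,
                         intercept = log10(tab$frequency[[1]]),
                         linetype = 2) +
    ggplot2::labs(x = "rank", y = "frequency",
                  title = sprintf("Rank-frequency (slope %.2f; dashed: Zipf)",
                                  attr(object, "slope"))) +
    ggplot2::theme_minimal()
}

#' Plot hidden-unit projective fields in sensitivity order
#'
#' Renders each hidden unit's weight row as an image over the circular patch
#' mask, ordered by the sensitivity ranking from [rank_units()].
#'
#' @param ranking The tibble returned by [rank_units()].
#' @param spec The [patch_spec()] describing the visible-pixel geometry.
#' @param top Number of units to show (default all).
#' @return A ggplot object.
#' @export
plot_projective_fields <- function(ranking, spec, top = nrow(ranking)) {
  stopifnot(inherits(spec, "patch_spec"))
  rows <- head(ranking, top)
  df <- purrr::map_dfr(seq_len(nrow(rows)), function(k) {
    tibble::tibble(
      rank = rows$rank[[k]], unit = rows$unit[[k]],
      dy = spec$offsets[, "dy"], dx = spec$offsets[, "dx"],
      weight = rows$projective_field[[k]]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$dx, -.data$dy,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~rank) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Projective fields by sensitivity rank") +
    ggplot2::theme_void()
}
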