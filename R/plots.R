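#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname tidy.max_asa_grid
#' @method glance max_asa_grid
#' @export
glance.max_asa_grid <- function(x, ...) {
  i <- which.max(x$max_asa)
  tibble(
    aa = attr(x, "aa") %||% NA_character_,
    step = attr(x, "step") %||% NA_real_,
    n_bins = nrow(x),
    max_asa = x$max_asa[i],
    argmax_phi = x$phi[i],
    argmax_psi = x$psi[i]
  )
}

#' Tidy and summarise maximum-ASA grids
#'
#' `tidy()` returns the per-bin records as a plain tibble (with the amino
#' acid attached as a column); `glance()` returns a one-row summary with
#' the global maximum and its location.
#'
#' @param x A `max_asa_grid`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy max_asa_grid
#' @export
tidy.max_asa_grid <- function(x, ...) {
  out <- as_tibble(x)
  out$aa <- attr(x, "aa") %||% NA_character_
  out
}

#' Ramachandran heat map of a maximum-ASA grid
#'
#' @param object A `max_asa_grid` (from [scan_max_asa()] or
#'   [empirical_max_grid()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot max_asa_grid
#' @export
autoplot.max_asa_grid <- function(object, ...) {
  bw <- attr(object, "bin_width") %||% 5
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi + bw / 2,
                                   y = .data$psi + bw / 2,
                                   fill = .data$max_asa)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression("max ASA (Å"^2 * ")")) +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-180, 180), expand = FALSE) +
    ggplot2::labs(x = expression(phi), y = expression(psi),
                  title = paste0("Maximum ASA, ",
                                 attr(object, "aa") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a Ramachandran region
#'
#' @param object A `rama_region` (see [define_region()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rama_region
#' @export
autoplot.rama_region <- function(object, ...) {
  bw <- attr(object, "bin_width")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$phi_bin + bw / 2,
                               y = .data$psi_bin + bw / 2)) +
    ggplot2::geom_tile(fill = "steelblue") +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-180, 180), expand = FALSE) +
    ggplot2::labs(x = expression(phi), y = expression(psi),
                  title = paste(attr(object, "kind"), "region")) +
    ggplot2::theme_minimal()
}

#' Plot RSA exceedance frequencies
#'
#' Bar chart of the per-amino-acid fraction of residues with RSA above 1
#' under each normalization scale.
#'
#' @param report Output of [rsa_exceedance()].
#' @return A ggplot object.
#' @export
plot_exceedance <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$aa, y = .data$frac_gt1,
                                       fill = .data$scale)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "amino acid", y = "fraction RSA > 1", fill = "scale") +
    ggplot2::theme_minimal()
}
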