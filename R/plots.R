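# ggplot2 autoplot methods for the package's result types.

#' Plot the convergence trail of a fluctuation-matching fit
#'
#' @param object an `fm_fit`.
#' @param ... unused.
#' @return a ggplot: |D| (mean variance mismatch) per iteration, log scale.
#' @method autoplot fm_fit
#' @export
autoplot.fm_fit <- function(object, ...) {
  df <- object$trail
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = abs(.data$D))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration",
                  y = expression("|D| = |" * sigma[target]^2 - sigma[model]^2 * "|  (nm"^2 * ")"),
                  title = "Fluctuation-matching convergence")
}

#' Plot a stress-strain curve with its linear fit
#'
#' @param object a `stress_strain_result`.
#' @param ... unused.
#' @return a ggplot of stress (GPa) against axial strain with the fitted
#'   line whose slope is the Young's modulus.
#' @method autoplot stress_strain_result
#' @export
autoplot.stress_strain_result <- function(object, ...) {
  df <- object$conditions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, y = .data$stress_gpa)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey50", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(epsilon[zz]), y = expression(sigma[zz] ~ "(GPa)"),
                  title = sprintf("E_a = %.3g +/- %.2g GPa",
                                  object$E_a, object$E_a_se))
}

#' Plot a radial density profile
#'
#' @param object a `radial_profile` from [radial_density()].
#' @param ... unused.
#' @return a ggplot of bulk-normalized density against radial distance; the
#'   bulk level 1 is marked.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$r, y = .data$density)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from axis (nm)",
                  y = "density (bulk = 1)", title = "Radial density profile")
}

#' Plot a lattice assembly as an axial-view scatter
#'
#' @param object a `lattice_assembly`.
#' @param ... unused.
#' @return a ggplot of sites projected on the plane normal to the axis,
#'   colored by protofilament.
#' @method autoplot lattice_assembly
#' @export
autoplot.lattice_assembly <- function(object, ...) {
  ggplot2::ggplot(object$sites,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = factor(.data$pf_index))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", color = "protofilament",
                  title = "Lattice assembly, axial view")
}
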