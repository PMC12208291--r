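# broom-style tidiers for the package's fitted objects.

#' Tidy the iteration trail of a fluctuation-matching fit
#'
#' @param x an `fm_fit` from [iterate_to_convergence()].
#' @param ... unused.
#' @return tibble with one row per iteration: `iteration`, `D` (mean
#'   variance mismatch, nm^2), `k_mean`, `n_springs`.
#' @method tidy fm_fit
#' @export
tidy.fm_fit <- function(x, ...) x$trail

#' One-row summary of a fluctuation-matching fit
#'
#' @inheritParams tidy.fm_fit
#' @return tibble: `iterations`, `D_final` (nm^2), `k_mean_final`,
#'   `converged`.
#' @method glance fm_fit
#' @export
glance.fm_fit <- function(x, ...) {
  tibble(iterations = nrow(x$trail),
         D_final = if (nrow(x$trail)) tail(x$trail$D, 1) else NA_real_,
         k_mean_final = mean(x$springs$k),
         converged = x$converged)
}

#' Per-condition table of a stress-strain fit
#'
#' @param x a `stress_strain_result` from [stress_strain_curve()].
#' @param ... unused.
#' @return the per-condition tibble (`run`, `strain`, `stress_gpa`, ...).
#' @method tidy stress_strain_result
#' @export
tidy.stress_strain_result <- function(x, ...) x$conditions

#' One-row summary of a stress-strain fit
#'
#' @inheritParams tidy.stress_strain_result
#' @return tibble: `E_a` (GPa), `E_a_se`, `r_squared`, `n_conditions`.
#' @method glance stress_strain_result
#' @export
glance.stress_strain_result <- function(x, ...) {
  tibble(E_a = x$E_a, E_a_se = x$E_a_se,
         r_squared = summary(x$fit)$r.squared,
         n_conditions = nrow(x$conditions))
}

#' Per-measurement table of a bending-rigidity result
#'
#' @param x a `bend_result` from [rigidity_from_bend()].
#' @param ... unused.
#' @return the measurement tibble with per-row `EI` (pN um^2).
#' @method tidy bend_result
#' @export
tidy.bend_result <- function(x, ...) x$measurements

#' One-row summary of a bending-rigidity result
#'
#' @inheritParams tidy.bend_result
#' @return tibble: `EI` (pN um^2), `EI_sd`, `n`, and `rate_agreement` when
#'   rates were supplied.
#' @method glance bend_result
#' @export
glance.bend_result <- function(x, ...) {
  tibble(EI = x$EI, EI_sd = x$EI_sd, n = nrow(x$measurements),
         rate_agreement = x$rate_agreement %||% NA_real_)
}
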