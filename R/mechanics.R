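# Mechanical inference: cross-section geometry from radial distributions,
# Young's modulus from axial stress-strain under periodic compression, and
# flexural rigidity from tip-load bending.

#' Hollow-cylinder cross-section geometry
#'
#' @param r_i,r_o inner and outer radii, nm (`0 < r_i < r_o`).
#' @return object of class `cylinder_geometry`: one-row tibble with `r_i`,
#'   `r_o`, the cross-sectional area `A_z = pi (r_o^2 - r_i^2)` (nm^2) and
#'   the second moment of area `I = pi/4 (r_o^4 - r_i^4)` (nm^4).
#' @examples
#' cylinder_geometry(8.4, 12.5)
#' @export
cylinder_geometry <- function(r_i, r_o) {
  if (!(r_i > 0 && r_i < r_o)) abort("need 0 < r_i < r_o")
  out <- tibble(r_i = r_i, r_o = r_o,
                A_z = pi * (r_o^2 - r_i^2),
                I = pi / 4 * (r_o^4 - r_i^4))
  class(out) <- c("cylinder_geometry", class(out))
  out
}

#' Infer cross-section geometry from radial distances
#'
#' Estimates the inner and outer wall radii of a hollow filament from the
#' distribution of site distances to the filament axis: the histogram is
#' smoothed with a Gaussian kernel (bandwidth two bin widths) and the two
#' inflection points — maximum positive slope on the rising flank and
#' maximum negative slope on the falling flank — are taken as `r_i` and
#' `r_o`. Area and second moment follow from the closed forms.
#'
#' @param radial_distances numeric vector of distances to the axis, nm
#'   (>= 1000 samples spanning an annulus).
#' @param bins histogram bin count (default 60).
#' @return a [cylinder_geometry()] with extra columns `bin_width` (nm) and
#'   the attribute `profile` (smoothed histogram tibble).
#' @examples
#' cl <- make_cylinder_cloud(8.4, 12.5, 50, 2e4, seed = 1)
#' infer_cross_section(cl$r)
#' @export
infer_cross_section <- function(radial_distances, bins = 60L) {
  r <- radial_distances[is.finite(radial_distances)]
  if (length(r) < 1000) abort("need >= 1000 radial samples")
  # bin from the axis out past the data so both annulus walls are interior
  breaks <- seq(0, max(r) * 1.05, length.out = bins + 1)
  counts <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  bw <- mids[2] - mids[1]
  # Gaussian smoothing, bandwidth = 2 bins
  m <- length(mids)
  w <- outer(seq_len(m), seq_len(m), function(a, b) exp(-((a - b)^2) / (2 * 2^2)))
  dens <- as.numeric(w %*% counts) / rowSums(w)
  slope <- c(NA, diff(dens)) / bw

  i_rise <- which.max(slope)
  i_fall <- which.min(slope)
  if (length(i_rise) == 0 || length(i_fall) == 0 || i_rise >= i_fall) {
    abort("radial distribution is not annular: no rising flank before a falling flank")
  }
  r_i <- mids[i_rise]
  r_o <- mids[i_fall]
  # guard against non-annular (filled) distributions: the region inside the
  # inner wall must be essentially empty
  inner <- dens[mids < r_i - 2 * bw]
  if (length(inner) && mean(inner) > 0.1 * max(dens)) {
    abort("radial distribution is not annular: substantial density inside the inferred inner radius")
  }
  if (r_i >= r_o) abort("inferred radii are inverted; distribution too narrow for the bin width")
  geom <- cylinder_geometry(r_i, r_o)
  geom$bin_width <- bw
  attr(geom, "profile") <- tibble(r = mids, density = dens, slope = slope)
  geom
}

#' Axial stress-strain curve and Young's modulus
#'
#' For each pressure condition the axial stress is
#' `sigma_zz = (P_zz - P_n) * <L_x L_y> / A_z` (pressures in bar, box
#' lengths in nm, reported in GPa) and the strain is
#' `eps_zz = (<L_z> - L_z_eq) / L_z_eq`, where `L_z_eq` is the mean axial
#' box length of the reference run. The axial Young's modulus `E_a` is the
#' least-squares slope of stress against strain, assuming an elastic regime.
#'
#' @param box_data long tibble of per-frame box records with columns `run`
#'   (condition id), `L_x`, `L_y`, `L_z` (nm), `P_zz` and `P_n` (bar,
#'   constant within a run).
#' @param geometry a [cylinder_geometry()] supplying `A_z`.
#' @param reference `run` value of the unloaded reference condition defining
#'   `L_z_eq`.
#' @param block optional number of blocks for block-averaged standard errors
#'   of the per-condition stress and strain.
#' @return object of class `stress_strain_result`: list with `conditions`
#'   (per-run tibble: `run`, `strain`, `stress_gpa`, errors when blocked),
#'   `E_a` (GPa), `E_a_se`, `L_z_eq` and the underlying `fit` (an `lm`).
#' @examples
#' runs <- make_box_runs(E_a = 0.64, geometry = cylinder_geometry(8.4, 12.5),
#'                       pressures = c(-0.25, 0, 0.5, 1, 2), seed = 1)
#' fit <- stress_strain_curve(runs, cylinder_geometry(8.4, 12.5), reference = "ref")
#' glance(fit)
#' @export
stress_strain_curve <- function(box_data, geometry, reference, block = NULL) {
  box_data <- as_tibble(box_data)
  stopifnot(all(c("run", "L_x", "L_y", "L_z", "P_zz", "P_n") %in% names(box_data)))
  if (any(box_data$L_x <= 0 | box_data$L_y <= 0 | box_data$L_z <= 0)) {
    abort("box lengths must be > 0")
  }
  if (!reference %in% box_data$run) abort("reference run not present in box_data")
  A_z <- geometry$A_z

  L_z_eq <- mean(box_data$L_z[box_data$run == reference])

  block_se <- function(x) {
    if (is.null(block)) return(NA_real_)
    per <- length(x) %/% block
    if (per < 1) return(NA_real_)
    bm <- colMeans(matrix(x[seq_len(per * block)], nrow = per))
    stats::sd(bm) / sqrt(block)
  }

  conditions <- box_data |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      P_zz = .data$P_zz[1], P_n = .data$P_n[1],
      strain = (mean(.data$L_z) - L_z_eq) / L_z_eq,
      stress_gpa = bar_to_gpa((.data$P_zz[1] - .data$P_n[1]) *
                                mean(.data$L_x * .data$L_y) / A_z),
      stress_se = bar_to_gpa((.data$P_zz[1] - .data$P_n[1]) / A_z *
                               block_se(.data$L_x * .data$L_y)),
      strain_se = block_se(.data$L_z) / L_z_eq,
      n_frames = dplyr::n(),
      .groups = "drop")

  if (length(unique(conditions$P_zz)) < 3) {
    abort("need >= 3 distinct applied pressures for a stress-strain fit")
  }
  fit <- lm(stress_gpa ~ strain, data = conditions)
  sm <- summary(fit)$coefficients
  structure(
    list(conditions = conditions, E_a = unname(coef(fit)["strain"]),
         E_a_se = unname(sm["strain", "Std. Error"]), L_z_eq = L_z_eq,
         fit = fit),
    class = "stress_strain_result"
  )
}

#' @export
print.stress_strain_result <- function(x, ...) {
  cat("<stress_strain_result> E_a = ", signif(x$E_a, 3), " +/- ",
      signif(x$E_a_se, 2), " GPa over ", nrow(x$conditions),
      " conditions\n", sep = "")
  invisible(x)
}

#' Synthetic periodic-compression box series
#'
#' Fixture generator for stress-strain inference: for each applied axial
#' pressure a run of box frames is produced whose mean axial length follows
#' the elastic response `L_z = L_z_eq * (1 + sigma / E_a)` for the seeded
#' Young's modulus, with optional Gaussian frame noise on all box lengths.
#' The transverse pressure is held at `P_n`.
#'
#' @param E_a true axial Young's modulus, GPa.
#' @param geometry a [cylinder_geometry()].
#' @param pressures applied axial pressures, bar; a reference run at
#'   `P_zz = P_n` labelled `"ref"` is always included.
#' @param P_n transverse (normal) pressure, bar (default 1).
#' @param L_xy,L_z_eq transverse and axial box lengths, nm.
#' @param n_frames_per_run frames per condition.
#' @param noise Gaussian standard deviation of box-length noise, nm.
#' @param seed integer seed.
#' @return long tibble in the [stress_strain_curve()] input layout.
#' @export
make_box_runs <- function(E_a, geometry, pressures, P_n = 1, L_xy = 30,
                          L_z_eq = 90, n_frames_per_run = 50L, noise = 0,
                          seed = 1L) {
  pressures <- unique(c(P_n, pressures))
  with_seed(seed, purrr::map_dfr(pressures, function(p) {
    sigma_gpa <- bar_to_gpa((p - P_n) * L_xy^2 / geometry$A_z)
    lz <- L_z_eq * (1 + sigma_gpa / E_a)
    tibble(
      run = if (p == P_n) "ref" else sprintf("P%+.2fbar", p),
      L_x = L_xy + rnorm(n_frames_per_run, sd = noise),
      L_y = L_xy + rnorm(n_frames_per_run, sd = noise),
      L_z = lz + rnorm(n_frames_per_run, sd = noise),
      P_zz = p, P_n = P_n)
  }))
}

#' Flexural rigidity from tip-load bending
#'
#' Inverts the Euler--Bernoulli clamped-beam relation `w = F L^3 / (3 EI)`
#' for each measurement and aggregates. When a `rate` column is present
#' (e.g. two steering rates), per-rate means and their agreement ratio
#' (max/min) are reported as a cross-rate consistency check.
#'
#' @param measurements tibble with columns `F` (pN), `L` (um), `w` (um,
#'   > 0), and optionally `rate`.
#' @return object of class `bend_result`: list with `measurements` (input
#'   plus per-row `EI`, pN um^2), `EI` (mean), `EI_sd`, and, with rates,
#'   `by_rate` and `rate_agreement`.
#' @examples
#' rigidity_from_bend(tibble::tibble(F = 10, L = 0.2, w = 0.0021164))
#' @export
rigidity_from_bend <- function(measurements) {
  m <- as_tibble(measurements)
  stopifnot(all(c("F", "L", "w") %in% names(m)))
  if (any(m$w <= 0)) abort("deflections w must be > 0")
  if (any(m$F < 0)) abort("forces must be >= 0")
  if (any(m$w / m$L > 0.1)) {
    warn("some deflections exceed 10% of the span; Euler-Bernoulli inversion is approximate there")
  }
  m$EI <- m$F * m$L^3 / (3 * m$w)
  out <- list(measurements = m, EI = mean(m$EI),
              EI_sd = if (nrow(m) > 1) sd(m$EI) else NA_real_)
  if ("rate" %in% names(m)) {
    by_rate <- m |>
      dplyr::group_by(.data$rate) |>
      dplyr::summarise(EI = mean(.data$EI), .groups = "drop")
    out$by_rate <- by_rate
    out$rate_agreement <- max(by_rate$EI) / min(by_rate$EI)
  }
  structure(out, class = "bend_result")
}

#' @export
print.bend_result <- function(x, ...) {
  cat("<bend_result> EI = ", signif(x$EI, 3),
      if (!is.na(x$EI_sd)) paste0(" +/- ", signif(x$EI_sd, 2)),
      " pN um^2 from ", nrow(x$measurements), " measurement(s)\n", sep = "")
  invisible(x)
}
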