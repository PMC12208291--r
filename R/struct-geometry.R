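# Geometric and statistical observables: line-fit angles, separation
# correlations, and cylindrical radial density profiles.

#' Angle between fitted 3D lines (or a line and an axis)
#'
#' Fits a line to each point set by total least squares (first principal
#' direction) and returns the acute angle between the two directions. The
#' second argument may instead be an explicit axis vector. Used for helix
#' orientation angles and protofilament-versus-filament-axis angles.
#'
#' @param points_a matrix or data frame of >= 3 points (columns x, y, z).
#' @param points_b second point set, or a length-3 direction vector.
#' @return acute angle in degrees, in `[0, 90]`.
#' @examples
#' helix <- cbind(0, 0, 1:10)
#' axis_angle(helix, c(1, 0, 0))  # 90
#' @export
axis_angle <- function(points_a, points_b) {
  dir_a <- principal_direction(points_a)
  dir_b <- if (is.numeric(points_b) && is.null(dim(points_b)) &&
               length(points_b) == 3) {
    if (sum(points_b^2) == 0) abort("axis vector must be non-zero")
    points_b
  } else {
    principal_direction(points_b)
  }
  acute_angle_deg(dir_a, dir_b)
}

principal_direction <- function(points) {
  if (is.data.frame(points)) points <- site_xyz(points)
  points <- as.matrix(points)
  if (nrow(points) < 3) abort("need >= 3 points to fit a line")
  ctr <- sweep(points, 2, colMeans(points))
  if (all(abs(ctr) < 1e-12)) abort("degenerate point set: zero variance")
  prcomp(points, center = TRUE)$rotation[, 1]
}

#' Correlation between two separation series
#'
#' Pearson correlation on the raw values plus a normalized mutual
#' information (NMI) score from a 2D histogram with `n_bins` bins per axis.
#' Mutual information is normalized by the arithmetic mean of the two
#' marginal entropies, giving a score in `[0, 1]` that equals 1 for
#' identical non-constant series. A constant marginal has zero entropy; NMI
#' is then 0 by convention (with a message), while Pearson is an error.
#'
#' @param series_a,series_b numeric vectors (equal length,
#'   >= `10 * n_bins`), e.g. interdimer separation series of adjacent
#'   protofilaments.
#' @param n_bins histogram bins per axis (default 20).
#' @return one-row tibble with `pearson` and `nmi`.
#' @examples
#' s <- make_correlated_series(0.5, 2000, seed = 1)
#' dimer_separation_correlation(s$a, s$b)
#' @export
dimer_separation_correlation <- function(series_a, series_b, n_bins = 20L) {
  if (length(series_a) != length(series_b)) abort("series lengths differ")
  if (length(series_a) < 10 * n_bins) {
    abort("series too short for the requested bin count (need >= 10 * n_bins)")
  }
  if (sd(series_a) == 0 || sd(series_b) == 0) {
    abort("Pearson correlation undefined for a constant series")
  }
  pearson <- cor(series_a, series_b)
  tibble(pearson = pearson,
         nmi = normalized_mutual_information(series_a, series_b, n_bins))
}

#' Normalized mutual information of two series
#'
#' @inheritParams dimer_separation_correlation
#' @return NMI in `[0, 1]`; 0 (with a message) when a marginal is constant.
#' @export
normalized_mutual_information <- function(series_a, series_b, n_bins = 20L) {
  br_a <- seq(min(series_a), max(series_a), length.out = n_bins + 1)
  br_b <- seq(min(series_b), max(series_b), length.out = n_bins + 1)
  if (br_a[1] == br_a[n_bins + 1] || br_b[1] == br_b[n_bins + 1]) {
    inform("constant marginal: NMI set to 0 by convention")
    return(0)
  }
  ia <- findInterval(series_a, br_a, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(series_b, br_b, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(ia, levels = seq_len(n_bins)),
                 factor(ib, levels = seq_len(n_bins)))
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h_a <- ent(pa); h_b <- ent(pb); h_ab <- ent(as.numeric(p))
  if (h_a == 0 || h_b == 0) {
    inform("constant marginal: NMI set to 0 by convention")
    return(0)
  }
  mi <- h_a + h_b - h_ab
  max(0, min(1, mi / mean(c(h_a, h_b))))
}

#' Radial density profile about an axis
#'
#' Bins distances of particles (e.g. ions, pooled over frames) from a
#' cylindrical axis into shells, divides by shell volume, and normalizes so
#' the mean density over `bulk_range` is 1. Optionally fits an exponential
#' decay `density = 1 + A exp(-(r - fit_from) / lambda)` beyond a given
#' radius, returning the screening length `lambda`.
#'
#' @param positions matrix or data frame of particle coordinates (nm),
#'   pooled over frames.
#' @param axis list with `point` (on the axis) and `direction`; default the
#'   z-axis through the origin.
#' @param bins number of radial bins (default 50).
#' @param bulk_range length-2 numeric: radial interval treated as bulk;
#'   must lie beyond the assembly's outer radius.
#' @param fit_screening_from radius beyond which to fit the exponential
#'   decay, or `NULL` to skip.
#' @return object of class `radial_profile`: tibble with `r` (bin centers,
#'   nm), `count`, `density` (bulk-normalized), plus attributes `bin_breaks`,
#'   `norm` (bulk density before normalization, counts/nm^3 per unit axial
#'   length) and `screening_length` (nm or NA).
#' @export
radial_density <- function(positions, axis = NULL, bins = 50L, bulk_range,
                           fit_screening_from = NULL) {
  if (is.data.frame(positions)) positions <- site_xyz(positions)
  positions <- as.matrix(positions)
  axis <- axis %||% list(point = c(0, 0, 0), direction = c(0, 0, 1))
  dir <- axis$direction / sqrt(sum(axis$direction^2))
  rel <- sweep(positions, 2, axis$point)
  par <- as.numeric(rel %*% dir)
  perp <- rel - outer(par, dir)
  r <- sqrt(rowSums(perp^2))

  breaks <- seq(0, max(r) * (1 + 1e-9), length.out = bins + 1)
  counts <- tabulate(findInterval(r, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  shell_area <- pi * diff(breaks^2)      # per unit axial length
  dens_raw <- counts / shell_area
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2

  in_bulk <- mids >= bulk_range[1] & mids <= bulk_range[2]
  if (!any(in_bulk) || sum(counts[in_bulk]) == 0) {
    abort("bulk_range contains no particles; cannot normalize")
  }
  bulk <- sum(counts[in_bulk]) / sum(shell_area[in_bulk])
  out <- tibble(r = mids, count = counts, density = dens_raw / bulk)

  lambda <- NA_real_
  if (!is.null(fit_screening_from)) {
    # fit only the contiguous enriched run beyond the surface: stop once the
    # excess decays below 2% of its starting value (noise floor)
    cand <- which(mids >= fit_screening_from)
    y_all <- out$density - 1
    run <- cand[cumall(y_all[cand] > 0.02 * max(0, y_all[cand[1]]))]
    if (length(run) >= 4) {
      df <- tibble(r = mids[run], y = y_all[run])
      fit <- tryCatch(
        nls(y ~ A * exp(-(r - min(df$r)) / lambda), data = df,
            start = list(A = max(df$y), lambda = diff(range(df$r)) / 3)),
        error = function(e) NULL)
      if (!is.null(fit)) lambda <- coef(fit)[["lambda"]]
    }
  }

  attr(out, "bin_breaks") <- breaks
  attr(out, "norm") <- bulk
  attr(out, "screening_length") <- lambda
  class(out) <- c("radial_profile", class(out))
  out
}
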