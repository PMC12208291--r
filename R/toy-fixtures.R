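# Geometric and statistical fixture generators. These provide ground-truth
# inputs for the radius-inference, correlation and lattice analyses.

#' Uniform point cloud in a hollow cylindrical shell
#'
#' Points are drawn uniformly from the annular shell `r_inner <= r <= r_outer`
#' with the axis along z, mimicking the backbone-site distribution of a hollow
#' filament for testing radius inference.
#'
#' @param r_inner,r_outer inner and outer radii, nm; `0 < r_inner < r_outer`.
#' @param length axial extent, nm.
#' @param n_points number of points.
#' @param seed integer seed.
#' @return tibble with columns `x`, `y`, `z` (nm) and the radial distance `r`.
#' @examples
#' cl <- make_cylinder_cloud(8.4, 12.5, 50, 1000, seed = 1)
#' range(cl$r)
#' @export
make_cylinder_cloud <- function(r_inner, r_outer, length, n_points, seed) {
  if (r_inner <= 0 || r_inner >= r_outer) {
    abort("need 0 < r_inner < r_outer")
  }
  with_seed(seed, {
    # uniform in the annulus: density of r proportional to r
    r <- sqrt(runif(n_points, r_inner^2, r_outer^2))
    phi <- runif(n_points, 0, 2 * pi)
    z <- runif(n_points, 0, length)
    tibble(x = r * cos(phi), y = r * sin(phi), z = z, r = r)
  })
}

#' Bivariate normal series with prescribed correlation
#'
#' Generates two standard-normal series with population Pearson correlation
#' `rho`, the oracle fixture for correlation and mutual-information
#' estimators.
#'
#' @param rho population correlation in `[-1, 1]`.
#' @param n series length (>= 2).
#' @param seed integer seed.
#' @return tibble with columns `a` and `b`.
#' @examples
#' s <- make_correlated_series(0.5, 1e4, seed = 2)
#' cor(s$a, s$b)
#' @export
make_correlated_series <- function(rho, n, seed) {
  if (abs(rho) > 1) abort("|rho| must be <= 1")
  if (n < 2) abort("n must be >= 2")
  with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    tibble(a = z1, b = rho * z1 + sqrt(1 - rho^2) * z2)
  })
}

#' Tip deflection of a clamped discrete elastic beam
#'
#' Independent numerical oracle for Euler--Bernoulli beam mechanics: a chain
#' of `n_segments` rigid segments clamped at one end, with bending energy
#' `EI/(2h) * sum (theta_i - theta_{i-1})^2` penalizing curvature at the
#' joints, is relaxed under a transverse tip load by quasi-Newton energy
#' minimization. For small deflections the tip deflection converges to the
#' continuum value `F L^3 / (3 EI)` as `n_segments` grows (the linearized
#' discrete solution is `F L^3/(3 EI) * (n+1)(2n+1)/(2n^2)`, about +1.5%
#' at n = 100).
#'
#' @param EI flexural rigidity, pN um^2.
#' @param length beam length, um.
#' @param tip_force transverse load at the free end, pN.
#' @param n_segments number of segments (>= 10).
#' @return tip deflection in um.
#' @examples
#' bend_beam_oracle(EI = 12.6, length = 0.2, tip_force = 10)
#' @export
bend_beam_oracle <- function(EI, length, tip_force, n_segments = 100L) {
  if (EI <= 0 || length <= 0) abort("EI and length must be > 0")
  if (n_segments < 10) abort("n_segments must be >= 10")
  n <- as.integer(n_segments)
  h <- length / n
  if (tip_force == 0) return(0)

  energy <- function(theta) {
    dth <- diff(c(0, theta))
    EI / (2 * h) * sum(dth^2) - tip_force * h * sum(sin(theta))
  }
  gradient <- function(theta) {
    th0 <- c(0, theta)
    d <- diff(th0)
    g <- numeric(n)
    g <- EI / h * (d - c(d[-1], 0))
    g - tip_force * h * cos(theta)
  }
  fit <- optim(rep(0, n), energy, gradient, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$convergence != 0) {
    abort(sprintf("elastica minimization failed to converge (code %d)",
                  fit$convergence))
  }
  w <- h * sum(sin(fit$par))
  if (w > 0.1 * length) {
    warn("deflection exceeds 10% of the beam length; outside the small-deflection regime")
  }
  w
}
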