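# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic operations in the package go through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# kT at 300 K in kJ/mol, the default thermal energy throughout.
KT_300K <- 2.494

#' Unit conversions used by the mechanics module
#'
#' Stress computed from pressures in bar and box areas in nm\eqn{^2} comes out
#' in bar; mechanics results are reported in GPa (1 bar = 10\eqn{^{-4}} GPa =
#' 10\eqn{^5} Pa). Rigidity computed as a modulus (GPa) times a second moment
#' (nm\eqn{^4}) is reported in pN um\eqn{^2}: 1 GPa nm\eqn{^4} =
#' 10\eqn{^{-27}} N m\eqn{^2} and 1 pN um\eqn{^2} = 10\eqn{^{-24}} N
#' m\eqn{^2}, so the bridge is 10\eqn{^{-3}}.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' bar_to_gpa(1e4)          # 1 GPa
#' gpa_nm4_to_pn_um2(1e3)   # 1 pN um^2
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
bar_to_gpa <- function(x) x * 1e-4

#' @rdname unit-conversions
#' @export
gpa_nm4_to_pn_um2 <- function(x) x * 1e-3

# Acute angle in degrees between two direction vectors.
acute_angle_deg <- function(u, v) {
  cu <- u / sqrt(sum(u^2))
  cv <- v / sqrt(sum(v^2))
  d <- abs(sum(cu * cv))
  acos(min(1, d)) * 180 / pi
}

# 3x3 rotation matrix about the z axis, angle in degrees.
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), nrow = 3)
}

# Coerce a sites object (tibble with x, y, z) to an n x 3 coordinate matrix.
site_xyz <- function(sites) {
  stopifnot(all(c("x", "y", "z") %in% names(sites)))
  cbind(sites$x, sites$y, sites$z)
}

# Optional-column accessor: tibble[,"col"] without the unknown-column warning.
col_or <- function(df, col, default) {
  if (col %in% names(df)) df[[col]] else default
}

# TRUE while all elements so far are TRUE (running conjunction).
cumall <- function(x) cumprod(as.logical(x)) > 0

# Wrap angles (degrees) into (-180, 180].
wrap_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}
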