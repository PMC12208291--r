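#' Helical lattice parameters
#'
#' Describes an N-protofilament helical filament lattice. Protofilament
#' `p` (1-based) is the asymmetric unit rotated by `(p-1) * twist_per_pf`
#' about the filament axis and translated by `(p-1) * rise_per_pf` along it;
#' dimer layers are axial copies spaced by `layer_period`. The defaults are
#' the 14-protofilament microtubule geometry (twist 25.77 degrees, rise
#' 0.874 nm per protofilament). Note `n_protofilaments * twist_per_pf` need
#' not close to 360 degrees; 14 x 25.77 = 360.78 and the 0.78-degree excess
#' is the lattice's intrinsic skew, which the builder preserves rather than
#' renormalizing away.
#'
#' @param n_protofilaments number of protofilaments (>= 1).
#' @param twist_per_pf rotation about the axis between adjacent
#'   protofilaments, degrees.
#' @param rise_per_pf axial translation between adjacent protofilaments, nm.
#' @param layer_period axial translation per dimer layer, nm; `NULL` (default)
#'   means take the axial extent of the input unit at build time.
#' @param n_layers number of core dimer layers per protofilament (>= 1).
#' @param cap_layers number of cap layers appended at the plus end (>= 0);
#'   built from a separate cap unit, mimicking a stabilized cap.
#' @param tip_max_removed maximum number of dimer layers removable per
#'   protofilament per end when randomizing tip lengths; 0 disables.
#' @param tip_seed integer seed for tip randomization (required when
#'   `tip_max_removed > 0`).
#' @return an object of class `helical_params`.
#' @examples
#' helical_params(n_layers = 19, cap_layers = 6)
#' @export
helical_params <- function(n_protofilaments = 14L, twist_per_pf = 25.77,
                           rise_per_pf = 0.874, layer_period = NULL,
                           n_layers = 1L, cap_layers = 0L,
                           tip_max_removed = 0L, tip_seed = NULL) {
  if (n_protofilaments < 1) abort("n_protofilaments must be >= 1")
  if (n_layers < 1) abort("n_layers must be >= 1")
  if (cap_layers < 0) abort("cap_layers must be >= 0")
  if (!is.null(layer_period) && layer_period <= 0) {
    abort("layer_period must be > 0")
  }
  if (tip_max_removed < 0 || tip_max_removed >= n_layers) {
    abort("tip_max_removed must satisfy 0 <= tip_max_removed < n_layers")
  }
  if (tip_max_removed > 0 && is.null(tip_seed)) {
    abort("tip_seed is required when tip_max_removed > 0")
  }
  structure(
    list(n_protofilaments = as.integer(n_protofilaments),
         twist_per_pf = twist_per_pf, rise_per_pf = rise_per_pf,
         layer_period = layer_period, n_layers = as.integer(n_layers),
         cap_layers = as.integer(cap_layers),
         tip_max_removed = as.integer(tip_max_removed), tip_seed = tip_seed),
    class = "helical_params"
  )
}

#' @export
print.helical_params <- function(x, ...) {
  cat("<helical_params> ", x$n_protofilaments, " pf, twist ", x$twist_per_pf,
      " deg, rise ", x$rise_per_pf, " nm, ", x$n_layers, " + ", x$cap_layers,
      " (cap) layers\n", sep = "")
  invisible(x)
}

#' Build a helical filament lattice from an asymmetric unit
#'
#' Replicates a dimer unit over protofilaments (rotation + rise about/along
#' the +z axis) and layers (axial translation). The minus end sits at low z
#' and the capped plus end at high z. Cap layers, when requested, are built
#' from `cap_unit` under the same helical rule and appended above the core
#' layers. The lattice seam arises purely from the helical symmetry; no
#' special seam conformation is introduced. Tip randomization removes an
#' independent uniform number of layers in `0..tip_max_removed` from each
#' protofilament at each end, drawn from a single RNG stream seeded by
#' `tip_seed`.
#'
#' @param unit sites of the asymmetric unit: a data frame with coordinates
#'   `x`, `y`, `z` in nm and any label columns (e.g. `chain_id`,
#'   `residue_index`, `monomer_id`, `region`). Label columns are carried to
#'   every copy.
#' @param params a [helical_params()].
#' @param cap_unit sites used for cap layers; required iff `cap_layers > 0`.
#' @return an object of class `lattice_assembly`: list with `sites` (tibble:
#'   unit columns plus `pf_index`, `layer_index` (1-based), `zone`
#'   ("core"/"cap")), `axis` (unit vector), `origin`, and `params`.
#' @examples
#' dimer <- tibble::tibble(x = c(0, 0), y = c(11, 11), z = c(0, 4),
#'                         monomer_id = c("alpha", "beta"))
#' mt <- build_lattice(dimer, helical_params(n_layers = 3, layer_period = 8))
#' nrow(mt$sites)
#' @export
build_lattice <- function(unit, params, cap_unit = NULL) {
  stopifnot(inherits(params, "helical_params"))
  unit <- as_tibble(unit)
  if (nrow(unit) == 0) abort("unit structure is empty")
  if (params$cap_layers > 0 && is.null(cap_unit)) {
    abort("cap_unit is required when cap_layers > 0")
  }
  period <- params$layer_period %||% (max(unit$z) - min(unit$z))
  if (period <= 0) {
    abort("layer_period could not be inferred from a flat unit; supply it explicitly")
  }

  one_copy <- function(u, pf, layer, zone) {
    xyz <- site_xyz(u) %*% t(rot_z((pf - 1) * params$twist_per_pf))
    xyz[, 3] <- xyz[, 3] + (pf - 1) * params$rise_per_pf +
      (layer - 1) * period
    out <- u
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    out$pf_index <- pf
    out$layer_index <- layer
    out$zone <- zone
    out
  }

  n_total <- params$n_layers + params$cap_layers
  grid <- tidyr::expand_grid(pf = seq_len(params$n_protofilaments),
                             layer = seq_len(n_total))

  if (params$tip_max_removed > 0) {
    keep <- with_seed(params$tip_seed, {
      n_minus <- sample.int(params$tip_max_removed + 1L,
                            params$n_protofilaments, replace = TRUE) - 1L
      n_plus <- sample.int(params$tip_max_removed + 1L,
                           params$n_protofilaments, replace = TRUE) - 1L
      list(minus = n_minus, plus = n_plus)
    })
    if (any(keep$minus + keep$plus >= n_total)) {
      abort("tip removal exceeds available layers on at least one protofilament")
    }
    grid <- dplyr::filter(grid,
      .data$layer > keep$minus[.data$pf],
      .data$layer <= n_total - keep$plus[.data$pf])
  }

  sites <- purrr::pmap_dfr(grid, function(pf, layer) {
    if (layer > params$n_layers) {
      one_copy(as_tibble(cap_unit), pf, layer, "cap")
    } else {
      one_copy(unit, pf, layer, "core")
    }
  })

  structure(
    list(sites = sites, axis = c(0, 0, 1), origin = c(0, 0, 0),
         params = params),
    class = "lattice_assembly"
  )
}

#' @export
print.lattice_assembly <- function(x, ...) {
  cat("<lattice_assembly> ", nrow(x$sites), " sites, ",
      length(unique(x$sites$pf_index)), " protofilaments, ",
      length(unique(x$sites$layer_index)), " layers\n", sep = "")
  invisible(x)
}

#' Apply a rigid-body transform to a lattice assembly
#'
#' Rotates (about the assembly origin) and translates every site, and carries
#' the assembly axis and origin along, so measured helical parameters are
#' invariant.
#'
#' @param assembly a [build_lattice()] result.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector, nm.
#' @return the transformed `lattice_assembly`.
#' @export
transform_assembly <- function(assembly, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  stopifnot(inherits(assembly, "lattice_assembly"))
  xyz <- site_xyz(assembly$sites) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  assembly$sites$x <- xyz[, 1]
  assembly$sites$y <- xyz[, 2]
  assembly$sites$z <- xyz[, 3]
  assembly$axis <- as.numeric(rotation %*% assembly$axis)
  assembly$origin <- as.numeric(rotation %*% assembly$origin + translation)
  assembly
}

#' Measure helical parameters from an assembly
#'
#' Inverse of [build_lattice()]: for every pair of adjacent protofilaments
#' and every layer they share, the centroid-to-centroid angular offset about
#' the assembly axis and the axial offset are computed; their means are the
#' helical twist and rise.
#'
#' @param assembly a `lattice_assembly` with >= 2 protofilaments carrying
#'   matched layers.
#' @return one-row tibble with `twist_per_pf` (degrees), `rise_per_pf` (nm)
#'   and `n_protofilaments`.
#' @examples
#' dimer <- tibble::tibble(x = 0, y = 11, z = 0)
#' mt <- build_lattice(dimer, helical_params(n_layers = 2, layer_period = 8))
#' measure_helical_params(mt)
#' @export
measure_helical_params <- function(assembly) {
  stopifnot(inherits(assembly, "lattice_assembly"))
  sites <- assembly$sites
  pfs <- sort(unique(sites$pf_index))
  if (length(pfs) < 2) abort("need >= 2 protofilaments to measure helical parameters")

  # orthonormal frame with e3 = axis
  e3 <- assembly$axis / sqrt(sum(assembly$axis^2))
  ref <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])

  cent <- sites |>
    dplyr::group_by(.data$pf_index, .data$layer_index) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     .groups = "drop")
  rel <- sweep(site_xyz(cent), 2, assembly$origin, "-")
  cent$u <- as.numeric(rel %*% e1)
  cent$v <- as.numeric(rel %*% e2)
  cent$w <- as.numeric(rel %*% e3)
  cent$radial <- sqrt(cent$u^2 + cent$v^2)
  if (any(cent$radial < 1e-9)) {
    abort("degenerate assembly: protofilament centroids lie on the axis")
  }
  cent$phi <- atan2(cent$v, cent$u) * 180 / pi

  offsets <- dplyr::inner_join(
    cent, dplyr::mutate(cent, pf_index = .data$pf_index - 1L),
    by = c("pf_index", "layer_index"), suffix = c("", "_next")
  )
  if (nrow(offsets) == 0) {
    abort("no adjacent protofilaments share a layer; cannot measure")
  }
  tibble(
    twist_per_pf = mean(wrap_deg(offsets$phi_next - offsets$phi)),
    rise_per_pf = mean(offsets$w_next - offsets$w),
    n_protofilaments = length(pfs)
  )
}
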