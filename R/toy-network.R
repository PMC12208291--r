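#' Construct a bead-spring network
#'
#' A bead-spring network is the minimal mechanical object the toolkit
#' simulates: point beads connected by harmonic springs, evolved by overdamped
#' Brownian dynamics at a fixed thermal energy. It stands in for a
#' coarse-grained protein patch when exercising the fluctuation-matching loop
#' without an external MD engine.
#'
#' @param positions numeric matrix (n x 3) of bead coordinates in nm, or a
#'   data frame with columns `x`, `y`, `z`.
#' @param springs data frame with columns `i`, `j` (1-based bead indices),
#'   `b0` (rest length, nm) and `k` (spring constant, kJ mol^-1 nm^-2).
#' @param friction effective drag coefficient (kJ mol^-1 ps nm^-2); velocity
#'   response is force / friction. Mass is absorbed into this constant.
#' @param kT thermal energy in kJ/mol; default 2.494 (300 K).
#' @param restrained integer vector of bead indices held fixed during
#'   simulation (an infinitely stiff restraint). A finite harmonic restraint
#'   is available through the `restraint_k` argument of [simulate_brownian()].
#'
#' @return an object of class `bead_network`.
#' @examples
#' net <- bead_network(
#'   positions = rbind(c(0, 0, 0), c(1, 0, 0)),
#'   springs   = data.frame(i = 1, j = 2, b0 = 1, k = 100)
#' )
#' net
#' @export
bead_network <- function(positions, springs, friction = 50, kT = KT_300K,
                         restrained = integer(0)) {
  if (is.data.frame(positions)) positions <- site_xyz(positions)
  positions <- as.matrix(positions)
  stopifnot(is.numeric(positions), ncol(positions) == 3)
  n <- nrow(positions)
  springs <- as_tibble(springs)
  stopifnot(all(c("i", "j", "b0", "k") %in% names(springs)))
  if (nrow(springs) > 0) {
    if (any(springs$i == springs$j)) {
      abort("spring endpoints must be distinct beads")
    }
    if (any(springs$i < 1 | springs$i > n | springs$j < 1 | springs$j > n)) {
      abort("spring bead index out of range")
    }
    if (any(springs$k < 0)) abort("spring constants must be >= 0")
    if (any(springs$b0 <= 0)) abort("spring rest lengths must be > 0")
  }
  if (kT < 0) abort("kT must be >= 0")
  if (friction <= 0) abort("friction must be > 0")
  restrained <- sort(unique(as.integer(restrained)))
  if (length(restrained) && (min(restrained) < 1 || max(restrained) > n)) {
    abort("restrained bead index out of range")
  }
  structure(
    list(positions = positions, springs = springs, friction = friction,
         kT = kT, restrained = restrained),
    class = "bead_network"
  )
}

#' @export
print.bead_network <- function(x, ...) {
  cat("<bead_network> ", nrow(x$positions), " beads, ", nrow(x$springs),
      " springs, kT = ", x$kT, " kJ/mol, ", length(x$restrained),
      " restrained\n", sep = "")
  invisible(x)
}

#' Total harmonic spring energy of a configuration
#'
#' @param network a [bead_network()].
#' @param positions optional coordinate matrix; defaults to the network's own.
#' @return energy in kJ/mol.
#' @export
spring_energy <- function(network, positions = network$positions) {
  sp <- network$springs
  if (nrow(sp) == 0) return(0)
  dvec <- positions[sp$i, , drop = FALSE] - positions[sp$j, , drop = FALSE]
  d <- sqrt(rowSums(dvec^2))
  sum(0.5 * sp$k * (d - sp$b0)^2)
}

#' Closed-form bond-length variance of an isolated harmonic pair
#'
#' In the stiff-spring / large-rest-length limit the bond length of a pair
#' connected by a harmonic spring of constant `k` fluctuates with variance
#' kT / k. This is the analytic oracle the Brownian simulator and the
#' fluctuation-matching loop are tested against.
#'
#' @param k spring constant, kJ mol^-1 nm^-2; must be > 0.
#' @param kT thermal energy, kJ/mol.
#' @return variance in nm^2.
#' @examples
#' analytic_pair_variance(249.4, 2.494)  # 0.01 nm^2
#' @export
analytic_pair_variance <- function(k, kT = KT_300K) {
  if (any(k <= 0)) abort("spring constant k must be > 0")
  if (any(kT < 0)) abort("kT must be >= 0")
  kT / k
}
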