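#' Configuration for heterogeneous elastic-network construction
#'
#' Collects every tunable of the network-building and fluctuation-matching
#' pipeline. Defaults follow standard coarse-grained elastic-network practice
#' for protein lattices: contacts between backbone sites 0.5--0.9 nm apart
#' and more than two residues apart in sequence, a 500 kJ mol^-1 nm^-2 base
#' constant, and an update gain `alpha = 1050` acting through
#' `alpha * kT / L_cutoff^4`.
#'
#' @param k0 base spring constant, kJ mol^-1 nm^-2 (default 500).
#' @param L_low,L_high contact distance window, nm (defaults 0.5 and 0.9).
#' @param L_cutoff_for_update length scale in the update gain, nm; defaults
#'   to the upper window bound 0.9.
#' @param alpha dimensionless update gain (default 1050).
#' @param kT thermal energy, kJ/mol (default 2.494, i.e. 300 K).
#' @param z_threshold z-score above which a contact whose structure-derived
#'   distance is an outlier of the reference fluctuation distribution is
#'   discarded (default 3, assuming a local normal distribution).
#' @param min_seq_sep minimal residue separation within a chain (default 3:
#'   contacts require `|i - j| > 2`); inter-chain pairs are always eligible.
#' @param excluded_regions named list, one entry per chain id, each a list of
#'   `c(first, last)` residue ranges excluded from the network (e.g.
#'   disordered C-terminal tails).
#' @param max_iterations iteration cap for the matching loop (default 50).
#' @param convergence_tol tolerance on the mean variance mismatch, nm^2
#'   (default 1e-4).
#' @param spring_floor lower bound applied to updated spring constants,
#'   kJ mol^-1 nm^-2 (default 0; bonds are floored, never deleted, so the
#'   contact-set topology is fixed across iterations).
#' @return an object of class `enm_config` (a named list).
#' @examples
#' enm_config()
#' enm_config(excluded_regions = list(A = list(c(20, 25))))
#' @export
enm_config <- function(k0 = 500, L_low = 0.5, L_high = 0.9,
                       L_cutoff_for_update = 0.9, alpha = 1050,
                       kT = KT_300K, z_threshold = 3, min_seq_sep = 3L,
                       excluded_regions = list(), max_iterations = 50L,
                       convergence_tol = 1e-4, spring_floor = 0) {
  if (!(L_low > 0 && L_low < L_high)) abort("need 0 < L_low < L_high")
  if (k0 <= 0) abort("k0 must be > 0")
  if (alpha <= 0) abort("alpha must be > 0")
  if (z_threshold <= 0) abort("z_threshold must be > 0")
  if (min_seq_sep < 1) abort("min_seq_sep must be >= 1")
  if (convergence_tol <= 0) abort("convergence_tol must be > 0")
  if (spring_floor < 0) abort("spring_floor must be >= 0")
  structure(
    list(k0 = k0, L_low = L_low, L_high = L_high,
         L_cutoff_for_update = L_cutoff_for_update, alpha = alpha, kT = kT,
         z_threshold = z_threshold, min_seq_sep = as.integer(min_seq_sep),
         excluded_regions = excluded_regions,
         max_iterations = as.integer(max_iterations),
         convergence_tol = convergence_tol, spring_floor = spring_floor),
    class = "enm_config"
  )
}

#' @export
print.enm_config <- function(x, ...) {
  cat("<enm_config> k0 =", x$k0, "| window", x$L_low, "-", x$L_high,
      "nm | alpha =", x$alpha, "| z >", x$z_threshold, "dropped\n")
  invisible(x)
}
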