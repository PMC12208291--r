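# The fluctuation-matching elastic network core: contact extraction,
# variance-inverse initialization, the iterative spring update, and the
# optimize-simulate loop driven through a pluggable fluctuation evaluator.

#' Extract elastic-network contacts from a reference structure
#'
#' Candidate site pairs become contacts when their reference distance lies in
#' the `[L_low, L_high]` window, they are more than `min_seq_sep - 1`
#' residues apart in sequence when on the same chain (inter-chain pairs are
#' always eligible), and neither site falls in an excluded region. When
#' reference fluctuation statistics are supplied, contacts whose structural
#' distance is a `>= z_threshold` sigma outlier of the per-pair fluctuation
#' distribution are dropped as well — this prunes the network away from
#' highly dynamic regions.
#'
#' @param sites reference structure: tibble with `x`, `y`, `z` (nm) and,
#'   optionally, `chain_id` and `residue_index` (defaults: one chain,
#'   residue index = row number).
#' @param stats optional distance statistics (tibble with `i`, `j`, `mean`,
#'   `var`) used for the outlier filter; candidate pairs missing from `stats`
#'   are kept and reported via a message.
#' @param config an [enm_config()].
#' @return tibble of contacts: `i`, `j` (site row indices, `i < j`),
#'   `chain_i`, `chain_j`, `d0` (nm).
#' @examples
#' coil <- tibble::tibble(x = cumsum(runif(10, 0.3, 0.4)), y = 0, z = 0)
#' extract_contacts(coil, config = enm_config())
#' @export
extract_contacts <- function(sites, stats = NULL, config = enm_config()) {
  sites <- as_tibble(sites)
  n <- nrow(sites)
  if (n < 2) abort("reference structure needs at least two sites")
  chain <- col_or(sites, "chain_id", rep("A", n))
  resid <- col_or(sites, "residue_index", seq_len(n))

  dm <- as.matrix(stats::dist(site_xyz(sites)))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  cand <- tibble(i = idx[, 1], j = idx[, 2], d0 = dm[idx])

  same_chain <- chain[cand$i] == chain[cand$j]
  sep_ok <- !same_chain | abs(resid[cand$i] - resid[cand$j]) >= config$min_seq_sep
  window_ok <- cand$d0 >= config$L_low & cand$d0 <= config$L_high

  excluded <- rep(FALSE, n)
  for (ch in names(config$excluded_regions)) {
    for (rg in config$excluded_regions[[ch]]) {
      excluded <- excluded | (chain == ch & resid >= rg[1] & resid <= rg[2])
    }
  }
  excl_ok <- !excluded[cand$i] & !excluded[cand$j]

  keep <- cand[sep_ok & window_ok & excl_ok, ]
  keep$chain_i <- chain[keep$i]
  keep$chain_j <- chain[keep$j]
  keep <- keep[, c("i", "j", "chain_i", "chain_j", "d0")]

  if (!is.null(stats)) {
    st <- dplyr::select(as_tibble(stats), "i", "j", "mean", "var")
    keep <- dplyr::left_join(keep, st, by = c("i", "j"))
    missing <- is.na(keep$var)
    if (any(missing)) {
      inform(sprintf(
        "%d candidate pair(s) missing from stats were kept without outlier screening",
        sum(missing)))
    }
    z <- abs(keep$d0 - keep$mean) / sqrt(keep$var)
    drop <- !missing & keep$var > 0 & z >= config$z_threshold
    keep <- keep[!drop, c("i", "j", "chain_i", "chain_j", "d0")]
  }

  if (nrow(keep) == 0) warn("contact extraction produced an empty contact set")
  keep
}

#' Initialize spring constants inversely proportional to distance variance
#'
#' Each contact gets `k_ij = k0 * min(var) / var_ij`, so the least-mobile
#' contact carries exactly the base constant `k0` and softer contacts scale
#' down with their fluctuation variance — a heterogeneous rather than uniform
#' network. Equilibrium lengths are the structural distances `d0`.
#'
#' @param contacts contact tibble from [extract_contacts()].
#' @param stats distance statistics covering every contact (`i`, `j`, `var`).
#' @param config an [enm_config()].
#' @return spring table: tibble `i`, `j`, `d0`, `k` with attribute
#'   `iteration = 0`.
#' @examples
#' contacts <- tibble::tibble(i = 1:3, j = 4:6, d0 = 0.7)
#' stats <- tibble::tibble(i = 1:3, j = 4:6, mean = 0.7,
#'                         var = c(0.005, 0.010, 0.020))
#' init_springs(contacts, stats)
#' @export
init_springs <- function(contacts, stats, config = enm_config()) {
  contacts <- as_tibble(contacts)
  st <- dplyr::select(as_tibble(stats), "i", "j", "var")
  tab <- dplyr::left_join(contacts, st, by = c("i", "j"))
  if (any(is.na(tab$var))) {
    bad <- tab[is.na(tab$var), ]
    abort(paste0("stats missing for contact(s): ",
                 paste(sprintf("(%d,%d)", bad$i, bad$j), collapse = ", ")))
  }
  if (any(tab$var <= 0)) {
    bad <- tab[tab$var <= 0, ]
    abort(paste0("non-positive variance for contact(s): ",
                 paste(sprintf("(%d,%d)", bad$i, bad$j), collapse = ", ")))
  }
  out <- tibble(i = tab$i, j = tab$j, d0 = tab$d0,
                k = config$k0 * min(tab$var) / tab$var)
  attr(out, "iteration") <- 0L
  out
}

#' One fluctuation-matching update of the spring table
#'
#' Applies `k <- k - alpha * kT / L_cutoff^4 * (var_target - var_current)`
#' per contact: when the current (coarse-grained) model fluctuates less than
#' the target, the spring softens; when it fluctuates more, it stiffens.
#' Updated constants are floored at `spring_floor` and the bond is retained,
#' keeping the network topology fixed across iterations.
#'
#' @param springs spring table (`i`, `j`, `d0`, `k`).
#' @param target,current distance statistics (`i`, `j`, `var`) for the
#'   reference and the current model; both must cover every spring.
#' @param config an [enm_config()].
#' @return the updated spring table, `iteration` attribute incremented.
#' @examples
#' springs <- tibble::tibble(i = 1, j = 4, d0 = 0.7, k = 500)
#' target <- tibble::tibble(i = 1, j = 4, var = 0.010)
#' current <- tibble::tibble(i = 1, j = 4, var = 0.011)
#' update_springs(springs, target, current)  # k -> 503.99
#' @export
update_springs <- function(springs, target, current, config = enm_config()) {
  springs <- as_tibble(springs)
  it <- attr(springs, "iteration") %||% 0L
  tg <- dplyr::select(as_tibble(target), "i", "j", var_target = "var")
  cu <- dplyr::select(as_tibble(current), "i", "j", var_current = "var")
  tab <- dplyr::left_join(springs, tg, by = c("i", "j"))
  tab <- dplyr::left_join(tab, cu, by = c("i", "j"))
  miss <- is.na(tab$var_target) | is.na(tab$var_current)
  if (any(miss)) {
    bad <- tab[miss, ]
    abort(paste0("stats missing for spring(s): ",
                 paste(sprintf("(%d,%d)", bad$i, bad$j), collapse = ", ")))
  }
  gain <- config$alpha * config$kT / config$L_cutoff_for_update^4
  k_new <- pmax(config$spring_floor,
                tab$k - gain * (tab$var_target - tab$var_current))
  out <- springs
  out$k <- k_new
  attr(out, "iteration") <- it + 1L
  out
}

#' Mean variance mismatch between target and current fluctuations
#'
#' The convergence metric of the matching loop: the signed arithmetic mean of
#' `var_target - var_current` over the contacts both tables cover.
#'
#' @param target,current distance statistics (`i`, `j`, `var`).
#' @return mean variance difference in nm^2.
#' @export
convergence_metric <- function(target, current) {
  tg <- dplyr::select(as_tibble(target), "i", "j", var_target = "var")
  cu <- dplyr::select(as_tibble(current), "i", "j", var_current = "var")
  tab <- dplyr::inner_join(tg, cu, by = c("i", "j"))
  if (nrow(tab) == 0) abort("target and current stats share no contacts")
  mean(tab$var_target - tab$var_current)
}

#' Run the fluctuation-matching loop to convergence
#'
#' Alternates a fluctuation evaluator (a function mapping a spring table to
#' distance statistics over the same contacts; in production an external MD
#' engine, in tests the Brownian toy simulator or the analytic kT/k oracle)
#' with [update_springs()]. Stops when `|D| <= convergence_tol`, when `D`
#' changes by no more than a tenth of the tolerance on two consecutive
#' iterations, or at `max_iterations`.
#'
#' @param initial initial spring table.
#' @param target reference distance statistics to match.
#' @param evaluator `function(springs) -> stats tibble (i, j, var)`.
#' @param config an [enm_config()].
#' @return object of class `fm_fit`: list with `springs` (final table),
#'   `trail` (tibble: `iteration`, `D`, `k_mean`, `n_springs`) and
#'   `converged` (logical).
#' @examples
#' target <- tibble::tibble(i = 1:2, j = 3:4, var = 2.494 / c(200, 400))
#' springs <- tibble::tibble(i = 1:2, j = 3:4, d0 = 0.7, k = c(500, 500))
#' fit <- iterate_to_convergence(springs, target, evaluator_analytic())
#' glance(fit)
#' @export
iterate_to_convergence <- function(initial, target, evaluator,
                                   config = enm_config()) {
  springs <- as_tibble(initial)
  if (is.null(attr(springs, "iteration"))) attr(springs, "iteration") <- 0L
  trail <- tibble(iteration = integer(), D = numeric(), k_mean = numeric(),
                  n_springs = integer())
  if (config$max_iterations == 0) {
    return(structure(list(springs = springs, trail = trail, converged = FALSE),
                     class = "fm_fit"))
  }
  D_prev <- NA_real_
  flat_run <- 0L
  converged <- FALSE
  for (n in seq_len(config$max_iterations + 1L) - 1L) {
    current <- tryCatch(evaluator(springs), error = function(e) {
      abort(sprintf("fluctuation evaluator failed at iteration %d: %s",
                    n, conditionMessage(e)))
    })
    if (!all(is.finite(current$var))) {
      return(structure(list(springs = springs, trail = trail, converged = FALSE,
                            error = sprintf("non-finite variances at iteration %d", n)),
                       class = "fm_fit"))
    }
    D <- convergence_metric(target, current)
    trail <- dplyr::bind_rows(trail, tibble(
      iteration = n, D = D, k_mean = mean(springs$k),
      n_springs = nrow(springs)))
    if (abs(D) <= config$convergence_tol) { converged <- TRUE; break }
    if (!is.na(D_prev) && abs(D - D_prev) <= 0.1 * config$convergence_tol) {
      flat_run <- flat_run + 1L
      if (flat_run >= 2L) { converged <- TRUE; break }
    } else {
      flat_run <- 0L
    }
    if (n == config$max_iterations) break
    D_prev <- D
    springs <- update_springs(springs, target, current, config)
  }
  structure(list(springs = springs, trail = trail, converged = converged),
            class = "fm_fit")
}

#' @export
print.fm_fit <- function(x, ...) {
  cat("<fm_fit> ", nrow(x$trail), " iteration(s), final D = ",
      signif(tail(x$trail$D, 1), 4), " nm^2, ",
      if (x$converged) "converged" else "not converged", "\n", sep = "")
  invisible(x)
}

#' Fluctuation evaluators for the matching loop
#'
#' `evaluator_analytic()` returns the closed-form stationary bond-length
#' variance kT/k per spring (independent pairs, stiff-spring limit) — fast
#' and exact for isolated-pair networks. `evaluator_brownian()` builds a
#' bead-spring network on fixed site positions from the spring table,
#' simulates it with [simulate_brownian()], and measures variances from the
#' trajectory (a burn-in fraction of early frames is discarded); this closes
#' the full optimize--simulate--measure loop in miniature.
#'
#' @param kT thermal energy, kJ/mol.
#' @param positions coordinate matrix for the network's beads.
#' @param friction,dt,n_steps,stride,seed simulation controls passed to
#'   [simulate_brownian()]; the evaluator derives a fresh sub-seed per call
#'   from `seed` and the spring table's iteration index.
#' @param burn_in fraction of initial frames discarded (default 0.2).
#' @param restrained beads held fixed during evaluation.
#' @param k_floor evaluators require k > 0; springs below `k_floor` are
#'   evaluated at `k_floor` (default 1e-3) to keep variances finite.
#' @return a `function(springs) -> tibble(i, j, mean, var)`.
#' @name evaluators
NULL

#' @rdname evaluators
#' @export
evaluator_analytic <- function(kT = KT_300K, k_floor = 1e-3) {
  force(kT)
  function(springs) {
    k <- pmax(springs$k, k_floor)
    tibble(i = springs$i, j = springs$j, mean = springs$d0, var = kT / k)
  }
}

#' @rdname evaluators
#' @export
evaluator_brownian <- function(positions, friction = 50, kT = KT_300K,
                               dt = 0.002, n_steps = 20000L, stride = 10L,
                               seed = 1L, burn_in = 0.2,
                               restrained = integer(0), k_floor = 1e-3) {
  force(positions)
  function(springs) {
    it <- attr(springs, "iteration") %||% 0L
    net <- bead_network(
      positions,
      tibble(i = springs$i, j = springs$j, b0 = springs$d0,
             k = pmax(springs$k, k_floor)),
      friction = friction, kT = kT, restrained = restrained)
    traj <- simulate_brownian(net, dt = dt, n_steps = n_steps,
                              seed = seed + it, stride = stride)
    nf <- n_frames(traj)
    first <- floor(burn_in * nf) + 1L
    pair_distance_stats(traj, springs[, c("i", "j")], window = first:nf)
  }
}
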