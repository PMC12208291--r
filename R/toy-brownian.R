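#' Overdamped Brownian dynamics on a bead-spring network
#'
#' First-order Euler--Maruyama integration of the overdamped Langevin
#' equation: each unrestrained bead moves by `(dt / friction) * force` plus a
#' Gaussian kick of standard deviation `sqrt(2 kT dt / friction)` per
#' coordinate. Restrained beads are held fixed unless a finite `restraint_k`
#' is supplied, in which case they are tethered harmonically to their initial
#' positions instead.
#'
#' The scheme is stable only when `dt * k / friction` is small for the
#' stiffest spring; the function refuses to run when that ratio reaches 0.1
#' rather than diverge silently. Note the relative coordinate of a pair
#' relaxes at twice the single-bead rate, so accurate stationary variances
#' need `dt * k / friction` well below the stability bound (the discretized
#' stationary variance is inflated by roughly `dt * k / friction` relative to
#' kT/k).
#'
#' @param network a [bead_network()].
#' @param dt time step in ps.
#' @param n_steps number of integration steps (>= 1).
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   trajectories.
#' @param stride record every `stride`-th step (default 1).
#' @param restraint_k finite restraint constant (kJ mol^-1 nm^-2) for the
#'   network's restrained beads; `Inf` (default) freezes them.
#'
#' @return an object of class `toy_trajectory`: a list with `frames` (array
#'   of dim `n_frames x n_beads x 3`, nm), `dt`, `stride`, `seed`, and
#'   `times` (ps, time of each recorded frame).
#' @examples
#' net <- bead_network(rbind(c(0, 0, 0), c(1.2, 0, 0)),
#'                     data.frame(i = 1, j = 2, b0 = 1, k = 100), kT = 0)
#' traj <- simulate_brownian(net, dt = 0.01, n_steps = 500, seed = 1)
#' dim(traj$frames)
#' @export
simulate_brownian <- function(network, dt, n_steps, seed, stride = 1L,
                              restraint_k = Inf) {
  stopifnot(inherits(network, "bead_network"))
  if (dt <= 0) abort("dt must be > 0")
  if (n_steps < 1) abort("n_steps must be >= 1")
  if (stride < 1) abort("stride must be >= 1")
  kmax <- if (nrow(network$springs)) max(network$springs$k) else 0
  if (is.finite(restraint_k)) kmax <- max(kmax, restraint_k)
  if (dt * kmax / network$friction >= 0.1) {
    abort(sprintf(
      "unstable parameters: dt * k_max / friction = %.3g >= 0.1; reduce dt",
      dt * kmax / network$friction))
  }

  pos <- network$positions
  n <- nrow(pos)
  sp <- network$springs
  mobile <- rep(TRUE, n)
  frozen <- integer(0)
  tether <- NULL
  if (length(network$restrained)) {
    if (is.finite(restraint_k)) {
      tether <- list(idx = network$restrained,
                     ref = pos[network$restrained, , drop = FALSE],
                     k = restraint_k)
    } else {
      frozen <- network$restrained
      mobile[frozen] <- FALSE
    }
  }

  grp <- c(sp$i, sp$j)
  mob_dt <- dt / network$friction
  noise_sd <- sqrt(2 * network$kT * dt / network$friction)
  n_frames <- n_steps %/% stride
  frames <- array(NA_real_, dim = c(n_frames, n, 3))
  f_at <- 0L

  with_seed(seed, {
    for (step in seq_len(n_steps)) {
      force <- matrix(0, n, 3)
      if (nrow(sp)) {
        dvec <- pos[sp$i, , drop = FALSE] - pos[sp$j, , drop = FALSE]
        d <- sqrt(rowSums(dvec^2))
        fmag <- -sp$k * (d - sp$b0) / d
        fvec <- dvec * fmag
        agg <- rowsum(rbind(fvec, -fvec), group = grp)
        force[as.integer(rownames(agg)), ] <- agg
      }
      if (!is.null(tether)) {
        force[tether$idx, ] <- force[tether$idx, ] -
          tether$k * (pos[tether$idx, , drop = FALSE] - tether$ref)
      }
      disp <- mob_dt * force
      if (noise_sd > 0) {
        disp <- disp + matrix(rnorm(3L * n, sd = noise_sd), n, 3)
      }
      if (length(frozen)) disp[frozen, ] <- 0
      pos <- pos + disp
      if (anyNA(pos) || any(is.infinite(pos))) {
        abort("integration diverged to non-finite coordinates")
      }
      if (step %% stride == 0L) {
        f_at <- f_at + 1L
        frames[f_at, , ] <- pos
      }
    }
  })

  structure(
    list(frames = frames, dt = dt, stride = as.integer(stride),
         seed = as.integer(seed),
         times = dt * stride * seq_len(n_frames)),
    class = "toy_trajectory"
  )
}

#' @export
print.toy_trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat("<toy_trajectory> ", d[1], " frames x ", d[2], " beads (dt = ", x$dt,
      " ps, stride = ", x$stride, ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `toy_trajectory` or a frames array (`n_frames x n_sites x 3`).
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  dim(traj_frames(traj))[1]
}

# Accept either a toy_trajectory or a bare frames array everywhere.
traj_frames <- function(traj) {
  if (inherits(traj, "toy_trajectory")) return(traj$frames)
  if (is.array(traj) && length(dim(traj)) == 3 && dim(traj)[3] == 3) return(traj)
  abort("expected a toy_trajectory or an n_frames x n_sites x 3 array")
}
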