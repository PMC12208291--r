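# Per-pair distance series and window statistics from trajectories of any
# provenance (toy simulator or MD-derived frame arrays).

#' Per-pair distance series
#'
#' @param traj a `toy_trajectory` or frames array (`n_frames x n_sites x 3`).
#' @param pairs data frame with site-index columns `i` and `j`.
#' @param box optional length-3 box vector (nm) applying the minimum-image
#'   convention to each displacement component — for trajectories from
#'   periodic MD input. Toy trajectories are non-periodic; leave `NULL`.
#' @return long tibble: `i`, `j`, `frame`, `distance` (nm).
#' @export
pair_distance_series <- function(traj, pairs, box = NULL) {
  frames <- traj_frames(traj)
  pairs <- as_tibble(pairs)
  purrr::pmap_dfr(pairs[, c("i", "j")], function(i, j) {
    dvec <- frames[, i, , drop = FALSE] - frames[, j, , drop = FALSE]
    if (!is.null(box)) {
      stopifnot(length(box) == 3, all(box > 0))
      for (c in 1:3) {
        dvec[, , c] <- dvec[, , c] - box[c] * round(dvec[, , c] / box[c])
      }
    }
    d <- sqrt(rowSums(dvec^2, dims = 1))
    tibble(i = i, j = j, frame = seq_len(dim(frames)[1]), distance = d)
  })
}

#' Per-pair distance means and variances over a trajectory window
#'
#' Computes the mean and the population variance (denominator `n`, treating
#' the window as the distribution itself) of each pair distance over the
#' requested frame window. With `block` set, the window is split into that
#' many equal contiguous blocks (remainder frames dropped from the tail) and
#' the standard error of the mean is estimated from the spread of block
#' means — the standard block-averaging error estimate for correlated series.
#'
#' @param traj a `toy_trajectory` or frames array.
#' @param pairs data frame with columns `i`, `j`.
#' @param window integer vector of frame indices (default: all frames).
#' @param block number of blocks for block-averaged errors, or `NULL`.
#' @param box optional periodic box (see [pair_distance_series()]).
#' @return tibble: `i`, `j`, `mean` (nm), `var` (nm^2), `n_frames`, and
#'   `se_block` when `block` is given.
#' @examples
#' frames <- array(0, c(3, 2, 3)); frames[, 2, 1] <- c(1, 2, 3)
#' pair_distance_stats(frames, data.frame(i = 1, j = 2))
#' @export
pair_distance_stats <- function(traj, pairs, window = NULL, block = NULL,
                                box = NULL) {
  frames <- traj_frames(traj)
  nf <- dim(frames)[1]
  window <- window %||% seq_len(nf)
  if (length(window) == 0) abort("window is empty")
  if (min(window) < 1 || max(window) > nf) {
    abort(sprintf("window [%d, %d] outside trajectory (1..%d)",
                  min(window), max(window), nf))
  }
  ns <- dim(frames)[2]
  pairs <- as_tibble(pairs)
  if (any(pairs$i < 1 | pairs$i > ns | pairs$j < 1 | pairs$j > ns)) {
    abort("pair site index outside trajectory")
  }
  sub <- frames[window, , , drop = FALSE]
  out <- purrr::pmap_dfr(pairs[, c("i", "j")], function(i, j) {
    dvec <- sub[, i, , drop = FALSE] - sub[, j, , drop = FALSE]
    if (!is.null(box)) {
      stopifnot(length(box) == 3, all(box > 0))
      for (c in 1:3) {
        dvec[, , c] <- dvec[, , c] - box[c] * round(dvec[, , c] / box[c])
      }
    }
    d <- sqrt(rowSums(dvec^2, dims = 1))
    n <- length(d)
    res <- tibble(i = i, j = j, mean = mean(d),
                  var = sum((d - mean(d))^2) / n, n_frames = n)
    if (!is.null(block)) {
      if (block < 2) abort("block must be >= 2")
      per <- n %/% block
      if (per < 1) abort("window too short for the requested block count")
      used <- d[seq_len(per * block)]
      bm <- colMeans(matrix(used, nrow = per))
      res$se_block <- stats::sd(bm) / sqrt(block)
    }
    res
  })
  out
}

#' End-to-end distance series of a chain
#'
#' Per-frame distance between two designated terminal sites of a chain — the
#' standard compactness metric for short disordered segments (less
#' error-prone than the radius of gyration at these lengths).
#'
#' @param traj a `toy_trajectory` or frames array.
#' @param sites site label tibble (one row per trajectory site) with a
#'   `chain_id` column.
#' @param chain chain identifier.
#' @param first,last site row indices of the chain termini.
#' @return tibble: `frame`, `distance` (nm).
#' @export
end_to_end_series <- function(traj, sites, chain, first, last) {
  sites <- as_tibble(sites)
  chain_col <- col_or(sites, "chain_id", rep("A", nrow(sites)))
  for (s in c(first, last)) {
    if (s < 1 || s > nrow(sites) || chain_col[s] != chain) {
      abort(sprintf("site %d does not belong to chain %s", s, chain))
    }
  }
  ser <- pair_distance_series(traj, tibble(i = first, j = last))
  tibble(frame = ser$frame, distance = ser$distance)
}
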