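# Shared fixtures, built in code at test time.

# Two-site dimer unit sitting at lattice radius ~11 nm (axis = z).
toy_dimer <- function() {
  tibble::tibble(
    x = c(0.3, 0.1), y = c(11, 11.2), z = c(0, 4),
    chain_id = c("A", "A"), residue_index = c(1L, 2L),
    monomer_id = c("alpha", "beta"), region = c("body", "body"))
}

# A dimer unit with n sites spread along z.
toy_dimer_n <- function(n) {
  tibble::tibble(
    x = rep(0.3, n), y = 11 + 0.2 * sin(seq_len(n)),
    z = seq(0, 4, length.out = n),
    chain_id = "A", residue_index = seq_len(n),
    monomer_id = rep(c("alpha", "beta"), each = ceiling(n / 2))[seq_len(n)],
    region = "body")
}

# Self-avoiding-ish random coil of n backbone sites.
random_coil <- function(n, seed = 1) {
  withr::with_seed(seed, {
    steps <- cbind(runif(n, 0.25, 0.4), rnorm(n, 0, 0.15), rnorm(n, 0, 0.15))
    xyz <- apply(steps, 2, cumsum)
    tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   chain_id = "A", residue_index = seq_len(n))
  })
}

# Network of n_pairs independent harmonic pairs with per-pair constants k,
# rest length b0 (beads 2p-1 and 2p form pair p).
isolated_pairs_network <- function(k, b0 = 5, friction = 50, kT = 2.494) {
  n_pairs <- length(k)
  pos <- matrix(0, 2 * n_pairs, 3)
  pos[seq(2, 2 * n_pairs, 2), 1] <- b0
  springs <- tibble::tibble(
    i = seq(1, 2 * n_pairs, 2), j = seq(2, 2 * n_pairs, 2), b0 = b0, k = k)
  bead_network(pos, springs, friction = friction, kT = kT)
}

# Labeled residue cloud for contact tests: n_res residues x sites_per sites,
# random labels over chains/dimers/protofilaments.
labeled_cloud <- function(n_res, sites_per = 2, seed = 1, spread = 1.2) {
  withr::with_seed(seed, {
    centers <- matrix(runif(n_res * 3, 0, spread), ncol = 3)
    purrr::map_dfr(seq_len(n_res), function(r) {
      tibble::tibble(
        x = centers[r, 1] + runif(sites_per, -0.1, 0.1),
        y = centers[r, 2] + runif(sites_per, -0.1, 0.1),
        z = centers[r, 3] + runif(sites_per, -0.1, 0.1),
        chain_id = sample(c("A", "B"), 1),
        residue_index = r,
        region = sample(c("body", "tail"), 1, prob = c(0.8, 0.2)),
        dimer_id = sample(1:3, 1),
        pf_index = sample(1:3, 1))
    })
  })
}

# Brute-force residue-contact oracle: all residue pairs, min site distance.
brute_force_contacts <- function(frame, cutoff, min_sep) {
  res <- unique(frame[, c("chain_id", "residue_index")])
  out <- list()
  for (a in seq_len(nrow(res) - 1)) {
    for (b in (a + 1):nrow(res)) {
      sa <- frame[frame$chain_id == res$chain_id[a] &
                    frame$residue_index == res$residue_index[a], ]
      sb <- frame[frame$chain_id == res$chain_id[b] &
                    frame$residue_index == res$residue_index[b], ]
      dmin <- Inf
      for (p in seq_len(nrow(sa))) {
        for (q in seq_len(nrow(sb))) {
          dmin <- min(dmin, sqrt((sa$x[p] - sb$x[q])^2 +
                                   (sa$y[p] - sb$y[q])^2 +
                                   (sa$z[p] - sb$z[q])^2))
        }
      }
      same <- res$chain_id[a] == res$chain_id[b]
      sep_ok <- !same ||
        abs(res$residue_index[a] - res$residue_index[b]) > min_sep
      if (dmin < cutoff && sep_ok) {
        out[[length(out) + 1]] <- data.frame(
          chain_a = res$chain_id[a], res_a = res$residue_index[a],
          chain_b = res$chain_id[b], res_b = res$residue_index[b])
      }
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# Canonical unordered residue-pair keys, invariant to column assignment.
pair_keys <- function(df) {
  a <- sprintf("%s:%04d", df$chain_a, df$res_a)
  b <- sprintf("%s:%04d", df$chain_b, df$res_b)
  sort(paste(pmin(a, b), pmax(a, b), sep = "|"))
}

# Brute-force survival oracle: scan runs, merging gaps <= tol.
brute_force_survival <- function(presence, tol) {
  p <- as.logical(presence)
  durations <- integer(0)
  i <- 1
  n <- length(p)
  while (i <= n) {
    if (!p[i]) { i <- i + 1; next }
    start <- i
    last_true <- i
    j <- i + 1
    while (j <= n) {
      if (p[j]) {
        last_true <- j; j <- j + 1
      } else {
        gap_end <- j
        while (gap_end <= n && !p[gap_end]) gap_end <- gap_end + 1
        if (gap_end <= n && (gap_end - j) <= tol) {
          j <- gap_end
        } else break
      }
    }
    durations <- c(durations, last_true - start + 1)
    i <- last_true + 1
  }
  durations
}
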