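# Residue-level contact detection, classification and survival analysis.

#' Residue contacts in a labeled frame
#'
#' Two residues are in contact when any pair of their sites lies closer than
#' `cutoff` (minimum inter-site distance) and, when on the same chain, their
#' residue indices differ by more than `min_sep`. Contacts are classified
#' from the site labels into mutually exclusive classes, with tail contacts
#' taking precedence: `tail-self` (both residues in a tail region of the
#' same chain), `tail-body-intradimer`, `tail-body-interdimer`, then
#' body-body `intradimer`, `interdimer` (same protofilament),
#' `interprotofilament`, and `seam` (the first/last protofilament pair of
#' the lattice).
#'
#' @param frame labeled site tibble with `x`, `y`, `z` (nm) and label
#'   columns `chain_id`, `residue_index`; classification additionally uses
#'   `region` ("body"/"tail"), `dimer_id`, `pf_index` when present.
#' @param cutoff contact distance, nm (default 0.7).
#' @param min_sep same-chain sequence-separation threshold (default 2:
#'   contact requires `|i - j| > 2`).
#' @param n_pf number of protofilaments in the lattice (used to tag seam
#'   contacts); default: `max(pf_index)` when available.
#' @return tibble of contacts: `chain_a`, `res_a`, `chain_b`, `res_b`,
#'   `min_distance`, `class`.
#' @export
residue_contacts <- function(frame, cutoff = 0.7, min_sep = 2L, n_pf = NULL) {
  frame <- as_tibble(frame)
  if (!all(c("chain_id", "residue_index") %in% names(frame))) {
    abort("sites must carry chain_id and residue_index labels")
  }
  key <- paste(frame$chain_id, frame$residue_index, sep = "\r")
  res <- frame |>
    dplyr::mutate(.key = key) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      chain = .data$chain_id[1], resid = .data$residue_index[1],
      region = if ("region" %in% names(frame)) .data$region[1] else "body",
      dimer = if ("dimer_id" %in% names(frame)) .data$dimer_id[1] else NA,
      pf = if ("pf_index" %in% names(frame)) .data$pf_index[1] else NA,
      .groups = "drop")

  # minimum inter-site distance between residues via site-level pairs
  dm <- as.matrix(stats::dist(site_xyz(frame)))
  grp <- match(key, res$.key)
  nr <- nrow(res)
  min_d <- matrix(Inf, nr, nr)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  ga <- grp[idx[, 1]]; gb <- grp[idx[, 2]]
  off <- ga != gb
  ga <- ga[off]; gb <- gb[off]
  dv <- dm[idx][off]
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  flat <- (hi - 1L) * nr + lo
  agg <- tapply(dv, flat, min)
  min_d[as.integer(names(agg))] <- agg

  pairs <- which(upper.tri(min_d) & min_d < cutoff, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(tibble(chain_a = character(), res_a = integer(),
                  chain_b = character(), res_b = integer(),
                  min_distance = numeric(), class = character()))
  }
  a <- pairs[, 1]; b <- pairs[, 2]
  same_chain <- res$chain[a] == res$chain[b]
  sep_ok <- !same_chain | abs(res$resid[a] - res$resid[b]) > min_sep
  a <- a[sep_ok]; b <- b[sep_ok]

  if (is.null(n_pf) && !all(is.na(res$pf))) n_pf <- max(res$pf, na.rm = TRUE)
  cls <- classify_contact(
    region_a = res$region[a], region_b = res$region[b],
    chain_a = res$chain[a], chain_b = res$chain[b],
    dimer_a = res$dimer[a], dimer_b = res$dimer[b],
    pf_a = res$pf[a], pf_b = res$pf[b], n_pf = n_pf)

  tibble(chain_a = res$chain[a], res_a = res$resid[a],
         chain_b = res$chain[b], res_b = res$resid[b],
         min_distance = min_d[cbind(a, b)], class = cls)
}

# Mutually exclusive contact classes; tail classes take precedence.
classify_contact <- function(region_a, region_b, chain_a, chain_b,
                             dimer_a, dimer_b, pf_a, pf_b, n_pf) {
  n_pf <- n_pf %||% -1L  # sentinel: no lattice, nothing tags as seam
  tail_a <- region_a == "tail"
  tail_b <- region_b == "tail"
  same_dimer <- !is.na(dimer_a) & !is.na(dimer_b) & dimer_a == dimer_b
  same_pf <- !is.na(pf_a) & !is.na(pf_b) & pf_a == pf_b
  seam <- !is.na(pf_a) & !is.na(pf_b) &
    pmin(pf_a, pf_b) == 1 & pmax(pf_a, pf_b) == n_pf & pf_a != pf_b

  dplyr::case_when(
    tail_a & tail_b ~ "tail-self",
    (tail_a | tail_b) & same_dimer ~ "tail-body-intradimer",
    tail_a | tail_b ~ "tail-body-interdimer",
    same_dimer ~ "intradimer",
    same_pf ~ "interdimer",
    seam ~ "seam",
    !is.na(pf_a) & !is.na(pf_b) & pf_a != pf_b ~ "interprotofilament",
    TRUE ~ "intradimer"
  )
}

#' Contact survival durations
#'
#' Converts a per-frame presence series of a contact into the durations of
#' its maximal survival runs, merging interruptions of at most
#' `gap_tolerance` frames into the surrounding run.
#'
#' @param presence logical (or 0/1) vector of per-frame contact presence.
#' @param gap_tolerance maximum gap length (frames) bridged inside a run
#'   (default 0).
#' @return integer vector of run durations in frames (gaps bridged inside a
#'   run count toward its duration).
#' @examples
#' contact_survival(c(1, 1, 1, 0, 0, 1, 1, 0))            # 3, 2
#' contact_survival(c(1, 1, 1, 0, 0, 1, 1, 0), gap = 2)   # 7
#' @export
contact_survival <- function(presence, gap_tolerance = 0L) {
  p <- as.logical(presence)
  if (length(p) == 0 || !any(p)) return(integer(0))
  r <- rle(p)
  # bridge interior FALSE runs no longer than the tolerance
  interior <- !r$values & seq_along(r$values) > 1 &
    seq_along(r$values) < length(r$values)
  r$values[interior & r$lengths <= gap_tolerance] <- TRUE
  r2 <- rle(inverse.rle(r))
  as.integer(r2$lengths[r2$values])
}
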