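# Table serialization (spring tables, distance stats as TSV with header
# comments), GROMACS-dialect elastic-bond topology, nonbonded rescaling,
# and the toy trajectory dump. All writers are byte-deterministic: stable
# ordering and fixed float formatting.

write_lines_det <- function(lines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read/write spring tables and distance statistics as TSV
#'
#' Plain tab-separated files with `#`-prefixed header comments carrying the
#' iteration index (spring tables) or the source label and window (distance
#' stats). Rows are ordered by `(i, j)` ascending and floats printed with
#' fixed precision, so repeated writes are byte-identical.
#'
#' @param springs spring table (`i`, `j`, `d0`, `k`).
#' @param stats distance statistics (`i`, `j`, `mean`, `var`).
#' @param path file path.
#' @param source,window label strings stored in the stats header.
#' @return the path (writers, invisibly) or the parsed tibble (readers).
#' @name table-io
NULL

#' @rdname table-io
#' @export
write_spring_table <- function(springs, path) {
  springs <- dplyr::arrange(as_tibble(springs), .data$i, .data$j)
  it <- attr(springs, "iteration") %||% 0L
  lines <- c(
    sprintf("# spring table, iteration %d", it),
    "# i\tj\td0_nm\tk_kJ_mol_nm2",
    sprintf("%d\t%d\t%.6f\t%.6f", springs$i, springs$j, springs$d0, springs$k))
  write_lines_det(lines, path)
}

#' @rdname table-io
#' @export
read_spring_table <- function(path) {
  lines <- readLines(path)
  it <- 0L
  m <- regmatches(lines[1], regexec("iteration ([0-9]+)", lines[1]))[[1]]
  if (length(m) == 2) it <- as.integer(m[2])
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  out <- tibble(
    i = as.integer(vapply(parts, `[[`, "", 1)),
    j = as.integer(vapply(parts, `[[`, "", 2)),
    d0 = as.numeric(vapply(parts, `[[`, "", 3)),
    k = as.numeric(vapply(parts, `[[`, "", 4)))
  attr(out, "iteration") <- it
  out
}

#' @rdname table-io
#' @export
write_distance_stats <- function(stats, path, source = "target",
                                 window = "all") {
  stats <- dplyr::arrange(as_tibble(stats), .data$i, .data$j)
  lines <- c(
    sprintf("# distance stats, source %s, window %s", source, window),
    "# i\tj\tmean_nm\tvar_nm2",
    sprintf("%d\t%d\t%.6f\t%.8f", stats$i, stats$j, stats$mean, stats$var))
  write_lines_det(lines, path)
}

#' @rdname table-io
#' @export
read_distance_stats <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  tibble(
    i = as.integer(vapply(parts, `[[`, "", 1)),
    j = as.integer(vapply(parts, `[[`, "", 2)),
    mean = as.numeric(vapply(parts, `[[`, "", 3)),
    var = as.numeric(vapply(parts, `[[`, "", 4)))
}

#' Write a spring table as a GROMACS elastic-bond topology fragment
#'
#' Emits a `[ bonds ]` section, one line per spring in fixed column order
#' `(i, j, func, b0, k)` with 1-based indices and `(i, j)`-ascending
#' ordering. The default function code 1 is the plain harmonic bond; Martini
#' elastic networks often use code 6, the harmonic bond that generates no
#' nonbonded exclusions — exposed via `function_type` since conventions
#' differ.
#'
#' @param springs non-empty spring table (`i`, `j`, `d0`, `k`).
#' @param path output path.
#' @param function_type GROMACS bond function code (default 6).
#' @param molecule_size optional declared site count; indices beyond it are
#'   an error.
#' @return the path, invisibly.
#' @export
write_elastic_itp <- function(springs, path, function_type = 6L,
                              molecule_size = NULL) {
  springs <- as_tibble(springs)
  if (nrow(springs) == 0) abort("refusing to write an empty elastic network")
  if (!is.null(molecule_size) &&
      max(springs$i, springs$j) > molecule_size) {
    abort("spring index exceeds declared molecule size")
  }
  springs <- dplyr::arrange(springs, .data$i, .data$j)
  it <- attr(springs, "iteration") %||% 0L
  lines <- c(
    sprintf("; elastic network bonds, iteration %d", it),
    "[ bonds ]",
    ";   i      j func       b0            k",
    sprintf("%6d %6d %4d %10.6f %12.4f",
            springs$i, springs$j, function_type, springs$d0, springs$k))
  write_lines_det(lines, path)
}

#' Parse an elastic-bond topology fragment back into a spring table
#'
#' @param path an ITP file written by [write_elastic_itp()].
#' @return spring table tibble (`i`, `j`, `d0`, `k`).
#' @export
read_elastic_itp <- function(path) {
  lines <- readLines(path)
  body <- grep("^\\s*[0-9]", lines, value = TRUE)
  parts <- strsplit(trimws(body), "\\s+")
  tibble(
    i = as.integer(vapply(parts, `[[`, "", 1)),
    j = as.integer(vapply(parts, `[[`, "", 2)),
    d0 = as.numeric(vapply(parts, `[[`, "", 4)),
    k = as.numeric(vapply(parts, `[[`, "", 5)))
}

#' Scale protein-water interaction strengths in a nonbonded parameter table
#'
#' Multiplies the interaction-strength (epsilon, last numeric field) of
#' every record in a `[ nonbond_params ]` section that pairs a water bead
#' with a non-water (protein) bead by `factor`, leaving every other line
#' byte-identical. Up-scaling protein-water interactions by a few percent is
#' the standard remedy for coarse-grained force fields over-compacting
#' disordered regions.
#'
#' @param topology_text character vector of topology lines.
#' @param factor positive scale factor (e.g. 1.06 for 6% up-scaling).
#' @param water_beads bead type names treated as water (default `W`, `SW`,
#'   `TW`).
#' @return modified character vector of lines.
#' @examples
#' top <- c("[ nonbond_params ]", " P1   W  1 0.470 0.500")
#' scale_protein_water(top, 1.06)
#' @export
scale_protein_water <- function(topology_text, factor,
                                water_beads = c("W", "SW", "TW")) {
  if (factor <= 0) abort("factor must be > 0")
  lines <- topology_text
  section <- ""
  changed <- 0L
  for (idx in seq_along(lines)) {
    ln <- lines[idx]
    sec <- regmatches(ln, regexec("^\\s*\\[\\s*([^]]+?)\\s*\\]", ln))[[1]]
    if (length(sec) == 2) { section <- sec[2]; next }
    if (section != "nonbond_params") next
    stripped <- sub(";.*$", "", ln)
    tok <- strsplit(trimws(stripped), "\\s+")[[1]]
    if (length(tok) < 5) next
    a_water <- tok[1] %in% water_beads
    b_water <- tok[2] %in% water_beads
    if (xor(a_water, b_water)) {
      old <- tok[length(tok)]
      dec <- if (grepl("\\.", old)) nchar(sub("^[^.]*\\.", "", old)) else 0
      new <- sprintf(paste0("%.", dec, "f"), as.numeric(old) * factor)
      # replace only the final numeric token, preserving spacing
      lines[idx] <- sub(paste0(old, "(\\s*(;.*)?)$"), paste0(new, "\\1"), ln)
      changed <- changed + 1L
    }
  }
  if (changed == 0L) {
    abort("no protein-water records found in [ nonbond_params ]; nothing written")
  }
  lines
}

#' Dump / load a toy trajectory as plain text
#'
#' Writes the frame array as a TSV (`frame`, `site`, `x`, `y`, `z`) plus a
#' JSON metadata sidecar (`dt`, `stride`, `seed`, dimensions), and reads the
#' pair back into a `toy_trajectory`.
#'
#' @param traj a `toy_trajectory`.
#' @param dir output directory (created if missing).
#' @return `write_trajectory`: the directory, invisibly;
#'   `read_trajectory`: a `toy_trajectory`.
#' @name trajectory-io
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "toy_trajectory"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(traj$frames)
  idx <- expand.grid(site = seq_len(d[2]), frame = seq_len(d[1]))
  lines <- c("frame\tsite\tx\ty\tz",
             sprintf("%d\t%d\t%.9g\t%.9g\t%.9g", idx$frame, idx$site,
                     traj$frames[cbind(idx$frame, idx$site, 1)],
                     traj$frames[cbind(idx$frame, idx$site, 2)],
                     traj$frames[cbind(idx$frame, idx$site, 3)]))
  write_lines_det(lines, file.path(dir, "frames.tsv"))
  jsonlite::write_json(
    list(dt = traj$dt, stride = traj$stride, seed = traj$seed,
         n_frames = d[1], n_sites = d[2]),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname trajectory-io
#' @export
read_trajectory <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  tab <- utils::read.delim(file.path(dir, "frames.tsv"), sep = "\t")
  frames <- array(NA_real_, c(meta$n_frames, meta$n_sites, 3))
  frames[cbind(tab$frame, tab$site, 1)] <- tab$x
  frames[cbind(tab$frame, tab$site, 2)] <- tab$y
  frames[cbind(tab$frame, tab$site, 3)] <- tab$z
  structure(
    list(frames = frames, dt = meta$dt, stride = meta$stride,
         seed = meta$seed, times = meta$dt * meta$stride * seq_len(meta$n_frames)),
    class = "toy_trajectory")
}
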