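# Structure readers/writers. Coordinates are nm internally; PDB files are
# Angstrom on disk and converted on read/write. Lattice label conventions on
# write: one chain letter per protofilament, residue number offset by layer
# (resno = residue_index + (layer_index - 1) * layer_resid_offset), segment
# id "Lnnn" carrying the layer index (PDB only; GRO has no segment field, so
# the residue-number offset alone encodes the layer there).

#' Read a structure file into a site tibble
#'
#' Supports PDB (via bio3d) and GRO (fixed-width reader). Coordinates are
#' returned in nm.
#'
#' @param path file path ending in `.pdb` or `.gro`.
#' @return tibble with `x`, `y`, `z` (nm), `chain_id`, `residue_index`,
#'   `residue_name`, `site_name`, and `segid` (PDB only).
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    tibble(
      x = at$x / 10, y = at$y / 10, z = at$z / 10,
      chain_id = ifelse(is.na(at$chain), "A", at$chain),
      residue_index = at$resno,
      residue_name = at$resid,
      site_name = at$elety,
      segid = ifelse(is.na(at$segid), "", at$segid))
  } else if (ext == "gro") {
    read_gro(path)
  } else {
    abort("unsupported structure format: use .pdb or .gro")
  }
}

#' Write sites or a lattice assembly to PDB or GRO
#'
#' @param x a site tibble (columns `x`, `y`, `z` in nm plus optional labels)
#'   or a `lattice_assembly`.
#' @param path output path ending in `.pdb` or `.gro`.
#' @param layer_resid_offset residue-number stride per layer when writing an
#'   assembly (default 1000); must exceed the largest residue index in the
#'   unit.
#' @return the path, invisibly.
#' @export
write_structure <- function(x, path, layer_resid_offset = 1000L) {
  sites <- if (inherits(x, "lattice_assembly")) {
    assembly_to_sites(x, layer_resid_offset)
  } else {
    as_tibble(x)
  }
  n <- nrow(sites)
  chain <- as.character(col_or(sites, "chain_id", rep("A", n)))
  resno <- as.integer(col_or(sites, "residue_index", seq_len(n)))
  resid <- as.character(col_or(sites, "residue_name", rep("BEA", n)))
  elety <- as.character(col_or(sites, "site_name", rep("BB", n)))
  segid <- as.character(col_or(sites, "segid", rep("", n)))

  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") {
    pdb_xyz <- as.numeric(t(site_xyz(sites) * 10))
    bio3d::write.pdb(file = path, xyz = pdb_xyz, resno = resno,
                     resid = resid, chain = chain, elety = elety,
                     segid = segid)
  } else if (ext == "gro") {
    write_gro(sites, path, resno = resno, resid = resid, elety = elety)
  } else {
    abort("unsupported structure format: use .pdb or .gro")
  }
  invisible(path)
}

# Flatten a lattice assembly into writable sites with the label conventions
# documented above.
assembly_to_sites <- function(assembly, layer_resid_offset = 1000L) {
  s <- assembly$sites
  if ("residue_index" %in% names(s) &&
      max(s$residue_index) >= layer_resid_offset) {
    abort("layer_resid_offset must exceed the largest unit residue index")
  }
  chain_pool <- c(LETTERS, letters, as.character(0:9))
  if (max(s$pf_index) > length(chain_pool)) {
    abort("too many protofilaments for single-character chain ids")
  }
  base_res <- col_or(s, "residue_index", seq_len(nrow(s)))
  tibble(
    x = s$x, y = s$y, z = s$z,
    chain_id = chain_pool[s$pf_index],
    residue_index = as.integer(base_res + (s$layer_index - 1L) * layer_resid_offset),
    residue_name = substr(toupper(col_or(s, "monomer_id", rep("BEA", nrow(s)))), 1, 3),
    site_name = col_or(s, "site_name", rep("BB", nrow(s))),
    segid = sprintf("L%03d", s$layer_index))
}

# -- GRO fixed-width format ---------------------------------------------
# Columns: resno (i5), resname (a5), atomname (a5), atom number (i5),
# x y z in nm (f8.3 each). Hand-written because no installed R package
# reads or writes GRO.

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort("malformed GRO file: line 2 is not an atom count")
  if (length(lines) < 2 + n + 1) {
    abort(sprintf("malformed GRO file: expected %d atom lines", n))
  }
  al <- lines[3:(2 + n)]
  parse_num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (any(is.na(v))) {
      abort(sprintf("malformed GRO record at line %d: bad %s field",
                    ln[which(is.na(v))[1]], what))
    }
    v
  }
  ln <- 3:(2 + n)
  tibble(
    residue_index = as.integer(parse_num(substr(al, 1, 5), "resno", ln)),
    residue_name = trimws(substr(al, 6, 10)),
    site_name = trimws(substr(al, 11, 15)),
    x = parse_num(substr(al, 21, 28), "x", ln),
    y = parse_num(substr(al, 29, 36), "y", ln),
    z = parse_num(substr(al, 37, 44), "z", ln),
    chain_id = "A")
}

write_gro <- function(sites, path, resno, resid, elety) {
  n <- nrow(sites)
  # GRO fields are 5 columns wide; wrap indices as GROMACS does
  lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                   resno %% 100000L, substr(resid, 1, 5),
                   substr(elety, 1, 5), seq_len(n) %% 100000L,
                   sites$x, sites$y, sites$z)
  box <- apply(site_xyz(sites), 2, function(v) max(v) - min(v) + 1)
  con <- file(path, "wb")  # binary mode: fixed newline, byte-deterministic
  on.exit(close(con))
  writeLines(c("generated by fmnet", sprintf("%5d", n), lines,
               sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3])),
             con, sep = "\n")
  invisible(path)
}
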