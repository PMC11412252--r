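#' Read the C-alpha trace of a protein domain
#'
#' Extracts an ordered C-alpha trace for one chain (optionally restricted to a
#' residue range in author numbering) from a PDB file. The trace is the only
#' structural information the elastic-network analysis consumes: connectivity
#' is decided downstream purely by the distance cutoff, so chain breaks are not
#' special-cased here. Only the first model of a multi-model file is used.
#'
#' Alternate locations are resolved to the highest-occupancy C-alpha (ties keep
#' the first encountered); residues lacking a C-alpha are skipped with a
#' warning. Insertion codes are preserved in the residue mapping.
#'
#' @param path Path to a PDB file.
#' @param chain_id Single chain identifier (e.g. `"A"`).
#' @param range Either `"all"` or an integer vector `c(from, to)` of author
#'   residue numbers (inclusive).
#' @param domain_id Label stored with the result; defaults to the file name.
#'
#' @return A tibble of class `dyn_domain` with one row per residue and columns
#'   `local_index` (1..n, the coordinate system used by every downstream
#'   function), `author_number`, `ins_code`, `chain`, `x`, `y`, `z` (angstrom).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' dom <- synth_domain(n = 40, architecture = "helix_bundle", seed = 1)
#' write_domain_pdb(dom, pdb)
#' read_domain(pdb, chain_id = "A")
#' @export
read_domain <- function(path, chain_id, range = "all", domain_id = NULL) {
  stopifnot(length(chain_id) == 1L)
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$chain %in% chain_id & atoms$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    abort(paste0("chain '", chain_id, "' not found in ", path))
  }
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]

  # resolve altlocs: per residue keep the highest-occupancy CA, first on ties
  ins <- ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert)
  key <- paste(ca$resno, ins, sep = "|")
  occ <- ifelse(is.na(ca$o), 1, ca$o)
  keep <- !logical(nrow(ca))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  ca <- ca[keep, , drop = FALSE]
  ins <- ins[keep]

  # residues present in the chain but with no CA atom
  all_key <- unique(paste(atoms$resno,
                          ifelse(is.na(atoms$insert) | atoms$insert == "", "",
                                 atoms$insert), sep = "|"))
  n_missing <- length(setdiff(all_key, paste(ca$resno, ins, sep = "|")))

  if (!identical(range, "all")) {
    stopifnot(is.numeric(range), length(range) == 2L)
    in_range <- ca$resno >= range[1] & ca$resno <= range[2]
    ca <- ca[in_range, , drop = FALSE]
    ins <- ins[in_range]
  }
  if (n_missing > 0L) {
    warn(paste0(n_missing, " residue(s) without a C-alpha atom were skipped"))
  }
  if (nrow(ca) < 2L) {
    abort("fewer than 2 C-alpha atoms in the requested range")
  }

  out <- tibble(
    local_index   = seq_len(nrow(ca)),
    author_number = as.integer(ca$resno),
    ins_code      = ins,
    chain         = chain_id,
    x = ca$x, y = ca$y, z = ca$z
  )
  new_dyn_domain(out, domain_id %||% basename(path))
}

new_dyn_domain <- function(tbl, domain_id) {
  attr(tbl, "domain_id") <- domain_id
  class(tbl) <- unique(c("dyn_domain", class(tbl)))
  validate_domain(tbl)
  tbl
}

validate_domain <- function(domain) {
  stopifnot(all(c("local_index", "x", "y", "z") %in% names(domain)))
  n <- nrow(domain)
  if (n < 2L) abort("a domain needs at least 2 residues")
  if (!identical(as.integer(domain$local_index), seq_len(n))) {
    abort("local_index must be 1..n, strictly increasing and gap-free")
  }
  if (anyNA(domain[, c("x", "y", "z")])) abort("missing coordinates")
  invisible(domain)
}

#' Domain identifier of a `dyn_domain`
#' @param domain A `dyn_domain` tibble from [read_domain()] or [synth_domain()].
#' @return A character scalar.
#' @export
domain_id <- function(domain) attr(domain, "domain_id") %||% "domain"

#' C-alpha coordinates as a numeric matrix
#' @inheritParams domain_id
#' @return An n x 3 matrix of coordinates in angstrom.
#' @export
domain_coords <- function(domain) {
  as.matrix(domain[, c("x", "y", "z")])
}

#' Residue index mapping table
#'
#' The bijection between the domain-local 1-based index and the author
#' numbering (with insertion codes) of the source structure.
#'
#' @inheritParams domain_id
#' @return A tibble with `local_index`, `author_number`, `ins_code`.
#' @export
domain_map <- function(domain) {
  if (!all(c("author_number", "ins_code") %in% names(domain))) {
    return(tibble(local_index = domain$local_index,
                  author_number = domain$local_index, ins_code = ""))
  }
  as_tibble(domain[, c("local_index", "author_number", "ins_code")])
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' Writes one ATOM record per residue (C-alpha only), suitable as a fixture or
#' for round-tripping through [read_domain()]. Coordinates are written with
#' three decimals, the PDB fixed-format precision.
#'
#' @inheritParams domain_id
#' @param path Output file path.
#' @param chain_id Chain identifier to write (default `"A"`).
#' @return `path`, invisibly.
#' @export
write_domain_pdb <- function(domain, path, chain_id = "A") {
  validate_domain(domain)
  resno <- if ("author_number" %in% names(domain)) domain$author_number else domain$local_index
  ins <- if ("ins_code" %in% names(domain)) {
    ifelse(domain$ins_code == "", " ", substr(domain$ins_code, 1, 1))
  } else " "
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    domain$local_index, chain_id, resno, ins, domain$x, domain$y, domain$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a domain from bare coordinates
#'
#' Convenience constructor used by the synthetic generator and by tests.
#'
#' @param coords An n x 3 numeric matrix of C-alpha coordinates (angstrom).
#' @param domain_id Label for the domain.
#' @return A `dyn_domain` tibble.
#' @export
as_domain <- function(coords, domain_id = "domain") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 2L)
  n <- nrow(coords)
  new_dyn_domain(
    tibble(local_index = seq_len(n), author_number = seq_len(n),
           ins_code = "", chain = "A",
           x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    domain_id
  )
}
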