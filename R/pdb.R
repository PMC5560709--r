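## PDB is a fixed-column format; no PDB reader ships with the installed R
## stack, so a minimal column-exact parser lives here. Only the fields the
## coarse-graining pipeline needs are extracted.

.pdb_field <- function(lines, from, to) substr(lines, from, to)

.element_from_record <- function(lines) {
  el <- toupper(trimws(.pdb_field(lines, 77, 78)))
  ## fall back on the atom-name column when the element field is blank:
  ## column 13 is blank for single-letter elements of standard residues
  name <- .pdb_field(lines, 13, 16)
  guess <- toupper(trimws(substr(name, 1, 2)))
  guess1 <- sub("^[0-9]*", "", guess)          # e.g. "1HB " -> "HB" -> H
  guess1 <- substr(guess1, 1, 1)
  ifelse(el == "", guess1, el)
}

#' Read heavy atoms from a PDB file
#'
#' Returns the heavy-atom (non-hydrogen, non-deuterium) coordinates of the
#' first model as a unit-weight [point_cloud()]. Alternate locations are
#' resolved to the highest occupancy (ties: first encountered); waters
#' (HOH/WAT) are always excluded; HETATM records are included only when
#' `include_hetero = TRUE`.
#'
#' @param path PDB file path.
#' @param include_hetero include HETATM records (ligands, ions)?
#' @return a [point_cloud()] with one unit-weight point per heavy atom.
#' @export
read_pdb_heavy_atoms <- function(path, include_hetero = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  ## first model only
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  rec <- .pdb_field(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_het <- rec == "HETATM"
  keep <- is_atom | (include_hetero & is_het)
  lines <- lines[keep]
  if (!length(lines)) stop("no atom records in PDB file")

  resname <- trimws(.pdb_field(lines, 18, 20))
  el <- .element_from_record(lines)
  heavy <- !(el %in% c("H", "D")) & !(resname %in% c("HOH", "WAT"))
  lines <- lines[heavy]
  if (!length(lines)) stop("no heavy atoms after filtering")

  x <- as.numeric(.pdb_field(lines, 31, 38))
  y <- as.numeric(.pdb_field(lines, 39, 46))
  z <- as.numeric(.pdb_field(lines, 47, 54))
  occ <- suppressWarnings(as.numeric(.pdb_field(lines, 55, 60)))
  occ[is.na(occ)] <- 1.0
  altloc <- .pdb_field(lines, 17, 17)

  ## resolve altlocs: group by atom identity, keep max occupancy
  ## (ties: the record encountered first)
  has_alt <- altloc != " " & altloc != ""
  if (any(has_alt)) {
    key <- paste(.pdb_field(lines, 13, 16), .pdb_field(lines, 18, 20),
                 .pdb_field(lines, 22, 22), .pdb_field(lines, 23, 27),
                 sep = "|")
    ord <- order(key, -occ, seq_along(key))
    first_of_key <- !duplicated(key[ord])
    sel <- sort(ord[first_of_key])
    ## atoms without altloc are singletons in their key group already
    x <- x[sel]; y <- y[sel]; z <- z[sel]
  }
  pos <- cbind(x, y, z)
  if (anyNA(pos)) stop("malformed coordinate fields in PDB file")
  point_cloud(unname(pos), source_id = basename(path))
}

#' Write a bead model as a PDB file of pseudoatoms
#'
#' One `ATOM` record per bead (element C, residue `BEA`), in the given
#' order. The bead radius `R_CG` and model standard deviation `s` are
#' recorded in `REMARK` lines; the file round-trips through
#' [read_pdb_heavy_atoms()] to the same coordinates within the 1e-3
#' Angstrom precision of the format.
#'
#' @param model a `bead_model` (from [run_gibbs()]) or a K x 3 matrix.
#' @param path output file path.
#' @param order permutation of `1:K` controlling record sequence, e.g. from
#'   [reorder_beads()]; the bead index becomes the residue number, so
#'   renderers coloring by residue show the path gradient.
#' @return invisibly, the path.
#' @export
write_bead_pdb <- function(model, path, order = NULL) {
  X <- if (is.matrix(model)) model else model$positions
  X <- .as_beads(X)
  K <- nrow(X)
  if (K < 1) stop("empty bead model")
  if (is.null(order)) order <- seq_len(K)
  order <- as.integer(order)
  if (!identical(sort(order), seq_len(K)))
    stop("order must be a permutation of 1..K")
  if (any(abs(X) >= 10000)) stop("coordinates exceed PDB fixed-width fields")
  con <- file(path, "wt")
  on.exit(close(con))
  hdr <- c("REMARK   3 COARSE-GRAINED BEAD MODEL")
  if (!is.matrix(model)) {
    if (!is.null(model$s_mean))
      hdr <- c(hdr, sprintf("REMARK   3 MODEL S (A): %.4f", model$s_mean))
    if (!is.null(model$R_CG_mean) && is.finite(model$R_CG_mean))
      hdr <- c(hdr, sprintf("REMARK   3 R_CG (A): %.4f", model$R_CG_mean))
  }
  writeLines(hdr, con)
  Xo <- X[order, , drop = FALSE]
  serial <- seq_len(K)
  recs <- sprintf(
    "ATOM  %5d  BB  BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    serial %% 100000L, ((serial - 1L) %% 9999L) + 1L,
    Xo[, 1], Xo[, 2], Xo[, 3])
  writeLines(recs, con)
  writeLines("END", con)
  invisible(path)
}
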