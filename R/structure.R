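# Structure container and PDB I/O.
#
# A loop_structure is a thin wrapper around an atom table (one row per heavy
# atom) with coordinates in Angstrom and element masses in amu. Parsing goes
# through bio3d; only ATOM records of protein heavy atoms are retained.

.element_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                     P = 30.974, SE = 78.971, H = 1.008)

.backbone_names <- c("N", "CA", "C", "O")

guess_element <- function(elety) {
  e <- gsub("[0-9']", "", toupper(trimws(elety)))
  ifelse(substr(e, 1L, 2L) %in% c("SE"), "SE", substr(e, 1L, 1L))
}

new_structure <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "elesy", "mass",
            "x", "y", "z", "backbone")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (any(atoms$mass <= 0)) stop("non-positive atomic mass")
  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) entries in atom table")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "loop_structure")
}

#' Read a protein structure from a PDB file
#'
#' Reads ATOM records only, drops hydrogens and waters, resolves alternate
#' locations to the highest-occupancy copy, and assigns standard atomic
#' masses by element. Insertion codes are rejected: silent misindexing of a
#' loop range is worse than a loud failure.
#'
#' @param path path to a PDB file
#' @return a \code{loop_structure}: a list with an \code{atoms} data frame
#'   (chain, resno, resid, elety, elesy, mass, x, y, z, backbone)
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported; renumber the chain first")
  elesy <- at$elesy
  bad <- is.na(elesy) | trimws(elesy) == ""
  elesy[bad] <- guess_element(at$elety[bad])
  elesy <- toupper(trimws(elesy))
  at$elesy <- elesy
  keep <- elesy != "H" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  # altloc: keep highest occupancy, ties broken by altloc label order
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(at$chain, at$resno, at$elety, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno,
                 match(at$elety, c(.backbone_names, "CB"), nomatch = 99L)), ,
           drop = FALSE]
  mass <- .element_masses[at$elesy]
  if (anyNA(mass)) mass[is.na(mass)] <- 12.011
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = at$elety, elesy = at$elesy, mass = unname(mass),
                    x = at$x, y = at$y, z = at$z,
                    backbone = at$elety %in% .backbone_names,
                    stringsAsFactors = FALSE)
  new_structure(out)
}

#' @export
print.loop_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("loop_structure: %d heavy atoms, %d residues, chain(s) %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

coords_matrix <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

pdb_atom_line <- function(i, a, x, y, z) {
  name <- a$elety[i]
  name <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000L, name, a$resid[i], a$chain[i], a$resno[i],
          x, y, z, 1, 0, a$elesy[i])
}

#' Write a structure to a single-model PDB file
#' @param structure a \code{loop_structure}
#' @param path output file
#' @return invisibly, the path
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  lines <- vapply(seq_len(nrow(a)), function(i)
    pdb_atom_line(i, a, a$x[i], a$y[i], a$z[i]), character(1L))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
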