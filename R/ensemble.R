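# Multi-model PDB output/input for conformational ensembles. All models
# share one atom table; loop atoms vary, environment atoms are constant.

#' Write an ensemble to a multi-model PDB file
#'
#' One MODEL/ENDMDL block per stored conformation; mobile atoms take the
#' conformation's coordinates, all other atoms keep the parent structure's.
#'
#' @param ensemble a \code{loop_ensemble}
#' @param path output file
#' @return invisibly, the path
#' @export
write_ensemble <- function(ensemble, path) {
  if (!inherits(ensemble, "loop_ensemble")) stop("not a loop_ensemble")
  n <- length(ensemble$xyz)
  if (n == 0L) stop("cannot write an empty ensemble")
  loop <- ensemble$model
  a <- loop$structure$atoms
  base <- coords_matrix(loop$structure)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n)) {
    xyz <- base
    xyz[loop$mobile, ] <- ensemble$xyz[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(vapply(seq_len(nrow(a)), function(i)
      pdb_atom_line(i, a, xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]),
      character(1L)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a coordinate ensemble
#'
#' @param path a multi-model PDB file
#' @return list with \code{atoms} (table of the first model's heavy atoms)
#'   and \code{xyz} (n_models x 3*n_atoms coordinate matrix, bio3d layout)
#' @export
read_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & toupper(ifelse(
    is.na(at$elesy) | trimws(at$elesy) == "",
    guess_element(at$elety), trimws(at$elesy))) != "H"
  xyz <- pdb$xyz
  cols <- as.numeric(t(cbind(3 * which(keep) - 2L, 3 * which(keep) - 1L,
                             3 * which(keep))))
  list(atoms = at[keep, c("chain", "resno", "resid", "elety")],
       xyz = xyz[, cols, drop = FALSE])
}

# snapshot matrix (n_conf x 3K) of selected backbone atoms of an ensemble
ensemble_snapshots <- function(ensemble,
                               elety = c("N", "CA", "C", "O")) {
  loop <- ensemble$model
  a <- loop$structure$atoms[loop$mobile, ]
  sel <- which(a$elety %in% elety & a$resno >= loop$spec$first &
               a$resno <= loop$spec$last)
  X <- t(vapply(ensemble$xyz,
                function(x) as.numeric(t(x[sel, , drop = FALSE])),
                numeric(3L * length(sel))))
  attr(X, "atoms") <- a[sel, c("chain", "resno", "resid", "elety")]
  X
}
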