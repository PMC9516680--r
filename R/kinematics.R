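# Torsional kinematics: degrees of freedom, dihedral extraction, Cartesian
# rebuild by sequential bond rotation, and analytic position derivatives.
#
# Sign convention throughout: rotating the moving (C-terminal) side of a bond
# b->c right-handedly about e = unit(r_c - r_b) by theta increases the
# a-b-c-d torsion by theta, so d r_i / d q = e x (r_i - r_b) for moving atoms.

#' Define the torsional degrees of freedom of a loop
#'
#' Returns the ordered DOF list phi_1, psi_1, (omega_1,) ..., phi(Ct):
#' n = 2N + 1 without omega, 3N + 1 with it. Each DOF carries its rotation
#' axis (bond atom pair), the four-atom torsion definition, and the moving
#' set: every mobile atom displaced when the bond rotates with the
#' N-terminal side held fixed. Moving sets are nested along the chain.
#'
#' @param loop a \code{loop_model}
#' @return list of DOF records (kind, resno, axis, quad, moving)
#' @export
define_dofs <- function(loop) {
  s <- loop$spec
  a <- loop$structure$atoms
  ct <- loop$ct_resno
  mob <- loop$mobile
  res_of <- a$resno[mob]
  atoms_of <- function(r) mob[res_of == r]
  downstream <- function(r) mob[res_of > r]
  id <- function(r, e) loop_atom(loop, r, e)

  dofs <- list()
  add <- function(kind, resno, axis, quad, moving) {
    dofs[[length(dofs) + 1L]] <<- list(kind = kind, resno = resno,
                                       axis = axis, quad = quad,
                                       moving = sort(moving))
  }
  for (r in s$first:s$last) {
    nr <- id(r, "N"); car <- id(r, "CA"); cr <- id(r, "C")
    add("phi", r, c(nr, car),
        c(id(r - 1L, "C"), nr, car, cr),
        c(setdiff(atoms_of(r), c(nr, car)), downstream(r)))
    add("psi", r, c(car, cr),
        c(nr, car, cr, id(r + 1L, "N")),
        c(id(r, "O"), downstream(r)))
    if (s$include_omega) {
      nn <- id(r + 1L, "N")
      add("omega", r, c(cr, nn),
          c(car, cr, nn, id(r + 1L, "CA")),
          setdiff(downstream(r), nn))
    }
  }
  nct <- id(ct, "N"); cact <- id(ct, "CA"); cct <- id(ct, "C")
  add("phi", ct, c(nct, cact),
      c(id(s$last, "C"), nct, cact, cct), cct)
  dofs
}

n_dof <- function(spec) {
  if (spec$include_omega) 3L * spec$N + 1L else 2L * spec$N + 1L
}

#' Extract the dihedral vector of a loop
#'
#' @param loop a \code{loop_model}
#' @param xyz optional full-structure coordinate matrix (defaults to the
#'   coordinates stored in the loop's structure)
#' @param dofs optional precomputed DOF list
#' @return numeric vector of torsions in radians, wrapped to (-pi, pi]
#' @export
extract_dihedrals <- function(loop, xyz = NULL, dofs = NULL) {
  if (is.null(xyz)) xyz <- coords_matrix(loop$structure)
  if (is.null(dofs)) dofs <- define_dofs(loop)
  vapply(dofs, function(d) {
    q <- d$quad
    torsion4(xyz[q[1L], ], xyz[q[2L], ], xyz[q[3L], ], xyz[q[4L], ])
  }, numeric(1L))
}

#' Rebuild loop coordinates from a dihedral vector
#'
#' Applies the wrapped difference between \code{q} and the current dihedrals
#' as sequential rigid rotations about each DOF bond, from the fixed
#' N-terminal anchor toward Ct. Bond lengths, bond angles and all non-DOF
#' torsions are preserved exactly, and \code{extract_dihedrals} after
#' \code{apply_dihedrals} returns \code{q}.
#'
#' @inheritParams extract_dihedrals
#' @param q target dihedral vector (radians), length n
#' @return the full coordinate matrix with mobile atoms rebuilt
#' @export
apply_dihedrals <- function(loop, q, xyz = NULL, dofs = NULL) {
  if (is.null(xyz)) xyz <- coords_matrix(loop$structure)
  if (is.null(dofs)) dofs <- define_dofs(loop)
  if (length(q) != length(dofs)) stop("dihedral vector has wrong length")
  for (k in seq_along(dofs)) {
    d <- dofs[[k]]
    qd <- d$quad
    cur <- torsion4(xyz[qd[1L], ], xyz[qd[2L], ], xyz[qd[3L], ], xyz[qd[4L], ])
    delta <- wrap_angle(q[k] - cur)
    if (abs(delta) < 1e-14) next
    b <- xyz[d$axis[1L], ]
    R <- rotation_about(xyz[d$axis[2L], ] - b, delta)
    mv <- d$moving
    xyz[mv, ] <- sweep(sweep(xyz[mv, , drop = FALSE], 2L, b) %*% t(R),
                       2L, b, "+")
  }
  xyz
}

#' Analytic derivatives of mobile-atom positions w.r.t. the dihedrals
#'
#' @inheritParams extract_dihedrals
#' @return a 3M x n matrix (M mobile atoms, xyz-interleaved rows) with
#'   column a equal to e_a x (r_i - r_axis) for atoms in the moving set of
#'   DOF a and zero elsewhere; units Angstrom/radian
#' @export
cartesian_derivatives <- function(loop, xyz = NULL, dofs = NULL) {
  if (is.null(xyz)) xyz <- coords_matrix(loop$structure)
  if (is.null(dofs)) dofs <- define_dofs(loop)
  mob <- loop$mobile
  M <- length(mob)
  D <- matrix(0, 3L * M, length(dofs))
  for (k in seq_along(dofs)) {
    d <- dofs[[k]]
    b <- xyz[d$axis[1L], ]
    e <- unit(xyz[d$axis[2L], ] - b)
    mv <- d$moving
    V <- sweep(xyz[mv, , drop = FALSE], 2L, b)
    CX <- cbind(e[2L] * V[, 3L] - e[3L] * V[, 2L],
                e[3L] * V[, 1L] - e[1L] * V[, 3L],
                e[1L] * V[, 2L] - e[2L] * V[, 1L])
    pos <- match(mv, mob)
    rows <- rep(3L * (pos - 1L), each = 3L) + rep(1:3, length(pos))
    D[rows, k] <- as.numeric(t(CX))
  }
  D
}

# row indices (within the full atom table) of loop backbone atoms, used for
# RMSD measurement
loop_backbone_idx <- function(loop, which = c("loop", "flanks")) {
  which <- match.arg(which)
  a <- loop$structure$atoms
  s <- loop$spec
  res <- if (which == "loop") s$first:s$last
         else c((s$first - 3L):(s$first - 1L), (s$last + 1L):(s$last + 3L))
  which(a$chain == s$chain & a$resno %in% res & a$backbone)
}
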