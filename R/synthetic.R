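# Synthetic ideal-geometry loop fixtures.
#
# Builds a poly-alanine segment with constant (Engh-Huber-style) bond lengths
# and angles, user-chosen phi/psi, trans peptide bonds, one rigid anchor
# residue at each end, and an optional scaffold shell of fixed atoms. Every
# module of the package is testable against these fixtures without any
# external structure files.

.geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  b_c_o = 1.231, b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_c_n_ca = 121.9,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.4,
  t_cb = -122.6   # torsion(C, N, CA, CB): L-configuration branch
)

fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Build a synthetic ideal-geometry loop structure
#'
#' Constructs a backbone of \code{N} flexible residues flanked by one rigid
#' anchor residue on each side (residue numbers 1 and N+2; the flexible span
#' is 2..N+1), with ideal bond lengths/angles, omega = 180 degrees, and the
#' requested phi/psi angles. Side chains are alanine C-beta atoms (glycine
#' positions, if given in \code{sequence}, carry none). Optionally decorates
#' the fixture with a shell of fixed scaffold pseudo-residues (CA-only) at a
#' given radius around the loop centroid; shell placement is deterministic
#' (Fibonacci sphere), so the seed does not affect coordinates.
#'
#' @param N number of flexible residues (>= 2)
#' @param phi_psi N x 2 matrix (or length-2 vector, recycled) of phi/psi in
#'   degrees, each in (-180, 180]
#' @param seed integer; accepted for interface stability, geometry is fully
#'   deterministic
#' @param sequence optional one-letter codes, length N + 2 ("A" or "G")
#' @param psi_nt,phi_ct,psi_ct anchor torsions in degrees
#' @param scaffold_radius radius (Angstrom) of the scaffold shell(s); vector
#'   for multiple shells; NULL for none
#' @param scaffold_n atoms per shell
#' @param chain chain identifier
#' @return a \code{loop_structure}
#' @export
build_synthetic_loop <- function(N, phi_psi = c(-57, -47), seed = 1L,
                                 sequence = NULL,
                                 psi_nt = -45, phi_ct = -70, psi_ct = -45,
                                 scaffold_radius = NULL, scaffold_n = 30L,
                                 chain = "A") {
  if (N < 2L) stop("N must be at least 2")
  if (is.null(dim(phi_psi))) phi_psi <- matrix(phi_psi, N, 2L, byrow = TRUE)
  phi_psi <- as.matrix(phi_psi)
  if (nrow(phi_psi) != N || ncol(phi_psi) != 2L)
    stop("phi_psi must be an N x 2 matrix of degrees")
  if (any(phi_psi <= -180 | phi_psi > 180))
    stop("phi/psi angles must lie in (-180, 180]")
  nres <- N + 2L
  if (is.null(sequence)) sequence <- rep("A", nres)
  if (length(sequence) != nres) stop("sequence must have length N + 2")

  g <- .geom
  # per-residue torsions used during the build (anchors included)
  phi <- c(NA, phi_psi[, 1L], phi_ct)            # phi[i] for residue i
  psi <- c(psi_nt, phi_psi[, 2L], psi_ct)        # psi[i]
  phi <- deg2rad(phi); psi <- deg2rad(psi)
  a_nc <- deg2rad(g$a_n_ca_c); a_cn <- deg2rad(g$a_ca_c_n)
  a_nca <- deg2rad(g$a_c_n_ca); a_co <- deg2rad(g$a_ca_c_o)
  a_cb <- deg2rad(g$a_n_ca_cb); t_cb <- deg2rad(g$t_cb)

  Np <- CAp <- Cp <- Op <- CBp <- vector("list", nres)
  Np[[1L]] <- c(0, 0, 0)
  CAp[[1L]] <- c(g$b_n_ca, 0, 0)
  Cp[[1L]] <- CAp[[1L]] + g$b_ca_c * c(-cos(a_nc), -sin(a_nc), 0)
  for (i in 2:nres) {
    Np[[i]] <- place_atom(Np[[i - 1L]], CAp[[i - 1L]], Cp[[i - 1L]],
                          g$b_c_n, a_cn, psi[i - 1L])
    CAp[[i]] <- place_atom(CAp[[i - 1L]], Cp[[i - 1L]], Np[[i]],
                           g$b_n_ca, a_nca, pi)          # trans peptide
    Cp[[i]] <- place_atom(Cp[[i - 1L]], Np[[i]], CAp[[i]],
                          g$b_ca_c, a_nc, phi[i])
  }
  for (i in 1:nres) {
    Op[[i]] <- place_atom(Np[[i]], CAp[[i]], Cp[[i]],
                          g$b_c_o, a_co, wrap_angle(psi[i] + pi))
    if (sequence[i] != "G")
      CBp[[i]] <- place_atom(Cp[[i]], Np[[i]], CAp[[i]],
                             g$b_ca_cb, a_cb, t_cb)
  }

  rows <- list()
  add <- function(resno, resid, elety, xyz, elesy) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = resid, elety = elety,
      elesy = elesy, mass = unname(.element_masses[elesy]),
      x = xyz[1L], y = xyz[2L], z = xyz[3L],
      backbone = elety %in% .backbone_names, stringsAsFactors = FALSE)
  }
  for (i in 1:nres) {
    resid <- if (sequence[i] == "G") "GLY" else "ALA"
    add(i, resid, "N", Np[[i]], "N")
    add(i, resid, "CA", CAp[[i]], "C")
    add(i, resid, "C", Cp[[i]], "C")
    add(i, resid, "O", Op[[i]], "O")
    if (sequence[i] != "G") add(i, resid, "CB", CBp[[i]], "C")
  }

  if (!is.null(scaffold_radius) && scaffold_n > 0L) {
    cen <- colMeans(do.call(rbind, CAp[2:(N + 1L)]))
    k <- 0L
    for (R in scaffold_radius) {
      pts <- sweep(R * fib_sphere(scaffold_n), 2L, cen, "+")
      for (j in seq_len(scaffold_n)) {
        k <- k + 1L
        add(9000L + k, "GLY", "CA", pts[j, ], "C")
      }
    }
  }
  new_structure(do.call(rbind, rows))
}

#' Loop specification matching a synthetic fixture
#' @param N flexible residue count used in \code{build_synthetic_loop}
#' @param include_omega treat omega dihedrals as degrees of freedom
#' @param chain chain identifier
#' @return a \code{loop_spec}
#' @export
synthetic_loop_spec <- function(N, include_omega = FALSE, chain = "A") {
  loop_spec(chain = chain, first = 2L, last = N + 1L,
            include_omega = include_omega)
}
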