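# Loop-closure constraints and the constrained eigenproblem.
#
# Six scalar constraints pin the Ct anchor: the three Cartesian coordinates
# of its CA atom, plus three projections of its N and C atoms in a local
# orthonormal frame (u, v, w) built around CA at equilibrium: u along
# CA->N, v normal to the N-CA-C plane, w = u x v in-plane. The fixed
# N-CA and CA-C bond lengths and the N-CA-C angle make the remaining three
# projections (r_N.u, r_C.u, r_C.w) redundant at first order. (With CA and
# N pinned, the only first-order freedom left to C is the rotation about
# the CA-N axis, whose velocity points along the plane normal v; hence
# r_C.v is the one independent projection, while r_C.w is frozen by the
# fixed bond geometry.) Constrained
# modes are the generalized eigenvectors of the bordered Hessian
#   H_B = [[H, Jg'], [Jg, 0]],  T_B = [[T, 0], [0, 0]];
# of its n + C solutions, 2C are spurious/infinite, leaving n - C
# closure-preserving modes. The default numerical route projects onto the
# null space of Jg (equivalent, and robust to the singular T_B); the
# bordered route is kept as a cross-check.

#' Local reference frame at the Ct anchor
#'
#' u points from CA to N, v is the unit normal of the N-CA-C plane
#' (u x CA->C direction), and w = u x v lies in the plane, orthogonal to u;
#' all computed from the equilibrium coordinates and held constant within
#' one linearization step. At equilibrium r_C.v = 0 by construction.
#'
#' @param loop a \code{loop_model}
#' @param xyz optional coordinate matrix
#' @return an \code{anchor_frame}: list(origin, u, v, w, iN, iCA, iC)
#' @export
anchor_frame <- function(loop, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords_matrix(loop$structure)
  iN <- loop_atom(loop, loop$ct_resno, "N")
  iCA <- loop_atom(loop, loop$ct_resno, "CA")
  iC <- loop_atom(loop, loop$ct_resno, "C")
  o <- xyz[iCA, ]
  u <- unit(xyz[iN, ] - o)
  cv <- xyz[iC, ] - o
  vn <- cross3(u, cv)
  if (vnorm(vn) < 1e-8)
    stop("degenerate Ct anchor: N, CA, C are collinear")
  v <- unit(vn)
  structure(list(origin = o, u = u, v = v, w = cross3(u, v),
                 iN = iN, iCA = iCA, iC = iC),
            class = "anchor_frame")
}

# scalar constraint values at arbitrary coordinates (zero-referenced at
# equilibrium by construct_constraints)
constraint_values <- function(frame, xyz) {
  rCA <- xyz[frame$iCA, ]
  rN <- xyz[frame$iN, ] - frame$origin
  rC <- xyz[frame$iC, ] - frame$origin
  c(rCA,
    sum(rN * frame$v), sum(rN * frame$w), sum(rC * frame$v))
}

#' Closure-constraint set and Jacobian
#'
#' Rows 1-3 of the Jacobian are the Cartesian derivative rows of the Ct CA
#' atom; rows 4-6 are the v- and w-projections of the Ct N derivatives and
#' the v-projection of the Ct C derivatives. Rank 6 is required.
#'
#' @param loop a \code{loop_model}
#' @param frame an \code{anchor_frame}
#' @param D derivative matrix at the same coordinates
#' @return a \code{constraint_set}: list(J, frame, C = 6, g0)
#' @export
constraint_jacobian <- function(loop, frame, D) {
  mob <- loop$mobile
  rowblock <- function(i) {
    p <- match(i, mob)
    D[(3L * p - 2L):(3L * p), , drop = FALSE]
  }
  Jca <- rowblock(frame$iCA)
  Jn <- rowblock(frame$iN)
  Jc <- rowblock(frame$iC)
  J <- rbind(Jca,
             crossprod(frame$v, Jn),
             crossprod(frame$w, Jn),
             crossprod(frame$v, Jc))
  sv <- svd(J)$d
  rk <- sum(sv > max(dim(J)) * max(sv) * 1e-10)
  if (rk < 6L)
    stop("constraint Jacobian is rank-deficient (rank ", rk,
         "): degenerate anchor geometry")
  structure(list(J = J, frame = frame, C = 6L),
            class = "constraint_set")
}

# orthonormal basis of the null space of J (n x (n - C))
nullspace_basis <- function(J) {
  n <- ncol(J)
  s <- svd(J, nu = 0, nv = n)
  r <- sum(s$d > max(dim(J)) * max(s$d) * 1e-12)
  s$v[, (r + 1L):n, drop = FALSE]
}

#' Solve the constrained torsional eigenproblem
#'
#' Returns the n - C closure-preserving modes, ascending in omega^2, each
#' with its C Lagrange-multiplier components. The \code{"nullspace"} route
#' (default) solves the reduced problem Z'HZ w = omega^2 Z'TZ w on a basis
#' Z of null(Jg); the \code{"bordered"} route solves the extended
#' generalized eigenproblem of the bordered matrices by shift-inversion and
#' discards the 2C infinite modes. The two coincide and are cross-checked
#' in the test suite.
#'
#' @param H internal Hessian (n x n)
#' @param Tm kinetic matrix (n x n)
#' @param constraints a \code{constraint_set}
#' @param method \code{"nullspace"} or \code{"bordered"}
#' @return a \code{constrained_modes}: list(values, vectors n x (n-C),
#'   lambda C x (n-C), J, frame, n, C)
#' @export
solve_constrained <- function(H, Tm, constraints,
                              method = c("nullspace", "bordered")) {
  method <- match.arg(method)
  J <- constraints$J
  C <- nrow(J)
  n <- ncol(J)
  if (C == 0L) {
    e <- geigen_sym(H, Tm)
    return(structure(list(values = e$values, vectors = e$vectors,
                          lambda = matrix(0, 0L, n), J = J,
                          frame = constraints$frame, n = n, C = 0L),
                     class = "constrained_modes"))
  }
  if (method == "nullspace") {
    Z <- nullspace_basis(J)
    e <- geigen_sym(crossprod(Z, H %*% Z), crossprod(Z, Tm %*% Z))
    V <- Z %*% e$vectors
    vals <- e$values
  } else {
    HB <- rbind(cbind(H, t(J)), cbind(J, matrix(0, C, C)))
    TB <- rbind(cbind(Tm, matrix(0, n, C)),
                cbind(matrix(0, C, n), matrix(0, C, C)))
    sigma <- -(1 + sum(abs(diag(H))) / n)
    M <- tryCatch(solve(HB - sigma * TB, TB),
                  error = function(e) stop("bordered eigen-solver failure: ",
                                           conditionMessage(e)))
    ev <- eigen(M)
    mu <- Re(ev$values)
    finite <- which(abs(mu) > 1e-8 * max(abs(mu)))
    vals <- sigma + 1 / mu[finite]
    ord <- order(vals)
    keep <- finite[ord][seq_len(min(n - C, length(finite)))]
    vals <- sort(vals)[seq_len(min(n - C, length(finite)))]
    Vb <- Re(ev$vectors[, keep, drop = FALSE])
    V <- Vb[seq_len(n), , drop = FALSE]
    # normalize the dihedral part in the T-metric for comparability
    nrm <- sqrt(pmax(colSums(V * (Tm %*% V)), 1e-300))
    V <- sweep(V, 2L, nrm, "/")
  }
  # Lagrange components from stationarity: H v + J' lambda = omega^2 T v
  R <- H %*% V - sweep(Tm %*% V, 2L, vals, "*")
  lambda <- -solve(tcrossprod(J), J %*% R)
  structure(list(values = vals, vectors = V, lambda = lambda, J = J,
                 frame = constraints$frame, n = n, C = C),
            class = "constrained_modes")
}

#' @export
print.constrained_modes <- function(x, ...) {
  cat(sprintf(
    "constrained_modes: %d modes (n = %d, C = %d), omega^2 in [%.3g, %.3g]\n",
    length(x$values), x$n, x$C, min(x$values), max(x$values)))
  invisible(x)
}

#' Measure the closure error after a finite mode displacement
#'
#' Applies q0 + amplitude * direction through the exact kinematics and
#' reports how far the Ct anchor moved: the CA position error and the
#' N/C frame-projection errors. For directions in the span of the
#' constrained modes these errors are second order in the amplitude.
#'
#' @param loop a \code{loop_model}
#' @param q0 reference dihedral vector
#' @param direction dihedral-space direction (length n)
#' @param amplitude scalar multiplier (radians)
#' @param dofs optional precomputed DOF list
#' @return list(ca_error, frame_errors, max_error) in Angstrom
#' @export
verify_closure <- function(loop, q0, direction, amplitude, dofs = NULL) {
  if (is.null(dofs)) dofs <- define_dofs(loop)
  xyz0 <- apply_dihedrals(loop, q0, dofs = dofs)
  frame <- anchor_frame(loop, xyz0)
  g0 <- constraint_values(frame, xyz0)
  xyz1 <- apply_dihedrals(loop, q0 + amplitude * direction, xyz = xyz0,
                          dofs = dofs)
  g1 <- constraint_values(frame, xyz1)
  ca_err <- vnorm(g1[1:3] - g0[1:3])
  fr_err <- abs(g1[4:6] - g0[4:6])
  list(ca_error = ca_err, frame_errors = fr_err,
       max_error = max(ca_err, fr_err))
}
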