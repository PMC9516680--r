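# Elastic network model and the internal-coordinate generalized eigenproblem
# H v = omega^2 T v.
#
# The network couples loop heavy atoms to each other and to the fixed
# environment. Because the input structure is the minimum of the ENM energy,
# the internal Hessian reduces to the Gram form over spring-length gradients
# (the force term vanishes), so H is symmetric PSD by construction.

#' Build the elastic network over a loop and its environment
#'
#' Springs connect every mobile-mobile or mobile-environment heavy-atom
#' pair within \code{cutoff}; environment-environment pairs carry no energy
#' dependence on the dihedrals and are omitted. Two force-constant rules are
#' available: \code{"power"} (k = k0 * d0^-p, the default with p = 2) and
#' \code{"cutoff"} (uniform k = k0).
#'
#' @param loop a \code{loop_model}
#' @param xyz optional full coordinate matrix (equilibrium geometry)
#' @param rule force-constant rule, \code{"power"} or \code{"cutoff"}
#' @param cutoff distance cap in Angstrom (default 10)
#' @param k0 force-constant scale
#' @param p inverse-power exponent for \code{rule = "power"}
#' @return a \code{loop_enm}: data frame of springs (i, j, k, d0) with i, j
#'   atom-row indices, i < j
#' @export
build_elastic_network <- function(loop, xyz = NULL,
                                  rule = c("power", "cutoff"),
                                  cutoff = 10, k0 = 1, p = 2) {
  rule <- match.arg(rule)
  if (is.null(xyz)) xyz <- coords_matrix(loop$structure)
  idx <- c(loop$mobile, loop$env)
  if (length(idx) < 2L) stop("need at least 2 atoms to build a network")
  X <- xyz[idx, , drop = FALSE]
  nm <- length(loop$mobile)
  pair <- which(upper.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
  # drop environment-environment pairs
  pair <- pair[pair[, 1L] <= nm | pair[, 2L] <= nm, , drop = FALSE]
  d0 <- sqrt(rowSums((X[pair[, 1L], , drop = FALSE] -
                      X[pair[, 2L], , drop = FALSE])^2))
  keep <- d0 <= cutoff & d0 > 1e-6
  pair <- pair[keep, , drop = FALSE]
  d0 <- d0[keep]
  k <- if (rule == "power") k0 * d0^(-p) else rep(k0, length(d0))
  i <- idx[pair[, 1L]]; j <- idx[pair[, 2L]]
  sw <- i > j
  springs <- data.frame(i = ifelse(sw, j, i), j = ifelse(sw, i, j),
                        k = k, d0 = d0)
  structure(list(springs = springs, rule = rule, cutoff = cutoff,
                 k0 = k0, p = p),
            class = "loop_enm")
}

#' @export
print.loop_enm <- function(x, ...) {
  cat(sprintf("loop_enm: %d springs (%s rule, cutoff %.1f A)\n",
              nrow(x$springs), x$rule, x$cutoff))
  invisible(x)
}

# spring-length Jacobian: row s = u_s . (dr_i/dq - dr_j/dq), an S x n matrix
spring_jacobian <- function(net, loop, D, xyz) {
  sp <- net$springs
  nat <- nrow(loop$structure$atoms)
  Dfull <- matrix(0, 3L * nat, ncol(D))
  mob <- loop$mobile
  rows <- rep(3L * (mob - 1L), each = 3L) + rep(1:3, length(mob))
  Dfull[rows, ] <- D
  U <- xyz[sp$j, , drop = FALSE] - xyz[sp$i, , drop = FALSE]
  U <- U / sqrt(rowSums(U^2))
  A <- U[, 1L] * (Dfull[3L * sp$j - 2L, , drop = FALSE] -
                  Dfull[3L * sp$i - 2L, , drop = FALSE]) +
       U[, 2L] * (Dfull[3L * sp$j - 1L, , drop = FALSE] -
                  Dfull[3L * sp$i - 1L, , drop = FALSE]) +
       U[, 3L] * (Dfull[3L * sp$j, , drop = FALSE] -
                  Dfull[3L * sp$i, , drop = FALSE])
  A
}

#' Internal-coordinate Hessian of the elastic energy
#'
#' H_ab = sum over springs of k * (dd/dq_a)(dd/dq_b), the exact second
#' derivative of the ENM energy at its minimum.
#'
#' @param net a \code{loop_enm}
#' @param loop a \code{loop_model}
#' @param D derivative matrix from \code{\link{cartesian_derivatives}}
#' @param xyz coordinates D was evaluated at
#' @return symmetric PSD n x n matrix
#' @export
internal_hessian <- function(net, loop, D, xyz = NULL) {
  if (is.null(xyz)) xyz <- coords_matrix(loop$structure)
  A <- spring_jacobian(net, loop, D, xyz)
  H <- crossprod(A * sqrt(net$springs$k))
  (H + t(H)) / 2
}

#' ENM potential energy of a displaced configuration
#' @param net a \code{loop_enm}
#' @param xyz full coordinate matrix
#' @return 0.5 * sum k (d - d0)^2
#' @export
enm_energy <- function(net, xyz) {
  sp <- net$springs
  d <- sqrt(rowSums((xyz[sp$i, , drop = FALSE] -
                     xyz[sp$j, , drop = FALSE])^2))
  0.5 * sum(sp$k * (d - sp$d0)^2)
}

#' Kinetic-energy (mass-metric) matrix in dihedral space
#'
#' T_ab = sum_i m_i (dr_i/dq_a) . (dr_i/dq_b).
#'
#' @param masses mobile-atom masses (amu), length M
#' @param D 3M x n derivative matrix
#' @return symmetric PSD n x n matrix
#' @export
kinetic_matrix <- function(masses, D) {
  if (3L * length(masses) != nrow(D))
    stop("masses and derivative matrix are inconsistent")
  Tm <- crossprod(D * sqrt(rep(masses, each = 3L)))
  (Tm + t(Tm)) / 2
}

# symmetric-definite generalized eigensolver via whitening of T, with the
# trace-scaled diagonal regularization used when nested moving sets make T
# numerically rank-deficient
geigen_sym <- function(H, Tm) {
  n <- nrow(Tm)
  tr <- sum(diag(Tm))
  if (tr <= 0) stop("kinetic matrix is numerically singular")
  eT <- eigen(Tm, symmetric = TRUE)
  if (min(eT$values) < 1e-12 * tr / n) {
    Tm <- Tm + diag(1e-10 * tr / n, n)
    eT <- eigen(Tm, symmetric = TRUE)
    if (min(eT$values) <= 0)
      stop("kinetic matrix is numerically singular beyond regularization")
  }
  W <- eT$vectors %*% diag(1 / sqrt(eT$values), n)
  Hw <- crossprod(W, H %*% W)
  e <- eigen((Hw + t(Hw)) / 2, symmetric = TRUE)
  ord <- seq(n, 1L)
  list(values = e$values[ord], vectors = W %*% e$vectors[, ord, drop = FALSE])
}

#' Solve the unconstrained torsional eigenproblem H v = omega^2 T v
#'
#' Baseline modes without closure constraints. No rigid-body filtering is
#' needed (and no Eckart conditions are imposed): the fixed anchors already
#' remove global motion.
#'
#' @param H internal Hessian
#' @param Tm kinetic-energy matrix
#' @return a \code{loop_modes}: eigenvalues omega^2 ascending, eigenvector
#'   columns T-orthonormal
#' @export
solve_unconstrained <- function(H, Tm) {
  e <- geigen_sym(H, Tm)
  structure(list(values = e$values, vectors = e$vectors, metric = "T"),
            class = "loop_modes")
}

#' @export
print.loop_modes <- function(x, ...) {
  cat(sprintf("loop_modes: %d modes, omega^2 in [%.3g, %.3g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}
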