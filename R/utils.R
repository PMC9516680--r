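# internal geometry and angle helpers shared across modules

#' Wrap angles into (-pi, pi]
#' @param x numeric vector of angles in radians
#' @return wrapped angles
#' @keywords internal
wrap_angle <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Torsion angle of four points (IUPAC sign convention)
#'
#' Computed with the atan2 formulation, numerically stable near 0 and pi.
#' @param a,b,c,d coordinate triples
#' @return angle in radians in (-pi, pi]
#' @keywords internal
torsion4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  y <- sum(cross3(n1, n2) * b2) / vnorm(b2)
  x <- sum(n1 * n2)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("torsion undefined: collinear atom triplet")
  wrap_angle(atan2(y, x))
}

# Rodrigues rotation matrix about unit axis e by angle theta (right-handed)
rotation_about <- function(e, theta) {
  e <- unit(e)
  K <- matrix(c(0, e[3L], -e[2L],
                -e[3L], 0, e[1L],
                e[2L], -e[1L], 0), 3L, 3L)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# NeRF atom placement: position d bonded to c with given bond length,
# bond angle at c (a-b-c-d chain) and torsion about b-c.
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion), sin(angle) * sin(torsion))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Kabsch least-squares superposition
#'
#' Finds the rigid rotation + translation of \code{mobile} minimizing RMSD to
#' \code{fixed}, via SVD of the covariance with determinant sign correction.
#' @param fixed,mobile M x 3 coordinate matrices, rows paired
#' @return list with rotated \code{xyz}, rotation \code{R}, and the centers
#' @keywords internal
kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(fixed, 2L, cf)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  xyz <- sweep(A %*% t(R), 2L, cf, "+")
  list(xyz = xyz, R = R, center_fixed = cf, center_mobile = cm)
}

#' Backbone RMSD between two coordinate sets
#'
#' @param A,B M x 3 coordinate matrices with identical row order
#' @param superpose if TRUE apply Kabsch superposition of B onto A first
#' @return RMSD in Angstrom
#' @export
backbone_rmsd <- function(A, B, superpose = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3L)
    stop("coordinate sets must be matching M x 3 matrices")
  if (superpose) B <- kabsch(A, B)$xyz
  sqrt(mean(rowSums((A - B)^2)))
}
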