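# Essential-dynamics comparison of conformational ensembles: covariance
# PCA about the member closest to the average, 90%-variance subspace
# overlap gamma, a permutation-null Z-score, and eigenvector-derived
# B-factor profiles.

#' Principal component analysis of a conformational ensemble
#'
#' Diagonalizes the Cartesian covariance of backbone fluctuations about the
#' reference snapshot (the member with the smallest RMSD to the coordinate
#' mean), mass-unweighted. Input is either a \code{loop_ensemble} (backbone
#' N/CA/C/O of the flexible residues are selected) or a plain snapshot
#' matrix (rows = conformations, columns = xyz-interleaved coordinates).
#'
#' @param x a \code{loop_ensemble} or an S x 3K numeric matrix
#' @param elety backbone atom names selected from an ensemble
#' @return a \code{loop_pca}: eigenvalues (descending, Angstrom^2),
#'   orthonormal eigenvector columns, reference index, \code{m90}, the
#'   snapshot matrix, and per-atom labels when available
#' @export
loop_pca <- function(x, elety = c("N", "CA", "C", "O")) {
  atoms <- NULL
  if (inherits(x, "loop_ensemble")) {
    X <- ensemble_snapshots(x, elety)
    atoms <- attr(X, "atoms")
  } else {
    X <- as.matrix(x)
    atoms <- attr(x, "atoms")
  }
  if (nrow(X) < 2L) stop("PCA needs at least 2 conformations")
  pca_core(X, atoms)
}

pca_core <- function(X, atoms = NULL) {
  S <- nrow(X)
  mu <- colMeans(X)
  dev2 <- rowSums(sweep(X, 2L, mu)^2)
  ref <- which.min(dev2)
  Dx <- sweep(X, 2L, X[ref, ])
  Cv <- crossprod(Dx) / S
  e <- eigen((Cv + t(Cv)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  tot <- sum(vals)
  m90 <- if (tot <= 0) 1L else
    which(cumsum(vals) / tot >= 0.9 - 1e-12)[1L]
  structure(list(values = vals, vectors = e$vectors, ref = ref,
                 m90 = as.integer(m90), total_variance = tot,
                 X = X, atoms = atoms),
            class = "loop_pca")
}

#' @export
print.loop_pca <- function(x, ...) {
  cat(sprintf(
    "loop_pca: %d snapshots, %d coordinates, total variance %.3g A^2, m90 = %d\n",
    nrow(x$X), ncol(x$X), x$total_variance, x$m90))
  invisible(x)
}

m_for <- function(p, variance_fraction, m) {
  if (!is.null(m)) return(as.integer(m))
  if (variance_fraction >= 1) return(ncol(p$vectors))
  vals <- p$values
  tot <- sum(vals)
  if (tot <= 0) return(1L)
  as.integer(which(cumsum(vals) / tot >= variance_fraction - 1e-12)[1L])
}

#' Subspace overlap gamma between two essential-dynamics decompositions
#'
#' gamma = (1 / max(m_A, m_B)) * sum over the leading m_A x m_B eigenvector
#' pairs of their squared inner products. Equals 1 when both sums run over
#' complete bases and 0 for orthogonal subspaces. By default each m is the
#' smallest eigenvector count explaining 90% of that ensemble's variance.
#' The eigenvalue-weighted RWSIP-style variant is available behind
#' \code{weighted = TRUE}.
#'
#' @param A,B \code{loop_pca} objects over the same atom selection
#' @param variance_fraction variance level defining m per ensemble
#' @param m fixed eigenvector count overriding \code{variance_fraction}
#' @param weighted use the eigenvalue-weighted (RWSIP) form
#' @return gamma in [0, 1]
#' @export
subspace_overlap <- function(A, B, variance_fraction = 0.9, m = NULL,
                             weighted = FALSE) {
  if (ncol(A$vectors) != ncol(B$vectors))
    stop("PCA results have mismatched coordinate dimensions")
  mA <- m_for(A, variance_fraction, m)
  mB <- m_for(B, variance_fraction, m)
  if (weighted) {
    P <- crossprod(A$vectors, B$vectors)^2
    num <- sum(outer(A$values, B$values) * P)
    den <- sum(A$values * B$values)
    return(sqrt(num / den))
  }
  U <- A$vectors[, seq_len(mA), drop = FALSE]
  W <- B$vectors[, seq_len(mB), drop = FALSE]
  sum(crossprod(U, W)^2) / max(mA, mB)
}

#' Permutation Z-score for a subspace overlap
#'
#' Builds the null distribution by independently permuting the atom order
#' of every snapshot of ensemble B (one random permutation per snapshot,
#' applied to all three coordinates of an atom), recomputing its PCA and
#' the overlap with A; by default 1000 null models. The \code{"both"}
#' option permutes both ensembles.
#'
#' @param A,B \code{loop_pca} objects (B must carry its snapshot matrix)
#' @param n_null number of null models
#' @param seed RNG seed (results are bit-reproducible under a fixed seed)
#' @param variance_fraction,m,weighted as in \code{\link{subspace_overlap}}
#' @param permute permute \code{"B"} (default) or \code{"both"}
#' @return a \code{loop_overlap}: gamma, Z, null mean/sd, m used, seed
#' @export
overlap_zscore <- function(A, B, n_null = 1000L, seed = 1L,
                           variance_fraction = 0.9, m = NULL,
                           weighted = FALSE, permute = c("B", "both")) {
  permute <- match.arg(permute)
  set.seed(as.integer(seed))
  gamma_obs <- subspace_overlap(A, B, variance_fraction, m, weighted)
  K <- ncol(B$X) / 3L
  permute_snapshots <- function(X) {
    for (s in seq_len(nrow(X))) {
      p <- sample.int(K)
      cols <- as.numeric(t(cbind(3 * p - 2L, 3 * p - 1L, 3 * p)))
      X[s, ] <- X[s, cols]
    }
    X
  }
  null <- vapply(seq_len(n_null), function(i) {
    Bp <- pca_core(permute_snapshots(B$X))
    Ap <- if (permute == "both") pca_core(permute_snapshots(A$X)) else A
    subspace_overlap(Ap, Bp, variance_fraction, m, weighted)
  }, numeric(1L))
  mu <- mean(null)
  sd0 <- stats::sd(null)
  z <- if (sd0 > 0) (gamma_obs - mu) / sd0 else NA_real_
  structure(list(gamma = gamma_obs, z = z, null_mean = mu, null_sd = sd0,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 m_A = m_for(A, variance_fraction, m),
                 m_B = m_for(B, variance_fraction, m),
                 degenerate_null = !(sd0 > 0)),
            class = "loop_overlap")
}

#' @export
print.loop_overlap <- function(x, ...) {
  cat(sprintf(
    "loop_overlap: gamma = %.3f (m_A = %d, m_B = %d), Z = %.1f (null %.3f +/- %.3f, %d models)\n",
    x$gamma, x$m_A, x$m_B, x$z, x$null_mean, x$null_sd, x$n_null))
  invisible(x)
}

#' B-factor profile from a PCA decomposition
#'
#' Per-atom mean-square fluctuation sum_k lambda_k |u_k(atom)|^2 scaled by
#' 8 pi^2 / 3, averaged over the backbone atoms of each residue when atom
#' labels are available.
#'
#' @param p a \code{loop_pca}
#' @param n_modes number of modes to include (default: all)
#' @param per_residue average over each residue's atoms (needs atom labels)
#' @return data frame (resno, b) or per-atom vector when no labels exist
#' @export
bfactor_profile <- function(p, n_modes = length(p$values),
                            per_residue = TRUE) {
  U <- p$vectors[, seq_len(n_modes), drop = FALSE]
  lam <- p$values[seq_len(n_modes)]
  msf3 <- rowSums(sweep(U^2, 2L, lam, "*"))
  msf <- colSums(matrix(msf3, nrow = 3L))
  b <- 8 * pi^2 / 3 * msf
  if (!per_residue || is.null(p$atoms)) return(b)
  agg <- tapply(b, p$atoms$resno, mean)
  data.frame(resno = as.integer(names(agg)), b = as.numeric(agg))
}

#' Spearman rank correlation between two flexibility profiles
#'
#' @param a,b numeric vectors of equal length >= 3
#' @return rank correlation coefficient (average ranks for ties)
#' @export
spearman_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("profiles must have equal length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("rank correlation undefined for a zero-variance profile")
  stats::cor(a, b, method = "spearman")
}
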