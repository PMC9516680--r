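test_that("covariance PCA reproduces degenerate closed forms", {
  # identical snapshots: all eigenvalues zero
  X0 <- matrix(rep(stats::rnorm(12), each = 4), nrow = 4)
  p0 <- loop_pca(X0)
  expect_lt(max(p0$values), 1e-20)

  # two conformations: rank one, eigenvector along the difference
  set.seed(41)
  x1 <- stats::rnorm(12); x2 <- x1 + stats::rnorm(12, sd = 0.5)
  p2 <- loop_pca(rbind(x1, x2))
  expect_equal(sum(p2$values > 1e-12), 1L)
  d <- (x2 - x1) / sqrt(sum((x2 - x1)^2))
  expect_equal(abs(sum(p2$vectors[, 1] * d)), 1, tolerance = 1e-10)

  expect_error(loop_pca(matrix(1, 1, 6)), "at least 2")
})

test_that("PCA conserves variance and its eigenvectors are orthonormal", {
  ens <- simulate(fx$fit8, nsim = 15L, seed = 19L, max_rmsd = 1.0,
                  spacing = 0.1)
  p <- loop_pca(ens)
  expect_true(all(diff(p$values) <= 1e-12))        # descending
  expect_gte(min(p$values), -1e-10)
  G <- crossprod(p$vectors)
  expect_equal(G, diag(nrow(G)), tolerance = 1e-10, ignore_attr = TRUE)
  # naive variance oracle: mean squared deviation about the reference
  Dx <- sweep(p$X, 2L, p$X[p$ref, ])
  expect_equal(sum(p$values), sum(Dx^2) / nrow(p$X), tolerance = 1e-8)
  # m90 is the smallest count reaching 90% of the variance
  cum <- cumsum(p$values) / sum(p$values)
  expect_gte(cum[p$m90], 0.9)
  if (p$m90 > 1L) expect_lt(cum[p$m90 - 1L], 0.9)
})

test_that("subspace overlap has the stated algebraic properties", {
  ens <- simulate(fx$fit8, nsim = 12L, seed = 3L, max_rmsd = 1.0,
                  spacing = 0.1)
  A <- loop_pca(ens)
  expect_equal(subspace_overlap(A, A), 1, tolerance = 1e-12)
  expect_equal(subspace_overlap(A, A, m = 3L), 1, tolerance = 1e-12)

  # orthogonal top eigenvectors with m = 1: gamma = 0
  d <- 12L
  mk <- function(v) {
    X <- rbind(-v, v) * 2
    loop_pca(X)
  }
  A1 <- mk(c(1, rep(0, d - 1L)))
  B1 <- mk(c(0, 1, rep(0, d - 2L)))
  expect_equal(subspace_overlap(A1, B1, m = 1L), 0, tolerance = 1e-12)

  # complete bases of two different ensembles: gamma = 1
  ens2 <- simulate(fx$fit8, nsim = 12L, seed = 4L, max_rmsd = 1.0,
                   spacing = 0.1)
  B <- loop_pca(ens2)
  expect_equal(subspace_overlap(A, B, variance_fraction = 1), 1,
               tolerance = 1e-8)

  # symmetry at equal m and invariance to within-subspace rotation
  g_ab <- subspace_overlap(A, B, m = 4L)
  g_ba <- subspace_overlap(B, A, m = 4L)
  expect_equal(g_ab, g_ba, tolerance = 1e-10)
  Brot <- B
  Q <- qr.Q(qr(matrix(stats::rnorm(16), 4L)))
  Brot$vectors[, 1:4] <- B$vectors[, 1:4] %*% Q
  expect_equal(subspace_overlap(A, Brot, m = 4L), g_ab, tolerance = 1e-10)

  # eigenvalue-weighted variant is 1 for self-comparison
  expect_equal(subspace_overlap(A, A, weighted = TRUE), 1,
               tolerance = 1e-8)
})

test_that("random subspaces concentrate at the analytic overlap m/(3K)", {
  set.seed(55)
  d <- 60L; m <- 5L
  gs <- replicate(30, {
    U <- qr.Q(qr(matrix(stats::rnorm(d * m), d)))
    W <- qr.Q(qr(matrix(stats::rnorm(d * m), d)))
    sum(crossprod(U, W)^2) / m
  })
  expect_equal(mean(gs), m / d, tolerance = 0.25)
})

test_that("permutation Z-scores are seeded, finite and tail-sensitive", {
  ensA <- simulate(fx$fit8, nsim = 12L, seed = 5L, max_rmsd = 1.0,
                   spacing = 0.1)
  ensB <- simulate(fx$fit8, nsim = 12L, seed = 6L, max_rmsd = 1.0,
                   spacing = 0.1)
  A <- loop_pca(ensA); B <- loop_pca(ensB)
  z1 <- overlap_zscore(A, B, n_null = 60L, seed = 9L)
  z2 <- overlap_zscore(A, B, n_null = 60L, seed = 9L)
  expect_identical(z1$z, z2$z)                   # bit-reproducible
  expect_true(is.finite(z1$z))
  expect_gt(z1$null_sd, 0)
  # two ensembles of the same harmonic basin overlap far above the null
  expect_gt(z1$z, 10)
  expect_gt(z1$gamma, z1$null_mean)
  expect_equal(eval(formals(overlap_zscore)$n_null), 1000L)
})

test_that("B-factor profiles follow the eigen-decomposition exactly", {
  # constructed rank-1 decomposition localized on one residue
  K <- 8L
  vec <- numeric(3L * K)
  vec[7:9] <- c(0.6, 0.8, 0) / 1     # atom 3 only
  p1 <- structure(list(values = c(2, rep(0, 3L * K - 1L)),
                       vectors = cbind(vec, matrix(0, 3L * K,
                                                   3L * K - 1L)),
                       atoms = data.frame(resno = rep(1:4, each = 2L),
                                          elety = "CA")),
                  class = "loop_pca")
  b_atom <- bfactor_profile(p1, per_residue = FALSE)
  expect_equal(which(b_atom > 0), 3L)
  b_res <- bfactor_profile(p1)
  expect_equal(b_res$b[b_res$resno == 2], 8 * pi^2 / 3 * 2 / 2)
  expect_true(all(b_res$b[b_res$resno != 2] == 0))

  # Parseval: per-atom MSF sums to the total variance
  ens <- simulate(fx$fit8, nsim = 12L, seed = 8L, max_rmsd = 1.0,
                  spacing = 0.1)
  p <- loop_pca(ens)
  b <- bfactor_profile(p, per_residue = FALSE)
  expect_equal(sum(b) / (8 * pi^2 / 3), sum(p$values), tolerance = 1e-8)
  # ... and matches the direct per-atom variance of the raw snapshots
  Dx <- sweep(p$X, 2L, p$X[p$ref, ])
  msf_direct <- colSums(matrix(colMeans(Dx^2), nrow = 3L))
  expect_equal(b / (8 * pi^2 / 3), msf_direct, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank correlation matches a rank-then-Pearson oracle", {
  a <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_correlation(a, a), 1)
  expect_equal(spearman_correlation(a, -a), -1)
  set.seed(77)
  for (i in 1:5) {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    expect_equal(spearman_correlation(x, y),
                 stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  expect_error(spearman_correlation(rep(1, 5), 1:5), "zero-variance")
  expect_error(spearman_correlation(1:2, 1:2), "length")
})
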