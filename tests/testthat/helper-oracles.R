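# Independent oracles and shared fixtures for the test suite. Every oracle
# here deliberately takes a different computational route than the package
# implementation it checks.

# shared small fixtures (built once per test run)
fx <- local({
  st8 <- build_synthetic_loop(8)
  st11 <- build_synthetic_loop(11)
  list(
    st8 = st8, lp8 = select_loop(st8, synthetic_loop_spec(8), 10),
    st11 = st11, lp11 = select_loop(st11, synthetic_loop_spec(11), 10),
    fit8 = loop_nma(st8, synthetic_loop_spec(8)),
    fit11 = loop_nma(st11, synthetic_loop_spec(11))
  )
})

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# torsion oracle: bio3d's implementation, degrees
torsion_oracle <- function(a, b, c, d) {
  bio3d::torsion.xyz(c(a, b, c, d)) * pi / 180
}

# quaternion (Horn) superposition oracle, an algorithm independent of the
# SVD-based Kabsch used by the package
quaternion_rmsd <- function(A, B) {
  cA <- colMeans(A); cB <- colMeans(B)
  X <- sweep(B, 2L, cB); Y <- sweep(A, 2L, cA)
  S <- crossprod(X, Y)
  K <- matrix(0, 4L, 4L)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# exhaustive assignment oracle for mode matching (m <= 8)
all_perms <- function(m) {
  if (m == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(m - 1L))
    for (k in seq_len(m))
      out[[length(out) + 1L]] <- append(p, m, after = k - 1L)
  out
}
best_assignment <- function(P) {
  m <- nrow(P)
  best <- NULL; best_val <- -Inf
  for (p in all_perms(m)) {
    val <- sum(abs(P[cbind(seq_len(m), unlist(p))]))
    if (val > best_val) { best_val <- val; best <- unlist(p) }
  }
  best
}

# finite-difference Hessian of the ENM energy along dihedrals
fd_hessian <- function(loop, net, q0, dofs, h = 1e-4) {
  n <- length(q0)
  E <- function(q) enm_energy(net, apply_dihedrals(loop, q, dofs = dofs))
  H <- matrix(0, n, n)
  E0 <- E(q0)
  for (a in seq_len(n)) {
    ea <- replace(numeric(n), a, h)
    H[a, a] <- (E(q0 + ea) - 2 * E0 + E(q0 - ea)) / h^2
    if (a < n) for (b in (a + 1L):n) {
      eb <- replace(numeric(n), b, h)
      H[a, b] <- H[b, a] <-
        (E(q0 + ea + eb) - E(q0 + ea - eb) -
         E(q0 - ea + eb) + E(q0 - ea - eb)) / (4 * h^2)
    }
  }
  H
}

# perturb a loop along a random combination of its constrained modes out to
# roughly target_rmsd (capped steps, per-step refresh), returning the
# perturbed full-structure coordinates
perturb_along_modes <- function(fit, target_rmsd, seed) {
  set.seed(seed)
  loop <- fit$model
  coefs <- stats::rnorm(length(fit$modes$values))
  coefs <- coefs / max(abs(coefs))
  bb <- loopnma:::loop_backbone_idx(loop, "loop")
  out <- loopnma:::flex_excursion(loop, fit$dofs,
                                  loopnma:::coords_matrix(loop$structure),
                                  coefs, target_rmsd, target_rmsd / 2,
                                  deg2rad(1), list(), bb,
                                  modes0 = fit$modes)
  out$xyz[[length(out$xyz)]]
}

# anchor deviation of coordinates vs the fixture equilibrium
anchor_deviation <- function(loop, xyz) {
  xyz0 <- loopnma:::coords_matrix(loop$structure)
  fr <- anchor_frame(loop, xyz0)
  g0 <- loopnma:::constraint_values(fr, xyz0)
  g <- loopnma:::constraint_values(fr, xyz)
  max(sqrt(sum((g[1:3] - g0[1:3])^2)), abs(g[4:6] - g0[4:6]))
}

# random generalized eigensystem with full-rank constraints, for the
# bordered-vs-nullspace equivalence checks
random_constrained_system <- function(n, C = 6L) {
  A <- matrix(stats::rnorm(n * n), n)
  H <- crossprod(A) / n
  B <- matrix(stats::rnorm(n * n), n)
  Tm <- crossprod(B) / n + diag(0.1, n)
  J <- matrix(stats::rnorm(C * n), C, n)
  list(H = H, Tm = Tm,
       cons = structure(list(J = J, frame = NULL, C = C),
                        class = "constraint_set"))
}
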