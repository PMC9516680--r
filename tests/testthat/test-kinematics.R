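test_that("degree-of-freedom tables follow the chain topology", {
  lp <- fx$lp11
  dofs <- define_dofs(lp)
  expect_length(dofs, 23L)              # n = 2N + 1
  # omega-enabled variant: n = 3N + 1
  lpo <- select_loop(fx$st11, synthetic_loop_spec(11, include_omega = TRUE),
                     10)
  expect_length(define_dofs(lpo), 34L)

  # last DOF is phi of Ct; its moving set is just the Ct carbonyl carbon
  last <- dofs[[length(dofs)]]
  expect_equal(last$kind, "phi")
  expect_equal(last$resno, lp$ct_resno)
  ct_c <- which(lp$structure$atoms$resno == lp$ct_resno &
                lp$structure$atoms$elety == "C")
  expect_equal(last$moving, ct_c)

  # moving sets are nested along the chain and never contain their axis
  for (k in seq_along(dofs)) {
    expect_false(any(dofs[[k]]$axis %in% dofs[[k]]$moving))
    if (k > 1L)
      expect_true(all(dofs[[k]]$moving %in% dofs[[k - 1L]]$moving))
  }
})

test_that("extracted torsions agree with an independent oracle", {
  set.seed(7)
  pp <- cbind(stats::runif(6, -170, 170), stats::runif(6, -170, 170))
  st <- build_synthetic_loop(6, pp)
  lp <- select_loop(st, synthetic_loop_spec(6, include_omega = TRUE), 10)
  dofs <- define_dofs(lp)
  q <- extract_dihedrals(lp, dofs = dofs)
  xyz <- loopnma:::coords_matrix(st)
  for (k in seq_along(dofs)) {
    quad <- dofs[[k]]$quad
    oracle <- torsion_oracle(xyz[quad[1], ], xyz[quad[2], ],
                             xyz[quad[3], ], xyz[quad[4], ])
    # compare modulo 2*pi: +pi and -pi are the same torsion
    expect_equal(loopnma:::wrap_angle(q[k] - oracle) + 1, 1,
                 tolerance = 1e-9)
  }
  # planar cis arrangement has omega = 0
  expect_equal(loopnma:::torsion4(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, 1, 0)), 0)
  # collinear triplets are rejected
  expect_error(loopnma:::torsion4(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                  c(3, 1, 0)), "collinear")
})

test_that("dihedral application is exact, invertible and preserves rigid geometry", {
  lp <- fx$lp8
  dofs <- define_dofs(lp)
  q0 <- extract_dihedrals(lp, dofs = dofs)
  xyz0 <- loopnma:::coords_matrix(lp$structure)

  # identity
  expect_lt(max(abs(apply_dihedrals(lp, q0, dofs = dofs) - xyz0)), 1e-9)

  # inverse pair at a random displacement
  set.seed(3)
  q1 <- q0 + stats::runif(length(q0), -1, 1)
  xyz1 <- apply_dihedrals(lp, q1, dofs = dofs)
  expect_lt(max(abs(loopnma:::wrap_angle(
    extract_dihedrals(lp, xyz1, dofs) - q1))), 1e-9)

  # rotating phi of the first flexible residue leaves its own N in place
  q2 <- q0; q2[1] <- loopnma:::wrap_angle(q2[1] + pi)
  xyz2 <- apply_dihedrals(lp, q2, dofs = dofs)
  iN <- which(lp$structure$atoms$resno == lp$spec$first &
              lp$structure$atoms$elety == "N")
  expect_equal(xyz2[iN, ], xyz0[iN, ])

  # every non-DOF internal coordinate is preserved essentially exactly
  a <- lp$structure$atoms
  bond <- function(xyz, i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  for (r in lp$spec$first:lp$spec$last) {
    iN <- which(a$resno == r & a$elety == "N")
    iCA <- which(a$resno == r & a$elety == "CA")
    iC <- which(a$resno == r & a$elety == "C")
    jN <- which(a$resno == r + 1 & a$elety == "N")
    for (p in list(c(iN, iCA), c(iCA, iC), c(iC, jN)))
      expect_equal(bond(xyz1, p[1], p[2]), bond(xyz0, p[1], p[2]),
                   tolerance = 1e-9)
    # omega is not a DOF here and must be untouched (modulo the branch cut)
    jCA <- which(a$resno == r + 1 & a$elety == "CA")
    om1 <- loopnma:::torsion4(xyz1[iCA, ], xyz1[iC, ], xyz1[jN, ],
                              xyz1[jCA, ])
    om0 <- loopnma:::torsion4(xyz0[iCA, ], xyz0[iC, ], xyz0[jN, ],
                              xyz0[jCA, ])
    expect_equal(loopnma:::wrap_angle(om1 - om0) + 1, 1, tolerance = 1e-9)
  }
})

test_that("analytic derivatives match central finite differences", {
  lp <- fx$lp8
  dofs <- define_dofs(lp)
  q0 <- extract_dihedrals(lp, dofs = dofs)
  D <- cartesian_derivatives(lp, dofs = dofs)
  h <- 1e-6
  for (k in seq_along(dofs)) {
    qp <- q0; qp[k] <- qp[k] + h
    qm <- q0; qm[k] <- qm[k] - h
    fd <- (apply_dihedrals(lp, qp, dofs = dofs)[lp$mobile, ] -
           apply_dihedrals(lp, qm, dofs = dofs)[lp$mobile, ]) / (2 * h)
    expect_lt(max(abs(as.numeric(t(fd)) - D[, k])), 1e-6)
  }
  # upstream atoms have exactly zero columns
  mob <- lp$mobile
  for (k in seq_along(dofs)) {
    still <- setdiff(mob, dofs[[k]]$moving)
    rows <- rep(3 * (match(still, mob) - 1), each = 3) + 1:3
    expect_true(all(D[rows, k] == 0))
  }
})

test_that("the linearization error is second order in the step", {
  lp <- fx$lp8
  dofs <- define_dofs(lp)
  q0 <- extract_dihedrals(lp, dofs = dofs)
  D <- cartesian_derivatives(lp, dofs = dofs)
  xyz0 <- loopnma:::coords_matrix(lp$structure)[lp$mobile, ]
  set.seed(5)
  dir <- stats::rnorm(length(q0)); dir <- dir / sqrt(sum(dir^2))
  hs <- 10^seq(-4, -2, length.out = 7)
  errs <- vapply(hs, function(h) {
    xyz1 <- apply_dihedrals(lp, q0 + h * dir, dofs = dofs)[lp$mobile, ]
    lin <- xyz0 + matrix(D %*% (h * dir), ncol = 3, byrow = TRUE)
    sqrt(sum((xyz1 - lin)^2))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(errs) ~ log(hs)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.05)
})

test_that("backbone RMSD matches closed forms and a quaternion oracle", {
  set.seed(11)
  A <- matrix(stats::rnorm(30), ncol = 3)
  expect_equal(backbone_rmsd(A, A), 0)
  B <- sweep(A, 2L, c(1, 0, 0), "+")
  expect_equal(backbone_rmsd(A, B, superpose = FALSE), 1.0)
  expect_equal(backbone_rmsd(A, B, superpose = TRUE), 0, tolerance = 1e-9)
  for (i in 1:5) {
    B2 <- matrix(stats::rnorm(30), ncol = 3)
    expect_equal(backbone_rmsd(A, B2, superpose = TRUE),
                 quaternion_rmsd(A, B2), tolerance = 1e-9)
  }
  expect_error(backbone_rmsd(A, B2[1:5, ]), "matching")
})
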