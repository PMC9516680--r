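test_that("structures survive a PDB write/read round trip", {
  st <- build_synthetic_loop(6, scaffold_radius = 12, scaffold_n = 8)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, f)
  st2 <- read_structure(f)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(st2$atoms$elety, st$atoms$elety)
  expect_equal(st2$atoms$resno, st$atoms$resno)
  expect_lt(max(abs(as.matrix(st2$atoms[, c("x", "y", "z")]) -
                    as.matrix(st$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_true(all(st2$atoms$mass > 0))
  expect_true(all(st2$atoms$backbone ==
                    (st2$atoms$elety %in% c("N", "CA", "C", "O"))))
})

test_that("alternate locations resolve to highest occupancy and insertion codes fail", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.999   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  st <- read_structure(f)
  ca <- st$atoms[st$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 1.458, tolerance = 1e-6)

  ins <- sub("^(.{26}) ", "\\1A", lines[1])
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(ins, lines[-1]), f2)
  expect_error(read_structure(f2), "insertion")
})

test_that("heavy atom counts follow the sequence (glycine drops CB)", {
  # 3 flexible + 2 anchors = 5 residues; all-ALA has 5 atoms each
  st <- build_synthetic_loop(3)
  expect_equal(nrow(st$atoms), 25L)
  stg <- build_synthetic_loop(3, sequence = c("A", "A", "G", "A", "A"))
  expect_equal(nrow(stg$atoms), 24L)
  expect_false(any(stg$atoms$resno == 3 & stg$atoms$elety == "CB"))
})

test_that("loop selection builds disjoint mobile and environment sets", {
  st <- build_synthetic_loop(6, scaffold_radius = 8, scaffold_n = 12)
  sp <- synthetic_loop_spec(6)
  lp0 <- select_loop(st, sp, env_cutoff = 0)
  expect_length(lp0$env, 0L)
  # mobile = heavy atoms of loop residues + anchor N/CA/C
  n_loop_atoms <- sum(st$atoms$resno >= 2 & st$atoms$resno <= 7)
  expect_length(lp0$mobile, n_loop_atoms + 3L)

  lp <- select_loop(st, sp, env_cutoff = 50)
  expect_length(intersect(lp$mobile, lp$env), 0L)
  # generous cutoff picks up every non-mobile atom including the scaffold
  expect_length(lp$env, nrow(st$atoms) - length(lp$mobile))
})

test_that("environment inclusion matches a brute-force pair-distance scan", {
  st <- build_synthetic_loop(6, scaffold_radius = c(5, 15), scaffold_n = 15)
  sp <- synthetic_loop_spec(6)
  cutoff <- 10
  lp <- select_loop(st, sp, env_cutoff = cutoff)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  other <- setdiff(seq_len(nrow(xyz)), lp$mobile)
  # oracle: residue is in iff any of its atoms is within cutoff of any
  # mobile atom (exhaustive O(M^2) scan)
  res_in <- character(0)
  for (i in other) {
    d <- sqrt(colSums((t(xyz[lp$mobile, ]) - xyz[i, ])^2))
    if (min(d) <= cutoff)
      res_in <- union(res_in, paste(st$atoms$chain[i], st$atoms$resno[i]))
  }
  expected <- other[paste(st$atoms$chain[other], st$atoms$resno[other])
                    %in% res_in]
  expect_setequal(lp$env, expected)
})

test_that("loop selection fails loudly on broken or incomplete chains", {
  st <- build_synthetic_loop(5)
  sp <- synthetic_loop_spec(5)
  # pull one mid-loop nitrogen far away -> chain break
  stb <- st
  i <- which(stb$atoms$resno == 4 & stb$atoms$elety == "N")
  stb$atoms$x[i] <- stb$atoms$x[i] + 50
  expect_error(select_loop(stb, sp, 10), "chain break")
  # delete a backbone atom -> structured error naming the residue
  std <- st
  std$atoms <- std$atoms[-which(std$atoms$resno == 5 &
                                std$atoms$elety == "CA"), ]
  expect_error(select_loop(std, sp, 10), "missing backbone atom CA.*5")
})

test_that("multi-model ensembles round-trip with a constant environment", {
  fit <- fx$fit8
  ens <- simulate(fit, nsim = 3L, seed = 11L, max_rmsd = 0.6,
                  spacing = 0.15)
  expect_length(ens$xyz, 3L)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  re <- read_ensemble(f)
  expect_equal(nrow(re$xyz), 3L)
  # model 2 coordinates match at PDB precision
  loop <- ens$model
  full <- loopnma:::coords_matrix(loop$structure)
  full[loop$mobile, ] <- ens$xyz[[2L]]
  got <- matrix(re$xyz[2L, ], ncol = 3L, byrow = TRUE)
  expect_lt(max(abs(got - full)), 1e-3)
  # environment atoms identical across models
  env_cols <- as.numeric(t(cbind(3 * loop$env - 2L, 3 * loop$env - 1L,
                                 3 * loop$env)))
  expect_equal(re$xyz[1L, env_cols], re$xyz[3L, env_cols])
  # empty ensembles are refused
  ens0 <- ens
  ens0$xyz <- list()
  expect_error(write_ensemble(ens0, f), "empty")
})

test_that("fixture geometry is ideal and deterministic", {
  st1 <- build_synthetic_loop(5, c(-63, -41), seed = 1L,
                              scaffold_radius = 10, scaffold_n = 6)
  st2 <- build_synthetic_loop(5, c(-63, -41), seed = 99L,
                              scaffold_radius = 10, scaffold_n = 6)
  expect_identical(st1$atoms, st2$atoms)

  lp <- select_loop(st1, synthetic_loop_spec(5), 0)
  q <- extract_dihedrals(lp)
  expect_equal(rad2deg(q[1:10]), rep(c(-63, -41), 5), tolerance = 1e-6)

  a <- st1$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pick <- function(r, e) xyz[which(a$resno == r & a$elety == e), ]
  for (r in 2:6) {
    expect_equal(sqrt(sum((pick(r, "N") - pick(r, "CA"))^2)), 1.458,
                 tolerance = 1e-6)
    expect_equal(sqrt(sum((pick(r, "CA") - pick(r, "C"))^2)), 1.525,
                 tolerance = 1e-6)
    expect_equal(sqrt(sum((pick(r, "C") - pick(r + 1, "N"))^2)), 1.329,
                 tolerance = 1e-6)
    # consecutive CA-CA distance for trans peptides
    expect_equal(sqrt(sum((pick(r, "CA") - pick(r + 1, "CA"))^2)), 3.809,
                 tolerance = 1e-3)
  }
})
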