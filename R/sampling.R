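# Iterative small-step mode application: morphing toward a target and
# random closed-ensemble generation. Every step recomputes the constrained
# NMA at the current geometry (the linearization is only locally exact),
# caps the largest single-dihedral change at max_step_deg, and re-identifies
# modes across steps by their dot products.

#' Options for the iterative morphing driver
#'
#' @param max_step_deg largest single-dihedral change per step, degrees
#'   (capped at 1, the validity range of the per-step linearization)
#' @param rmsd_tol convergence tolerance: stop when the best backbone RMSD
#'   has improved by less than this (Angstrom) over \code{patience}
#'   consecutive iterations
#' @param max_iters iteration cap
#' @param patience convergence window, iterations
#' @param superpose_mode \code{"full"} (Kabsch on all shared heavy atoms),
#'   \code{"flanks"} (backbone of anchors +/- 2 residues), or \code{"none"}
#' @param direction_space \code{"dihedral"} (wrapped angle differences),
#'   \code{"cartesian"} (project the coordinate difference onto the
#'   Cartesian images D v_k of the modes), or \code{"auto"} (the default:
#'   dihedral differences, falling back to the Cartesian direction when
#'   progress stalls far from the target — the wrapped dihedral difference
#'   can become orthogonal to the mode span at points where the Cartesian
#'   distance is still large)
#' @return a list of validated options
#' @export
morph_options <- function(max_step_deg = 1.0, rmsd_tol = 0.05,
                          max_iters = 2000L, patience = 25L,
                          superpose_mode = c("full", "flanks", "none"),
                          direction_space = c("auto", "dihedral",
                                              "cartesian")) {
  if (max_step_deg <= 0 || max_step_deg > 1.0)
    stop("max_step_deg must lie in (0, 1]")
  if (max_iters < 1L) stop("max_iters must be >= 1")
  list(max_step_deg = max_step_deg, rmsd_tol = rmsd_tol,
       max_iters = as.integer(max_iters), patience = as.integer(patience),
       superpose_mode = match.arg(superpose_mode),
       direction_space = match.arg(direction_space))
}

#' Match a fresh mode set to the previous one
#'
#' Greedy assignment maximizing the absolute dot product of the dihedral
#' parts, with signs flipped so every matched dot product is positive.
#' Keeps mode identities stable across per-step NMA refreshes.
#'
#' @param previous,current \code{constrained_modes} with equal mode counts
#' @return \code{current} with columns permuted and sign-fixed
#' @export
match_modes <- function(previous, current) {
  P <- crossprod(previous$vectors, current$vectors)
  m <- ncol(P)
  if (m != nrow(P)) stop("mode counts differ")
  perm <- integer(m)
  A <- abs(P)
  for (step in seq_len(m)) {
    ij <- arrayInd(which.max(A), dim(A))
    perm[ij[1L]] <- ij[2L]
    A[ij[1L], ] <- -Inf
    A[, ij[2L]] <- -Inf
  }
  sgn <- sign(P[cbind(seq_len(m), perm)])
  sgn[sgn == 0] <- 1
  current$vectors <- sweep(current$vectors[, perm, drop = FALSE], 2L, sgn, "*")
  current$values <- current$values[perm]
  current$lambda <- sweep(current$lambda[, perm, drop = FALSE], 2L, sgn, "*")
  current$permutation <- perm
  current
}

# superpose a target structure's coordinates onto the reference frame of
# `loop`, using atoms shared by both structures
superpose_target <- function(loop, target, mode) {
  a <- loop$structure$atoms
  b <- target$atoms
  xyz_b <- as.matrix(b[, c("x", "y", "z")])
  if (mode == "none") return(xyz_b)
  key_a <- paste(a$chain, a$resno, a$elety)
  key_b <- paste(b$chain, b$resno, b$elety)
  idx_a <- if (mode == "flanks") loop_backbone_idx(loop, "flanks")
           else seq_len(nrow(a))
  shared <- intersect(key_a[idx_a], key_b)
  if (length(shared) < 3L) stop("too few shared atoms for superposition")
  ia <- idx_a[match(shared, key_a[idx_a])]
  ib <- match(shared, key_b)
  fit <- kabsch(as.matrix(a[ia, c("x", "y", "z")]),
                xyz_b[ib, , drop = FALSE])
  sweep(sweep(xyz_b, 2L, fit$center_mobile) %*% t(fit$R),
        2L, fit$center_fixed, "+")
}

#' Morph a loop toward a target conformation along constrained modes
#'
#' At each iteration the constrained NMA is recomputed at the current
#' geometry, the remaining difference to the target is projected onto the
#' modes (the step is their overlap-weighted combination), the step is
#' scaled so the largest dihedral change equals \code{max_step_deg}, and
#' the move is applied through the exact kinematics. Iteration stops when
#' the backbone RMSD to the target stalls or \code{max_iters} is reached.
#'
#' @param loop a \code{loop_model}
#' @param target a \code{loop_structure} containing the same loop residues
#'   and atoms
#' @param opts a \code{\link{morph_options}} list
#' @param enm_args list of elastic-network options passed to the per-step
#'   NMA refresh
#' @return a \code{loop_morph}: list(final_rmsd, initial_rmsd, rmsd_trace,
#'   n_iter, xyz, q, converged)
#' @export
morph_to_target <- function(loop, target, opts = morph_options(),
                            enm_args = list()) {
  dofs <- define_dofs(loop)
  bbsel <- loop_backbone_idx(loop, "loop")
  a <- loop$structure$atoms
  b <- target$atoms
  key_b <- paste(b$chain, b$resno, b$elety)
  tmap <- match(paste(a$chain, a$resno, a$elety)[bbsel], key_b)
  if (anyNA(tmap)) stop("target structure lacks loop backbone atoms")
  xyz_t <- superpose_target(loop, target, opts$superpose_mode)
  # target dihedrals, from the target's own geometry
  map_all <- match(paste(a$chain, a$resno, a$elety), key_b)
  q_t <- vapply(dofs, function(d) {
    q <- map_all[d$quad]
    if (anyNA(q)) stop("target structure lacks atoms for a DOF torsion")
    torsion4(xyz_t[q[1L], ], xyz_t[q[2L], ], xyz_t[q[3L], ], xyz_t[q[4L], ])
  }, numeric(1L))

  xyz <- coords_matrix(loop$structure)
  bb_t <- xyz_t[tmap, , drop = FALSE]
  rmsd0 <- backbone_rmsd(bb_t, xyz[bbsel, , drop = FALSE])
  best <- list(rmsd = rmsd0, xyz = xyz)
  trace <- rmsd0
  best_hist <- rmsd0
  max_step <- deg2rad(opts$max_step_deg)
  frame0 <- anchor_frame(loop, xyz)
  g0 <- constraint_values(frame0, xyz)
  use_dihedral <- opts$direction_space != "cartesian"
  best_at_switch <- Inf
  dead_flips <- 0L
  it <- 0L
  while (it < opts$max_iters) {
    it <- it + 1L
    eng <- do.call(nma_engine, c(list(loop, xyz, dofs), enm_args))
    V <- eng$modes$vectors
    q <- extract_dihedrals(loop, xyz, dofs)
    if (use_dihedral) {
      dq <- wrap_angle(q_t - q)
      # overlap-weighted combination of modes = the component of the target
      # direction achievable inside the closure-preserving span (the modes
      # are T-orthonormal, so the Euclidean projection needs the Gram solve)
      step <- V %*% solve(crossprod(V), crossprod(V, dq))
    } else {
      dr <- as.numeric(t(xyz_t[match(paste(a$chain, a$resno, a$elety)[loop$mobile],
                                     key_b), , drop = FALSE] -
                         xyz[loop$mobile, , drop = FALSE]))
      X <- eng$D %*% V
      w <- colSums(X * dr) / pmax(colSums(X * X), 1e-12)
      step <- V %*% w
    }
    mx <- max(abs(step))
    if (mx < 1e-9) break
    step <- step * min(1, max_step / mx)
    corr <- closure_correction(loop, eng$D, frame0,
                               constraint_values(frame0, xyz) - g0)
    xyz <- apply_dihedrals(loop, q + as.numeric(step) + corr,
                           xyz = xyz, dofs = dofs)
    r <- backbone_rmsd(bb_t, xyz[bbsel, , drop = FALSE])
    trace <- c(trace, r)
    if (r < best$rmsd) best <- list(rmsd = r, xyz = xyz)
    best_hist <- c(best_hist, best$rmsd)
    # converged when the windowed improvement of the best RMSD stalls
    if (length(best_hist) > opts$patience &&
        best_hist[length(best_hist) - opts$patience] - best$rmsd <
          opts$rmsd_tol) {
      # in auto mode a stall flips the target-direction measure; morphing
      # ends only when both measures stall back-to-back with no real
      # progress in between
      progressed <- best_at_switch - best$rmsd >= opts$rmsd_tol
      if (opts$direction_space == "auto" && (progressed || dead_flips < 1L)) {
        dead_flips <- if (progressed) 0L else dead_flips + 1L
        use_dihedral <- !use_dihedral
        best_at_switch <- best$rmsd
        best_hist <- best$rmsd
      } else break
    }
  }
  structure(list(final_rmsd = best$rmsd, initial_rmsd = rmsd0,
                 rmsd_trace = trace, n_iter = it, xyz = best$xyz,
                 q = extract_dihedrals(loop, best$xyz, dofs),
                 converged = it < opts$max_iters),
            class = "loop_morph")
}

#' @export
print.loop_morph <- function(x, ...) {
  cat(sprintf(
    "loop_morph: backbone RMSD %.2f -> %.3f A in %d iterations%s\n",
    x$initial_rmsd, x$final_rmsd, x$n_iter,
    if (x$converged) "" else " (iteration cap reached)"))
  invisible(x)
}

# First-order restoration of the closure constraints toward their original
# values. The per-step linearization leaves a second-order anchor drift;
# because the constraints pin the anchor to the FIXED protein, each refresh
# folds the minimum-norm Newton step -J^+ (g - g0) back into the move,
# keeping the accumulated drift at the scale of a single step's quadratic
# error rather than letting it grow along the trajectory.
closure_correction <- function(loop, D, frame0, g_delta) {
  mob <- loop$mobile
  rowblock <- function(i) {
    p <- match(i, mob)
    D[(3L * p - 2L):(3L * p), , drop = FALSE]
  }
  J <- rbind(rowblock(frame0$iCA),
             crossprod(frame0$v, rowblock(frame0$iN)),
             crossprod(frame0$w, rowblock(frame0$iN)),
             crossprod(frame0$v, rowblock(frame0$iC)))
  -as.numeric(crossprod(J, solve(tcrossprod(J), g_delta)))
}

# one random-direction excursion used by sample_ensemble and mode animation:
# flex along `coefs` (mode-space coefficients, refreshed/matched each step)
# until `max_rmsd` from the start, saving frames every `spacing` of RMSD
# drift from the last saved frame
flex_excursion <- function(loop, dofs, xyz0, coefs, max_rmsd, spacing,
                           max_step, enm_args = list(), bbsel,
                           modes0 = NULL, max_steps = 1000L,
                           spacing_mode = c("drift", "radial")) {
  spacing_mode <- match.arg(spacing_mode)
  xyz <- xyz0
  bb0 <- xyz0[bbsel, , drop = FALSE]
  saved_xyz <- list()
  saved_rmsd <- numeric(0)
  last_saved <- bb0
  next_radial <- spacing
  prev_modes <- modes0
  frame0 <- anchor_frame(loop, xyz0)
  g0 <- constraint_values(frame0, xyz0)
  for (s in seq_len(max_steps)) {
    eng <- do.call(nma_engine, c(list(loop, xyz, dofs), enm_args))
    modes <- eng$modes
    if (!is.null(prev_modes)) modes <- match_modes(prev_modes, modes)
    prev_modes <- modes
    step <- modes$vectors %*% coefs
    mx <- max(abs(step))
    if (mx < 1e-12) break
    step <- step * min(1, max_step / mx)
    corr <- closure_correction(loop, eng$D, frame0,
                               constraint_values(frame0, xyz) - g0)
    q <- extract_dihedrals(loop, xyz, dofs)
    xyz <- apply_dihedrals(loop, q + as.numeric(step) + corr,
                           xyz = xyz, dofs = dofs)
    bb <- xyz[bbsel, , drop = FALSE]
    r0 <- backbone_rmsd(bb0, bb)
    save_now <- if (spacing_mode == "drift")
      backbone_rmsd(last_saved, bb) > spacing else r0 >= next_radial
    if (save_now) {
      saved_xyz[[length(saved_xyz) + 1L]] <- xyz
      saved_rmsd <- c(saved_rmsd, r0)
      last_saved <- bb
      if (spacing_mode == "radial")
        next_radial <- spacing * (floor(r0 / spacing) + 1L)
    }
    if (r0 >= max_rmsd) break
  }
  list(xyz = saved_xyz, rmsd = saved_rmsd)
}

#' Sample an ensemble of closed-loop conformations
#'
#' Repeats random excursions from the starting structure: draw random mode
#' coefficients (standard normal, scaled by 1/omega so low-frequency modes
#' dominate, as for thermal amplitudes of harmonic modes; or equal weights),
#' flex in capped steps with per-step NMA refresh and dot-product mode
#' matching, save a conformation whenever the backbone RMSD from the last
#' saved one exceeds \code{spacing}, stop the excursion at \code{max_rmsd}
#' and return to the start, until \code{n_samples} conformations are stored.
#' The starting conformation is always stored first. Deterministic under a
#' fixed seed.
#'
#' @param loop a \code{loop_model}
#' @param n_samples conformations to store (default 10000)
#' @param max_rmsd excursion amplitude cap, Angstrom
#' @param spacing save spacing, Angstrom (default 0.1)
#' @param seed integer RNG seed
#' @param max_step_deg per-step dihedral cap, degrees
#' @param coef_dist \code{"thermal"} (1/omega scaling) or \code{"equal"}
#' @param enm_args elastic-network options for the per-step refresh
#' @return a \code{loop_ensemble}: shared atom table plus, per stored
#'   conformation, the mobile coordinates, dihedral vector, backbone RMSD
#'   from start, and closure error
#' @export
sample_ensemble <- function(loop, n_samples = 10000L, max_rmsd = 1.5,
                            spacing = 0.1, seed = 1L, max_step_deg = 1.0,
                            coef_dist = c("thermal", "equal"),
                            enm_args = list()) {
  coef_dist <- match.arg(coef_dist)
  if (max_rmsd < 0) stop("max_rmsd must be >= 0")
  set.seed(as.integer(seed))
  dofs <- define_dofs(loop)
  bbsel <- loop_backbone_idx(loop, "loop")
  xyz0 <- coords_matrix(loop$structure)
  eng0 <- do.call(nma_engine, c(list(loop, xyz0, dofs), enm_args))
  frame0 <- eng0$frame
  g0 <- constraint_values(frame0, xyz0)
  nm <- length(eng0$modes$values)

  xyz_list <- list(xyz0)
  q_list <- list(extract_dihedrals(loop, xyz0, dofs))
  rmsd <- 0
  closure <- 0
  max_step <- deg2rad(max_step_deg)
  while (length(xyz_list) < n_samples && max_rmsd > 0) {
    coefs <- stats::rnorm(nm)
    if (coef_dist == "thermal")
      coefs <- coefs / sqrt(pmax(eng0$modes$values, 1e-12))
    coefs <- coefs / max(abs(coefs))
    exc <- flex_excursion(loop, dofs, xyz0, coefs, max_rmsd, spacing,
                          max_step, enm_args, bbsel, modes0 = eng0$modes)
    for (k in seq_along(exc$xyz)) {
      if (length(xyz_list) >= n_samples) break
      xyz_list[[length(xyz_list) + 1L]] <- exc$xyz[[k]]
      q_list[[length(q_list) + 1L]] <- extract_dihedrals(loop, exc$xyz[[k]],
                                                         dofs)
      rmsd <- c(rmsd, exc$rmsd[k])
      g <- constraint_values(frame0, exc$xyz[[k]])
      closure <- c(closure, max(vnorm(g[1:3] - g0[1:3]), abs(g[4:6] - g0[4:6])))
    }
  }
  structure(list(model = loop,
                 xyz = lapply(xyz_list, function(x) x[loop$mobile, ,
                                                      drop = FALSE]),
                 q = do.call(rbind, q_list), rmsd = rmsd, closure = closure,
                 meta = list(seed = seed, max_rmsd = max_rmsd,
                             spacing = spacing, max_step_deg = max_step_deg,
                             coef_dist = coef_dist)),
            class = "loop_ensemble")
}

#' @export
print.loop_ensemble <- function(x, ...) {
  cat(sprintf(
    "loop_ensemble: %d conformations, RMSD from start %.2f-%.2f A, max closure error %.2g A\n",
    length(x$xyz), min(x$rmsd), max(x$rmsd), max(x$closure)))
  invisible(x)
}

#' Simulate closed-loop conformations from a fitted loop NMA
#'
#' Convenience wrapper: \code{simulate} on a \code{loop_nma} fit draws an
#' ensemble with \code{\link{sample_ensemble}} under the fit's elastic
#' network options.
#'
#' @param object a \code{loop_nma} fit
#' @param nsim number of conformations
#' @param seed RNG seed
#' @param ... passed to \code{\link{sample_ensemble}}
#' @return a \code{loop_ensemble}
#' @export
simulate.loop_nma <- function(object, nsim = 100L, seed = 1L, ...) {
  o <- object$opts
  sample_ensemble(object$model, n_samples = nsim, seed = seed,
                  enm_args = list(enm_rule = o$enm_rule,
                                  enm_cutoff = o$enm_cutoff,
                                  enm_k0 = o$enm_k0,
                                  enm_power = o$enm_power),
                  ...)
}
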