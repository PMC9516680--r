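# The model-fitting front end: loop_nma() assembles the whole pipeline
# (loop selection, DOFs, elastic network, H and T, closure constraints,
# constrained eigenproblem) and returns a classed fit object.

#' Constrained torsional normal mode analysis of a protein loop
#'
#' Fits the elastic-network normal modes of a loop in backbone dihedral
#' space under exact loop-closure constraints at the C-terminal anchor.
#' For an N-residue loop with phi/psi degrees of freedom (n = 2N + 1) and
#' C = 6 closure constraints, the fit carries n - C = 2N - 5 modes; with
#' omega dihedrals enabled, 3N - 5.
#'
#' @param structure a \code{loop_structure}, or a path to a PDB file
#' @param spec a \code{loop_spec}; ignored if \code{structure} is already a
#'   \code{loop_model}
#' @param env_cutoff environment inclusion cutoff in Angstrom
#' @param enm_rule,enm_cutoff,enm_k0,enm_power elastic network options
#'   (see \code{\link{build_elastic_network}})
#' @param constrained if FALSE, skip the closure constraints (baseline NMA)
#' @param solver \code{"nullspace"} (default) or \code{"bordered"}
#' @return an object of class \code{loop_nma} with components
#'   \code{model} (the \code{loop_model}), \code{dofs}, \code{q0},
#'   \code{enm}, \code{H}, \code{Tmat}, \code{frame}, \code{constraints},
#'   and \code{modes} (a \code{constrained_modes} or \code{loop_modes})
#' @examples
#' st <- build_synthetic_loop(11)
#' fit <- loop_nma(st, synthetic_loop_spec(11))
#' fit
#' length(fit$modes$values)   # 2N - 5 = 17
#' @export
loop_nma <- function(structure, spec = NULL, env_cutoff = 10,
                     enm_rule = c("power", "cutoff"), enm_cutoff = 10,
                     enm_k0 = 1, enm_power = 2, constrained = TRUE,
                     solver = c("nullspace", "bordered")) {
  enm_rule <- match.arg(enm_rule)
  solver <- match.arg(solver)
  loop <- if (inherits(structure, "loop_model")) structure
          else {
            if (is.character(structure)) structure <- read_structure(structure)
            if (is.null(spec)) stop("a loop_spec is required")
            select_loop(structure, spec, env_cutoff = env_cutoff)
          }
  dofs <- define_dofs(loop)
  xyz <- coords_matrix(loop$structure)
  parts <- nma_engine(loop, xyz, dofs,
                      enm_rule = enm_rule, enm_cutoff = enm_cutoff,
                      enm_k0 = enm_k0, enm_power = enm_power,
                      constrained = constrained, solver = solver)
  structure(c(list(model = loop, dofs = dofs,
                   q0 = extract_dihedrals(loop, xyz, dofs),
                   opts = list(enm_rule = enm_rule, enm_cutoff = enm_cutoff,
                               enm_k0 = enm_k0, enm_power = enm_power,
                               constrained = constrained, solver = solver)),
              parts),
            class = "loop_nma")
}

# one NMA evaluation at given coordinates; reused at every refinement step
# of the morphing/sampling drivers
nma_engine <- function(loop, xyz, dofs, enm_rule = "power", enm_cutoff = 10,
                       enm_k0 = 1, enm_power = 2, constrained = TRUE,
                       solver = "nullspace") {
  D <- cartesian_derivatives(loop, xyz, dofs)
  net <- build_elastic_network(loop, xyz, rule = enm_rule,
                               cutoff = enm_cutoff, k0 = enm_k0,
                               p = enm_power)
  H <- internal_hessian(net, loop, D, xyz)
  Tm <- kinetic_matrix(loop$structure$atoms$mass[loop$mobile], D)
  if (constrained) {
    frame <- anchor_frame(loop, xyz)
    cons <- constraint_jacobian(loop, frame, D)
    modes <- solve_constrained(H, Tm, cons, method = solver)
  } else {
    frame <- NULL; cons <- NULL
    modes <- solve_unconstrained(H, Tm)
  }
  list(D = D, enm = net, H = H, Tmat = Tm, frame = frame,
       constraints = cons, modes = modes)
}

#' @export
print.loop_nma <- function(x, ...) {
  s <- x$model$spec
  m <- x$modes
  cat("Constrained torsional NMA fit\n")
  cat(sprintf("  loop: chain %s residues %d-%d (N = %d%s)\n",
              s$chain, s$first, s$last, s$N,
              if (s$include_omega) ", omega DOFs" else ""))
  cat(sprintf("  degrees of freedom: %d; springs: %d\n",
              length(x$dofs), nrow(x$enm$springs)))
  if (!is.null(x$constraints))
    cat(sprintf("  closure constraints: %d (rank %d)\n",
                x$constraints$C, qr(x$constraints$J)$rank))
  cat(sprintf("  modes: %d, omega^2 range [%.4g, %.4g]\n",
              length(m$values), min(m$values), max(m$values)))
  invisible(x)
}

#' @export
summary.loop_nma <- function(object, ...) {
  m <- object$modes
  tab <- data.frame(mode = seq_along(m$values),
                    omega2 = m$values,
                    frequency = sqrt(pmax(m$values, 0)))
  if (inherits(m, "constrained_modes"))
    tab$closure_residual <- apply(abs(m$J %*% m$vectors), 2L, max)
  structure(list(spec = object$model$spec, table = tab,
                 n = length(object$dofs)),
            class = "summary.loop_nma")
}

#' @export
print.summary.loop_nma <- function(x, ...) {
  cat(sprintf("Loop NMA summary: N = %d, n = %d, %d modes\n",
              x$spec$N, x$n, nrow(x$table)))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.loop_nma <- function(object, ...) object$modes$vectors

#' Eigenvalue spectrum and per-mode dihedral amplitudes
#' @param x a \code{loop_nma} fit
#' @param ... passed to \code{barplot}
#' @export
plot.loop_nma <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::barplot(x$modes$values, names.arg = seq_along(x$modes$values),
                    xlab = "mode", ylab = expression(omega^2),
                    main = "eigenvalue spectrum", ...)
  graphics::image(seq_len(ncol(x$modes$vectors)),
                  seq_len(nrow(x$modes$vectors)),
                  t(abs(x$modes$vectors)),
                  xlab = "mode", ylab = "dihedral DOF",
                  main = "|mode components|")
  invisible(x)
}

#' Per-residue mean-square fluctuations implied by the modes
#'
#' Thermal-amplitude weighting 1/omega^2 over the constrained modes,
#' propagated to Cartesian space through the derivative matrix and averaged
#' over the backbone atoms of each flexible residue.
#'
#' @param object a \code{loop_nma} fit
#' @param ... unused
#' @return data frame (resno, msf)
#' @export
fluctuations <- function(object, ...) {
  stopifnot(inherits(object, "loop_nma"))
  V <- object$modes$vectors
  w2 <- pmax(object$modes$values, 1e-12)
  X <- object$D %*% V           # 3M x nmodes Cartesian mode shapes
  msf_atom <- rowSums(sweep(X^2, 2L, w2, "/"))
  msf_atom <- colSums(matrix(msf_atom, nrow = 3L))
  a <- object$model$structure$atoms[object$model$mobile, ]
  keep <- a$backbone & a$resno >= object$model$spec$first &
          a$resno <= object$model$spec$last
  agg <- tapply(msf_atom[keep], a$resno[keep], mean)
  data.frame(resno = as.integer(names(agg)), msf = as.numeric(agg))
}
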