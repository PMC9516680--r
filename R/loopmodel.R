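# Loop selection: the mobile region (N flexible residues plus the N/CA/C
# atoms of the rigid carboxy-terminal anchor) and its fixed elastic-network
# environment.

#' Define a flexible loop span
#'
#' Residue numbers follow the deposited PDB numbering and the range is
#' inclusive. The residue after \code{last} is the rigid C-terminal (Ct)
#' anchor whose N/CA/C geometry the closure constraints preserve; the residue
#' before \code{first} is the fixed N-terminal anchor the loop is rebuilt
#' from. With \code{include_omega = FALSE} the degrees of freedom are the
#' phi/psi pairs of the flexible residues plus phi of Ct (n = 2N + 1);
#' with omega enabled, n = 3N + 1.
#'
#' @param chain chain identifier
#' @param first,last first and last flexible residue numbers (inclusive)
#' @param include_omega treat omega dihedrals as degrees of freedom
#' @return a \code{loop_spec}
#' @export
loop_spec <- function(chain, first, last, include_omega = FALSE) {
  first <- as.integer(first); last <- as.integer(last)
  N <- last - first + 1L
  if (N < 2L) stop("a loop needs at least 2 flexible residues")
  structure(list(chain = chain, first = first, last = last, N = N,
                 include_omega = isTRUE(include_omega)),
            class = "loop_spec")
}

#' @export
print.loop_spec <- function(x, ...) {
  cat(sprintf("loop_spec: chain %s residues %d-%d (N = %d%s)\n",
              x$chain, x$first, x$last, x$N,
              if (x$include_omega) ", omega enabled" else ""))
  invisible(x)
}

atom_row <- function(atoms, chain, resno, elety) {
  i <- which(atoms$chain == chain & atoms$resno == resno &
             atoms$elety == elety)
  if (length(i) != 1L) NA_integer_ else i
}

#' Select a loop and its elastic-network environment
#'
#' The mobile set holds the heavy atoms of the flexible residues plus the
#' N/CA/C atoms of the Ct anchor. The environment set holds the heavy atoms
#' of every other residue that has at least one atom within
#' \code{env_cutoff} of a mobile atom; these atoms never move but their
#' springs to mobile atoms keep the loop energetics grounded in the context
#' of the whole protein.
#'
#' @param structure a \code{loop_structure}
#' @param spec a \code{loop_spec}
#' @param env_cutoff environment inclusion cutoff in Angstrom (default 10)
#' @return a \code{loop_model}
#' @export
select_loop <- function(structure, spec, env_cutoff = 10) {
  a <- structure$atoms
  ct <- spec$last + 1L
  nt <- spec$first - 1L
  # complete backbone over the loop span plus anchors
  for (r in nt:ct) {
    need <- if (r == nt) "C" else if (r == ct) c("N", "CA", "C")
            else c("N", "CA", "C", "O")
    for (e in need)
      if (is.na(atom_row(a, spec$chain, r, e)))
        stop(sprintf("missing backbone atom %s in residue %d chain %s",
                     e, r, spec$chain))
  }
  # chain continuity across the span
  for (r in nt:(ct - 1L)) {
    ic <- atom_row(a, spec$chain, r, "C")
    jn <- atom_row(a, spec$chain, r + 1L, "N")
    d <- sqrt(sum((as.numeric(a[ic, c("x", "y", "z")]) -
                   as.numeric(a[jn, c("x", "y", "z")]))^2))
    if (d > 2.0)
      stop(sprintf("chain break between residues %d and %d (C-N %.2f A)",
                   r, r + 1L, d))
  }
  in_loop <- a$chain == spec$chain & a$resno >= spec$first &
             a$resno <= spec$last
  mobile <- c(which(in_loop),
              vapply(c("N", "CA", "C"),
                     function(e) atom_row(a, spec$chain, ct, e), integer(1L)))
  mobile <- sort(unique(mobile))

  env <- integer(0)
  if (env_cutoff > 0) {
    other <- setdiff(seq_len(nrow(a)), mobile)
    if (length(other)) {
      xyz <- as.matrix(a[, c("x", "y", "z")])
      mx <- xyz[mobile, , drop = FALSE]
      # residue-level inclusion: any atom within cutoff pulls in the residue
      dmin <- vapply(other, function(i)
        sqrt(min(colSums((t(mx) - xyz[i, ])^2))), numeric(1L))
      hit <- unique(paste(a$chain[other], a$resno[other])[dmin <= env_cutoff])
      env <- other[paste(a$chain[other], a$resno[other]) %in% hit]
    }
  }
  structure(list(structure = structure, spec = spec,
                 mobile = mobile, env = env,
                 ct_resno = ct, nt_resno = nt, env_cutoff = env_cutoff),
            class = "loop_model")
}

#' @export
print.loop_model <- function(x, ...) {
  cat(sprintf(paste0("loop_model: chain %s residues %d-%d (N = %d), ",
                     "%d mobile atoms, %d environment atoms\n"),
              x$spec$chain, x$spec$first, x$spec$last, x$spec$N,
              length(x$mobile), length(x$env)))
  invisible(x)
}

loop_atom <- function(loop, resno, elety) {
  i <- atom_row(loop$structure$atoms, loop$spec$chain, resno, elety)
  if (is.na(i)) stop(sprintf("atom %s of residue %d not found", elety, resno))
  i
}
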