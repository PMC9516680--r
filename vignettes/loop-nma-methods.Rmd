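---
title: "Closure-constrained torsional normal modes: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closure-constrained torsional normal modes: models, numerics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopnma)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, the numerical choices, what
the synthetic fixtures do and do not emulate, and the known limitations.

## The model

### Degrees of freedom

A loop of `N` flexible residues is described purely by backbone torsions:
φ and ψ of each flexible residue plus φ of the rigid C-terminal anchor
residue (`n = 2N + 1`), optionally including the ω dihedrals
(`n = 3N + 1`). All bond lengths, bond angles, and non-variable torsions
are frozen at their input values; side chains are carried rigidly but are
not degrees of freedom. The chain is rebuilt from the fixed N-terminal
side, so rotating a bond moves every atom downstream toward the
C-terminus. This makes the moving sets of the ordered DOFs nested, which
is also why the mass-metric matrix can become ill-conditioned for short
loops (see *Numerics* below).

### Elastic network potential

The potential is a network of Hookean springs connecting heavy atoms,
with the input structure as the minimum. Springs couple mobile atoms to
each other and to a fixed environment — every heavy atom of a residue
with at least one atom within `env_cutoff` (default 10 Å) of the mobile
set. The environment contributes no degrees of freedom but its springs
enter the Hessian, which is how the loop's energetics stay grounded in
the context of the surrounding protein: motions that would drive the loop
into its neighbors are stiff.

Because the input structure is the ENM minimum, the internal Hessian is
the Gram matrix `H = Σ k_ij (∂d_ij/∂q)(∂d_ij/∂q)ᵀ` — symmetric positive
semidefinite by construction, with no force term. The kinetic matrix is
`T = Dᵀ M D` with `D` the analytic derivative matrix (`∂r/∂q = ê × (r −
r_axis)` for downstream atoms) and `M` the diagonal mass matrix with
per-element atomic masses. Two spring rules are available:

* `power` (default): `k = k0 · d0⁻²` for all pairs within 10 Å. The
  inverse-square decay is a common distance-weighted ENM choice and makes
  results insensitive to the exact cutoff;
* `cutoff`: uniform `k = k0` within a cutoff.

The absolute scale `k0` only scales the eigenvalues; mode shapes, and
everything built from them, are invariant to it.

### Closure constraints

Closure means the anchor's N/Cα/C geometry keeps its position and
orientation relative to the fixed protein. Six scalars suffice: the three
Cartesian coordinates of the anchor Cα, and three projections of the
anchor N and C atoms onto a local frame at Cα. The frame used here is `u`
along Cα→N, `v` the unit normal of the N–Cα–C plane, and `w = u × v`
(in-plane, orthogonal to `u`). The projections constrained are `r_N·v`,
`r_N·w`, and `r_C·v`.

The choice of which three projections to constrain is forced, not free.
With Cα pinned and the N–Cα bond length fixed, N moves on a sphere: two
projections (`v` and `w` components) pin it, while `r_N·u` is redundant.
With Cα and N pinned and the Cα–C length and N–Cα–C angle fixed, the only
first-order freedom left to C is rotation about the Cα–N axis — and the
velocity of that rotation points along the plane normal `v`. So `r_C·v`
is the one independent projection; `r_C·u` and `r_C·w` are frozen by bond
geometry. The package verifies this numerically: appending any of the
redundant rows to the Jacobian leaves its rank at 6, and choosing
`r_C·w` instead would produce a rank-5 (unsolvable) constraint set.

### The constrained eigenproblem

Imposing the constraints with Lagrange multipliers yields the extended
("bordered") generalized eigenproblem

$$
\begin{pmatrix} H & J_g^\top \\ J_g & 0 \end{pmatrix}
\begin{pmatrix} v \\ \lambda \end{pmatrix}
= \omega^2
\begin{pmatrix} T & 0 \\ 0 & 0 \end{pmatrix}
\begin{pmatrix} v \\ \lambda \end{pmatrix}
$$

of size `n + C` with `2C` spurious/infinite solutions, leaving `n − C`
closure-preserving modes (`2N − 5` for the φ/ψ parameterization). The
modes are orthogonal in the extended space but not in plain dihedral
space; no re-orthogonalization is applied. Lagrange components are stored
with each mode but excluded from all dihedral-space operations.

## Numerics

* **Solver route.** The default solver projects onto an orthonormal SVD
  basis `Z` of `null(J_g)` and solves the reduced symmetric-definite
  problem `ZᵀHZ w = ω² ZᵀTZ w` by whitening. The bordered route (solved
  by shift-inversion of the singular pencil) is retained as an option and
  agrees with the null-space route to 1e-8 on random systems up to
  `n = 40` in the test suite; it is not the default because filtering its
  `2C` infinite eigenvalues is inherently more fragile.
* **Metric regularization.** If the smallest eigenvalue of `T` falls
  below `1e-12 · tr(T)/n`, `1e-10 · tr(T)/n` is added to the diagonal.
  Nested moving sets make `T` nearly collinear for very short loops; the
  perturbation is far below any physical eigenvalue of interest.
* **Rank decisions.** Constraint-set rank and null-space dimension use
  singular values with a `max(dim) · max(σ) · 1e-10` threshold; a
  rank-deficient constraint set is a hard error (degenerate anchor), not
  a warning.
* **Step cap and refresh.** The modes respect closure exactly only to
  first order, so finite motion is taken in steps whose largest single
  dihedral change is `max_step_deg` (default and maximum 1°), with the
  full NMA recomputed at every step. Single-step anchor errors are
  second order in amplitude (measured log–log slope 2.00).
* **Closure restoration.** Second-order per-step errors accumulate along
  a trajectory. Because the constraints pin the anchor to the *fixed*
  protein, each step folds in the minimum-norm first-order correction
  `−J⁺(g − g₀)` toward the original constraint values. This keeps the
  anchor drift near one step's quadratic error regardless of trajectory
  length: ≤ 1e-3 Å over 4 Å excursions at 1° steps, and halving the step
  more than quarters the drift. This is not post-hoc loop repair in the
  inverse-kinematics sense — the trajectory never leaves the constraint
  manifold by more than a single linearization residual.
* **Mode matching.** Across refreshes, modes are re-identified by greedy
  assignment on absolute dot products of dihedral parts, with signs fixed
  to keep matched products positive. Greedy matching agrees with
  exhaustive assignment whenever the refresh is a small perturbation
  (all diagonal dot products above 1/√2), which a 1° step guarantees in
  practice.
* **Morph direction and convergence.** The step direction is the
  Euclidean projection of the remaining dihedral difference onto the mode
  span (the modes are T-orthonormal, so the projection needs the Gram
  solve, not a plain `VVᵀ`). Overlap weights are recomputed fresh each
  iteration rather than accumulated. The wrapped dihedral difference is a
  finite secant, not a tangent, and at large amplitudes it can become
  orthogonal to the current mode span while the Cartesian distance is
  still large — a genuine fixed point of the dihedral-direction map. The
  default `"auto"` mode therefore flips to the Cartesian target direction
  (coordinate difference projected onto the Cartesian mode images `D v_k`)
  whenever the best backbone RMSD improves by less than `rmsd_tol`
  (default 0.05 Å) over 25 consecutive iterations, and keeps alternating
  as long as each flip is followed by real progress; morphing ends when
  both measures stall back-to-back, or at `max_iters` (default 2000).
  Pure `"dihedral"` and `"cartesian"` variants remain available. On 4 Å
  synthetic transitions the alternation recovers targets that either pure
  variant alone misses.
* **Torsion conventions.** IUPAC sign convention, angles wrapped to
  (−π, π]; torsions at the ±180° branch cut are compared modulo 2π.
  Collinear atom triplets raise an error.

## Sampling and comparison choices

* **Random coefficients.** Mode coefficients are standard normal scaled
  by 1/ω, matching the thermal amplitudes of harmonic modes, so
  low-frequency (collective) modes dominate; an equal-weight option
  exists. Excursions restart from the exact start conformation, which
  bounds drift and makes ensembles reproducible under a seed.
* **Saving rule.** During sampling a conformation is stored when its
  backbone RMSD from the last stored one exceeds `spacing` (default
  0.1 Å), up to the excursion amplitude `max_rmsd`; defaults store
  10,000 conformations. Mode animations instead space frames by RMSD
  from the start (every 0.25 Å up to 3 Å), which is the natural spacing
  for visualizing a single pathway.
* **PCA reference.** Covariance is taken about the snapshot closest to
  the coordinate mean (not the mean itself), mass-unweighted, over
  N/Cα/C/O of the flexible residues.
* **Overlap normalization.** γ sums squared inner products over the
  leading `m_A × m_B` eigenvector pairs and divides by `max(m_A, m_B)`,
  with each `m` the smallest count explaining 90% of that ensemble's
  variance. This form is 1 for complete bases and 0 for orthogonal
  subspaces; an eigenvalue-weighted RWSIP-style variant is available
  behind a flag. The permutation null re-permutes the atom order of
  every snapshot of the second ensemble independently (the same
  permutation applied to an atom's three coordinates), re-runs its PCA,
  and recomputes γ; 1000 null models by default.

## The synthetic fixture generator

`build_synthetic_loop()` builds poly-alanine loops with constant
Engh–Huber-style geometry (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å;
backbone angles 111.2°/116.6°/121.9°; ω = 180°), chosen φ/ψ, one rigid
anchor residue at each end, optional glycines, and an optional
deterministic scaffold shell of fixed pseudo-atoms. It emulates exactly
the features the formalism depends on — a kinematic chain with rigid
bond geometry, a well-defined anchor, and an enclosing elastic
environment. It does **not** emulate real structures' heterogeneous bond
geometry, side-chain packing, or irregular environments. Consequently,
passing tests demonstrate the correctness of the kinematics, the
constraint algebra, the eigen-solvers and the samplers; they do not
certify prediction quality on deposited structures, where deviations in
bond lengths/angles and ω between conformers put part of the difference
outside the reachable torsional manifold.

## Problem sizes used by the tests and the acceptance script

Chosen as the smallest sizes at which every property is sharply testable:
loops of N = 4–20 for mode counting; N = 8 and N = 11 fixtures for
kinematics, closure scaling (4 Å excursions), and morph recovery (20
seeded perturbations of 1–3 Å); 50 random constrained systems up to
n = 40 for solver equivalence; ensembles of 12–100 snapshots for
essential-dynamics checks, with 200 permutation models for the Z-score in
the acceptance script.

## Known limitations

* Only backbone torsions move; differences residing in bond angles,
  bond lengths, or (unless enabled) ω cannot be reproduced, which floors
  the final RMSD of morphs between real conformers.
* The elastic network is a stand-in for the unstated reference network
  of the surrounding literature; its rule and cutoff are configurable,
  and mode shapes are robust to the choice, but absolute frequencies are
  not meaningful.
* No energetic scoring of sampled loops and no steric-clash filtering
  beyond what the elastic environment implies.
* The PCA reference convention ("closest to average") makes the
  covariance a second-moment matrix about a member, not the textbook
  mean-centered covariance; the two coincide as ensembles grow.
* Insertion codes, mmCIF input, and side-chain rotamers are out of
  scope; chains with breaks inside the loop span are rejected.
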