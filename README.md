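# loopnma

Constrained normal mode analysis (NMA) of protein loops in backbone
torsion-angle space.

Protein loops move, and most of the interesting motion happens while both
ends of the loop stay covalently attached to the rest of the protein. Plain
NMA of a loop does not respect that: perturbing a structure along
unconstrained torsional modes tears the loop off its C-terminal anchor.
`loopnma` computes an orthogonal set of loop motions that preserve closure
*exactly to first order*, and provides the iterative machinery (small-step
application with per-step refresh) that keeps closure tight at finite
amplitudes. It is aimed at structural bioinformaticians who need fast,
closure-respecting loop conformational sampling — for loop modeling,
refinement, or comparison against molecular dynamics ensembles.

## The model

A loop of `N` flexible residues is parameterized by its backbone dihedrals
(φ and ψ of each flexible residue plus φ of the rigid C-terminal anchor
residue, `n = 2N + 1` degrees of freedom; ω dihedrals optional). The
potential is an elastic network of Hookean springs over the heavy atoms of
the loop *and* its spatial environment, with the input structure as the
energy minimum, giving the generalized torsional eigenproblem

    H v = ω² T v

with `H` the internal-coordinate Hessian and `T` the kinetic-energy
(mass-metric) matrix. Loop closure is imposed through `C = 6` scalar
constraints `g₁..g₆`: the Cartesian position of the anchor Cα, plus three
projections of the anchor N and C atoms in an orthonormal frame `(u, v, w)`
built at the anchor Cα (`u` along Cα→N, `v` the N–Cα–C plane normal,
`w = u × v`). Only six constraints are needed — the fixed N–Cα and Cα–C
bond lengths and the N–Cα–C bond angle make the remaining projections
redundant. With the constraint Jacobian `J_g`, the Lagrange-multiplier
stationarity conditions assemble the bordered Hessian eigenproblem

    [ H   J_gᵀ ] [ v ]        [ T  0 ] [ v ]
    [ J_g  0   ] [ λ ]  = ω²  [ 0  0 ] [ λ ]

whose `n − C = 2N − 5` finite eigenpairs are the closure-preserving modes
(the `2C` remaining solutions are spurious or infinite). The solver
default projects onto the null space of `J_g`, which is numerically robust
to the singular right-hand metric; the bordered route is kept and
cross-checked against it in the test suite.

On top of the mode computation the package provides:

* **morphing** — iteratively flexing a loop toward a target conformation
  along the overlap-weighted combination of its constrained modes, with
  per-step NMA refresh, dot-product mode matching, and a 1° cap on any
  single dihedral change per step;
* **ensemble sampling** — random thermal-weighted mode combinations,
  flexed in capped steps to a chosen RMSD amplitude, stored every 0.1 Å
  of drift until the requested number of closed conformations (10,000 by
  default) is reached;
* **essential dynamics** — covariance PCA about the snapshot closest to
  the ensemble average, the 90%-variance subspace overlap γ between two
  ensembles, a permutation-null Z-score for γ, and eigenvector-derived
  per-residue B-factor profiles with Spearman rank correlations.

## Worked example

Everything below runs on a synthetic ideal-geometry fixture — no external
structure files needed. An 11-residue loop has `n = 23` torsional degrees
of freedom and `2N − 5 = 17` constrained modes:

```r
library(loopnma)

st  <- build_synthetic_loop(11)              # ideal-geometry fixture
fit <- loop_nma(st, synthetic_loop_spec(11)) # constrained torsional NMA
fit
#> Constrained torsional NMA fit
#>   loop: chain A residues 2-12 (N = 11)
#>   degrees of freedom: 23; springs: 1454
#>   closure constraints: 6 (rank 6)
#>   modes: 17, omega^2 range [0.002384, 0.05434]

head(summary(fit)$table, 5)
#>   mode      omega2  frequency closure_residual
#> 1    1 0.002383630 0.04882243     6.392673e-17
#> 2    2 0.003659075 0.06049029     7.996327e-17
#> 3    3 0.005045687 0.07103300     1.121267e-16
#> 4    4 0.006884812 0.08297477     6.879377e-17
#> 5    5 0.013699082 0.11704308     1.877125e-16
```

The `closure_residual` column is `max |J_g v|` per mode: the modes lie in
the constraint null space to machine precision. A *finite* displacement
along a mode leaves closure only to second order — a full 1° step along
the softest mode moves the anchor by less than 10⁻⁴ Å:

```r
v   <- fit$modes$vectors[, 1]; v <- v / max(abs(v))
err <- verify_closure(fit$model, fit$q0, v, 1 * pi / 180, fit$dofs)
#> closure error at 1 degree along mode 1: 6.60e-05 A
```

Sampling a closed ensemble and analyzing it:

```r
ens <- simulate(fit, nsim = 50, seed = 7, max_rmsd = 1.5, spacing = 0.1)
ens
#> loop_ensemble: 50 conformations, RMSD from start 0.00-1.51 A,
#>   max closure error 0.0014 A

p <- loop_pca(ens)
p
#> loop_pca: 50 snapshots, 132 coordinates, total variance 31.5 A^2, m90 = 3
head(bfactor_profile(p), 3)
#>   resno        b
#> 1     2 1.387361
#> 2     3 5.933205
#> 3     4 8.108557
```

Every stored conformation stays closed to about 10⁻³ Å even after
excursions of 1.5 Å backbone RMSD; three principal components explain 90%
of the sampled variance, and the B-factor profile peaks mid-loop, away
from the pinned anchors — exactly what closure should produce.

`morph_to_target(loop, target)` drives a loop between two closed
conformations; on mode-space perturbations of several Å it recovers the
target to well under 0.1 Å. A command-line front end wrapping the same
functions ships in `inst/cli/loopmodes` with `nma`, `morph`, `sample` and
`compare` subcommands.

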