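Package: loopnma
Title: Constrained Torsion-Space Normal Mode Analysis for Protein Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Normal mode analysis of protein loops in backbone dihedral
    (torsion-angle) space under exact loop-closure constraints. An elastic
    network model over the loop and its environment supplies the potential;
    the closure conditions at the carboxy-terminal anchor are imposed through
    a bordered-Hessian (Lagrange multiplier) eigenproblem, yielding an
    orthogonal set of 2N-5 closure-preserving modes for an N-residue loop.
    Includes iterative mode-following tools for morphing a loop toward a
    target conformation and for sampling ensembles of closed loops, plus
    essential-dynamics utilities (covariance PCA, subspace overlap with
    permutation Z-scores, B-factor profiles) for comparing ensembles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
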