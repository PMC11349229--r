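---
title: "Slow feature analysis collective variables: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow feature analysis collective variables: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowcv)
```

# The problem

Rare conformational transitions — a tryptophan χ1/χ2 flip that opens a
cryptic pocket, a DFG-motif rearrangement in a kinase — happen on
timescales far beyond routine unbiased molecular dynamics, because the
barriers between metastable basins are many kT. Metadynamics
accelerates sampling by depositing repulsive Gaussians along collective
variables (CVs), but it only works when the CVs actually parameterize
the slow transition. `slowcv` derives such CVs directly from data: it
extracts, by slow feature analysis (SFA), the linear combinations of
periodic dihedral features that vary most slowly across an ensemble of
short unbiased trajectories, and hands them to PLUMED as explicit
affine CVs.

# The model

## Featurization

Side-chain (χ1, χ2) and backbone (φ, ψ) torsions are computed with the
IUPAC signed-dihedral convention: the angle between the plane of atoms
(1,2,3) and the plane of atoms (2,3,4), measured looking from atom 2
to atom 3, clockwise positive, cis = 0, range (−π, π]. The convention
is computed from the two plane normals with a two-argument arctangent
and is rigid-motion invariant. Because angles live on a circle, every
torsion enters the analysis as the *pair* (sin θ, cos θ); this removes
the branch cut and makes any affine combination of the features an
aperiodic quantity (hence `PERIODIC=NO` in the PLUMED export).
Residues that lack a requested angle (χ2 of alanine, say) raise an
explicit per-selection error rather than being skipped: a silently
shrunken feature set would silently change the meaning of the fitted
weights.

Independent trajectories are concatenated with recorded segment
boundaries. All temporal statistics respect those boundaries.

## Slow feature analysis

Given features C(t), the fit composes four stages:

1. **Normalization.** Each column is centered by its temporal mean and
   divided by its population root-mean-square deviation, so all
   features are dimensionless and comparable. Statistics throughout use
   population (1/T) normalization — the natural reading of temporal
   averages ⟨·⟩ — because sample (1/(T−1)) normalization, while
   materially identical, breaks the exact identities the tests assert
   (unit variance to 1e−6, Δy_k = λ_k to 1e−8).
2. **Expansion.** Order 1 is the identity: linear SFA, the mode used
   for molecular data. Order 2 appends all degree-two monomials
   (c₁c₁, c₁c₂, …, c_Jc_J), enabling recovery of features that are
   only quadratically expressible.
3. **Whitening.** PCA-based sphering z = S(Z − ⟨Z⟩) with
   S = D^(−1/2)Uᵀ from the eigendecomposition of the population
   covariance, so ⟨zzᵀ⟩ = I on the retained rank.
4. **Slowness PCA.** Forward differences ż(t) = z(t+1) − z(t) are
   taken *within segments only*; the eigenvectors of the raw second
   moment ⟨żżᵀ⟩ with the smallest eigenvalues are the slow features,
   ordered ascending. On the training data each output has exactly
   zero mean, unit variance, zero cross-moments, and slowness
   Δy_k = ⟨ẏ_k²⟩ = λ_k.

No lag time exists anywhere in this construction — the point that
separates SFA from tICA: there is nothing to scan or cross-validate
before the CVs are usable.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `order` | 1 | — | linear SFA suffices for sin/cos dihedral features; order 2 exists for signals whose slow content is quadratic |
| `n_components` | 2 | — | metadynamics in practice biases the first two slow features |
| `floor_rel` (whitening floor) | 1e−10 | relative | principal directions with eigenvalue < 1e−10 × the largest are discarded: near-null directions explode under D^(−1/2) and would contaminate the slowest features with numerical noise |
| Gaussian `height` | 1.5 | kJ/mol | standard protein well-tempered choice |
| `pace` | 500 | steps | ditto |
| `biasfactor` | 20 | — | ditto |
| widths | std/3 of each CV over the first 10000 unbiased frames | CV units | the early-trajectory spread estimates the basin width; a third of it resolves basins without washing them out |
| funnel (`zcc`, `rcyl`, `alpha`, `kappa`) | 2.0 nm, 0.1 nm, 0.5 rad, 50000 kJ/mol/nm² | — | standard ligand-binding funnel geometry |

# Numerical choices and conventions

**Sign convention.** Slow features are sign-indeterminate; for
deterministic output each weight vector is flipped so that its
largest-magnitude pulled-back input coefficient is positive, ties
broken by feature index. Note the interaction with scale invariance:
rescaling a raw input column by a *positive* constant leaves every
y_k(t) unchanged to machine precision (normalization absorbs it), but a
*negative* constant, or a rescaling large enough to change which
coefficient has the largest magnitude, can legitimately flip a
component's sign. The invariant object is the feature up to sign; the
tests assert exact invariance for positive rescaling and up-to-sign
invariance otherwise.

**Degenerate eigenvalues.** Under (near-)ties the individual
eigenvectors are solver-dependent; the contract is the spanned
subspace, which is what the generalized-eigenproblem oracle test
compares (principal angles, not vectors).

**Zero-variance columns** (e.g. the sine of an angle pinned at zero)
are dropped with a warning and recorded in the model rather than
failing the fit; at predict time such columns are ignored if present.

**Difference moment.** The second moment of the differences is used
raw (uncentered): differences of a stationary series are near zero-mean,
and the independent oracle uses the same choice, keeping the
equivalence exact rather than approximate.

**Export.** An order-1 model over sin/cos torsion features is an
affine map; `cv_from_model()` folds means, scales, the expansion mean
and the sphering matrix into one offset plus one coefficient per base
feature. The central correctness property — CV evaluation equals
`predict()` to 1e−6 on arbitrary frames — is asserted in the tests.
Emitted PLUMED text uses fixed 9-significant-digit formatting and no
timestamps, so identical inputs give identical bytes (golden-file
testing). The funnel restraint is realized as the standard
cone-plus-cylinder radius profile R(z) = R_cyl + (Z_cc − z)·tan α for
z ≤ Z_cc and R_cyl beyond, enforced by a harmonic upper wall on the
radial excess about the anchor–ligand axis.

**Reweighting.** The Tiwary–Parrinello factor
c(t) = (1/β) ln[Σ exp(βγ/(γ−1)V)/Σ exp(β/(γ−1)V)] is evaluated on a CV
grid (default 100 points per dimension, padded 3 maximum hill widths
beyond the sampled range; a refinement oracle in the tests bounds the
quadrature error below 0.01 kJ/mol). Between depositions c(t) is
stepwise-constant (right-continuous): the bias only changes at
depositions. Frame weights are w_t ∝ exp(β(V(s_t,t) − c(t))),
normalized. Two conventions are explicit because silently mixing them
corrupts every downstream number: hill heights are taken as *actually
deposited* (`heights = "raw"`, the toy engine's dialect) or rescaled by
(γ−1)/γ (`heights = "scaled"`, PLUMED's well-tempered HILLS dialect).
Free-energy surfaces are −kT ln of the binned weight mass, min-shifted
to zero; empty bins carry an explicit flag, never an arbitrary cap.
c(t) of a converging run rises to an asymptotic plateau; it is monotone
only up to small estimator noise (increments of a few 1e−3 kT can be
negative because the γ-weighted grid averages are not pointwise
monotone under every new hill), which is why the convergence test
asserts non-decrease within a 0.01 kT tolerance plus the plateau,
rather than strict monotonicity.

**Units.** Coordinates are nm, times ps, angles rad, energies kJ/mol
on the PLUMED side (kT via the molar gas constant at the given
temperature); the toy engine works in kT = 1 reduced units, and
`toy_to_kjmol()` is the explicit conversion boundary.

# What the toy engine emulates — and what it does not

The synthetic generators define the conditions under which the package
validates itself:

- `wiskott_signal()` — the canonical two-component construction
  x₁ = sin t + cos² 11t, x₂ = cos 11t, whose identity x₁ − x₂² = sin t
  guarantees that quadratic SFA has an exactly recoverable slow
  feature. With n = 5000 frames over ten slow periods the fitted first
  component correlates with sin t above 0.99.
- `two_state_dihedral()` — one angle flipping between wells near −π/3
  and +2π/3 as a symmetric telegraph process (default per-frame flip
  probability 0.001 over T = 100000 frames, i.e. ~100 flips, with
  0.1 rad within-well jitter) among 9 independent-uniform fast angles.
  A telegraph process rather than Langevin dynamics keeps the flip
  count exactly binomial for rate tests, and the construction
  guarantees the flip is the slowest process, so ≥ 80% of SF1's
  squared pulled-back weight must land on the flip angle's sin/cos
  pair — the structural analogue of the Trp/Tyr attribution a real
  training set produces.
- `langevin()` / `wt_metad()` — overdamped Euler–Maruyama dynamics
  (kT = 1) on built-in potentials, and the same dynamics with
  well-tempered Gaussian deposition (deposited height
  h·exp(−V/((γ−1)kT))). Euler–Maruyama rather than BAOAB because it is
  adequate for overdamped toy potentials and trivially auditable. The
  end-to-end validation runs 400000 steps (dt = 0.005, friction 1,
  pace 500, height 0.5 kT, width 0.15, γ = 10) on the quartic double
  well U = 4(x² − 1)² and requires the reweighted surface to match the
  analytic one within 0.5 kT across both wells and the barrier.
  These problem sizes keep the whole suite under a minute on one core
  while leaving comfortable statistical margins.

What passing these tests shows: the algebra (constraints, oracle
equivalence, export fidelity) is exact, and the estimator chain
(bias → c(t) → weights → FES) is consistent on a system whose answer
is known analytically. What it does not show: that two slow features
suffice for a given protein, that dihedral features capture the
relevant slow modes, or that a real metadynamics run has converged —
those remain scientific judgments on real data. The toy data also lack
features of real trajectories: correlated noise across features,
multiscale relaxation within basins, and anharmonic coupling between
the biased CV and orthogonal degrees of freedom.

# Design choices on open points

- The source formulation describes whitening the *input* signal and
  PCA on its differences (pure linear SFA) alongside the general
  expanded formulation; both are supported, with order 1 the default
  and the documented mode for molecular data. Feature-weight
  attributions are defined per input feature for order 1 and per
  expanded monomial for order 2.
- No fixed feature list is hard-coded for any particular protein; the
  features module exposes arbitrary residue/angle-kind selections.
- The funnel is emitted as hand-built walls (axis from the two anchor
  COM groups) because only the four geometric parameters of the funnel
  are ever published; any implementation with the same R(z) profile
  and spring constant is equivalent for the exported file's purpose.
- The c(t) grid discretization is not published either; the defaults
  above are this package's choice and are exposed as options.
- R uses 1-based indexing; frame i sits at time (i−1)·dt. File formats
  record segment starts 1-based and document it in their headers.

# Known limitations

- The compiled toy integrator supports coordinate CVs and affine
  sin/cos CVs (the exact form of exported slow-feature CVs); arbitrary
  R-function CVs would require a slow interpreted loop and are not
  provided.
- Trajectory input covers PDB (topology and multi-model trajectory)
  and DCD; XTC/TRR would need a reader that the R ecosystem does not
  provide.
- Kernel/deep variants, incremental fitting, Markov-state-model
  construction on the SFA space, and alternative reweighting
  estimators are out of scope.
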