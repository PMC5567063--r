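---
title: "Methods: plane-stress mandible biomechanics and comparative statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plane-stress mandible biomechanics and comparative statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mandibleFEA)
```

This vignette is the package's own account of its models, conventions and
numerical choices — the decisions a maintainer or reviewer would want
written down, in one place.

## The mechanical model

A mandible in lateral view is idealised as a **plane-stress** body: a thin
plate of constant thickness loaded in its plane, with the out-of-plane
stress components set to zero.  The material is isotropic, homogeneous and
linear elastic; the default is cortical bone with Young's modulus
E = 10 GPa and Poisson ratio ν = 0.4.  Because the analysis is
comparative — only stress *ratios* between specimens are interpreted — the
absolute modulus is immaterial; it cancels from every stress field under
load control.

The package works in the consistent **N–mm–MPa** unit system: coordinates
in mm, forces in N, moduli and stresses in MPa (N/mm²).  Unit consistency
is the caller's contract; it is documented, not enforced.  The default
`materialProps()` therefore stores E = 1e4 (MPa).

The constant thickness of each model is the mean of three mandibular width
measurements (thk1–thk3: at the first premolar, the mid-point of the
cheek-teeth row, and the posterior end of the molar row), stored per
specimen; the mesh carries the single averaged value.

### Discretisation

Meshes are 8-node serendipity quadrilaterals (QUAD8): quadratic edges, 4
corner nodes counter-clockwise plus 4 mid-side nodes.  Element stiffness is
integrated with a **3×3 Gauss rule** (full integration).  Reduced 2×2
integration is available (`nGauss = 2`) because commercial codes often use
it, but full integration is the default: it is free of hourglass modes,
which matters when the mesh zoo is generated rather than hand-checked.

Files with clockwise elements are canonicalised on construction (forgiving
I/O, strict core); elements that remain non-positive-Jacobian after
re-winding are rejected by id.  Constraints are applied by row/column
elimination, so fixed degrees of freedom are exactly zero; the reduced
system is solved by sparse Cholesky factorisation, which doubles as the
well-posedness check (alongside an explicit rank test of the rigid-body
modes restricted to the fixed dofs).

### Stress sampling

Stress is recovered at the **element centroid** and paired with the whole
element's area as its statistical weight.  Commercial post-processors
variously report nodal-averaged or element stresses; the centroid
convention is a declared, internally consistent choice — it avoids the
extrapolation ambiguity of nodal recovery and pairs naturally with area
weighting.  The exported von Mises scalar is
√(σx² + σy² − σxσy + 3τxy²), the standard plane-stress form.

### Bite boundary conditions

Each of the four bite cases (IB incisive, CB canine, PB premolar, MB molar)
is modelled as:

* condyle node fixed in x and y (the jaw joint),
* the case's bite node fixed **vertically**; its reaction is the bite
  force,
* the total adductor force applied over the masseter and temporalis
  insertion node sets, along each muscle's pull direction.

Modelling the bite point as a displacement constraint (rather than an
applied tooth force) follows the established 2D-mandible FEA protocol:
with muscle forces prescribed, constraining the bite point is what closes
the load path.  The condyle is a **single node**; the stress singularity
this point support induces is handled downstream by flagging every element
that touches a constrained node (`adjacentToConstraint`) and excluding the
flagged elements from summaries by default.  Flagging rather than deleting
keeps the raw field intact in all exports.

Muscle force is split between masseter and temporalis in proportion to
their **insertion areas**, which are specimen metadata (in the intended
workflow they are measured on the bone, not derivable from a 2D outline).
Distribution over an insertion node set uses consistent loads for a
uniform traction on quadratic edges: per edge of length L the weights are
L/6, 4L/6, L/6 (mid-side nodes carry 4× a same-edge corner).  This — not
equal lumping — is what makes the constant-stress patch test exact.

### Force scaling between specimens

Specimens differ in size, so a fixed muscle force would confound size with
performance.  The quasi-homothetic transformation

F_B = √(S_B/S_A) · (t_B/t_A) · F_A

(S: planar model area; t: thickness; A: the reference specimen, by default
the cohort's first, with F_A = 1 N) makes plane-stress fields of
geometrically similar models *identical*, not merely comparable.  This is
exact in theory and the package's flagship invariant test: a specimen
scaled by k in plan and r in thickness, loaded with the rescaled force,
reproduces the reference von Mises field element-wise to 1e-6 relative
(observed: ~1e-12).  Note the scaling removes isometric size effects only;
allometric shape differences remain in the data, by design.

## Mesh-weighted stress summaries

Element counts and sizes vary across meshes, so plain means and medians of
element stresses are biased by the meshing.  The package reports, per
specimen × bite case:

* AM, M — unweighted mean and median,
* MWAM — area-weighted mean Σσᵢaᵢ/Σaᵢ,
* MWM = M(50%), and M(25%), M(75%), M(95%) — area-weighted percentiles,
* PEofAM = |AM − MWAM|/MWAM·100 and PEofM = |M − MWM|/MWM·100,
* a quasi-ideal-mesh flag: PEofAM < 2 and PEofM < 5.

**Weighted-percentile convention.**  Sort stresses ascending carrying
areas; return the smallest stress whose cumulative area reaches p of the
total.  This lower-value cumulative rule is unambiguous on ties and tiny
meshes.  An interpolating variant (element mass at its cumulative-area
midpoint) is available behind a flag, since the exact convention of the
quasi-ideal-mesh literature is not nailed down in text form.  The
*unweighted* median in PEofM uses the same cumulative rule with unit
weights, so that equal-area meshes give exactly zero error — the defining
property of the quasi-ideal mesh — rather than a spurious discrepancy from
the even-count averaging of the conventional sample median.

The percentage-error denominators are the **weighted** statistics (the
mesh-convergent values), with absolute value taken.

## Two-way PERMANOVA

Responses (one column, or the four percentiles jointly) are converted to a
Euclidean distance matrix; the Gower-centred inner-product matrix G is
partitioned by the projection (hat) matrices of the sequential model
intercept → + diet → + hardness → + diet:hardness.  With Euclidean
distances this partition is *numerically identical* to classical ANOVA's
sequential sums of squares, which is the package's primary correctness
oracle (agreement to 1e-10; `vegan::adonis2` is a second, independent
cross-check in the tests).

The permutation test permutes **raw observations, unrestricted** — the
scheme of the PAST software this protocol historically ran on; restricted
or residual-permutation variants are out of scope.  The p-value includes
the observed statistic in the null set, p = (#\{F\* ≥ F\} + 1)/(nPerm + 1),
so p > 0 always.  The reference protocol uses 9999 permutations and
α = 0.05.  For unbalanced designs sequential decompositions depend on term
order; the function warns and keeps the documented order (main effects
before interaction).  Fixed seeds give bit-identical results.

A Shapiro–Wilk gate (`shapiroWilkGate()`) is provided to document the
non-normality that motivates the permutation test; it does not switch
methods automatically.

## Phylogenetic signal and ancestral states

**Pagel's λ** multiplies the off-diagonal entries of the Brownian-motion
tip covariance (shared root-to-tip path lengths) while preserving the
diagonals — implemented on the covariance matrix, never by editing branch
lengths.  For each λ the root state μ and rate σ² are profiled analytically
by GLS; the profile log-likelihood is maximised over λ ∈ [0, 1] by bounded
scalar optimisation (tolerance 1e-8) with the endpoints checked explicitly.
The domain stops at 1 because only [0, 1] is interpreted; the
tree-specific algebraic upper bound above 1 is deliberately not explored,
which is also why independent reimplementations that do search beyond 1
(e.g. `phytools::phylosig`) can report λ̂ slightly above 1 on the same
data.

Degenerate inputs return a diagnostic instead of an arbitrary number:
constant traits, and star-like phylogenies where λ does not enter the
likelihood, are reported with `degenerate = TRUE` and λ = NA.

`fitLambdaOverTrees()` repeats the fit across a sample of phylogenies
(e.g. a posterior sample) and returns the per-tree estimates plus summary
quantiles.  Whether a published single-number λ is a consensus-tree
estimate or a summary over a tree sample is often unstated; both paths are
provided and neither is privileged.

**Ancestral state reconstruction** under Brownian motion uses the GLS
formulation: â = μ̂ + C_{node,tips} V⁻¹ (x − μ̂), with μ̂ the GLS
phylogenetic mean — which is therefore also the root estimate.  At ~30
tips the O(n³) inversion is trivial; a pruning-algorithm implementation
would be the alternative at large n.  Estimates at the tips reproduce the
observed traits exactly.  Along-branch values are **linear** interpolations
of the endpoint estimates at requested fractions — sufficient for the CSV
export feeding tree-painting tools; the conditional-variance interpolation
of the full Brownian bridge is out of scope.

`simulateBM()` draws tip traits with covariance σ²C(λ) via Cholesky; it is
the test harness for the recovery simulations.

## The synthetic cohort generator

The generator replaces the specimen-digitisation workflow (photography,
orientation, muscle tracing) with a parametric template, so the pipeline
can be exercised download-free and with known ground truth.  It is
first-class, tested code, not a fixture.

The template is a **swept strip**: a horizontal corpus of depth
`corpus_height`, a circular gonial blend (radius = corpus height, which
keeps Jacobians positive for the whole documented parameter range), and an
ascending ramus of length `ramus_height` at interior angle `ramus_angle`
∈ (90°, 180°); a Gaussian bump on the anterior ramus border stands in for
the coronoid process and `condyle_sharpness` tapers the condylar end.  A
quadratic lattice swept over this geometry yields a structured QUAD8 mesh
with near-uniform element areas — quasi-ideal by construction (verified in
the tests: PEofAM < 2 and PEofM < 5 for smooth test fields).  Template
meshing was chosen over free quad meshing of arbitrary outlines because
the scientific content of the pipeline is downstream of meshing, and a
structured template guarantees element quality without implementing a
general mesher.

Named node sets are assigned automatically: the posterior condylar node;
bite points at fixed fractions of the alveolar margin (IB 0.03, CB 0.16,
PB 0.45, MB 0.65 of corpus length — MB approximating the centre of the
first molar); masseter on the posteroventral ramus border around the
gonial angle; temporalis on the coronoid region.  Muscle directions run
from each insertion centroid toward template origin points above the jaw
(zygomatic and temporal analogues), emulating the centroid-based
construction used on real specimens and guaranteeing a compressive bite.

**Study conditions.**  The default cohort layout is 31 species — 12
frugivores, 11 omnivores, 8 folivores, split into hard/soft cells
(5/6, 6/6, 2/6) — matching the scale and imbalance of the primate cohort
this protocol was designed around.  Default category effects encode the
expected biology at moderate size: hard-food eaters get ×1.15 corpus
height and ×1.10 thickness; folivores ×0.92 and omnivores ×1.08 corpus
height (gracile vs robust jaws).  Parameter noise is lognormal with
sd = 0.06, a realistic within-guild coefficient of variation.  These are
the generator's fixed conditions, not tuning knobs.  Baseline template
dimensions (60 mm corpus, 14 mm depth, 35 mm ramus, 115° angle, 10 mm
thickness) are in the macaque size range.

What the generator does *not* emulate: real outline geometry of any
species, cortical/trabecular heterogeneity, tooth sockets, bilateral
(working/balancing side) loading, or allometric covariance structure
beyond the injected multiplicative effects.  Passing tests therefore
demonstrate the *method chain* — solver correctness, scaling exactness,
statistical calibration and effect recovery — not claims about any real
taxon.

Phylogenies are seeded pure-birth trees rescaled to unit depth.  In the
default pipeline the tree is simulated independently of the traits, so
λ ≈ 0 is the expected outcome there; λ-recovery is validated separately by
simulating traits on the tree.

## Numerical choices and problem sizes

* Quadrature 3×3; areas by the same rule (exact for the polynomial
  Jacobians of QUAD8).
* Sparse symmetric Cholesky (`Matrix`), deterministic for identical input.
* λ optimisation: `optimize()` on [0, 1], tol 1e-8, endpoints compared
  explicitly; flat-likelihood detection at 1e-8 relative.
* Weighted percentiles: cumulative rule with a 1e-12 relative tolerance on
  the target to absorb rounding in the cumulative sums.
* Permutation p-values: +1/+1 convention; seeds restore the caller's RNG
  state.

The validation suite uses sizes chosen to make each property sharp but the
whole run quick: patch tests at several densities; the cantilever at
64×8 elements (1% of beam theory, with h-convergence measured against a
64×16 reference because the plane-stress limit includes shear deformation
the slender-beam formula omits); type-I calibration with 1000 null
datasets × 999 permutations on a balanced 12-specimen design; λ recovery
with 50 replicates on 128-tip trees; end-to-end effect recovery on a
24-species cohort at coarse mesh density with 9999 permutations.  The
acceptance script repeats the same computations at comparable sizes (800
null datasets × 499 permutations; 25 λ replicates on 96-tip trees) and
writes the resulting numbers to JSON.

## Known limitations

* 2D plane stress only: no 3D geometry, no orthotropy or density-mapped
  bone, no contact at the temporomandibular joint, no gape-angle or
  bilateral-muscle variation.
* The condyle support is one node; results inside the flagged
  constraint-adjacent band are not interpretable and are excluded from
  summaries by default.
* Sequential sums of squares make unbalanced-design results
  order-dependent (warned).
* λ is a point estimate on [0, 1]; no significance test against λ = 0 and
  no other trait models (OU etc.).
* The synthetic template is a stylised mandible; it supports method
  validation and power exploration, not species-level inference.
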