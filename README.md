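# mandibleFEA

Comparative biomechanics of two-dimensional mandible models in R.

Studies of mandibular ecomorphology ask whether jaws of species with
different diets — omnivores, frugivores, folivores, and within each, hard-
versus soft-food consumers — differ in mechanical performance, not just in
shape. `mandibleFEA` implements the full quantitative chain behind that
question for planar (lateral-view) mandible models:

1. **Plane-stress finite element analysis** on 8-node serendipity
   quadrilateral (QUAD8) meshes: element stiffness by 3×3 Gauss quadrature,
   sparse Cholesky solution, centroid stress recovery, von Mises equivalent
   stress
   σ<sub>vM</sub> = √(σ<sub>x</sub>² + σ<sub>y</sub>² − σ<sub>x</sub>σ<sub>y</sub> + 3τ<sub>xy</sub>²).
2. **Bite scenarios**: the condyle is fixed, one of four bite points
   (incisive IB, canine CB, premolar PB, molar MB) is constrained
   vertically, and the adductor muscle force is split between masseter and
   temporalis in proportion to their insertion areas.  Between specimens of
   different size, forces are rescaled by the quasi-homothetic
   transformation
   F<sub>B</sub> = √(S<sub>B</sub>/S<sub>A</sub>) · (t<sub>B</sub>/t<sub>A</sub>) · F<sub>A</sub>
   (S = planar model area, t = thickness), which makes the stress fields of
   geometrically similar models exactly comparable.
3. **Mesh-weighted stress summaries**: area-weighted mean (MWAM), weighted
   median (MWM) and weighted percentiles M(25–95%), with the
   quasi-ideal-mesh error diagnostics PEofAM and PEofM and automatic
   exclusion of elements adjacent to point supports (numerical
   singularities).
4. **Comparative statistics**: Shapiro–Wilk normality gate; two-way
   PERMANOVA (Euclidean distance, unrestricted permutations, sequential
   sums of squares) of the stress summaries against diet and food-hardness
   factors; Pagel's λ phylogenetic signal by maximum likelihood (single
   trees or tree samples); Brownian-motion ancestral state reconstruction
   with along-branch interpolation.
5. **A synthetic cohort generator**: parametric mandible-like QUAD8
   templates whose shape co-varies with diet/hardness labels at controlled
   effect sizes, plus seeded pure-birth phylogenies — so the whole pipeline
   can be exercised and validated without any specimen data.

The package is aimed at functional morphologists who want a scriptable,
fully reproducible version of this analysis protocol, and at methods
developers who need a tested reference implementation of mesh-weighted
stress statistics and distance-based two-way PERMANOVA.

Units are the consistent N–mm–MPa system: coordinates in mm, forces in N,
moduli and stresses in MPa (default material: cortical bone, E = 10 GPa =
1e4 MPa, ν = 0.4).

## Worked example

A 12-species synthetic cohort (two species per diet × hardness cell) with
the default category effects, solved under all four bite cases and pushed
through the statistical battery:

```r
library(mandibleFEA)

spec <- cohortSpec(
  nPerCell = c(omnivore.hard = 2, omnivore.soft = 2,
               frugivore.hard = 2, frugivore.soft = 2,
               folivore.hard = 2, folivore.soft = 2),
  seed = 42)
cfg <- runConfig(cohortSpec = spec, nPerm = 999, permSeed = 1, treeSeed = 1)
res <- runPipeline(cfg, "demo_run")

head(res$summaries[, c("specimen", "bite", "MWAM", "MWM", "M95",
                       "PEofAM", "PEofM", "diet", "hardness")], 4)
#> specimen bite     MWAM      MWM      M95 PEofAM   PEofM     diet hardness
#>     sp01   CB 0.005266 0.004419 0.010862 0.3904 1.20082 omnivore     hard
#>     sp01   IB 0.005482 0.004789 0.011227 0.4025 5.80707 omnivore     hard
#>     sp01   MB 0.003669 0.003511 0.009404 0.3025 0.08839 omnivore     hard
#>     sp01   PB 0.004331 0.003998 0.009843 0.2951 0.61794 omnivore     hard
```

Stresses are in MPa under a 1 N reference muscle load, so magnitudes are
small; only their ratios between specimens matter.  The PERMANOVA grid for
the weighted median (one of the three response sets the battery runs):

```r
subset(res$battery$grid, response_set == "MWM")
#> bite response_set          term     p
#>   IB          MWM          diet 0.033
#>   IB          MWM      hardness 0.046
#>   IB          MWM diet:hardness 0.301
#>   CB          MWM          diet 0.025
#>   CB          MWM      hardness 0.029
#>   CB          MWM diet:hardness 0.235
#>   PB          MWM          diet 0.039
#>   PB          MWM      hardness 0.055
#>   PB          MWM diet:hardness 0.258
#>   MB          MWM          diet 0.104
#>   MB          MWM      hardness 0.045
#>   MB          MWM diet:hardness 0.652
```

Even at n = 12 the injected hardness effect (hard-food eaters get deeper,
thicker corpora, hence stiffer, lower-stress jaws) is picked up at α = 0.05
in three of four bite cases, while the diet × hardness interaction stays
non-significant — the expected pattern.  `res$lambdaGrid` holds the Pagel's
λ estimates per bite case and stress variable (λ ≈ 0 here because the demo
phylogeny is simulated independently of the traits), and
`demo_run/asr_branches.csv` the ancestral-state export backing painted-tree
figures.  All intermediate products (per-specimen stress fields, summary
tables, the tree, a JSON manifest with every seed) are written under
`demo_run/` and are byte-identical across reruns.

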