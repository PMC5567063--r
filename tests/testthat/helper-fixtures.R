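# single unit-square QUAD8 element; mid-side displacement `bulge` moves the
# top mid-side node outward (parabolic top edge)
unitSquareMesh <- function(bulge = 0, thickness = 1, nodeSets = list()) {
  mesh2D(
    nodes = data.frame(
      id = 1:8,
      x = c(0, 1, 1, 0, 0.5, 1, 0.5, 0),
      y = c(0, 0, 1, 1, 0, 0.5, 1 + bulge, 0.5)),
    elements = matrix(c(1L, 1:8), 1, 9),
    nodeSets = nodeSets, thickness = thickness)
}

# build a SpecimenRecord around a generated mandible mesh
makeSpecimen <- function(params = mandibleParams(), density = 0.15,
                         id = "spA", diet = "omnivore", hardness = "hard") {
  mesh <- generateMandibleMesh(params, density = density)
  S <- sum(allElementAreas(mesh))
  dirs <- mandibleFEA:::muscleDirections(mesh, params)
  muscles <- list(
    muscleSpec("masseter", "masseter", params$masseter_area, dirs$masseter),
    muscleSpec("temporalis", "temporalis", params$temporalis_area,
               dirs$temporalis))
  specimenRecord(id, mesh, params$thickness_triplet, S, diet, hardness,
                 muscles)
}

referenceOf <- function(specimen, F_A = 1) {
  list(S_A = specimen@surfaceArea, t_A = specimen@mesh@thickness, F_A = F_A)
}

# balanced 2x3 factorial design with n replicates per cell
balancedDesign <- function(n = 2) {
  expand.grid(diet = c("omnivore", "frugivore", "folivore"),
              hardness = c("hard", "soft"), rep = seq_len(n),
              stringsAsFactors = FALSE)
}

# brute-force weighted percentile: cumulative-area scan, written
# independently of the package implementation
bruteWeightedPercentile <- function(s, a, p) {
  o <- order(s)
  s <- s[o]; a <- a[o]
  cum <- 0
  for (i in seq_along(s)) {
    cum <- cum + a[i]
    if (cum >= p * sum(a) - 1e-12 * sum(a)) return(s[i])
  }
  s[length(s)]
}

# cantilever tip deflection on an nx x ny mesh (tip load P at the free end)
cantileverDeflection <- function(nx, ny, L = 10, h = 1, E = 1e7, P = 1) {
  m <- structuredRectangleMesh(nx, ny, L, h)
  ns <- nodeSets(m)
  fixed <- rbind(data.frame(node = ns$left, dir = "x"),
                 data.frame(node = ns$left, dir = "y"))
  f <- consistentEdgeForces(m, "right", c(0, -P))
  sol <- solvePlaneStress(m, materialProps(E, 0), loadCase(fixed, f))
  midTip <- intersect(ns$right,
                      m@nodeIds[abs(m@coords[, 2] - h / 2) < 1e-9])
  -mean(sol$displacements$uy[match(midTip, sol$displacements$node)])
}

# evaluate an expression under a local seed, restoring the RNG state
withSeedHelper <- function(seed, expr) mandibleFEA:::withSeed(seed, expr)
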