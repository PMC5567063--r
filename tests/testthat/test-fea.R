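test_that("QUAD8 stiffness is symmetric with exactly three rigid-body modes", {
  m <- generateMandibleMesh(mandibleParams(), density = 0.12)
  mat <- materialProps(E = 1e4, nu = 0.3)
  for (eid in m@elementIds[c(1, 7, length(m@elementIds))]) {
    K <- elementStiffnessQuad8(m, eid, mat)
    expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 3L)
  }
})

test_that("stiffness scales linearly with thickness and Young's modulus", {
  sq1 <- unitSquareMesh(thickness = 1)
  sq2 <- unitSquareMesh(thickness = 2)
  K1 <- elementStiffnessQuad8(sq1, 1, materialProps(1e4, 0.3))
  expect_equal(elementStiffnessQuad8(sq2, 1, materialProps(1e4, 0.3)),
               2 * K1, tolerance = 1e-14)
  expect_equal(elementStiffnessQuad8(sq1, 1, materialProps(3e4, 0.3)),
               3 * K1, tolerance = 1e-14)
})

test_that("uniform uniaxial strain carries the closed-form strain energy", {
  # u = x on a unit square with E = 1, nu = 0, t = 1:
  # energy = 1/2 integral sigma*eps dV = 1/2
  sq <- unitSquareMesh()
  K <- elementStiffnessQuad8(sq, 1, materialProps(1, 0))
  u <- as.vector(rbind(sq@coords[, 1], 0))
  expect_equal(0.5 * sum(u * (K %*% u)), 0.5, tolerance = 1e-12)
})

test_that("patch test: uniform traction gives exact constant stress", {
  for (cfg in list(list(nx = 4, ny = 3, Lx = 2.0, Ly = 1.0, E = 1e4, nu = 0.3),
                   list(nx = 7, ny = 2, Lx = 3.5, Ly = 0.8, E = 2e3, nu = 0.45),
                   list(nx = 2, ny = 5, Lx = 1.0, Ly = 4.0, E = 5e5, nu = 0.0))) {
    t <- 1.3; sigma0 <- 2.7
    m <- structuredRectangleMesh(cfg$nx, cfg$ny, cfg$Lx, cfg$Ly, thickness = t)
    ns <- nodeSets(m)
    fixed <- rbind(data.frame(node = ns$left, dir = "x"),
                   data.frame(node = ns$left[1], dir = "y"))
    f <- consistentEdgeForces(m, "right", c(sigma0 * cfg$Ly * t, 0))
    sol <- solvePlaneStress(m, materialProps(cfg$E, cfg$nu),
                            loadCase(fixed, f))
    expect_lt(max(abs(vonMises(sol$stress) - sigma0)), 1e-8 * sigma0)
    expect_lt(max(abs(sol$stress@sigma[, 1] - sigma0)), 1e-8 * sigma0)
    expect_lt(max(abs(sol$stress@sigma[, 2:3])), 1e-8 * sigma0)
    expect_lt(sol$equilibriumResidual, 1e-8)
  }
})

test_that("zero load produces zero displacement and stress", {
  m <- structuredRectangleMesh(3, 2, 1, 1)
  ns <- nodeSets(m)
  fixed <- rbind(data.frame(node = ns$left, dir = "x"),
                 data.frame(node = ns$left[1], dir = "y"))
  sol <- solvePlaneStress(m, materialProps(),
                          loadCase(fixed, data.frame(node = ns$right[1],
                                                     fx = 0, fy = 0)))
  expect_equal(max(abs(c(sol$displacements$ux, sol$displacements$uy))), 0)
  expect_equal(max(vonMises(sol$stress)), 0)
})

test_that("external work balances internal strain energy", {
  m <- structuredRectangleMesh(8, 4, 4, 1)
  ns <- nodeSets(m)
  fixed <- rbind(data.frame(node = ns$left, dir = "x"),
                 data.frame(node = ns$left, dir = "y"))
  f <- consistentEdgeForces(m, "right", c(0.3, -1))
  mat <- materialProps(5e3, 0.25)
  sol <- solvePlaneStress(m, mat, loadCase(fixed, f))
  u <- sol$displacements
  Wext <- 0.5 * sum(f$fx * u$ux[match(f$node, u$node)] +
                    f$fy * u$uy[match(f$node, u$node)])
  K <- mandibleFEA:::assembleStiffness(m, mat)
  uv <- as.vector(rbind(u$ux, u$uy))
  Wint <- 0.5 * sum(uv * as.numeric(K %*% uv))
  expect_equal(Wext, Wint, tolerance = 1e-8)
})

test_that("solution is invariant under node renumbering", {
  m <- structuredRectangleMesh(4, 2, 2, 1)
  ns <- nodeSets(m)
  fixed <- rbind(data.frame(node = ns$left, dir = "x"),
                 data.frame(node = ns$left[1], dir = "y"))
  f <- consistentEdgeForces(m, "right", c(1, 0.2))
  sol <- solvePlaneStress(m, materialProps(), loadCase(fixed, f))

  set.seed(5)
  perm <- sample(m@nodeIds)           # new id for old id i is perm[i]
  m2 <- m
  m2@nodeIds <- perm[m@nodeIds]
  m2@conn[] <- perm[m@conn]
  m2@nodeSets <- lapply(m@nodeSets, function(s) perm[s])
  f2 <- f; f2$node <- perm[f$node]
  fixed2 <- fixed; fixed2$node <- perm[fixed$node]
  sol2 <- solvePlaneStress(m2, materialProps(), loadCase(fixed2, f2))
  expect_equal(vonMises(sol2$stress), vonMises(sol$stress),
               tolerance = 1e-9)
})

test_that("rigid rotation of geometry and loads leaves von Mises unchanged", {
  m <- structuredRectangleMesh(6, 3, 3, 1)
  ns <- nodeSets(m)
  fixed <- rbind(data.frame(node = ns$left, dir = "x"),
                 data.frame(node = ns$left, dir = "y"))
  f <- consistentEdgeForces(m, "right", c(0, -1))
  sol <- solvePlaneStress(m, materialProps(), loadCase(fixed, f))

  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m2 <- m
  m2@coords <- m@coords %*% t(R)
  fr <- t(R %*% t(as.matrix(f[c("fx", "fy")])))
  f2 <- data.frame(node = f$node, fx = fr[, 1], fy = fr[, 2])
  # rotated supports: clamp both directions at the same nodes
  sol2 <- solvePlaneStress(m2, materialProps(), loadCase(fixed, f2))
  expect_equal(vonMises(sol2$stress), vonMises(sol$stress),
               tolerance = 1e-8)
})

test_that("consistent edge forces follow the 1:4:1 quadratic-edge weights", {
  sq <- unitSquareMesh(nodeSets = list(edge = c(1L, 2L, 5L),
                                       lone = 3L))
  f <- consistentEdgeForces(sq, "edge", c(6, 0))
  f <- f[order(f$node), ]
  expect_equal(f$fx, c(1, 1, 4))
  expect_equal(f$fy, c(0, 0, 0))
  # singleton set carries the whole force
  f1 <- consistentEdgeForces(sq, "lone", c(0, -1))
  expect_equal(f1$fy, -1)
  # conservation on an arbitrary multi-edge set
  m <- structuredRectangleMesh(5, 3, 2.3, 1.1)
  fr <- consistentEdgeForces(m, "top", c(0.7, -2.2))
  expect_equal(sum(fr$fx), 0.7, tolerance = 1e-12)
  expect_equal(sum(fr$fy), -2.2, tolerance = 1e-12)
  expect_error(consistentEdgeForces(m, integer(0), c(1, 0)), "empty")
})

test_that("under-constrained models are reported", {
  m <- structuredRectangleMesh(2, 2, 1, 1)
  ns <- nodeSets(m)
  # three parallel x-constraints leave y rigid-body motion free
  fixed <- data.frame(node = ns$left[1:3], dir = "x")
  f <- consistentEdgeForces(m, "right", c(1, 0))
  expect_error(solvePlaneStress(m, materialProps(), loadCase(fixed, f)),
               "under-constrained")
})

test_that("cantilever deflection error decreases monotonically under refinement", {
  # reference: a much finer mesh (the FE limit includes shear deformation,
  # which the slender-beam closed form omits)
  ref <- cantileverDeflection(64, 16)
  errs <- vapply(list(c(8, 2), c(16, 4), c(32, 8)), function(nn) {
    abs(cantileverDeflection(nn[1], nn[2]) - ref) / ref
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
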