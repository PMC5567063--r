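#' @import methods
#' @importFrom stats median optimize quantile rnorm runif sd setNames shapiro.test var aggregate approx dist model.matrix xtabs
#' @importFrom utils read.csv write.csv
NULL

REQUIRED_NODE_SETS <- c("condyle", "bite_IB", "bite_CB", "bite_PB", "bite_MB",
                        "masseter", "temporalis")

#' Material properties for linear isotropic plane-stress elasticity
#'
#' Young's modulus and Poisson ratio of a homogeneous, isotropic, linear
#' elastic material.  The package works in a consistent N-mm-MPa unit system:
#' coordinates in mm, forces in N, moduli and stresses in MPa (N/mm^2).
#' The default corresponds to cortical (haversian) bone: E = 10 GPa
#' (1e4 MPa), Poisson ratio 0.4.
#'
#' @slot E Young's modulus (MPa), > 0.
#' @slot nu Poisson ratio, in [0, 0.5).
#' @export
setClass("MaterialProps", representation(E = "numeric", nu = "numeric"))

setValidity("MaterialProps", function(object) {
  if (length(object@E) != 1L || !is.finite(object@E) || object@E <= 0)
    return("E must be a single positive number")
  if (length(object@nu) != 1L || !is.finite(object@nu) ||
      object@nu < 0 || object@nu >= 0.5)
    return("nu must lie in [0, 0.5)")
  TRUE
})

#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @rdname MaterialProps-class
#' @export
materialProps <- function(E = 1e4, nu = 0.4) {
  new("MaterialProps", E = as.numeric(E), nu = as.numeric(nu))
}

#' A 2D QUAD8 mesh with named node sets
#'
#' Planar mesh of 8-node serendipity quadrilaterals.  Node coordinates are in
#' mm; every element stores its node ids as 4 corner nodes in
#' counter-clockwise order followed by the 4 mid-side nodes in edge order
#' (edge 1-2, 2-3, 3-4, 4-1).  A constant out-of-plane thickness (mm) is
#' attached to the mesh, matching the constant-thickness idealisation used
#' for planar mandible models.
#'
#' @slot nodeIds integer vector of node ids (unique).
#' @slot coords numeric matrix (n x 2) of x,y coordinates, rows parallel to
#'   `nodeIds`.
#' @slot elementIds integer vector of element ids.
#' @slot conn integer matrix (ne x 8) of node ids per element.
#' @slot nodeSets named list of integer vectors of node ids.
#' @slot thickness single positive numeric (mm).
#' @export
setClass("Mesh2D", representation(
  nodeIds = "integer", coords = "matrix",
  elementIds = "integer", conn = "matrix",
  nodeSets = "list", thickness = "numeric"))

setValidity("Mesh2D", function(object) {
  if (anyDuplicated(object@nodeIds)) return("node ids must be unique")
  if (nrow(object@coords) != length(object@nodeIds) || ncol(object@coords) != 2)
    return("coords must be an n x 2 matrix parallel to nodeIds")
  if (length(object@elementIds) != nrow(object@conn))
    return("elementIds must parallel the connectivity matrix")
  if (anyDuplicated(object@elementIds)) return("element ids must be unique")
  if (nrow(object@conn) > 0 && ncol(object@conn) != 8)
    return("connectivity must have 8 nodes per element")
  if (!all(object@conn %in% object@nodeIds))
    return("element connectivity references unknown node ids")
  if (length(object@thickness) != 1L || !is.finite(object@thickness) ||
      object@thickness <= 0)
    return("thickness must be a single positive number")
  for (nm in names(object@nodeSets)) {
    ns <- object@nodeSets[[nm]]
    if (length(ns) == 0L) return(sprintf("node set '%s' is empty", nm))
    if (!all(ns %in% object@nodeIds))
      return(sprintf("node set '%s' references unknown node ids", nm))
  }
  TRUE
})

setMethod("show", "Mesh2D", function(object) {
  cat(sprintf("Mesh2D: %d nodes, %d QUAD8 elements, thickness %.4g mm\n",
              length(object@nodeIds), length(object@elementIds),
              object@thickness))
  if (length(object@nodeSets))
    cat("  node sets:",
        paste(sprintf("%s(%d)", names(object@nodeSets),
                      lengths(object@nodeSets)), collapse = ", "), "\n")
})

#' Accessors for Mesh2D
#'
#' @param mesh A [Mesh2D-class] object.
#' @return `meshNodes()` a data.frame (id, x, y); `meshElements()` the ne x 8
#'   connectivity matrix with element ids as rownames; `nodeSets()` the named
#'   list of node-id vectors; `meshThickness()` the constant thickness (mm).
#' @export
meshNodes <- function(mesh) {
  data.frame(id = mesh@nodeIds, x = mesh@coords[, 1], y = mesh@coords[, 2])
}

#' @rdname meshNodes
#' @export
meshElements <- function(mesh) {
  m <- mesh@conn
  rownames(m) <- mesh@elementIds
  m
}

#' @rdname meshNodes
#' @export
nodeSets <- function(mesh) mesh@nodeSets

#' @rdname meshNodes
#' @export
meshThickness <- function(mesh) mesh@thickness

#' A load case: fixed degrees of freedom plus nodal forces
#'
#' @slot fixedDofs data.frame with columns `node` (id) and `dir` ("x" or "y").
#' @slot nodalForces data.frame with columns `node`, `fx`, `fy` (N); at most
#'   one row per node.
#' @export
setClass("LoadCase", representation(fixedDofs = "data.frame",
                                    nodalForces = "data.frame"))

setValidity("LoadCase", function(object) {
  fd <- object@fixedDofs
  if (!all(c("node", "dir") %in% names(fd)))
    return("fixedDofs needs columns node, dir")
  if (!all(fd$dir %in% c("x", "y"))) return("dir must be 'x' or 'y'")
  if (anyDuplicated(fd[c("node", "dir")])) return("duplicate fixed dofs")
  if (nrow(fd) < 3L)
    return("at least 3 fixed dofs are required to suppress rigid-body motion")
  nf <- object@nodalForces
  if (!all(c("node", "fx", "fy") %in% names(nf)))
    return("nodalForces needs columns node, fx, fy")
  if (anyDuplicated(nf$node)) return("duplicate force rows for a node")
  # a node must not be force-loaded and displacement-fixed in the same dir
  for (d in c("x", "y")) {
    fixed <- fd$node[fd$dir == d]
    comp <- if (d == "x") nf$fx else nf$fy
    bad <- nf$node[comp != 0 & nf$node %in% fixed]
    if (length(bad))
      return(sprintf("node %d is both %s-loaded and %s-fixed", bad[1], d, d))
  }
  TRUE
})

#' @param fixedDofs data.frame(node, dir).
#' @param nodalForces data.frame(node, fx, fy).
#' @rdname LoadCase-class
#' @export
loadCase <- function(fixedDofs, nodalForces) {
  fixedDofs$node <- as.integer(fixedDofs$node)
  fixedDofs$dir <- as.character(fixedDofs$dir)
  nodalForces$node <- as.integer(nodalForces$node)
  new("LoadCase", fixedDofs = fixedDofs, nodalForces = nodalForces)
}

#' Per-element centroid stress field
#'
#' Stress components and von Mises equivalent stress sampled at element
#' centroids, together with element areas (the weights of all downstream
#' statistics) and a flag marking elements adjacent to any constrained node,
#' where the point supports induce a numerical singularity.
#'
#' @slot elementIds integer element ids.
#' @slot sigma numeric ne x 3 matrix (sigma_x, sigma_y, tau_xy), MPa.
#' @slot vonMises numeric vector (MPa).
#' @slot areas numeric vector (mm^2).
#' @slot adjacentToConstraint logical vector.
#' @export
setClass("StressField", representation(
  elementIds = "integer", sigma = "matrix", vonMises = "numeric",
  areas = "numeric", adjacentToConstraint = "logical"))

setValidity("StressField", function(object) {
  ne <- length(object@elementIds)
  if (nrow(object@sigma) != ne || length(object@vonMises) != ne ||
      length(object@areas) != ne || length(object@adjacentToConstraint) != ne)
    return("all slots must have one entry per element")
  if (any(object@vonMises < -1e-12)) return("von Mises stress must be >= 0")
  if (any(object@areas <= 0)) return("element areas must be positive")
  TRUE
})

setMethod("show", "StressField", function(object) {
  cat(sprintf(
    "StressField: %d elements (%d adjacent to constraints)\n  von Mises range [%.4g, %.4g] MPa\n",
    length(object@elementIds), sum(object@adjacentToConstraint),
    min(object@vonMises), max(object@vonMises)))
})

#' @param field A [StressField-class].
#' @rdname StressField-class
#' @export
vonMises <- function(field) field@vonMises

#' @rdname StressField-class
#' @export
elementAreas <- function(field) field@areas

#' @rdname StressField-class
#' @export
adjacentToConstraint <- function(field) field@adjacentToConstraint

#' Muscle insertion specification
#'
#' @slot name muscle name ("masseter" or "temporalis").
#' @slot nodeSet name of the insertion node set on the mesh.
#' @slot area insertion area (mm^2), measured on the specimen, > 0.
#' @slot direction unit 2-vector of muscle pull.
#' @export
setClass("MuscleSpec", representation(name = "character", nodeSet = "character",
                                      area = "numeric", direction = "numeric"))

setValidity("MuscleSpec", function(object) {
  if (object@area <= 0) return("insertion area must be > 0")
  if (length(object@direction) != 2L) return("direction must be a 2-vector")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-12)
    return("direction must be a unit vector")
  TRUE
})

#' @param name,nodeSet,area,direction see slots.
#' @rdname MuscleSpec-class
#' @export
muscleSpec <- function(name, nodeSet = name, area, direction) {
  direction <- as.numeric(direction)
  n <- sqrt(sum(direction^2))
  if (n == 0) stop("direction must be non-zero")
  new("MuscleSpec", name = name, nodeSet = nodeSet, area = as.numeric(area),
      direction = direction / n)
}

#' One specimen of the comparative cohort
#'
#' Couples a mesh with the specimen-level metadata used to build and scale
#' bite loads: the three mandibular width measurements whose mean is the
#' model thickness, the planar model area entering the quasi-homothetic
#' force scaling, diet and food-hardness categories, and muscle insertion
#' specifications.
#'
#' @slot specimenId character id (matches phylogeny tip labels).
#' @slot mesh the specimen's [Mesh2D-class].
#' @slot thk numeric length-3 vector of mandibular widths (mm).
#' @slot surfaceArea planar model area S (mm^2).
#' @slot diet one of "omnivore", "frugivore", "folivore".
#' @slot hardness one of "hard", "soft".
#' @slot muscles list of [MuscleSpec-class].
#' @export
setClass("SpecimenRecord", representation(
  specimenId = "character", mesh = "Mesh2D", thk = "numeric",
  surfaceArea = "numeric", diet = "character", hardness = "character",
  muscles = "list"))

DIET_LEVELS <- c("omnivore", "frugivore", "folivore")
HARDNESS_LEVELS <- c("hard", "soft")

setValidity("SpecimenRecord", function(object) {
  if (length(object@thk) != 3L || any(object@thk <= 0))
    return("thk must be three positive widths")
  if (abs(object@mesh@thickness - mean(object@thk)) >
      1e-8 * max(object@mesh@thickness, 1))
    return("mesh thickness must equal mean(thk1..thk3)")
  if (object@surfaceArea <= 0) return("surfaceArea must be > 0")
  if (!object@diet %in% DIET_LEVELS)
    return("diet must be omnivore, frugivore or folivore")
  if (!object@hardness %in% HARDNESS_LEVELS)
    return("hardness must be hard or soft")
  if (!all(vapply(object@muscles, is, TRUE, class2 = "MuscleSpec")))
    return("muscles must be a list of MuscleSpec")
  TRUE
})

#' @param specimenId,mesh,thk,surfaceArea,diet,hardness,muscles see slots.
#' @rdname SpecimenRecord-class
#' @export
specimenRecord <- function(specimenId, mesh, thk, surfaceArea, diet, hardness,
                           muscles) {
  new("SpecimenRecord", specimenId = specimenId, mesh = mesh,
      thk = as.numeric(thk), surfaceArea = as.numeric(surfaceArea),
      diet = diet, hardness = hardness, muscles = muscles)
}

setMethod("show", "SpecimenRecord", function(object) {
  cat(sprintf("SpecimenRecord '%s': %s/%s, S = %.4g mm^2, t = %.4g mm\n",
              object@specimenId, object@diet, object@hardness,
              object@surfaceArea, object@mesh@thickness))
})

#' The four bite scenarios
#'
#' Named vector mapping bite-case codes to the node set holding the bite
#' point: IB incisive, CB canine, PB premolar, MB molar bite.
#' @export
BITE_CASES <- c(IB = "bite_IB", CB = "bite_CB", PB = "bite_PB", MB = "bite_MB")

#' Mesh-weighted stress summary for one specimen and bite case
#'
#' @slot specimenId,biteCase identifiers.
#' @slot AM arithmetic mean of element von Mises stress.
#' @slot M unweighted median.
#' @slot MWAM area-weighted (mesh-weighted) mean.
#' @slot MWM area-weighted median (equals M50).
#' @slot M25,M50,M75,M95 area-weighted percentiles.
#' @slot PEofAM,PEofM percentage errors of the unweighted statistics relative
#'   to their weighted counterparts.
#' @slot qimCompliant TRUE when PEofAM < 2 and PEofM < 5 (quasi-ideal mesh).
#' @slot nExcluded number of constraint-adjacent elements excluded.
#' @export
setClass("StressSummary", representation(
  specimenId = "character", biteCase = "character",
  AM = "numeric", M = "numeric", MWAM = "numeric", MWM = "numeric",
  M25 = "numeric", M50 = "numeric", M75 = "numeric", M95 = "numeric",
  PEofAM = "numeric", PEofM = "numeric", qimCompliant = "logical",
  nExcluded = "integer"))

setValidity("StressSummary", function(object) {
  if (!(object@M25 <= object@M50 + 1e-12 && object@M50 <= object@M75 + 1e-12 &&
        object@M75 <= object@M95 + 1e-12))
    return("weighted percentiles must be non-decreasing")
  if (object@MWM != object@M50) return("MWM must equal M50")
  TRUE
})

setMethod("show", "StressSummary", function(object) {
  cat(sprintf("StressSummary %s/%s: MWAM %.4g, MWM %.4g (PEofAM %.2f%%, PEofM %.2f%%, QIM %s, %d excluded)\n",
              object@specimenId, object@biteCase, object@MWAM, object@MWM,
              object@PEofAM, object@PEofM, object@qimCompliant,
              object@nExcluded))
})

#' Two-way PERMANOVA result
#'
#' @slot table data.frame with one row per term (diet, hardness,
#'   diet:hardness, residual, total): df, SS, pseudo-F, permutation p.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @export
setClass("PermanovaResult", representation(table = "data.frame",
                                           nPerm = "integer",
                                           seed = "integer"))

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("Two-way PERMANOVA (%d permutations, seed %d)\n",
              object@nPerm, object@seed))
  print(object@table, row.names = FALSE, digits = 5)
})

#' Pagel's lambda fit
#'
#' @slot lambda ML estimate in [0, 1] (NA when degenerate).
#' @slot logLik log-likelihood at the optimum.
#' @slot sigma2 ML Brownian-motion rate.
#' @slot mu GLS root state (phylogenetic mean).
#' @slot degenerate TRUE when the likelihood is flat in lambda (constant
#'   trait or star phylogeny) and the point estimate is not identifiable.
#' @slot note diagnostic message.
#' @export
setClass("PhyloSignalResult", representation(
  lambda = "numeric", logLik = "numeric", sigma2 = "numeric", mu = "numeric",
  degenerate = "logical", note = "character"))

setMethod("show", "PhyloSignalResult", function(object) {
  if (object@degenerate) {
    cat(sprintf("Pagel's lambda: unidentifiable (%s)\n", object@note))
  } else {
    cat(sprintf("Pagel's lambda = %.4f (logLik %.4f, sigma2 %.4g, mu %.4g)\n",
                object@lambda, object@logLik, object@sigma2, object@mu))
  }
})
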