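#' Shape parameters of a synthetic mandible model
#'
#' Parameter set of the template used to generate mandible-like planar QUAD8
#' meshes.  The template is a bent strip: a horizontal corpus (tooth-bearing
#' body) joined to an ascending ramus through a smooth gonial arc, with a
#' coronoid bump on the anterior ramus border and a tapered condylar end.
#' All lengths in mm.
#'
#' @param corpus_length length of the corpus (anterior end to gonial
#'   region), > 0.
#' @param corpus_height depth of the corpus (the bending-beam depth, the
#'   main stiffness lever), > 0.
#' @param ramus_height length of the ascending ramus, > 0.
#' @param ramus_angle interior angle between corpus and ramus in degrees,
#'   in (90, 180); 180 would be a straight strip.
#' @param condyle_sharpness taper factor of the condylar end in `[1, 3]`;
#'   1 = blunt (no taper), larger = more pointed condyle.
#' @param coronoid_height height of the coronoid bump above the ramus
#'   border, >= 0.
#' @param thickness_triplet three mandibular width measurements thk1..thk3
#'   (mm); their mean becomes the constant model thickness.
#' @param masseter_area,temporalis_area muscle insertion areas (mm^2,
#'   specimen metadata, not recomputed from the 2D outline).
#' @return named list of validated parameters.
#' @export
mandibleParams <- function(corpus_length = 60, corpus_height = 14,
                           ramus_height = 35, ramus_angle = 115,
                           condyle_sharpness = 1.5, coronoid_height = 5,
                           thickness_triplet = c(9, 10, 11),
                           masseter_area = 900, temporalis_area = 1100) {
  p <- list(corpus_length = corpus_length, corpus_height = corpus_height,
            ramus_height = ramus_height, ramus_angle = ramus_angle,
            condyle_sharpness = condyle_sharpness,
            coronoid_height = coronoid_height,
            thickness_triplet = as.numeric(thickness_triplet),
            masseter_area = masseter_area, temporalis_area = temporalis_area)
  validateMandibleParams(p)
  p
}

validateMandibleParams <- function(p) {
  pos <- c("corpus_length", "corpus_height", "ramus_height",
           "masseter_area", "temporalis_area")
  for (nm in pos)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter out of range: ", nm, " must be > 0")
  if (p$ramus_angle <= 90 || p$ramus_angle >= 180)
    stop("parameter out of range: ramus_angle must lie in (90, 180) degrees")
  if (p$condyle_sharpness < 1 || p$condyle_sharpness > 3)
    stop("parameter out of range: condyle_sharpness must lie in [1, 3]")
  if (p$coronoid_height < 0 || p$coronoid_height > p$ramus_height)
    stop("parameter out of range: coronoid_height")
  if (length(p$thickness_triplet) != 3 || any(p$thickness_triplet <= 0))
    stop("parameter out of range: thickness_triplet must be 3 positive widths")
  invisible(p)
}

# swept-strip geometry: centreline with a circular gonial blend, plus
# asymmetric offset profiles for the two boundaries.
mandibleGeometry <- function(p) {
  Lc <- p$corpus_length
  theta <- pi * (180 - p$ramus_angle) / 180      # upward turn of the ramus
  R <- p$corpus_height                           # blend radius > half-width
  arcLen <- R * theta
  Lr <- p$ramus_height
  L <- Lc + arcLen + Lr
  centre <- function(s) {
    if (s <= Lc) {
      list(c = c(s, 0), t = c(1, 0))
    } else if (s <= Lc + arcLen) {
      phi <- (s - Lc) / R
      list(c = c(Lc + R * sin(phi), R * (1 - cos(phi))),
           t = c(cos(phi), sin(phi)))
    } else {
      phi <- theta
      p1 <- c(Lc + R * sin(phi), R * (1 - cos(phi)))
      list(c = p1 + (s - Lc - arcLen) * c(cos(phi), sin(phi)),
           t = c(cos(phi), sin(phi)))
    }
  }
  smoothstep <- function(u) {
    u <- pmin(1, pmax(0, u)); u * u * (3 - 2 * u)
  }
  hw <- function(s) {
    base <- p$corpus_height / 2
    # taper toward the condylar end over the last quarter of the ramus
    taperStart <- L - 0.25 * Lr
    f <- 1 - (1 - 1 / p$condyle_sharpness) *
      smoothstep((s - taperStart) / (L - taperStart))
    base * f
  }
  sCor <- Lc + arcLen + 0.55 * Lr                # coronoid bump position
  wCor <- 0.16 * Lr
  upper <- function(s) hw(s)                     # +n side: alveolar margin,
                                                 # posterior ramus border
  lower <- function(s)                            # -n side: ventral corpus,
    hw(s) + p$coronoid_height * exp(-((s - sCor) / wCor)^2)  # coronoid bump
  point <- function(s, t) {
    ct <- centre(s)
    n <- c(-ct$t[2], ct$t[1])
    off <- if (t >= 0) t * upper(s) else t * lower(s)
    ct$c + off * n
  }
  list(L = L, Lc = Lc, arcLen = arcLen, Lr = Lr, theta = theta,
       point = point, sCor = sCor, wCor = wCor)
}

# fractions of corpus length where the bite points sit on the alveolar margin
BITE_FRACTIONS <- c(IB = 0.03, CB = 0.16, PB = 0.45, MB = 0.65)

#' Generate a synthetic mandible-like QUAD8 mesh
#'
#' Builds a structured QUAD8 mesh of the parametric mandible template by
#' sweeping a quadratic lattice over the bent-strip geometry, and assigns
#' the named node sets the loading module requires: `condyle` (single
#' posterior condylar node), `bite_IB/CB/PB/MB` (single nodes at fixed
#' fractions of the alveolar margin), `masseter` (posteroventral ramus
#' border around the gonial angle) and `temporalis` (coronoid region).
#' Element sizes are near-uniform by construction, so the mesh is
#' quasi-ideal (PEofAM < 2, PEofM < 5) for smooth stress fields.
#'
#' @param params parameter list from [mandibleParams()].
#' @param density target element density (elements per mm of length).
#' @return A [Mesh2D-class] with thickness `mean(thickness_triplet)`.
#' @export
generateMandibleMesh <- function(params, density = 0.15) {
  validateMandibleParams(params)
  g <- mandibleGeometry(params)
  nS <- max(10L, as.integer(ceiling(g$L * density)))
  nT <- 2L * max(1L, as.integer(ceiling(params$corpus_height * density / 2)))
  # lattice (2nS+1) x (2nT+1) without odd-odd interior nodes; t = 0 falls on
  # an element boundary because nT is even, keeping the two offset profiles
  # in separate element rows
  id <- matrix(NA_integer_, 2 * nS + 1, 2 * nT + 1)
  ids <- integer(0); xs <- ys <- numeric(0)
  nid <- 0L
  for (j in 0:(2 * nT)) for (i in 0:(2 * nS)) {
    if (i %% 2 == 1 && j %% 2 == 1) next
    nid <- nid + 1L
    id[i + 1, j + 1] <- nid
    s <- g$L * i / (2 * nS)
    t <- -1 + j / nT
    xy <- g$point(s, t)
    ids <- c(ids, nid); xs <- c(xs, xy[1]); ys <- c(ys, xy[2])
  }
  conn <- matrix(0L, nS * nT, 8)
  e <- 0L
  for (j in seq_len(nT)) for (i in seq_len(nS)) {
    e <- e + 1L
    i0 <- 2 * (i - 1) + 1; j0 <- 2 * (j - 1) + 1
    conn[e, ] <- c(id[i0, j0], id[i0 + 2, j0], id[i0 + 2, j0 + 2],
                   id[i0, j0 + 2], id[i0 + 1, j0], id[i0 + 2, j0 + 1],
                   id[i0 + 1, j0 + 2], id[i0, j0 + 1])
  }
  sOfLattice <- g$L * (0:(2 * nS)) / (2 * nS)
  topRow <- 2 * nT + 1; bottomRow <- 1
  latticeAt <- function(s) 1L + as.integer(round(2 * nS * s / g$L))
  biteSets <- lapply(BITE_FRACTIONS, function(f) {
    i <- latticeAt(f * g$Lc)
    if (i %% 2 == 0) i <- i - 1L        # snap to a corner node
    id[i, topRow]
  })
  names(biteSets) <- paste0("bite_", names(BITE_FRACTIONS))
  # boundary node runs snapped to whole element edges so that consistent
  # edge loads see complete (corner, mid-side, corner) triplets
  boundaryRun <- function(sFrom, sTo, row) {
    eFrom <- max(1L, min(nS, 1L + (latticeAt(sFrom) - 1L) %/% 2L))
    eTo <- max(eFrom, min(nS, 1L + (latticeAt(sTo) - 1L) %/% 2L))
    iRange <- (2 * (eFrom - 1) + 1):(2 * eTo + 1)
    as.integer(id[iRange, row])
  }
  masseter <- boundaryRun(g$Lc + 0.3 * g$arcLen,
                          g$Lc + g$arcLen + 0.35 * g$Lr, topRow)
  temporalis <- boundaryRun(g$sCor - g$wCor, g$sCor + g$wCor, bottomRow)
  sets <- c(list(condyle = id[2 * nS + 1, topRow],
                 masseter = masseter, temporalis = temporalis), biteSets)
  mesh <- mesh2D(nodes = data.frame(id = ids, x = xs, y = ys),
                 elements = cbind(seq_len(nS * nT), conn),
                 nodeSets = sets,
                 thickness = mean(params$thickness_triplet),
                 requiredSets = REQUIRED_NODE_SETS)
  mesh
}

# template origin points of the jaw adductors, used to orient muscle pull
muscleDirections <- function(mesh, params) {
  centroidOf <- function(setName) {
    idx <- match(mesh@nodeSets[[setName]], mesh@nodeIds)
    colMeans(mesh@coords[idx, , drop = FALSE])
  }
  yTop <- max(mesh@coords[, 2])
  massCentroid <- centroidOf("masseter")
  tempCentroid <- centroidOf("temporalis")
  massOrigin <- c(0.55 * params$corpus_length,
                  yTop + 0.4 * params$ramus_height)
  tempOrigin <- c(tempCentroid[1] - 0.15 * params$corpus_length,
                  yTop + 0.8 * params$ramus_height)
  normalize <- function(v) v / sqrt(sum(v^2))
  list(masseter = normalize(massOrigin - massCentroid),
       temporalis = normalize(tempOrigin - tempCentroid))
}

#' Specification of a synthetic cohort
#'
#' Controls the cohort generator: species counts per diet x hardness cell,
#' multiplicative parameter effects per factor level, lognormal noise, mesh
#' density and seed.  The default cell counts mirror a 31-species primate
#' cohort (12 frugivores, 11 omnivores, 8 folivores) and the default effects
#' encode the expected biology: hard-food eaters get deeper, thicker corpora
#' (stiffer jaws), folivores slightly gracile and omnivores slightly robust
#' mandibles.
#'
#' @param nPerCell named integer vector `diet.hardness` -> count.
#' @param effects list with elements `diet` and `hardness`, each a named
#'   list level -> named numeric vector of parameter multipliers (> 0).
#' @param noiseSd standard deviation of the lognormal parameter noise.
#' @param density mesh density (elements per mm).
#' @param seed RNG seed.
#' @return validated list of class `cohortSpec`.
#' @export
cohortSpec <- function(
    nPerCell = c(omnivore.hard = 5, omnivore.soft = 6,
                 frugivore.hard = 6, frugivore.soft = 6,
                 folivore.hard = 2, folivore.soft = 6),
    effects = list(
      diet = list(omnivore = c(corpus_height = 1.08),
                  frugivore = c(),
                  folivore = c(corpus_height = 0.92)),
      hardness = list(hard = c(corpus_height = 1.15,
                               thickness_triplet = 1.10),
                      soft = c())),
    noiseSd = 0.06, density = 0.15, seed = 1L) {
  cells <- as.vector(outer(DIET_LEVELS, HARDNESS_LEVELS, paste, sep = "."))
  if (!all(names(nPerCell) %in% cells))
    stop("nPerCell names must be diet.hardness combinations")
  for (f in names(effects)) for (lv in names(effects[[f]]))
    if (length(effects[[f]][[lv]]) && any(effects[[f]][[lv]] <= 0))
      stop("effect multipliers must be > 0")
  structure(list(nPerCell = nPerCell, effects = effects, noiseSd = noiseSd,
                 density = density, seed = as.integer(seed)),
            class = "cohortSpec")
}

applyMultipliers <- function(params, mult) {
  for (nm in names(mult)) params[[nm]] <- params[[nm]] * mult[[nm]]
  params
}

#' Generate a synthetic specimen cohort
#'
#' For every diet x hardness cell, draws the requested number of species:
#' template parameters are the baseline times the cell's category effects
#' times per-parameter lognormal noise, the mesh is generated, the planar
#' model area measured on the mesh, and muscle directions computed from the
#' insertion-set centroids toward template origin points.  Bit-reproducible
#' for a fixed seed.
#'
#' @param spec a [cohortSpec()].
#' @param baseline baseline parameters ([mandibleParams()]).
#' @return list with `specimens` (list of [SpecimenRecord-class]) and
#'   `traits` (data.frame of specimen, diet, hardness and key parameters).
#' @export
generateCohort <- function(spec, baseline = mandibleParams()) {
  stopifnot(inherits(spec, "cohortSpec"))
  noisy <- names(baseline)[vapply(baseline, is.numeric, TRUE)]
  noisy <- setdiff(noisy, c("ramus_angle", "condyle_sharpness"))
  specimens <- list(); rows <- list()
  withSeed(spec$seed, {
    k <- 0L
    for (cell in names(spec$nPerCell)) {
      n <- spec$nPerCell[[cell]]
      if (n == 0) next
      parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
      diet <- parts[1]; hardness <- parts[2]
      for (r in seq_len(n)) {
        k <- k + 1L
        id <- sprintf("sp%02d", k)
        p <- baseline
        p <- applyMultipliers(p, spec$effects$diet[[diet]])
        p <- applyMultipliers(p, spec$effects$hardness[[hardness]])
        if (spec$noiseSd > 0) {
          for (nm in noisy)
            p[[nm]] <- p[[nm]] * exp(rnorm(1, 0, spec$noiseSd))
        }
        mesh <- generateMandibleMesh(p, density = spec$density)
        S <- sum(allElementAreas(mesh))
        dirs <- muscleDirections(mesh, p)
        muscles <- list(
          muscleSpec("masseter", "masseter", p$masseter_area,
                     dirs$masseter),
          muscleSpec("temporalis", "temporalis", p$temporalis_area,
                     dirs$temporalis))
        specimens[[id]] <- specimenRecord(
          specimenId = id, mesh = mesh, thk = p$thickness_triplet,
          surfaceArea = S, diet = diet, hardness = hardness,
          muscles = muscles)
        rows[[id]] <- data.frame(
          specimen = id, diet = diet, hardness = hardness,
          corpus_length = p$corpus_length, corpus_height = p$corpus_height,
          ramus_height = p$ramus_height, ramus_angle = p$ramus_angle,
          thickness = mean(p$thickness_triplet), surface_area = S,
          masseter_area = p$masseter_area,
          temporalis_area = p$temporalis_area)
      }
    }
  })
  list(specimens = specimens, traits = do.call(rbind, c(rows,
                                                        make.row.names = FALSE)))
}

#' Simulate a cohort phylogeny
#'
#' Seeded pure-birth tree with the requested number of tips, rescaled to
#' unit root-to-tip depth (ultrametric).
#'
#' @param nTips number of tips (>= 2).
#' @param seed RNG seed.
#' @param tipLabels optional labels (default sp01, sp02, ...).
#' @return an ape "phylo".
#' @export
simulateTree <- function(nTips, seed = 1L, tipLabels = NULL) {
  if (nTips < 2) stop("nTips must be >= 2")
  tree <- withSeed(seed, ape::rphylo(nTips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- if (is.null(tipLabels)) sprintf("sp%02d", seq_len(nTips))
                    else tipLabels
  tree
}
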