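# plane-stress constitutive matrix D = E/(1-nu^2) [[1,nu,0],[nu,1,0],[0,0,(1-nu)/2]]
constitutiveMatrix <- function(mat) {
  E <- mat@E; nu <- mat@nu
  E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
}

#' QUAD8 element stiffness matrix
#'
#' 16x16 plane-stress stiffness of one 8-node serendipity quadrilateral,
#' integrated with a 3x3 Gauss rule (full integration; pass `nGauss = 2` for
#' reduced integration).  Dof ordering is (ux1, uy1, ..., ux8, uy8) in the
#' element's node order.
#'
#' @param mesh A [Mesh2D-class].
#' @param elementId Element id.
#' @param mat A [MaterialProps-class].
#' @param nGauss quadrature order per direction (3 or 2).
#' @return 16 x 16 symmetric matrix; scales linearly with E and thickness and
#'   has exactly three rigid-body zero-energy modes.
#' @export
elementStiffnessQuad8 <- function(mesh, elementId, mat, nGauss = 3L) {
  xy <- elementCoords(mesh, elementId)
  D <- constitutiveMatrix(mat)
  t <- mesh@thickness
  g <- gaussRule(nGauss)
  K <- matrix(0, 16, 16)
  B <- matrix(0, 3, 16)
  for (k in seq_len(nrow(g))) {
    s <- quad8Shape(g$xi[k], g$eta[k])
    J <- crossprod(s$dN, xy)
    detJ <- det(J)
    if (detJ <= 0)
      stop(sprintf("degenerate element %d: non-positive Jacobian", elementId))
    dNxy <- s$dN %*% t(solve(J))
    B[1, seq(1, 15, 2)] <- dNxy[, 1]
    B[2, seq(2, 16, 2)] <- dNxy[, 2]
    B[3, seq(1, 15, 2)] <- dNxy[, 2]
    B[3, seq(2, 16, 2)] <- dNxy[, 1]
    K <- K + (t * g$w[k] * detJ) * crossprod(B, D %*% B)
  }
  (K + t(K)) / 2
}

dofIndex <- function(nodeRow, dir) 2L * (nodeRow - 1L) + ifelse(dir == "x", 1L, 2L)

# assemble the global sparse stiffness (2n x 2n)
assembleStiffness <- function(mesh, mat, nGauss = 3L) {
  ne <- length(mesh@elementIds)
  ii <- jj <- integer(256L * ne); xx <- numeric(256L * ne)
  pos <- 0L
  for (r in seq_len(ne)) {
    Ke <- elementStiffnessQuad8(mesh, mesh@elementIds[r], mat, nGauss)
    rows <- match(mesh@conn[r, ], mesh@nodeIds)
    edofs <- as.vector(rbind(2L * rows - 1L, 2L * rows))
    idx <- pos + seq_len(256L)
    ii[idx] <- rep(edofs, times = 16)
    jj[idx] <- rep(edofs, each = 16)
    xx[idx] <- as.vector(Ke)
    pos <- pos + 256L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(2L, 2L) * length(mesh@nodeIds))
}

#' Solve a plane-stress load case
#'
#' Assembles the global stiffness, applies the fixed dofs by row/column
#' elimination (exact zeros at supports), solves the reduced sparse system by
#' direct factorization, and recovers the stress at each element centroid
#' through the plane-stress constitutive law.  Elements touching any
#' constrained node are flagged `adjacentToConstraint` (point supports are
#' numerical singularities; the summary layer can exclude them).
#'
#' @param mesh A [Mesh2D-class].
#' @param mat A [MaterialProps-class].
#' @param load A [LoadCase-class].
#' @param nGauss stiffness quadrature order (3 = full, 2 = reduced).
#' @return List with `displacements` (data.frame node, ux, uy), `stress`
#'   (a [StressField-class]), `reactions` (data.frame node, dir, value) and
#'   `equilibriumResidual` (relative out-of-balance force).
#' @export
solvePlaneStress <- function(mesh, mat, load, nGauss = 3L) {
  validObject(load)
  n <- length(mesh@nodeIds)
  K <- assembleStiffness(mesh, mat, nGauss)
  f <- numeric(2L * n)
  if (nrow(load@nodalForces)) {
    rows <- match(load@nodalForces$node, mesh@nodeIds)
    if (anyNA(rows)) stop("nodal force on unknown node id")
    f[2L * rows - 1L] <- f[2L * rows - 1L] + load@nodalForces$fx
    f[2L * rows] <- f[2L * rows] + load@nodalForces$fy
  }
  fixedRows <- match(load@fixedDofs$node, mesh@nodeIds)
  if (anyNA(fixedRows)) stop("fixed dof on unknown node id")
  fixed <- dofIndex(fixedRows, load@fixedDofs$dir)
  free <- setdiff(seq_len(2L * n), fixed)
  # well-posedness: the constraints must suppress all three rigid-body modes
  # (x/y translation and in-plane rotation); rank test of the mode space
  # restricted to the fixed dofs
  xy <- mesh@coords[fixedRows, , drop = FALSE]
  isX <- load@fixedDofs$dir == "x"
  A <- cbind(ifelse(isX, 1, 0), ifelse(isX, 0, 1),
             ifelse(isX, -xy[, 2], xy[, 1]))
  if (qr(A)$rank < 3L)
    stop("under-constrained model: constraints leave a rigid-body mode free")
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u <- numeric(2L * n)
  # sparse Cholesky: the reduced stiffness of a well-posed load case is SPD,
  # so a factorization failure means rigid-body motion is left unconstrained
  ch <- tryCatch(Matrix::Cholesky(Kff, perm = TRUE, LDL = FALSE,
                                  super = FALSE),
                 error = function(e)
                   stop("under-constrained model: singular stiffness after applying constraints"))
  uf <- as.numeric(Matrix::solve(ch, f[free], system = "A"))
  if (any(!is.finite(uf)))
    stop("numerical failure: non-finite solution")
  rr <- max(abs(as.numeric(Kff %*% uf) - f[free]))
  if (rr > 1e-6 * max(abs(f[free]), 1e-300))
    stop("under-constrained model: singular stiffness after applying constraints")
  u[free] <- uf
  # reactions at fixed dofs
  r <- as.numeric(K %*% u) - f
  reactions <- data.frame(node = load@fixedDofs$node, dir = load@fixedDofs$dir,
                          value = r[fixed])
  fscale <- max(abs(f), abs(r[fixed]), 1e-300)
  # global equilibrium: applied + reactions per component
  sumFx <- sum(f[seq(1, 2 * n, 2)]) + sum(reactions$value[reactions$dir == "x"])
  sumFy <- sum(f[seq(2, 2 * n, 2)]) + sum(reactions$value[reactions$dir == "y"])
  resid <- sqrt(sumFx^2 + sumFy^2) / fscale

  D <- constitutiveMatrix(mat)
  ne <- length(mesh@elementIds)
  sigma <- matrix(0, ne, 3)
  vm <- areas <- numeric(ne)
  centroid <- quad8Shape(0, 0)
  B <- matrix(0, 3, 16)
  for (rI in seq_len(ne)) {
    rows <- match(mesh@conn[rI, ], mesh@nodeIds)
    xy <- mesh@coords[rows, , drop = FALSE]
    J <- crossprod(centroid$dN, xy)
    dNxy <- centroid$dN %*% t(solve(J))
    B[1, seq(1, 15, 2)] <- dNxy[, 1]
    B[2, seq(2, 16, 2)] <- dNxy[, 2]
    B[3, seq(1, 15, 2)] <- dNxy[, 2]
    B[3, seq(2, 16, 2)] <- dNxy[, 1]
    ue <- u[as.vector(rbind(2L * rows - 1L, 2L * rows))]
    s <- as.numeric(D %*% (B %*% ue))
    sigma[rI, ] <- s
    vm[rI] <- sqrt(max(0, s[1]^2 + s[2]^2 - s[1] * s[2] + 3 * s[3]^2))
    areas[rI] <- elementArea(mesh, mesh@elementIds[rI])
  }
  fixedNodes <- unique(load@fixedDofs$node)
  adj <- apply(mesh@conn, 1, function(cn) any(cn %in% fixedNodes))
  field <- new("StressField", elementIds = mesh@elementIds, sigma = sigma,
               vonMises = vm, areas = areas, adjacentToConstraint = adj)
  disp <- data.frame(node = mesh@nodeIds,
                     ux = u[seq(1, 2 * n, 2)], uy = u[seq(2, 2 * n, 2)])
  list(displacements = disp, stress = field, reactions = reactions,
       equilibriumResidual = resid)
}

#' Distribute a total force over a boundary node set with edge-consistent
#' weights
#'
#' Splits `totalForce` over the nodes of a set so that the vector sum equals
#' `totalForce` exactly.  Where the set contains whole QUAD8 boundary edges
#' (corner, mid-side, corner), the consistent load vector of a uniform
#' traction on a quadratic edge is used: per edge of length L, weights
#' L/6, 4L/6, L/6 — so a mid-side node receives four times the weight of a
#' same-edge corner, and corners interior to a chain of edges accumulate the
#' contributions of both edges.  If the set contains no complete edge
#' (e.g. a single node), nodes are weighted 4:1 (mid-side:corner) directly.
#'
#' @param mesh A [Mesh2D-class].
#' @param nodeSet name of a node set on `mesh`, or an integer vector of node
#'   ids.
#' @param totalForce length-2 numeric (Fx, Fy) in N.
#' @return data.frame(node, fx, fy); `sum(fx), sum(fy)` equal `totalForce`
#'   to machine precision.
#' @export
consistentEdgeForces <- function(mesh, nodeSet, totalForce) {
  ids <- if (is.character(nodeSet)) {
    if (is.null(mesh@nodeSets[[nodeSet]]))
      stop(sprintf("incomplete model: missing node set '%s'", nodeSet))
    mesh@nodeSets[[nodeSet]]
  } else as.integer(nodeSet)
  if (length(ids) == 0L) stop("empty node set")
  w <- setNames(numeric(length(ids)), ids)
  # collect element edges fully contained in the set
  edgeCorn <- list(c(1, 2, 5), c(2, 3, 6), c(3, 4, 7), c(4, 1, 8))
  found <- FALSE
  for (r in seq_len(nrow(mesh@conn))) {
    cn <- mesh@conn[r, ]
    for (ed in edgeCorn) {
      tri <- cn[ed]            # corner, corner, mid-side
      if (all(tri %in% ids)) {
        found <- TRUE
        xy <- mesh@coords[match(tri, mesh@nodeIds), , drop = FALSE]
        # quadratic edge length via 3-point Gauss along the edge
        gp <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); gw <- c(5, 8, 5) / 9
        L <- 0
        for (k in 1:3) {
          s <- gp[k]
          # edge shape derivative: nodes at s=-1, +1, 0
          dN <- c(s - 0.5, s + 0.5, -2 * s)
          dxy <- crossprod(dN, xy)
          L <- L + gw[k] * sqrt(sum(dxy^2))
        }
        wEdge <- L * c(1 / 6, 1 / 6, 4 / 6)
        w[as.character(tri)] <- w[as.character(tri)] + wEdge
      }
    }
  }
  if (!found) {
    # fall back: 4:1 mid-side:corner weighting by node role
    mids <- unique(as.vector(mesh@conn[, 5:8, drop = FALSE]))
    w[] <- ifelse(ids %in% mids, 4, 1)
  } else if (any(w == 0)) {
    # nodes of the set not on any complete edge share the leftover evenly at
    # corner weight so no requested node is silently dropped
    w[w == 0] <- min(w[w > 0]) / 4
  }
  w <- w / sum(w)
  data.frame(node = ids, fx = w * totalForce[1], fy = w * totalForce[2],
             row.names = NULL)
}

#' Export a stress field or displacement field to CSV
#'
#' @param field A [StressField-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
exportStressCSV <- function(field, path) {
  df <- data.frame(element = field@elementIds, area = field@areas,
                   sigma_x = field@sigma[, 1], sigma_y = field@sigma[, 2],
                   tau_xy = field@sigma[, 3], von_mises = field@vonMises,
                   adjacent_to_constraint = field@adjacentToConstraint)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
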