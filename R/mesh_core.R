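# QUAD8 node numbering: corners 1-4 counter-clockwise, mid-sides 5-8 on
# edges 1-2, 2-3, 3-4, 4-1.  Local coordinates of the 8 nodes:
QUAD8_XI  <- c(-1, 1, 1, -1, 0, 1, 0, -1)
QUAD8_ETA <- c(-1, -1, 1, 1, -1, 0, 1, 0)

# shape functions and their local derivatives at (xi, eta)
quad8Shape <- function(xi, eta) {
  N <- numeric(8); dN <- matrix(0, 8, 2)
  for (i in 1:4) {
    xi_i <- QUAD8_XI[i]; eta_i <- QUAD8_ETA[i]
    N[i] <- 0.25 * (1 + xi * xi_i) * (1 + eta * eta_i) *
      (xi * xi_i + eta * eta_i - 1)
    dN[i, 1] <- 0.25 * xi_i * (1 + eta * eta_i) * (2 * xi * xi_i + eta * eta_i)
    dN[i, 2] <- 0.25 * eta_i * (1 + xi * xi_i) * (xi * xi_i + 2 * eta * eta_i)
  }
  for (i in c(5L, 7L)) {        # mid-sides with xi_i = 0
    eta_i <- QUAD8_ETA[i]
    N[i] <- 0.5 * (1 - xi^2) * (1 + eta * eta_i)
    dN[i, 1] <- -xi * (1 + eta * eta_i)
    dN[i, 2] <- 0.5 * (1 - xi^2) * eta_i
  }
  for (i in c(6L, 8L)) {        # mid-sides with eta_i = 0
    xi_i <- QUAD8_XI[i]
    N[i] <- 0.5 * (1 + xi * xi_i) * (1 - eta^2)
    dN[i, 1] <- 0.5 * xi_i * (1 - eta^2)
    dN[i, 2] <- -(1 + xi * xi_i) * eta
  }
  list(N = N, dN = dN)
}

# 3x3 Gauss-Legendre rule on [-1,1]^2 (full integration of the serendipity
# element); 2x2 available as reduced integration.
gaussRule <- function(n = 3L) {
  if (n == 3L) {
    p <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)); w <- c(5, 8, 5) / 9
  } else if (n == 2L) {
    p <- c(-1, 1) / sqrt(3); w <- c(1, 1)
  } else stop("unsupported quadrature order")
  g <- expand.grid(xi = p, eta = p)
  g$w <- as.vector(outer(w, w))
  g
}

# cache of shape evaluations at the 3x3 rule, used by stiffness and area
.quad8Cache <- local({
  g <- gaussRule(3L)
  list(rule = g, shapes = lapply(seq_len(nrow(g)), function(k)
    quad8Shape(g$xi[k], g$eta[k])))
})

elementCoords <- function(mesh, elementId) {
  row <- match(elementId, mesh@elementIds)
  if (is.na(row)) stop(sprintf("unknown element id %s", elementId))
  idx <- match(mesh@conn[row, ], mesh@nodeIds)
  mesh@coords[idx, , drop = FALSE]
}

# signed area of the 4-corner polygon; used for winding canonicalization
cornerSignedArea <- function(xy) {
  x <- xy[1:4, 1]; y <- xy[1:4, 2]
  0.5 * sum(x * y[c(2, 3, 4, 1)] - x[c(2, 3, 4, 1)] * y)
}

# flip a clockwise QUAD8 connectivity row to counter-clockwise
rewindQuad8 <- function(conn) conn[c(1, 4, 3, 2, 8, 7, 6, 5)]

#' Construct and validate a QUAD8 mesh
#'
#' Builds a [Mesh2D-class] from node and element tables.  Elements whose four
#' corner nodes are wound clockwise are re-ordered to the canonical
#' counter-clockwise form; elements that remain degenerate (non-positive
#' Jacobian at any 3x3 Gauss point) raise an error.
#'
#' @param nodes data.frame with columns id, x, y.
#' @param elements data.frame/matrix: element id followed by 8 node ids
#'   (corners counter-clockwise then mid-sides), or an ne x 8 connectivity
#'   matrix with ids in `elementIds`.
#' @param nodeSets named list of node-id vectors.
#' @param thickness constant mesh thickness (mm).
#' @param requiredSets character vector of node-set names that must be
#'   present and non-empty; defaults to none (mandible models are checked by
#'   [readMesh()]).
#' @return A validated [Mesh2D-class].
#' @export
mesh2D <- function(nodes, elements, nodeSets = list(), thickness = 1,
                   requiredSets = character(0)) {
  nodeIds <- as.integer(nodes$id)
  coords <- cbind(as.numeric(nodes$x), as.numeric(nodes$y))
  elements <- as.matrix(elements)
  if (ncol(elements) == 9L) {
    elementIds <- as.integer(elements[, 1]); conn <- elements[, -1, drop = FALSE]
  } else if (ncol(elements) == 8L) {
    elementIds <- seq_len(nrow(elements)); conn <- elements
  } else stop("elements must have 8 node ids (plus optional leading id)")
  storage.mode(conn) <- "integer"
  missing <- setdiff(requiredSets, names(nodeSets))
  if (length(missing))
    stop(sprintf("incomplete model: missing node set '%s'", missing[1]))
  for (nm in requiredSets)
    if (length(nodeSets[[nm]]) == 0L)
      stop(sprintf("incomplete model: node set '%s' is empty", nm))
  nodeSets <- lapply(nodeSets, as.integer)
  mesh <- new("Mesh2D", nodeIds = nodeIds, coords = coords,
              elementIds = elementIds, conn = conn,
              nodeSets = nodeSets, thickness = as.numeric(thickness))
  canonicalizeWinding(mesh)
}

canonicalizeWinding <- function(mesh) {
  for (r in seq_along(mesh@elementIds)) {
    idx <- match(mesh@conn[r, ], mesh@nodeIds)
    xy <- mesh@coords[idx, , drop = FALSE]
    if (cornerSignedArea(xy) < 0)
      mesh@conn[r, ] <- rewindQuad8(mesh@conn[r, ])
  }
  # after canonicalization every element must have positive Jacobian
  for (r in seq_along(mesh@elementIds)) {
    eid <- mesh@elementIds[r]
    xy <- elementCoords(mesh, eid)
    for (s in .quad8Cache$shapes) {
      J <- crossprod(s$dN, xy)
      if (det(J) <= 0)
        stop(sprintf("degenerate element %d: non-positive Jacobian", eid))
    }
  }
  mesh
}

#' Element area by Gauss quadrature of the isoparametric Jacobian
#'
#' @param mesh A [Mesh2D-class].
#' @param elementId Element id (scalar) for `elementArea`; `allElementAreas`
#'   returns the areas of every element in mesh order.
#' @return Area in mm^2 (strictly positive for valid elements).
#' @export
elementArea <- function(mesh, elementId) {
  xy <- elementCoords(mesh, elementId)
  a <- 0
  g <- .quad8Cache$rule
  for (k in seq_len(nrow(g))) {
    J <- crossprod(.quad8Cache$shapes[[k]]$dN, xy)
    a <- a + g$w[k] * det(J)
  }
  a
}

#' @rdname elementArea
#' @export
allElementAreas <- function(mesh) {
  vapply(mesh@elementIds, function(e) elementArea(mesh, e), numeric(1))
}

#' Element-size homogeneity report
#'
#' Summary statistics of element areas used to diagnose how close a mesh is
#' to the quasi-ideal condition (homogeneous element sizes, so unweighted
#' stress statistics approximate area-weighted ones).
#'
#' @param mesh A [Mesh2D-class].
#' @return Named list: n, min, max, mean, sd, cv (coefficient of variation;
#'   0 for identical elements).
#' @export
meshUniformityReport <- function(mesh) {
  a <- allElementAreas(mesh)
  m <- mean(a)
  s <- if (length(a) > 1L) sd(a) else 0
  list(n = length(a), min = min(a), max = max(a), mean = m, sd = s,
       cv = if (m > 0) s / m else NA_real_)
}

## ---- mesh file format -----------------------------------------------------
## Sectioned plain text:
##   MESH2D v1
##   THICKNESS
##   <t>
##   NODES
##   <id> <x> <y>
##   ELEMENTS
##   <id> <n1> ... <n8>
##   NODESETS
##   <name> <id> <id> ...
## '#' starts a comment; blank lines ignored.

#' Read and write the package's plain-text mesh format
#'
#' The format is sectioned (THICKNESS, NODES, ELEMENTS, NODESETS) and
#' human-writable; see the package vignette for the full schema.  On read,
#' clockwise elements are canonicalized to counter-clockwise winding and the
#' mesh is validated.  Coordinates are written with 17 significant digits so
#' that a write/read round trip is bit-exact.
#'
#' @param path File path.
#' @param requiredSets Node sets that must be present; the default is the
#'   full set a mandible model needs (condyle, four bite points, masseter and
#'   temporalis insertions).  Pass `character(0)` for generic meshes.
#' @return `readMesh` returns a [Mesh2D-class]; `writeMesh` returns `path`
#'   invisibly.
#' @export
readMesh <- function(path, requiredSets = REQUIRED_NODE_SETS) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^MESH2D", lines[1]))
    stop("not a MESH2D file (missing header)")
  lines <- lines[-1]
  section <- NA_character_
  thickness <- NA_real_
  nodes <- list(); elems <- list(); sets <- list()
  for (ln in lines) {
    if (ln %in% c("THICKNESS", "NODES", "ELEMENTS", "NODESETS")) {
      section <- ln; next
    }
    if (is.na(section)) stop(sprintf("content before any section: '%s'", ln))
    if (section == "THICKNESS") {
      thickness <- as.numeric(ln)
    } else if (section == "NODES") {
      v <- strsplit(ln, "\\s+")[[1]]
      if (length(v) != 3) stop(sprintf("bad node line: '%s'", ln))
      nodes[[length(nodes) + 1L]] <- as.numeric(v)
    } else if (section == "ELEMENTS") {
      v <- as.integer(strsplit(ln, "\\s+")[[1]])
      if (length(v) != 9) stop(sprintf("bad element line: '%s'", ln))
      elems[[length(elems) + 1L]] <- v
    } else {
      v <- strsplit(ln, "\\s+")[[1]]
      sets[[v[1]]] <- as.integer(v[-1])
    }
  }
  if (!is.finite(thickness)) stop("missing THICKNESS section")
  nm <- do.call(rbind, nodes)
  em <- do.call(rbind, elems)
  mesh2D(nodes = data.frame(id = nm[, 1], x = nm[, 2], y = nm[, 3]),
         elements = em, nodeSets = sets, thickness = thickness,
         requiredSets = requiredSets)
}

#' @param mesh A [Mesh2D-class] to write.
#' @rdname readMesh
#' @export
writeMesh <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("MESH2D v1", con)
  writeLines(c("THICKNESS", sprintf("%.17g", mesh@thickness)), con)
  writeLines("NODES", con)
  writeLines(sprintf("%d %.17g %.17g", mesh@nodeIds,
                     mesh@coords[, 1], mesh@coords[, 2]), con)
  writeLines("ELEMENTS", con)
  writeLines(paste(mesh@elementIds,
                   apply(mesh@conn, 1, paste, collapse = " ")), con)
  if (length(mesh@nodeSets)) {
    writeLines("NODESETS", con)
    for (nm in names(mesh@nodeSets))
      writeLines(paste(nm, paste(mesh@nodeSets[[nm]], collapse = " ")), con)
  }
  invisible(path)
}

#' Import a minimal Abaqus-style .inp mesh
#'
#' Supports the keyword subset *NODE, *ELEMENT (8-node plane elements, e.g.
#' TYPE=CPS8) and *NSET (ids listed inline, comma separated).  Thickness is
#' not part of the .inp subset and must be supplied.
#'
#' @param path .inp file path.
#' @param thickness mesh thickness (mm).
#' @inheritParams readMesh
#' @return A [Mesh2D-class].
#' @export
readAbaqusMesh <- function(path, thickness = 1,
                           requiredSets = character(0)) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "**")]
  section <- NA_character_; setName <- NA_character_
  nodes <- list(); elems <- list(); sets <- list()
  for (ln in lines) {
    if (startsWith(ln, "*")) {
      kw <- toupper(sub("^\\*([A-Za-z]+).*$", "\\1", ln))
      section <- kw
      if (kw == "NSET") {
        setName <- sub('.*NSET\\s*=\\s*([^,\\s]+).*', "\\1",
                       ln, ignore.case = TRUE)
        sets[[setName]] <- integer(0)
      }
      next
    }
    v <- strsplit(ln, "\\s*,\\s*")[[1]]
    v <- v[nzchar(v)]
    if (identical(section, "NODE")) {
      nodes[[length(nodes) + 1L]] <- as.numeric(v[1:3])
    } else if (identical(section, "ELEMENT")) {
      if (length(v) != 9) stop(sprintf("bad element line: '%s'", ln))
      elems[[length(elems) + 1L]] <- as.integer(v)
    } else if (identical(section, "NSET")) {
      sets[[setName]] <- c(sets[[setName]], as.integer(v))
    }
  }
  nm <- do.call(rbind, nodes)
  mesh2D(nodes = data.frame(id = nm[, 1], x = nm[, 2], y = nm[, 3]),
         elements = do.call(rbind, elems), nodeSets = sets,
         thickness = thickness, requiredSets = requiredSets)
}

#' Structured QUAD8 rectangle mesh
#'
#' Regular nx x ny grid of QUAD8 elements over `[0, Lx] x [0, Ly]`, with
#' boundary node sets "left", "right", "bottom", "top".  Used for solver
#' benchmarks (patch test, cantilever) and refinement studies.
#'
#' @param nx,ny elements along x and y.
#' @param Lx,Ly side lengths (mm).
#' @param thickness mesh thickness (mm).
#' @return A [Mesh2D-class].
#' @export
structuredRectangleMesh <- function(nx, ny, Lx = 1, Ly = 1, thickness = 1) {
  # serendipity grid: (2nx+1) x (2ny+1) lattice without odd-odd interior nodes
  id <- matrix(NA_integer_, 2 * nx + 1, 2 * ny + 1)
  xs <- ys <- numeric(0); ids <- integer(0)
  nid <- 0L
  for (j in 0:(2 * ny)) for (i in 0:(2 * nx)) {
    if (i %% 2 == 1 && j %% 2 == 1) next
    nid <- nid + 1L
    id[i + 1, j + 1] <- nid
    ids <- c(ids, nid)
    xs <- c(xs, Lx * i / (2 * nx)); ys <- c(ys, Ly * j / (2 * ny))
  }
  conn <- matrix(0L, nx * ny, 8)
  e <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    i0 <- 2 * (i - 1) + 1; j0 <- 2 * (j - 1) + 1   # 1-based lattice corner
    conn[e, ] <- c(id[i0, j0], id[i0 + 2, j0], id[i0 + 2, j0 + 2],
                   id[i0, j0 + 2], id[i0 + 1, j0], id[i0 + 2, j0 + 1],
                   id[i0 + 1, j0 + 2], id[i0, j0 + 1])
  }
  nodes <- data.frame(id = ids, x = xs, y = ys)
  eps <- 1e-12 * max(Lx, Ly)
  sets <- list(
    left = ids[abs(xs) < eps], right = ids[abs(xs - Lx) < eps],
    bottom = ids[abs(ys) < eps], top = ids[abs(ys - Ly) < eps])
  mesh2D(nodes, cbind(seq_len(nx * ny), conn), nodeSets = sets,
         thickness = thickness)
}
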