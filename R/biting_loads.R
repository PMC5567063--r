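#' Quasi-homothetic force scaling between models
#'
#' Rescales a reference muscle force so that plane-stress fields of
#' geometrically similar models become directly comparable:
#' `F_B = sqrt(S_B / S_A) * (t_B / t_A) * F_A`, where S is planar model area
#' and t model thickness.  A model scaled by k in plan and r in thickness,
#' loaded with the rescaled force, develops exactly the same stress field as
#' the reference.
#'
#' @param S_A,t_A,F_A reference model area (mm^2), thickness (mm) and total
#'   force (N).
#' @param S_B,t_B target model area and thickness.
#' @return Scaled total force F_B (N).
#' @export
scaleForce <- function(S_A, t_A, F_A, S_B, t_B) {
  vals <- c(S_A = S_A, t_A = t_A, F_A = F_A, S_B = S_B, t_B = t_B)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all scaling inputs must be positive: ",
         paste(names(vals)[!(is.finite(vals) & vals > 0)], collapse = ", "))
  sqrt(S_B / S_A) * (t_B / t_A) * F_A
}

#' Split a total muscle force proportionally to insertion areas
#'
#' Muscle force is assumed proportional to the insertion area, so the total
#' force is divided between the masseter and temporalis (or any list of
#' muscles) in proportion to their areas.  Magnitudes sum to `totalForce`
#' exactly.
#'
#' @param totalForce total force magnitude (N).
#' @param muscles list of [MuscleSpec-class] (or a named numeric vector of
#'   areas).
#' @return named numeric vector of force magnitudes.
#' @export
splitMuscleForces <- function(totalForce, muscles) {
  if (is.numeric(muscles)) {
    areas <- muscles
  } else {
    if (!length(muscles)) stop("at least one muscle is required")
    areas <- setNames(vapply(muscles, function(m) m@area, numeric(1)),
                      vapply(muscles, function(m) m@name, character(1)))
  }
  if (any(areas <= 0) || sum(areas) <= 0)
    stop("insertion areas must be positive")
  out <- totalForce * areas / sum(areas)
  # force exact conservation against rounding
  out[length(out)] <- totalForce - sum(out[-length(out)])
  out
}

#' Build the load case for one bite scenario
#'
#' Encodes the boundary conditions of a bite simulation: the condyle node(s)
#' are fixed in both directions (the jaw-joint contact), the bite point of
#' the requested case is fixed vertically (its reaction is the bite force),
#' and the quasi-homothetically scaled total muscle force is split across
#' the muscles by insertion area and distributed over each insertion node
#' set along the muscle's pull direction.
#'
#' @param specimen A [SpecimenRecord-class].
#' @param case bite case code: "IB", "CB", "PB" or "MB".
#' @param reference list with `S_A`, `t_A`, `F_A` — area, thickness and total
#'   force of the reference model (the paper-style convention is F_A = 1 N on
#'   the reference specimen).
#' @return A [LoadCase-class].
#' @export
buildBiteCase <- function(specimen, case, reference) {
  if (!case %in% names(BITE_CASES)) stop("unknown bite case: ", case)
  mesh <- specimen@mesh
  biteSet <- BITE_CASES[[case]]
  for (s in c("condyle", biteSet))
    if (is.null(mesh@nodeSets[[s]]) || !length(mesh@nodeSets[[s]]))
      stop(sprintf("incomplete model: missing node set '%s'", s))
  FB <- scaleForce(S_A = reference$S_A, t_A = reference$t_A,
                   F_A = reference$F_A,
                   S_B = specimen@surfaceArea, t_B = specimen@mesh@thickness)
  mags <- splitMuscleForces(FB, specimen@muscles)
  forces <- do.call(rbind, lapply(specimen@muscles, function(m) {
    consistentEdgeForces(mesh, m@nodeSet, mags[[m@name]] * m@direction)
  }))
  # merge duplicate nodes across insertion sets
  forces <- stats::aggregate(cbind(fx, fy) ~ node, data = forces, FUN = sum)
  fixed <- rbind(
    data.frame(node = rep(mesh@nodeSets[["condyle"]], each = 2),
               dir = rep(c("x", "y"), length(mesh@nodeSets[["condyle"]]))),
    data.frame(node = mesh@nodeSets[[biteSet]], dir = "y"))
  loadCase(fixedDofs = fixed, nodalForces = forces)
}

#' Vertical bite reaction force
#'
#' Sum of the vertical reactions at the bite point(s) of a solved bite case;
#' positive values indicate a compressive bite.
#'
#' @param solution result of [solvePlaneStress()].
#' @param mesh the specimen mesh.
#' @param case bite case code.
#' @return bite force (N).
#' @export
biteReaction <- function(solution, mesh, case) {
  biteNodes <- mesh@nodeSets[[BITE_CASES[[case]]]]
  rx <- solution$reactions
  # reactions are support forces on the jaw; the force the tooth exerts on
  # the food item is their opposite, so a compressive bite is positive
  -sum(rx$value[rx$dir == "y" & rx$node %in% biteNodes])
}
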