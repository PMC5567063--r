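#' Mesh-weighted (area-weighted) mean stress
#'
#' `sum(sigma_i * A_i) / sum(A_i)`: the area-weighted mean of element von
#' Mises stresses, correcting the plain arithmetic mean for non-uniform
#' element sizes.
#'
#' @param stresses per-element von Mises values (MPa).
#' @param areas per-element areas (mm^2), same length, all > 0.
#' @return MWAM (MPa).
#' @export
meshWeightedMean <- function(stresses, areas) {
  checkStressAreas(stresses, areas)
  sum(stresses * areas) / sum(areas)
}

checkStressAreas <- function(stresses, areas) {
  if (length(stresses) == 0L) stop("empty stress input")
  if (length(stresses) != length(areas))
    stop("stresses and areas must have equal length")
  if (any(areas <= 0)) stop("areas must be positive")
  invisible(TRUE)
}

#' Area-weighted percentile of a stress field
#'
#' Sorts stresses ascending carrying their areas and returns the smallest
#' stress whose cumulative area reaches `p` of the total (lower-value
#' cumulative rule, no interpolation — unambiguous on ties and small
#' meshes).  An interpolating variant is available via
#' `interpolate = TRUE`.  The mesh-weighted median MWM is the p = 0.5 case.
#'
#' @inheritParams meshWeightedMean
#' @param p fraction in (0, 1).
#' @param interpolate if TRUE, linearly interpolate between adjacent sorted
#'   stresses on the cumulative-area scale.
#' @return the weighted percentile (MPa).
#' @export
weightedPercentile <- function(stresses, areas, p, interpolate = FALSE) {
  checkStressAreas(stresses, areas)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  o <- order(stresses)
  s <- stresses[o]; a <- areas[o]
  cum <- cumsum(a)
  target <- p * cum[length(cum)]
  if (!interpolate) {
    return(s[which(cum >= target - 1e-12 * cum[length(cum)])[1]])
  }
  # interpolating variant: treat each element's mass as located at its
  # cumulative-area midpoint
  mid <- cum - a / 2
  stats::approx(mid, s, xout = target, rule = 2, ties = "ordered")$y
}

#' Quasi-ideal-mesh percentage errors
#'
#' Percentage disagreement between the unweighted statistics (arithmetic
#' mean AM, median M) and their area-weighted counterparts (MWAM, MWM):
#' `PEofAM = |AM - MWAM| / MWAM * 100`, `PEofM = |M - MWM| / MWM * 100`.
#' A mesh is treated as quasi-ideal when PEofAM < 2 and PEofM < 5, i.e. the
#' mesh is homogeneous enough that unweighted statistics are trustworthy.
#'
#' @inheritParams meshWeightedMean
#' @return named numeric vector c(PEofAM, PEofM); NA with a warning when a
#'   weighted statistic is zero while its unweighted counterpart is not.
#' @export
percentageErrors <- function(stresses, areas) {
  checkStressAreas(stresses, areas)
  AM <- mean(stresses)
  # unweighted median under the same cumulative rule as the weighted one, so
  # that equal-area meshes give exactly zero error
  M <- weightedPercentile(stresses, rep(1, length(stresses)), 0.5)
  MWAM <- meshWeightedMean(stresses, areas)
  MWM <- weightedPercentile(stresses, areas, 0.5)
  pe <- function(un, wt) {
    if (wt == 0) {
      if (un == 0) return(0)
      warning("weighted statistic is zero; percentage error undefined")
      return(NA_real_)
    }
    abs(un - wt) / wt * 100
  }
  c(PEofAM = pe(AM, MWAM), PEofM = pe(M, MWM))
}

#' Summarize a stress field into mesh-weighted statistics
#'
#' Computes the full set of summary statistics for one specimen x bite case:
#' arithmetic mean and median, area-weighted mean (MWAM) and median (MWM),
#' weighted percentiles M25/M50/M75/M95, the quasi-ideal-mesh percentage
#' errors and compliance flag.  By default, elements adjacent to constrained
#' nodes are excluded first: stresses there are artificially inflated by the
#' numerical singularity of point supports and are not biologically
#' meaningful.
#'
#' @param field A [StressField-class].
#' @param excludeConstraintAdjacent drop flagged elements before
#'   summarizing (default TRUE).
#' @param specimenId,biteCase identifiers carried into the summary.
#' @param interpolate use the interpolating weighted-percentile variant.
#' @return A [StressSummary-class].
#' @export
summarizeStress <- function(field, excludeConstraintAdjacent = TRUE,
                            specimenId = "", biteCase = "",
                            interpolate = FALSE) {
  keep <- if (excludeConstraintAdjacent) !field@adjacentToConstraint
          else rep(TRUE, length(field@elementIds))
  if (!any(keep))
    stop("degenerate model: exclusion removed every element")
  s <- field@vonMises[keep]; a <- field@areas[keep]
  MWAM <- meshWeightedMean(s, a)
  wp <- function(p) weightedPercentile(s, a, p, interpolate = interpolate)
  M50 <- wp(0.5)
  pe <- suppressWarnings(percentageErrors(s, a))
  qim <- isTRUE(pe[["PEofAM"]] < 2) && isTRUE(pe[["PEofM"]] < 5)
  new("StressSummary",
      specimenId = specimenId, biteCase = biteCase,
      AM = mean(s),
      M = weightedPercentile(s, rep(1, length(s)), 0.5,
                             interpolate = interpolate),
      MWAM = MWAM, MWM = M50,
      M25 = wp(0.25), M50 = M50, M75 = wp(0.75), M95 = wp(0.95),
      PEofAM = pe[["PEofAM"]], PEofM = pe[["PEofM"]],
      qimCompliant = qim, nExcluded = sum(!keep))
}

summaryRow <- function(x) {
  data.frame(specimen = x@specimenId, bite = x@biteCase, AM = x@AM, M = x@M,
             MWAM = x@MWAM, MWM = x@MWM, M25 = x@M25, M50 = x@M50,
             M75 = x@M75, M95 = x@M95, PEofAM = x@PEofAM, PEofM = x@PEofM,
             qim_compliant = x@qimCompliant, n_excluded = x@nExcluded)
}

#' Tabulate stress summaries
#'
#' `summaryTable` binds a list of [StressSummary-class] into a data.frame
#' (one row per specimen x bite case, fixed column order); `boxplotExport`
#' writes the quartile table backing stress box-plots to CSV.
#'
#' @param summaries list of [StressSummary-class].
#' @return `summaryTable`: data.frame; `boxplotExport`: the path, invisibly.
#' @export
summaryTable <- function(summaries) {
  if (!length(summaries)) {
    return(summaryRow(new("StressSummary", specimenId = "x", biteCase = "x",
                          AM = 0, M = 0, MWAM = 0, MWM = 0, M25 = 0, M50 = 0,
                          M75 = 0, M95 = 0, PEofAM = 0, PEofM = 0,
                          qimCompliant = TRUE, nExcluded = 0L))[0, ])
  }
  do.call(rbind, lapply(summaries, summaryRow))
}

#' @param path output CSV path.
#' @rdname summaryTable
#' @export
boxplotExport <- function(summaries, path) {
  tab <- summaryTable(summaries)
  tab <- tab[, c("specimen", "bite", "M25", "M50", "M75", "M95",
                 "MWAM", "MWM")]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
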