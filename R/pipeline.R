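#' Pipeline run configuration
#'
#' Bundles everything one end-to-end analysis run needs.  Defaults mirror
#' the reference protocol: cortical-bone material (E = 10 GPa = 1e4 MPa,
#' Poisson 0.4), 1 N total muscle force on the reference specimen, all four
#' bite cases, 9999 permutations, alpha = 0.05, constraint-adjacent
#' elements excluded from summaries.
#'
#' @param cohortSpec a [cohortSpec()] describing the synthetic cohort (or
#'   NULL when `cohort` is passed to [runPipeline()] directly).
#' @param material a [MaterialProps-class].
#' @param referenceSpecimen id of the reference model of the force scaling;
#'   NULL means the cohort's first specimen.
#' @param referenceForce total muscle force on the reference model (N).
#' @param biteCases bite cases to run.
#' @param nPerm PERMANOVA permutations.
#' @param alpha significance level.
#' @param excludeSingular exclude constraint-adjacent elements from
#'   summaries.
#' @param interpolatePercentiles use the interpolating weighted-percentile
#'   variant.
#' @param treeSeed,permSeed seeds for the phylogeny simulation and the
#'   permutation test.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(cohortSpec = NULL, material = materialProps(),
                      referenceSpecimen = NULL, referenceForce = 1,
                      biteCases = names(BITE_CASES), nPerm = 9999L,
                      alpha = 0.05, excludeSingular = TRUE,
                      interpolatePercentiles = FALSE,
                      treeSeed = 1L, permSeed = 1L) {
  stopifnot(is(material, "MaterialProps"))
  if (!all(biteCases %in% names(BITE_CASES)))
    stop("unknown bite case(s): ",
         paste(setdiff(biteCases, names(BITE_CASES)), collapse = ", "))
  structure(list(cohortSpec = cohortSpec, material = material,
                 referenceSpecimen = referenceSpecimen,
                 referenceForce = referenceForce, biteCases = biteCases,
                 nPerm = as.integer(nPerm), alpha = alpha,
                 excludeSingular = excludeSingular,
                 interpolatePercentiles = interpolatePercentiles,
                 treeSeed = as.integer(treeSeed),
                 permSeed = as.integer(permSeed)),
            class = "runConfig")
}

#' Solve every bite case for one specimen
#'
#' @param specimen a [SpecimenRecord-class].
#' @param config a [runConfig()].
#' @param reference list(S_A, t_A, F_A) of the reference model.
#' @return named list of [solvePlaneStress()] results, one per bite case.
#' @export
solveSpecimen <- function(specimen, config, reference) {
  out <- list()
  for (bc in config$biteCases) {
    load <- buildBiteCase(specimen, bc, reference)
    out[[bc]] <- solvePlaneStress(specimen@mesh, config$material, load)
  }
  out
}

#' Run the full comparative pipeline
#'
#' Orchestrates generate -> solve (4 bite cases x N specimens) ->
#' mesh-weighted summaries -> two-way PERMANOVA battery -> Pagel's lambda
#' grid -> Brownian-motion ancestral reconstruction, and writes a stable
#' output layout: per-specimen stress CSVs, a cohort summary table, the
#' p-value grid, the lambda grid, ASR exports, and a JSON run manifest with
#' the seeds and configuration.  Reruns with an identical configuration are
#' byte-identical.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (created if needed).
#' @param cohort optional pre-built cohort (as from [generateCohort()]);
#'   by default generated from `config$cohortSpec`.
#' @param tree optional cohort phylogeny; by default a seeded pure-birth
#'   tree over the specimen ids.
#' @return invisibly, a list with the summary table, battery, lambda grid,
#'   ASR results and output paths.
#' @export
runPipeline <- function(config, outDir, cohort = NULL, tree = NULL) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stressDir <- file.path(outDir, "stress")
  dir.create(stressDir, showWarnings = FALSE)
  if (is.null(cohort)) {
    if (is.null(config$cohortSpec))
      stop("config has no cohortSpec and no cohort was supplied")
    cohort <- generateCohort(config$cohortSpec)
  }
  specimens <- cohort$specimens
  ids <- vapply(specimens, function(s) s@specimenId, character(1))
  refId <- config$referenceSpecimen %||% ids[[1]]
  if (!refId %in% ids) stop("reference specimen not in cohort: ", refId)
  ref <- specimens[[refId]]
  reference <- list(S_A = ref@surfaceArea, t_A = ref@mesh@thickness,
                    F_A = config$referenceForce)

  summaries <- list()
  for (id in ids) {
    sols <- solveSpecimen(specimens[[id]], config, reference)
    for (bc in names(sols)) {
      exportStressCSV(sols[[bc]]$stress,
                      file.path(stressDir, sprintf("%s_%s.csv", id, bc)))
      summaries[[paste(id, bc)]] <- summarizeStress(
        sols[[bc]]$stress,
        excludeConstraintAdjacent = config$excludeSingular,
        specimenId = id, biteCase = bc,
        interpolate = config$interpolatePercentiles)
    }
  }
  tab <- summaryTable(summaries)
  meta <- cohort$traits[, c("specimen", "diet", "hardness")]
  tab <- merge(tab, meta, by = "specimen", sort = TRUE)
  tab <- tab[order(tab$specimen, tab$bite), ]
  write.csv(tab, file.path(outDir, "stress_summaries.csv"),
            row.names = FALSE)
  boxplotExport(summaries, file.path(outDir, "boxplot_data.csv"))

  battery <- runHypothesisBattery(tab, biteCases = config$biteCases,
                                  nPerm = config$nPerm,
                                  seed = config$permSeed)
  write.csv(battery$grid, file.path(outDir, "permanova_grid.csv"),
            row.names = FALSE)

  if (is.null(tree))
    tree <- simulateTree(length(ids), seed = config$treeSeed,
                         tipLabels = sort(ids))
  ape::write.tree(tree, file.path(outDir, "cohort_tree.nwk"))
  vars <- c("MWAM", "MWM", "M25", "M50", "M75", "M95")
  lambdaGrid <- list(); asrRows <- list()
  for (bc in config$biteCases) {
    sub <- tab[tab$bite == bc, ]
    for (v in vars) {
      traits <- setNames(sub[[v]], sub$specimen)
      fit <- fitLambdaML(tree, traits)
      lambdaGrid[[length(lambdaGrid) + 1L]] <- data.frame(
        bite = bc, variable = v,
        lambda = if (fit@degenerate) NA_real_ else fit@lambda,
        logLik = fit@logLik, degenerate = fit@degenerate)
    }
    mwm <- setNames(sub$MWM, sub$specimen)
    asr <- asrML(tree, mwm)
    interp <- interpolateBranchStates(asr, fractions = seq(0, 1, 0.25))
    interp$bite <- bc
    asrRows[[bc]] <- interp
  }
  lambdaGrid <- do.call(rbind, lambdaGrid)
  write.csv(lambdaGrid, file.path(outDir, "lambda_grid.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, asrRows), file.path(outDir, "asr_branches.csv"),
            row.names = FALSE)

  manifest <- list(
    package = "mandibleFEA",
    version = as.character(utils::packageVersion("mandibleFEA")),
    n_specimens = length(ids), bite_cases = config$biteCases,
    reference_specimen = refId,
    material = list(E = config$material@E, nu = config$material@nu),
    reference_force = config$referenceForce,
    n_permutations = config$nPerm, alpha = config$alpha,
    exclude_singular = config$excludeSingular,
    seeds = list(cohort = if (!is.null(config$cohortSpec))
                   config$cohortSpec$seed else NA,
                 tree = config$treeSeed, permutation = config$permSeed))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summaries = tab, battery = battery,
                 lambdaGrid = lambdaGrid, tree = tree, outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
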