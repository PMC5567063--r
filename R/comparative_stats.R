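# run code with a local, seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Shapiro-Wilk normality gate
#'
#' Standard Shapiro-Wilk test with a boolean verdict at alpha; used to decide
#' whether parametric tests would be admissible before falling back to
#' permutation methods.
#'
#' @param values numeric response sample, n >= 3, not constant.
#' @param alpha significance level (default 0.05).
#' @return list(W, p, normal).
#' @export
shapiroWilkGate <- function(values, alpha = 0.05) {
  if (length(values) < 3L) stop("Shapiro-Wilk requires n >= 3")
  if (var(values) == 0) stop("undefined test: constant input")
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value, normal = ht$p.value >= alpha)
}

# Gower-centered inner-product matrix from a Euclidean response matrix
gowerMatrix <- function(Y) {
  Y <- as.matrix(Y)
  d2 <- as.matrix(stats::dist(Y))^2
  n <- nrow(d2)
  C <- diag(n) - matrix(1 / n, n, n)
  -0.5 * C %*% d2 %*% C
}

hatMatrix <- function(X) {
  qr.X <- qr(X)
  Q <- qr.Q(qr.X)[, seq_len(qr.X$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Two-way PERMANOVA on Euclidean distances
#'
#' Distance-based two-way analysis of variance (Anderson's decomposition)
#' of one or more response columns against the crossed factors diet and
#' hardness, with an unrestricted permutation test of the pseudo-F of each
#' term (main effects and interaction).  With Euclidean distances and a
#' univariate response, the sums of squares coincide with classical ANOVA's.
#' Sums of squares are sequential (diet, then hardness, then interaction);
#' for unbalanced designs, where sequential decompositions differ, a warning
#' is emitted.  The permutation p-value includes the observed statistic in
#' the null set: `p = (#\{F_perm >= F_obs\} + 1) / (nPerm + 1)`.
#'
#' @param table data.frame with the response columns plus factors `diet` and
#'   `hardness`.
#' @param responses character vector naming the response column(s).
#' @param nPerm number of permutations (>= 99; the reference protocol uses
#'   9999).
#' @param seed RNG seed; fixed seed gives bit-identical results.
#' @return A [PermanovaResult-class].
#' @export
twoWayPermanova <- function(table, responses, nPerm = 9999L, seed = 1L) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 99L) stop("nPerm must be at least 99")
  if (!all(responses %in% names(table)))
    stop("response columns missing from table")
  if (!all(c("diet", "hardness") %in% names(table)))
    stop("table needs factor columns 'diet' and 'hardness'")
  diet <- factor(table$diet); hardness <- factor(table$hardness)
  if (nlevels(diet) < 2L || nlevels(hardness) < 2L)
    stop("degenerate design: a factor has a single level")
  if (length(unique(stats::xtabs(~ diet + hardness))) > 1L)
    warning("unbalanced design: sequential sums of squares depend on term order")
  Y <- as.matrix(table[, responses, drop = FALSE])
  if (anyNA(Y)) stop("missing responses are not allowed")
  n <- nrow(Y)
  G <- gowerMatrix(Y)
  X0 <- matrix(1, n, 1)
  X1 <- stats::model.matrix(~ diet)
  X2 <- stats::model.matrix(~ diet + hardness)
  X3 <- stats::model.matrix(~ diet + hardness + diet:hardness)
  H0 <- hatMatrix(X0); H1 <- hatMatrix(X1); H2 <- hatMatrix(X2)
  H3 <- hatMatrix(X3)
  Q <- list(diet = H1 - H0, hardness = H2 - H1,
            `diet:hardness` = H3 - H2, residual = diag(n) - H3)
  df <- c(diet = qr(X1)$rank - 1L, hardness = qr(X2)$rank - qr(X1)$rank,
          `diet:hardness` = qr(X3)$rank - qr(X2)$rank,
          residual = n - qr(X3)$rank)
  ssOf <- function(Gp) vapply(Q, function(q) sum(q * Gp), numeric(1))
  ss <- ssOf(G)
  ssTotal <- sum(diag(G))
  msRes <- ss[["residual"]] / df[["residual"]]
  terms <- c("diet", "hardness", "diet:hardness")
  Fobs <- (ss[terms] / df[terms]) / msRes
  degenerateField <- ssTotal <= 1e-12 * max(1, sum(Y^2))
  exceed <- setNames(numeric(3), terms)
  withSeed(seed, {
    for (b in seq_len(nPerm)) {
      p <- sample.int(n)
      ssp <- ssOf(G[p, p])
      Fp <- (ssp[terms] / df[terms]) / (ssp[["residual"]] / df[["residual"]])
      exceed <- exceed + (Fp >= Fobs - 1e-12 * abs(Fobs))
    }
  })
  pvals <- (exceed + 1) / (nPerm + 1)
  if (degenerateField) {
    Fobs[] <- NA_real_; pvals[] <- 1
  }
  tab <- data.frame(
    term = c(terms, "residual", "total"),
    df = c(df[terms], df[["residual"]], n - 1L),
    SS = c(ss[terms], ss[["residual"]], ssTotal),
    pseudoF = c(Fobs, NA, NA),
    p = c(pvals, NA, NA))
  new("PermanovaResult", table = tab, nPerm = nPerm, seed = as.integer(seed))
}

#' Table-shaped battery of PERMANOVA tests
#'
#' For each bite case, runs the two-way PERMANOVA three ways — on MWAM
#' alone, on MWM alone, and on the four weighted percentiles jointly — and
#' collects a grid of p-values for the diet, hardness and interaction terms
#' (4 bite cases x 3 response sets x 3 terms).
#'
#' @param cohort data.frame of stress summaries with columns `specimen`,
#'   `bite`, `MWAM`, `MWM`, `M25`, `M50`, `M75`, `M95`, `diet`, `hardness`.
#' @param biteCases bite-case codes to analyse.
#' @param nPerm,seed passed to [twoWayPermanova()].
#' @return list with `grid` (the p-value grid) and `results` (named list of
#'   [PermanovaResult-class] for full SS/F detail).
#' @export
runHypothesisBattery <- function(cohort, biteCases = names(BITE_CASES),
                                 nPerm = 9999L, seed = 1L) {
  responseSets <- list(MWAM = "MWAM", MWM = "MWM",
                       percentiles = c("M25", "M50", "M75", "M95"))
  missing <- setdiff(biteCases, unique(cohort$bite))
  if (length(missing))
    stop("no summaries for bite case(s): ", paste(missing, collapse = ", "))
  grid <- list(); results <- list()
  for (bc in biteCases) {
    sub <- cohort[cohort$bite == bc, , drop = FALSE]
    for (rs in names(responseSets)) {
      res <- twoWayPermanova(sub, responseSets[[rs]], nPerm = nPerm,
                             seed = seed)
      results[[paste(bc, rs, sep = ".")]] <- res
      tt <- res@table
      keep <- tt$term %in% c("diet", "hardness", "diet:hardness")
      grid[[length(grid) + 1L]] <- data.frame(
        bite = bc, response_set = rs, term = tt$term[keep], p = tt$p[keep])
    }
  }
  list(grid = do.call(rbind, grid), results = results)
}
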