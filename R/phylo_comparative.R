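#' Read a Newick tree with branch lengths
#'
#' Thin wrapper over [ape::read.tree()] that additionally requires every
#' branch to carry a length (the Brownian-motion machinery needs them) and
#' unique tip labels.  Polytomies are allowed.
#'
#' @param path Newick file path.
#' @return an `ape` "phylo" object.
#' @export
readNewickTree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed Newick file: ", path)
  checkTree(tree)
  tree
}

checkTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  invisible(tree)
}

#' Phylogenetic trait covariance under Pagel's lambda
#'
#' Brownian-motion tip covariance matrix with its off-diagonal entries
#' (shared root-to-tip path lengths) multiplied by lambda; diagonals (tip
#' depths) are preserved exactly, the standard Pagel construction.  lambda
#' = 1 is plain Brownian motion; lambda = 0 the star phylogeny of
#' independent tips.
#'
#' @param tree a rooted "phylo" with branch lengths.
#' @param lambda signal parameter in [0, 1].
#' @return tip x tip covariance matrix (tip labels as dimnames).
#' @export
phyloCovariance <- function(tree, lambda = 1) {
  checkTree(tree)
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  C <- ape::vcv(tree)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}

# profile log-likelihood of the lambda model: mu and sigma2 profiled by GLS
lambdaProfile <- function(C0, x, lambda) {
  n <- length(x)
  V <- lambda * C0
  diag(V) <- diag(C0)
  R <- tryCatch(chol(V), error = function(e)
    stop("numerical error: C(lambda) not positive definite at lambda = ",
         signif(lambda, 4)))
  logdet <- 2 * sum(log(diag(R)))
  one <- rep(1, n)
  Vi1 <- backsolve(R, forwardsolve(t(R), one))
  Vix <- backsolve(R, forwardsolve(t(R), x))
  mu <- sum(Vi1 * x) / sum(Vi1)
  r <- x - mu
  s2 <- sum(r * (Vix - mu * Vi1)) / n
  s2 <- max(s2, .Machine$double.xmin)
  ll <- -0.5 * (n * log(2 * pi) + n * log(s2) + logdet + n)
  list(logLik = ll, mu = mu, sigma2 = s2)
}

#' Maximum-likelihood fit of Pagel's lambda
#'
#' Profiles the root state (GLS mean) and the Brownian rate analytically for
#' each lambda and maximizes the resulting multivariate-normal profile
#' likelihood over lambda in [0, 1] by bounded scalar optimization
#' (tolerance 1e-8), with the endpoints checked explicitly.  When the
#' likelihood is flat in lambda — constant traits, or a star phylogeny where
#' lambda is unidentifiable — a degenerate result is returned instead of an
#' arbitrary point estimate.
#'
#' @param tree rooted "phylo" with branch lengths.
#' @param traits named numeric vector covering all tips (>= 4 tips).
#' @return A [PhyloSignalResult-class].
#' @export
fitLambdaML <- function(tree, traits) {
  checkTree(tree)
  traits <- alignTraits(tree, traits)
  if (length(traits) < 4L) stop("at least 4 tips are required")
  if (var(traits) == 0)
    return(new("PhyloSignalResult", lambda = NA_real_, logLik = NA_real_,
               sigma2 = 0, mu = traits[[1]], degenerate = TRUE,
               note = "constant traits: likelihood flat in lambda"))
  C0 <- ape::vcv(tree)
  f <- function(l) lambdaProfile(C0, traits, l)$logLik
  ll0 <- f(0); ll1 <- f(1); llHalf <- f(0.5)
  if (max(ll0, ll1, llHalf) - min(ll0, ll1, llHalf) <
      1e-8 * max(1, abs(ll1)))
    return(new("PhyloSignalResult", lambda = NA_real_, logLik = ll1,
               sigma2 = lambdaProfile(C0, traits, 1)$sigma2,
               mu = lambdaProfile(C0, traits, 1)$mu, degenerate = TRUE,
               note = "flat likelihood: lambda unidentifiable (star-like tree)"))
  opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll0), c(1, ll1))
  best <- cand[which.max(cand[, 2]), ]
  prof <- lambdaProfile(C0, traits, best[1])
  new("PhyloSignalResult", lambda = best[1], logLik = best[2],
      sigma2 = prof$sigma2, mu = prof$mu, degenerate = FALSE, note = "")
}

alignTraits <- function(tree, traits) {
  if (is.null(names(traits)))
    stop("traits must be named by tip label")
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing))
    stop("traits missing for tips: ", paste(missing, collapse = ", "))
  as.numeric(traits[tree$tip.label])
}

#' Pagel's lambda over a sample of trees
#'
#' Fits lambda on every tree of a sample (e.g. a posterior sample of
#' phylogenies) for the same trait vector and summarizes the per-tree
#' estimates.
#'
#' @param trees list of "phylo" objects (or an ape "multiPhylo") sharing a
#'   tip set.
#' @param traits named numeric vector covering the shared tips.
#' @return list with `estimates` (per-tree lambda), `fits` (list of
#'   [PhyloSignalResult-class]) and `summary` (mean, median, quartiles of
#'   the non-degenerate estimates).
#' @export
fitLambdaOverTrees <- function(trees, traits) {
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  tipSet <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tipSet))
      stop("tree ", i, " has a different tip set")
  }
  fits <- lapply(trees, fitLambdaML, traits = traits)
  est <- vapply(fits, function(f) f@lambda, numeric(1))
  ok <- est[!is.na(est)]
  list(estimates = est, fits = fits,
       summary = c(mean = mean(ok), median = median(ok),
                   quantile(ok, c(0.025, 0.25, 0.75, 0.975))))
}

# covariance of every node (tips + internals) with every tip: the depth of
# their most recent common ancestor
nodeTipCovariance <- function(tree) {
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  depths <- ape::node.depth.edgelength(tree)   # root-to-node distances
  mr <- ape::mrca(tree, full = TRUE)           # (nTip+nNode)^2 mrca ids
  M <- matrix(depths[mr], nrow(mr), ncol(mr))
  list(full = M, nTip = nTip, nNode = nNode, depths = depths)
}

#' Brownian-motion ancestral state reconstruction
#'
#' Maximum-likelihood (equivalently GLS conditional-expectation) estimates
#' of ancestral states at every internal node under Brownian motion:
#' `a = mu + Cov(node, tips) V^-1 (x - mu)` with `mu` the GLS phylogenetic
#' mean, which is also the root estimate.  Tip "estimates" reproduce the
#' observed traits exactly.
#'
#' @param tree rooted "phylo" with branch lengths.
#' @param traits named numeric vector covering all tips.
#' @return list of class `ancestralReconstruction`: `nodeStates` (named by
#'   node number, internals first element is the root), `tipStates`, `mu`,
#'   `tree`.
#' @export
asrML <- function(tree, traits) {
  checkTree(tree)
  x <- alignTraits(tree, traits)
  nTip <- length(tree$tip.label)
  V <- ape::vcv(tree)
  R <- chol(V)
  one <- rep(1, nTip)
  Vi1 <- backsolve(R, forwardsolve(t(R), one))
  mu <- sum(Vi1 * x) / sum(Vi1)
  Vir <- backsolve(R, forwardsolve(t(R), x - mu))
  cov <- nodeTipCovariance(tree)
  internalRows <- nTip + seq_len(cov$nNode)
  Cnt <- cov$full[internalRows, seq_len(nTip), drop = FALSE]
  nodeStates <- as.numeric(mu + Cnt %*% Vir)
  names(nodeStates) <- as.character(internalRows)
  tipStates <- setNames(x, tree$tip.label)
  structure(list(nodeStates = nodeStates, tipStates = tipStates, mu = mu,
                 tree = tree),
            class = "ancestralReconstruction")
}

#' @export
print.ancestralReconstruction <- function(x, ...) {
  cat(sprintf("Brownian-motion ASR: %d internal nodes, root state %.4g\n",
              length(x$nodeStates), x$nodeStates[[1]]))
  invisible(x)
}

# state at either end of an edge, tips included
edgeEndStates <- function(asr) {
  tree <- asr$tree
  nTip <- length(tree$tip.label)
  stateOf <- function(node) {
    if (node <= nTip) asr$tipStates[[tree$tip.label[node]]]
    else asr$nodeStates[[as.character(node)]]
  }
  cbind(parent = vapply(tree$edge[, 1], stateOf, numeric(1)),
        child = vapply(tree$edge[, 2], stateOf, numeric(1)))
}

#' Interpolate reconstructed states along branches
#'
#' Linear interpolation of the ancestral estimates between the two ends of
#' every branch, at the requested fractional positions — the data backing
#' continuous-trait "painted" tree figures.
#'
#' @param asr result of [asrML()].
#' @param fractions positions along each branch in [0, 1] (0 = parent end).
#' @return data.frame: edge index, parent, child, fraction, state.
#' @export
interpolateBranchStates <- function(asr, fractions = seq(0, 1, 0.25)) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  ends <- edgeEndStates(asr)
  tree <- asr$tree
  out <- expand.grid(edge = seq_len(nrow(tree$edge)), fraction = fractions)
  out <- out[order(out$edge, out$fraction), ]
  out$parent <- tree$edge[out$edge, 1]
  out$child <- tree$edge[out$edge, 2]
  out$state <- ends[out$edge, "parent"] +
    out$fraction * (ends[out$edge, "child"] - ends[out$edge, "parent"])
  rownames(out) <- NULL
  out[, c("edge", "parent", "child", "fraction", "state")]
}

#' Simulate tip traits under lambda-transformed Brownian motion
#'
#' Draws one multivariate-normal trait vector with mean `rootState` and
#' covariance `sigma2 * C(lambda)`; deterministic for a fixed seed.
#'
#' @param tree rooted "phylo" with branch lengths.
#' @param sigma2 Brownian rate (> 0).
#' @param rootState ancestral state at the root.
#' @param lambda signal parameter in [0, 1].
#' @param seed RNG seed.
#' @return named numeric vector of tip traits.
#' @export
simulateBM <- function(tree, sigma2 = 1, rootState = 0, lambda = 1,
                       seed = 1L) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
  C <- phyloCovariance(tree, lambda)
  R <- chol(sigma2 * C)
  z <- withSeed(seed, rnorm(nrow(C)))
  setNames(rootState + as.numeric(crossprod(R, z)), rownames(C))
}
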