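test_that("Newick reading validates lengths and round-trips", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", path)
  tr <- readNewickTree(path)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(unname(ape::node.depth.edgelength(tr)[1:2]), c(1, 1))

  tr2 <- simulateTree(16, seed = 2)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr2, path2)
  back <- readNewickTree(path2)
  expect_equal(suppressWarnings(ape::dist.topo(back, tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr2$edge.length),
               tolerance = 1e-9)

  path3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B);", path3)
  expect_error(readNewickTree(path3), "branch length")
})

test_that("lambda transform preserves diagonals and endpoint structure", {
  tr <- simulateTree(12, seed = 5)
  C1 <- phyloCovariance(tr, 1)
  expect_equal(C1, ape::vcv(tr))
  C0 <- phyloCovariance(tr, 0)
  expect_equal(C0, diag(diag(C1)), ignore_attr = TRUE)
  Ch <- phyloCovariance(tr, 0.6)
  expect_equal(diag(Ch), diag(C1))
  off <- row(C1) != col(C1)
  expect_equal(Ch[off], 0.6 * C1[off])
  expect_error(phyloCovariance(tr, 1.2), "lambda")

  # 2-tip cherry: no shared path, C is diagonal for every lambda
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(phyloCovariance(cherry, 0.5),
               diag(2), ignore_attr = TRUE)
})

test_that("lambda ML fit beats a grid search and ignores branch-length scale", {
  tr <- simulateTree(24, seed = 9)
  x <- simulateBM(tr, sigma2 = 2, rootState = 1, lambda = 0.6, seed = 4)
  fit <- fitLambdaML(tr, x)
  C0 <- ape::vcv(tr)
  gridLL <- vapply(seq(0, 1, length.out = 21), function(l)
    mandibleFEA:::lambdaProfile(C0, unname(x[tr$tip.label]), l)$logLik,
    numeric(1))
  expect_gte(fit@logLik, max(gridLL) - 1e-6)
  expect_gte(fit@lambda, 0); expect_lte(fit@lambda, 1)

  tr2 <- tr; tr2$edge.length <- tr$edge.length * 37.5
  fit2 <- fitLambdaML(tr2, x)
  expect_equal(fit2@lambda, fit@lambda, tolerance = 1e-4)
})

test_that("lambda agrees with an independent ML implementation", {
  skip_if_not_installed("phytools")
  tr <- simulateTree(48, seed = 13)
  x <- simulateBM(tr, sigma2 = 1, rootState = 0, lambda = 0.5, seed = 6)
  fit <- fitLambdaML(tr, x)
  ps <- phytools::phylosig(tr, x, method = "lambda")
  # phytools searches lambda slightly beyond 1; compare where both interior
  if (ps$lambda <= 1) {
    expect_equal(fit@lambda, ps$lambda, tolerance = 1e-3)
    expect_equal(fit@logLik, ps$logL, tolerance = 1e-5)
  }
})

test_that("degenerate lambda cases return the flat-likelihood diagnostic", {
  tr <- simulateTree(8, seed = 3)
  con <- setNames(rep(2.5, 8), tr$tip.label)
  fit <- fitLambdaML(tr, con)
  expect_true(fit@degenerate)
  expect_true(is.na(fit@lambda))

  # star phylogeny: lambda unidentifiable
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  x <- setNames(rnorm(5), star$tip.label)
  fitStar <- fitLambdaML(star, x)
  expect_true(fitStar@degenerate)
})

test_that("per-tree lambda fits aggregate transparently", {
  tr <- simulateTree(16, seed = 7)
  x <- simulateBM(tr, sigma2 = 1, rootState = 0, lambda = 1, seed = 2)
  single <- fitLambdaML(tr, x)
  multi <- fitLambdaOverTrees(list(tr, tr, tr), x)
  expect_equal(unname(multi$estimates), rep(single@lambda, 3))
  expect_equal(unname(multi$summary["mean"]), single@lambda)
  tr2 <- simulateTree(16, seed = 8)
  tr2$tip.label[1] <- "other"
  expect_error(fitLambdaOverTrees(list(tr, tr2), x), "tree 2")
})

test_that("ASR matches GLS closed forms", {
  # 2-tip tree: root is the precision-weighted mean of the tips
  for (v in list(c(1, 1), c(0.5, 2))) {
    txt <- sprintf("(A:%g,B:%g);", v[1], v[2])
    tr <- ape::read.tree(text = txt)
    x <- c(A = 3, B = 7)
    asr <- asrML(tr, x)
    expect_equal(unname(asr$nodeStates[1]),
                 (3 / v[1] + 7 / v[2]) / (1 / v[1] + 1 / v[2]),
                 tolerance = 1e-8)
  }
  # root estimate equals the GLS phylogenetic mean from the lambda fit at 1
  tr <- simulateTree(20, seed = 11)
  x <- simulateBM(tr, sigma2 = 1, rootState = 4, lambda = 1, seed = 9)
  asr <- asrML(tr, x)
  prof <- mandibleFEA:::lambdaProfile(ape::vcv(tr), unname(x[tr$tip.label]), 1)
  expect_equal(unname(asr$nodeStates[1]), prof$mu, tolerance = 1e-8)
  # constant traits reconstruct constant ancestors
  con <- setNames(rep(1.5, 20), tr$tip.label)
  expect_equal(unname(asrML(tr, con)$nodeStates), rep(1.5, 19),
               tolerance = 1e-10)
})

test_that("ASR agrees with ape::ace and is affine-equivariant", {
  tr <- simulateTree(24, seed = 17)
  x <- simulateBM(tr, sigma2 = 2, rootState = -1, lambda = 1, seed = 5)
  asr <- asrML(tr, x)
  ac <- ape::ace(x[tr$tip.label], tr, method = "ML")
  expect_equal(unname(asr$nodeStates), unname(ac$ace), tolerance = 1e-4)
  shifted <- asrML(tr, x + 10)
  expect_equal(shifted$nodeStates, asr$nodeStates + 10, tolerance = 1e-8)
  scaled <- asrML(tr, 3 * x)
  expect_equal(scaled$nodeStates, 3 * asr$nodeStates, tolerance = 1e-8)
})

test_that("branch interpolation stays between endpoint estimates", {
  tr <- simulateTree(12, seed = 19)
  x <- simulateBM(tr, sigma2 = 1, rootState = 0, lambda = 1, seed = 3)
  asr <- asrML(tr, x)
  interp <- interpolateBranchStates(asr, fractions = seq(0, 1, 0.1))
  ends <- mandibleFEA:::edgeEndStates(asr)
  for (e in seq_len(nrow(tr$edge))) {
    v <- interp$state[interp$edge == e]
    expect_gte(min(v), min(ends[e, ]) - 1e-12)
    expect_lte(max(v), max(ends[e, ]) + 1e-12)
  }
  # fraction 0 is the parent estimate, 1 the child estimate
  expect_equal(interp$state[interp$fraction == 0], unname(ends[, "parent"]))
  expect_equal(interp$state[interp$fraction == 1], unname(ends[, "child"]))
  expect_error(interpolateBranchStates(asr, c(-0.1, 0.5)), "0, 1")
})

test_that("BM simulation is seed-stable with the advertised covariance", {
  tr <- simulateTree(5, seed = 23)
  x1 <- simulateBM(tr, sigma2 = 1.5, rootState = 2, lambda = 0.7, seed = 42)
  x2 <- simulateBM(tr, sigma2 = 1.5, rootState = 2, lambda = 0.7, seed = 42)
  expect_identical(x1, x2)
  # near-zero rate pins every tip at the root state
  x0 <- simulateBM(tr, sigma2 = 1e-12, rootState = 2, seed = 1)
  expect_equal(unname(x0), rep(2, 5), tolerance = 1e-4)
  # Monte-Carlo covariance check
  C <- 1.5 * phyloCovariance(tr, 0.7)
  X <- vapply(1:2000, function(i)
    simulateBM(tr, sigma2 = 1.5, rootState = 2, lambda = 0.7, seed = i),
    numeric(5))
  Chat <- cov(t(X))
  expect_lt(max(abs(Chat - C)) / max(abs(C)), 0.1)
})
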