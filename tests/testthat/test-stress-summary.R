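test_that("mesh-weighted mean matches hand-computed weighted sums", {
  expect_equal(meshWeightedMean(c(1, 2, 3), c(2, 2, 2)), 2.0)
  expect_equal(meshWeightedMean(c(1, 2, 3), c(1, 1, 2)), 2.25)
  expect_equal(meshWeightedMean(5.5, 0.3), 5.5)
  expect_error(meshWeightedMean(numeric(0), numeric(0)), "empty")
  expect_error(meshWeightedMean(c(1, 2), c(1, -1)), "positive")
})

test_that("weighted percentile follows the cumulative-area rule", {
  expect_equal(weightedPercentile(c(1, 2, 3, 4), rep(1, 4), 0.5), 2)
  expect_equal(weightedPercentile(c(1, 5, 100), c(3, 1, 1), 0.5), 1)
  expect_equal(weightedPercentile(c(4, 2, 9), c(1, 1, 1), 1e-9), 2)
  expect_error(weightedPercentile(c(1, 2), c(1, 1), 0), "\\(0, 1\\)")
  expect_error(weightedPercentile(c(1, 2), c(1, 1), 1), "\\(0, 1\\)")
})

test_that("percentage errors compare unweighted and weighted statistics", {
  expect_equal(unname(percentageErrors(c(1, 7, 3, 2), rep(2, 4))), c(0, 0))
  pe <- percentageErrors(c(2, 4), c(1, 3))
  expect_equal(pe[["PEofAM"]], abs(3 - 3.5) / 3.5 * 100, tolerance = 1e-12)
  expect_equal(unname(percentageErrors(rep(4.2, 5), runif(5, 1, 2))), c(0, 0))
})

test_that("summaries equal brute-force recomputation on random fields", {
  set.seed(11)
  for (i in 1:25) {
    ne <- sample(5:60, 1)
    s <- rexp(ne); a <- runif(ne, 0.5, 2)
    adj <- runif(ne) < 0.2
    field <- new("StressField", elementIds = seq_len(ne),
                 sigma = matrix(0, ne, 3), vonMises = s, areas = a,
                 adjacentToConstraint = adj)
    if (all(adj)) next
    sm <- summarizeStress(field, excludeConstraintAdjacent = TRUE)
    keep <- !adj
    expect_equal(sm@AM, mean(s[keep]))
    expect_equal(sm@M, bruteWeightedPercentile(s[keep], rep(1, sum(keep)), 0.5))
    expect_equal(sm@MWAM, sum(s[keep] * a[keep]) / sum(a[keep]))
    for (p in c(0.25, 0.5, 0.75, 0.95)) {
      got <- slot(sm, c("0.25" = "M25", "0.5" = "M50", "0.75" = "M75",
                        "0.95" = "M95")[[as.character(p)]])
      expect_equal(got, bruteWeightedPercentile(s[keep], a[keep], p))
    }
    expect_equal(sm@MWM, sm@M50)
    expect_equal(sm@nExcluded, sum(adj))
    # exclusion off summarizes everything
    smAll <- summarizeStress(field, excludeConstraintAdjacent = FALSE)
    expect_equal(smAll@MWAM, sum(s * a) / sum(a))
    expect_equal(smAll@nExcluded, 0L)
  }
})

test_that("a huge singular stress vanishes from the summary when excluded", {
  s <- c(1, 2, 3, 1e6); a <- rep(1, 4)
  field <- new("StressField", elementIds = 1:4, sigma = matrix(0, 4, 3),
               vonMises = s, areas = a,
               adjacentToConstraint = c(FALSE, FALSE, FALSE, TRUE))
  sm <- summarizeStress(field)
  expect_equal(sm@MWAM, 2)
  expect_equal(sm@nExcluded, 1L)
  allAdj <- new("StressField", elementIds = 1:2, sigma = matrix(0, 2, 3),
                vonMises = c(1, 2), areas = c(1, 1),
                adjacentToConstraint = c(TRUE, TRUE))
  expect_error(summarizeStress(allAdj), "degenerate model")
})

test_that("summary statistics respect ordering, refinement and scaling laws", {
  set.seed(4)
  for (i in 1:10) {
    ne <- sample(4:40, 1)
    s <- rlnorm(ne); a <- runif(ne, 0.2, 3)
    q <- vapply(c(0.25, 0.5, 0.75, 0.95),
                function(p) weightedPercentile(s, a, p), numeric(1))
    expect_true(all(diff(q) >= 0))
    expect_gte(q[1], min(s)); expect_lte(q[4], max(s))
    expect_gte(weightedPercentile(s, a, 0.5), min(s))

    # uniform refinement: split every element into 3 equal-area children
    s3 <- rep(s, each = 3); a3 <- rep(a / 3, each = 3)
    expect_equal(meshWeightedMean(s3, a3), meshWeightedMean(s, a))
    for (p in c(0.25, 0.5, 0.95))
      expect_equal(weightedPercentile(s3, a3, p), weightedPercentile(s, a, p))

    # scaling stresses by c scales statistics and leaves the errors alone
    cc <- 7.3
    expect_equal(meshWeightedMean(cc * s, a), cc * meshWeightedMean(s, a))
    expect_equal(weightedPercentile(cc * s, a, 0.75),
                 cc * weightedPercentile(s, a, 0.75))
    expect_equal(percentageErrors(cc * s, a), percentageErrors(s, a),
                 tolerance = 1e-10)
  }
  # equal areas: weighted mean equals the arithmetic mean exactly
  s <- rexp(9)
  expect_equal(meshWeightedMean(s, rep(2.5, 9)), mean(s))
})

test_that("boxplot export writes one fixed-schema row per summary", {
  field <- new("StressField", elementIds = 1:3, sigma = matrix(0, 3, 3),
               vonMises = c(1, 2, 3), areas = rep(1, 3),
               adjacentToConstraint = rep(FALSE, 3))
  sums <- lapply(c("A", "B", "C"), function(id)
    summarizeStress(field, specimenId = id, biteCase = "IB"))
  path <- withr::local_tempfile(fileext = ".csv")
  boxplotExport(sums, path)
  got <- read.csv(path)
  expect_equal(nrow(got), 3L)
  expect_equal(names(got),
               c("specimen", "bite", "M25", "M50", "M75", "M95",
                 "MWAM", "MWM"))
  # empty input: header-only file
  path2 <- withr::local_tempfile(fileext = ".csv")
  boxplotExport(list(), path2)
  expect_equal(nrow(read.csv(path2)), 0L)
})
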