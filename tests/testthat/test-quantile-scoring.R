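test_that("bonds on a fitted quantile line score at that level", {
  ## noiseless exponential decay: every quantile line coincides, and any
  ## point on the line scores 0.5 by the tie rule
  d <- seq(5, 40, length.out = 60)
  pi <- exp(-0.3 * d)
  m <- fitIntrinsicModel(pi, d, grid = c(0.25, 0.5, 0.75))
  expect_equal(m@covariates, "d")
  expect_equal(scoreBonds(m, exp(-0.3 * 20), 20), 0.5, tolerance = 1e-9)
  ## off-line points clamp to 0 or 1
  expect_equal(scoreBonds(m, exp(-0.3 * 20 + 1), 20), 1)
  expect_equal(scoreBonds(m, exp(-0.3 * 20 - 1), 20), 0)
})

test_that("zero propensities are excluded from the fit and score 0", {
  withr::with_seed(5L, {
    d <- runif(100, 5, 40)
    pi <- exp(-0.3 * d + rnorm(100))
    pi[1:5] <- 0
  })
  expect_warning(m <- fitIntrinsicModel(pi, d, grid = c(0.2, 0.5, 0.8)),
                 "zero propensity")
  p <- scoreBonds(m, pi, d)
  expect_equal(p[1:5], rep(0, 5))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("degenerate and undersized fits are rejected", {
  d <- 1:30
  expect_error(fitIntrinsicModel(rep(0.5, 30), d, grid = 0.5), "all propensities")
  expect_error(suppressWarnings(
    fitIntrinsicModel(c(rep(0, 25), exp(1:5)), d, grid = 0.5)), "at least 20")
})

test_that("monotone rearrangement removes quantile crossing", {
  ## force crossing lines, then check scores are monotone in propensity
  m <- new("QuantileModel", grid = c(0.3, 0.7),
           coefficients = rbind(c(0, 0.5), c(4, -0.5)),
           covariates = "d", n = 10L)
  ## at d = 8 the 0.3-line (4.0) is above the 0.7-line (0.0): rearranged
  q <- bondprop:::rearranged_quantiles(m, 8)
  expect_equal(q, c(0, 4))
  p <- scoreBonds(m, exp(c(1, 3)), c(8, 8))
  expect_true(p[1] < p[2])
})

test_that("in-sample scores are approximately uniform (PIT)", {
  b <- simulateBondSample(n = 1000L, seed = 40L)
  m <- fitIntrinsicModel(b$pi, b$d)
  p <- scoreBonds(m, b$pi, b$d)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("reference model recovers plane structure and E-duplication invariance", {
  tr <- simulateReferenceTriplets(nProteins = 10L, bondsPerProtein = 50L,
                                  noiseSd = 0, seed = 8L)
  m <- fitReferenceModel(tr, grid = 0.5)
  expect_equal(unname(m@coefficients[1, 2]), -0.3, tolerance = 1e-6)
  expect_equal(unname(m@coefficients[1, 3]), -1, tolerance = 1e-6)
  ## duplicating every protein leaves the fit unchanged
  m2 <- fitReferenceModel(rbind(tr, tr), grid = 0.5)
  expect_equal(m2@coefficients, m@coefficients, tolerance = 1e-8)
  ## a bond on the median plane scores 0.5
  q <- as.numeric(m@coefficients %*% c(1, 20, log(1000)))
  grid3 <- fitReferenceModel(tr, grid = c(0.25, 0.5, 0.75))
  expect_equal(scoreReference(grid3, exp(q), 20, 1000), 0.5, tolerance = 1e-6)
})

test_that("reference scoring of the reference sample is approximately uniform", {
  tr <- simulateReferenceTriplets(nProteins = 12L, bondsPerProtein = 120L,
                                  seed = 9L)
  m <- fitReferenceModel(tr)
  p <- scoreReference(m, tr$pi, tr$d, tr$E)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("reference fitting enforces its preconditions", {
  tr <- simulateReferenceTriplets(nProteins = 4L, bondsPerProtein = 50L,
                                  seed = 2L)
  tr$E <- 1000L
  expect_error(fitReferenceModel(tr), "distinct")
  tr2 <- simulateReferenceTriplets(nProteins = 2L, bondsPerProtein = 10L,
                                   seed = 2L)
  expect_error(fitReferenceModel(tr2, minTriplets = 100L), "at least 100")
})

test_that("reference models round-trip through versioned JSON", {
  tr <- simulateReferenceTriplets(nProteins = 8L, bondsPerProtein = 60L,
                                  seed = 4L)
  m <- fitReferenceModel(tr, grid = c(0.1, 0.5, 0.9))
  path <- withr::local_tempfile(fileext = ".json")
  writeReferenceModel(m, path)
  m2 <- readReferenceModel(path)
  expect_equal(m2@coefficients, m@coefficients)
  expect_equal(m2@grid, m@grid)
  expect_equal(m2@covariates, m@covariates)
  expect_equal(m2@n, m@n)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad)
  expect_error(readReferenceModel(bad), "not a bondprop")
})

test_that("scoreTable scores bonds and residues with the same machinery", {
  txt <- makeToyProteinPDB(seed = 21L)
  g <- buildAtomisticGraph(readStructure(txt))
  res <- bondPropensity(g, siteSpec(ligand = attr(txt, "activeLigand")))
  st <- scoreTable(res, reference = reference_model_cached())
  bt <- bondScores(st)
  rt <- residueScores(st)
  expect_true(all(bt$pB >= 0 & bt$pB <= 1))
  expect_true(all(bt$pRef >= 0 & bt$pRef <= 1))
  expect_true(all(rt$pR >= 0 & rt$pR <= 1))
  ## only weak scored bonds are tabulated
  b <- bonds(res)
  expect_equal(nrow(bt), sum(b$scored & b$weak))
  ## residue scores rank with residue propensities at fixed distance
  expect_equal(quantileGrid(st@bondModel), defaultQuantileGrid())
})
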