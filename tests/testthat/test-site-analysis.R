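## A small fitted score table shared by the site-measure tests.
toy_scores <- function(seed = 31L) {
  txt <- makeToyProteinPDB(seed = seed)
  s <- readStructure(txt)
  g <- buildAtomisticGraph(s)
  res <- bondPropensity(g, siteSpec(ligand = attr(txt, "activeLigand")))
  list(txt = txt, s = s,
       st = scoreTable(res, reference = reference_model_cached()))
}

test_that("site measures are the stated means and proportions", {
  st <- new("ScoreTable",
            bonds = data.frame(id = 1:4, kind = "hbond",
                               res1 = c("A:1", "A:1", "A:2", "B:9"),
                               res2 = c("A:2", "B:9", "M:1", "B:8"),
                               propensity = 0.1, dist = 1,
                               pB = c(0.9, 1.0, 0.99, 0.2)),
            residues = data.frame(resid = c("A:1", "A:2", "B:9"),
                                  propensity = 0.1, minDist = 1,
                                  pR = c(0.5, 0.7, 0.1)),
            bondModel = new("QuantileModel", grid = 0.5,
                            coefficients = cbind(0, 0), covariates = "d",
                            n = 4L),
            residueModel = new("QuantileModel", grid = 0.5,
                               coefficients = cbind(0, 0), covariates = "d",
                               n = 3L))
  m <- siteMeasures(st, c("A:1", "A:2"), excludeResidues = "M:1")
  expect_equal(m@meanBond, mean(c(0.9, 1.0)))     # bond to M:1 excluded
  expect_equal(m@propHigh, 0.5)
  expect_equal(m@meanResidue, mean(c(0.5, 0.7)))
  expect_equal(m@nBonds, 2L)
  expect_true(is.na(m@meanRef))
  ## all-0.5 scores give means 0.5 and no high bonds
  st@bonds$pB <- 0.5
  m2 <- siteMeasures(st, c("A:1", "A:2"))
  expect_equal(m2@meanBond, 0.5)
  expect_equal(m2@propHigh, 0)
  ## a site with no weak bonds warns and returns NA measures
  expect_warning(m3 <- siteMeasures(st, "Z:1"), "no weak bonds")
  expect_true(is.na(m3@meanBond))
})

test_that("surrogate sites obey both structural constraints, reproducibly", {
  ts <- toy_scores()
  target <- attr(ts$txt, "plantedSite")
  sur <- generateSurrogateSites(ts$s, target, n = 200L, seed = 12L,
                                excludeResidues = c("L:1", "M:1"))
  expect_length(sur@sites, 200L)
  a <- atoms(ts$s)
  diam <- function(res) {
    P <- as.matrix(a[a$resid %in% res, c("x", "y", "z")])
    sqrt(max(bondprop:::sq_dist(P, P)))
  }
  expect_true(all(lengths(sur@sites) == length(target)))
  expect_true(all(vapply(sur@sites, diam, 0) <= sur@targetDiameter + 1e-9))
  expect_false(any(unlist(sur@sites) %in% c("L:1", "M:1")))
  ## seed reproducibility
  sur2 <- generateSurrogateSites(ts$s, target, n = 200L, seed = 12L,
                                 excludeResidues = c("L:1", "M:1"))
  expect_identical(sur@sites, sur2@sites)
  ## single-residue target: surrogates are single residues
  s1 <- generateSurrogateSites(ts$s, "A:5", n = 20L, seed = 3L)
  expect_true(all(lengths(s1@sites) == 1L))
})

test_that("bootstrap CI is percentile-based, seeded, and shrinks as n^-1/2", {
  expect_error(bootstrapMeanCI(numeric()), "no values")
  c1 <- bootstrapMeanCI(rep(3, 10), nBoot = 100L, seed = 1L)
  expect_equal(c(c1$mean, c1$lower, c1$upper), c(3, 3, 3))
  v50 <- rep(c(0, 1), 25); v500 <- rep(c(0, 1), 250)
  a <- bootstrapMeanCI(v50, nBoot = 2000L, seed = 2L)
  b <- bootstrapMeanCI(v500, nBoot = 2000L, seed = 2L)
  expect_true(a$lower < 0.5 && a$upper > 0.5)
  ratio <- (a$upper - a$lower) / (b$upper - b$lower)
  expect_gt(ratio, 2); expect_lt(ratio, 4.5)   # ~ sqrt(10)
  a2 <- bootstrapMeanCI(v50, nBoot = 2000L, seed = 2L)
  expect_identical(a, a2)
})

test_that("detectAllosteric applies the four thresholds definitionally", {
  sur <- new("SurrogateEnsemble",
             sites = rep(list("A:1"), 50L),
             scores = data.frame(meanBond = runif(50, 0.2, 0.4),
                                 meanResidue = runif(50, 0.2, 0.4),
                                 propHigh = 0, meanRef = 0.3,
                                 nBonds = 3L, nResidues = 1L),
             targetResidues = "A:9", targetDiameter = 5)
  hi <- new("SiteScore", meanBond = 0.9, meanResidue = 0.95, propHigh = 0.04,
            meanRef = 0.7, nBonds = 10L, nResidues = 4L)
  det <- detectAllosteric(hi, sur, nBoot = 500L, seed = 5L)
  expect_equal(det$measure,
               c("meanBond", "meanResidue", "propHigh", "meanRef"))
  expect_equal(det$detected, c(TRUE, TRUE, FALSE, TRUE))  # 0.04 < 0.05
  expect_equal(det$value - det$threshold, det$margin)
  lo <- new("SiteScore", meanBond = 0.1, meanResidue = 0.1, propHigh = 0.06,
            meanRef = 0.4, nBonds = 10L, nResidues = 4L)
  det2 <- detectAllosteric(lo, sur, nBoot = 500L, seed = 5L)
  expect_equal(det2$detected, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(detectAllosteric(hi, new("SurrogateEnsemble",
                                        sites = list(), scores = data.frame(),
                                        targetResidues = character(),
                                        targetDiameter = 1)),
               "surrogateScores")
})

test_that("ensemble statistics aggregate residue propensities across models", {
  mk <- function(vals) {
    new("PropensityResult",
        bonds = data.frame(scored = logical(), norm = numeric()),
        residues = data.frame(resid = names(vals), propensity = unname(vals),
                              minDist = 1, stringsAsFactors = FALSE),
        sourceBonds = 1L, weakBondCount = 10L, normalizedOver = "all")
  }
  r1 <- mk(c("A:1" = 0.1, "A:2" = 0.5))
  r2 <- mk(c("A:1" = 0.3, "A:2" = 0.5))
  es <- ensembleStats(list(r1, r2))
  expect_equal(es@table$mean, c(0.2, 0.5))
  expect_equal(es@table$sd, c(0.1, 0))        # population SD
  expect_equal(es@nModels, 2L)
  ## identical models have zero SD
  es2 <- ensembleStats(list(r1, r1, r1))
  expect_equal(es2@table$sd, c(0, 0))
  ## differing residue sets intersect with a warning
  r3 <- mk(c("A:1" = 0.2, "A:3" = 0.9))
  expect_warning(es3 <- ensembleStats(list(r1, r3)), "shared residues")
  expect_equal(es3@table$resid, "A:1")
  expect_error(ensembleStats(list(r1)), "at least two")
  top <- topVariableResidues(es, fraction = 0.5)
  expect_equal(top$resid[1], "A:1")
})

test_that("multi-model structures yield a propensity per conformer", {
  txt <- makeToyProteinPDB(nModels = 3L, seed = 17L)
  s <- readStructure(txt)
  rs <- propensityEnsemble(s, siteSpec(ligand = attr(txt, "activeLigand")))
  expect_length(rs, 3L)
  ## jitter can add/remove weak bonds, so residue sets may differ slightly
  es <- suppressWarnings(ensembleStats(rs))
  expect_true(all(es@table$sd >= 0))
  expect_gt(max(es@table$sd), 0)
})

test_that("Cook's distance flags the influential conformer residue", {
  x <- seq(0.01, 0.2, length.out = 20)
  names(x) <- paste0("A:", 1:20)
  y <- x
  y["A:20"] <- 0.9   # gross outlier
  ci <- conformerInfluence(y, x)
  expect_equal(ci$table$resid[1], "A:20")
  expect_gt(ci$table$cooks[1], 10 * ci$table$cooks[2])
  ## perfectly linear data: all distances 0
  ci0 <- conformerInfluence(2 * x + 0.01, x)
  expect_equal(max(ci0$table$cooks), 0, tolerance = 1e-20)
  expect_equal(ci0$r, 1)
  expect_error(conformerInfluence(y, setNames(rep(1, 20), names(x))),
               "constant")
})

test_that("rank-sum comparison behaves at the extremes and under the null", {
  same <- ranksumCompare(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$pValue, 0.9)
  sep <- ranksumCompare(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$statistic, 9)         # all ranks above: W = n1*n2
  expect_lt(sep$pValue, 0.1)
  ## type-I error near nominal under the null
  withr::with_seed(77L, {
    rej <- mean(replicate(2000, {
      ranksumCompare(rnorm(15), rnorm(15))$pValue < 0.05
    }))
  })
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})

test_that("site reports serialise measures and detections as JSON", {
  m <- new("SiteScore", meanBond = 0.8, meanResidue = 0.9, propHigh = 0.2,
           meanRef = 0.7, nBonds = 5L, nResidues = 3L)
  det <- data.frame(measure = "meanBond", value = 0.8, threshold = 0.4,
                    detected = TRUE, margin = 0.4)
  path <- withr::local_tempfile(fileext = ".json")
  writeSiteReport(m, det, path, id = "toy")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$measures$meanBond, 0.8)
  expect_true(obj$detection$detected[1])
  expect_equal(obj$id, "toy")
})
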