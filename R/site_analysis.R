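## Site-level statistics: the four site measures, the surrogate-site
## structural bootstrap that provides their null distribution, ensemble
## (multi-model) statistics and conformer comparison.

site_bond_rows <- function(scores, siteResidues, excludeResidues = character()) {
  b <- scores@bonds
  inSite <- (b$res1 %in% siteResidues) | (b$res2 %in% siteResidues)
  if (length(excludeResidues))
    inSite <- inSite & !(b$res1 %in% excludeResidues) &
                       !(b$res2 %in% excludeResidues)
  b[inSite, , drop = FALSE]
}

#' Site-level significance measures
#'
#' Computes the four measures of a candidate site from a fitted
#' \linkS4class{ScoreTable}: (i) the mean intrinsic bond quantile score
#' over the site's weak bonds, (ii) the mean residue quantile score over
#' the site's residues, (iii) the proportion of site bonds scoring above
#' \code{highCutoff}, and (iv) the mean reference bond quantile score
#' (NA when the table has no reference scores). Site bonds are the weak
#' bonds with at least one endpoint in a site residue; bonds touching
#' \code{excludeResidues} (typically the bound effector ligand itself)
#' are excluded so the measures stay protein-intrinsic.
#'
#' @param scores a \linkS4class{ScoreTable}.
#' @param siteResidues character residue keys of the site.
#' @param excludeResidues residue keys whose bonds are dropped.
#' @param highCutoff threshold of measure (iii), default 0.95.
#' @return a \linkS4class{SiteScore}.
#' @export
siteMeasures <- function(scores, siteResidues, excludeResidues = character(),
                         highCutoff = 0.95) {
  stopifnot(length(siteResidues) > 0L)
  sb <- site_bond_rows(scores, siteResidues, excludeResidues)
  sr <- scores@residues[scores@residues$resid %in% siteResidues, , drop = FALSE]
  if (nrow(sb) == 0L) {
    warning("site has no weak bonds; bond measures are NA")
    return(new("SiteScore", meanBond = NA_real_,
               meanResidue = if (nrow(sr)) mean(sr$pR) else NA_real_,
               propHigh = NA_real_, meanRef = NA_real_,
               nBonds = 0L, nResidues = nrow(sr)))
  }
  new("SiteScore",
      meanBond = mean(sb$pB),
      meanResidue = if (nrow(sr)) mean(sr$pR) else NA_real_,
      propHigh = mean(sb$pB > highCutoff),
      meanRef = if ("pRef" %in% names(sb)) mean(sb$pRef) else NA_real_,
      nBonds = nrow(sb), nResidues = nrow(sr))
}

site_diameter <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sqrt(max(sq_dist(coords, coords)))
}

#' Generate surrogate sites matched to a target site
#'
#' Draws random residue sets that satisfy the two structural constraints of
#' the bootstrap null: each surrogate has the same number of residues as
#' the target site, and its diameter (maximum distance between any two of
#' its atoms) does not exceed the target's. Each surrogate is grown from a
#' uniformly random seed residue by repeatedly adding the unused residue
#' whose centroid is nearest the growing set; a grown set whose diameter
#' exceeds the target's is rejected and regrown from a fresh seed residue.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param targetResidues residue keys of the target site.
#' @param n number of surrogate sites.
#' @param seed integer seed (surrogates are seed-reproducible).
#' @param model model index used for coordinates.
#' @param excludeResidues residues never used in surrogates (the target's
#'   ligand, waters are excluded automatically).
#' @param maxTries global cap on grow attempts (default \code{100 * n}).
#' @return a \linkS4class{SurrogateEnsemble} with empty scores (fill with
#'   \code{\link{surrogateScores}}).
#' @export
generateSurrogateSites <- function(structure, targetResidues, n = 1000L,
                                   seed = NULL, model = 1L,
                                   excludeResidues = character(),
                                   maxTries = 100L * n) {
  stopifnot(n >= 1L, length(targetResidues) >= 1L)
  a <- atoms(structure, model = model)
  a <- a[!a$isWater, , drop = FALSE]
  tgt <- a[a$resid %in% targetResidues, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("target residues not found in the structure")
  dTarget <- site_diameter(as.matrix(tgt[, c("x", "y", "z")]))

  pool <- setdiff(unique(a$resid), excludeResidues)
  k <- length(targetResidues)
  if (length(pool) <= k)
    stop("protein has too few residues to draw surrogates of size ", k)

  ## per-residue centroids and atom blocks
  cen <- t(vapply(pool, function(r) {
    m <- a[a$resid == r, c("x", "y", "z"), drop = FALSE]
    colMeans(as.matrix(m))
  }, numeric(3L)))
  atomsOf <- lapply(pool, function(r)
    as.matrix(a[a$resid == r, c("x", "y", "z"), drop = FALSE]))
  D2 <- sq_dist(cen, cen)

  grow_one <- function() {
    s <- sample.int(length(pool), 1L)
    members <- s
    while (length(members) < k) {
      d <- apply(D2[, members, drop = FALSE], 1L, min)
      d[members] <- Inf
      members <- c(members, which.min(d))
    }
    coords <- do.call(rbind, atomsOf[members])
    if (site_diameter(coords) <= dTarget + 1e-9) members else NULL
  }

  run <- function() {
    sites <- vector("list", n)
    got <- 0L; tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > maxTries)
        stop("could not generate ", n, " surrogate sites within ", maxTries,
             " attempts; the target diameter may be unusually small")
      m <- grow_one()
      if (is.null(m)) next
      got <- got + 1L
      sites[[got]] <- pool[m]
    }
    sites
  }
  sites <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  new("SurrogateEnsemble", sites = sites,
      scores = data.frame(),
      targetResidues = as.character(targetResidues),
      targetDiameter = dTarget)
}

#' Score every surrogate site
#'
#' Applies \code{\link{siteMeasures}} to each surrogate residue set and
#' stores the per-site measures in the ensemble.
#'
#' @param ensemble a \linkS4class{SurrogateEnsemble}.
#' @param scores a \linkS4class{ScoreTable} of the same protein.
#' @param excludeResidues,highCutoff passed to \code{\link{siteMeasures}}.
#' @return the ensemble with its \code{scores} slot filled.
#' @export
surrogateScores <- function(ensemble, scores, excludeResidues = character(),
                            highCutoff = 0.95) {
  rows <- lapply(ensemble@sites, function(s) {
    m <- suppressWarnings(
      siteMeasures(scores, s, excludeResidues, highCutoff))
    data.frame(meanBond = m@meanBond, meanResidue = m@meanResidue,
               propHigh = m@propHigh, meanRef = m@meanRef,
               nBonds = m@nBonds, nResidues = m@nResidues)
  })
  ensemble@scores <- do.call(rbind, rows)
  validObject(ensemble)
  ensemble
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the values with replacement \code{nBoot} times and returns the
#' percentile interval of the resampled means.
#'
#' @param values numeric vector (length >= 2 unless constant).
#' @param nBoot number of resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return list with \code{mean}, \code{lower}, \code{upper}.
#' @export
bootstrapMeanCI <- function(values, nBoot = 10000L, level = 0.95,
                            seed = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to bootstrap")
  n <- length(values)
  run <- function() {
    means <- vapply(seq_len(nBoot), function(i)
      mean(values[sample.int(n, n, replace = TRUE)]), 0)
    alpha <- (1 - level) / 2
    q <- quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
    list(mean = mean(values), lower = q[1], upper = q[2])
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Call a candidate allosteric site by the four measures
#'
#' Measures (i) mean bond score and (ii) mean residue score are detected
#' when the site value exceeds the upper bound of the surrogate-ensemble
#' bootstrap confidence interval of the corresponding mean. Measure (iii)
#' is detected when the proportion of site bonds above 0.95 exceeds the
#' expected proportion 0.05, and measure (iv) when the mean reference
#' score exceeds 0.5.
#'
#' @param site a \linkS4class{SiteScore} of the candidate site.
#' @param surrogates a scored \linkS4class{SurrogateEnsemble}.
#' @param nBoot,level,seed bootstrap settings (see
#'   \code{\link{bootstrapMeanCI}}).
#' @param propExpected threshold of measure (iii), default 0.05.
#' @param refExpected threshold of measure (iv), default 0.5.
#' @return data.frame with one row per measure: \code{measure},
#'   \code{value}, \code{threshold}, \code{detected}, \code{margin}.
#' @export
detectAllosteric <- function(site, surrogates, nBoot = 10000L, level = 0.95,
                             seed = NULL, propExpected = 0.05,
                             refExpected = 0.5) {
  if (!nrow(surrogates@scores))
    stop("surrogate ensemble has no scores; run surrogateScores() first")
  ciB <- bootstrapMeanCI(surrogates@scores$meanBond, nBoot, level, seed)
  ciR <- bootstrapMeanCI(surrogates@scores$meanResidue, nBoot, level,
                         if (is.null(seed)) NULL else seed + 1L)
  row <- function(measure, value, threshold) {
    det <- !is.na(value) && !is.na(threshold) && value > threshold
    data.frame(measure = measure, value = value, threshold = threshold,
               detected = det,
               margin = if (is.na(value) || is.na(threshold)) NA_real_
                        else value - threshold)
  }
  out <- rbind(
    row("meanBond", site@meanBond, ciB$upper),
    row("meanResidue", site@meanResidue, ciR$upper),
    row("propHigh", site@propHigh, propExpected),
    row("meanRef", site@meanRef, refExpected)
  )
  rownames(out) <- NULL
  out
}

#' Residue propensities for every model of a structure
#'
#' Builds the graph and computes the bond-to-bond propensity once per
#' model of a multi-model structure (for example, an NMR ensemble), with
#' identical construction settings.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param site site passed to \code{\link{bondPropensity}}.
#' @param models integer model indices (default all).
#' @param builder graph construction function taking \code{(structure,
#'   model = i, ...)}, default \code{\link{buildAtomisticGraph}}.
#' @param ... further arguments to the builder.
#' @return list of \linkS4class{PropensityResult}, one per model.
#' @export
propensityEnsemble <- function(structure, site,
                               models = seq_len(nModels(structure)),
                               builder = buildAtomisticGraph, ...) {
  lapply(models, function(i) {
    g <- builder(structure, model = i, ...)
    bondPropensity(g, site)
  })
}

#' Mean and variability of residue propensities across models
#'
#' Population mean and standard deviation of each residue's propensity
#' over a list of per-model results. Residues absent from some models are
#' dropped with a warning.
#'
#' @param results list of \linkS4class{PropensityResult} (>= 2).
#' @return an \linkS4class{EnsembleStats}.
#' @export
ensembleStats <- function(results) {
  if (length(results) < 2L) stop("need at least two models")
  tabs <- lapply(results, function(r) r@residues)
  common <- Reduce(intersect, lapply(tabs, `[[`, "resid"))
  if (!length(common)) stop("models share no residues")
  if (any(vapply(tabs, nrow, 0L) != length(common)))
    warning("residue sets differ across models; restricting to the ",
            length(common), " shared residues")
  P <- vapply(tabs, function(t) t$propensity[match(common, t$resid)],
              numeric(length(common)))
  if (is.null(dim(P))) P <- matrix(P, nrow = length(common))
  mu <- rowMeans(P)
  sdev <- sqrt(rowMeans(P^2) - mu^2)
  tab <- data.frame(resid = common, mean = mu, sd = pmax(sdev, 0),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$resid), , drop = FALSE]
  rownames(tab) <- NULL
  new("EnsembleStats", table = tab, nModels = length(results))
}

#' Residues ranked by ensemble variability
#'
#' @param stats an \linkS4class{EnsembleStats}.
#' @param fraction top fraction by standard deviation (default 0.1).
#' @return data.frame of the top residues, highest SD first.
#' @export
topVariableResidues <- function(stats, fraction = 0.1) {
  tab <- stats@table[order(-stats@table$sd), , drop = FALSE]
  k <- max(1L, ceiling(fraction * nrow(tab)))
  out <- head(tab, k)
  rownames(out) <- NULL
  out
}

#' Influence of individual residues between two conformers
#'
#' Regresses the residue propensities of conformer A on those of conformer
#' B by ordinary least squares and reports Cook's distance per residue:
#' residues whose propensity changes most between the conformations have
#' the largest influence on the fit. Also reports the Pearson correlation
#' of the two propensity vectors.
#'
#' @param piA,piB named numeric vectors of residue propensities (names are
#'   residue keys; matched by name, or positionally when unnamed).
#' @return list with \code{table} (resid, piA, piB, cooks; sorted by
#'   decreasing Cook's distance) and \code{r} (Pearson correlation).
#' @export
conformerInfluence <- function(piA, piB) {
  if (!is.null(names(piA)) && !is.null(names(piB))) {
    common <- intersect(names(piA), names(piB))
    piA <- piA[common]; piB <- piB[common]
    ids <- common
  } else {
    stopifnot(length(piA) == length(piB))
    ids <- as.character(seq_along(piA))
  }
  if (length(piA) < 4L) stop("need at least four shared residues")
  if (sd(piB) < 1e-15) stop("conformer B propensities are constant")
  fit <- lm(piA ~ piB)
  ## an (almost) exact linear relation makes Cook's distance 0/0; report 0
  if (sqrt(mean(residuals(fit)^2)) <= 1e-10 * (sd(piA) + 1e-300)) {
    D <- rep(0, length(piA))
  } else {
    D <- cooks.distance(fit)
  }
  tab <- data.frame(resid = ids, piA = as.numeric(piA),
                    piB = as.numeric(piB), cooks = as.numeric(D),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$cooks), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, r = cor(piA, piB))
}

#' Wilcoxon rank-sum comparison of two score groups
#'
#' Two-sided rank-sum test (normal approximation with tie correction)
#' comparing, for example, allosteric-site residue scores with the rest of
#' the protein.
#'
#' @param siteValues,otherValues numeric vectors.
#' @return list with \code{statistic} (W) and \code{pValue}.
#' @export
ranksumCompare <- function(siteValues, otherValues) {
  stopifnot(length(siteValues) > 0L, length(otherValues) > 0L)
  ht <- suppressWarnings(
    wilcox.test(siteValues, otherValues, alternative = "two.sided",
                exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), pValue = ht$p.value)
}

#' JSON site report
#'
#' Writes the four site measures, the surrogate ensemble means and
#' bootstrap bounds, and the detection calls for one protein.
#'
#' @param site a \linkS4class{SiteScore}.
#' @param detection data.frame from \code{\link{detectAllosteric}}.
#' @param path output JSON path.
#' @param id protein identifier recorded in the report.
#' @return invisibly, the path.
#' @export
writeSiteReport <- function(site, detection, path, id = "") {
  obj <- list(
    id = id,
    measures = list(meanBond = site@meanBond,
                    meanResidue = site@meanResidue,
                    propHigh = site@propHigh,
                    meanRef = site@meanRef,
                    nBonds = site@nBonds, nResidues = site@nResidues),
    detection = detection
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
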