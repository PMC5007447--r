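## Quantile scoring of propensities: conditional quantile curves of
## log-propensity against distance (intrinsic, within one protein) or
## against distance and log weak-bond count (reference, across proteins),
## inverted at each bond's covariates to yield a score in [0, 1].

#' Default quantile-level grid
#'
#' Levels 0.01, 0.02, ..., 0.99 with a refined upper tail to 0.999, so
#' that scores in the extreme tail (where allosteric bonds live) are
#' resolved to three decimals.
#'
#' @return numeric vector of strictly increasing levels in (0, 1).
#' @export
defaultQuantileGrid <- function() {
  c(seq(0.01, 0.99, by = 0.01), seq(0.991, 0.999, by = 0.001))
}

fit_quantile_model <- function(y, X, grid, covariates, class = "QuantileModel") {
  co <- matrix(NA_real_, length(grid), ncol(X) + 1L)
  for (k in seq_along(grid))
    co[k, ] <- as.numeric(quantileRegress(y, X, p = grid[k]))
  new(class, grid = grid, coefficients = co, covariates = covariates,
      n = length(y))
}

#' Fit the intrinsic quantile model of a protein
#'
#' Linear quantile regression of log-propensity on distance from the active
#' site, at every level of the grid. Bonds with zero propensity are
#' excluded from the fit (they are later scored 0).
#'
#' @param pi propensities (a numeric vector), or a
#'   \linkS4class{PropensityResult} whose scored weak bonds are used.
#' @param d distances from the active site (ignored when \code{pi} is a
#'   result object).
#' @param grid quantile levels, see \code{\link{defaultQuantileGrid}}.
#' @param minBonds minimum number of usable bonds (default 20).
#' @return a \linkS4class{QuantileModel} with covariate "d".
#' @export
fitIntrinsicModel <- function(pi, d = NULL, grid = defaultQuantileGrid(),
                              minBonds = 20L) {
  if (is(pi, "PropensityResult")) {
    b <- pi@bonds
    use <- b$scored & b$weak
    d <- b$dist[use]
    pi <- b$norm[use]
  }
  stopifnot(length(pi) == length(d), all(is.finite(d)))
  pos <- pi > 0
  if (any(!pos))
    warning(sum(!pos), " bond(s) with zero propensity excluded from the fit")
  y <- log(pi[pos]); x <- d[pos]
  if (length(y) < minBonds)
    stop("need at least ", minBonds, " weak bonds with positive propensity")
  if (diff(range(y)) < 1e-12)
    stop("degenerate fit: all propensities are equal")
  fit_quantile_model(y, matrix(x, ncol = 1L), grid, covariates = "d")
}

## Fitted quantile values at one covariate row, monotonically rearranged.
rearranged_quantiles <- function(model, xrow) {
  q <- as.numeric(model@coefficients %*% c(1, xrow))
  sort(q)
}

score_one <- function(model, y, xrow) {
  q <- rearranged_quantiles(model, xrow)
  g <- model@grid
  if (y < q[1]) return(0)
  if (y > q[length(q)]) return(1)
  if (diff(range(q)) < 1e-12) return(0.5)
  stats::approx(q, g, xout = y, ties = mean)$y
}

score_many <- function(model, y, X) {
  vapply(seq_along(y), function(i) {
    if (!is.finite(y[i])) return(0)   # log(0): numerically dead bond
    score_one(model, y[i], X[i, ])
  }, 0)
}

#' Intrinsic quantile scores of bonds
#'
#' For each bond, finds the level p at which the fitted (monotonically
#' rearranged) conditional quantile at the bond's distance equals the
#' bond's log-propensity, by piecewise-linear interpolation over the grid.
#' Values above the top fitted quantile map to 1, below the bottom to 0;
#' zero-propensity bonds score 0.
#'
#' @param model a fitted \linkS4class{QuantileModel} (covariate "d").
#' @param pi propensities, or a \linkS4class{PropensityResult} (scored weak
#'   bonds are used, and a data.frame with ids is returned).
#' @param d distances.
#' @return numeric scores in [0, 1] (or a data.frame when \code{pi} is a
#'   result object).
#' @export
scoreBonds <- function(model, pi, d = NULL) {
  if (is(pi, "PropensityResult")) {
    b <- pi@bonds
    use <- b$scored & b$weak
    p <- score_many(model, log(b$norm[use]), matrix(b$dist[use], ncol = 1L))
    return(data.frame(id = b$id[use], pB = p))
  }
  stopifnot(length(pi) == length(d))
  score_many(model, log(pi), matrix(d, ncol = 1L))
}

#' Fit the multi-protein reference quantile model
#'
#' Quantile planes for log-propensity against distance d and log E, where
#' E is the weak-bond count of the protein each bond belongs to. The mean
#' propensity scales as 1/E (normalisation over E bonds), so a power-law
#' dependence on E - linear in log E - is assumed for every quantile.
#'
#' @param pi,d,E numeric vectors over all weak bonds of all reference
#'   proteins (E is constant within a protein), or \code{pi} may be a
#'   data.frame with columns \code{pi}, \code{d}, \code{E}.
#' @param grid quantile levels.
#' @param minTriplets minimum usable observations (default 100).
#' @return a \linkS4class{ReferenceModel} with covariates (d, logE).
#' @export
fitReferenceModel <- function(pi, d = NULL, E = NULL,
                              grid = defaultQuantileGrid(),
                              minTriplets = 100L) {
  if (is.data.frame(pi)) { d <- pi$d; E <- pi$E; pi <- pi$pi }
  stopifnot(length(pi) == length(d), length(pi) == length(E))
  if (length(unique(E)) < 2L)
    stop("reference set must contain proteins with at least two distinct ",
         "weak-bond counts E (a single protein carries no E information)")
  pos <- pi > 0 & is.finite(d) & E > 0
  if (any(!pos))
    warning(sum(!pos), " triplet(s) excluded (zero propensity or bad covariates)")
  if (sum(pos) < minTriplets)
    stop("need at least ", minTriplets, " usable (pi, d, E) triplets")
  X <- cbind(d = d[pos], logE = log(E[pos]))
  fit_quantile_model(log(pi[pos]), X, grid, covariates = c("d", "logE"),
                     class = "ReferenceModel")
}

#' Reference (absolute) quantile scores
#'
#' Scores bonds of any protein against a fitted multi-protein reference
#' model, given each bond's distance from its active site and the weak-bond
#' count E of its protein.
#'
#' @param model a \linkS4class{ReferenceModel}.
#' @param pi propensities, or a \linkS4class{PropensityResult} (its stored
#'   weak-bond count is then used for E).
#' @param d distances.
#' @param E weak-bond count(s); recycled to the length of \code{pi}.
#' @return numeric scores in [0, 1] (or a data.frame for a result object).
#' @export
scoreReference <- function(model, pi, d = NULL, E = NULL) {
  if (is(pi, "PropensityResult")) {
    b <- pi@bonds
    use <- b$scored & b$weak
    X <- cbind(b$dist[use], log(pi@weakBondCount))
    p <- score_many(model, log(b$norm[use]), X)
    return(data.frame(id = b$id[use], pRef = p))
  }
  stopifnot(length(pi) == length(d))
  E <- rep_len(E, length(pi))
  score_many(model, log(pi), cbind(d, log(E)))
}

#' Score a propensity result at bond and residue level
#'
#' Fits the intrinsic quantile model to the scored weak bonds, scores them,
#' and applies the identical machinery to the residue propensities (against
#' each residue's minimum bond distance). Optionally adds reference scores
#' from a fitted \linkS4class{ReferenceModel}.
#'
#' @param result a \linkS4class{PropensityResult}.
#' @param grid quantile levels.
#' @param reference optional \linkS4class{ReferenceModel}.
#' @return a \linkS4class{ScoreTable}.
#' @export
scoreTable <- function(result, grid = defaultQuantileGrid(), reference = NULL) {
  b <- result@bonds
  use <- b$scored & b$weak
  bm <- suppressWarnings(
    fitIntrinsicModel(b$norm[use], b$dist[use], grid = grid))
  pB <- score_many(bm, log(b$norm[use]), matrix(b$dist[use], ncol = 1L))
  bt <- data.frame(id = b$id[use], kind = b$kind[use],
                   res1 = b$res1[use], res2 = b$res2[use],
                   propensity = b$norm[use], dist = b$dist[use], pB = pB,
                   stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    X <- cbind(b$dist[use], log(result@weakBondCount))
    bt$pRef <- score_many(reference, log(b$norm[use]), X)
  }
  r <- result@residues
  rm_ <- suppressWarnings(
    fitIntrinsicModel(r$propensity, r$minDist, grid = grid,
                      minBonds = min(20L, nrow(r))))
  pR <- score_many(rm_, log(r$propensity), matrix(r$minDist, ncol = 1L))
  rt <- data.frame(resid = r$resid, propensity = r$propensity,
                   minDist = r$minDist, pR = pR, stringsAsFactors = FALSE)
  new("ScoreTable", bonds = bt, residues = rt, bondModel = bm,
      residueModel = rm_)
}

#' Serialise / restore a reference model as versioned JSON
#'
#' The JSON file stores the grid, covariate names and coefficient matrix,
#' so a reference set fitted once can be shipped and reused without
#' recomputing the regression.
#'
#' @param model a \linkS4class{ReferenceModel}.
#' @param path JSON file path.
#' @return \code{writeReferenceModel}: invisibly, the path.
#' @export
writeReferenceModel <- function(model, path) {
  obj <- list(
    format = "bondprop-reference-model",
    version = 1L,
    grid = model@grid,
    covariates = model@covariates,
    coefficients = unname(apply(model@coefficients, 1L, as.numeric,
                                simplify = FALSE)),
    n = model@n
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeReferenceModel
#' @return \code{readReferenceModel}: the restored
#'   \linkS4class{ReferenceModel}.
#' @export
readReferenceModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "bondprop-reference-model"))
    stop("not a bondprop reference-model file: ", path)
  co <- obj$coefficients
  if (is.list(co) && !is.data.frame(co))
    co <- do.call(rbind, lapply(co, as.numeric))
  co <- as.matrix(co)
  storage.mode(co) <- "double"
  dimnames(co) <- NULL
  new("ReferenceModel", grid = as.numeric(obj$grid),
      coefficients = co, covariates = as.character(obj$covariates),
      n = as.integer(obj$n))
}
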