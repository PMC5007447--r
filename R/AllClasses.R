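#' @import methods
#' @importFrom stats approx coef cooks.distance cor lm median na.omit qnorm
#'   quantile rlnorm rnorm runif sd setNames wilcox.test lm.fit
#' @importFrom utils combn head read.csv write.csv
NULL

#' Parsed protein structure
#'
#' Holds one or more atomic models read from a PDB file, together with any
#' LINK records. Atom identity (chain, residue number, insertion code, atom
#' name) is shared across models; coordinates are stored per model.
#'
#' @slot atoms data.frame with one row per atom: \code{serial}, \code{name},
#'   \code{altloc}, \code{resname}, \code{chain}, \code{resno}, \code{icode},
#'   \code{x}, \code{y}, \code{z} (model 1 coordinates), \code{occ},
#'   \code{bfactor}, \code{element}, \code{isHetero}, \code{isWater},
#'   \code{resid} (residue key \code{chain:resno[icode]}).
#' @slot xyz numeric matrix, \code{nModels} rows by \code{3 * nrow(atoms)}
#'   columns, coordinates in Angstrom.
#' @slot links data.frame of LINK records with resolved atom indices
#'   (\code{atom1}, \code{atom2}; \code{NA} when unresolvable).
#' @slot id character identifier (PDB file name or title).
#' @slot hasHydrogens logical, TRUE when explicit hydrogens are present.
#'
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(
    atoms = "data.frame",
    xyz = "matrix",
    links = "data.frame",
    id = "character",
    hasHydrogens = "logical"
  )
)

setValidity("ProteinStructure", function(object) {
  msg <- character()
  if (nrow(object@atoms) == 0L) msg <- c(msg, "structure contains no atoms")
  if (ncol(object@xyz) != 3L * nrow(object@atoms))
    msg <- c(msg, "xyz width does not match atom count")
  if (nrow(object@xyz) < 1L) msg <- c(msg, "at least one model is required")
  if (!all(is.finite(object@xyz))) msg <- c(msg, "non-finite coordinates")
  if (any(!nzchar(object@atoms$element)))
    msg <- c(msg, "empty element symbols")
  key <- paste(object@atoms$chain, object@atoms$resno, object@atoms$icode,
               object@atoms$name, object@atoms$altloc)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (chain, resno, icode, name, altloc) atom identity")
  if (length(msg)) msg else TRUE
})

#' Site specification
#'
#' Describes a site either as a ligand selection (residues are then picked by
#' a distance criterion around the ligand atoms) or as an explicit residue
#' list.
#'
#' @slot mode "ligand" or "residues".
#' @slot ligand data.frame with columns \code{chain}, \code{resname},
#'   \code{resno} (one row per ligand residue).
#' @slot residues character vector of residue keys (\code{chain:resno}).
#' @slot contactCutoff numeric contact distance in Angstrom (default 3.5).
#'
#' @exportClass SiteSpec
setClass("SiteSpec",
  representation(
    mode = "character",
    ligand = "data.frame",
    residues = "character",
    contactCutoff = "numeric"
  )
)

setValidity("SiteSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("ligand", "residues"))
    msg <- c(msg, "mode must be 'ligand' or 'residues'")
  if (object@contactCutoff <= 0) msg <- c(msg, "contactCutoff must be > 0")
  if (object@mode == "ligand" && nrow(object@ligand) == 0L)
    msg <- c(msg, "ligand selection is empty")
  if (object@mode == "residues" && length(object@residues) == 0L)
    msg <- c(msg, "residue list is empty")
  if (length(msg)) msg else TRUE
})

#' Energy-weighted atomistic (or residue-level) graph
#'
#' @slot nodes data.frame, one row per node (atom or residue) with
#'   coordinates and residue key \code{resid}.
#' @slot bonds data.frame, one row per undirected edge: \code{id},
#'   \code{from}, \code{to} (node indices), \code{kind} (covalent, hbond,
#'   saltbridge, hydrophobic, electrostatic, rrin-contact), \code{energy}
#'   (kJ/mol, > 0), midpoint \code{mx}, \code{my}, \code{mz}, residue keys
#'   \code{res1}, \code{res2}, and logical \code{weak}.
#' @slot level "atomistic" or "rrin".
#'
#' @exportClass AtomGraph
setClass("AtomGraph",
  representation(nodes = "data.frame", bonds = "data.frame", level = "character")
)

setValidity("AtomGraph", function(object) {
  b <- object@bonds
  msg <- character()
  if (!object@level %in% c("atomistic", "rrin"))
    msg <- c(msg, "level must be 'atomistic' or 'rrin'")
  if (nrow(b)) {
    if (any(b$from == b$to)) msg <- c(msg, "self-loop edge present")
    if (any(!is.finite(b$energy)) || any(b$energy <= 0))
      msg <- c(msg, "all bond energies must be finite and > 0")
    key <- paste(pmin(b$from, b$to), pmax(b$from, b$to))
    if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edge")
    if (!identical(b$weak, b$kind != "covalent"))
      msg <- c(msg, "weak flag inconsistent with bond kind")
  }
  if (length(msg)) msg else TRUE
})

#' Weighted graph Laplacian with component bookkeeping
#'
#' @slot L symmetric sparse Laplacian (dgCMatrix), zero row sums.
#' @slot membership integer vector assigning each node to a connected
#'   component.
#' @slot nComponents integer number of connected components.
#'
#' @exportClass LaplacianSystem
setClass("LaplacianSystem",
  representation(L = "Matrix", membership = "integer", nComponents = "integer")
)

#' Bond and residue propensities
#'
#' @slot bonds data.frame: the graph's bond table extended with
#'   \code{isSource} (active-site ligand--protein source bond),
#'   \code{scored}, \code{raw} (unnormalised propensity), \code{norm}
#'   (normalised propensity, sums to 1 over scored bonds) and \code{dist}
#'   (minimum midpoint distance to any source bond, Angstrom).
#' @slot residues data.frame: \code{resid}, \code{propensity} (sum of
#'   incident bonds' normalised propensities) and \code{minDist}.
#' @slot sourceBonds integer ids of the source bonds.
#' @slot weakBondCount integer, number of weak (non-covalent) bonds in the
#'   graph (the covariate E of the reference model).
#' @slot normalizedOver "all" or "weak".
#'
#' @exportClass PropensityResult
setClass("PropensityResult",
  representation(
    bonds = "data.frame",
    residues = "data.frame",
    sourceBonds = "integer",
    weakBondCount = "integer",
    normalizedOver = "character"
  )
)

setValidity("PropensityResult", function(object) {
  b <- object@bonds
  msg <- character()
  sc <- b$scored
  if (any(b$norm[sc] < 0, na.rm = TRUE)) msg <- c(msg, "negative propensity")
  norm_set <- if (identical(object@normalizedOver, "weak")) sc & b$weak else sc
  if (sum(norm_set) > 0L && abs(sum(b$norm[norm_set]) - 1) > 1e-9)
    msg <- c(msg, "normalised propensities must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Fitted conditional quantile model
#'
#' Linear quantile-regression coefficients for log-propensity against a set
#' of covariates, at an ordered grid of quantile levels. Fitted values at any
#' covariate point are made non-decreasing in the level by monotone
#' rearrangement before score inversion.
#'
#' @slot grid strictly increasing quantile levels in (0, 1).
#' @slot coefficients matrix, one row per level: intercept then one column
#'   per covariate.
#' @slot covariates character names of covariates ("d" for the intrinsic
#'   model; c("d", "logE") for the reference model).
#' @slot n integer number of observations used in the fit.
#'
#' @exportClass QuantileModel
setClass("QuantileModel",
  representation(grid = "numeric", coefficients = "matrix",
                 covariates = "character", n = "integer")
)

setValidity("QuantileModel", function(object) {
  msg <- character()
  if (any(diff(object@grid) <= 0)) msg <- c(msg, "grid must be strictly increasing")
  if (any(object@grid <= 0 | object@grid >= 1)) msg <- c(msg, "grid levels must lie in (0,1)")
  if (nrow(object@coefficients) != length(object@grid))
    msg <- c(msg, "one coefficient row per grid level required")
  if (ncol(object@coefficients) != length(object@covariates) + 1L)
    msg <- c(msg, "coefficient columns must be intercept + covariates")
  if (length(msg)) msg else TRUE
})

#' Multi-protein reference quantile model
#'
#' A \linkS4class{QuantileModel} with covariates (d, log E): quantile planes
#' for log-propensity against distance from the active site and the log of
#' the protein's weak-bond count. Serialisable to JSON so a fitted reference
#' set can be reused without recomputation.
#'
#' @exportClass ReferenceModel
setClass("ReferenceModel", contains = "QuantileModel")

#' Quantile scores for bonds and residues
#'
#' @slot bonds data.frame: \code{id}, \code{kind}, \code{res1}, \code{res2},
#'   \code{propensity}, \code{dist}, \code{pB} (intrinsic quantile score) and
#'   optionally \code{pRef}.
#' @slot residues data.frame: \code{resid}, \code{propensity},
#'   \code{minDist}, \code{pR}.
#' @slot bondModel,residueModel the fitted \linkS4class{QuantileModel}s.
#'
#' @exportClass ScoreTable
setClass("ScoreTable",
  representation(bonds = "data.frame", residues = "data.frame",
                 bondModel = "QuantileModel", residueModel = "QuantileModel")
)

setValidity("ScoreTable", function(object) {
  msg <- character()
  pb <- object@bonds$pB
  pr <- object@residues$pR
  if (any(pb < 0 | pb > 1, na.rm = TRUE)) msg <- c(msg, "pB outside [0,1]")
  if (any(pr < 0 | pr > 1, na.rm = TRUE)) msg <- c(msg, "pR outside [0,1]")
  if (length(msg)) msg else TRUE
})

#' Site-level significance measures
#'
#' The four site measures: mean bond quantile score, mean residue quantile
#' score, proportion of site bonds with score above 0.95, and mean reference
#' (absolute) bond quantile score.
#'
#' @slot meanBond,meanResidue,propHigh,meanRef numeric (NA when undefined).
#' @slot nBonds,nResidues integer counts.
#'
#' @exportClass SiteScore
setClass("SiteScore",
  representation(meanBond = "numeric", meanResidue = "numeric",
                 propHigh = "numeric", meanRef = "numeric",
                 nBonds = "integer", nResidues = "integer")
)

setValidity("SiteScore", function(object) {
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  msg <- character()
  if (!ok(object@meanBond) || !ok(object@meanResidue) ||
      !ok(object@propHigh) || !ok(object@meanRef))
    msg <- c(msg, "quantile means and proportions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Surrogate-site structural bootstrap ensemble
#'
#' Random residue sets matched to a target site in residue count and
#' maximum atom-pair diameter, with their per-site measures. The ensemble
#' provides the null distribution against which a candidate allosteric
#' site is judged.
#'
#' @slot sites list of character vectors of residue keys.
#' @slot scores data.frame, one row per surrogate: \code{meanBond},
#'   \code{meanResidue}, \code{propHigh}, \code{meanRef}, \code{nBonds},
#'   \code{nResidues}.
#' @slot targetResidues character, the target site's residue keys.
#' @slot targetDiameter numeric, the target site's atom-pair diameter (A).
#'
#' @exportClass SurrogateEnsemble
setClass("SurrogateEnsemble",
  representation(sites = "list", scores = "data.frame",
                 targetResidues = "character", targetDiameter = "numeric")
)

setValidity("SurrogateEnsemble", function(object) {
  msg <- character()
  k <- length(object@targetResidues)
  if (k > 0L && !all(lengths(object@sites) == k))
    msg <- c(msg, "every surrogate must have the target's residue count")
  if (nrow(object@scores) && nrow(object@scores) != length(object@sites))
    msg <- c(msg, "one score row per surrogate site required")
  if (length(msg)) msg else TRUE
})

#' Per-residue statistics over a structural ensemble
#'
#' Mean and population standard deviation of the residue propensity across
#' the models of an ensemble (for example, NMR conformers).
#'
#' @slot table data.frame: \code{resid}, \code{mean}, \code{sd} (population,
#'   divide by n), sorted by residue key.
#' @slot nModels integer number of models aggregated.
#'
#' @exportClass EnsembleStats
setClass("EnsembleStats",
  representation(table = "data.frame", nModels = "integer")
)

setValidity("EnsembleStats", function(object) {
  msg <- character()
  if (object@nModels < 2L) msg <- c(msg, "at least two models are required")
  if (any(object@table$sd < 0)) msg <- c(msg, "negative standard deviation")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure", sQuote(object@id), "\n")
  cat("  atoms:", nrow(object@atoms), " models:", nrow(object@xyz),
      " links:", nrow(object@links), "\n")
  cat("  waters:", sum(object@atoms$isWater),
      " hetero:", sum(object@atoms$isHetero),
      " hydrogens:", if (object@hasHydrogens) "present" else "absent", "\n")
})

setMethod("show", "SiteSpec", function(object) {
  if (object@mode == "ligand") {
    cat("SiteSpec (ligand mode, cutoff", object@contactCutoff, "A):",
        paste(object@ligand$chain, object@ligand$resname, object@ligand$resno,
              sep = ":", collapse = ", "), "\n")
  } else {
    cat("SiteSpec (residue list):", paste(object@residues, collapse = ", "), "\n")
  }
})

setMethod("show", "AtomGraph", function(object) {
  cat("AtomGraph (", object@level, "): ", nrow(object@nodes), " nodes, ",
      nrow(object@bonds), " bonds (", sum(object@bonds$weak), " weak)\n",
      sep = "")
  if (nrow(object@bonds))
    print(table(object@bonds$kind))
})

setMethod("show", "LaplacianSystem", function(object) {
  cat("LaplacianSystem:", nrow(object@L), "nodes,",
      object@nComponents, "connected component(s)\n")
})

setMethod("show", "PropensityResult", function(object) {
  sc <- object@bonds$scored
  cat("PropensityResult:", sum(sc), "scored bonds (",
      length(object@sourceBonds), "source bonds,",
      object@weakBondCount, "weak bonds in graph )\n")
  cat("  normalised over:", object@normalizedOver,
      "; sum(norm) =", format(sum(object@bonds$norm[sc])), "\n")
})

setMethod("show", "QuantileModel", function(object) {
  cat(class(object), ": ", length(object@grid), " levels, covariates (",
      paste(object@covariates, collapse = ", "), "), n = ", object@n, "\n",
      sep = "")
  med <- which.min(abs(object@grid - 0.5))
  cat("  median-level coefficients:",
      paste(format(object@coefficients[med, ], digits = 4), collapse = " "), "\n")
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@bonds), "bonds,",
      nrow(object@residues), "residues",
      if ("pRef" %in% names(object@bonds)) "(with reference scores)" else "",
      "\n")
})

setMethod("show", "SurrogateEnsemble", function(object) {
  cat("SurrogateEnsemble:", length(object@sites), "surrogate sites of",
      length(object@targetResidues), "residues (target diameter",
      format(object@targetDiameter, digits = 4), "A)\n")
  if (nrow(object@scores))
    cat(sprintf("  ensemble means: <p_b> = %.3f  <p_R> = %.3f  P(>0.95) = %.3f\n",
                mean(object@scores$meanBond, na.rm = TRUE),
                mean(object@scores$meanResidue, na.rm = TRUE),
                mean(object@scores$propHigh, na.rm = TRUE)))
})

setMethod("show", "EnsembleStats", function(object) {
  cat("EnsembleStats over", object@nModels, "models,",
      nrow(object@table), "residues\n")
  top <- head(object@table[order(-object@table$sd), ], 5L)
  cat("  highest SD:", paste(top$resid, collapse = ", "), "\n")
})

setMethod("show", "SiteScore", function(object) {
  cat("SiteScore:", object@nBonds, "bonds /", object@nResidues, "residues\n")
  cat(sprintf("  <p_b> = %.3f  <p_R> = %.3f  P(p_b>0.95) = %.3f  <p_ref> = %s\n",
              object@meanBond, object@meanResidue, object@propHigh,
              if (is.na(object@meanRef)) "NA" else sprintf("%.3f", object@meanRef)))
})
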