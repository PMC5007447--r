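#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @param ... further arguments passed to methods (e.g. \code{model} for
#'   \code{atoms}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("links", function(x) standardGeneric("links"))

#' @rdname accessors
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' @rdname accessors
#' @export
setGeneric("hasHydrogens", function(x) standardGeneric("hasHydrogens"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname accessors
#' @export
setGeneric("weakBondCount", function(x) standardGeneric("weakBondCount"))

#' @rdname accessors
#' @export
setGeneric("bondScores", function(x) standardGeneric("bondScores"))

#' @rdname accessors
#' @export
setGeneric("residueScores", function(x) standardGeneric("residueScores"))

#' @rdname accessors
#' @export
setGeneric("quantileGrid", function(x) standardGeneric("quantileGrid"))

## Methods on ProteinStructure -------------------------------------------

#' @describeIn accessors atom table of a \linkS4class{ProteinStructure};
#'   coordinates are taken from the requested \code{model}.
#' @param model integer model index (1-based).
#' @export
setMethod("atoms", "ProteinStructure", function(x, model = 1L) {
  model <- as.integer(model)
  if (model < 1L || model > nrow(x@xyz))
    stop("model ", model, " not present (structure has ", nrow(x@xyz),
         " model(s))")
  a <- x@atoms
  xyz <- x@xyz[model, ]
  a$x <- xyz[seq(1L, length(xyz), by = 3L)]
  a$y <- xyz[seq(2L, length(xyz), by = 3L)]
  a$z <- xyz[seq(3L, length(xyz), by = 3L)]
  a
})

#' @describeIn accessors LINK record table.
#' @export
setMethod("links", "ProteinStructure", function(x) x@links)

#' @describeIn accessors number of models.
#' @export
setMethod("nModels", "ProteinStructure", function(x) nrow(x@xyz))

#' @describeIn accessors whether explicit hydrogens are present.
#' @export
setMethod("hasHydrogens", "ProteinStructure", function(x) x@hasHydrogens)

## Methods on AtomGraph ---------------------------------------------------

#' @describeIn accessors node table of an \linkS4class{AtomGraph}.
#' @export
setMethod("nodes", "AtomGraph", function(x) x@nodes)

#' @describeIn accessors bond (edge) table of an \linkS4class{AtomGraph}.
#' @export
setMethod("bonds", "AtomGraph", function(x) x@bonds)

#' @describeIn accessors number of weak (non-covalent) bonds.
#' @export
setMethod("weakBondCount", "AtomGraph", function(x) sum(x@bonds$weak))

## Methods on PropensityResult -------------------------------------------

#' @describeIn accessors bond table with propensities.
#' @export
setMethod("bonds", "PropensityResult", function(x) x@bonds)

#' @describeIn accessors residue propensity table.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setMethod("residues", "PropensityResult", function(x) x@residues)

#' @describeIn accessors weak-bond count of the underlying graph.
#' @export
setMethod("weakBondCount", "PropensityResult", function(x) x@weakBondCount)

## Methods on ScoreTable --------------------------------------------------

#' @describeIn accessors per-bond quantile scores.
#' @export
setMethod("bondScores", "ScoreTable", function(x) x@bonds)

#' @describeIn accessors per-residue quantile scores.
#' @export
setMethod("residueScores", "ScoreTable", function(x) x@residues)

#' @describeIn accessors quantile level grid of a fitted model.
#' @export
setMethod("quantileGrid", "QuantileModel", function(x) x@grid)
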