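## Bond-to-bond propensity via the edge-to-edge transfer matrix
## M = G B L^+ B^T, computed column-by-column through sparse Laplacian
## solves (no pseudo-inverse is ever materialised).

#' Weighted graph Laplacian of an atom graph
#'
#' L has off-diagonal entries \code{-w_ij} for every bond and diagonal
#' entries equal to the weighted degree, so row sums vanish and the nullity
#' equals the number of connected components.
#'
#' @param graph an \linkS4class{AtomGraph}.
#' @return a \linkS4class{LaplacianSystem}.
#' @export
graphLaplacian <- function(graph) {
  b <- graph@bonds
  n <- nrow(graph@nodes)
  if (n == 0L) stop("empty graph")
  L <- Matrix::sparseMatrix(
    i = c(b$from, b$to, b$from, b$to),
    j = c(b$to, b$from, b$from, b$to),
    x = c(-b$energy, -b$energy, b$energy, b$energy),
    dims = c(n, n)
  )
  ig <- igraph::graph_from_edgelist(cbind(b$from, b$to), directed = FALSE)
  if (igraph::vcount(ig) < n)
    ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
  comp <- igraph::components(ig)
  new("LaplacianSystem", L = L, membership = as.integer(comp$membership),
      nComponents = as.integer(comp$no))
}

## Cached grounded Cholesky factorisation for one component.
component_solver <- function(system, comp) {
  idx <- which(system@membership == comp)
  if (length(idx) < 2L)
    stop("component ", comp, " has fewer than two nodes")
  Lc <- system@L[idx, idx, drop = FALSE]
  Lg <- Lc[-1L, -1L, drop = FALSE]     # ground the first node
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE, perm = TRUE)
  list(idx = idx, Lc = Lc, chol = ch)
}

solve_grounded <- function(sol, Rc, tol = 1e-10, maxRefine = 4L) {
  ## Solve Lc x = Rc (columns), x mean-centred per column, with iterative
  ## refinement to the relative-residual contract.
  Rg <- Rc[-1L, , drop = FALSE]
  Xg <- as.matrix(Matrix::solve(sol$chol, Rg, system = "A"))
  X <- rbind(0, Xg)
  for (k in seq_len(maxRefine)) {
    Res <- Rc - as.matrix(sol$Lc %*% X)
    rel <- sqrt(colSums(Res^2)) / pmax(sqrt(colSums(Rc^2)), .Machine$double.eps)
    if (all(rel <= tol)) break
    X <- X + rbind(0, as.matrix(Matrix::solve(sol$chol, Res[-1L, , drop = FALSE],
                                              system = "A")))
  }
  sweep(X, 2L, colMeans(X))   # orthogonal to the constant vector
}

#' Solve L x = rhs on the graph's connected components
#'
#' Returns the minimum-norm solution (per component: orthogonal to the
#' constant vector), equivalent to applying the Moore-Penrose pseudo-inverse
#' of the Laplacian. The right-hand side must sum to zero on every
#' component, which holds by construction for incidence-row sources.
#'
#' @param system a \linkS4class{LaplacianSystem}.
#' @param rhs numeric node vector.
#' @param tol relative residual tolerance (default 1e-10).
#' @return numeric node vector x with \code{L x = rhs}.
#' @export
solveOnComponent <- function(system, rhs, tol = 1e-10) {
  n <- nrow(system@L)
  stopifnot(length(rhs) == n)
  x <- numeric(n)
  scale <- max(abs(rhs))
  if (scale == 0) return(x)
  for (comp in seq_len(system@nComponents)) {
    idx <- which(system@membership == comp)
    r <- rhs[idx]
    if (all(r == 0)) next
    if (abs(sum(r)) > 1e-8 * scale)
      stop("rhs does not sum to zero on component ", comp,
           " - sources must be balanced within one component")
    if (length(idx) < 2L)
      stop("nonzero rhs on an isolated node")
    sol <- component_solver(system, comp)
    x[idx] <- solve_grounded(sol, matrix(r, ncol = 1L), tol = tol)
  }
  x
}

#' Columns of the edge-to-edge transfer matrix for a set of source bonds
#'
#' Computes \eqn{M = G B L^+ B^T} restricted to the requested source-bond
#' columns: one sparse Laplacian solve per source bond (against the signed
#' incidence row of that bond), followed by incidence differences scaled by
#' the bond energies. \code{M[b, b']} measures how a fluctuation of source
#' bond b' loads bond b, weighted by b's strength; its diagonal entries
#' relate to the mean energy stored in the bond's own fluctuations. M is
#' invariant under uniform rescaling of all edge weights.
#'
#' @param graph an \linkS4class{AtomGraph}.
#' @param sourceBondIds integer bond ids (rows of \code{bonds(graph)});
#'   all sources must lie in a single connected component.
#' @param system optionally, a precomputed \linkS4class{LaplacianSystem}.
#' @param tol relative residual tolerance of the solves.
#' @return numeric matrix (all bonds x sources) with attributes
#'   \code{sourceBonds} (the column ids) and \code{component} (the
#'   component holding the sources). Rows of bonds in other components are
#'   NA.
#' @export
transferColumns <- function(graph, sourceBondIds, system = NULL, tol = 1e-10) {
  b <- graph@bonds
  sourceBondIds <- as.integer(sourceBondIds)
  if (!length(sourceBondIds) || !all(sourceBondIds %in% b$id))
    stop("source bond ids not found in the graph")
  if (is.null(system)) system <- graphLaplacian(graph)
  src <- b[match(sourceBondIds, b$id), , drop = FALSE]
  comps <- unique(system@membership[c(src$from, src$to)])
  if (length(comps) != 1L)
    stop("source bonds span several connected components")
  sol <- component_solver(system, comps)
  idx <- sol$idx
  pos <- integer(nrow(system@L)); pos[idx] <- seq_along(idx)

  Rc <- matrix(0, length(idx), nrow(src))
  Rc[cbind(pos[src$from], seq_len(nrow(src)))] <- 1
  Rc[cbind(pos[src$to], seq_len(nrow(src)))] <- -1
  Z <- solve_grounded(sol, Rc, tol = tol)

  inComp <- system@membership[b$from] == comps
  M <- matrix(NA_real_, nrow(b), nrow(src))
  fi <- pos[b$from[inComp]]; ti <- pos[b$to[inComp]]
  M[inComp, ] <- b$energy[inComp] *
    (Z[fi, , drop = FALSE] - Z[ti, , drop = FALSE])
  rownames(M) <- b$id
  structure(M, sourceBonds = sourceBondIds, component = comps)
}

resolve_source_bonds <- function(graph, site) {
  b <- graph@bonds
  if (is(site, "SiteSpec")) {
    if (site@mode == "ligand") {
      a <- graph@nodes
      hit <- rep(FALSE, nrow(a))
      for (i in seq_len(nrow(site@ligand))) {
        l <- site@ligand[i, ]
        hit <- hit | (a$chain == l$chain & a$resname == l$resname &
                      a$resno == l$resno)
      }
      lig_res <- unique(a$resid[hit])
    } else lig_res <- site@residues
  } else lig_res <- as.character(site)
  if (!length(lig_res)) stop("ligand selection resolves to no residues")
  one_in <- xor(b$res1 %in% lig_res, b$res2 %in% lig_res)
  ids <- b$id[one_in & b$weak]
  if (!length(ids))
    stop("no weak ligand-protein bonds found at the active site; ",
         "check the ligand specification, include waters, or loosen the ",
         "interaction cutoffs")
  list(ids = ids, ligandResidues = lig_res)
}

#' Bond-to-bond propensities relative to an active site
#'
#' The source bonds are the weak ligand-protein interactions at the active
#' site. For every other bond b the raw propensity is the summed absolute
#' transfer \eqn{\tilde\Pi_b = \sum_{b'} |M_{b b'}|} over source bonds b',
#' and the normalised propensity divides by the total over all scored bonds
#' so that \eqn{\sum_b \Pi_b = 1}. Each bond also gets the minimum midpoint
#' distance \code{dist} to any source bond. Residue propensities sum the
#' normalised propensities of each residue's bonds.
#'
#' Bonds in connected components that do not contain the active site are
#' excluded from scoring with a warning. Both covalent and weak bonds are
#' scored; downstream quantile analysis conventionally uses the weak subset.
#'
#' @param graph an \linkS4class{AtomGraph}.
#' @param site a \linkS4class{SiteSpec} (ligand mode resolved against the
#'   graph's nodes), or a character vector of ligand residue keys.
#' @param normalizeOver "all" (default) to normalise over all scored bonds,
#'   or "weak" to normalise over the weak subset only.
#' @param tol solver tolerance.
#' @return a \linkS4class{PropensityResult}.
#' @export
bondPropensity <- function(graph, site, normalizeOver = c("all", "weak"),
                           tol = 1e-10) {
  normalizeOver <- match.arg(normalizeOver)
  src <- resolve_source_bonds(graph, site)
  b <- graph@bonds
  M <- transferColumns(graph, src$ids, tol = tol)

  isSource <- b$id %in% src$ids
  inComp <- !is.na(M[, 1])
  if (any(!inComp))
    warning(sum(!inComp), " bond(s) lie in components disconnected from ",
            "the active site and are excluded from scoring")
  scored <- inComp & !isSource

  raw <- rep(NA_real_, nrow(b))
  raw[inComp] <- rowSums(abs(M[inComp, , drop = FALSE]))
  norm <- rep(NA_real_, nrow(b))
  denom_set <- if (normalizeOver == "all") scored else scored & b$weak
  total <- sum(raw[denom_set])
  if (total <= 0) stop("all scored propensities are zero")
  norm[scored] <- raw[scored] / total

  srcRows <- b[isSource, , drop = FALSE]
  sm <- as.matrix(srcRows[, c("mx", "my", "mz")])
  bm <- as.matrix(b[, c("mx", "my", "mz")])
  D2 <- sq_dist(bm, sm)
  dist <- sqrt(pmax(apply(D2, 1L, min), 0))

  bonds <- cbind(b, isSource = isSource, scored = scored,
                 raw = raw, norm = norm, dist = dist)
  res <- residue_table(bonds)
  new("PropensityResult", bonds = bonds, residues = res,
      sourceBonds = as.integer(src$ids),
      weakBondCount = sum(b$weak),
      normalizedOver = normalizeOver)
}

residue_table <- function(bonds) {
  sc <- bonds[bonds$scored, , drop = FALSE]
  long <- rbind(
    data.frame(resid = sc$res1, norm = sc$norm, dist = sc$dist,
               stringsAsFactors = FALSE),
    data.frame(resid = sc$res2[sc$res2 != sc$res1],
               norm = sc$norm[sc$res2 != sc$res1],
               dist = sc$dist[sc$res2 != sc$res1],
               stringsAsFactors = FALSE)
  )
  agg <- stats::aggregate(long$norm, by = list(resid = long$resid), FUN = sum)
  mind <- stats::aggregate(long$dist, by = list(resid = long$resid), FUN = min)
  out <- data.frame(resid = agg$resid, propensity = agg$x,
                    minDist = mind$x[match(agg$resid, mind$resid)],
                    stringsAsFactors = FALSE)
  out[order(out$resid), , drop = FALSE]
}

#' Recompute residue propensities from a bond-level result
#'
#' Every scored bond contributes its normalised propensity to both endpoint
#' residues (once per residue). The sum over residues therefore equals the
#' bond total plus the inter-residue bond total (bonds between two residues
#' are counted for each).
#'
#' @param result a \linkS4class{PropensityResult}.
#' @return data.frame with \code{resid}, \code{propensity}, \code{minDist}.
#' @export
residuePropensity <- function(result) {
  residue_table(result@bonds)
}

#' Export propensity results as CSV
#'
#' @param result a \linkS4class{PropensityResult}.
#' @param bondPath,residuePath output CSV paths (either may be NULL).
#' @return invisibly, a list of the written paths.
#' @export
exportPropensity <- function(result, bondPath = NULL, residuePath = NULL) {
  if (!is.null(bondPath)) {
    b <- result@bonds
    write.csv(b[, c("id", "from", "to", "res1", "res2", "kind", "energy",
                    "dist", "raw", "norm", "isSource", "scored", "weak")],
              bondPath, row.names = FALSE)
  }
  if (!is.null(residuePath))
    write.csv(result@residues, residuePath, row.names = FALSE)
  invisible(list(bonds = bondPath, residues = residuePath))
}
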