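## Synthetic inputs: analytic toy graphs, toy protein PDBs with a planted
## allosteric pocket, and synthetic reference-set triplets. Everything is
## deterministic given its seed.

#' Construct small analytic graphs
#'
#' Toy \linkS4class{AtomGraph}s for testing and illustration: a single
#' edge, a path, a cycle (the 3-cycle is the analytic triangle), or a
#' random connected graph (random spanning tree plus extra edges). Each
#' node is its own residue, so residue-level machinery works unchanged;
#' all edges are weak.
#'
#' @param kind "edge", "path", "cycle", "triangle" or "random-connected".
#' @param n number of nodes (ignored for "edge" and "triangle").
#' @param weights "unit" for all-one energies, "random" for Uniform(0.5, 2)
#'   energies, or a numeric vector with one energy per edge.
#' @param seed integer seed controlling topology and random weights.
#' @return an \linkS4class{AtomGraph} (level "atomistic").
#' @export
makeToyGraph <- function(kind = c("edge", "path", "cycle", "triangle",
                                  "random-connected"),
                         n = 10L, weights = "unit", seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "edge") n <- 2L
  if (kind == "triangle") { kind <- "cycle"; n <- 3L }
  n <- as.integer(n)
  stopifnot(n >= 2L)

  build <- function() {
    if (kind == "path" || n == 2L) {
      ft <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
      P <- cbind(seq_len(n) - 1, 0, 0)
    } else if (kind == "cycle") {
      ft <- rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L), c(n, 1L))
      th <- 2 * pi * (seq_len(n) - 1L) / n
      P <- cbind(cos(th), sin(th), 0)
    } else {
      ## spanning tree guarantees connectivity, then extra random edges
      ft <- cbind(vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L), 2:n)
      extra <- max(0L, round(n / 2))
      seen <- pair_key(ft[, 1], ft[, 2])
      while (extra > 0L) {
        ij <- sample.int(n, 2L)
        k <- pair_key(ij[1], ij[2])
        if (!k %in% seen) {
          ft <- rbind(ft, ij)
          seen <- c(seen, k)
          extra <- extra - 1L
        }
      }
      P <- matrix(runif(3L * n, 0, 10), n, 3L)
    }
    m <- nrow(ft)
    en <- if (is.numeric(weights)) {
      stopifnot(length(weights) == m, all(weights > 0))
      weights
    } else if (identical(weights, "random")) runif(m, 0.5, 2) else rep(1, m)
    list(ft = ft, P = P, en = en)
  }
  g <- withr::with_seed(seed, build())

  nodes <- data.frame(
    serial = seq_len(n), name = "X", altloc = "", resname = "TOY",
    chain = "A", resno = seq_len(n), icode = "",
    x = g$P[, 1], y = g$P[, 2], z = g$P[, 3],
    occ = 1, bfactor = 0, element = "C", charge = "",
    isHetero = FALSE, isWater = FALSE,
    resid = resid_key("A", seq_len(n), ""),
    stringsAsFactors = FALSE
  )
  e <- data.frame(from = pmin(g$ft[, 1], g$ft[, 2]),
                  to = pmax(g$ft[, 1], g$ft[, 2]),
                  kind = "hbond", energy = g$en, stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]
  make_atom_graph(nodes, g$P, e, level = "atomistic")
}

## Geometry of the toy protein: three straight arms (chains A, B, C) at
## 120 degrees in the xy-plane. Along each arm, residue j sits at
## (0.5 + 3.5 j) u with backbone N/CA/C/O, an amide hydrogen aimed
## exactly at O of residue j-2 (a regular hydrogen-bond ladder), and a
## CB (+ HB) raised out of plane. Arm A is serine: its OG atoms form a
## chain of strong LINK-mediated interactions - the planted communication
## pathway from the central active-site ligand to the arm A tip, where a
## marker ligand defines the planted pocket.
ARM_FRAMES <- list(
  A = list(u = c(1, 0, 0), v = c(0, 1, 0)),
  B = list(u = c(-0.5, sqrt(3) / 2, 0), v = c(-sqrt(3) / 2, -0.5, 0)),
  C = list(u = c(-0.5, -sqrt(3) / 2, 0), v = c(sqrt(3) / 2, -0.5, 0))
)

toy_arm_atoms <- function(chain, perArm) {
  fr <- ARM_FRAMES[[chain]]
  u <- fr$u; v <- fr$v; z <- c(0, 0, 1)
  ser <- chain == "A"
  rows <- list()
  for (j in seq_len(perArm)) {
    b <- (0.5 + 3.5 * j) * u
    at <- rbind(
      N  = b - 1.46 * u,
      CA = b,
      C  = b + 1.52 * u,
      O  = b + 1.52 * u + 1.23 * (cos(pi / 6) * u + sin(pi / 6) * v),
      CB = b + 1.53 * z,
      H  = b - 1.46 * u + (-0.979 * u + 0.204 * v)
    )
    ## serine's OG replaces the beta hydrogen so the two never overlap
    at <- rbind(at, if (ser) b + 2.93 * z else b + 2.63 * z)
    rownames(at)[nrow(at)] <- if (ser) "OG" else "HB"
    rows[[j]] <- data.frame(
      name = rownames(at),
      resname = if (ser) "SER" else "ALA",
      chain = chain, resno = j,
      x = at[, 1], y = at[, 2], z = at[, 3],
      element = substr(rownames(at), 1, 1),
      isHetero = FALSE, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

toy_link_line <- function(name1, resname1, chain1, resno1,
                          name2, resname2, chain2, resno2) {
  sprintf("LINK        %-4s %-3s %1s%4d                %-4s %-3s %1s%4d",
          name1, resname1, chain1, resno1, name2, resname2, chain2, resno2)
}

#' Generate a toy protein PDB with a planted allosteric pocket
#'
#' Emits PDB text for a three-armed synthetic protein: chains A, B and C
#' radiate from a central two-atom ligand (HETATM \code{LIG}, the active
#' site), each with a covalent backbone, a regular hydrogen-bond ladder
#' and out-of-plane side-chain carbons carrying hydrophobic tethers. Arm A
#' is a serine arm whose consecutive OG atoms are joined by LINK records,
#' so a chain of strong electrostatic interactions runs from the
#' active-site ligand to the arm A tip. A two-atom marker ligand (HETATM
#' \code{ALM}) sits against the last four arm A residues and defines the
#' planted allosteric pocket; the mirror-image residue set at the arm B
#' tip, which lacks the strong pathway, serves as a decoy. Two structural
#' waters sit near the middle of arm B.
#'
#' The returned text carries attributes locating the planted structure:
#' \code{activeLigand} and \code{allostericLigand} ("CHAIN:RESNAME:RESNO"
#' selectors for \code{\link{siteSpec}}), \code{plantedSite} and
#' \code{decoySite} (residue-key vectors).
#'
#' @param nResidues total residue count over the three arms (>= 21,
#'   default 45; the arm length is \code{nResidues \%/\% 3}).
#' @param noise standard deviation (Angstrom) of Gaussian coordinate
#'   jitter. With several models, each model is jittered independently
#'   with at least 0.08 Angstrom so the ensemble has spread.
#' @param nModels number of MODEL blocks.
#' @param seed integer seed; output text is byte-identical per seed.
#' @return character scalar of PDB text, with the attributes above.
#' @export
makeToyProteinPDB <- function(nResidues = 45L, noise = 0, nModels = 1L,
                              seed = 1L) {
  stopifnot(nResidues >= 21L, nModels >= 1L, noise >= 0)
  perArm <- nResidues %/% 3L
  prot <- rbind(toy_arm_atoms("A", perArm), toy_arm_atoms("B", perArm),
                toy_arm_atoms("C", perArm))

  uA <- ARM_FRAMES$A$u; vA <- ARM_FRAMES$A$v
  uB <- ARM_FRAMES$B$u; vB <- ARM_FRAMES$B$v
  k <- perArm
  het <- data.frame(
    name = c("C1", "C2", "C1", "C2", "O", "O"),
    resname = c("LIG", "LIG", "ALM", "ALM", "HOH", "HOH"),
    chain = c("L", "L", "M", "M", "W", "W"),
    resno = c(1L, 1L, 1L, 1L, 1L, 2L),
    x = 0, y = 0, z = 0,
    element = c("C", "C", "C", "C", "O", "O"),
    isHetero = TRUE, stringsAsFactors = FALSE
  )
  het[1, c("x", "y", "z")] <- c(0, 0, 0.9)
  het[2, c("x", "y", "z")] <- c(0, 0, -0.9)
  het[3, c("x", "y", "z")] <- (0.5 + 3.5 * (k - 1) + 1.75) * uA - 3.0 * vA
  het[4, c("x", "y", "z")] <- (0.5 + 3.5 * (k - 3) + 1.75) * uA - 3.0 * vA
  mid <- (0.5 + 3.5 * ceiling(perArm / 2))
  het[5, c("x", "y", "z")] <- mid * uB + 6.0 * vB + c(0, 0, 1)
  het[6, c("x", "y", "z")] <- mid * uB + 6.0 * vB + c(0, 0, 4)

  a <- rbind(prot, het)
  a$serial <- seq_len(nrow(a))
  a$altloc <- ""; a$icode <- ""; a$occ <- 1

  links <- c(
    ## active-site ligand to the three arms
    toy_link_line("C1", "LIG", "L", 1L, "OG", "SER", "A", 1L),
    toy_link_line("C1", "LIG", "L", 1L, "CB", "ALA", "B", 1L),
    toy_link_line("C2", "LIG", "L", 1L, "CB", "ALA", "C", 1L),
    ## planted strong pathway along arm A
    vapply(seq_len(perArm - 1L), function(j)
      toy_link_line("OG", "SER", "A", j, "OG", "SER", "A", j + 1L), ""),
    ## close the circuit: tip -> marker ligand -> back to the centre, so
    ## the planted chain carries through-flux (a dead-end branch would
    ## carry none)
    toy_link_line("OG", "SER", "A", k, "C1", "ALM", "M", 1L),
    toy_link_line("C1", "ALM", "M", 1L, "C2", "ALM", "M", 1L),
    toy_link_line("C2", "ALM", "M", 1L, "CB", "ALA", "B", 1L)
  )

  P0 <- as.matrix(a[, c("x", "y", "z")])
  jitter_sd <- if (nModels > 1L) max(noise, 0.08) else noise
  blocks <- withr::with_seed(seed, lapply(seq_len(nModels), function(m) {
    P <- P0
    if (jitter_sd > 0)
      P <- P + matrix(rnorm(length(P), 0, jitter_sd), nrow(P))
    am <- a; am$x <- P[, 1]; am$y <- P[, 2]; am$z <- P[, 3]
    lines <- pdb_atom_lines(am, rep(0, nrow(am)))
    if (nModels > 1L) c(sprintf("MODEL     %4d", m), lines, "ENDMDL")
    else lines
  }))

  txt <- paste(c("HEADER    SYNTHETIC THREE-ARM TOY PROTEIN",
                 links, unlist(blocks), "END"), collapse = "\n")
  structure(txt,
            activeLigand = "L:LIG:1",
            allostericLigand = "M:ALM:1",
            plantedSite = resid_key("A", (k - 3L):k, ""),
            decoySite = resid_key("B", (k - 3L):k, ""))
}

#' Simulate reference-set (propensity, distance, E) triplets
#'
#' Synthetic stand-in for a multi-protein reference set: each protein gets
#' a weak-bond count E, and each of its bonds a distance d uniform on
#' \code{dRange} and a propensity \eqn{\Pi = E^{-1} \exp(-decay \cdot d +
#' Normal(0, noiseSd))}. By construction the log-propensity quantile
#' planes have slope \code{-decay} in d and exactly \code{-1} in log E.
#'
#' @param nProteins number of proteins (>= 2, default 100).
#' @param bondsPerProtein bonds simulated per protein (default 200).
#' @param decay exponential distance-decay rate (default 0.3 per Angstrom).
#' @param noiseSd lognormal noise standard deviation (default 1).
#' @param eRange range the per-protein weak-bond counts are drawn from.
#' @param dRange distance range in Angstrom.
#' @param seed integer seed.
#' @return data.frame with columns \code{protein}, \code{pi}, \code{d},
#'   \code{E}.
#' @export
simulateReferenceTriplets <- function(nProteins = 100L,
                                      bondsPerProtein = 200L,
                                      decay = 0.3, noiseSd = 1,
                                      eRange = c(500L, 5000L),
                                      dRange = c(5, 40), seed = 1L) {
  stopifnot(nProteins >= 2L, bondsPerProtein >= 1L)
  withr::with_seed(seed, {
    E <- round(runif(nProteins, eRange[1], eRange[2]))
    rows <- lapply(seq_len(nProteins), function(i) {
      d <- runif(bondsPerProtein, dRange[1], dRange[2])
      pi <- exp(-decay * d + rnorm(bondsPerProtein, 0, noiseSd)) / E[i]
      data.frame(protein = i, pi = pi, d = d, E = E[i])
    })
    do.call(rbind, rows)
  })
}

#' Simulate a single-protein synthetic bond sample
#'
#' Bonds with distance d uniform on \code{dRange} and propensity
#' \eqn{\Pi = \exp(-decay \cdot d + Normal(0, noiseSd))}: the generator
#' behind the in-sample uniformity checks of the intrinsic quantile model.
#'
#' @param n number of bonds (default 2000).
#' @param decay,noiseSd,dRange,seed as in
#'   \code{\link{simulateReferenceTriplets}}.
#' @return data.frame with columns \code{pi}, \code{d}.
#' @export
simulateBondSample <- function(n = 2000L, decay = 0.3, noiseSd = 1,
                               dRange = c(5, 40), seed = 1L) {
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    d <- runif(n, dRange[1], dRange[2])
    data.frame(pi = exp(-decay * d + rnorm(n, 0, noiseSd)), d = d)
  })
}
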