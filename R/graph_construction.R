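## Construction of the energy-weighted atomistic graph and of coarse-grained
## residue-residue interaction networks (RRINs).

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")

elem_pair <- function(e1, e2) {
  paste(pmin(e1, e2), pmax(e1, e2), sep = "|")
}

covalent_energy <- function(e1, e2, cfg) {
  key <- elem_pair(e1, e2)
  en <- cfg$covalent$energies[key]
  if (anyNA(en)) {
    bad <- unique(key[is.na(en)])
    stop("no covalent dissociation energy for element pair(s): ",
         paste(bad, collapse = ", "),
         " - add them to the covalent$energies table")
  }
  unname(en)
}

sq_dist <- function(P, Q) {
  ## squared Euclidean distances between rows of P and rows of Q
  outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
}

interp_table <- function(tab, r) {
  stats::approx(tab$r, tab$e, xout = r, rule = 2)$y
}

#' Build the energy-weighted atomistic graph of a structure
#'
#' Nodes are atoms; edges are covalent bonds and weak interactions, each
#' weighted by a positive interaction energy (kJ/mol):
#' \itemize{
#'   \item Covalent bonds from per-residue topology templates for the 20
#'     standard amino acids (hydrogens attached by distance; the peptide
#'     C-N bond joins consecutive residues of a chain), with a
#'     distance-based fallback (covalent radius sum times a tolerance
#'     factor) for ligands, waters and non-standard residues. Energies come
#'     from a bond dissociation-energy table keyed by element pair.
#'   \item Hydrogen bonds by donor-H...acceptor geometry, weighted by the
#'     magnitude of a DREIDING-type 12-10 term
#'     \eqn{D_0 [5 (R_0/R)^{12} - 6 (R_0/R)^{10}] \cos^4\theta} evaluated at
#'     the donor-acceptor distance R and donor-H-acceptor angle
#'     \eqn{\theta}; repulsive candidates are dropped.
#'   \item Salt bridges between charged side-chain groups
#'     (Asp/Glu carboxylates, Lys NZ, Arg guanidinium NH, doubly protonated
#'     His, chain termini, HETATM formal charges), weighted by a screened
#'     Coulomb energy.
#'   \item Hydrophobic tethers between apolar carbon/sulphur atoms within a
#'     potential-of-mean-force range, weighted by a tabulated well depth at
#'     the observed separation.
#'   \item Electrostatic coordination edges from the PDB LINK records, with
#'     screened Coulomb weights.
#' }
#' When one atom pair qualifies for several interaction types, a single
#' edge is kept with precedence covalent > electrostatic (LINK) >
#' salt bridge > hydrogen bond > hydrophobic.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param model model index used for coordinates.
#' @param includeWaters logical; when TRUE water molecules become graph
#'   nodes (and can mediate hydrogen-bond pathways).
#' @param config parameter list from \code{\link{defaultEnergyConfig}}.
#' @param implicitHbonds logical; allows a geometric donor-acceptor
#'   fallback (no angular factor) for structures without explicit
#'   hydrogens. Structures lacking hydrogens are refused otherwise.
#' @return an \linkS4class{AtomGraph} (level "atomistic").
#' @export
buildAtomisticGraph <- function(structure, model = 1L, includeWaters = FALSE,
                                config = defaultEnergyConfig(),
                                implicitHbonds = FALSE) {
  a <- atoms(structure, model = model)
  lk <- links(structure)
  if (!includeWaters) {
    keep <- !a$isWater
    remap <- cumsum(keep)
    if (nrow(lk)) {
      dropped <- (!is.na(lk$atom1) & !keep[lk$atom1]) |
                 (!is.na(lk$atom2) & !keep[lk$atom2])
      if (any(dropped))
        warning(sum(dropped), " LINK record(s) reference excluded waters; skipped")
      lk <- lk[!dropped, , drop = FALSE]
    }
    lk$atom1 <- ifelse(is.na(lk$atom1), NA_integer_, remap[lk$atom1])
    lk$atom2 <- ifelse(is.na(lk$atom2), NA_integer_, remap[lk$atom2])
    a <- a[keep, , drop = FALSE]
    rownames(a) <- NULL
  }
  n <- nrow(a)
  if (n == 0L) stop("no atoms left to build a graph from")
  P <- as.matrix(a[, c("x", "y", "z")])
  hasH <- any(a$element == "H")

  edges <- list()
  add_edges <- function(i, j, kind, energy) {
    keep <- i != j & energy > 0 & is.finite(energy)
    if (!any(keep)) return(NULL)
    data.frame(from = pmin(i, j)[keep], to = pmax(i, j)[keep],
               kind = kind, energy = energy[keep], stringsAsFactors = FALSE)
  }

  ## ---- covalent edges -------------------------------------------------
  ci <- integer(); cj <- integer()
  res_split <- split(seq_len(n), a$resid)
  for (idx in res_split) {
    rn <- a$resname[idx[1]]
    nm <- a$name[idx]
    heavy <- idx[a$element[idx] != "H"]
    if (rn %in% names(SIDECHAIN_TEMPLATES)) {
      tmpl <- c(list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
                     c("CA", "CB")),
                SIDECHAIN_TEMPLATES[[rn]])
      for (pr in tmpl) {
        i1 <- idx[match(pr[1], nm)]; i2 <- idx[match(pr[2], nm)]
        if (!is.na(i1) && !is.na(i2)) { ci <- c(ci, i1); cj <- c(cj, i2) }
      }
    } else if (length(heavy) > 1L) {
      ## distance fallback for ligands/waters/non-standard residues
      D2 <- sq_dist(P[heavy, , drop = FALSE], P[heavy, , drop = FALSE])
      rr <- config$covalent$radii[a$element[heavy]]
      if (anyNA(rr))
        stop("no covalent radius for element(s): ",
             paste(unique(a$element[heavy][is.na(rr)]), collapse = ", "))
      lim <- (outer(rr, rr, "+") * config$covalent$radiusScale)^2
      hit <- which(D2 <= lim & upper.tri(D2), arr.ind = TRUE)
      if (nrow(hit)) {
        ci <- c(ci, heavy[hit[, 1]]); cj <- c(cj, heavy[hit[, 2]])
      }
    }
    ## attach hydrogens to the nearest heavy atom of the same residue
    hs <- idx[a$element[idx] == "H"]
    if (length(hs) && length(heavy)) {
      D2 <- sq_dist(P[hs, , drop = FALSE], P[heavy, , drop = FALSE])
      nearest <- heavy[apply(D2, 1L, which.min)]
      ok <- sqrt(D2[cbind(seq_along(hs), apply(D2, 1L, which.min))]) <= 1.6
      ci <- c(ci, hs[ok]); cj <- c(cj, nearest[ok])
    }
  }
  ## peptide bonds between consecutive residues of each chain
  res_tab <- a[!duplicated(a$resid) & !a$isWater & !a$isHetero, , drop = FALSE]
  for (ch in unique(res_tab$chain)) {
    rr <- res_tab$resid[res_tab$chain == ch]
    if (length(rr) < 2L) next
    for (k in seq_len(length(rr) - 1L)) {
      i1 <- which(a$resid == rr[k] & a$name == "C")
      i2 <- which(a$resid == rr[k + 1L] & a$name == "N")
      if (length(i1) && length(i2)) {
        d <- sqrt(sum((P[i1[1], ] - P[i2[1], ])^2))
        if (d <= config$covalent$peptideMax) {
          ci <- c(ci, i1[1]); cj <- c(cj, i2[1])
        }
      }
    }
  }
  if (length(ci)) {
    en <- covalent_energy(a$element[ci], a$element[cj], config)
    edges$covalent <- add_edges(ci, cj, "covalent", en)
  }

  ## covalent adjacency used for exclusion rules
  adj <- vector("list", n)
  if (!is.null(edges$covalent)) {
    for (k in seq_len(nrow(edges$covalent))) {
      i <- edges$covalent$from[k]; j <- edges$covalent$to[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  excluded_pair <- function(i, j) {
    ## covalently bonded (1-2) or sharing a covalent neighbour (1-3)
    mapply(function(ii, jj) {
      jj %in% adj[[ii]] || length(intersect(adj[[ii]], adj[[jj]])) > 0L
    }, i, j)
  }

  ## ---- electrostatic edges from LINK records --------------------------
  if (nrow(lk)) {
    unres <- is.na(lk$atom1) | is.na(lk$atom2)
    if (any(unres))
      warning(sum(unres), " LINK record(s) with unresolvable endpoints; skipped")
    lk2 <- lk[!unres, , drop = FALSE]
    if (nrow(lk2)) {
      q1 <- parse_formal_charge(a$charge[lk2$atom1], config$electrostatic$defaultCharge)
      q2 <- parse_formal_charge(a$charge[lk2$atom2], config$electrostatic$defaultCharge)
      d <- sqrt(rowSums((P[lk2$atom1, , drop = FALSE] -
                         P[lk2$atom2, , drop = FALSE])^2))
      en <- config$kCoulomb * abs(q1 * q2) / (config$electrostatic$dielectric * d)
      edges$electrostatic <- add_edges(lk2$atom1, lk2$atom2, "electrostatic", en)
    }
  }

  ## ---- salt bridges ----------------------------------------------------
  q <- atom_charges(a, adj)
  pos <- which(q > 0 & a$element %in% c("N", "O"))
  neg <- which(q < 0 & a$element %in% c("N", "O"))
  if (length(pos) && length(neg)) {
    D2 <- sq_dist(P[pos, , drop = FALSE], P[neg, , drop = FALSE])
    hit <- which(D2 <= config$saltbridge$maxDist^2, arr.ind = TRUE)
    if (nrow(hit)) {
      i <- pos[hit[, 1]]; j <- neg[hit[, 2]]
      ok <- !excluded_pair(i, j)
      i <- i[ok]; j <- j[ok]
      if (length(i)) {
        d <- sqrt(rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2))
        en <- config$kCoulomb * abs(q[i] * q[j]) /
          (config$saltbridge$dielectric * pmax(d, 0.5))
        edges$saltbridge <- add_edges(i, j, "saltbridge", en)
      }
    }
  }

  ## ---- hydrogen bonds --------------------------------------------------
  hb <- config$hbond
  acc <- which(a$element %in% c("N", "O"))
  if (hasH) {
    hyd <- which(a$element == "H")
    donor_of <- vapply(hyd, function(h) {
      nb <- adj[[h]]
      nb <- nb[a$element[nb] %in% c("N", "O", "S")]
      if (length(nb)) nb[1] else NA_integer_
    }, 1L)
    ok <- !is.na(donor_of)
    hyd <- hyd[ok]; donor_of <- donor_of[ok]
    if (length(hyd) && length(acc)) {
      D2 <- sq_dist(P[donor_of, , drop = FALSE], P[acc, , drop = FALSE])
      hit <- which(D2 <= hb$maxDA^2 & D2 > 1e-6, arr.ind = TRUE)
      if (nrow(hit)) {
        hI <- hyd[hit[, 1]]; dI <- donor_of[hit[, 1]]; aI <- acc[hit[, 2]]
        keep <- dI != aI & !excluded_pair(dI, aI) & aI != hI
        hI <- hI[keep]; dI <- dI[keep]; aI <- aI[keep]
        if (length(dI)) {
          v1 <- P[dI, , drop = FALSE] - P[hI, , drop = FALSE]
          v2 <- P[aI, , drop = FALSE] - P[hI, , drop = FALSE]
          cosq <- rowSums(v1 * v2) /
            (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
          theta <- acos(pmin(1, pmax(-1, cosq))) * 180 / pi
          R <- sqrt(rowSums((P[dI, , drop = FALSE] - P[aI, , drop = FALSE])^2))
          x <- (hb$R0 / R)
          en <- hb$D0 * (6 * x^10 - 5 * x^12) * cosq^4
          keep2 <- theta >= hb$minAngle & en > 0
          if (any(keep2)) {
            df <- data.frame(from = pmin(dI, aI)[keep2],
                             to = pmax(dI, aI)[keep2],
                             kind = "hbond", energy = en[keep2],
                             stringsAsFactors = FALSE)
            ## several hydrogens can serve one donor-acceptor pair: keep max
            key <- paste(df$from, df$to)
            df <- df[order(key, -df$energy), , drop = FALSE]
            edges$hbond <- df[!duplicated(paste(df$from, df$to)), , drop = FALSE]
          }
        }
      }
    }
  } else {
    if (!implicitHbonds)
      stop("structure has no hydrogens: protonate it first, or set ",
           "implicitHbonds = TRUE for a geometric donor-acceptor fallback")
    if (length(acc) > 1L) {
      D2 <- sq_dist(P[acc, , drop = FALSE], P[acc, , drop = FALSE])
      hit <- which(D2 <= hb$maxDA^2 & upper.tri(D2), arr.ind = TRUE)
      if (nrow(hit)) {
        i <- acc[hit[, 1]]; j <- acc[hit[, 2]]
        keep <- a$resid[i] != a$resid[j] & !excluded_pair(i, j)
        i <- i[keep]; j <- j[keep]
        if (length(i)) {
          R <- sqrt(rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2))
          x <- hb$R0 / R
          en <- hb$D0 * (6 * x^10 - 5 * x^12)
          edges$hbond <- add_edges(i, j, "hbond", en)
        }
      }
    }
  }

  ## ---- hydrophobic tethers --------------------------------------------
  hp <- config$hydrophobic
  apolar <- which(vapply(seq_len(n), function(i) {
    a$element[i] %in% c("C", "S") &&
      !any(a$element[adj[[i]]] %in% c("N", "O"))
  }, TRUE))
  if (length(apolar) > 1L) {
    D2 <- sq_dist(P[apolar, , drop = FALSE], P[apolar, , drop = FALSE])
    hit <- which(D2 >= hp$rmin^2 & D2 <= hp$rmax^2 & upper.tri(D2),
                 arr.ind = TRUE)
    if (nrow(hit)) {
      i <- apolar[hit[, 1]]; j <- apolar[hit[, 2]]
      keep <- a$resid[i] != a$resid[j]
      i <- i[keep]; j <- j[keep]
      if (length(i)) {
        d <- sqrt(rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2))
        en <- interp_table(hp$table, d)
        edges$hydrophobic <- add_edges(i, j, "hydrophobic", en)
      }
    }
  }

  ## ---- assemble with precedence ---------------------------------------
  order_kinds <- c("covalent", "electrostatic", "saltbridge", "hbond",
                   "hydrophobic")
  all_edges <- do.call(rbind, edges[intersect(order_kinds, names(edges))])
  if (is.null(all_edges) || nrow(all_edges) == 0L)
    stop("no bonds found - check the structure and configuration")
  dup <- duplicated(pair_key(all_edges$from, all_edges$to))
  all_edges <- all_edges[!dup, , drop = FALSE]
  rownames(all_edges) <- NULL

  make_atom_graph(a, P, all_edges, level = "atomistic")
}

make_atom_graph <- function(nodes, P, e, level) {
  e$id <- seq_len(nrow(e))
  mid <- (P[e$from, , drop = FALSE] + P[e$to, , drop = FALSE]) / 2
  e$mx <- mid[, 1]; e$my <- mid[, 2]; e$mz <- mid[, 3]
  e$res1 <- nodes$resid[e$from]
  e$res2 <- nodes$resid[e$to]
  e$weak <- e$kind != "covalent"
  e <- e[, c("id", "from", "to", "kind", "energy", "mx", "my", "mz",
             "res1", "res2", "weak")]
  rownames(nodes) <- NULL
  new("AtomGraph", nodes = nodes, bonds = e, level = level)
}

parse_formal_charge <- function(ch, default) {
  out <- rep(default, length(ch))
  has <- !is.na(ch) & nzchar(trimws(ch))
  if (any(has)) {
    s <- trimws(ch[has])
    ## PDB charge column style "1+", "2-"; also tolerate "+1"
    num <- suppressWarnings(as.numeric(gsub("[+-]", "", s)))
    sgn <- ifelse(grepl("-", s, fixed = TRUE), -1, 1)
    val <- num * sgn
    out[has] <- ifelse(is.na(val), default, val)
  }
  out
}

atom_charges <- function(a, adj) {
  q <- numeric(nrow(a))
  for (rn in names(CHARGED_GROUPS)) {
    grp <- CHARGED_GROUPS[[rn]]
    for (nm in names(grp)) {
      hit <- which(a$resname == rn & a$name == nm)
      q[hit] <- q[hit] + grp[[nm]]
    }
  }
  ## doubly protonated histidines carry +1 split over the ring nitrogens
  his <- unique(a$resid[a$resname == "HIS"])
  for (r in his) {
    idx <- which(a$resid == r)
    nm <- a$name[idx]
    if (all(c("HD1", "HE2") %in% nm)) {
      q[idx[nm == "ND1"]] <- q[idx[nm == "ND1"]] + 0.5
      q[idx[nm == "NE2"]] <- q[idx[nm == "NE2"]] + 0.5
    }
  }
  ## termini: N-terminal amine +1, C-terminal carboxylate -1 on OXT
  std <- a$resname %in% names(SIDECHAIN_TEMPLATES)
  for (ch in unique(a$chain[std])) {
    idx <- which(std & a$chain == ch)
    first <- a$resid[idx[1]]
    nt <- idx[a$resid[idx] == first & a$name[idx] == "N"]
    q[nt] <- q[nt] + 1
  }
  q[std & a$name == "OXT"] <- q[std & a$name == "OXT"] - 1
  ## HETATM formal charges from the PDB charge column
  het <- which(a$isHetero & !a$isWater & nzchar(trimws(a$charge)))
  if (length(het)) q[het] <- parse_formal_charge(a$charge[het], 0)
  q
}

#' Build a coarse-grained residue-residue interaction network
#'
#' One node per residue (placed at the C-alpha atom; centroid fallback with
#' a warning), with a unit-weight edge between residues having any
#' heavy-atom pair within \code{cutoff}. Consecutive backbone neighbours of
#' a chain are always connected and marked covalent; all other contacts are
#' weak "rrin-contact" edges.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param cutoff contact cutoff in Angstrom (default 6).
#' @param model model index.
#' @param includeHetero include non-water HETATM residues (e.g. ligands) as
#'   nodes, so that active-site source bonds exist at the residue level.
#' @param includeWaters include waters as nodes.
#' @return an \linkS4class{AtomGraph} (level "rrin").
#' @export
buildRRIN <- function(structure, cutoff = 6, model = 1L,
                      includeHetero = TRUE, includeWaters = FALSE) {
  stopifnot(cutoff > 0)
  a <- atoms(structure, model = model)
  keep <- (!a$isWater | includeWaters) & (!a$isHetero | includeHetero | a$isWater)
  a <- a[keep, , drop = FALSE]
  heavy <- a[a$element != "H", , drop = FALSE]
  rids <- unique(a$resid)
  pos <- matrix(NA_real_, length(rids), 3)
  nocA <- character()
  for (k in seq_along(rids)) {
    idx <- which(heavy$resid == rids[k])
    ca <- idx[heavy$name[idx] == "CA" & heavy$element[idx] == "C"]
    if (length(ca)) {
      pos[k, ] <- as.numeric(heavy[ca[1], c("x", "y", "z")])
    } else {
      nocA <- c(nocA, rids[k])
      pos[k, ] <- colMeans(heavy[idx, c("x", "y", "z"), drop = FALSE])
    }
  }
  if (length(nocA))
    warning("no C-alpha for residue(s) ", paste(nocA, collapse = ", "),
            "; using heavy-atom centroid")

  hp <- as.matrix(heavy[, c("x", "y", "z")])
  rix <- match(heavy$resid, rids)
  D2 <- sq_dist(hp, hp)
  hit <- which(D2 <= cutoff^2 & upper.tri(D2), arr.ind = TRUE)
  ef <- rix[hit[, 1]]; et <- rix[hit[, 2]]
  ok <- ef != et
  prs <- unique(pair_key(ef[ok], et[ok]))

  ## consecutive backbone neighbours always connected
  prot <- a[!a$isWater & !a$isHetero, , drop = FALSE]
  backbone <- character()
  for (ch in unique(prot$chain)) {
    rr <- unique(prot$resid[prot$chain == ch])
    if (length(rr) > 1L) {
      i1 <- match(rr[-length(rr)], rids); i2 <- match(rr[-1], rids)
      backbone <- c(backbone, pair_key(i1, i2))
    }
  }
  prs <- union(prs, backbone)
  ft <- do.call(rbind, strsplit(prs, "|", fixed = TRUE))
  e <- data.frame(from = as.integer(ft[, 1]), to = as.integer(ft[, 2]),
                  kind = ifelse(prs %in% backbone, "covalent", "rrin-contact"),
                  energy = 1, stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), , drop = FALSE]

  nodes <- data.frame(
    serial = seq_along(rids), name = "RES",
    resname = a$resname[match(rids, a$resid)],
    chain = a$chain[match(rids, a$resid)],
    resno = a$resno[match(rids, a$resid)],
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    element = "X", resid = rids, stringsAsFactors = FALSE
  )
  make_atom_graph(nodes, pos, e, level = "rrin")
}

#' Randomly perturb weak-bond energies
#'
#' Multiplies every weak-bond energy by an independent lognormal factor with
#' mean 1 and the requested relative standard deviation; covalent energies
#' are untouched. A robustness utility: propensity rankings should be stable
#' under moderate energy noise.
#'
#' @param graph an \linkS4class{AtomGraph}.
#' @param relativeSd relative standard deviation of the multiplicative
#'   factors (0 leaves the graph unchanged).
#' @param seed optional integer seed (reproducible, leaves the global RNG
#'   state untouched).
#' @return a perturbed \linkS4class{AtomGraph}.
#' @export
perturbEnergies <- function(graph, relativeSd, seed = NULL) {
  if (!is.numeric(relativeSd) || length(relativeSd) != 1L || relativeSd < 0)
    stop("relativeSd must be a single non-negative number")
  if (relativeSd == 0) return(graph)
  b <- graph@bonds
  nw <- sum(b$weak)
  sdlog <- sqrt(log(1 + relativeSd^2))
  draw <- function() rlnorm(nw, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  fac <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  b$energy[b$weak] <- b$energy[b$weak] * fac
  initialize(graph, bonds = b)
}

#' Export a graph as an edge-list CSV
#'
#' @param graph an \linkS4class{AtomGraph}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
exportGraph <- function(graph, path) {
  b <- graph@bonds
  nd <- graph@nodes
  out <- data.frame(
    bond = b$id,
    atom1 = nd$serial[b$from], name1 = nd$name[b$from], res1 = b$res1,
    atom2 = nd$serial[b$to], name2 = nd$name[b$to], res2 = b$res2,
    kind = b$kind, energy = b$energy,
    mx = b$mx, my = b$my, mz = b$mz
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
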