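## PDB reading/writing and site selection.

WATER_NAMES <- c("HOH", "WAT", "H2O", "DOD")

resid_key <- function(chain, resno, icode) {
  ic <- ifelse(is.na(icode) | icode == "", "", icode)
  ch <- ifelse(is.na(chain) | chain == "", "_", chain)
  paste0(ch, ":", resno, ic)
}

#' Read a protein structure from PDB text or a PDB file
#'
#' Parses ATOM/HETATM/MODEL/LINK records. One model is created per MODEL
#' block (a single model when none are present). Waters are flagged by
#' residue name (HOH/WAT/H2O/DOD). Alternate locations are resolved by
#' keeping the highest-occupancy conformer, ties broken alphabetically
#' (so 'A' wins a tie). Atom parsing is delegated to \pkg{bio3d}; LINK
#' records, which bio3d does not expose, are scanned from the raw text.
#'
#' @param input either a path to a PDB file or a character scalar containing
#'   PDB-format text (recognised by embedded newlines).
#' @param id optional identifier stored in the object.
#' @return a \linkS4class{ProteinStructure}.
#' @export
readStructure <- function(input, id = NULL) {
  stopifnot(is.character(input), length(input) == 1L)
  if (grepl("\n", input, fixed = TRUE)) {
    txt <- strsplit(input, "\n", fixed = TRUE)[[1]]
    path <- tempfile(fileext = ".pdb")
    writeLines(txt, path)
    on.exit(unlink(path))
    if (is.null(id)) id <- "pdb-text"
  } else {
    path <- input
    if (!file.exists(path)) stop("no such file: ", path)
    txt <- readLines(path, warn = FALSE)
    if (is.null(id)) id <- basename(path)
  }

  nmodels <- max(1L, sum(grepl("^MODEL", txt)))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = nmodels > 1L,
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error: ", conditionMessage(e))
  )
  a <- pdb$atom
  if (nrow(a) == 0L) stop("empty structure: no ATOM/HETATM records parsed")
  if (anyNA(a$x) || anyNA(a$y) || anyNA(a$z)) {
    bad <- which(is.na(a$x) | is.na(a$y) | is.na(a$z))[1]
    stop("malformed coordinate fields for atom serial ", a$eleno[bad])
  }

  element <- a$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(a))
  element <- toupper(trimws(element))
  miss <- is.na(element) | element == ""
  if (any(miss)) element[miss] <- element_from_name(a$elety[miss])

  atoms <- data.frame(
    serial = a$eleno,
    name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o),
    bfactor = ifelse(is.na(a$b), 0, a$b),
    element = element,
    charge = ifelse(is.na(a$charge), "", a$charge),
    isHetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$isWater <- atoms$resname %in% WATER_NAMES
  atoms$resid <- resid_key(atoms$chain, atoms$resno, atoms$icode)

  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)

  ## altloc policy: highest occupancy wins, ties alphabetical
  keep <- resolve_altlocs(atoms)
  atoms <- atoms[keep, , drop = FALSE]
  cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
  xyz <- xyz[, cols, drop = FALSE]
  rownames(atoms) <- NULL

  links <- parse_link_records(txt, atoms)

  new("ProteinStructure",
      atoms = atoms, xyz = xyz, links = links, id = id,
      hasHydrogens = any(atoms$element == "H"))
}

element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA",
                          "CU", "NI", "CO", "SE"),
               two, substr(gsub("^[0-9]+", "", nm), 1, 1))
  ## atom names like "1HB" or "HG1" are hydrogens
  el
}

resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name)
  keep <- rep(TRUE, nrow(atoms))
  for (idx in split(seq_len(nrow(atoms)), key)) {
    if (length(idx) > 1L) {
      ord <- order(-atoms$occ[idx], atoms$altloc[idx])
      keep[idx[-ord[1]]] <- FALSE
    }
  }
  which(keep)
}

parse_link_records <- function(txt, atoms) {
  ln <- txt[startsWith(txt, "LINK")]
  empty <- data.frame(
    name1 = character(), resname1 = character(), chain1 = character(),
    resno1 = integer(), icode1 = character(),
    name2 = character(), resname2 = character(), chain2 = character(),
    resno2 = integer(), icode2 = character(),
    dist = numeric(), atom1 = integer(), atom2 = integer(),
    stringsAsFactors = FALSE
  )
  if (!length(ln)) return(empty)
  fld <- function(s, a, b) trimws(substr(s, a, b))
  out <- data.frame(
    name1 = fld(ln, 13, 16), resname1 = fld(ln, 18, 20),
    chain1 = fld(ln, 22, 22), resno1 = suppressWarnings(as.integer(fld(ln, 23, 26))),
    icode1 = fld(ln, 27, 27),
    name2 = fld(ln, 43, 46), resname2 = fld(ln, 48, 50),
    chain2 = fld(ln, 52, 52), resno2 = suppressWarnings(as.integer(fld(ln, 53, 56))),
    icode2 = fld(ln, 57, 57),
    dist = suppressWarnings(as.numeric(fld(ln, 74, 78))),
    stringsAsFactors = FALSE
  )
  find_atom <- function(name, chain, resno, icode) {
    hit <- which(atoms$name == name & atoms$chain == chain &
                 atoms$resno == resno & atoms$icode == icode)
    if (length(hit)) hit[1] else NA_integer_
  }
  out$atom1 <- mapply(find_atom, out$name1, out$chain1, out$resno1, out$icode1)
  out$atom2 <- mapply(find_atom, out$name2, out$chain2, out$resno2, out$icode2)
  out
}

#' Construct a site specification
#'
#' @param ligand a data.frame (or list coercible to one) with columns
#'   \code{chain}, \code{resname}, \code{resno}, one row per ligand residue;
#'   or a character vector of "CHAIN:RESNAME:RESNO" strings.
#' @param residues character vector of residue keys (\code{chain:resno}),
#'   used instead of a ligand selection.
#' @param contactCutoff contact distance in Angstrom for residue selection
#'   around the ligand (default 3.5).
#' @return a \linkS4class{SiteSpec}.
#' @export
siteSpec <- function(ligand = NULL, residues = NULL, contactCutoff = 3.5) {
  if (!is.null(ligand)) {
    if (is.character(ligand)) {
      parts <- strsplit(ligand, ":", fixed = TRUE)
      bad <- lengths(parts) != 3L
      if (any(bad)) stop("ligand strings must be CHAIN:RESNAME:RESNO")
      ligand <- data.frame(
        chain = vapply(parts, `[`, "", 1L),
        resname = vapply(parts, `[`, "", 2L),
        resno = as.integer(vapply(parts, `[`, "", 3L)),
        stringsAsFactors = FALSE
      )
    }
    ligand <- as.data.frame(ligand, stringsAsFactors = FALSE)
    new("SiteSpec", mode = "ligand", ligand = ligand,
        residues = character(), contactCutoff = contactCutoff)
  } else if (!is.null(residues)) {
    new("SiteSpec", mode = "residues", ligand = data.frame(),
        residues = as.character(residues), contactCutoff = contactCutoff)
  } else stop("supply either a ligand selection or a residue list")
}

ligand_atom_idx <- function(atoms, spec) {
  hit <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(spec@ligand))) {
    l <- spec@ligand[i, ]
    hit <- hit | (atoms$chain == l$chain & atoms$resname == l$resname &
                  atoms$resno == l$resno)
  }
  which(hit)
}

#' Select residues in contact with a ligand site
#'
#' Returns the residues having at least one non-hydrogen atom within
#' \code{contactCutoff} of at least one ligand atom. The ligand's own
#' residues are excluded.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param site a \linkS4class{SiteSpec}; in "residues" mode the residue list
#'   is returned as-is (after checking it resolves).
#' @param model model index used for coordinates.
#' @return sorted character vector of residue keys.
#' @export
selectSiteResidues <- function(structure, site, model = 1L) {
  a <- atoms(structure, model = model)
  if (site@mode == "residues") {
    missing <- setdiff(site@residues, a$resid)
    if (length(missing))
      stop("residues not found in structure: ", paste(missing, collapse = ", "))
    return(sort(unique(site@residues)))
  }
  li <- ligand_atom_idx(a, site)
  if (!length(li)) {
    het <- unique(paste(a$chain[a$isHetero], a$resname[a$isHetero],
                        a$resno[a$isHetero], sep = ":"))
    stop("ligand selection resolves to no atoms; HETATM residues present: ",
         paste(het, collapse = ", "))
  }
  lig_res <- unique(a$resid[li])
  cand <- which(a$element != "H" & !(a$resid %in% lig_res))
  if (!length(cand)) return(character())
  lx <- as.matrix(a[li, c("x", "y", "z")])
  cx <- as.matrix(a[cand, c("x", "y", "z")])
  ## squared distances candidate x ligand
  d2 <- outer(rowSums(cx^2), rowSums(lx^2), "+") - 2 * cx %*% t(lx)
  near <- rowSums(d2 <= site@contactCutoff^2 + 1e-12) > 0
  sort(unique(a$resid[cand[near]]))
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Residues found in \code{scores} receive their score (2-decimal fixed
#' width); all others get 0.00. Useful for colouring structures by quantile
#' score in molecular viewers.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param scores named numeric vector; names are residue keys
#'   (\code{chain:resno}).
#' @param path output file path.
#' @param model model index to write.
#' @return invisibly, the path.
#' @export
writeScoredPDB <- function(structure, scores, path, model = 1L) {
  if (length(scores) && (is.null(names(scores)) || any(!is.finite(scores))))
    stop("scores must be a named, finite numeric vector")
  a <- atoms(structure, model = model)
  b <- rep(0, nrow(a))
  hit <- match(a$resid, names(scores))
  b[!is.na(hit)] <- scores[hit[!is.na(hit)]]
  lines <- pdb_atom_lines(a, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

pdb_atom_lines <- function(a, bfac) {
  rec <- ifelse(a$isHetero, "HETATM", "ATOM  ")
  ## PDB atom-name column convention: names of <4 chars for 1-2 letter
  ## elements start in column 14
  nm <- vapply(seq_along(a$name), function(i) {
    n <- a$name[i]
    if (nchar(n) >= 4L) substr(n, 1, 4)
    else if (nchar(a$element[i]) == 2L) sprintf("%-4s", n)
    else sprintf(" %-3s", n)
  }, "")
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, a$serial %% 100000L, nm,
          substr(a$altloc, 1, 1), substr(a$resname, 1, 3),
          substr(a$chain, 1, 1), a$resno %% 10000L, substr(a$icode, 1, 1),
          a$x, a$y, a$z, a$occ, bfac, a$element)
}

#' Export residue selections or scores as CSV
#'
#' @param x a character vector of residue keys or a data.frame.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
exportSelection <- function(x, path) {
  if (is.character(x)) x <- data.frame(resid = x, stringsAsFactors = FALSE)
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
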