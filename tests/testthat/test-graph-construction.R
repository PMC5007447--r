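toy_structure <- function(...) readStructure(makeToyProteinPDB(...))

test_that("atomistic graph has covalent backbone, H-bond ladder and LINK edges", {
  s <- toy_structure(seed = 11L)
  g <- buildAtomisticGraph(s)
  b <- bonds(g)
  expect_s4_class(g, "AtomGraph")
  expect_setequal(unique(b$kind),
                  c("covalent", "electrostatic", "hbond", "hydrophobic"))
  expect_true(all(b$energy > 0))
  expect_identical(b$weak, b$kind != "covalent")
  ## no duplicate undirected edges
  expect_false(anyDuplicated(paste(b$from, b$to)) > 0)
  ## every protein residue is covalently wired internally (N-CA present)
  n1 <- which(nodes(g)$resid == "A:5" & nodes(g)$name == "N")
  ca <- which(nodes(g)$resid == "A:5" & nodes(g)$name == "CA")
  expect_true(any((b$from == min(n1, ca) & b$to == max(n1, ca))))
})

test_that("DREIDING hydrogen-bond energies match a hand evaluation", {
  s <- toy_structure(seed = 11L)
  g <- buildAtomisticGraph(s)
  b <- bonds(g)
  a <- nodes(g)
  ## the arm ladder bond N(A:5)...O(A:3) has known exact geometry:
  ## R = |(-2.955, 0.615)| and a perfectly linear donor-H-acceptor angle
  i <- which(a$resid == "A:5" & a$name == "N")
  j <- which(a$resid == "A:3" & a$name == "O")
  row <- b[b$from == min(i, j) & b$to == max(i, j), ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$kind, "hbond")
  R <- sqrt(2.955^2 + 0.615^2)
  x <- 2.75 / R
  expect_equal(row$energy, 39.7 * (6 * x^10 - 5 * x^12), tolerance = 1e-6)
})

test_that("LINK records become electrostatic edges with screened Coulomb weights", {
  s <- toy_structure(seed = 11L)
  g <- buildAtomisticGraph(s)
  b <- bonds(g)
  a <- nodes(g)
  i <- which(a$resid == "A:4" & a$name == "OG")
  j <- which(a$resid == "A:5" & a$name == "OG")
  row <- b[b$from == min(i, j) & b$to == max(i, j), ]
  expect_equal(row$kind, "electrostatic")
  expect_equal(row$energy, 1389.35 / (4 * 3.5), tolerance = 1e-6)
})

test_that("hydrophobic tethers only join apolar carbons in range", {
  s <- toy_structure(seed = 11L)
  g <- buildAtomisticGraph(s)
  b <- bonds(g)
  a <- nodes(g)
  hyd <- b[b$kind == "hydrophobic", ]
  expect_gt(nrow(hyd), 0L)
  expect_true(all(a$element[hyd$from] %in% c("C", "S")))
  expect_true(all(a$element[hyd$to] %in% c("C", "S")))
  ## serine CB carries a covalent oxygen (OG) and must never be apolar
  serCB <- which(a$name == "CB" & a$resname == "SER")
  expect_false(any(c(hyd$from, hyd$to) %in% serCB))
  d <- sqrt((a$x[hyd$from] - a$x[hyd$to])^2 + (a$y[hyd$from] - a$y[hyd$to])^2 +
            (a$z[hyd$from] - a$z[hyd$to])^2)
  expect_true(all(d >= 3.8 - 1e-9 & d <= 8 + 1e-9))
})

test_that("water handling: excluded by default, included on request", {
  s <- toy_structure(seed = 11L)
  g0 <- buildAtomisticGraph(s)
  g1 <- buildAtomisticGraph(s, includeWaters = TRUE)
  expect_equal(nrow(nodes(g1)), nrow(nodes(g0)) + 2L)
  expect_false(any(nodes(g0)$isWater))
  expect_true(any(nodes(g1)$isWater))
})

test_that("structures without hydrogens are refused unless implicit mode", {
  txt <- makeToyProteinPDB(seed = 11L)
  ## strip hydrogen atoms (element column) from the PDB text
  ln <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  isH <- startsWith(ln, "ATOM") & trimws(substr(ln, 77, 78)) == "H"
  noH <- readStructure(paste(ln[!isH], collapse = "\n"))
  expect_false(hasHydrogens(noH))
  expect_error(buildAtomisticGraph(noH), "hydrogens")
  g <- buildAtomisticGraph(noH, implicitHbonds = TRUE)
  expect_true(any(bonds(g)$kind == "hbond"))
})

test_that("unknown covalent element pairs fail with an actionable error", {
  cfg <- defaultEnergyConfig()
  expect_error(bondprop:::covalent_energy("C", "XX", cfg), "C\\|XX")
})

test_that("RRIN places nodes at C-alpha with unit contact edges", {
  s <- toy_structure(seed = 11L)
  ## hetero residues have no C-alpha; the fallback is announced
  expect_warning(g <- buildRRIN(s, cutoff = 6), "heavy-atom centroid")
  nd <- nodes(g)
  b <- bonds(g)
  expect_equal(g@level, "rrin")
  ## one node per non-water residue (ligand + marker included)
  expect_equal(nrow(nd), 45L + 2L)
  expect_true(all(b$energy == 1))
  ## consecutive backbone neighbours are covalent (non-weak)
  i <- which(nd$resid == "B:3"); j <- which(nd$resid == "B:4")
  row <- b[b$from == min(i, j) & b$to == max(i, j), ]
  expect_equal(row$kind, "covalent")
  ## C-alpha coordinates: node of A:2 sits at (0.5 + 3.5*2, 0, 0)
  k <- which(nd$resid == "A:2")
  expect_equal(c(nd$x[k], nd$y[k], nd$z[k]), c(7.5, 0, 0))
})

test_that("perturbEnergies only touches weak bonds, reproducibly", {
  s <- toy_structure(seed = 11L)
  g <- buildAtomisticGraph(s)
  p1 <- perturbEnergies(g, 0.2, seed = 4L)
  p2 <- perturbEnergies(g, 0.2, seed = 4L)
  expect_equal(bonds(p1)$energy, bonds(p2)$energy)
  w <- bonds(g)$weak
  expect_equal(bonds(p1)$energy[!w], bonds(g)$energy[!w])
  expect_false(all(bonds(p1)$energy[w] == bonds(g)$energy[w]))
  expect_identical(perturbEnergies(g, 0), g)
  expect_error(perturbEnergies(g, -1), "non-negative")
})
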