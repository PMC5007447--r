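test_that("PDB text round-trips with atoms, waters, hetero flags and LINKs", {
  txt <- makeToyProteinPDB(seed = 11L)
  s <- readStructure(txt)
  a <- atoms(s)
  expect_s4_class(s, "ProteinStructure")
  expect_true(hasHydrogens(s))
  expect_equal(nModels(s), 1L)
  expect_equal(sum(a$isWater), 2L)
  expect_equal(sum(a$isHetero), 6L)
  expect_true(all(c("SER", "ALA", "LIG", "ALM", "HOH") %in% a$resname))
  lk <- links(s)
  expect_gt(nrow(lk), 0L)
  expect_false(anyNA(lk$atom1))
  expect_false(anyNA(lk$atom2))
  ## resolved LINK endpoints agree with the named atoms
  expect_equal(a$name[lk$atom1], lk$name1)
  expect_equal(a$chain[lk$atom2], lk$chain2)
})

test_that("multi-model structures expose per-model coordinates", {
  txt <- makeToyProteinPDB(nModels = 3L, seed = 7L)
  s <- readStructure(txt)
  expect_equal(nModels(s), 3L)
  a1 <- atoms(s, model = 1L)
  a3 <- atoms(s, model = 3L)
  expect_equal(a1$name, a3$name)
  expect_false(all(a1$x == a3$x))
  expect_error(atoms(s, model = 4L), "not present")
})

test_that("alternate locations resolve to highest occupancy, ties to A", {
  mk <- function(alt, occ, x) {
    sprintf("ATOM      1  CA %sALA A   1    %8.3f   0.000   0.000%6.2f  0.00           C",
            alt, x, occ)
  }
  txt <- paste(c(mk("A", 0.4, 1), mk("B", 0.6, 2),
                 sub(" CA ", " CB ", mk("B", 0.5, 3)),
                 sub(" CA ", " CB ", mk("A", 0.5, 4)), "END"), collapse = "\n")
  s <- readStructure(txt)
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$name == "CA"], 2)   # occupancy 0.6 wins
  expect_equal(a$x[a$name == "CB"], 4)   # tie: altloc A wins
})

test_that("malformed input fails with actionable messages", {
  expect_error(readStructure("/no/such/file.pdb"), "no such file")
  expect_error(readStructure("REMARK only\nEND\n"), "empty structure|parse")
})

test_that("siteSpec parses CHAIN:RESNAME:RESNO strings and validates", {
  sp <- siteSpec(ligand = "L:LIG:1")
  expect_s4_class(sp, "SiteSpec")
  expect_equal(sp@ligand$resno, 1L)
  expect_error(siteSpec(ligand = "L:LIG"), "CHAIN:RESNAME:RESNO")
  expect_error(siteSpec(), "supply either")
})

test_that("selectSiteResidues finds the pocket and errors helpfully", {
  txt <- makeToyProteinPDB(seed = 11L)
  s <- readStructure(txt)
  sel <- selectSiteResidues(s, siteSpec(ligand = attr(txt, "allostericLigand")))
  expect_identical(sel, attr(txt, "plantedSite"))
  ## unknown ligand lists the available HETATM residues
  expect_error(selectSiteResidues(s, siteSpec(ligand = "X:FOO:9")),
               "L:LIG:1")
  ## residue mode passes through, unknown keys error
  expect_identical(
    selectSiteResidues(s, siteSpec(residues = c("A:2", "A:1"))),
    c("A:1", "A:2"))
  expect_error(selectSiteResidues(s, siteSpec(residues = "Z:99")),
               "not found")
})

test_that("writeScoredPDB writes scores into the B-factor column", {
  txt <- makeToyProteinPDB(seed = 11L)
  s <- readStructure(txt)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeScoredPDB(s, c("A:1" = 0.87, "B:2" = 0.25), path)
  s2 <- readStructure(path)
  a2 <- atoms(s2)
  expect_equal(unique(a2$bfactor[a2$resid == "A:1"]), 0.87)
  expect_equal(unique(a2$bfactor[a2$resid == "B:2"]), 0.25)
  expect_equal(unique(a2$bfactor[a2$resid == "A:3"]), 0)
  expect_equal(nrow(a2), nrow(atoms(s)))
  expect_error(writeScoredPDB(s, c(0.5, 0.2), path), "named")
})
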