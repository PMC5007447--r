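test_that("Laplacian solves satisfy the contract on each component", {
  g <- makeToyGraph("random-connected", n = 40L, weights = "random", seed = 2L)
  sys <- graphLaplacian(g)
  expect_equal(sys@nComponents, 1L)
  expect_equal(Matrix::rowSums(sys@L), rep(0, 40), tolerance = 1e-12)
  b <- bonds(g)
  rhs <- numeric(40); rhs[b$from[1]] <- 1; rhs[b$to[1]] <- -1
  x <- solveOnComponent(sys, rhs)
  expect_lt(sqrt(sum((as.numeric(sys@L %*% x) - rhs)^2)) / sqrt(2), 1e-10)
  expect_equal(mean(x), 0, tolerance = 1e-12)   # minimum-norm solution
  ## unbalanced right-hand sides are rejected
  expect_error(solveOnComponent(sys, c(1, numeric(39))), "sum to zero")
})

test_that("transfer columns: single-edge and triangle closed forms", {
  e <- makeToyGraph("edge")
  M <- transferColumns(e, 1L)
  expect_equal(as.numeric(M), 1)
  tri <- makeToyGraph("triangle")
  M <- transferColumns(tri, 1L)   # source edge (1,2); unit weights
  b <- bonds(tri)
  src <- which(b$from == 1L & b$to == 2L)
  expect_equal(unname(M[src, 1]), 2 / 3, tolerance = 1e-12)
  expect_equal(sort(abs(as.numeric(M[-src, 1]))), c(1 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("edges of a tree beyond the source carry no flux", {
  g <- makeToyGraph("path", n = 12L)
  M <- transferColumns(g, 1L)
  expect_equal(abs(unname(M[1, 1])), 1, tolerance = 1e-10)
  expect_equal(as.numeric(M[-1, 1]), rep(0, 10), tolerance = 1e-10)
})

test_that("bondPropensity output is internally consistent", {
  g <- makeToyGraph("random-connected", n = 50L, weights = "random", seed = 5L)
  res <- bondPropensity(g, "A:7")
  b <- bonds(res)
  expect_equal(sum(b$norm[b$scored]), 1, tolerance = 1e-9)
  expect_true(all(b$norm[b$scored] >= 0))
  expect_true(all(is.na(b$norm[!b$scored])))
  ## residue propensities equal the sum over incident scored bonds
  r <- residues(res)
  sc <- b[b$scored, ]
  manual <- sum(sc$norm[sc$res1 == "A:3" | sc$res2 == "A:3"])
  expect_equal(r$propensity[r$resid == "A:3"], manual, tolerance = 1e-12)
  expect_equal(residuePropensity(res), r)
  ## distances are midpoint distances to the nearest source bond
  src <- b[b$isSource, ]
  k <- which(b$scored)[1]
  d2 <- (b$mx[k] - src$mx)^2 + (b$my[k] - src$my)^2 + (b$mz[k] - src$mz)^2
  expect_equal(b$dist[k], sqrt(min(d2)), tolerance = 1e-12)
})

test_that("normalising over the weak subset restricts the denominator", {
  txt <- makeToyProteinPDB(seed = 3L)
  g <- buildAtomisticGraph(readStructure(txt))
  site <- siteSpec(ligand = attr(txt, "activeLigand"))
  rAll <- bondPropensity(g, site)
  rWeak <- bondPropensity(g, site, normalizeOver = "weak")
  bA <- bonds(rAll); bW <- bonds(rWeak)
  sel <- bW$scored & bW$weak
  expect_equal(sum(bW$norm[sel]), 1, tolerance = 1e-9)
  expect_gt(sum(bW$norm[bW$scored], na.rm = TRUE), 1)
  ## raw propensities identical; only the normalisation changes
  expect_equal(bA$raw, bW$raw)
})

test_that("disconnected components are excluded with a warning", {
  ## two disjoint toy graphs glued into one AtomGraph
  g1 <- makeToyGraph("cycle", n = 6L)
  nd <- nodes(g1); b <- bonds(g1)
  nd2 <- nd
  nd2$chain <- "B"
  nd2$resid <- paste0("B:", nd2$resno)
  nodes_all <- rbind(nd, nd2)
  b2 <- b; b2$from <- b2$from + 6L; b2$to <- b2$to + 6L
  e <- rbind(b[, c("from", "to", "kind", "energy")],
             b2[, c("from", "to", "kind", "energy")])
  P <- as.matrix(nodes_all[, c("x", "y", "z")])
  g <- bondprop:::make_atom_graph(nodes_all, P, e, "atomistic")
  expect_warning(res <- bondPropensity(g, nodes_all$resid[1]),
                 "disconnected")
  bb <- bonds(res)
  expect_true(all(is.na(bb$norm[7:12])))
  expect_equal(sum(bb$norm[bb$scored]), 1, tolerance = 1e-9)
})

test_that("missing source bonds produce an actionable error", {
  g <- makeToyGraph("path", n = 5L)
  expect_error(bondPropensity(g, "Z:99"), "no weak ligand-protein bonds")
})
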