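test_that("adjacency follows the soft-threshold formulas", {
  ## exact correlations by construction: cor(g1,g2) = 1, cor(g1,g3) = -1,
  ## cor(g1,g4) = 0.5
  m <- rbind(g1 = c(1, 0, -1),
             g2 = c(2, 0, -2),
             g3 = c(-1, 0, 1),
             g4 = c(0, 1, -1))
  ds <- matrixDataset(m, rep("x", 3))

  s <- adjacencyMatrix(ds, networkParams(beta = 16))
  expect_equal(s["g1", "g2"], 1)
  expect_equal(s["g1", "g3"], 0)          # signed, cor = -1
  u <- adjacencyMatrix(ds, networkParams(beta = 2,
                                         adjacencyType = "unsigned"))
  expect_equal(u["g1", "g4"], 0.25)       # |0.5|^2
  expect_equal(u["g1", "g3"], 1)          # |-1|^2

  ## symmetry, range, unit diagonal on random data
  a <- adjacencyMatrix(randomDataset(nGenes = 25, seed = 2),
                       networkParams())
  expect_equal(a, t(a))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(unname(diag(a)), rep(1, 25))

  ## zero-variance gene is an error naming the gene
  m2 <- rbind(gA = c(1, 1, 1), gB = c(1, 2, 3), gC = c(2, 1, 3))
  expect_error(adjacencyMatrix(matrixDataset(m2, rep("x", 3))), "gA")
})

test_that("topological overlap matches the shared-neighbor formula", {
  ## complete graph: everything overlaps fully
  A <- matrix(1, 3, 3)
  expect_equal(topologicalOverlap(A), matrix(1, 3, 3))

  ## empty graph: no overlap off the diagonal
  A <- diag(3)
  expect_equal(topologicalOverlap(A), diag(3))

  ## hand-evaluated 3-gene network: a12 = a13 = 0.5, a23 = 0
  A <- matrix(c(1, .5, .5, .5, 1, 0, .5, 0, 1), 3, 3)
  tom <- topologicalOverlap(A)
  expect_equal(tom[2, 3], 1 / 6)  # (0.25 + 0) / (0.5 + 1 - 0)
  expect_equal(tom[1, 2], 0.5)    # (0 + 0.5) / (0.5 + 1 - 0.5)

  ## symmetry and bounds on an adjacency from random data
  a <- adjacencyMatrix(randomDataset(nGenes = 30, seed = 4),
                       networkParams())
  tom <- topologicalOverlap(a)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(unname(diag(tom)), rep(1, 30))
})

test_that("module eigengene is the first PC with the sign convention", {
  ## all genes exact copies of one profile
  v <- c(3, 1, 4, 1, 5, 9)
  m <- rbind(g1 = v, g2 = 2 * v + 1, g3 = -0 + v)
  ds <- matrixDataset(m)
  e <- moduleEigengene(ds, c("g1", "g2", "g3"))
  expect_equal(attr(e, "varExplained"), 1)
  zs <- scale(v)[, 1]
  expect_equal(unname(as.numeric(e)), zs / sqrt(sum(zs^2)))
  expect_equal(sum(e^2), 1)

  ## negating every gene leaves correlation with mean profile non-negative
  dsNeg <- matrixDataset(-m)
  eNeg <- moduleEigengene(dsNeg, rownames(m))
  zneg <- t(scale(t(-m)))
  expect_gte(cor(as.numeric(eNeg), colMeans(zneg)), 0)

  ## two exactly uncorrelated genes split the variance evenly
  m2 <- rbind(gA = c(1, 0, -1, 0), gB = c(0, 1, 0, -1))
  e2 <- moduleEigengene(matrixDataset(m2), c("gA", "gB"))
  expect_equal(attr(e2, "varExplained"), 0.5)

  expect_error(moduleEigengene(ds, "g1"), "2")
})

test_that("planted orthogonal modules are recovered almost completely", {
  ## 2 orthogonal latent factors, 150 genes each, 1000 background genes,
  ## 10v10 samples
  sim <- simulateExpression(nGenes = 1300, nModules = 2, moduleSize = 150,
                            nTraitModules = 0, samplesPerGroup = 10,
                            latents = "orthogonal", seed = 21)
  dec <- detectModules(sim$dataset, networkParams())
  found <- moduleAssignment(dec)
  mods <- setdiff(unique(found), "unassigned")
  expect_length(mods, 2)
  for (p in c("P1", "P2")) {
    inMod <- found[sim$truth$assignment == p]
    recall <- max(table(factor(inMod[inMod != "unassigned"],
                               levels = mods)), 0) / 150
    expect_gte(recall, 0.95)
  }
})

test_that("pure-noise datasets yield no modules", {
  for (s in 1:10) {
    set.seed(300 + s)
    m <- matrix(rnorm(500 * 20), 500, 20)
    dec <- detectModules(matrixDataset(m), networkParams())
    expect_true(all(moduleAssignment(dec) == "unassigned"),
                label = sprintf("seed %d: all unassigned", s))
  }
})

test_that("modules driven by one latent end up as a single module", {
  ## two planted blocks whose latents correlate > 0.95: either the
  ## dendrogram never separates them or the eigengene merge joins them
  set.seed(33)
  ns <- 20
  e <- rnorm(ns)
  f <- rnorm(ns)
  e2 <- sqrt(0.96) * e + sqrt(0.04) * f
  m <- matrix(rnorm(700 * ns), 700, ns)
  m[1:150, ] <- 0.8 * matrix(e, 150, ns, byrow = TRUE) +
    0.6 * matrix(rnorm(150 * ns), 150, ns)
  m[151:300, ] <- 0.8 * matrix(e2, 150, ns, byrow = TRUE) +
    0.6 * matrix(rnorm(150 * ns), 150, ns)
  dec <- detectModules(matrixDataset(m), networkParams())
  mods <- setdiff(unique(moduleAssignment(dec)), "unassigned")
  expect_length(mods, 1)
  ## and the bulk of the planted genes sit in that module
  expect_gte(sum(moduleAssignment(dec)[1:300] == mods), 200)
})

test_that("module assignment is invariant to gene input order", {
  sim <- simulateExpression(nGenes = 600, nModules = 2, moduleSize = 120,
                            nTraitModules = 0, samplesPerGroup = 10,
                            latents = "orthogonal", seed = 5)
  ds <- sim$dataset
  dec1 <- detectModules(ds, networkParams())
  set.seed(1)
  perm <- sample(nrow(ds))
  dsPerm <- ExpressionDataset(exprValues(ds)[perm, ], sampleGroups(ds))
  dec2 <- detectModules(dsPerm, networkParams())
  a1 <- moduleAssignment(dec1)
  a2 <- moduleAssignment(dec2)[names(a1)]
  expect_equal(ari(a1, a2), 1)
})

test_that("eigengene merging terminates before exhausting the modules", {
  sim <- simulateExpression(nGenes = 800, nModules = 3, moduleSize = 120,
                            nTraitModules = 3, samplesPerGroup = 10,
                            seed = 8)
  dec <- detectModules(sim$dataset, networkParams())
  nMods <- length(setdiff(unique(moduleAssignment(dec)), "unassigned"))
  initial <- nMods + nrow(mergeLog(dec))   # every merge removes one module
  expect_gte(nMods, 1)
  expect_lt(nrow(mergeLog(dec)), initial)
  ## merged pairs were below the threshold when merged
  if (nrow(mergeLog(dec)))
    expect_true(all(mergeLog(dec)$dissimilarity < 0.1))
})

test_that("module-trait statistics use the t-distribution and Bonferroni", {
  ## eigengene exactly aligned with the trait
  trait <- c(0, 0, 0, 1, 1, 1)
  v <- trait / sqrt(sum(trait^2))
  assignment <- setNames(rep(c("M1", "M2"), each = 2), paste0("g", 1:4))
  w <- scale(c(0.3, -1, 2, 0.5, -0.2, 0.1))[, 1]
  me <- cbind(M1 = v, M2 = w / sqrt(sum(w^2)))
  rownames(me) <- paste0("s", 1:6)
  dec <- methods::new("ModuleDecomposition", assignment = assignment,
                      eigengenes = me,
                      mergeLog = data.frame(moduleA = character(),
                                            moduleB = character(),
                                            dissimilarity = numeric()),
                      params = networkParams(minModuleSize = 2))
  res <- moduleTraitRelationships(dec, trait)
  r1 <- res[res$module == "M1", ]
  expect_equal(r1$r, 1)
  expect_equal(r1$p, 0)
  expect_true(r1$significant)

  ## adjusted p = min(1, m * p), flags derive from the threshold
  expect_equal(res$p_bonf, pmin(1, nrow(res) * res$p))
  expect_identical(res$significant, res$p_bonf < 0.05)

  ## t-to-p mapping matches cor.test
  r2 <- res[res$module == "M2", ]
  ct <- cor.test(me[, "M2"], trait)
  expect_equal(r2$p, ct$p.value)

  expect_error(moduleTraitRelationships(dec, rep(1, 6)), "constant")
  expect_error(moduleTraitRelationships(dec, trait[1:3]), "length")
})

test_that("hypergeometric over-representation matches closed forms", {
  universe <- paste0("g", 1:20)
  mod <- paste0("g", 1:5)
  sets <- list(exact = paste0("g", 1:5),
               whole = universe,
               none = paste0("g", 11:15))
  res <- moduleEnrichment(mod, sets, universe)

  ## module identical to a 5-gene set: p = 1 / C(20, 5)
  expect_equal(res$p[res$set == "exact"], 1 / choose(20, 5))
  ## set covering the universe: overlap forced to module size, p = 1
  expect_equal(res$overlap[res$set == "whole"], 5)
  expect_equal(res$p[res$set == "whole"], 1)
  ## BH over the three sets; single set keeps its raw p
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  one <- moduleEnrichment(mod, sets["exact"], universe)
  expect_equal(one$p_adj, one$p)

  ## brute-force hypergeometric check for a partial overlap
  res2 <- moduleEnrichment(mod, list(s = paste0("g", 4:9)), universe)
  pBrute <- sum(vapply(res2$overlap:5, function(k)
    choose(6, k) * choose(14, 5 - k), 0)) / choose(20, 5)
  expect_equal(res2$p, pBrute)

  expect_error(moduleEnrichment(mod, sets, character(0)), "universe")
  expect_error(moduleEnrichment(c(mod, "zz"), sets, universe), "subset")
})

test_that("GMT files round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sets.gmt")
  sets <- list(alpha = c("g1", "g2"), beta = c("g9", "g3", "g4"))
  writeGmt(sets, path)
  expect_identical(readGmt(path), sets)
})
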