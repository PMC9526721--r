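test_that("tag-KS statistic matches hand evaluations", {
  r <- namedRanks(1:10)
  expect_equal(ksTagStatistic(c("g1", "g2"), r), 0.8)
  expect_equal(ksTagStatistic(c("g9", "g10"), r), -0.9)
  expect_error(ksTagStatistic("nope", r), "universe")
  expect_error(ksTagStatistic(names(r), r), "t < n|not.*TRUE")
})

test_that("tag-KS statistic equals the CDF-scan oracle exhaustively", {
  ## every placement of t tags in a universe of n, n <= 8, t <= 4
  for (n in 3:8) {
    r <- namedRanks(1:n)
    for (t in 1:min(4, n - 1)) {
      combos <- combn(n, t)
      for (j in seq_len(ncol(combos))) {
        tags <- paste0("g", combos[, j])
        expect_equal(ksTagStatistic(tags, r), ksOracle(combos[, j], n),
                     label = sprintf("n=%d tags={%s}", n,
                                     paste(combos[, j], collapse = ",")))
      }
    }
  }
})

test_that("raw instance score applies the opposite-sign rule", {
  r <- namedRanks(1:10)
  s <- instanceRawScore(c("g1", "g2"), c("g9", "g10"), r)
  expect_equal(s$ks_up, 0.8)
  expect_equal(s$ks_down, -0.9)
  expect_equal(s$raw, 1.7)

  ## both tag sets at the top: same sign, null instance
  sNull <- instanceRawScore(c("g1", "g2"), c("g3", "g4"), r)
  expect_gt(sNull$ks_up, 0)
  expect_gt(sNull$ks_down, 0)
  expect_equal(sNull$raw, 0)

  expect_error(instanceRawScore(c("g1"), c("g1", "g2"), r), "disjoint")
})

test_that("top/bottom placement maximizes the raw score (exhaustive)", {
  ## all disjoint placements of 2 up + 2 down tags in 8 genes
  n <- 8
  r <- namedRanks(1:n)
  best <- instanceRawScore(c("g1", "g2"), c("g7", "g8"), r)$raw
  combos <- combn(n, 2)
  mx <- -Inf
  for (i in seq_len(ncol(combos))) {
    for (j in seq_len(ncol(combos))) {
      if (length(intersect(combos[, i], combos[, j]))) next
      s <- instanceRawScore(paste0("g", combos[, i]),
                            paste0("g", combos[, j]), r)$raw
      mx <- max(mx, s)
    }
  }
  expect_equal(best, mx)
  expect_gt(best, 0)
})

test_that("score scaling pins the extremes to +1 and -1", {
  expect_equal(scaleConnectivityScores(c(1.7, -0.85, 0.34)),
               c(1, -1, 0.2))
  expect_equal(scaleConnectivityScores(0.42), 1)
  expect_warning(out <- scaleConnectivityScores(c(0, 0)), "zero")
  expect_equal(out, c(0, 0))

  ## invariance to a positive rescaling of the raw scores
  set.seed(2)
  raw <- rnorm(20)
  expect_equal(scaleConnectivityScores(raw * 7.3),
               scaleConnectivityScores(raw))
})

test_that("compound summaries average instances and count non-nulls", {
  inst <- data.frame(
    instance_id = paste0("i", 1:6),
    compound = c("A", "A", "B", "B", "B", "B"),
    scaled = c(1, 0.5, 0.9, 0.2, 0, -0.1))
  cmp <- compoundSummary(inst)
  expect_equal(cmp$mean_score[cmp$compound == "A"], 0.75)
  expect_equal(cmp$percent_nonnull[cmp$compound == "A"], 100)
  ## B: mean 0.25 > 0; two of four instances nonzero and positive
  expect_equal(cmp$percent_nonnull[cmp$compound == "B"], 50)

  expect_equal(percentNonnull(c(0.5, -0.5)), 0)     # mean 0 convention
  expect_equal(percentNonnull(c(-0.2, -0.9)), 100)
})

test_that("a concordant and a discordant instance scale to +1 and -1", {
  set.seed(5)
  n <- 100
  genes <- paste0("g", 1:n)
  up <- genes[1:10]
  down <- genes[91:100]
  concordant <- 1:n
  discordant <- n:1
  rk <- cbind(concordant, discordant,
              replicate(3, sample(n)))
  colnames(rk) <- paste0("i", 1:5)
  rownames(rk) <- genes
  comp <- RankedCompendium(rk, data.frame(instance_id = colnames(rk),
                                          compound = paste0("c", 1:5)))
  sig <- methods::new("QuerySignature", upTags = up, downTags = down,
                      alpha = 0.005)
  rep <- scoreCompendium(sig, comp)
  sc <- instanceScores(rep)
  expect_equal(sc$scaled[sc$instance_id == "i1"], 1)
  expect_equal(sc$scaled[sc$instance_id == "i2"], -1)
  expect_true(all(abs(sc$scaled) <= 1))
})

test_that("permutation p-values are reproducible and bounded below", {
  set.seed(9)
  n <- 60
  genes <- paste0("g", 1:n)
  rk <- replicate(3, sample(n))
  rk[, 1] <- 1:n   # one strongly concordant instance
  colnames(rk) <- paste0("i", 1:3)
  rownames(rk) <- genes
  comp <- RankedCompendium(rk, data.frame(instance_id = colnames(rk),
                                          compound = rep("drug", 3)))
  sig <- methods::new("QuerySignature", upTags = genes[1:5],
                      downTags = genes[56:60], alpha = 0.005)
  p1 <- permutationPvalue("drug", sig, comp, B = 99, seed = 4)
  p2 <- permutationPvalue("drug", sig, comp, B = 99, seed = 4)
  expect_identical(p1, p2)
  expect_gte(p1$p, 1 / 100)           # add-one estimator floor
  expect_length(p1$null, 99)

  ## observed zero can never beat |null| >= 0: p = 1
  sigNull <- methods::new("QuerySignature", upTags = genes[1:3],
                          downTags = genes[4:6], alpha = 0.005)
  rkTop <- matrix(1:n, n, 1, dimnames = list(genes, "j1"))
  compTop <- RankedCompendium(rkTop, data.frame(instance_id = "j1",
                                                compound = "x"))
  pz <- permutationPvalue("x", sigNull, compTop, B = 49, seed = 1)
  expect_equal(pz$observed, 0)
  expect_equal(pz$p, 1)

  bigSig <- methods::new("QuerySignature", upTags = genes[1:40],
                         downTags = paste0("h", 1:25), alpha = 1)
  expect_error(permutationPvalue("drug", bigSig, comp, B = 9),
               "universe smaller")
  expect_error(permutationPvalue("unknown", sig, comp, B = 9), "unknown")
})

test_that("specificity counts decoys scoring at least as strongly", {
  set.seed(31)
  n <- 80
  genes <- paste0("g", 1:n)
  rk <- cbind(1:n, replicate(5, sample(n)))
  colnames(rk) <- paste0("i", 1:6)
  rownames(rk) <- genes
  comp <- RankedCompendium(
    rk, data.frame(instance_id = colnames(rk),
                   compound = c("hit", "hit", "a", "a", "b", "b")))
  sig <- methods::new("QuerySignature", upTags = genes[1:8],
                      downTags = genes[73:80], alpha = 0.005)
  decoys <- lapply(1:10, function(i) {
    set.seed(100 + i)
    tags <- sample(genes, 16)
    methods::new("QuerySignature", upTags = tags[1:8],
                 downTags = tags[9:16], alpha = 0.005)
  })
  spec <- specificityScore("hit", sig, decoys, comp)
  expect_lte(spec, 0.2)  # strong planted concordance beats random decoys
  expect_error(specificityScore("hit", sig, list(), comp), "decoy")
})

test_that("compound ranking sorts by p, then |mean|, then name", {
  sig <- methods::new("QuerySignature", upTags = "g1", downTags = "g2",
                      alpha = 0.005)
  rep <- methods::new(
    "ConnectivityReport",
    instances = data.frame(instance_id = "i", compound = "A",
                           ks_up = 0, ks_down = 0, raw = 0, scaled = 0),
    compounds = data.frame(
      compound = c("A", "B", "C", "D"),
      n_instances = 1L,
      mean_score = c(0.9, -0.3, 0.9, 0.3),
      percent_nonnull = 100,
      p_perm = c(0.2, 0.01, 0.01, 0.2)),
    signature = sig)
  ranked <- compoundScores(rankSmallMolecules(rep))
  expect_identical(ranked$compound, c("C", "B", "A", "D"))
  expect_identical(ranked$rank, 1:4)
})

test_that("compendium TSV files round-trip and validate", {
  dir <- withr::local_tempdir()
  set.seed(8)
  n <- 30
  rk <- replicate(4, sample(n))
  rownames(rk) <- paste0("g", 1:n)
  info <- data.frame(instance_id = paste0("i", 1:4),
                     compound = c("a", "a", "b", "b"))
  colnames(rk) <- info$instance_id
  comp <- RankedCompendium(rk, info)
  writeCompendium(comp, file.path(dir, "r.tsv"), file.path(dir, "m.tsv"))
  back <- readCompendium(file.path(dir, "r.tsv"), file.path(dir, "m.tsv"))
  expect_equal(compendiumRanks(back), compendiumRanks(comp))
  expect_equal(instanceInfo(back), instanceInfo(comp))

  ## tied ranks rejected unless tie-breaking is requested
  rk2 <- rk
  rk2[1, 1] <- rk2[2, 1]
  df <- data.frame(gene = rownames(rk2), rk2, check.names = FALSE)
  write.table(df, file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(readCompendium(file.path(dir, "bad.tsv"),
                              file.path(dir, "m.tsv")),
               "permutation")
  fixed <- suppressMessages(readCompendium(file.path(dir, "bad.tsv"),
                                           file.path(dir, "m.tsv"),
                                           breakTies = TRUE))
  expect_s4_class(fixed, "RankedCompendium")
})
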