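miniGenome <- function(id = "G1", group = "heterotroph", fams, copies = NULL,
                       lengths = NULL) {
  n <- length(fams)
  new("SyntheticGenome", genomeId = id, group = group,
      genes = data.frame(
        gene_id = sprintf("%s_g%02d", id, seq_len(n)),
        family_id = fams,
        copies = if (is.null(copies)) rep(1L, n) else as.integer(copies),
        length = if (is.null(lengths)) rep(900L, n) else
          as.integer(lengths),
        stringsAsFactors = FALSE))
}

test_that("genome generation is deterministic and group-structured", {
  g1 <- generateGenomes(seed = 42)
  g2 <- generateGenomes(seed = 42)
  expect_length(g1, 15L)
  expect_identical(lapply(g1, genomeGenes), lapply(g2, genomeGenes))
  expect_false(identical(lapply(g1, genomeGenes),
                         lapply(generateGenomes(seed = 43),
                                genomeGenes)))

  markers <- defaultMarkerSets()
  chemo <- g1[vapply(g1, genomeGroup, character(1)) == "chemoautotroph"]
  het <- g1[vapply(g1, genomeGroup, character(1)) == "heterotroph"]
  amo <- markers$chemoautotroph[1]
  for (g in chemo)
    expect_true(amo %in% genomeGenes(g)$family_id)
  for (g in het)
    expect_false(amo %in% genomeGenes(g)$family_id)
  # designated multi-copy marker
  for (g in chemo)
    expect_gte(
      genomeGenes(g)$copies[which(genomeGenes(g)$family_id == "K00368")],
      2L)
})

test_that("overlapping marker sets are rejected", {
  ms <- defaultMarkerSets()
  ms$heterotroph[1] <- ms$photoautotroph[1]
  expect_error(generateGenomes(1, markerSets = ms), "disjoint")
  expect_error(
    generateGenomes(1, sharedSet = defaultMarkerSets()$photoautotroph[1]),
    "disjoint")
})

test_that("ground truth follows the closed-form weight*copies expectation", {
  g <- miniGenome(fams = c("k1", "k2"))
  d <- CommunityDesign("s", c(G1 = 1))
  tr <- familyAbundances(groundTruthProfile(d, list(g)))
  expect_equal(tr, c(k1 = 5e5, k2 = 5e5))

  # scale invariance of weights
  d2 <- CommunityDesign("s", c(G1 = 2))
  expect_equal(familyAbundances(groundTruthProfile(d2, list(g))), tr)

  # a two-copy gene has exactly twice the truth abundance
  g2 <- miniGenome(fams = c("k1", "k2"), copies = c(2L, 1L))
  tr2 <- familyAbundances(groundTruthProfile(d, list(g2)))
  expect_equal(unname(tr2["k1"] / tr2["k2"]), 2)

  # filler genes dilute the denominator but report no family
  g3 <- miniGenome(fams = c("k1", NA))
  tr3 <- familyAbundances(groundTruthProfile(d, list(g3)))
  expect_equal(tr3, c(k1 = 5e5))

  expect_error(groundTruthProfile(CommunityDesign("s", c(nope = 1)),
                                  list(g)), "unknown genomes")
})

test_that("count simulation is seeded, depth-0-safe, and unbiased", {
  genomes <- generateGenomes(seed = 3, nPerGroup = 2, fillerPerGenome = 5)
  d <- defaultCommunityDesigns(genomes)[[5]]
  c1 <- simulateCounts(d, genomes, depth = 2e4, seed = 9)
  c2 <- simulateCounts(d, genomes, depth = 2e4, seed = 9)
  expect_identical(c1, c2)
  expect_equal(sum(c1$reads), 2e4)

  c0 <- simulateCounts(d, genomes, depth = 0, seed = 9)
  expect_true(all(c0$reads == 0))

  # each gene count within 5 sigma of its multinomial expectation
  w <- designWeights(d)
  mass <- unlist(unname(lapply(genomes, function(g) {
    wg <- w[genomeId(g)]
    if (wg == 0) return(NULL)
    gg <- genomeGenes(g)
    stats::setNames(wg * gg$copies * gg$length, gg$gene_id)
  })))
  p <- mass[c1$gene_id] / sum(mass)
  n <- sum(c1$reads)
  sigma <- sqrt(p * (1 - p) * n)
  expect_true(all(abs(c1$reads - n * p) <= 5 * sigma + 1e-9))
})

test_that("profile correlation handles identity, inversion and degeneracy", {
  a <- AbundanceProfile("x", c(k1 = 1, k2 = 2, k3 = 5))
  expect_equal(profilePcc(a, a), 1.0)
  expect_equal(profilePcc(c(k1 = 1, k2 = 2), c(k1 = 2, k2 = 1)), -1.0)
  expect_error(profilePcc(c(k1 = 1, k2 = 1), c(k1 = 1, k2 = 2)),
               "zero variance")
  # union semantics: disjoint families are zeros on the other side
  expect_lt(profilePcc(c(k1 = 1, k2 = 3), c(k1 = 1, k2 = 3, k3 = 9)), 1)
})

test_that("group-exclusive markers have zero truth weight off their group", {
  genomes <- generateGenomes(seed = 21)
  designs <- defaultCommunityDesigns(genomes)
  photoMarker <- defaultMarkerSets()$photoautotroph[1]
  # sample3 is chemoautotroph-only
  tr <- familyAbundances(groundTruthProfile(designs[[3]], genomes))
  expect_false(photoMarker %in% names(tr))
  # but present in the photoautotroph-only sample
  tr1 <- familyAbundances(groundTruthProfile(designs[[1]], genomes))
  expect_true(photoMarker %in% names(tr1))
})

test_that("the pipeline recovers designed profiles and improves with depth", {
  res <- runBenchmark(depth = 2e4, seed = 4)
  expect_length(samplePcc(res), 5L)
  expect_equal(minPcc(res), min(samplePcc(res)))
  expect_gt(minPcc(res), 0.9)

  shallow <- vapply(1:4, function(s)
    minPcc(runBenchmark(depth = 1e3, seed = s, nPerGroup = 2)),
    numeric(1))
  deep <- vapply(1:4, function(s)
    minPcc(runBenchmark(depth = 1e5, seed = s, nPerGroup = 2)),
    numeric(1))
  expect_gt(mean(deep), mean(shallow))
})

test_that("benchmark reports write one row per sample", {
  res <- runBenchmark(depth = 5e3, seed = 2, nPerGroup = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeBenchmarkReport(res, p)
  tab <- read.table(p, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$pcc, unname(samplePcc(res)))
})
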