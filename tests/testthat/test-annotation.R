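koThr <- function(ids, thr, type = "full") {
  data.frame(family_id = ids, threshold = thr, score_type = type,
             has_threshold = is.finite(thr), definition = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("KO assignment applies per-family thresholds, boundary inclusive", {
  thr <- koThr("K00392", 150)
  expect_equal(assignKos(makeHits("g1", "K00392", full = 210.3), thr),
               list(g1 = "K00392"))
  expect_equal(assignKos(makeHits("g1", "K00392", full = 150.0), thr),
               list(g1 = "K00392"))
  expect_length(assignKos(makeHits("g1", "K00392", full = 149.99), thr), 0L)
})

test_that("domain score type thresholds the domain score, not the full one", {
  thr <- koThr("K00380", 100, type = "domain")
  expect_length(
    assignKos(makeHits("g1", "K00380", full = 150, dom = 90), thr), 0L)
  expect_equal(
    assignKos(makeHits("g1", "K00380", full = 90, dom = 100), thr),
    list(g1 = "K00380"))
})

test_that("a gene keeps every accepted KO and duplicates count once", {
  thr <- koThr(c("K00362", "K00363"), c(100, 100))
  hits <- makeHits(c("g1", "g1", "g1"), c("K00362", "K00363", "K00362"),
                   full = c(120, 130, 111))
  expect_equal(assignKos(hits, thr), list(g1 = c("K00362", "K00363")))
})

test_that("threshold-less KOs fall back to the E-value ceiling", {
  thr <- koThr("K99999", NA_real_, type = "-")
  expect_equal(
    assignKos(makeHits("g1", "K99999", evalue = 1e-6, full = 10), thr),
    list(g1 = "K99999"))
  expect_length(
    assignKos(makeHits("g1", "K99999", evalue = 1e-4, full = 500), thr), 0L)
  expect_equal(
    assignKos(makeHits("g1", "K99999", evalue = 1e-4, full = 500), thr,
              fallbackEvalue = 1e-3),
    list(g1 = "K99999"))
})

test_that("hits to KOs absent from the threshold table are dropped loudly", {
  thr <- koThr("K00392", 150)
  hits <- makeHits(c("g1", "g2"), c("K00392", "K11111"), full = 200)
  expect_message(ann <- assignKos(hits, thr), "dropped")
  expect_equal(names(ann), "g1")
})

test_that("custom families accept by E-value ceiling, boundary inclusive", {
  cut <- dmspCutoffs()
  expect_equal(
    assignCustomFamilies(makeHits("g1", "DmdA", evalue = 1e-140), cut),
    list(g1 = "DmdA"))
  expect_length(
    assignCustomFamilies(makeHits("g1", "DmdA", evalue = 1e-100), cut), 0L)
  expect_equal(
    assignCustomFamilies(makeHits("g1", "DsyB", evalue = 1e-67), cut),
    list(g1 = "DsyB"))
})

test_that("a custom hit with no configured cutoff is a configuration error", {
  expect_error(
    assignCustomFamilies(makeHits("g1", "NotAFamily", evalue = 1e-99),
                         dmspCutoffs()),
    "NotAFamily")
})

test_that("annotation merge is a per-gene set union", {
  expect_equal(mergeAnnotations(list(g1 = "K1"), list(g1 = "dmdA")),
               list(g1 = c("dmdA", "K1")[order(c("dmdA", "K1"))]))
  x <- list(g1 = c("K1", "K2"), g2 = "K3")
  expect_equal(mergeAnnotations(list(), x), x[order(names(x))])
  both <- mergeAnnotations(list(g1 = "K1"), list(g2 = "K2"))
  expect_setequal(names(both), c("g1", "g2"))
  expect_equal(mergeAnnotations(x, x), x[order(names(x))])
})

test_that("lowering thresholds or raising ceilings never removes a KO call", {
  set.seed(101)
  for (rep in 1:20) {
    fams <- paste0("K", sample(100:999, 4))
    hits <- makeHits(sample(paste0("g", 1:5), 12, replace = TRUE),
                     sample(fams, 12, replace = TRUE),
                     evalue = 10^-stats::runif(12, 1, 10),
                     full = stats::runif(12, 50, 250))
    thr <- koThr(fams, c(stats::runif(3, 60, 240), NA),
                 type = c("full", "full", "domain", "-"))
    a <- suppressMessages(assignKos(hits, thr, fallbackEvalue = 1e-5))
    thr2 <- thr
    thr2$threshold <- thr2$threshold - 50
    b <- suppressMessages(assignKos(hits, thr2, fallbackEvalue = 1e-3))
    for (g in names(a))
      expect_true(all(a[[g]] %in% b[[g]]))
  }
})

test_that("KO assignment matches an independent brute-force filter", {
  set.seed(77)
  for (rep in 1:25) {
    fams <- paste0("K", sample(1000:9999, 5))
    hits <- makeHits(sample(paste0("g", 1:6), 15, replace = TRUE),
                     sample(fams, 15, replace = TRUE),
                     evalue = 10^-stats::runif(15, 1, 12),
                     full = stats::runif(15, 20, 300))
    hits$dom_score <- hits$full_score - stats::runif(15, 0, 30)
    thr <- koThr(fams[1:4],
                 c(stats::runif(3, 50, 250), NA),
                 type = c("full", "domain", "full", "-"))
    got <- suppressMessages(assignKos(hits, thr))
    want <- bruteForceAssign(hits, thr)
    expect_equal(got, want)
  }
})
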