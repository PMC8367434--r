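test_that("tblout rows parse into hits with both scores populated", {
  f <- withr::local_tempfile()
  writeLines(c(
    "# target name  accession  query name ...",
    paste("g1 - K00392 - 1e-50 210.3 0.1 1e-49 209.0 0.1",
          "1 1 0 1 1 1 1 1 Sulfite reductase")), f)
  hits <- readHmmTable(f, "tblout")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene_id, "g1")
  expect_equal(hits$family_id, "K00392")
  expect_equal(hits$full_score, 210.3)
  expect_equal(hits$dom_score, 209.0)
  expect_equal(hits$evalue, 1e-50)
})

test_that("domtblout rows take the per-domain score column", {
  f <- withr::local_tempfile()
  writeDomtblout(makeHits("g2", "K00380", evalue = 1e-33, full = 120.5,
                          dom = 118.2), f)
  hits <- readHmmTable(f, "domtblout")
  expect_equal(hits$family_id, "K00380")
  expect_equal(hits$full_score, 120.5)
  expect_equal(hits$dom_score, 118.2)
  expect_equal(hits$evalue, 1e-33)
})

test_that("comment-only files give an empty hit table", {
  f <- withr::local_tempfile()
  writeLines(c("# only", "# comments", "#"), f)
  hits <- readHmmTable(f)
  expect_equal(nrow(hits), 0L)
  expect_named(hits, c("gene_id", "family_id", "full_score", "dom_score",
                       "evalue"))
})

test_that("malformed hit rows fail naming the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("# header",
               paste("g1 - K00392 - 1e-50 NOTASCORE 0.1 1e-49 209.0 0.1",
                     "1 1 0 1 1 1 1 1 desc")), f)
  expect_error(readHmmTable(f), "line 2.*non-numeric")
  writeLines("g1 - K00392 1e-50", f)
  expect_error(readHmmTable(f), "line 1.*columns")
  expect_error(readHmmTable(f, "badformat"))
})

test_that("multiple hits for the same gene/family pair are all returned", {
  f <- withr::local_tempfile()
  writeTblout(makeHits(c("g1", "g1"), c("K00392", "K00392"),
                       full = c(210, 180)), f)
  expect_equal(nrow(readHmmTable(f)), 2L)
})

test_that("ko_list tables parse with threshold-less rows flagged", {
  f <- withr::local_tempfile()
  writeKoList(data.frame(
    family_id = c("K00392", "K00380", "K99999"),
    threshold = c("150.00", "73.10", "-"),
    score_type = c("full", "domain", "-"),
    definition = c("sulfite reductase", "cysJ", "uncharacterized")), f)
  thr <- readKoThresholds(f)
  expect_equal(thr$threshold[1], 150)
  expect_equal(thr$score_type[2], "domain")
  expect_true(all(thr$has_threshold[1:2]))
  expect_false(thr$has_threshold[3])
  expect_true(is.na(thr$threshold[3]))
})

test_that("ko_list tables without required columns are rejected", {
  f <- withr::local_tempfile()
  writeLines(c("knum\tthreshold", "K1\t10"), f)
  expect_error(readKoThresholds(f), "score_type")
})

test_that("counts tables read in both modes and reject bad schemas", {
  f <- withr::local_tempfile()
  writeLines(c("gene_id\tlength\treads", "g1\t300\t30"), f)
  rec <- readCountsTable(f)
  expect_equal(attr(rec, "mode"), "reads")
  expect_equal(rec$reads, 30)

  writeLines(c("gene_id\tlength\tavg_coverage", "g1\t300\t12.5"), f)
  rec <- readCountsTable(f)
  expect_equal(attr(rec, "mode"), "coverage")
  expect_equal(rec$avg_coverage, 12.5)

  writeLines(c("gene_id\tlength\treads\tavg_coverage", "g1\t300\t30\t1"), f)
  expect_error(readCountsTable(f), "exactly one")
  writeLines(c("gene_id\tlength", "g1\t300"), f)
  expect_error(readCountsTable(f), "exactly one")
  writeLines(c("gene_id\tlength\treads", "g1\t0\t30"), f)
  expect_error(readCountsTable(f), "positive")
})

test_that("pathway definition files parse routes and components in order", {
  f <- withr::local_tempfile()
  writeLines(c(
    "pathway_id\tdisplay_name\tcycle\troute_index\tcomponent_index\tfamilies",
    "ASR\tASR\tsulfur\t1\t1\tK00392",
    "ASR\tASR\tsulfur\t2\t1\tK00380",
    "ASR\tASR\tsulfur\t2\t2\tK00381"), f)
  defs <- readPathwayDefinitions(f)
  expect_length(defs, 1L)
  expect_equal(lengths(routes(defs$ASR)), c(1L, 2L))
})

test_that("definition files with empty components or duplicate ids fail", {
  f <- withr::local_tempfile()
  hdr <- "pathway_id\tdisplay_name\tcycle\troute_index\tcomponent_index\tfamilies"
  writeLines(c(hdr, "P1\tP1\tother\t1\t1\t"), f)
  expect_error(readPathwayDefinitions(f))
  writeLines(c(hdr,
               "P1\tP1\tother\t1\t1\tK1",
               "P2\tP2\tother\t1\t1\tK2",
               "P1\tP1 again\tother\t1\t1\tK3"), f)
  expect_error(readPathwayDefinitions(f), "duplicate pathway id")
})

test_that("table writers round-trip bit-exact ids and near-exact floats", {
  td <- withr::local_tempdir()
  defs <- builtinDefinitions()
  p <- file.path(td, "defs.tsv")
  writePathwayDefinitions(defs, p)
  back <- readPathwayDefinitions(p)
  expect_equal(names(back), names(defs))
  for (id in names(defs))
    expect_equal(routes(back[[id]]), routes(defs[[id]]))

  set.seed(42)
  m <- matrix(stats::runif(12, 0, 1e6), 4, 3,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  p <- file.path(td, "ab.tsv")
  writeAbundanceTable(m, p)
  expect_equal(readAbundanceTable(p), m, tolerance = 1e-12)

  counts <- data.frame(gene_id = c("g1", "g2"), length = c(10L, 20L),
                       reads = c(5L, 7L))
  p <- file.path(td, "counts.tsv")
  writeCountsTable(counts, p)
  expect_equal(readCountsTable(p)$reads, counts$reads)

  ann <- list(g1 = c("K1", "K2"), g2 = "DmdA")
  p <- file.path(td, "ann.tsv")
  writeAnnotationTable(ann, p)
  expect_equal(readAnnotationTable(p), ann)
})
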