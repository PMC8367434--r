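# Fixture builders shared across the test files. Everything is generated in
# code at test time; nothing binary is stored.

# one HMMER3 tblout data line: 18 whitespace columns + description
tbloutLine <- function(gene, family, evalue, full, dom) {
  paste(gene, "-", family, "-",
        format(evalue, scientific = TRUE), full, "0.1",
        format(evalue * 10, scientific = TRUE), dom, "0.1",
        "1 1 1 1 1 1 1 1", "test hit")
}

writeTblout <- function(hits, path) {
  lines <- c("#                    --- full sequence ---- (crafted fixture)",
             mapply(tbloutLine, hits$gene_id, hits$family_id, hits$evalue,
                    hits$full_score, hits$dom_score))
  writeLines(lines, path)
  path
}

# one domtblout data line: 22 whitespace columns + description
domtbloutLine <- function(gene, family, evalue, full, dom) {
  paste(gene, "-", "500", family, "-", "300",
        format(evalue, scientific = TRUE), full, "0.1",
        "1", "1",
        format(evalue, scientific = TRUE),
        format(evalue, scientific = TRUE), dom, "0.1",
        "1 100 1 100 1 100 0.9", "test domain hit")
}

writeDomtblout <- function(hits, path) {
  writeLines(c("# crafted domtblout fixture",
               mapply(domtbloutLine, hits$gene_id, hits$family_id,
                      hits$evalue, hits$full_score, hits$dom_score)), path)
  path
}

writeKoList <- function(entries, path) {
  writeLines(c("knum\tthreshold\tscore_type\tdefinition",
               sprintf("%s\t%s\t%s\t%s", entries$family_id,
                       entries$threshold, entries$score_type,
                       entries$definition)), path)
  path
}

makeHits <- function(gene, family, evalue = 1e-50, full = 200,
                     dom = full - 1) {
  data.frame(gene_id = gene, family_id = family, full_score = full,
             dom_score = dom, evalue = evalue, stringsAsFactors = FALSE)
}

# independently coded brute-force evaluator of the pathway formula:
# sum over routes of (sum of per-component family sums) / n
bruteForcePathway <- function(definition, abundance) {
  total <- 0
  for (route in routes(definition)) {
    n <- length(route)
    s <- 0
    for (component in route) {
      for (fam in component) {
        if (fam %in% names(abundance)) s <- s + abundance[[fam]]
      }
    }
    total <- total + s / n
  }
  total
}

# independent acceptance predicate for KO assignment (loop form)
bruteForceAssign <- function(hits, thresholds, fallbackEvalue = 1e-5) {
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    j <- which(thresholds$family_id == h$family_id)
    if (!length(j)) next
    t <- thresholds[j[1], ]
    ok <- if (!t$has_threshold) h$evalue <= fallbackEvalue
          else if (t$score_type == "domain") h$dom_score >= t$threshold
          else h$full_score >= t$threshold
    if (ok) out[[h$gene_id]] <- sort(unique(c(out[[h$gene_id]],
                                              h$family_id)))
  }
  out[order(names(out))]
}

randomProfile <- function(families, max = 100) {
  stats::setNames(stats::runif(length(families), 0, max), families)
}
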