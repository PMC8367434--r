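# Per-family threshold filtering of homology-search hits. A gene keeps every
# accepted family (no best-hit resolution), mirroring hmmsearch -T/--domT
# reporting semantics: score >= threshold and E-value <= ceiling both accept.

#' Assign KEGG Orthology families to genes
#'
#' Applies each KO's own suggested bit-score cutoff to the homology hits: a
#' hit is accepted when its full-sequence score (score type `"full"`) or its
#' best/per-domain score (score type `"domain"`) reaches the KO's threshold,
#' boundary inclusive. KOs flagged threshold-less in the threshold table are
#' instead accepted when the full-sequence E-value is at most
#' `fallbackEvalue`. A gene assigned to multiple KOs keeps all of them;
#' duplicate accepted hits to the same (gene, family) pair count once.
#'
#' Hits to families absent from `thresholds` are dropped; the number dropped
#' is reported via `message()`.
#'
#' @param hits data.frame of hits as returned by [readHmmTable()].
#' @param thresholds data.frame as returned by [readKoThresholds()].
#' @param fallbackEvalue E-value ceiling used for threshold-less KOs
#'   (default `1e-5`).
#' @return Named list mapping gene id to a sorted character vector of
#'   accepted family ids; genes with no accepted hit are absent.
#' @examples
#' hits <- data.frame(gene_id = "g1", family_id = "K00392",
#'                    full_score = 210.3, dom_score = 209.0, evalue = 1e-50)
#' thr <- data.frame(family_id = "K00392", threshold = 150, score_type = "full",
#'                   has_threshold = TRUE, definition = NA)
#' assignKos(hits, thr)
#' @export
assignKos <- function(hits, thresholds, fallbackEvalue = 1e-5) {
  if (!nrow(hits)) return(stats::setNames(list(), character()))
  idx <- match(hits$family_id, thresholds$family_id)
  unknown <- is.na(idx)
  if (any(unknown))
    message(sum(unknown), " hit(s) to families absent from the threshold ",
            "table were dropped")
  hits <- hits[!unknown, , drop = FALSE]
  idx <- idx[!unknown]
  if (!nrow(hits)) return(stats::setNames(list(), character()))
  hasThr <- thresholds$has_threshold[idx]
  thr <- thresholds$threshold[idx]
  st <- thresholds$score_type[idx]
  score <- ifelse(st == "domain", hits$dom_score, hits$full_score)
  accepted <- ifelse(hasThr, score >= thr, hits$evalue <= fallbackEvalue)
  annotationsFromPairs(hits$gene_id[accepted], hits$family_id[accepted])
}

#' Assign curated custom families to genes
#'
#' Accepts a hit when its full-sequence E-value is at most the family's
#' configured ceiling (boundary inclusive). Unlike the KO database, the
#' custom database must be fully specified: a hit to a family with no
#' configured cutoff is a configuration error.
#'
#' @param hits data.frame of hits as returned by [readHmmTable()].
#' @param cutoffs data.frame with columns `family_id` and `max_evalue`
#'   (positive E-value ceilings), e.g. [dmspCutoffs()].
#' @return Named list mapping gene id to accepted family ids.
#' @seealso [dmspCutoffs()]
#' @export
assignCustomFamilies <- function(hits, cutoffs) {
  stopifnot(all(c("family_id", "max_evalue") %in% names(cutoffs)))
  if (any(!is.finite(cutoffs$max_evalue)) || any(cutoffs$max_evalue <= 0))
    stop("custom family cutoffs must be positive")
  if (!nrow(hits)) return(stats::setNames(list(), character()))
  idx <- match(hits$family_id, cutoffs$family_id)
  if (anyNA(idx))
    stop("no cutoff configured for custom families: ",
         paste(unique(hits$family_id[is.na(idx)]), collapse = ", "))
  accepted <- hits$evalue <= cutoffs$max_evalue[idx]
  annotationsFromPairs(hits$gene_id[accepted], hits$family_id[accepted])
}

annotationsFromPairs <- function(genes, families) {
  if (!length(genes)) return(stats::setNames(list(), character()))
  out <- lapply(split(families, genes), function(f) sort(unique(f)))
  out[order(names(out))]
}

#' Merge two gene annotation maps
#'
#' Per-gene set union of families; genes present in either input appear in
#' the result. Used to combine KO and custom-database annotations, because a
#' gene keeps every accepted family across both databases.
#'
#' @param a,b named lists mapping gene id to family ids.
#' @return Merged named list (genes sorted by id, families sorted).
#' @export
mergeAnnotations <- function(a, b) {
  genes <- union(names(a), names(b))
  out <- lapply(genes, function(g)
    sort(unique(c(a[[g]], b[[g]]))))
  stats::setNames(out, genes)[order(genes)]
}

#' Curated DMSP-cycling family cutoffs
#'
#' Returns the shipped per-family E-value ceilings for the curated
#' organosulfur (DMSP cycling) gene database. The default set holds exactly
#' the twenty manually collected gene families spanning DMSP biosynthesis
#' (DSYB, DsyB, MmtN), demethylation (DmdA; DmdB/DmdC/DmdD, AcuH), cleavage
#' (the eight lyases DddD, DddK, DddL, DddP, DddQ, DddW, DddY, Alma1), DMS
#' oxidation (DmoA), DMSO reduction (DorA), the MddA pathway and MeSH
#' oxidation (MTO). `all = TRUE` additionally returns the DMS dehydrogenase
#' subunits DdhA/DdhB/DdhC and Tmm, which cover the DMS to DMSO step of the
#' built-in pathway set at a 1e-30 ceiling; the source description of that
#' step is ambiguous about whether the complex carries one cutoff or one per
#' subunit, so each subunit is listed separately at the same ceiling.
#' DorA's ceiling is not individually documented upstream and defaults to
#' 1e-30.
#'
#' @param all return the supplementary DMS-oxidation families too.
#' @return data.frame with columns `family_id`, `max_evalue`, `set`.
#' @seealso [assignCustomFamilies()]
#' @export
dmspCutoffs <- function(all = FALSE) {
  path <- system.file("extdata", "dmsp_cutoffs.tsv", package = "biogeopath",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all) tab <- tab[tab$set == "core", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
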