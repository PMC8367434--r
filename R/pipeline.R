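# One-step orchestration: annotation + quantification + pathway inference +
# reporting over a set of samples, starting from post-assembly inputs
# (HMMER3 search tables and per-gene counts). Assembly, ORF calling and
# read mapping are external pre-steps; their outputs are what this
# pipeline ingests.

#' Annotate and quantify one sample
#'
#' Reads the sample's homology-search table(s) and counts table, applies
#' the per-family thresholds, and returns the per-family TPM profile plus
#' the intermediate objects.
#'
#' @param sample sample identifier.
#' @param koHitsPath HMMER3 table of hits against the KO database (or
#'   `NULL`).
#' @param countsPath per-gene counts/coverage TSV.
#' @param koThresholds data.frame from [readKoThresholds()] (required when
#'   `koHitsPath` is given).
#' @param customHitsPath HMMER3 table of hits against the custom family
#'   database (or `NULL`).
#' @param customCutoffs data.frame of family E-value ceilings (default
#'   [dmspCutoffs()] with the supplementary families included).
#' @param hmmDialect `"tblout"` or `"domtblout"`.
#' @param fallbackEvalue E-value ceiling for threshold-less KOs.
#' @return List with `profile` ([AbundanceProfile-class]), `tpm`,
#'   `annotations`.
#' @export
profileSample <- function(sample, koHitsPath, countsPath,
                          koThresholds = NULL, customHitsPath = NULL,
                          customCutoffs = dmspCutoffs(all = TRUE),
                          hmmDialect = "tblout", fallbackEvalue = 1e-5) {
  ann <- stats::setNames(list(), character())
  if (!is.null(koHitsPath)) {
    if (is.null(koThresholds))
      stop("KO hits supplied without a KO threshold table")
    ann <- assignKos(readHmmTable(koHitsPath, hmmDialect), koThresholds,
                     fallbackEvalue = fallbackEvalue)
  }
  if (!is.null(customHitsPath))
    ann <- mergeAnnotations(
      ann, assignCustomFamilies(readHmmTable(customHitsPath, hmmDialect),
                                customCutoffs))
  tpm <- computeTpm(readCountsTable(countsPath))
  list(profile = aggregateProfile(sample, tpm, ann), tpm = tpm,
       annotations = ann)
}

# union-of-ids matrix from a list of named vectors (absent = 0)
bindProfiles <- function(vectors, sampleIds) {
  ids <- sort(unique(unlist(lapply(vectors, names))))
  m <- matrix(0, nrow = length(ids), ncol = length(vectors),
              dimnames = list(ids, sampleIds))
  for (i in seq_along(vectors)) {
    v <- vectors[[i]]
    if (length(v)) m[names(v), i] <- v
  }
  m
}

#' Run the full profiling pipeline over a set of samples
#'
#' For every sample: parse HMMER3 hit tables, assign KO and custom
#' families, compute per-gene TPM, aggregate per-family profiles; then
#' evaluate the pathway definitions over all samples, normalize across
#' samples, and write the result tables, figures and a JSON run manifest
#' into `outDir`. All outputs are deterministic given identical inputs.
#'
#' Output files: `gene_tpm.tsv` (genes x samples), `family_abundance.tsv`
#' (families x samples), `pathway_abundance.tsv` (pathways x samples),
#' `pathway_normalized.tsv`, per-sample `annotations_<sample>.tsv`,
#' `heatmap.<fmt>`, `sketch_<cycle>.<fmt>` for each cycle with pathways
#' present, and `run_manifest.json` (package version, parameters, input
#' checksums).
#'
#' @param koHits named character vector, sample id to KO hit-table path
#'   (names define the sample set; use `NA` entries to skip KO annotation
#'   for a sample).
#' @param counts named character vector, sample id to counts TSV path;
#'   names must match `koHits`.
#' @param koListPath path to the KO threshold table (ko_list dialect).
#' @param outDir output directory (created if needed).
#' @param customHits optional named character vector of custom-database
#'   hit-table paths.
#' @param customCutoffs data.frame of custom family ceilings (default
#'   [dmspCutoffs()] including the supplementary families).
#' @param definitions list of [PathwayDefinition-class] (default
#'   [builtinDefinitions()]).
#' @param hmmDialect `"tblout"` (default) or `"domtblout"`.
#' @param fallbackEvalue E-value ceiling for threshold-less KOs.
#' @param figureFormat `"png"` (default) or `"svg"`.
#' @param figures draw the heatmap and cycle sketches (default TRUE).
#' @return Invisibly, a list with `profiles`, `pathwayTable`
#'   ([PathwayAbundanceTable-class]), `normalized`, and `files` (paths
#'   written).
#' @export
runPipeline <- function(koHits, counts, koListPath, outDir,
                        customHits = NULL,
                        customCutoffs = dmspCutoffs(all = TRUE),
                        definitions = builtinDefinitions(),
                        hmmDialect = "tblout", fallbackEvalue = 1e-5,
                        figureFormat = c("png", "svg"), figures = TRUE) {
  figureFormat <- match.arg(figureFormat)
  samples <- names(koHits)
  if (is.null(samples) || !identical(sort(samples), sort(names(counts))))
    stop("'koHits' and 'counts' must be named by the same sample ids")
  inputs <- c(stats::na.omit(unname(koHits)), unname(counts),
              koListPath, if (!is.null(customHits)) unname(customHits))
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  thresholds <- readKoThresholds(koListPath)
  per <- lapply(samples, function(s) {
    tryCatch(
      profileSample(s,
        koHitsPath = if (!is.na(koHits[[s]])) koHits[[s]],
        countsPath = counts[[s]],
        koThresholds = thresholds,
        customHitsPath = if (!is.null(customHits) &&
                             !is.na(customHits[s])) customHits[[s]],
        customCutoffs = customCutoffs,
        hmmDialect = hmmDialect, fallbackEvalue = fallbackEvalue),
      error = function(e)
        stop("sample '", s, "': ", conditionMessage(e), call. = FALSE))
  })
  names(per) <- samples

  profiles <- lapply(per, `[[`, "profile")
  pat <- buildPathwayTable(definitions, profiles)
  norm <- normalizeAcrossSamples(pat)

  files <- character()
  geneTpm <- bindProfiles(
    lapply(per, function(x) stats::setNames(x$tpm$tpm, x$tpm$gene_id)),
    samples)
  files["gene_tpm"] <- writeAbundanceTable(
    geneTpm, file.path(outDir, "gene_tpm.tsv"), idColumn = "gene_id")
  famMat <- bindProfiles(lapply(profiles, familyAbundances), samples)
  files["family_abundance"] <- writeAbundanceTable(
    famMat, file.path(outDir, "family_abundance.tsv"),
    idColumn = "family_id")
  files["pathway_abundance"] <- writeAbundanceTable(
    abundanceMatrix(pat), file.path(outDir, "pathway_abundance.tsv"),
    idColumn = "pathway_id")
  files["pathway_normalized"] <- writeAbundanceTable(
    norm, file.path(outDir, "pathway_normalized.tsv"),
    idColumn = "pathway_id")
  for (s in samples)
    files[paste0("annotations_", s)] <- writeAnnotationTable(
      per[[s]]$annotations,
      file.path(outDir, paste0("annotations_", s, ".tsv")))

  if (figures) {
    files["heatmap"] <- renderHeatmap(
      pat, file.path(outDir, paste0("heatmap.", figureFormat)))
    cycles <- unique(vapply(definitions, function(d) d@cycle, character(1)))
    for (cy in cycles) {
      ids <- vapply(definitions, pathwayId, character(1))
      inCycle <- ids[vapply(definitions, function(d) d@cycle, character(1))
                     == cy]
      if (!any(rowSums(abundanceMatrix(pat)[inCycle, , drop = FALSE]) > 0))
        next
      sketchPath <- file.path(outDir,
                              paste0("sketch_", cy, ".", figureFormat))
      renderCycleSketch(norm, cy, sketchPath, definitions = definitions)
      files[paste0("sketch_", cy)] <- sketchPath
    }
  }

  manifest <- list(
    tool = "biogeopath",
    version = as.character(utils::packageVersion("biogeopath")),
    parameters = list(hmmDialect = hmmDialect,
                      fallbackEvalue = fallbackEvalue,
                      figureFormat = figureFormat),
    samples = samples,
    input_md5 = as.list(tools::md5sum(inputs)))
  manifestPath <- file.path(outDir, "run_manifest.json")
  withAtomicFile(manifestPath, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE))
  files["manifest"] <- manifestPath

  invisible(list(profiles = profiles, pathwayTable = pat,
                 normalized = norm, files = files))
}
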