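#' @rdname accessors
#' @aliases sampleId,AbundanceProfile-method
setMethod("sampleId", "AbundanceProfile", function(object) object@sampleId)

#' @rdname accessors
#' @aliases sampleId,CommunityDesign-method
setMethod("sampleId", "CommunityDesign", function(object) object@sampleId)

#' @rdname accessors
#' @aliases familyAbundances,AbundanceProfile-method
setMethod("familyAbundances", "AbundanceProfile",
          function(object) object@abundance)

#' @rdname accessors
#' @aliases pathwayId,PathwayDefinition-method
setMethod("pathwayId", "PathwayDefinition", function(object) object@pathwayId)

#' @rdname accessors
#' @aliases displayName,PathwayDefinition-method
setMethod("displayName", "PathwayDefinition",
          function(object) object@displayName)

#' @rdname accessors
#' @aliases cycle,PathwayDefinition-method
setMethod("cycle", "PathwayDefinition", function(object) object@cycle)

#' @rdname accessors
#' @aliases routes,PathwayDefinition-method
setMethod("routes", "PathwayDefinition", function(object) object@routes)

#' @rdname accessors
#' @aliases abundanceMatrix,PathwayAbundanceTable-method
setMethod("abundanceMatrix", "PathwayAbundanceTable", function(object)
  SummarizedExperiment::assay(object, "abundance"))

#' @rdname accessors
#' @aliases samplePcc,BenchmarkResult-method
setMethod("samplePcc", "BenchmarkResult", function(object)
  stats::setNames(object@pcc, object@sampleIds))

#' @rdname accessors
#' @aliases minPcc,BenchmarkResult-method
setMethod("minPcc", "BenchmarkResult", function(object) object@minPcc)

#' @rdname accessors
#' @aliases genomeId,SyntheticGenome-method
setMethod("genomeId", "SyntheticGenome", function(object) object@genomeId)

#' @rdname accessors
#' @aliases genomeGroup,SyntheticGenome-method
setMethod("genomeGroup", "SyntheticGenome", function(object) object@group)

#' @rdname accessors
#' @aliases genomeGenes,SyntheticGenome-method
setMethod("genomeGenes", "SyntheticGenome", function(object) object@genes)

#' @rdname accessors
#' @aliases designWeights,CommunityDesign-method
setMethod("designWeights", "CommunityDesign", function(object) object@weights)

setMethod("show", "PathwayDefinition", function(object) {
  nComp <- vapply(object@routes, length, integer(1))
  cat("PathwayDefinition '", object@pathwayId, "' (", object@cycle, ")\n",
      "  ", object@displayName, "\n",
      "  ", length(object@routes), " route(s) with ",
      paste(nComp, collapse = ", "), " component(s)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "AbundanceProfile", function(object) {
  cat("AbundanceProfile for sample '", object@sampleId, "': ",
      length(object@abundance), " famil",
      if (length(object@abundance) == 1L) "y" else "ies", "\n", sep = "")
  if (length(object@abundance)) {
    top <- sort(object@abundance, decreasing = TRUE)
    top <- utils::head(top, 5L)
    cat("  top:", paste(sprintf("%s=%.4g", names(top), top),
                        collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "SyntheticGenome", function(object) {
  g <- object@genes
  cat("SyntheticGenome '", object@genomeId, "' (", object@group, "): ",
      nrow(g), " genes, ", sum(!is.na(g$family_id)),
      " family-labelled\n", sep = "")
  invisible(NULL)
})

setMethod("show", "CommunityDesign", function(object) {
  w <- object@weights
  cat("CommunityDesign '", object@sampleId, "': ", sum(w > 0), " of ",
      length(w), " genomes with positive weight\n", sep = "")
  invisible(NULL)
})

setMethod("show", "BenchmarkResult", function(object) {
  cat("BenchmarkResult over", length(object@sampleIds), "samples\n")
  print(round(stats::setNames(object@pcc, object@sampleIds), 6))
  cat("  min PCC:", format(object@minPcc, digits = 6), "\n")
  invisible(NULL)
})
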