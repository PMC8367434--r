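#' @import methods
#' @importFrom stats cor hclust as.dist sd setNames
#' @importFrom utils read.table write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
NULL

PATHWAY_CYCLES <- c("carbon", "nitrogen", "sulfur", "DMSP", "other")

GENOME_GROUPS <- c("photoautotroph", "chemoautotroph", "heterotroph")

#' PathwayDefinition: a pathway as alternative routes of required components
#'
#' A biogeochemical transformation is modelled as one or more alternative
#' *routes* (independent enzyme systems that each accomplish the pathway).
#' A route is an ordered list of *components* (required steps/subunits), and
#' each component is a set of alternative gene-family identifiers (KEGG
#' Orthology ids such as `"K00392"` or curated family names such as
#' `"DmdA"`) any one of which fulfils that step.
#'
#' The pathway relative abundance is the sum over routes of the mean
#' component abundance within each route; see [pathwayAbundance()].
#'
#' @slot pathwayId single identifier string, unique within a definition set.
#' @slot displayName human-readable pathway name.
#' @slot cycle one of `"carbon"`, `"nitrogen"`, `"sulfur"`, `"DMSP"`,
#'   `"other"`.
#' @slot routes list of routes; each route is a list of character vectors
#'   (the components' alternative family ids).
#'
#' @seealso [PathwayDefinition()], [routeAbundance()], [builtinDefinitions()]
#' @export
setClass("PathwayDefinition",
  representation(
    pathwayId   = "character",
    displayName = "character",
    cycle       = "character",
    routes      = "list"
  )
)

setValidity("PathwayDefinition", function(object) {
  msg <- character()
  if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId))
    msg <- c(msg, "'pathwayId' must be a single non-empty string")
  if (length(object@displayName) != 1L || !nzchar(object@displayName))
    msg <- c(msg, "'displayName' must be a single non-empty string")
  if (length(object@cycle) != 1L || !object@cycle %in% PATHWAY_CYCLES)
    msg <- c(msg, sprintf("'cycle' must be one of: %s",
                          paste(PATHWAY_CYCLES, collapse = ", ")))
  if (length(object@routes) < 1L)
    msg <- c(msg, "a pathway needs at least one route")
  for (r in object@routes) {
    if (!is.list(r) || length(r) < 1L) {
      msg <- c(msg, "every route needs at least one component")
      break
    }
    for (comp in r) {
      if (!is.character(comp) || length(comp) < 1L || any(!nzchar(comp))) {
        msg <- c(msg, "every component needs at least one non-empty family id")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayDefinition
#'
#' @param pathwayId pathway identifier.
#' @param routes list of routes; each route a list of character vectors
#'   (components). A bare character vector is promoted to a single-component
#'   route.
#' @param displayName human-readable name; defaults to `pathwayId`.
#' @param cycle biogeochemical cycle label (default `"other"`).
#'
#' @return A [PathwayDefinition-class] object.
#' @examples
#' # Assimilatory sulfite reduction: Sir, or CysJ + CysI
#' asr <- PathwayDefinition("ASR",
#'   routes = list(list("K00392"), list("K00380", "K00381")),
#'   cycle = "sulfur")
#' @export
PathwayDefinition <- function(pathwayId, routes, displayName = pathwayId,
                              cycle = "other") {
  routes <- lapply(routes, function(r) {
    if (is.character(r)) r <- list(r)
    lapply(r, as.character)
  })
  new("PathwayDefinition", pathwayId = as.character(pathwayId),
      displayName = as.character(displayName), cycle = as.character(cycle),
      routes = routes)
}

#' AbundanceProfile: per-sample family relative abundances
#'
#' Maps gene-family identifiers (KO ids and/or curated family names) to
#' TPM-scale relative abundance in one sample. Families absent from the map
#' are semantically zero.
#'
#' @slot sampleId sample identifier.
#' @slot abundance named non-negative numeric vector, names are family ids.
#'
#' @seealso [aggregateProfile()], [familyAbundances()]
#' @export
setClass("AbundanceProfile",
  representation(sampleId = "character", abundance = "numeric")
)

setValidity("AbundanceProfile", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-empty string")
  a <- object@abundance
  if (length(a)) {
    if (is.null(names(a)) || any(!nzchar(names(a))))
      msg <- c(msg, "'abundance' must be named by family id")
    else if (anyDuplicated(names(a)))
      msg <- c(msg, "duplicate family ids in 'abundance'")
    if (any(!is.finite(a)) || any(a < 0))
      msg <- c(msg, "abundances must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceProfile
#'
#' @param sampleId sample identifier.
#' @param abundance named numeric vector of family abundances (may be empty).
#' @return An [AbundanceProfile-class] object.
#' @examples
#' AbundanceProfile("s1", c(K00392 = 4, K00380 = 2))
#' @export
AbundanceProfile <- function(sampleId, abundance = numeric()) {
  new("AbundanceProfile", sampleId = as.character(sampleId),
      abundance = abundance)
}

#' PathwayAbundanceTable: pathways x samples abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single
#' `"abundance"` assay (pathways as rows, samples as columns) and per-row
#' metadata columns `displayName` and `cycle` carried over from the
#' definitions. Built by [buildPathwayTable()].
#'
#' @seealso [abundanceMatrix()], [normalizeAcrossSamples()]
#' @export
setClass("PathwayAbundanceTable", contains = "SummarizedExperiment")

setValidity("PathwayAbundanceTable", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must carry an 'abundance' assay")
  else {
    m <- SummarizedExperiment::assay(object, "abundance")
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msg <- c(msg, "'abundance' assay needs pathway rownames and sample colnames")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "pathway abundances must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticGenome: a designed genome for the community benchmark
#'
#' A genome is a table of genes, each carrying an optional gene-family label
#' (NA marks unannotated filler genes that absorb reads but contribute to no
#' family), a copy number and a nucleotide length.
#'
#' @slot genomeId genome identifier.
#' @slot group functional group, one of `"photoautotroph"`,
#'   `"chemoautotroph"`, `"heterotroph"`.
#' @slot genes data.frame with columns `gene_id`, `family_id` (character,
#'   NA allowed), `copies` (integer >= 1), `length` (integer > 0).
#'
#' @seealso [generateGenomes()]
#' @export
setClass("SyntheticGenome",
  representation(genomeId = "character", group = "character",
                 genes = "data.frame")
)

setValidity("SyntheticGenome", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "'genomeId' must be a single non-empty string")
  if (length(object@group) != 1L || !object@group %in% GENOME_GROUPS)
    msg <- c(msg, sprintf("'group' must be one of: %s",
                          paste(GENOME_GROUPS, collapse = ", ")))
  g <- object@genes
  need <- c("gene_id", "family_id", "copies", "length")
  if (!all(need %in% names(g)))
    msg <- c(msg, sprintf("'genes' must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(g$gene_id))
      msg <- c(msg, "gene ids must be unique within a genome")
    if (any(g$copies < 1L)) msg <- c(msg, "'copies' must be >= 1")
    if (any(g$length <= 0L)) msg <- c(msg, "'length' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' CommunityDesign: genome mixing weights for one simulated sample
#'
#' @slot sampleId sample identifier.
#' @slot weights named non-negative numeric vector of relative genome
#'   abundances (names are genome ids); at least one weight is positive.
#'   Only ratios matter: scaling all weights leaves the design unchanged.
#'
#' @seealso [defaultCommunityDesigns()], [simulateCounts()]
#' @export
setClass("CommunityDesign",
  representation(sampleId = "character", weights = "numeric")
)

setValidity("CommunityDesign", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-empty string")
  w <- object@weights
  if (!length(w) || is.null(names(w)) || any(!nzchar(names(w))))
    msg <- c(msg, "'weights' must be a non-empty vector named by genome id")
  else {
    if (any(!is.finite(w)) || any(w < 0))
      msg <- c(msg, "weights must be finite and non-negative")
    if (!any(w > 0)) msg <- c(msg, "at least one weight must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityDesign
#' @param sampleId sample identifier.
#' @param weights named non-negative numeric vector of genome weights.
#' @return A [CommunityDesign-class] object.
#' @export
CommunityDesign <- function(sampleId, weights) {
  new("CommunityDesign", sampleId = as.character(sampleId), weights = weights)
}

#' BenchmarkResult: per-sample profile-recovery correlations
#'
#' @slot sampleIds sample identifiers.
#' @slot pcc Pearson correlation between the pipeline-computed and the
#'   ground-truth family profile, one value per sample.
#' @slot minPcc minimum of `pcc`.
#'
#' @seealso [runBenchmark()]
#' @export
setClass("BenchmarkResult",
  representation(sampleIds = "character", pcc = "numeric", minPcc = "numeric")
)

setValidity("BenchmarkResult", function(object) {
  msg <- character()
  if (length(object@sampleIds) != length(object@pcc))
    msg <- c(msg, "'sampleIds' and 'pcc' lengths differ")
  if (any(object@pcc < -1 - 1e-12) || any(object@pcc > 1 + 1e-12))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(object@minPcc) != 1L ||
      !isTRUE(all.equal(object@minPcc, min(object@pcc))))
    msg <- c(msg, "'minPcc' must equal min(pcc)")
  if (length(msg)) msg else TRUE
})
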