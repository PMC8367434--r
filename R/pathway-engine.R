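# The route/mean formula engine. A pathway's relative abundance is the sum
# over its alternative routes of the mean abundance of each route's
# components: A_i = sum_m ( (a_m_1 + ... + a_m_n) / n ). An undetected
# component contributes 0 to the numerator while the denominator stays n
# (the thiosulfate-disproportionation case: phsB undetected, divisor still
# 3). Within a component, alternative families pool by sum.

#' Abundance of one pathway component
#'
#' A component is a set of alternative gene families any one of which
#' fulfils the step; its abundance is the sum of the profile's abundances
#' over those families, counting absent families as zero.
#'
#' @param component character vector of alternative family ids.
#' @param profile an [AbundanceProfile-class] or named numeric vector.
#' @return A single non-negative number.
#' @export
componentAbundance <- function(component, profile) {
  a <- if (is(profile, "AbundanceProfile")) familyAbundances(profile)
       else profile
  vals <- a[component]
  sum(vals[!is.na(vals)])
}

#' Abundance of one pathway route
#'
#' The arithmetic mean of the route's component abundances; undetected
#' components contribute 0 to the numerator and the denominator stays the
#' number of components (essential subunits) in the route.
#'
#' @param route list of components (character vectors).
#' @param profile an [AbundanceProfile-class] or named numeric vector.
#' @return A single non-negative number.
#' @examples
#' # thiosulfate reductase: phsB undetected, divisor stays 3
#' routeAbundance(list("phsA", "phsB", "phsC"),
#'                c(phsA = 6, phsC = 3))   # (6 + 0 + 3) / 3 = 3
#' @export
routeAbundance <- function(route, profile) {
  sum(vapply(route, componentAbundance, numeric(1), profile = profile)) /
    length(route)
}

#' Relative abundance of a pathway in one sample
#'
#' Sum of [routeAbundance()] over the pathway's alternative routes. For
#' assimilatory sulfite reduction this evaluates
#' `a_K00392 + (a_K00380 + a_K00381)/2`; for dissimilatory nitrite
#' reduction to ammonia, `(a_K00362 + a_K00363)/2 + (a_K03385 +
#' a_K15876)/2`.
#'
#' @param definition a [PathwayDefinition-class].
#' @param profile an [AbundanceProfile-class] or named numeric vector.
#' @return A single non-negative number.
#' @examples
#' asr <- PathwayDefinition("ASR",
#'   routes = list(list("K00392"), list("K00380", "K00381")),
#'   cycle = "sulfur")
#' pathwayAbundance(asr, c(K00392 = 4, K00380 = 2, K00381 = 6))  # 4 + 4 = 8
#' @export
pathwayAbundance <- function(definition, profile) {
  sum(vapply(routes(definition), routeAbundance, numeric(1),
             profile = profile))
}

#' Evaluate pathway definitions over sample profiles
#'
#' Evaluates every definition against every profile and assembles the
#' pathways x samples matrix. Row order follows definition order, column
#' order follows input sample order; pathways absent everywhere keep their
#' all-zero row.
#'
#' @param definitions list of [PathwayDefinition-class] objects.
#' @param profiles list of [AbundanceProfile-class] objects with distinct
#'   sample ids.
#' @return A [PathwayAbundanceTable-class] (a `SummarizedExperiment` with
#'   one `"abundance"` assay and rowData columns `displayName`, `cycle`).
#' @export
buildPathwayTable <- function(definitions, profiles) {
  stopifnot(length(profiles) >= 1L, length(definitions) >= 1L)
  sids <- vapply(profiles, sampleId, character(1))
  if (anyDuplicated(sids))
    stop("duplicate sample ids: ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "))
  pids <- vapply(definitions, pathwayId, character(1))
  m <- vapply(profiles, function(p)
    vapply(definitions, pathwayAbundance, numeric(1), profile = p),
    numeric(length(definitions)))
  m <- matrix(m, nrow = length(definitions), ncol = length(profiles),
              dimnames = list(pids, sids))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = m),
    rowData = S4Vectors::DataFrame(
      displayName = vapply(definitions, displayName, character(1)),
      cycle = vapply(definitions, cycle, character(1)),
      row.names = pids))
  new("PathwayAbundanceTable", se)
}

#' Built-in pathway definitions
#'
#' The shipped subset of the pathway formula catalogue, loaded from the
#' package's definition file (the same schema users can extend or replace):
#' assimilatory sulfite reduction, dissimilatory nitrite reduction to
#' ammonia, thiosulfate disproportionation (the three thiosulfate reductase
#' subunits phsA/phsB/phsC), the DMSP cycle (biosynthesis, demethylation
#' DMSP to MMPA and MMPA to MeSH, cleavage by the eight lyases, DMS and
#' MeSH oxidation, DMSO reduction, the MddA pathway), the three
#' sulfoquinovose degradation pathways (sulfo-EMP, sulfo-ED, SFT), and
#' isoprene degradation. Additional pathways load from user files via
#' [readPathwayDefinitions()].
#'
#' @return Named list of [PathwayDefinition-class] objects.
#' @export
builtinDefinitions <- function() {
  readPathwayDefinitions(system.file("extdata", "pathway_definitions.tsv",
                                     package = "biogeopath",
                                     mustWork = TRUE))
}
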