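#' Accessors for biogeopath classes
#'
#' Small accessor generics so that slots are never reached into directly:
#' `sampleId()` returns the sample identifier of a profile or design,
#' `familyAbundances()` the named abundance vector of an
#' [AbundanceProfile-class], `pathwayId()`, `displayName()`, `cycle()` and
#' `routes()` the corresponding parts of a [PathwayDefinition-class],
#' `abundanceMatrix()` the pathways x samples matrix of a
#' [PathwayAbundanceTable-class], and `samplePcc()` / `minPcc()` the
#' correlations of a [BenchmarkResult-class].
#'
#' @param object an object of the documented class.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("familyAbundances",
           function(object) standardGeneric("familyAbundances"))

#' @rdname accessors
#' @export
setGeneric("pathwayId", function(object) standardGeneric("pathwayId"))

#' @rdname accessors
#' @export
setGeneric("displayName", function(object) standardGeneric("displayName"))

#' @rdname accessors
#' @export
setGeneric("cycle", function(object) standardGeneric("cycle"))

#' @rdname accessors
#' @export
setGeneric("routes", function(object) standardGeneric("routes"))

#' @rdname accessors
#' @export
setGeneric("abundanceMatrix",
           function(object) standardGeneric("abundanceMatrix"))

#' @rdname accessors
#' @export
setGeneric("samplePcc", function(object) standardGeneric("samplePcc"))

#' @rdname accessors
#' @export
setGeneric("minPcc", function(object) standardGeneric("minPcc"))

#' @rdname accessors
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))

#' @rdname accessors
#' @export
setGeneric("genomeGroup", function(object) standardGeneric("genomeGroup"))

#' @rdname accessors
#' @export
setGeneric("genomeGenes", function(object) standardGeneric("genomeGenes"))

#' @rdname accessors
#' @export
setGeneric("designWeights", function(object) standardGeneric("designWeights"))

#' Normalize a pathway table across samples
#'
#' Divides each pathway's abundance in a sample by the summed abundance of
#' that pathway over all samples, so every non-zero row becomes a vector of
#' within-pathway fractions summing to 1; all-zero rows are kept as zeros.
#' This is the normalization used for the cross-sample cycle sketches.
#'
#' @param table a [PathwayAbundanceTable-class] or a numeric matrix with
#'   pathways as rows and samples as columns.
#' @return A numeric matrix of the same shape with row-wise fractions.
#' @examples
#' m <- matrix(c(2, 3, 5), nrow = 1,
#'             dimnames = list("ASR", c("s1", "s2", "s3")))
#' normalizeAcrossSamples(m)   # 0.2 0.3 0.5
#' @export
setGeneric("normalizeAcrossSamples",
           function(table) standardGeneric("normalizeAcrossSamples"))
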