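# TPM quantification and aggregation of gene TPM into per-family profiles.

#' Compute per-gene TPM
#'
#' TPM (transcripts per million) of gene *i* is its length-normalized read
#' rate divided by the sample's total rate, times 10^6:
#' `tpm_i = 1e6 * (X_i / L_i) / sum_j (X_j / L_j)`, where `X_i` is the
#' number of reads mapped to the gene and `L_i` its length. In coverage
#' mode the average per-base coverage is used directly as the rate, since
#' coverage is already proportional to `X_i / L_i` (coverage =
#' reads x read length / gene length); both modes therefore agree exactly
#' after the within-sample normalization.
#'
#' If every rate is zero (e.g. an empty control), all TPM values are zero
#' rather than an error.
#'
#' @param records data.frame with columns `gene_id`, `length`, and `reads`
#'   or `avg_coverage`, for one sample; typically from [readCountsTable()]
#'   or [simulateCounts()]. The mode is taken from the `"mode"` attribute
#'   when present, else from which value column exists.
#' @return data.frame with columns `gene_id` and `tpm`; TPM sums to 10^6
#'   whenever any gene has signal.
#' @examples
#' rec <- data.frame(gene_id = c("A", "B"), length = c(100, 400),
#'                   reads = c(10, 20))
#' computeTpm(rec)   # rates 0.1, 0.05 -> TPM 666666.67, 333333.33
#' @export
computeTpm <- function(records) {
  mode <- attr(records, "mode")
  if (is.null(mode))
    mode <- if ("reads" %in% names(records)) "reads" else "coverage"
  if (anyDuplicated(records$gene_id))
    stop("duplicate gene ids in counts table")
  rate <- if (mode == "reads") {
    if (any(!is.finite(records$length)) || any(records$length <= 0))
      stop("gene lengths must be positive")
    if (any(records$reads < 0)) stop("read counts must be non-negative")
    records$reads / records$length
  } else {
    if (any(records$avg_coverage < 0)) stop("coverage must be non-negative")
    records$avg_coverage
  }
  total <- sum(rate)
  tpm <- if (total > 0) 1e6 * rate / total else rep(0, length(rate))
  data.frame(gene_id = records$gene_id, tpm = tpm, stringsAsFactors = FALSE)
}

#' Aggregate gene TPM into a per-family abundance profile
#'
#' Each family's abundance is the summed TPM of the genes annotated with it.
#' A gene annotated with k families contributes its full TPM to each of the
#' k families (no splitting), and unannotated genes contribute to no family
#' while still having absorbed part of the TPM denominator. Multi-copy
#' families therefore show proportionally larger abundance — intended
#' signal, not an artifact.
#'
#' @param sampleId sample identifier for the resulting profile.
#' @param tpms data.frame from [computeTpm()].
#' @param annotations named list (gene id to family ids), e.g. from
#'   [assignKos()] / [mergeAnnotations()].
#' @return An [AbundanceProfile-class].
#' @export
aggregateProfile <- function(sampleId, tpms, annotations) {
  keep <- tpms$gene_id %in% names(annotations)
  if (!any(keep))
    return(AbundanceProfile(sampleId))
  tp <- tpms[keep, , drop = FALSE]
  fams <- annotations[tp$gene_id]
  reps <- lengths(fams)
  flat <- data.frame(family = unlist(fams, use.names = FALSE),
                     tpm = rep(tp$tpm, reps))
  ab <- vapply(split(flat$tpm, flat$family), sum, numeric(1))
  AbundanceProfile(sampleId, ab[order(names(ab))])
}
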