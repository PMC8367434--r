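# Readers/writers for the external formats the pipeline touches. Downstream
# modules only ever see the parsed objects, never raw files.

# write to a temp file in the target directory, then rename into place
withAtomicFile <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not write '", path, "'")
  invisible(path)
}

stopIfMissing <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: '", path, "'")
}

#' Read an HMMER3 tabular search result
#'
#' Parses the per-sequence (`tblout`) or per-domain (`domtblout`) tabular
#' output of `hmmsearch`. These files are whitespace-aligned, not TSV: the
#' first 18 (`tblout`) / 22 (`domtblout`) fields are split on whitespace and
#' the remainder of each line is the free-text description. Lines starting
#' with `#` are comments. A gene hit by the same family more than once
#' yields one row per reported hit.
#'
#' Column mapping (HMMER3 layout): the target name is the gene, the query
#' name is the family (KO id or curated family name); `tblout` provides the
#' full-sequence E-value/score and the best-single-domain score, `domtblout`
#' the full-sequence E-value/score and the per-domain score.
#'
#' @param path path to the file.
#' @param dialect `"tblout"` (default) or `"domtblout"`.
#' @return A data.frame with columns `gene_id`, `family_id`, `full_score`,
#'   `dom_score`, `evalue` — one row per reported hit.
#' @examples
#' f <- tempfile()
#' writeLines(c(
#'   "# comment",
#'   paste("g1 - K00392 - 1e-50 210.3 0.1 1e-49 209.0 0.1",
#'         "1 1 0 1 1 1 1 1 some description")), f)
#' readHmmTable(f)
#' @export
readHmmTable <- function(path, dialect = c("tblout", "domtblout")) {
  dialect <- match.arg(dialect)
  stopIfMissing(path)
  ncols <- if (dialect == "tblout") 18L else 22L
  cols <- if (dialect == "tblout") {
    # target acc query acc fullE fullScore fullBias domE domScore domBias ...
    list(gene = 1L, family = 3L, evalue = 5L, full = 6L, dom = 9L)
  } else {
    # target acc tlen query acc qlen fullE fullScore fullBias # of cE iE
    # domScore ...
    list(gene = 1L, family = 4L, evalue = 7L, full = 8L, dom = 14L)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  k <- 0L
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(fields) < ncols)
      stop(sprintf("%s line %d: expected at least %d columns, found %d",
                   dialect, i, ncols, length(fields)))
    num <- suppressWarnings(as.numeric(
      fields[c(cols$evalue, cols$full, cols$dom)]))
    if (anyNA(num))
      stop(sprintf("%s line %d: non-numeric score or E-value", dialect, i))
    if (num[1L] < 0)
      stop(sprintf("%s line %d: negative E-value", dialect, i))
    k <- k + 1L
    out[[k]] <- data.frame(
      gene_id = fields[cols$gene], family_id = fields[cols$family],
      full_score = num[2L], dom_score = num[3L], evalue = num[1L],
      stringsAsFactors = FALSE)
  }
  if (k == 0L)
    return(data.frame(gene_id = character(), family_id = character(),
                      full_score = numeric(), dom_score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

#' Read a KO threshold table (ko_list dialect)
#'
#' Reads the KOfam `ko_list` table of per-KO adaptive cutoffs: each KO
#' carries its own suggested bit-score threshold and a score type saying
#' whether the full-sequence or the best-domain score is thresholded.
#' Some KOs ship without a numeric threshold (marked `"-"`); these are
#' retained but flagged `has_threshold = FALSE`, and annotation falls back
#' to an E-value ceiling for them (see [assignKos()]).
#'
#' @param path path to a tab-separated file with a header row; required
#'   columns are the KO id (named `knum`, `ko`, or `family_id`),
#'   `threshold`, and `score_type` (`"full"` or `"domain"`); a `definition`
#'   column is carried through when present.
#' @return A data.frame with columns `family_id`, `threshold` (NA when
#'   absent), `score_type`, `has_threshold`, `definition`; one row per KO.
#' @export
readKoThresholds <- function(path) {
  stopIfMissing(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  idCol <- intersect(c("knum", "ko", "family_id"), names(tab))[1]
  if (is.na(idCol) || !all(c("threshold", "score_type") %in% names(tab)))
    stop("ko_list table needs a KO id column ('knum'/'ko'/'family_id'), ",
         "'threshold' and 'score_type'")
  thr <- suppressWarnings(as.numeric(tab$threshold))
  st <- as.character(tab$score_type)
  bad <- !st %in% c("full", "domain") & is.finite(thr)
  if (any(bad))
    stop("invalid score_type (must be 'full' or 'domain') for: ",
         paste(utils::head(tab[[idCol]][bad], 5L), collapse = ", "))
  data.frame(
    family_id = as.character(tab[[idCol]]),
    threshold = thr,
    score_type = st,
    has_threshold = is.finite(thr),
    definition = if ("definition" %in% names(tab))
      as.character(tab$definition) else NA_character_,
    stringsAsFactors = FALSE)
}

#' Read a per-gene counts/coverage table
#'
#' The quantification input is a TSV with a header and columns `gene_id`,
#' `length` (nucleotides), and exactly one of `reads` (mapped read count)
#' or `avg_coverage` (average per-base coverage, e.g. from pileup).
#'
#' @param path path to the TSV.
#' @return A data.frame with columns `gene_id`, `length`, and the value
#'   column; attribute `"mode"` is `"reads"` or `"coverage"`.
#' @seealso [computeTpm()]
#' @export
readCountsTable <- function(path) {
  stopIfMissing(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length") %in% names(tab)))
    stop("counts table needs 'gene_id' and 'length' columns")
  hasReads <- "reads" %in% names(tab)
  hasCov <- "avg_coverage" %in% names(tab)
  if (hasReads == hasCov)
    stop("counts table needs exactly one of 'reads' or 'avg_coverage'")
  if (any(!is.finite(tab$length)) || any(tab$length <= 0))
    stop("gene lengths must be positive")
  val <- if (hasReads) tab$reads else tab$avg_coverage
  if (any(!is.finite(val)) || any(val < 0))
    stop("counts/coverage must be finite and non-negative")
  out <- tab[, c("gene_id", "length", if (hasReads) "reads" else
    "avg_coverage")]
  attr(out, "mode") <- if (hasReads) "reads" else "coverage"
  out
}

#' Write a per-gene counts table
#'
#' Inverse of [readCountsTable()]; the benchmark writes this dialect so the
#' production reader is exercised end to end.
#'
#' @param records data.frame as returned by [readCountsTable()] or
#'   [simulateCounts()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCountsTable <- function(records, path) {
  withAtomicFile(path, function(tmp)
    utils::write.table(records, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Read pathway definitions
#'
#' The definition file is a TSV with a header and one row per component:
#' `pathway_id`, `display_name`, `cycle`, `route_index`, `component_index`,
#' `families` (comma-separated alternative family ids). Route and component
#' indices are 1-based and consecutive within a pathway; rows of one
#' pathway must be contiguous, and a pathway id may only be defined once.
#'
#' @param path path to the TSV.
#' @return A named list of [PathwayDefinition-class] objects in file order.
#' @seealso [builtinDefinitions()], [writePathwayDefinitions()]
#' @export
readPathwayDefinitions <- function(path) {
  stopIfMissing(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  need <- c("pathway_id", "display_name", "cycle", "route_index",
            "component_index", "families")
  if (!all(need %in% names(tab)))
    stop("pathway definition file needs columns: ",
         paste(need, collapse = ", "))
  blocks <- rle(tab$pathway_id)$values
  if (anyDuplicated(blocks))
    stop("duplicate pathway id: ",
         paste(unique(blocks[duplicated(blocks)]), collapse = ", "))
  defs <- lapply(blocks, function(pid) {
    rows <- tab[tab$pathway_id == pid, , drop = FALSE]
    routes <- lapply(sort(unique(rows$route_index)), function(ri) {
      rr <- rows[rows$route_index == ri, , drop = FALSE]
      rr <- rr[order(rr$component_index), , drop = FALSE]
      if (!identical(as.integer(rr$component_index),
                     seq_len(nrow(rr))))
        stop("pathway '", pid, "' route ", ri,
             ": component indices must be consecutive from 1")
      lapply(rr$families, function(f) {
        fams <- trimws(strsplit(f, ",", fixed = TRUE)[[1]])
        if (!length(fams) || any(!nzchar(fams)))
          stop("pathway '", pid, "': empty component family list")
        fams
      })
    })
    ri <- sort(unique(rows$route_index))
    if (!identical(as.integer(ri), seq_along(ri)))
      stop("pathway '", pid, "': route indices must be consecutive from 1")
    PathwayDefinition(pid, routes,
                      displayName = rows$display_name[[1]],
                      cycle = rows$cycle[[1]])
  })
  stats::setNames(defs, blocks)
}

#' Write pathway definitions
#'
#' Inverse of [readPathwayDefinitions()].
#'
#' @param definitions list of [PathwayDefinition-class] objects.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePathwayDefinitions <- function(definitions, path) {
  rows <- lapply(definitions, function(d) {
    rts <- routes(d)
    do.call(rbind, lapply(seq_along(rts), function(ri)
      do.call(rbind, lapply(seq_along(rts[[ri]]), function(ci)
        data.frame(pathway_id = pathwayId(d), display_name = displayName(d),
                   cycle = cycle(d), route_index = ri, component_index = ci,
                   families = paste(rts[[ri]][[ci]], collapse = ","),
                   stringsAsFactors = FALSE)))))
  })
  tab <- do.call(rbind, rows)
  withAtomicFile(path, function(tmp)
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Write an abundance matrix as TSV
#'
#' Writes a features x samples matrix (gene TPM, family abundance, pathway
#' abundance, or normalized fractions) as UTF-8 TSV with `.` decimals and a
#' leading id column.
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @param idColumn name for the leading id column (default `"id"`).
#' @return The path, invisibly.
#' @export
writeAbundanceTable <- function(mat, path, idColumn = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  tab <- data.frame(rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- idColumn
  withAtomicFile(path, function(tmp)
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Read an abundance matrix written by [writeAbundanceTable()]
#'
#' @param path path to the TSV.
#' @return A numeric matrix with row names from the leading id column.
#' @export
readAbundanceTable <- function(path) {
  stopIfMissing(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Write a gene annotation table
#'
#' One row per annotated gene: `gene_id` and the comma-joined family ids.
#'
#' @param annotations named list of character vectors (gene id to family
#'   ids), as returned by [assignKos()] and friends.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeAnnotationTable <- function(annotations, path) {
  tab <- data.frame(
    gene_id = names(annotations),
    families = vapply(annotations, function(f)
      paste(sort(f), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  withAtomicFile(path, function(tmp)
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}

#' Read a gene annotation table written by [writeAnnotationTable()]
#'
#' @param path path to the TSV.
#' @return Named list of character vectors (gene id to family ids).
#' @export
readAnnotationTable <- function(path) {
  stopIfMissing(path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "families") %in% names(tab)))
    stop("annotation table needs 'gene_id' and 'families' columns")
  stats::setNames(strsplit(tab$families, ",", fixed = TRUE), tab$gene_id)
}
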