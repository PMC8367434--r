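# Desk-scale replication of the simulated-community validation: designed
# genomes with known family content, multinomial count simulation, an
# analytically derived truth profile, and Pearson-correlation scoring of
# profile recovery. Read simulation and assembly are deliberately not
# modelled: counts are drawn directly at the gene level, which preserves
# exactly what the validation compares (family relative-abundance
# profiles).

#' Default group-exclusive marker family sets
#'
#' Three pairwise-disjoint marker sets emulating the functional structure
#' of a three-group community: photoautotrophs carry photosystem-like
#' families, chemoautotrophs ammonia-oxidation families (including a
#' designated multi-copy nitrite-reductase-like marker), heterotrophs
#' transporter/osmolyte families. The ids are representative KO ids chosen
#' for realism; the benchmark only relies on the group structure, not on
#' the biological identity of each id.
#'
#' @return Named list of character vectors, one per group.
#' @seealso [generateGenomes()]
#' @export
defaultMarkerSets <- function() {
  list(
    photoautotroph = c("K02703", "K02706", "K02689", "K02690", "K02634",
                       "K02636"),
    chemoautotroph = c("K10944", "K10945", "K10946", "K00368", "K01428",
                       "K01429"),
    heterotroph    = c("K02035", "K02036", "K02037", "K05845", "K05846",
                       "K03070")
  )
}

#' Default shared (core) family set
#'
#' Families carried by every genome regardless of group, emulating core
#' housekeeping and energy-conversion genes.
#'
#' @return Character vector of family ids.
#' @export
defaultSharedFamilies <- function() {
  c("K02111", "K02112", "K02108", "K01689", "K00927", "K00134", "K01803",
    "K04077")
}

#' Generate synthetic genomes for the benchmark
#'
#' Builds `n_per_group` genomes for each of the three functional groups.
#' Every genome carries all of its group's marker families (one copy each,
#' except the designated multi-copy marker, emulating a multi-copy nitrite
#' reductase), all shared families, plus unannotated filler genes that
#' absorb reads without contributing to any family. Shared-family copy
#' numbers are drawn per genome from `sharedCopyRange`, emulating the
#' copy-number variation of real genomes; without it a single-group
#' community would have a constant truth profile, whose recovery
#' correlation is undefined. Gene lengths are drawn uniformly from
#' `lengthRange`. Fully deterministic under `seed`.
#'
#' @param seed integer seed; identical seeds give identical genomes.
#' @param nPerGroup genomes per group (default 5, for 15 genomes total).
#' @param markerSets named list of pairwise-disjoint marker family sets,
#'   one per group (default [defaultMarkerSets()]).
#' @param sharedSet families present in every genome, disjoint from all
#'   marker sets (default [defaultSharedFamilies()]).
#' @param multiCopyFamily marker carried in multiple copies by genomes of
#'   its group (default `"K00368"`); `NA` disables.
#' @param multiCopyCopies copy number for `multiCopyFamily` (default 3).
#' @param fillerPerGenome unannotated filler genes per genome (default 20).
#' @param lengthRange integer range of gene lengths in nt (default
#'   300–3000).
#' @param sharedCopyRange integer range of per-genome copy numbers for
#'   shared families (default 1–3).
#' @return List of [SyntheticGenome-class] objects.
#' @export
generateGenomes <- function(seed, nPerGroup = 5L,
                            markerSets = defaultMarkerSets(),
                            sharedSet = defaultSharedFamilies(),
                            multiCopyFamily = "K00368",
                            multiCopyCopies = 3L,
                            fillerPerGenome = 20L,
                            lengthRange = c(300L, 3000L),
                            sharedCopyRange = c(1L, 3L)) {
  allMarkers <- unlist(markerSets, use.names = FALSE)
  if (anyDuplicated(allMarkers) || length(intersect(allMarkers, sharedSet)))
    stop("marker sets must be pairwise disjoint and disjoint from the ",
         "shared set")
  set.seed(as.integer(seed))
  genomes <- list()
  for (group in names(markerSets)) {
    for (i in seq_len(nPerGroup)) {
      gid <- sprintf("%s_%02d", group, i)
      fams <- c(markerSets[[group]], sharedSet)
      copies <- c(rep(1L, length(markerSets[[group]])),
                  sample(sharedCopyRange[1]:sharedCopyRange[2],
                         length(sharedSet), replace = TRUE))
      if (!is.na(multiCopyFamily) && multiCopyFamily %in% fams)
        copies[fams == multiCopyFamily] <- as.integer(multiCopyCopies)
      fams <- c(fams, rep(NA_character_, fillerPerGenome))
      copies <- c(copies, rep(1L, fillerPerGenome))
      genes <- data.frame(
        gene_id = sprintf("%s_g%03d", gid, seq_along(fams)),
        family_id = fams,
        copies = copies,
        length = sample(lengthRange[1]:lengthRange[2], length(fams),
                        replace = TRUE),
        stringsAsFactors = FALSE)
      genomes[[gid]] <- new("SyntheticGenome", genomeId = gid,
                            group = group, genes = genes)
    }
  }
  genomes
}

#' Default five-sample community designs
#'
#' Mirrors the structure of the reference validation: five samples spanning
#' single-group communities (sample 1 photoautotrophs only, sample 2
#' heterotrophs only, sample 3 chemoautotrophs only) and two mixed
#' communities (sample 4 at group ratio 2:2:1, sample 5 at 1:1:1,
#' photoautotroph:heterotroph:chemoautotroph). Within a group, weight is
#' split equally over its genomes. The exact mixing ratios of the mixed
#' samples are structural stand-ins, not reproductions.
#'
#' @param genomes list of [SyntheticGenome-class] objects.
#' @return List of [CommunityDesign-class] objects.
#' @export
defaultCommunityDesigns <- function(genomes) {
  groups <- vapply(genomes, genomeGroup, character(1))
  gids <- vapply(genomes, genomeId, character(1))
  ratios <- list(
    sample1 = c(photoautotroph = 1, heterotroph = 0, chemoautotroph = 0),
    sample2 = c(photoautotroph = 0, heterotroph = 1, chemoautotroph = 0),
    sample3 = c(photoautotroph = 0, heterotroph = 0, chemoautotroph = 1),
    sample4 = c(photoautotroph = 2, heterotroph = 2, chemoautotroph = 1),
    sample5 = c(photoautotroph = 1, heterotroph = 1, chemoautotroph = 1))
  lapply(names(ratios), function(sid) {
    w <- ratios[[sid]][groups] / as.vector(table(groups)[groups])
    CommunityDesign(sid, stats::setNames(as.numeric(w), gids))
  })
}

#' Analytically derived ground-truth family profile
#'
#' Under the count model of [simulateCounts()], a gene's expected reads are
#' proportional to `weight * copies * length`, so its expected
#' length-normalized rate is proportional to `weight * copies`. The truth
#' abundance of family f is therefore `sum_g weight_g * copies_{f,g}`
#' normalized to 10^6 over *all* gene instances — filler genes included in
#' the denominator, mirroring the real pipeline where unannotated ORFs
#' still absorb reads — and then restricted to labelled families.
#'
#' @param design a [CommunityDesign-class].
#' @param genomes list of [SyntheticGenome-class] objects covering every
#'   genome the design references.
#' @return An [AbundanceProfile-class] of TPM-scale truth abundances.
#' @export
groundTruthProfile <- function(design, genomes) {
  w <- designWeights(design)
  gids <- vapply(genomes, genomeId, character(1))
  if (!all(names(w) %in% gids))
    stop("design references unknown genomes: ",
         paste(setdiff(names(w), gids), collapse = ", "))
  tabs <- lapply(genomes, function(g) {
    wg <- w[genomeId(g)]
    if (is.na(wg) || wg == 0) return(NULL)
    genes <- genomeGenes(g)
    data.frame(family_id = genes$family_id, rate = wg * genes$copies,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  total <- sum(tab$rate)
  if (total <= 0) stop("design has no positive-weight genes")
  lab <- tab[!is.na(tab$family_id), , drop = FALSE]
  fam <- vapply(split(lab$rate, lab$family_id), sum, numeric(1))
  AbundanceProfile(sampleId(design), 1e6 * fam[order(names(fam))] / total)
}

#' Simulate per-gene mapped-read counts for one sample
#'
#' Draws a multinomial sample of `depth` reads over all gene instances of
#' the community, with per-gene probability proportional to
#' `weight * copies * length` (longer and higher-copy genes attract
#' proportionally more reads, as in shotgun sequencing). Read length does
#' not enter the count model and is accepted for interface completeness
#' only.
#'
#' @param design a [CommunityDesign-class].
#' @param genomes list of [SyntheticGenome-class] objects.
#' @param depth total reads for the sample (default 1e5).
#' @param readLen nominal read length in nt (unused by the count model).
#' @param seed integer seed; identical seeds give identical counts.
#' @return data.frame in reads mode (columns `gene_id`, `length`, `reads`;
#'   attribute `"mode" = "reads"`), one row per gene of every
#'   positive-weight genome.
#' @export
simulateCounts <- function(design, genomes, depth = 1e5, readLen = 150L,
                           seed) {
  stopifnot(depth >= 0)
  w <- designWeights(design)
  tabs <- lapply(genomes, function(g) {
    wg <- w[genomeId(g)]
    if (is.na(wg) || wg == 0) return(NULL)
    genes <- genomeGenes(g)
    data.frame(gene_id = genes$gene_id, length = genes$length,
               mass = wg * genes$copies * genes$length,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  rownames(tab) <- NULL
  set.seed(as.integer(seed))
  counts <- if (depth > 0)
    as.vector(stats::rmultinom(1, size = as.integer(depth),
                               prob = tab$mass / sum(tab$mass)))
  else rep(0L, nrow(tab))
  out <- data.frame(gene_id = tab$gene_id, length = tab$length,
                    reads = counts, stringsAsFactors = FALSE)
  attr(out, "mode") <- "reads"
  out
}

#' Pearson correlation between two family profiles
#'
#' Computed over the union of the two profiles' family ids, counting absent
#' families as zero. A profile with zero variance over that union has no
#' defined correlation and is an error.
#'
#' @param a,b [AbundanceProfile-class] objects or named numeric vectors.
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
profilePcc <- function(a, b) {
  av <- if (is(a, "AbundanceProfile")) familyAbundances(a) else a
  bv <- if (is(b, "AbundanceProfile")) familyAbundances(b) else b
  fams <- union(names(av), names(bv))
  x <- ifelse(is.na(av[fams]), 0, av[fams])
  y <- ifelse(is.na(bv[fams]), 0, bv[fams])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a profile has zero variance over the ",
         "family union")
  stats::cor(x, y)
}

# perfect annotations straight from the genome designs (gene -> family)
genomeAnnotations <- function(genomes) {
  tabs <- lapply(genomes, function(g) {
    genes <- genomeGenes(g)
    genes[!is.na(genes$family_id), c("gene_id", "family_id")]
  })
  tab <- do.call(rbind, tabs)
  stats::setNames(as.list(tab$family_id), tab$gene_id)
}

#' Run the community-recovery benchmark
#'
#' For each community design: simulate counts, push them through the
#' production quantification path ([computeTpm()] then
#' [aggregateProfile()], with the genomes' own family labels standing in
#' for perfect annotation), and score the computed profile against the
#' analytic ground truth with [profilePcc()].
#'
#' @param depth reads per sample (default 1e5).
#' @param seed integer master seed: genomes are generated with `seed` and
#'   sample counts with `seed * 10 + 1, 2, ...` per sample.
#' @param nPerGroup genomes per group (default 5).
#' @param genomes optional pre-built genome list; defaults to
#'   [generateGenomes()] under `seed`.
#' @param designs optional list of [CommunityDesign-class]; defaults to
#'   [defaultCommunityDesigns()].
#' @return A [BenchmarkResult-class].
#' @examples
#' \donttest{
#' res <- runBenchmark(depth = 1e5, seed = 1)
#' minPcc(res)
#' }
#' @export
runBenchmark <- function(depth = 1e5, seed = 1L, nPerGroup = 5L,
                         genomes = NULL, designs = NULL) {
  if (is.null(genomes))
    genomes <- generateGenomes(seed, nPerGroup = nPerGroup)
  if (is.null(designs))
    designs <- defaultCommunityDesigns(genomes)
  ann <- genomeAnnotations(genomes)
  pcc <- vapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    counts <- simulateCounts(d, genomes, depth = depth,
                             seed = as.integer(seed) * 10L + i)
    prof <- aggregateProfile(sampleId(d), computeTpm(counts), ann)
    profilePcc(prof, groundTruthProfile(d, genomes))
  }, numeric(1))
  sids <- vapply(designs, sampleId, character(1))
  new("BenchmarkResult", sampleIds = sids, pcc = pcc, minPcc = min(pcc))
}

#' Write a benchmark report TSV
#'
#' @param result a [BenchmarkResult-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeBenchmarkReport <- function(result, path) {
  tab <- data.frame(sample_id = result@sampleIds, pcc = result@pcc,
                    stringsAsFactors = FALSE)
  withAtomicFile(path, function(tmp)
    utils::write.table(tab, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE))
}
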