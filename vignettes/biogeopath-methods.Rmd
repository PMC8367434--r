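---
title: "Methods: pathway relative abundance from metagenomic gene profiles"
author: "biogeopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway relative abundance from metagenomic gene profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biogeopath)
```

## Scope and data flow

`biogeopath` starts where the heavyweight external tools stop. Assembly,
ORF prediction and read mapping are upstream, external steps; the package
ingests their outputs — HMMER3 `tblout`/`domtblout` search tables, a
`ko_list`-style per-KO threshold table, and per-gene counts or coverage
TSVs — and produces pathway relative-abundance tables and figures. This
split keeps the package's own computation (thresholded annotation, TPM,
the pathway formula, the benchmark) fully reproducible without any
external binary.

The stages are: `readHmmTable()` → `assignKos()` /
`assignCustomFamilies()` → `mergeAnnotations()`; `readCountsTable()` →
`computeTpm()` → `aggregateProfile()`; then `buildPathwayTable()`,
`normalizeAcrossSamples()` and the renderers. `runPipeline()` wires them
together.

## Quantification model

Per-gene relative abundance is TPM: the gene's length-normalized read
rate `X_i / L_i` divided by the sample's total rate, times 10^6. Two
input modes exist because mapping pipelines report either raw mapped-read
counts or average per-base coverage:

* **reads mode** — the rate is `X_i / L_i` (reads per nucleotide);
* **coverage mode** — the average coverage is used directly as the rate,
  since coverage = reads × read length / gene length is proportional to
  `X_i / L_i`; the proportionality constant (read length) cancels in the
  within-sample normalization, so the two modes agree exactly, which the
  test suite pins.

Degenerate inputs are defined, not fatal: a sample in which every gene
has zero signal yields all-zero TPM so that empty controls flow through
the pipeline. Gene TPM sums to 10^6 (to floating-point tolerance)
whenever any rate is positive, and is exactly invariant to rescaling all
counts.

Family abundance is the plain sum of TPM over the genes annotated with
the family. Two deliberate consequences: a gene with k families
contributes its full TPM to each (no splitting — both functions are
genuinely present), and a family carried by more gene copies shows
proportionally higher abundance. No copy-number correction is applied;
multi-copy amplification is treated as signal (a multi-copy nitrite
reductase should look abundant).

## Annotation thresholds

Each KO family carries its own suggested bit-score cutoff and a score
type: `full` thresholds the full-sequence score, `domain` the
best/per-domain score. Acceptance is boundary-inclusive
(`score >= threshold`, `evalue <= ceiling`), matching the reporting
semantics of `hmmsearch -T` / `--domT`. Threshold tables in the wild
contain KOs whose threshold field is `-`; these are kept but flagged, and
annotation for them falls back to a full-sequence E-value ceiling
(default `1e-5`, tunable via `fallbackEvalue`) rather than silently
accepting or dropping everything.

The curated DMSP-cycling database is configuration, not code:
`dmspCutoffs()` returns the shipped table of per-family E-value
ceilings. The default set contains exactly the twenty manually collected
families (three synthesis, four demethylation-path, eight lyases, AcuH,
DmoA, DorA, MddA, MTO). Two judgement calls are recorded here:

* DorA is among the twenty collected genes but its individual ceiling is
  not documented upstream; it defaults to `1e-30`, the value used for
  the other weakly-constrained families.
* The DMS→DMSO step is covered by the DMS dehydrogenase complex and Tmm,
  which are *not* in the twenty-gene set, and the upstream description of
  their cutoff ("both DdhABC, DdhB, and Tmm") is ambiguous about whether
  the complex carries one cutoff or one per subunit. The shipped
  resolution lists DdhA, DdhB, DdhC and Tmm each at `1e-30` in a
  `supplementary` set returned by `dmspCutoffs(all = TRUE)`, so the
  built-in `dms_to_dmso` definition is fully covered while the core set
  stays at twenty.

## The pathway formula

A pathway is one or more alternative routes; a route is an ordered list
of components; a component is a set of alternative families. The
abundance of pathway *i* is

\[
A_i = \sum_{m\ \in\ \text{routes}} \frac{a_{m\_1} + a_{m\_2} + \dots +
a_{m\_n}}{n}
\]

the arithmetic mean over the `n` components of each route, summed over
routes. The mean (not the sum) makes multi-gene pathways comparable with
single-gene pathways within a sample. Three evaluation rules matter:

* **Missing components count 0, the divisor stays `n`.** Thiosulfate
  disproportionation is the anchor case: the thiosulfate reductase
  electron-transport subunit (phsB) is frequently undetected in real
  metagenomes, yet the pathway is still `(a_phsA + 0 + a_phsC)/3` — a
  deliberately conservative estimate of an incompletely observed system.
* **Within a component, alternatives pool by sum.** The catalogue's
  worked formulas never exercise this rule, so it was an open choice;
  sum was chosen because DMSP cleavage is conventionally reported as the
  pooled abundance of all eight lyase genes, and max/mean would
  understate a community using several isoenzymes. Component and route
  order never affect values.
* **Definitions are data.** The engine evaluates whatever the TSV schema
  encodes (`pathway_id`, `display_name`, `cycle`, `route_index`,
  `component_index`, comma-joined families), so the full pathway
  catalogue can be transcribed in user files without touching code.
  `builtinDefinitions()` ships a documented subset: ASR, DNRA,
  thiosulfate disproportionation, the nine DMSP-cycle transformations,
  the three sulfoquinovose pathways and isoprene degradation. The
  thiosulfate subunits are identified by gene name (phsA/phsB/phsC), as
  in the literature for that pathway; ids are opaque to the engine. The
  sulfo-ED and SF-transaldolase enzymes have no standard gene symbols
  (the sources give EC numbers), so they carry descriptive ids (SQDH,
  SGLL, SGDT, KDSGA, SLADH, SFTA); the SFT route reuses K18479 (the
  sulfo-EMP isomerase) and SLADH, shared steps of those pathways.

## The synthetic benchmark

The benchmark answers one question: does the quantification path recover
a community's family profile? Fifteen genomes (five per functional
group) carry group-exclusive marker families, shared housekeeping
families, and unannotated filler genes; five community designs span
single-group communities (samples 1–3) and two mixed ratios (2:2:1 and
1:1:1). Per-gene counts are multinomial with probability ∝ weight ×
copies × length, the shotgun-sequencing expectation; the analytic truth
for family f is the normalized `sum_g weight_g × copies_{f,g}` (lengths
cancel in expectation because TPM divides by length). Filler genes stay
in the truth denominator, mirroring real pipelines where unannotated
ORFs still absorb reads.

Design choices worth recording:

* **Counts, not reads.** Read simulation, assembly and mapping noise are
  deliberately not modelled: the validation compares family profiles,
  which direct count simulation preserves at a fraction of the cost.
  Consequently a passing benchmark certifies the quantification and
  aggregation arithmetic under sampling noise — not robustness to
  assembly fragmentation, chimeras or mapping ambiguity.
* **Copy-number variation in shared families.** Shared-family copy
  numbers are drawn per genome from 1–3. With every family at exactly
  one copy, a single-group community would have a *constant* truth
  profile, and a Pearson correlation against it is undefined (zero
  variance); real genomes vary in copy number, and this variation is
  what makes single-group samples informative. Markers stay single-copy
  except one designated multi-copy marker (three copies) in the
  chemoautotroph group, emulating the multi-copy nitrite reductase
  pattern of ammonia-oxidizing archaea.
* **Exact mixing ratios** of the mixed samples (2:2:1, 1:1:1) are
  structural stand-ins: the benchmark's claim is profile recovery across
  community structures, not reproduction of any particular mixture.
* All randomness flows through explicit seeds (genomes from the master
  seed, per-sample counts from `seed*10 + i`); identical seeds give
  bit-identical designs, counts and scores.

At 100 000 reads per sample the minimum per-sample PCC is ≥ 0.99 for the
default design; recovery degrades gracefully with depth and improves
monotonically in expectation, which the suite checks by comparing mean
PCC across depths. The test suite runs the full 15-genome benchmark at
depths of 10^3–10^5 reads and the property suites at 20–50 random
replicates per invariant — sizes chosen so the whole suite stays
interactive while keeping multinomial standard errors well below the
tolerances asserted.

## Reporting

* `normalizeAcrossSamples()` divides each pathway's abundance by its
  cross-sample total (all-zero rows stay zero), giving the within-pathway
  fractions used by the cycle sketches; it is idempotent on normalized
  rows.
* `bubbleTransform()` is `log10(1000·x)` with zeros masked as `NA`
  rather than pseudo-counted — undetected pathways render as absent, and
  no arbitrary pseudo-count leaks into the colour/size scale.
* `clusterSamples()` uses Bray–Curtis dissimilarity with average
  linkage, the community-ecology default; both are arguments because the
  choice is conventional, not principled. Samples are sorted by id
  before the distance computation so the tree is independent of input
  column order.
* Renderers write SVG or PNG according to the output extension (one
  format per call — callers asking for `figure.svg` should not receive a
  surprise sibling file), write atomically (temp file + rename), and
  never mutate their inputs. `renderCycleSketch()` draws markers whose
  *area* is linear in the normalized fraction and returns the marker
  geometry invisibly, so the linearity is testable from geometry rather
  than pixels.

## Known limitations

* No between-sample compositional correction: TPM is a within-sample
  measure, and cross-sample comparisons inherit its compositional
  caveats.
* Multi-mapped reads are whatever the upstream counting produced; the
  counts-table contract deliberately pushes that choice upstream.
* The benchmark does not model sequencing error, assembly or mapping
  noise (above), and the shipped pathway subset is a small fraction of a
  full catalogue — the schema, not the subset, is the interface.
* Pathway abundance is genetic potential; it says nothing about
  expression or rates without metatranscriptomes or process
  measurements.
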