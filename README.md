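# biogeopath

Functional profiling of biogeochemical cycles from metagenomic and
metatranscriptomic data. `biogeopath` turns per-gene read counts and
homology-search results into relative abundances of carbon, nitrogen,
sulfur and DMSP (dimethylsulfoniopropionate) cycling pathways across
samples, and ships a synthetic-community benchmark that quantifies how
accurately the pipeline recovers known gene-family profiles.

It is aimed at microbial ecologists who have already assembled their
reads, predicted ORFs, searched the proteins against profile HMMs
(KOfam and/or a curated family database) and mapped reads back to genes
— i.e. everything downstream of the heavyweight external tools.

## The model

**Gene quantification.** The relative abundance of gene *i* in a sample
is its TPM,

```
TPM_i = 10^6 * (X_i / L_i) / sum_j (X_j / L_j)
```

with `X_i` mapped reads and `L_i` gene length; average per-base coverage
can be used directly in place of `X_i / L_i` (it is proportional to it).

**Annotation.** A hit against KO family *k* is accepted when its bit
score reaches that family's own adaptive threshold (full-sequence or
best-domain score, per the threshold table's score type; boundary
inclusive), rather than a universal cutoff. Curated DMSP-cycling
families are accepted by per-family E-value ceilings (e.g. DmdA at
1e-130). A gene keeps *every* accepted family.

**Pathway abundance.** A pathway is a set of alternative routes; each
route is a list of required components (enzymes/subunits), and the
family abundance `a` feeds the formula

```
A_i = sum over routes m of  (a_m_1 + a_m_2 + ... + a_m_n) / n
```

— the mean over a route's `n` components (undetected components count 0
but the divisor stays `n`), summed over alternative routes. For example
assimilatory sulfite reduction (Sir, or CysJ+CysI) evaluates as
`A_ASR = a_K00392 + (a_K00380 + a_K00381)/2`.

**Benchmark.** Designed genomes in three functional groups
(photoautotroph / chemoautotroph / heterotroph) are mixed into
communities, per-gene counts are drawn multinomially, and the
pipeline-computed family profile is scored against the analytically
known truth with Pearson's correlation (PCC).

## Worked example

```r
library(biogeopath)

counts <- data.frame(gene_id = paste0("g", 1:4),
                     length  = c(300, 600, 900, 1200),
                     reads   = c(30, 60, 90, 12))
tpm <- computeTpm(counts)
#   gene_id       tpm
# 1      g1 322580.65
# 2      g2 322580.65
# 3      g3 322580.65
# 4      g4  32258.06

ann  <- list(g1 = "K00392", g2 = "K00380", g3 = "K00381", g4 = "DmdA")
prof <- aggregateProfile("vent1", tpm, ann)
defs <- builtinDefinitions()
m <- abundanceMatrix(buildPathwayTable(defs, list(prof)))
round(m[m[, 1] > 0, , drop = FALSE], 2)
#                        vent1
# ASR                645161.29
# dmsp_demethylation  32258.06
```

Genes g1–g3 have equal read rates (reads/length), so each gets TPM
322 580.65 out of the million; g4's rate is ten times lower. The ASR
value is the worked formula above: `322580.65 + (322580.65 +
322580.65)/2 = 645161.29`, and DMSP demethylation equals its single
marker DmdA. On real data the same numbers come from
`runPipeline()`, which reads HMMER3 `tblout`/`domtblout` tables, a
`ko_list`-style threshold table and per-gene counts TSVs, and writes
the gene/family/pathway tables, figures and a JSON run manifest.

The benchmark prints per-sample recovery correlations:

```r
runBenchmark(depth = 1e5, seed = 1)
# BenchmarkResult over 5 samples
#  sample1  sample2  sample3  sample4  sample5
# 0.998809 0.998422 0.999416 0.999644 0.999465
#   min PCC: 0.998422
```

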