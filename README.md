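# karyoscope

Somatic copy-number analysis of tumor cohorts from multi-platform signals,
built around an explicit answer to the question low-pass sequencing cannot
answer on its own: *what is this genome's baseline?*

Tumor read depth and SNP-array log R ratio (LRR) are relative signals — a
whole-genome doubled tumor looks flat in both, exactly like a diploid one.
karyoscope reconstructs allele-specific **virtual karyotypes** by jointly
segmenting binned read depth and SNP-array (LRR, BAF) signals, then fitting
tumor purity `p` and baseline ploidy `ψ` by a grid search in which every
segment maps to its nearest integer (total, minor) copy-number state under

```
LRR*(n)   = log2((p·n + 2(1−p))/2) − log2((p·ψ + 2(1−p))/2)
dBAF*(n,b) = | 1/2 − (p·b + (1−p)) / (p·n + 2(1−p)) |
```

The mirrored heterozygous BAF deviation `dBAF` is what breaks the baseline
ambiguity: doubled-LOH (4+0) and 3+1 states, the hallmark of genome-doubled
tumors, are inconsistent with a diploid reading of flat LRR. Ties between
exactly degenerate interpretations go to the lower ploidy.

On top of per-sample karyotypes, the package provides the cohort layer:

* cytogenetic-band CNA matrices (a band is called when ≥60% covered),
  with F10/region-boundary scores for how well bands represent segments;
* per-sample genomic-instability metrics, including the **aneuploidy
  score** (number of chromosome arms ≥80% covered by CNA);
* GISTIC-style recurrence scores with a cyclic-shift permutation null;
* Ward clustering of band alteration patterns (binary or cosine distance);
* 48-channel copy-number signature profiles matched to reference
  signatures by Euclidean similarity;
* gene-dosage integration: per-gene copy-number/expression correlation,
  band-level expression summaries, a rank-based differential test, and
  CpG-island methylation/copy-number correlations;
* a fully parameterised synthetic-cohort generator that emits all five
  data layers (read depth, SNP LRR/BAF, expression counts, methylation β)
  with known ground truth, and a `runPipeline()` orchestrator with a
  checksummed manifest.

It is intended for method developers and analysts working with low-pass
WGS + SNP-array tumor profiling (the motivating setting is pituitary
tumor cytogenetics, where one tumor cluster is near-tetraploid and another
carries recurrent chromosome-11 monosomy), and for anyone needing a
self-contained, simulation-backed copy-number analysis stack.

## Worked example

Simulate a small cohort, rebuild one sample's karyotype from its raw
signals, and check the fit:

```r
library(karyoscope)

model <- syntheticGenomeModel(chroms = c(1, 8, 11, 16, 19, 22))
cfg   <- cohortConfig(nWgd = 1, nChr11Loss = 1, nMultidel = 0, nStable = 1,
                      seed = 7)
co    <- simulateCohort(cfg, model)

kt <- buildKaryotype(co@readDepth[[2]], co@snp[[2]], sampleId = "S02", seed = 7)
kt$fit
#> PurityPloidyFit: purity 0.66, ploidy 1.82 (psi 1.75), objective 0.0006341, BAF used
kt$consensus
#> VirtualKaryotype S02 [consensus]: 9 segments, purity 0.66, ploidy 1.82
#>   CNA (vs diploid):  1 gains, 2 losses

instabilityMetrics(kt$consensus, model)
#> $cnaCount
#> [1] 3
#> $fractionAltered
#> [1] 0.2957447
#> $aneuploidyScore
#> [1] 2
```

Sample S02 is the planted chromosome-11 monosomy (true purity 0.66 —
recovered exactly): the chr11 loss covers both chr11 arms (aneuploidy
score 2) and the sample carries two focal extras, three consensus CNAs in
all over 30% of this reduced six-chromosome genome. The WGD sample in the
same cohort fits at ploidy 3.49 with BAF; refitting its SNP segments with
`fitPurityPloidy(segs, useBaf = FALSE)` yields 2.49 — the depth-only
mis-baselining the package exists to fix.

Cohort-level calls follow the same pattern on the full default genome:
`bandCnaMatrix()` → `cohortInstability()` / `gisticLikeScores()` /
`clusterSamples()` / `cohortProfile()` → `bestMatch()`.

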