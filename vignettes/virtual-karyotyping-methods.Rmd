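---
title: "Virtual karyotyping and cohort copy-number analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual karyotyping and cohort copy-number analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscope)
```

karyoscope reconstructs allele-specific integer copy-number profiles
("virtual karyotypes") of tumor genomes from three relative signal layers —
binned sequencing read depth, SNP-array log R ratio (LRR) and B-allele
frequency (BAF) — and analyzes cohorts of such profiles at cytogenetic-band
resolution: genomic-instability metrics, recurrence statistics, clustering,
copy-number signature matching, and gene-dosage integration with expression
and methylation layers. This vignette states the models, the tunable
parameters and their defaults, the numerical choices, and what the bundled
synthetic cohort does and does not emulate.

## The signal model

A tumor sample is a mixture of tumor cells at fraction $p$ (purity) and
normal diploid cells at fraction $1-p$. A genomic segment carries an
integer total copy number $n$ and minor-allele copy number $b \le n/2$ in
the tumor compartment. The bulk DNA amount at that segment is proportional
to $p\,n + 2(1-p)$.

Neither sequencing depth nor array intensity carries an absolute scale:
depth is set by the sequencing run and arrays are intensity-normalized. All
log-ratio signals are therefore *relative*, and the package centers them by
the length-weighted mean before model fitting. For a candidate baseline
ploidy $\psi$, the expected centered log ratio of a segment is

$$\mathrm{LRR}^*(n) \;=\; \log_2\frac{p\,n + 2(1-p)}{2} \;-\;
  \log_2\frac{p\,\psi + 2(1-p)}{2},$$

and the expected mirrored heterozygous BAF deviation of an $(n, b)$ state is

$$d^*(n, b) \;=\; \left|\,\tfrac12 - \frac{p\,b + (1-p)}{p\,n + 2(1-p)}\right|.$$

Two consequences of relative signals drive the design:

* a perfectly balanced genome-doubled sample (2+2 everywhere) is
  *mathematically indistinguishable* from a diploid one — depth and LRR are
  flat and every heterozygous BAF sits at 0.5. Identifiability comes from
  the allelically imbalanced states real genome-doubled tumors carry
  (doubled-LOH 4+0, pre-doubling trisomy 3+1), which only BAF can see;
* exact degeneracy families exist: shifting every allele count by $-1$
  while moving purity to $p/(1+p)$, or doubling every allele count while
  moving purity to $p/(2-p)$, reproduces every LRR and BAF value exactly.
  These are resolved by explicit rules, not by the data (below).

## Segmentation

Each chromosome is segmented by recursive binary splitting. For read depth,
counts are converted to $\log_2$ ratios against the sample median; the
candidate boundary maximizes the two-sample $t$ statistic, and a split is
accepted when its permutation $p$-value (1000 permutations of the bin
order, seeded, early-stopped once 20 exceedances make rejection certain)
falls below `alpha = 0.01` with at least `minBins = 5` bins per side. SNP
data are segmented jointly on LRR and mirrored heterozygous BAF deviation
with the statistic $t^2_{\mathrm{LRR}} + t^2_{\mathrm{BAF}}$ and at least
10 heterozygous SNPs per segment. Heterozygosity is taken from the array
genotype column when present; the fallback window BAF $\in (0.15, 0.85)$
cannot see fully collapsed LOH at high purity, which is exactly the
evidence that re-baselines genome-doubled samples — genotypes should be
supplied whenever available. A region without usable heterozygous SNPs
falls back to LRR-only evidence and is flagged. Segmentation is invariant
to a constant multiplicative factor on the input counts.

## Purity and ploidy fitting

`fitPurityPloidy()` scans purity $\in [0.2, 1]$ in steps of 0.01 and
$\psi \in [1.5, 5.5]$ in steps of 0.05. For each candidate, every segment
maps to its nearest $(n, b)$ lattice point ($n \le 8$) and the objective is
the length-weighted squared distance in LRR and BAF. Three numerical
choices matter:

* **Folded BAF model.** The observed mean of $|{\rm BAF} - 1/2|$ has a
  noise floor $\sigma\sqrt{2/\pi}$ even for balanced segments. The model
  therefore predicts the folded-normal mean of $d^*$ given a per-sample
  noise $\sigma$ estimated from homozygous-SNP residuals. Without this the
  search drifts toward dense low-purity lattices that can chase the bias.
* **Spacing-normalized residuals.** LRR and BAF residuals are scored in
  units of the local lattice spacing (the LRR step between adjacent totals
  and the BAF step between adjacent minor states at the baseline).
  Low-purity candidates compress the lattice; without normalization small
  absolute residuals hand them an artificial advantage.
* **Admissibility.** A candidate must be self-consistent — the implied
  ploidy (length-weighted mean fitted total) within 0.5 of $\psi$ — and may
  not assign more than 5% of the genome to total copy 0: large homozygous
  deletions are lethal, and unconstrained zero-copy assignments admit an
  exact degenerate family in which the diploid bulk is "deleted" at low
  purity and every alteration becomes LOH.

Ties go to lower ploidy: all candidates whose objective lies within a
relative band of the minimum ($3\times$ the minimum plus a small absolute
floor — the width of grid-snapping and noise differences between *exactly*
degenerate interpretations) are treated as equivalent, the branch around
the lowest such ploidy is selected, and that branch's own optimum is
returned. This is the conservative default of allele-specific copy-number
practice; decisive BAF evidence (doubled-LOH and 3+1 states) overrides it,
which is precisely how genome-doubled samples are re-baselined, and why
depth-only fitting of the same samples settles on ploidy 2.

Integer assignment (`assignIntegerCopyNumber()`) reuses the fitted lattice
and produces two CNA class encodings per segment: `class` relative to
$\mathrm{round}(\hat\psi)$ and `class2` relative to the diploid state. A
3-copy segment in a tetraploid genome is a baseline-relative loss but a
diploid-relative gain; band-level cohort representations consume the
diploid-relative encoding so that genome-doubled samples appear as the
globally duplicated genomes they are.

## Platform integration and exclusion filtering

`mergePlatformCalls()` intersects (default) the two platforms'
baseline-relative CNA calls per class; only extents where both agree
survive, with copy-number values taken from the SNP platform (it carries
allele-specific calls). Union mode keeps single-platform extents flagged
and resolves opposite-class conflicts toward the platform with more
markers. Everything outside consensus CNA is re-tiled as neutral baseline.
Two hygiene rules keep segment counts meaningful: baseline filler pieces
shorter than 100 kb (platform boundary jitter) adopt their wider neighbor's
copy number, and adjacent segments with identical state are consolidated.
`filterExcludedRegions()` subtracts blacklist-style intervals from every
CNA call and drops fragments shorter than 50 kb (5 bins).

## Band representation and instability metrics

A band is labeled gain (loss) when segments of that class cover at least
60% of it; if both classes qualify the larger covered fraction wins and an
exact tie goes to neutral with a warning. Band copy number is the
length-weighted mean total, rounded half-up. Representation quality is
scored by $F_{\beta}$ with $\beta = 10$ (recall-weighted), treating
base-pair-resolution band labels as prediction and segment labels as
truth, per class and combined by alteration-length weighting; and by a
region boundary score (RBS): the mean, over CNA segment boundaries, of the
distance to the nearest band boundary divided by the chromosome length,
so 0 is perfect. The RBS formula is this package's own; no numeric
equivalence with any external implementation is claimed. A sample with no
CNA returns NA for both scores (undefined, not perfect).

Per sample, three instability measures are computed from the
diploid-relative encoding: the number of CNA segments, the genome fraction
covered by CNA, and the aneuploidy score — the number of chromosome arms
whose union of CNA segments covers at least 80% of the arm. All autosomal
arms are scored by default; `armSubset` restricts the set (e.g. dropping
acrocentric p arms), since arm panels differ between studies.

## Recurrence and clustering

`gisticLikeScores()` assigns each band and class a G-score
$\sum_s |{\rm CN}_{bs} - 2| \cdot \mathbb{1}[{\rm state}_{bs} = c]$. The
null preserves each sample's burden and within-genome structure while
destroying cross-sample alignment: every sample's genome-ordered band
vector is cyclically shifted by an independent uniform offset, 1000 times.
A band's $p$-value is the fraction of the *pooled genome-wide* permuted
band scores at least as large as its observed score (+1 correction);
Benjamini–Hochberg within class gives $q$, with 0.25 as the conventional
reporting threshold. This is a documented reimplementation of the G-score
idea, not a numerical reproduction of any packaged implementation.

`clusterSamples()` encodes each sample as a binary vector over band ×
{gain, loss} features and clusters with Ward agglomeration (`ward.D2`, the
squared-dissimilarity update) on either the asymmetric binary (Jaccard)
distance — discordant features over features present in at least one
sample, with distance 0 between two all-neutral samples by convention — or
cosine distance with the same zero-vector convention. `cutClusters()`
renumbers cut labels by first occurrence so labelings are stable.

## Copy-number signatures

`encodeSegments()` maps every segment to one of 48 channels: 3 homozygous-
deletion size classes, LOH (minor 0) × 5 total-copy classes × 5 size
classes, and heterozygous × 4 total-copy classes × 5 size classes. Neutral
heterozygous segments are counted by default (the encoding describes the
whole genome, not only alterations); `includeNeutral = FALSE` restricts to
CNA. Calls made on a scaled-down genome pass `lengthScale` so segment
lengths map to real-genome size classes. Cohort profiles sum channel counts
and L2-normalize; similarity to a reference profile is $1 - d/\sqrt2$ with
$d$ the Euclidean distance between unit vectors (in $[0,1]$ for nonnegative
vectors; 1 iff equal, 0 at disjoint support), with $1/(1+d)$ available as
an alternative. The bundled reference matrix is a *synthetic* two-column
fixture — a CN1-like diploid profile (heterozygous 2-copy mass) and a
CN2-like tetraploid profile (heterozygous 3–4-copy and doubled-LOH mass) —
for testing discrimination; real reference signature matrices are external
content the user supplies in the same 48-row format.

## Dosage integration

Expression counts are normalized to $\log_2(\mathrm{CPM}+1)$. Band-level
expression is the mean per-gene z-score over the genes whose midpoint falls
in the band — scale-free, matching heat-map semantics; no covariate
adjustment is performed. Gene copy number is the length-weighted mean total
over the gene span per source, averaged across sources. Gene-wise
CN–expression association uses Spearman correlation with $|\rho| > 0.5$ as
the moderate/high flag; genes with zero copy-number variance are excluded.
The two-group differential test is a per-gene Mann–Whitney test on
normalized expression with BH correction and a $|FC| > 2$, $q < 0.05$ DEG
flag; per-chromosome DEG enrichment uses one-sided binomial tests against
the genome-wide rate, BH-corrected per direction. Methylation analyses use
median β per CpG category (island/shore/shelf/open-sea and seven gene
regions) Spearman-correlated with per-sample CNA count, and per-band
Pearson correlation between band copy number and the median β of the
band's CpG-island (or gene-5′) probes, requiring three probes and
copy-number variance. Spearman at gene level and Pearson at band level
mirror the conventions of the analyses this package operationalizes.

One caveat the synthetic experiments make explicit: CPM-style
normalization cancels genome-wide dosage. In a sample with more than half
its genome gained, the library size scales with ploidy and gained genes
show little CPM-scale effect; dosage is recoverable where copy number
varies against a stable background (deletions, individual trisomies), and
the dosage-recovery validation therefore uses a cohort of that shape.

## The synthetic cohort

`simulateCohort()` is first-class, tested code that defines the study
conditions for every cohort-level validation. The default configuration is
a 40-sample cohort: 15 WGD-like high-aneuploidy samples, 6 with
chromosome-11 monosomy, 3 multi-deletion samples (losses among 1p, 15q, 16,
22), and 16 near-stable samples; purity uniform in 0.5–0.9.

The genome frame is a deterministic scaled autosomal genome:
hg19-proportional chromosome lengths divided by 35 (≈79 Mb total),
hg19-like centromere positions, ~0.5 Mb bands (165 bands), ~2000 genes
placed at per-chromosome totals proportional to real protein-coding counts
with a within-chromosome density gradient, and a 7-probe methylation panel
per gene (promoter island/shore probes, body/3′/intergenic open-sea
probes, occasional shelf probes). The scale keeps a full cohort simulation
and karyotype reconstruction within minutes on one CPU; problem sizes in
the validation suite (40-sample cohorts, a 20-sample purity × archetype
grid, 10 tetraploid fits, 100-replicate band oracles) are stated choices
of this package.

Generator structure worth knowing when interpreting test results:

* WGD samples gain whole chromosomes/arms, preferentially gene-poor, until
  a per-sample target fraction (uniform 0.5–0.8) of the genome is gained;
  gained units are 3 copies (2+1) or 4 copies split 60% 2+2, 20% 3+1, 20%
  4+0. The imbalanced states make ploidy identifiable from BAF, as in real
  genome-doubled tumors.
* Focal gains recur at ten fixed gene-poor hotspot bands (focal
  duplications in tumors are recurrent); focal losses center on bands drawn
  proportionally to gene density. This reproduces the positive
  loss-density / negative gain-density band correlations.
* Stable samples carry 0–3 focal events with only 10% entirely flat —
  tumor genomes with literally zero CNAs are rare.
* Emission: bin counts are negative binomial with mean
  $d\,(p\,n + 2(1-p))$ for depth-per-copy $d$ (default 50 per 10 kb bin);
  LRR/BAF get Gaussian noise (sd 0.13 and 0.03), SNPs at 0.2/kb with 50%
  heterozygous and a germline genotype column; expression is negative
  binomial with mean $\propto (\mathrm{bulk\ CN}/2)^{\rm slope}$ (slope 1,
  20% dosage-insensitive genes); methylation β is beta-distributed with
  low baselines on island/5′ probes and a $+\Delta\beta\cdot p$ shift
  (default 0.25) on island/5′ probes over segments with total copy below
  2.

What it does **not** emulate — and hence what green tests do *not* show
about real data: no GC/mappability waves or replication-timing structure in
depth, no array "genomic waves", no subclonal (fractional) copy number, no
chromothripsis breakpoint microstructure, no real reference signature
content, no biological covariation between expression programs and
methylation beyond copy-number coupling, and an idealized blacklist. The
validations demonstrate internal correctness and identifiability under the
stated noise model, not robustness to artifacts absent from it.

## Reproducibility and degenerate inputs

Every stochastic routine takes or derives an explicit seed; identical
configuration and seed give byte-identical cohorts and pipeline output
checksums (`runPipeline()` writes per-stage md5 sums into its manifest).
Degenerate inputs have defined behavior rather than accidents: empty
interval sets are identities; zero-CNA samples yield NA representation
scores and zero instability; zero-variance metrics, constant gene density,
constant band copy number and single-sample cohorts return NA sentinels
with warnings; single-sample recurrence returns $q = 1$ with a warning;
all-zero signature profiles are flagged. The 60% band rule and 80% arm
rule are exact at their boundaries (coverage is computed from integer
widths with a $10^{-9}$ guard).

## Known limitations

* The purity grid starts at 0.2; lower-purity samples are not fitted.
* Maximum lattice total is 8 copies; higher amplifications saturate.
* Homozygous-deletion fractions above 5% of the genome are treated as
  inadmissible fits, so genuinely massive biallelic loss would be
  mis-modeled (it is also biologically implausible).
* A sample with no allelic imbalance anywhere and flat LRR is reported at
  the lowest consistent ploidy by design; its true ploidy is not
  identifiable from relative signals.
* The recurrence scheme shares GISTIC's intent, not its implementation;
  q-values are comparable within a run, not across tools.
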