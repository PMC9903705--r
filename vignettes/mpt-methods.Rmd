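---
title: "Methods: clonal inference from multi-patient targeted scDNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal inference from multi-patient targeted scDNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptsc)
```

## The setting

Multi-patient targeted (MPT) single-cell DNA sequencing pools the somatic
mutations of a patient cohort into one custom amplicon panel and profiles
each tumor's cells against it. Every cell yields two aligned observables:
a genotype matrix (cells × variants, with codes 0 = hom ref, 1 = het,
2 = hom alt and a missing sentinel that is never conflated with 0) and an
amplicon read-count matrix (cells × amplicons). From these, `mptsc`
recovers the clonal substructure: which subclones exist, their consensus
genotypes and copy-number states, which cells are droplet doublets, and
the mutational lineage tree relating the subclones to the diploid
population.

## Quality filtering

Barcodes are first called as cells when at least 80% of amplicons have
nonzero reads and the total reads pass a cutoff; the absolute cutoff used
by vendor pipelines is not portable across depths, so the default is the
scale-free `0.2 ×` median per-cell total (configurable).

The genotype cascade (`filter_single_cell_matrix()`) applies, in a fixed
logged order: entry-level masking to missing (genotype quality < 30,
depth < 10, or an alternate call with allele fraction < 20% — reference
calls are not AF-masked); removal of variants genotyped in < 50% of
cells; of cells genotyped at < 50% of variants; of variants mutated in
< 1% of cells; of heterozygous germline variants present in > 95% of
cells; and finally of rows/columns with > 50% missing entries. The
percentage filters are defined over *genotyped* (non-missing) cells —
the source pipelines do not state the denominator, and the genotyped
denominator makes the germline and mutated-fraction rules independent of
missingness. Entry masking runs first because every percentage is
defined over genotyped entries. The cascade is idempotent and its ledger
satisfies exact accounting (input = output + removals per axis); both
are tested properties. Bulk variant tables get the matching consensus
filter (≥ 3 supporting reads), a clustered-region filter that removes
*all* members of any group of mutations within 10 bp of one another
(the source rule is ambiguous about whether the first member survives;
removing all is the conservative reading), and low-coverage (< 10×)
flagging as missing rather than removal.

## Clustering and consensus profiles

Cells are clustered by agglomerative hierarchical clustering (complete
linkage, Euclidean distance) on genotype codes, with missing entries
imputed as reference **only** for distance and embedding computations —
never for consensus or fraction statistics. The cluster count is chosen
by the largest mean silhouette width over k = 2..8; the source analyses
picked k by visual inspection of UMAP plots, which is not automatable,
and the silhouette criterion is the standard replacement. Clusters
smaller than `max(20, 1% of cells)` are outliers; the cluster whose
consensus genotype carries the fewest mutant calls is the diploid
(normal) population. A PCA→UMAP embedding (components explaining ≥ 90%
variance, capped at 10; `n_neighbors = 15, a = 1, b = 1`, with the
inter-patient preset `a = b = 1.2` available) is computed for reporting;
clustering operates in genotype space because UMAP dispersion is
dominated by technical noise in highly clonal samples.

Consensus genotypes are the modal non-missing code per cluster per
variant, ties broken toward the lower code; clusters with no genotyped
cell at a variant give missing.

## Copy number

`estimate_copy_ratios()` implements the two-step normalization: each
cell's counts are divided by that cell's total reads, then each amplicon
by the median of the normalized values over the normal (reference)
cells. The result is a copy ratio with 1.0 ≈ diploid representation;
cluster medians summarize it and a gain/loss is called at
|log2 median| ≥ 0.32 (≈ 1.25× / 0.8×; the source annotates gains and
losses without stating cutoffs, so the thresholds are configurable).
Per-cell total normalization makes ratios compositional: a clone whose
total genomic content differs from diploid is biased by a clone-constant
factor. Ratios are therefore reported on the relative scale, and
absolute calibration is left to the FACS ploidy model:
`integer_cn_profile()` multiplies segment ratios by the mean ploidy
(2 × aneuploid/diploid peak position) and rounds half away from zero
(avoiding banker's-rounding surprises at 0.5), with the consensus
profile the per-segment median over cells. Circular binary segmentation
is out of scope; the function accepts precomputed segment ratios.

## Doublet identification

A droplet doublet carries roughly twice the genomic content of a
singlet. Crucially, the per-cell total normalization above cancels this
signal *exactly* — every cell's mean ratio is ≈ 1 regardless of content
— so the doublet screen uses ratios computed **without** the per-cell
step (`per_cell_normalize = FALSE`): counts divided by the reference
per-amplicon medians, which preserves total content.

The screen takes a cluster assignment, selects the cluster with the
highest log2 grand-mean ratio as candidate, and compares its per-variant
mean ratio vector against the mean over the remaining clusters with a
one-sided paired t-test across variants. Two calibration problems arise:
the candidate is a *maximum*, and per-cell capture efficiency shifts all
variants of a cluster coherently, so the analytic Student reference is
drastically anti-conservative under the null (pure capture noise yields
|t| ≈ 10 at a few thousand cells). The flag decision therefore compares
the same max-selected paired statistic against a label-permutation
reference (199 permutations), which is exactly exchangeable under the
null; the analytic t, df, mean difference and CI are still reported for
comparability. Two further gates reflect the physics: a candidate needs
≥ 10 cells for a stable mean, and its elevation must be on the
doubled-content scale (log2 ≥ 0.5 ≈ 1.4×). Without the effect gate,
iterative testing would wholesale-remove real clones that are merely
contaminated by a few percent of residual doublets — elevations of
~ 10% are statistically detectable at these cell numbers but are not
doublet clusters. Type-I control of the full decision rule is a tested
property.

In the pipeline the screen runs on a deliberately *overclustered*
assignment (k = 12 by default): doublets of two different clones form
small genotype classes that the silhouette-selected k would absorb into
the major clusters. Flagged and outlier cells are removed and the final
clustering runs on the cleaned cells. Doublets formed from two cells of
the *same* clone are genotype-identical to that clone and cannot be
identified in genotype space; a fraction of them remains inside the
clone clusters by design, which slightly elevates those clusters'
ratios but does not perturb consensus genotypes or singlet assignments.

## Lineage reconstruction

Neighbor joining (via `ape::nj`) runs on pairwise distances between
cluster consensus genotype vectors, rooted on the branch to the normal
cluster; the MRCA is the most rootward node ancestral to all tumor
leaves, and internal nodes are named MRCA, A1, A2, … by distance from
the root. The default distance is **Manhattan** over genotype codes —
the number of allele differences, the natural genetic distance here —
with missing entries handled pairwise-complete (sums rescaled by the
fraction observed, as `stats::dist` does). Plain Euclidean distance is
available but not the default: the square root is concave, so Euclidean
distances over genotype codes are not additive even when the underlying
mutation counts are, and on clone configurations where one subclone
carries only the truncal mutations (sitting at the internal node, a
zero-length edge away) it deterministically resolves the quartet the
wrong way; Manhattan distances are additive in that setting and NJ
recovers the generating topology, a property verified against an
exhaustive least-squares topology search on random additive matrices.
Negative NJ branch lengths are clamped to zero and counted.

Each mutation is placed on the branch above the smallest clade
containing all clusters whose consensus is mutant; mutations mutant in
every tumor cluster are truncal (root→MRCA). CNA events are placed the
same way from the cluster-level calls. Carrier sets that are not clades
are placement conflicts: they are flagged, placed at the MRCA of their
carriers, and reported — not errors, since allelic dropout or a
misassigned cluster can produce them. Events within a branch are not
ordered. Deleterious-impact ranking passes variants with PolyPhen > 0.8
or (1 − SIFT) > 0.8, ranks by CADD descending, keeps the top 30 and
reports the CADD scaled-percentile band (> 10 top 10%, > 20 top 1%,
> 30 top 0.1%).

## Benchmarking

The Gini index uses the mean-absolute-difference definition
Σᵢⱼ|xᵢ−xⱼ| / (2n²x̄), computed via the equivalent sorted closed form and
tested against the O(n²) brute force. Coverage metrics summarise
per-amplicon Gini/CV across cells and per-cell Gini/CV across amplicons
by their means (CV uses the sample SD, n−1, and is reported in
percent). Allelic dropout (ADO) is the fraction of genotyped entries at
known heterozygous (germline SNP) sites called homozygous; amplicon
success is the fraction of amplicons with mean reads above 0.2 × the
grand mean. Concordance aggregates single-cell VAF per variant as
ΣNGT / (2 × n genotyped) over singlet cells and reports Pearson
correlations against bulk references; correlation is scale-free, so the
ratio-scale CN estimates compare directly against integer pseudo-bulk
profiles.

Depth downsampling replaces read-level subsampling with binomial
thinning of the count matrix — the two are statistically equivalent for
independent reads — followed by re-masking of genotypes under the depth
filter; mutation and cell downsampling draw uniform subsets. Each
condition reruns the full detection pipeline (cascade, doublet screen,
silhouette clustering) and records the number of detectable clusters.
Detection counts *major genotype profiles*: non-outlier clusters whose
consensus genotypes differ by fewer than 2 allele counts are merged
before counting, since a cluster one allelic-dropout flip away from a
clone is an artifact class, not a subclone. Without this merge, very
small variant panels fragment into dropout-combination clusters and the
count becomes non-monotone in the number of mutations.

## The synthetic-data generator

`simulate_truth()` builds a diploid population plus tumor subclones on a
caterpillar ancestor chain under perfect phylogeny: truncal mutations
(default 15, homozygous, reflecting the LOH-heavy truncal events of
triple-negative breast tumors) shared by all clones, plus disjoint
heterozygous private blocks per clone (default 0/8/28, so the clones
carry 15/23/43 mutations); remaining panel variants are reference-only
sites, as in a multi-patient panel where other patients' sites read
reference. Copy-number events assign integer states (defaults span
1, 3, 4) to amplicon sets, truncal or branch-specific, balanced so each
clone's total content stays near diploid — the compositional
normalization is then unbiased, which is also how the recovery criteria
are stated. Defaults emulate the study conditions: ~330 amplicons,
164× mean depth, 20% diploid cells, 9% ADO, 8% doublets.

Counts are negative binomial (size 10 by default; the observed
amplicon-coverage overdispersion motivates the law but none is named in
the source, so it is configurable) with mean
`mean_depth × capture × efficiency × CN/2`; per-amplicon efficiencies
are lognormal (sdlog 0.6) and per-cell capture factors lognormal
(σ = 0.3), chosen once to reproduce the qualitative coverage-inequality
structure (per-cell inequality above per-amplicon inequality) rather
than any numeric target. Doublets draw two clones independently; their
counts sum both cells' content (≈ 2× total before capture noise) and
their genotypes pool alleles (4 alleles; 0 or 4 alternate copies give a
homozygote, anything else a heterozygote). ADO flips each true-het
entry to either homozygote with probability 0.09, symmetrically — the
source does not state allele bias — and genotype errors (rate 0.005,
small as joint-called high-depth data warrant) replace the code with a
random other one; errored entries receive low genotype quality, so the
cascade masks most of them, while dropout entries are confident wrong
calls with high quality, as in real data. `noise = FALSE` gives the
exact noise-free limit (counts equal expectations, genotypes equal
truth), used by identity tests. `derive_pseudobulk()` returns the exact
mixture references: VAF = Σ p·CN·NGT/2 / Σ p·CN per variant and
CN = Σ p·CN per amplicon.

What the generator does **not** emulate: linked read structure and
phasing, subclonal CNA breakpoints within amplicons, GC- or
position-dependent efficiency (efficiencies are exchangeable),
barcode-sharing artifacts other than whole-cell doublets, and
sequencing-error AF structure beyond binomial read sampling. Passing
tests therefore demonstrate correctness of the algorithms under the
stated generative assumptions, not performance on any particular real
dataset.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at 2,000–4,000 cells ×
330 amplicons with 10–20 replicate seeds per stochastic claim — sizes
chosen so every distributional claim has comfortable binomial/SE margins
while a full run stays in the minutes range on one core. Every
stochastic stage derives its seed from one master seed and a stage
name, so partial reruns are bit-identical. Tolerances follow from the
statistics, not the data: Gini vs brute force at 1e-12 (pure floating
point), LLN checks at 3 SE, binomial rates at 3 SD, copy-ratio medians
at ±0.15 (≈ 5× the median's SE at 200 cells, leaving room for residual
doublet contamination), permutation tests at 199 draws. Ties in the
consensus mode break toward the lower genotype code; `which.max` takes
the first maximum, so silhouette ties break toward smaller k.

## Known limitations

Same-clone doublets are undetectable in genotype space (above).
Absolute copy number in non-diploid-total clones requires the ploidy
model; ratio-scale output is deliberate. The silhouette criterion can
merge subclones separated by very few mutations when doublet classes
dominate the geometry — the pipeline's overclustered screen mitigates
but does not eliminate this. The clustered-region bulk filter removes
true mutations that happen to be within 10 bp of each other. Panel
overlap resolution keeps the higher-VAF variant rather than re-tiling
amplicons; tiling is out of scope.
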