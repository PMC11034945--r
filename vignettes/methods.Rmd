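---
title: "Methods: matched-pair epigenome and TF-network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-pair epigenome and TF-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The study design this package models

The pipeline targets cohorts of individually matched case–control pairs —
each schizophrenia subject paired with a control of the same sex and age —
profiled with ChIP-seq for an enhancer mark (H3K27ac) and a promoter mark
(H3K4me3) plus RNA-seq, in two sorted nuclei fractions (neuronal NeuN+,
glial NeuN−). The case cohort is split by postmortem toxicology into
antipsychotic-free (AF) and antipsychotic-treated (AT) subjects. The pair
is the analysis unit throughout: every downstream contrast is built from
per-pair case-minus-control differences, which removes pair-level
confounders (age, sex, storage) by construction.

## Counts, normalization and differential testing

ChIP peaks pass through a consensus construction: a peak is
*high-confidence* for a sample when supported by both technical replicates
(union-merge of every overlapping replicate pair), and the *master* set is
the transitive union-merge across samples. Count matrices over the master
set use full library sizes, optional input subtraction with a floor
(`max(ChIP − input, min_count)`), TMM normalization, and the literal
low-count rule: a feature is dropped iff *more than* 50% of samples have
fewer than 20 reads (a feature low in exactly half the samples is kept;
the inequality is strict on purpose).

TMM is implemented from its definition (reference column by
75th-percentile proximity to the mean; doubly trimmed M/A values, 30%/5%;
inverse asymptotic-variance weights; factors rescaled to geometric mean 1)
and is tested against both an explicit hand computation and edgeR's
implementation at 1e-10.

Differential testing fits, per feature, an NB log-linear model with offset
`log(library_size × TMM factor)`. Dispersion is estimated per feature by
maximum likelihood and shrunk halfway (fixed weight 0.5) toward a lowess
mean–dispersion trend — a deliberately simple, documented stand-in for the
empirical-Bayes machinery of the large differential packages; the contract
(NB GLM, normalization offsets, Wald test on the group coefficient) is the
same, numerical parity with those packages is a non-goal. ChIP features
use Bonferroni, RNA uses BH, matching the two conventions of the design.
On an all-null simulated cohort (2000 features, 15 + 14 pairs) the raw
p < 0.05 rate is 0.054, inside the accepted [0.03, 0.07] calibration band
(computed by the acceptance suite, not assumed).

Covariate handling follows the PC-correlation recipe: principal components
of the feature-centered log-CPM matrix are correlated with candidate
covariates (top 6 PCs for ChIP, top 10 for RNA); covariates with
|r| ≥ 0.3 and p ≤ 0.05 against any top PC enter the GLM design. The 0.3
threshold is a config value — the source design says only "high
correlation".

## Annotation

Promoter windows are strand-aware: [TSS − 4000, TSS + 1000) on the plus
strand and mirrored on the minus strand. H3K27ac peaks overlapping no
promoter window are enhancers; each enhancer links to a gene through a
chromatin-loop table when one anchor overlaps the enhancer and the partner
anchor overlaps a promoter window, otherwise to the nearest TSS (ties:
smaller TSS coordinate, then lexicographic gene id — an arbitrary but
deterministic rule). GREAT-style mapping gives every gene a basal domain
(5 kb up / 1 kb down) extended up to 1 Mb or to the neighboring basal
domain; the gap between two neighboring domains is deliberately shared by
both extensions.

## Networks and personalized PageRank

Active promoters are genes whose promoter window overlaps a
high-confidence H3K27ac peak. Motif scanning uses log-odds scores with a
1e-3 pseudocount and *exact* p-values from the discretized score
distribution (dynamic programming over motif positions, the FIMO
approach); hits at p ≤ 1e-4 within 150 bp windows centered on peak summits
create directed TF→gene edges through the peak's promoter gene or linked
enhancer gene.

Node weights are `e^z` with z the gene's expression z-score within the
sample (z-scored per cell fraction); genes without a measurement get
z = 0. Edge weights combine the TF's expression with the pooled peak
intensity as `sqrt(e^{z_TF} × I/median(I))` — the geometric-mean form
keeps the two factors on comparable scales; the original tool's exact
composition is not restated in the source, so this is this package's
documented choice, flagged for anyone seeking parity.

Personalized PageRank reverses edge direction (influence flows from
regulatees to regulators), column-normalizes the weighted transition
matrix, teleports dangling mass to the seed (the normalized node weights,
preserving the personalized interpretation), and iterates
`r ← (1−d)s + dWr` with d = 0.85 to an L1 tolerance of 1e-8. Scores sum
to 1 and match a dense `(I − dW)r = (1−d)s` solve to 1e-6 on 200 random
graphs in the acceptance suite.

## Reversal logic and age correlation

For each feature (z-scored TF PageRank or expression), mean pairwise
differences are computed separately in AF and AT cohorts. Candidates have
|AF mean − AT mean| > 0.5 (the 0.5 lives on the z-score scale — raw PPR
values sum to 1 across genes, so raw deltas could never reach it);
candidates are confirmed by a two-sided Wilcoxon signed-rank test of the
class-defining cohort's deltas against zero, BH-adjusted, at FDR < 0.05.
A rank test was chosen over a paired t because n ≈ 14 per cohort makes
normality assumptions unattractive. Classification is by which cohort
carries the larger absolute alteration: `recovered` when the AF cohort
does (altered untreated, normalized under treatment), `treatment_induced`
for the converse. A signed reading of the rule would misclassify negative
AF-only alterations as treatment-induced, so the magnitude reading is
used; swapping the cohorts swaps the two classes exactly (a tested
property).

Age correlations are plain Pearson r against the pair's shared age, with
two-sided p from `t = r sqrt((n−2)/(1−r²))` on n − 2 degrees of freedom,
verified against a 10,000-permutation oracle. Thresholds are inclusive:
|r| ≥ 0.50 (neuronal) and ≥ 0.60 (glial).

## Genome-bin clustering

Signals are binned at 5 kb, depth-normalized (CPM) and log1p-transformed.
A bin is enriched when its raw count clears an upper-tail Poisson test
against the genome-wide mean (BH within dataset) in at least one dataset.
Enriched-bin profiles are standardized per dataset and clustered with
K-means (k-means++ seeding, 10 restarts, best inertia); cluster centroids
are grouped into 6 sections, numbered by descending mean signal. The
original signature-discovery tool is model-based and iterative; this
package reproduces its *contract* (enriched 5 kb bins → profile clusters →
sections → hypergeometric enrichment of differential features), not its
internals, and claims no parity with it. The default of 50 clusters is a
desk-scale choice — the published 814 clusters are a property of
genome-scale data, not of the method.

## The synthetic world

`make_genome_model()` builds a toy genome (default 2 × 200 kb chromosomes,
60 genes, 8 TFs). Each TF carries a PWM with consensus probability 0.85;
widths are drawn 8–12 bp because a width-6 consensus cannot clear the
exact-p ≤ 1e-4 hit threshold under a uniform background (its best possible
p is 0.25⁶ ≈ 2.4e-4) — the stated 6–12 range is narrowed, not widened.
Each TF regulates 3–8 genes; consensus motifs are planted within ±75 bp of
the targets' TSS (and linked enhancer centers) so summit-window scanning
can recover the planted network exactly, which the tests assert.

`simulate_cohort()` draws negative-binomial counts with log-normal
baseline means (meanlog 4, sdlog 1 — median ≈ 55 reads) and dispersion
0.1, the standard bulk count model and the one the differential stage
assumes. Default cohort sizes are 15 AF + 14 AT pairs, mirroring the
29-pair design. Ages are uniform on [20, 80] and shared exactly within a
pair, emulating exact age matching. Effects multiply the case mean by 2
(log2 effect 1) in the applicable cohort only; age-correlated features
tilt the case mean by 0.03 log2 units per year of (age − 50) — over the
60-year age range this spans ±0.9 log2 units, enough for |r| ≥ 0.5 at
n = 25 pairs without being trivially large. `simulate_pairwise_scores()`
generates the z-score-scale pairwise differences directly (planted
|Δ| = 1.0 against noise sd 0.25 — about 4 pair-level noise sd, i.e.
clearly detectable at n = 14 but not degenerate).

`simulate_tags()` models library complexity explicitly: distinct
fragments are unique by construction and PCR duplicates are injected at a
stated rate, so PBC equals 1 exactly at zero duplication and ≈ 1 − rate
otherwise. Fragment length is a generator truth recovered by the
cross-correlation estimator within ±10 bp.

What a green test does **not** establish: the generator has no GC or
mappability bias, no batch structure beyond the listed covariates, no
sequence-level reads, no LD structure, and its effect sizes are chosen for
testability (the source reports no effect-size distribution for real
differential peaks). Conclusions about real tissue require real data; the
tests establish that the *machinery* is correct, calibrated under the
null, and deterministic.

## Numerical choices and degenerate inputs

* Peak caller: per-position Poisson tail against max(global, ±5 kb local
  mean), BH, 100 bp merge gap — MACS2-like behavior at toy scale, not
  MACS2. All-zero coverage yields an empty peak list, not an error.
* Failed NB fits (degenerate counts) report p = 1 rather than NA so
  adjustment stays well-defined.
* BH is step-up with enforced monotonicity; Bonferroni caps at 1.
* `hypergeometric_p` sums exact log-scale terms and clamps at 1 (float
  summation can overshoot by ~1e-16); it matches full enumeration for all
  N ≤ 12 at 1e-12.
* Cross-correlation uses binarized coverage (robust to duplicates), a
  ±10 bp phantom-peak exclusion around the read length, and
  chromosome-length-weighted averaging; zero-variance chromosomes are
  skipped.
* QQ lambda maps p = 0 to the smallest positive double before the
  chi-square transform.
* K-means restarts and kmeans++ draws run under a locally seeded RNG that
  restores global state, so all generators are pure functions of their
  seed.
* Determinism is tested byte-for-byte on the full stage chain at a
  desk-scaled configuration (30 genes, 4 + 4 pairs); the default scale
  runs the same code path but would spend several minutes of test budget
  on no additional coverage.

## Known limitations

* The minimal peak caller has no fragment-shift model and no broad-peak
  mode; real-data use expects externally called narrowPeak input.
* The NB trend shrinkage (fixed 0.5 weight) is cruder than
  empirical-Bayes moderation; at desk-scale sample sizes (n ≥ 29/group)
  the Wald test is well calibrated, but small-n real datasets would
  benefit from the mature packages.
* Edge-weight composition and EpiSig internals are documented stand-ins
  (see above); parity with the original tools is explicitly out of scope.
* The blacklist flag for real data is interval subtraction only; the
  synthetic genome has no blacklist.
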