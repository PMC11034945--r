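# epiregpair

Integrative epigenome/transcriptome analysis for **individually matched
case–control pairs**, built around the design of postmortem brain studies
that profile histone marks (H3K27ac, H3K4me3) and RNA in sorted neuronal
(NeuN+) and glial (NeuN−) nuclei from schizophrenia subjects and controls,
with the case cohort split into antipsychotic-free (AF) and
antipsychotic-treated (AT) subjects by toxicology.

The package implements the full analysis chain as reusable, tested stages:

1. **QC** — ENCODE-style metrics on strand-specific read tags: FRiP, PBC1,
   strand cross-correlation with NSC/RSC and fragment-length estimation,
   saturation curves, replicate correlation, and ChIP-qPCR enrichment
   `2^(Cq_N − Cq_P)`.
2. **Peaks & counts** — a minimal Poisson-background peak caller (a
   documented stand-in for MACS2 at synthetic scale), replicate-supported
   high-confidence peaks, a union-merged master consensus set, count
   matrices with input subtraction, TMM normalization, the
   "fewer than 20 reads in over 50% of samples" filter, and PC-guided
   covariate selection/regression.
3. **Differential** — per-feature negative-binomial Wald tests with
   `offset(log(library_size × TMM))`, ML dispersion shrunk 50% toward a
   mean–dispersion trend; Bonferroni for ChIP, BH (FDR) for RNA.
   Enhancer/promoter classification (4 kb/1 kb TSS windows),
   chromatin-loop enhancer–gene linking with nearest-gene fallback,
   GREAT-style basal-plus-extension mapping (5 kb/1 kb, ≤1 Mb), exact
   hypergeometric overlap tests, QQ lambda.
4. **Networks & PageRank** — per-sample TF→gene networks from PWM motif
   scans (exact p-values by dynamic programming, FIMO-style) in 150 bp
   peak-summit windows; node weights `e^z` from expression z-scores; edge
   weights `sqrt(e^{z_TF} × I_peak / median(I))`; personalized PageRank on
   the reversed graph seeded by the node weights
   (`r = (1−d)s + dWr`, d = 0.85).
5. **Cohort comparison** — per-pair case-minus-control differences; TFs
   ranked by |mean pairwise ΔPPR|; **reversal classification**
   (|AF − AT mean Δ| > 0.5, Wilcoxon signed-rank + BH): `recovered` =
   altered untreated but not under treatment, `treatment_induced` = the
   converse; regulatees of the top TFs via differential edge weights;
   cohort-specific DEG sets; Pearson age correlations with t(n−2) p-values
   and inclusive |r| ≥ 0.50 (neuron) / 0.60 (glia) thresholds.
6. **Genome-bin clustering** — 5 kb bins, CPM/log1p, Poisson enrichment
   detection, k-means++ profile clustering, 6 sections, annotation
   coverage, hypergeometric enrichment of differential features.
7. **Synthetic study generator** — a small genome with genes, TFs, planted
   motifs, a known regulatory network, chromatin loops, matched-pair
   cohorts with negative-binomial counts and planted
   AF-reversed/AT-induced/shared/age-correlated effects, and read-level
   tags; every downstream stage can be scored against this ground truth.

## Worked example

Classify planted reversal effects on simulated pairwise PageRank scores
(15 AF + 14 AT pairs, 10 planted AF-reversed and 10 AT-induced TFs with
|Δ| = 1.0 against noise sd 0.25):

```r
library(epiregpair)
sim <- simulate_pairwise_scores(n_features = 100, n_pairs_af = 15, n_pairs_at = 14,
                                n_af_reversed = 10, n_at_induced = 10,
                                delta = 1.0, seed = 6)
calls <- classify_reversal(sim$af, sim$at, threshold = 0.5, alpha = 0.05)
table(calls$class)
#>           neither         recovered treatment_induced
#>                80                10                10

head(calls[calls$class != "neither", ], 4)
#>    feature_id af_mean_delta at_mean_delta             class         fdr
#> 3       TF003    0.05833549    1.11676248 treatment_induced 0.001097051
#> 8       TF008    1.02024564    0.05814247         recovered 0.001097051
#> 10      TF010    0.04397196    0.99434208 treatment_induced 0.001097051
#> 11      TF011   -0.95840476   -0.10208346         recovered 0.001097051
```

All 20 planted effects are recovered with no false calls
(`truth_report()` sensitivity 1.0, false rate 0.0 for both classes).
`TF008` reads: its PageRank influence differs between schizophrenia cases
and their matched controls in the untreated cohort (mean pairwise Δ ≈ 1.0)
but not in the treated cohort (Δ ≈ 0.06) — the signature of an alteration
normalized by antipsychotic treatment.

The whole pipeline on a generated study:

```r
res <- run_pipeline("study_dir", pipeline_config(seed = 1))
res$report          # recovery of planted truth by the differential stages
```

or from the shell, stage by stage:

```sh
Rscript inst/scripts/epiregpair simulate --dir study --seed 1
Rscript inst/scripts/epiregpair qc --dir study
Rscript inst/scripts/epiregpair differential --dir study
Rscript inst/scripts/epiregpair compare --dir study
```

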