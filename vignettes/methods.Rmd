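---
title: "Methods: SMOTE-balanced GWAS and Manhattan-image similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SMOTE-balanced GWAS and Manhattan-image similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(smotescan)
```

This vignette explains the models and procedures `smotescan` implements,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data experiments do and do not show.
No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

In biobank case–control GWAS, many diseases have case:control ratios from
1:10 down to 1:100. Under such imbalance the usual association tests lose
power and the resulting Manhattan plots change character. One line of work
treats the Manhattan plot itself as the analysis object: rebalance the
minority class with SMOTE, re-run the association scan, render the result
as an image, and use a convolutional classifier's softmax output as a
*similarity score* between the rebalanced scan and a reference scan of the
same trait. `smotescan` implements that whole chain as tested, reusable
components, exercised end to end on synthetic cohorts with known causal
truth.

## Cohort simulation

`simulate_cohort()` draws, for SNP $j$, a minor allele frequency
$f_j \sim U(f_{\min}, f_{\max})$ and genotypes
$g_{ij} \sim \mathrm{Binomial}(2, f_j)$ — Hardy–Weinberg proportions, no
linkage disequilibrium. Ages are $U(30, 70)$ years, sex is Bernoulli(1/2).
Each binary trait $t$ follows a logistic model

$$\mathrm{logit}\, P(y_{it}=1) = b_{0t} + \beta_t \sum_{c \in C_t} g_{ic}
  + b^{\mathrm{sex}}_t \mathbb{1}[\mathrm{male}_i]
  + b^{\mathrm{age}}_t (\mathrm{age}_i - 50) + \lambda z_{i,B(t)},$$

where $C_t$ are the trait's causal SNPs, and $z_{i,B(t)}$ is a standard
normal latent factor shared by all traits of comorbidity block $B(t)$ with
loading $\lambda$ (default 1.5). Sharing a latent factor is the simplest
mechanism that yields tunable positive φ-correlation within blocks without
touching the genotypes. The intercept $b_{0t}$ is found by bisection of
$\bar{p}(b) = \mathrm{mean}_i\, \mathrm{logis}(b + \eta_{it})$ against the
target prevalence, which avoids closed-form approximation error; if the
target is unreachable (e.g. a saturating negative effect), the error names
the trait.

Assumptions and deliberate omissions: no linkage disequilibrium, no
population structure, no X/Y chromosomes, no quantitative traits. Ages are
uniform rather than biobank-shaped. These are stand-ins: no generative model
of a real biobank is attempted, and results on this simulator bound what
the pipeline can do under ideal conditions, not what it would do on real
genotypes (where LD makes association peaks regional rather than punctate,
and population structure inflates the null).

`inject_missingness()` and `inject_hwe_violations()` plant the specific
violations (low call rate; heterozygote deficit via an
inbreeding-coefficient distortion with $P(\mathrm{het}) = 2pq(1-f)$) that
the QC filters are tested against.

## Quality control and association

`apply_qc()` filters in the conventional order: subjects by call rate, then
SNPs by call rate, minor allele frequency (recomputed on retained
subjects), and an exact Hardy–Weinberg test computed in the controls of the
target trait (the standard practice when cases may be enriched for true
departures). All inequalities are strict — call rate > 0.95, MAF > 0.01,
HWE p > 0.001 — so records at exact equality are removed. The HWE test is
the Levene–Haldane conditional exact test: all heterozygote counts
compatible with the observed allele totals are enumerated through a
log-space kernel and the p-value is the summed probability of outcomes no
more probable than the observed one (no mid-p). The chi-square
approximation is provided separately for cross-checking.

`assoc_scan()` offers the allelic chi-square (1 df, no continuity
correction) for integer genotypes, and per-SNP logistic regression of trait
on dosage + sex + age with a Wald p-value for fractional dosages — the only
test applicable after SMOTE, whose interpolated dosages have no allele
counts. The logistic fits use a Newton–Raphson solver warm-started from the
covariate-only null model; it is cross-checked against `stats::glm` in the
tests and reports separation or non-convergence as p = 1 with a flag rather
than dropping the SNP. Null calibration is verified by KS uniformity of
p-values and genomic-control $\lambda$ (median statistic / 0.456) within
[0.9, 1.1] on 2000 subjects × 2000 null SNPs.

## Comorbidity clustering

Trait similarity is the φ-correlation (Pearson correlation of binary
vectors, computed from the 2×2 table in double precision). The distance is
$d = 1 - \varphi$, mapping perfect comorbidity to 0 and perfect
anti-comorbidity to 2. A cosine alternative
($1 - \cos$ similarity of the 0/1 vectors) is provided because both
appear in the literature this design follows; φ is the default since it
corrects for marginal prevalence, which cosine does not. Clustering is
k-medoids: for small instances (at most 500 candidate medoid subsets) the
optimum is found by enumeration — single-swap local search, including the
classical BUILD+SWAP and `cluster::pam`, demonstrably stalls one swap short
of the optimum on a few percent of random small instances — while larger
instances use greedy BUILD followed by best-improvement SWAP until no
single exchange helps. Everything is deterministic, with ties broken by
lowest index; `select_k()` picks k by maximal mean silhouette, ties to the
smallest k. `prune_comorbid_controls()` then removes controls carrying any
same-cluster disease; cases are never touched.

## Stratified SMOTE

The generation rule is the classical interpolation
$x_{\mathrm{new}} = x_i + (x_{ij} - x_i)\,\gamma$ with one
$\gamma \sim U(0,1)$ per synthetic sample shared across attributes (a
per-attribute-γ variant exists behind a flag for sensitivity checks).
Neighbors are the k = 5 nearest minority samples by Euclidean distance,
self excluded, ties by lowest index. Stratification uses 8 strata — 2 sexes
× 4 age bands cut at 47/55/60 years — and within each stratum
`round(ratio × n_majority)` synthetic cases are generated. The ratio
denominator is a documented choice: with majority-count semantics the
conventional grid 0.1, 0.03, 0.005, 0.001 spans from near-rebalancing to
homeopathic augmentation for heavily imbalanced traits; an alternative
`target_minority_fraction` mode is provided. Sparse strata fall back
gracefully (k reduced to n−1; strata with fewer than 2 cases merged into
the age-adjacent stratum of the same sex), keeping the 8-stratum design
without failing on small cohorts. Synthetic subjects inherit sex and age
from their base sample — interpolating age across a stratum boundary is
impossible by construction — and carry a `synthetic` flag plus full
provenance (base, neighbor, γ, stratum).

SMOTE duplicates information: oversampled scans show inflated
−log10(p), on null SNPs as well as causal ones. This is a property of the
method, not a bug in the scan, and it drives two design choices below.

## Manhattan rendering

`render_manhattan()` produces a pure data raster: black discs (radius 1) on
white, no axes or text, x = cumulative genomic position (chromosome lengths
concatenated with a 5 Mb gap; first and last base map to the first and last
pixel column), y = −log10(p) linearly into pixel rows, capped at `y_max`.
Rendering is deterministic and order-invariant, so identical inputs give
bit-identical PNGs. `y_max` defaults to 30; `y_max = NA` auto-scales each
image to its own maximum −log10(p), the way plotting tools fit axis
limits. The end-to-end experiment uses auto-scaling because SMOTE inflates
the y scale by an order of magnitude relative to the reference arm: under a
fixed cap the two arms' peaks sit at incomparable heights and the
classifier cannot transfer between them, whereas per-image scaling makes
"where the tall peaks are" the shared feature.

## Image preprocessing

The morphological operators are defined feature-bright: dilation is the
neighborhood maximum over a structuring element (default 3×3 square),
erosion the minimum, gradient their difference; borders replicate edge
pixels. Manhattan rasters are dark-on-white, so by default the operators
run on the inverted image and invert back — "dilation" enlarges the marks,
as intended. The Gaussian filter is a separable truncated kernel (5×5,
σ = 1, weights normalized to 1 within 1e-9); the median filter default is
3×3, deliberately matched to the renderer's disc size: a 5-pixel disc
survives a 3×3 median while isolated single-pixel noise is removed, whereas
a 5×5 median erases the data marks themselves — including the causal peaks
the classifier needs. All five operators are verified exactly (Gaussian to
1e-5) against naive double-loop oracles. The four canonical chains are GD,
GG, MD, MG (filter then morphology).

## The CNN and similarity

The classifier is a compact, fully from-scratch CNN (RcppArmadillo):
three blocks of 3×3 valid convolution → ReLU → 2×2 max-pooling with
32/32/64 filters, flatten, dense(64, ReLU), softmax over trait classes.
The dense head, Adam optimizer (lr 1e-3) and Glorot-uniform initialization
are standard minimal choices. Inputs are resized (nearest neighbor) to a
square side (default 128; 64 in the experiments), inverted to
feature-bright [0,1]. Training draws `steps_per_epoch` batches of
`batch_size` per epoch from an augmented stream — random shifts up to 10%
and zooms up to ±10% with constant fill; flips are disabled because the
axes carry genomic and significance semantics. The corpus is split
stratified 85/15 (per class, `max(1, round(0.15 n))` to validation).
Softmax rows sum to 1 within 1e-6; argmax ties break to the lowest class
index. Backpropagation is verified against central-difference numerical
gradients, and a random-label control trains to chance, guarding against
leakage through augmentation or splitting. Training is deterministic from
the seed in single-threaded use; multi-threaded BLAS backends may reorder
floating-point reductions.

## The end-to-end experiment

`cross_arm_experiment()` is the headline computation at desk scale: 3
traits at prevalence 0.05 (≈1:20 imbalance), n = 3000 subjects × 3000
SNPs, 6 causal SNPs per trait with per-allele log-odds 1.0 and maf ∈
[0.1, 0.5] — effect sizes chosen so the reference arm shows clear but not
saturated peaks; 6 SMOTE replicates per trait at ratio 0.1 form the
training corpus (MD chain, 256×128 rasters, auto-scaled y, 64×64 network
input, 10 epochs × 3 steps of batch 16). The model trained only on
SMOTE-arm images then classifies the reference-arm image of each trait;
recovery means the true class has the highest mean similarity. A negative
control repeats the evaluation against a freshly simulated cohort whose
causal sets are forced to be disjoint; its true-class similarity should
drop, showing that the signal is the shared causal architecture, not
rendering style. Five seeds are averaged. These problem sizes are the
package's chosen study conditions; the test suite and `scripts/acceptance.R`
run exactly them.

What passing shows: under ideal punctate signals, SMOTE-rebalanced imagery
is recognizably trait-specific to a small CNN across analysis arms. What it
does not show: performance under LD, population structure, realistic
phenotype correlation, or biobank scale, and it does not reproduce any
real-data similarity value.

## Other numerical choices and limitations

* VCF round trips preserve dosages to 1e-6 (DS field printed with 6
  decimals); PNG round trips are bit-exact after 8-bit quantization.
* p-values are clamped into (0, 1]; degenerate 2×2 margins give p = 1 with
  a flag.
* `run_pipeline()` hashes every artifact (MD5) into a manifest and skips
  recomputation when the configuration signature and all file hashes are
  unchanged.
* Known limitations: no LD or ancestry structure in the simulator; the
  reference arm is a plain association scan (mixed-model comparators are
  out of scope); PAM beyond the exact-enumeration size is a local
  optimizer; CNN training on large corpora is CPU-bound R/C++, not a GPU
  framework.
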