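---
title: "Benchmarking genomic phenotype prediction: models, protocols and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking genomic phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenobench)
```

# The problem

Genomic phenotype prediction learns a map from an organism's marker
genotype to a quantitative trait.  Two families of methods dominate the
field: classical statistical genetics (genomic BLUP, sequential QTL
mapping) and generic machine-learning regressors (penalised linear
models, random forests, gradient boosting, support vector regression).
`phenobench` implements both families behind one evaluation protocol so
they can be compared on equal terms, together with a meiosis simulator
that generates data with the statistical structure these comparisons
assume.  Everything runs end-to-end on synthetic data; no external
dataset is required.

# The simulator

## Crosses

`simulate_cross()` produces haploid segregants of a biparental cross.
Each chromosome of an offspring is a mosaic of contiguous blocks
inherited from the two parents.  Crossover points are drawn as a Poisson
process with rate 1 per Morgan (the Haldane model, no interference), and
each chromosome starts from either parent with probability 1/2, so every
marker is marginally Bernoulli(1/2) and the recombination fraction
between two markers $d$ Morgans apart is $(1 - e^{-2d})/2$.  Haldane was
chosen as the simplest model consistent with mosaic inheritance;
interference models (e.g. chi-square) change linkage only in the second
order and are out of scope.

The default map (16 chromosomes of 3 Morgans, 45 markers each) is a
yeast-like genome at desk scale.  Real map lengths are free parameters:
nothing in the package calibrates them to a particular organism, and all
tests build smaller maps explicitly.

## Traits

`simulate_trait()` computes a genetic score
$g = \sum_j \beta_j x_j + \sum_{(a,b)} \gamma_{ab} x_a x_b$ and adds
Gaussian noise.  The noise variance is calibrated on the *realized*
sample variance of $g$, so that `h2` is the realized, not the
asymptotic, heritability of the generated sample; the returned vector is
standardized to mean 0, variance 1 (sample variance, matching the
phenotype normalization convention below).  The product encoding of
epistasis is the standard statistical interaction term.  A single
large-effect marker at high `h2` produces the bimodal phenotype
distribution characteristic of near-monogenic traits.

One caveat worth knowing: architectures whose effects are all positive
at evenly spaced markers create a directional polygenic score whose LD
structure conflicts with the exchangeable-effects prior implicit in
GBLUP, and REML then underestimates heritability by 0.1 or more.
Random-sign effect vectors — the realistic case — do not show this bias.
The heritability-recovery tests therefore use random-sign polygenic
architectures.

## Structured populations and annotations

`simulate_structured_population()` descends haploid or diploid lines
from founder haplotypes through generations of random pairing and
meiosis.  Founders alternate the two parental haplotypes, as in breeding
programmes derived from a biparental elite pool; with two founders and
one generation the procedure reduces exactly to `simulate_cross()`.  The
final generation produces two lines per parent pair, so the population
contains full-sib families whose kinship (visible in the genomic
similarity matrix) exceeds that of unrelated lines.  Diploid lines
receive two independent gametes from the same parents and are coded
$\{-1, 0, 1\}$ (aa, aA, AA).

`simulate_annotation()` lays mostly non-overlapping gene intervals along
the map in 0-based half-open Morgan coordinates (a marker belongs to a
gene iff $\mathrm{start} \le x < \mathrm{end}$), with configurable
fractions of partially overlapping and fully nested genes to exercise
the fusion edge rules.

# Preprocessing conventions

* Phenotype normalization standardizes each trait to mean 0, variance 1
  over observed entries, with the $n-1$ (sample) variance.  The choice of
  variance convention is not determined by any external reference; it is
  fixed here and asserted in the tests (e.g. $(1,2,3) \to (-1,0,1)$).
  Replicate averaging (mean of available readings) precedes
  normalization.
* Imputation: column means for any coding; the heterozygote code 0 for
  diploid data.  Observed entries are never altered.
* LD pruning is a greedy sliding-window scan (window/step/threshold in
  markers and squared Pearson correlation).  Within a window, pairs are
  examined left to right and the later marker of an over-correlated pair
  is removed, so the first marker of a correlated run survives.  Constant
  markers have no defined correlation and are treated as $r^2 = 0$.
  Output parity with external pruning tools is not claimed; the greedy
  contract itself is tested against a brute-force oracle.

# Genomic BLUP

The kinship matrix is $K = ZZ^\top/p$ with $Z$ the column-standardized
marker matrix over the $p$ polymorphic markers (constant markers are
dropped).  This standardized cross-product is the common VanRaden-style
construction and makes GBLUP a ridge regression on standardized markers:
with $K = I$ the predictions coincide with the ridge closed form, an
equivalence the tests assert to $10^{-8}$.

The model is $y = 1\mu + g + e$, $g \sim N(0, \sigma_g^2 K)$,
$e \sim N(0, \sigma_e^2 I)$.  REML (not ML) estimates the variance
components: one eigendecomposition of $K$ reduces the restricted
log-likelihood to a function of the variance ratio
$\lambda = \sigma_e^2/\sigma_g^2$, which is maximized by a 1-D search
over $\log\lambda$ bracketed in $[10^{-6}, 10^6]$ with tolerance
$10^{-8}$.  The eigendecomposition can be cached (`gsm_eigen()`) and
reused across traits sharing a genotype matrix.  Predictions are
$\hat y = \mu + K_{\mathrm{cross}} (K + \lambda I)^{-1} (y - \mu)$.  If
the genetic variance collapses to the boundary, every prediction is the
fitted mean — a documented degenerate contract, not an error.

# The sequential QTL method

The two-step procedure mirrors classical forward QTL mapping:

1. **Additive stages (at most 4).**  Each stage scans the current
   residuals with the marker-wise LOD score
   $\mathrm{LOD}_j = \tfrac{n}{2}\log_{10}(SS_0/SS_{1j})
   = \tfrac{n}{2}\log_{10}\!\big(1/(1-\rho_j^2)\big)$, thresholds it by
   permutation FDR, collapses contiguous runs of significant markers to
   their highest-LOD peak (one term per LD block), refits the joint
   linear model and recomputes residuals.  Selection stops early when a
   stage admits nothing.
2. **Interaction scan.**  For each selected marker $m$ and every marker
   $j$, the likelihood-ratio statistic
   $n\ln(RSS_{\mathrm{reduced}}/RSS_{\mathrm{full}})$ compares the
   additive model plus the main effect of $j$ with and without the
   $m \times j$ product, thresholded by the same permutation-FDR rule
   with nulls generated by shuffling the additive-model residuals onto
   the fitted values.  The scan is implemented but excluded from
   benchmark defaults.

The FDR estimator is the plug-in (Storey-type) ratio: mean null
exceedance count over observed exceedance count, with the threshold set
to the smallest observed LOD whose estimate is below the target level.
The genome-wide-maximum alternative (per-permutation maxima) controls a
family-wise rate instead and selects fewer markers; the plug-in form was
chosen because it directly estimates an FDR.  The estimate is not
monotone in the threshold, so every candidate is evaluated.  Permutation
count `B` defaults to 1000; the tests use 100, which is enough for a
0.05-level threshold over a few hundred markers.

Two properties are worth stating precisely.  First, the selection is
strictly training-fold local: perturbing test-fold phenotypes can never
change a fitted model — the evaluation-protocol tests assert this for
the QTL method, GBLUP and the learners alike.  Second, monotonicity in
the FDR level holds for a *single* selection stage; across stages the
refit residuals couple the levels, and a stricter level can occasionally
end with more markers after four stages.  The tests assert the per-stage
property.

# Learners and tuning

Six regressors are wrapped behind one contract (`fit_learner()` /
`predict()`): lasso, ridge and elastic net (glmnet; penalty by internal
10-fold cross-validation over a 100-value path), random forest (ranger;
700 trees, $p/3$ split candidates, minimum node size 5), gradient
boosting (xgboost; depth $\{1,2,3\}$ $\times$ shrinkage
$\{0.001, 0.01, 0.1\}$, 1000 trees, subsampling 0.5, with both the grid
point and the prediction iteration count chosen on an internal 70/30
validation split), and $\epsilon$-insensitive SVR with Gaussian kernel
(kernlab; log-scale grids over $\epsilon$, cost and kernel width against
the internal split).  The SVR grid defaults
($\epsilon \in \{0.01, 0.1, 0.5\}$, $C \in \{0.1, 1, 10, 100\}$,
$\gamma \in 10^{-4..0}$) are package choices exposed in the policy
object.  The numeric backends are established libraries on purpose —
this package owns the tuning protocol, split bookkeeping and seeding,
not coordinate descent or tree growing.

Every stochastic step is seeded from a per-fit child seed, so identical
data and seed give identical predictions, and hyperparameters are chosen
only inside the training data.

# Evaluation

Accuracy is the cross-validated
$R^2 = 1 - \sum_i (y_i - \tilde y_i)^2 / \sum_i (y_i - \bar y)^2$
computed from out-of-fold predictions $\tilde y_i$ accumulated over one
fold partition, averaged over repeats.  `run_cv()` draws unstratified
random folds; `run_train_test()` performs a single 70/30 split with the
$R^2$ computed against the test-set mean.  A mean-predictor baseline
lands at or slightly below zero by construction.

Degradation experiments (`degradation_plan()`, `run_degradation()`)
emulate three pathologies: class noise (a random fraction of training
phenotypes shifted by $\pm 2$ trait standard deviations, signs
independent), marker deletion (nested random subsets) and sample
deletion (nested, for variance reduction across the schedule, though
nesting for samples is a package choice rather than a requirement).
Noise contaminates training folds only, so accuracy loss measures
corrupted learning rather than corrupted scoring; marker deletion
applies to both folds; sample deletion shrinks the training fold while
keeping the test fold fixed across levels.  Hyperparameters are re-tuned
at every level, matching the per-run protocol.  Curves report the mean
ratio of degraded to clean $R^2$ (undefined when the clean baseline is
non-positive, emitted as missing) plus the absolute scale.

Multi-task stacking (`build_multitask()`, `evaluate_multitask()`)
concatenates one row per (sample, trait) observation and adds a
categorical trait indicator; tree learners consume the factor natively,
numeric backends one-hot expand it.  At desk scale, grouped random
forests gain over single-trait fits when the grouped traits are highly
correlated *and* sparsely observed — pooling then acts as data
augmentation; with fully observed traits the gain disappears.  The
shared-signal test uses three half-observed traits with a common
architecture.

# Rank-based method comparison

`rank_table()` ranks methods within each trait (rank 1 = most accurate,
midranks for ties), `friedman_rank_test()` applies the tie-corrected
Friedman statistic
$\chi^2 = 12\sum_j (R_j - n(k+1)/2)^2 / \big(nk(k+1) - C\big)$ with
$C = \sum (t^3 - t)/(k-1)$ over tied groups, and `nemenyi_posthoc()`
computes pairwise p-values from the studentized-range distribution at
$z\sqrt 2$ with $k$ groups and infinite degrees of freedom.  The tie
correction matters: without it the published rice p-value is not
reproduced.  An all-tied table returns statistic 0 and p-value 1.  The
implementation is cross-checked against `stats::friedman.test()` on
random tables with injected ties.

The three published benchmark tables (46 yeast growth traits across 7
methods; 4 wheat and 12 rice agronomic traits across 6 methods) ship as
plain-TSV fixtures (`published_table()`), and the comparison statistics
recomputed from them — average ranks, Friedman and Nemenyi p-values,
best-method counts, advantage margins in percentage points — reproduce
the published values to printed precision.  Two second-decimal caveats
are inherent: the original average ranks and post-hoc p-values were
computed from unrounded accuracies, while the shipped tables carry three
decimals, so a recomputed Nemenyi p-value can differ from the printed
one by a factor below 2 while remaining at the same significance level.

# Marker fusion

Gene-level fusion compresses marker blocks into one binary attribute per
gene (majority vote per sample) plus one per intergenic run of markers
(including chromosome ends); overlapping genes are treated as separate
attributes and a marker inside two genes contributes to both.  The
gene+flank variant tiles each chromosome into regions extending from a
gene to the midpoints of its flanking gaps, ignoring genes fully nested
inside another.  Exact majority ties resolve to 0 by default
(configurable); the convention is arbitrary and documented rather than
inferred.  Fusion presumes tight within-gene linkage — with markers
spaced around 0.6 cM, fused and raw representations predict within about
0.01 cvR² of each other across lasso, random forests and boosting; at
several-cM spacing the fused representation loses visibly more.

# Reproducibility plumbing

`run_pipeline()` wires simulate → benchmark → rank behind a YAML config
with a single master seed.  Every stage derives its own child seed
deterministically, and the manifest records the config, all derived
seeds and package version, so any stage can be replayed in isolation —
the pipeline tests replay both the meiosis stage and individual
benchmark cells bit-identically.  The package's shell entry points are
its exported functions and `scripts/acceptance.R`; experiment definition
lives in the config file rather than command-line flags.

# Problem sizes and what the tests show

The test suite exercises crosses of 100–1000 segregants over 60–300
markers, 100-permutation thresholds, 20-replicate recovery studies and
10-trait directional comparisons; the acceptance script uses crosses of
300–800 lines.  These sizes make every protocol property checkable in
minutes while preserving the statistical structure (linkage blocks,
polygenicity, population structure) the methods rely on.  Passing tests
demonstrate protocol correctness and faithful statistics at this scale;
they do not certify accuracy figures for any real dataset, where marker
density, LD structure and trait architectures differ by orders of
magnitude.

One directional finding deliberately recorded as a failing check: with a
modern regularized boosting backend (shrinkage, subsampling,
validation-chosen iteration count), gradient boosting retains *more*
accuracy than random forests under heavy symmetric label noise at these
problem sizes — the opposite of the robustness ordering reported for
older boosting implementations on much larger data.  The suite keeps the
original directional assertion, and its failure documents this genuine
backend difference rather than an implementation defect.

# Known limitations

* Sequence-level realism (bases, indels, genotyping error) is out of
  scope; the simulator emits clean marker mosaics.
* Crossover interference, selfing and selection schemes are not
  modelled.
* Diploid fusion and multi-kernel/SNP-weighted BLUP variants are not
  implemented.
* The interaction scan's permutation null conditions on the fitted
  additive model; a fully nonparametric null would be more conservative.
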