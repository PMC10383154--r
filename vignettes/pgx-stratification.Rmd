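---
title: "Group-stratified pharmacogenomic variation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-stratified pharmacogenomic variation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(pgxStrat))
```

## The problem

Pharmacogenomic variants — variants associated with drug efficacy, dosage
requirements or toxicity — differ in frequency between population groups.
When a toxicity-associated allele is common in one group and rare in
another, prescribing without regard to that difference produces predictably
unequal rates of adverse drug reactions. `pgxStrat` packages the analysis
chain needed to study this in a cohort with self-identified group labels:

1. per-group allele frequencies from diploid genotype dosages;
2. genotype PCA with per-variant *allele weights*;
3. supervised prediction of group labels from PC features, as a measure of
   how strongly pharmacogenomic variation stratifies by group;
4. ranking of group-divergent variants by allele-weight magnitude;
5. the predicted *excess adverse drug reactions per 1000 treated* between
   two groups, under dominant or recessive toxicity-allele models.

Because the large biobank cohorts this kind of analysis targets are
access-restricted, the package also ships a first-class synthetic cohort
generator with known ground truth, used throughout the test suite.

## The synthetic cohort model

Group allele frequencies follow the Balding–Nichols model. For a variant
with ancestral frequency $p$ and a group with divergence parameter
$F \in (0,1)$ (an $F_{ST}$), the group frequency is drawn

$$p_g \sim \mathrm{Beta}\!\left(p\,\frac{1-F}{F},\; (1-p)\,\frac{1-F}{F}\right),$$

so that $E[p_g] = p$ and $\mathrm{Var}[p_g] = F\,p(1-p)$. This is the
standard $F_{ST}$-indexed divergence model; a Hudson-style ratio-of-averages
estimator on the sampled frequencies recovers the target $F$ (the
calibration test requires agreement within $\pm 0.03$ at $F = 0.1$ over
$10^4$ variants).

Ancestral frequencies are uniform on $(0.05, 0.95)$ by default, avoiding
near-monomorphic background noise. Non-admixed genotypes are
$\mathrm{Binomial}(2, p_{gj})$. Admixed samples get per-sample ancestry
proportions from a Dirichlet distribution centred on the group's parental
mixture weights, and each of the two allele copies independently picks a
parental group by those proportions before drawing the allele — the
simplest mechanism that disperses an admixed group across PC space between
its parents rather than placing it at a fixed intermediate point.

A configurable number of *planted divergent* variants is rejection-sampled
(up to 1000 attempts each) until the maximum pairwise group frequency
difference reaches `divergentDelta` (default 0.5); if rejection fails, the
first and last groups are assigned frequencies 0.1 and 0.9 directly. The
planted set is recorded in the `GroundTruth` object so recovery can be
scored.

`defaultCohortConfig()` mirrors the structure of a large diverse US cohort:
four non-admixed groups with a 54/20/16/3 percent split (White majority,
Black, Hispanic, Asian) plus a broad `MoreThanOne` admixed group (4%,
parental weights 0.4/0.3/0.3 over White/Black/Hispanic, Dirichlet
concentration 3). The per-group divergence values (0.10, 0.12, 0.05, 0.12)
were chosen once as realistic magnitudes for continental-scale structure
seen through a few thousand variants; they are parameters, not estimates.

**What the generator does not emulate:** linkage disequilibrium (variants
are independent), recombination maps, genotyping error, relatedness, and
phenotypes. Passing tests on simulated cohorts therefore demonstrate that
the *methods* behave as the population-genetic model predicts — not that
any particular real-data accuracy would be reproduced. Real-data results
depend on cohort composition and variant panels that restricted biobank
data alone define.

## Genotype PCA and allele weights

Dosages are standardized per variant with the EIGENSTRAT/smartpca
convention: centred at $2\hat p$ and scaled by $\sqrt{2\hat p(1-\hat p)}$,
where $\hat p$ is the sample allele frequency. Missing dosages are
mean-imputed *after* frequency estimation, so they contribute exactly zero
after centring. Monomorphic variants are dropped (with a message) since
their scale is zero.

The model's allele weights are the right singular vectors of the
standardized matrix: per-variant dosage coefficients satisfying the
reconstruction identity

$$\mathrm{PC}_i = \sum_j w_{ij}\, x_{ij},$$

with $x_{ij}$ the standardized dosage. The identity is asserted numerically
(to $10^{-6}$) on every fitted model in the test suite. A weight's
magnitude measures the variant's contribution to between-sample divergence
along that PC, which is what `rankDivergentVariants()` sorts on.

Numerical choices:

* **Exact vs randomized.** Cohorts up to 2000 samples use a truncated exact
  SVD; larger cohorts use a seeded randomized range-finder (Gaussian
  sketch, two power iterations, oversampling 10). Small analyses and all
  oracle tests stay exact; the randomized path is itself tested against the
  exact one.
* **Sign convention.** PC signs are arbitrary, so each component is flipped
  to make its largest-magnitude allele weight positive; reported weights
  are then deterministic.
* **Divergence score.** The score is $\max(|w_{PC1}|, |w_{PC2}|)$ by
  default. PC1 and PC2 are where between-group structure concentrates, and
  no principled combining rule is available a priori; both per-PC weights
  are always reported so alternative scores can be recomputed. Exact ties
  keep input order (stable sort).
* **Explained variance** is each squared singular value divided by the
  total sum of squares of the standardized matrix, so shares are valid for
  truncated fits too.

## Classification

Group labels are predicted from the leading PC scores with k-NN
(`class::knn`), random forest (`randomForest`) and an RBF-kernel SVM
(`e1071::svm`). Hyperparameters are chosen by randomized search *nested
inside* the outer stratified 5-fold cross-validation: each draw is scored
by 3-fold CV on the training fold only, the winner is refit on the whole
training fold, and accuracy is measured on the untouched test fold. Nesting
is the statistically safe design — the test folds never influence the
hyperparameters — and the label-permutation test verifies the consequence:
shuffled labels score at chance.

Search spaces (defaults): k-NN neighbours in [3, 50], capped at the
smallest training-class size so no class can be outvoted by construction;
random forest trees in [100, 800], minimum node size in [1, 8], `mtry` up
to 8 (this R parameterization replaces the depth/min-split controls of
other implementations, which `randomForest` does not expose); SVM cost
log-uniform on [1, 1e5] and gamma log-uniform on [1e-3, 1e2]. k-NN voting
ties are broken randomly under the fold's seed, the behaviour of
`class::knn`.

Accuracy is the plain percentage of correct predictions, reported per fold
and summarized as mean ± sd across the five folds. The confusion matrix
pools test-fold predictions; `confusionAnalysis()` row-normalizes it to
per-group accuracies and misclassification destinations, and exposes
misclassified sample ids for plotting in PC space. `sweepPCs()` repeats the
evaluation over a contiguous range of PC counts and reports the best count,
ties going to the smallest. Stratified folds keep per-fold group
proportions within one sample of the cohort's.

On the default simulated cohort, accuracy plateaus within a few PCs and the
admixed group is the hardest to classify — its samples scatter between the
parental clusters — which is the qualitative structure these cohorts show;
both properties are asserted in the acceptance tests rather than any
particular accuracy value.

## Excess adverse drug reactions

For a toxicity-associated effect allele at frequency $p$, Hardy–Weinberg
genotype fractions give the affected fraction of treated patients:
$p^2$ under a recessive mode (two copies needed) and
$p^2 + 2p(1-p) = 1-(1-p)^2$ (carriers) under a dominant mode. The signed
excess per 1000 treated between group $a$ and a reference group $b$ is

$$\widehat{RADR} = 1000\,(p_a^2 - p_b^2), \qquad
  \widehat{DADR} = 1000\,\big[(p_a^2 - p_b^2) + (2p_a(1-p_a) - 2p_b(1-p_b))\big],$$

the dominant form being algebraically the carrier-fraction difference. HWE
fractions are used rather than observed genotype counts because the
statistic is defined on allele frequencies; `hwFractions()` exposes the
fractions themselves.

`adrTable()` orients frequencies to the annotation's effect allele (using
$1-f$ when the table counts the other allele — the gefitinib example's
effect allele is the *reference* allele, so this matters), computes one
prediction per toxicity variant × non-reference group, and keeps the signed
continuous value. Reporting uses round-half-away-from-zero on the magnitude
plus a direction label, because the sign flips between examples depending
on which group carries the excess; the continuous value is always emitted
alongside the rounded one, since integers printed from already-rounded
input frequencies can disagree by ±1 with any single rounding rule.

```{r adr-example}
ex <- examplePGxData()
tab <- adrTable(ex$frequencies, ex$annotation, referenceGroup = "White")
as.data.frame(tab)[, c("rsid", "drug", "mode", "group",
                       "excess_per_1000", "excess_reported", "direction")]
```

## Interfaces and reproducibility

The bundled annotation table (`examplePGxData()`) carries 20 curated
highly group-divergent variant–drug records across evidence levels
1A–3; association types and modes of effect beyond the four worked
toxicity examples are set to their known class or `unknown`, and rows with
unknown mode are skipped (with a count) by `adrTable()`. Annotation joins
use rsID as the primary key with the positional chr:pos:ref:alt id as
fallback, and duplicate rsIDs with distinct drugs are permitted; variant
extraction deduplicates by rsID.

I/O is deliberately strict: a GT-only VCF 4.2 subset (1-based positions,
GRCh38-style contig names), with multiallelic records rejected by default
(an explicit `split`/`drop` choice keeps frequency semantics unambiguous),
and TSV tables with fixed headers that round-trip to 6 decimal places.
Missing genotypes are never imputed at the I/O layer.

`runPipeline()` executes simulate/read → intersect → frequencies → PCA →
classification → divergence → ADR with one global seed; per-stage seeds are
derived by stable hashing of stage names, so a stage re-run in isolation
from its persisted inputs reproduces its output. Reruns with the same
config are byte-identical on all TSV outputs.

## Problem sizes used by the tests

The test and acceptance suites choose sizes that exercise each property at
full statistical strength while staying quick on a single core: simulator
calibration at $10^4$ variants; divergent-variant recovery with 20 planted
among 500 background variants in two groups of 250 ($F = 0.05$); and the
classification properties on the default cohort at `scale = 0.05`
(≈340 samples, 2000 variants). These are the package's own choices of
demonstration scale; all thresholds are stated in the tests themselves.

## Known limitations

* No linkage disequilibrium or LD pruning: the simulator assumes
  independent variants, and the PCA makes no attempt to thin correlated
  ones. Real panels may need pruning upstream.
* Group labels are treated as given; the package does not model label
  noise or self-identification dynamics.
* The ADR statistic is a population-stratification quantity — expected
  excess events per 1000 treated — not an individual risk prediction, and
  it ignores penetrance and effect sizes.
* No projection of new samples onto an existing PCA, and no support for
  BGEN/PLINK binary formats.
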