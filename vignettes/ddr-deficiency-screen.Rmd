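---
title: "Methods: screening DDR gene deficiencies from mutational patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening DDR gene deficiencies from mutational patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ddrscreen` implements a genome-wide screen for deficiencies of
DNA-damage-response (DDR) genes: it annotates loss-of-function (LOF)
events, summarises each tumour's mutational patterns, and asks — gene by
gene — whether the pattern predicts the deficiency. This vignette is the
package's own account of the method: the model and its assumptions, the
parameters that matter, what the synthetic data do and do not emulate, and
the numerical choices behind the implementation.

## The LOF annotation model

A gene in a tumour is assigned one of four states from two evidence
channels.

**Variants.** Small variants are curated before any classification:
records must be PASS-filtered (and, in the PCAWG-style dialect, supported
by at least two callers); variants carried by more than 200 samples across
data sets are treated as polymorphisms or artefacts; somatic variants need
a variant allele fraction (VAF) of at least 0.2 (subclonal calls and
contamination score lower); germline variants with population frequency
above 0.5% are presumed benign. Curated variants are then classed by CADD
phred score — ≥ 25 pathogenic (the top 10^(−2.5) ≈ 0.3% most deleterious
substitutions), in (10, 25) a variant of unknown significance (VUS) when
non-synonymous, otherwise benign. A ClinVar pathogenic/benign assertion
overrides the score; a conflicting or absent ClinVar record falls back to
it. This precedence is a package decision: ClinVar carries curated clinical
evidence where it exists, and the score fills the gaps for genes ClinVar
covers poorly.

**Copy number.** Any ≥ 1 bp overlap between a gene and a segment with
minor-allele copy number below 0.2 flags loss of heterozygosity (LOH);
total copy number below 0.3 flags a deep deletion (which implies LOH). All
thresholds are strict inequalities, exactly as stated above.

**Zygosity.** A deep deletion, two or more pathogenic variants (assumed in
trans — phasing is out of scope), or one pathogenic variant with
overlapping LOH is a *biallelic* loss. One unaccompanied pathogenic
variant is *monoallelic*. LOH alone is never a hit: LOH events are broad
and roughly an order of magnitude more frequent than deep deletions, so on
their own they carry little gene-specific information. A sample whose only
events in the gene are VUS is a *VUS carrier*; all others are wild type.

**Stratification.** For a biallelic-mode model the biallelic samples are
positives and the wild-type samples the background; VUS carriers are
excluded as inconclusive, and monoallelic-only samples are likewise
excluded — they are neither clean positives nor clean background. In
monoallelic mode, biallelic samples join the positives (a biallelic loss
is a special case of monoallelic loss). The excluded-monoallelic rule is
forced by the worked-example arithmetic: in a 645-sample cohort with 17
biallelic, 7 monoallelic and 53 VUS samples the biallelic model's
background is the 568 wild-type samples.

## Mutational features

Per tumour the package computes:

* **SBS-96 counts and signature exposures.** Each single-nucleotide
  variant maps to one of 96 pyrimidine-strand trinucleotide channels
  (purine-reference variants are reverse-complemented, so the counts are
  strand symmetric). Exposures solve the non-negative least-squares
  problem e = argmin‖c − S·e‖₂, e ≥ 0, by the Lawson–Hanson active-set
  algorithm. NNLS was chosen over bootstrap-based fitters because the
  exposures are consumed downstream as model features and a deterministic
  fit makes the whole pipeline reproducible; the signature catalogue (and
  any organ-to-reference conversion matrix) is an input, with novel
  signature labels passing through conversion unchanged. The age-related
  signature SBS1 is excluded from modelling — it proxies patient age, and
  a model using it would separate old from young patients rather than
  repair-proficient from repair-deficient ones. Signature 5 is retained
  despite its weaker age association.
* **Indel categories.** Insertions are counted as one class. A deletion
  whose full deleted sequence recurs immediately 3′ of the breakpoint is
  repeat-mediated; otherwise a deletion of length ≥ 2 sharing at least a
  1 bp prefix with its 3′ flank is a microhomology deletion (the footprint
  of microhomology-mediated end joining); the rest are "other". The length
  thresholds (≥ 2 bp deletion, ≥ 1 bp match, one full downstream copy) are
  configurable; repeat context takes precedence over microhomology.
* **SV categories.** 32 categories: {clustered, non-clustered} ×
  ({deletion, tandem duplication, inversion} × five size bins ∪
  {translocation}). Size bins are left-closed/right-open —
  [1, 10), [10, 100) kb, [100 kb, 1 Mb), [1, 10) Mb, ≥ 10 Mb — with
  sub-kilobase events placed in the smallest bin; boundary membership is a
  package convention since only the interval list itself is fixed.
  Clusters are runs of ≥ 10 breakpoints whose consecutive gaps are at most
  one tenth of the sample's mean inter-rearrangement distance (the mean of
  per-chromosome consecutive-breakpoint gaps, pooled genome-wide). The
  detector chains gaps greedily (single linkage); this is the simplest
  algorithm satisfying the threshold rule exactly and is validated against
  a brute-force chain enumeration, though it approximates the
  piecewise-fitting behaviour of the original rearrangement tools.

Feature values enter the models as log(x + 1), z-scored per feature. The
centre and scale are estimated on the modelling samples and frozen, so
evaluation on a held-out cohort reuses the training transform and no
information leaks. Whether to model raw or transformed counts is
configurable; transformed is the default because the count features span
four orders of magnitude.

## The deficiency models

One candidate model exists per gene × cohort × data set × zygosity mode,
eligible when the positive class is large enough: more than five biallelic
tumours, or more than ten mono-∪-biallelic tumours.

Each model is a logistic regression with an L1 penalty (alpha = 1).
Samples are weighted by one minus their class proportion — positives get
1 − k/n and background k/n — so both classes contribute equally to the
weighted likelihood despite prevalences of a few percent. Lambda is chosen
by 5-fold cross-validation as the largest value whose mean weighted
binomial deviance is within one standard error of the minimum (the usual
guard against overfitting the deviance curve). Sparsity is additionally
capped at ⌈k/10⌉ + 1 features; when the one-SE solution is denser, lambda
is increased along the path to the smallest value that satisfies the cap,
which preserves the L1 optimisation semantics rather than truncating
coefficients post hoc. Negative coefficients are kept: a deficiency could
in principle protect against a mutational process, and excluding them
would bias the screen.

Out-of-fold scores come from an outer loop with k folds (k = number of
positives): each fold holds out exactly one positive and a round-robin
share of the background, the entire procedure (including the nested CV) is
rerun on the remainder, and the held-out samples are scored. Every sample
is thus scored exactly once by a model that never saw it. The reported
model is a final refit on all samples by the same rule. Fold composition
is a package decision — with one positive per fold, k folds is the finest
split that keeps a positive out of every training run.

All fold assignments and permutations derive from a single user seed, so
identical inputs give identical models.

## Evaluation, permutation and shortlisting

With prevalences of a few percent, ROC curves are dominated by the
background class, so the screen scores models by the precision-recall AUC
enrichment **PR-AUC-E = PR-AUC − π**, where π = k/n is the prevalence and
also the PR-AUC of an unskilled model; PR-AUC-E is therefore comparable
across models of different k. PR-AUC is computed as step-wise average
precision (not trapezoidal interpolation, which is optimistic for PR
curves); tied scores are processed as a block, with every member of a tie
block receiving the block-end precision. AUROC is reported alongside,
computed by the rank (Mann–Whitney) estimator with half-credit for ties.

Significance comes from Monte Carlo permutation: the deficiency labels are
shuffled and the *entire* fitting procedure — nested CV, lambda selection,
cap — is rerun on each permuted label set, so the null distribution
reflects the full selection process, not just a frozen score vector. The
schedule is adaptive: at least 10,000 permutations, and while fewer than
five permuted statistics reach the observed PR-AUC-E, another 10,000 are
added up to 30,000. The p-value is (r + 1)/n, clipped to 1. Across the
model grid of a run the p-values are Benjamini–Hochberg adjusted once, and
a model is shortlisted when PR-AUC-E > 0.2 and q < 0.05.

**Fast mode.** Rerunning the outer k-fold loop inside every permutation is
the full procedure; for tests and the bundled acceptance runs the package
provides a reduced mode in which the out-of-fold scores of each (permuted)
fit come from a single 5-fold cross-validated LASSO (its prevalidated
scores) over a shortened lambda path. The observed statistic is always
recomputed in the same mode as its permutations, so observed and null
values remain exchangeable. Fast mode is labelled as such on every fitted
object and is not the full configuration.

Cross-data-set evaluation freezes a fitted model (coefficients and feature
transform), scores the opposite cohort, and permutes only the labels with
the scores fixed — refitting would be both unnecessary (nothing is
selected on the new cohort) and prohibitively expensive at 30,000
permutations.

## Survival

Overall survival is reconstructed per data-set dialect: metastatic-cohort
(HMF-style) records run from biopsy date to death for deceased patients
(event) and to treatment end otherwise (censored); primary-cohort
(PCAWG-style) records use the registered survival time, falling back to
the last-followup interval as censored time. Samples without usable dates
are dropped, not imputed. Each shortlisted deficiency is then related to
survival by a univariate Cox proportional-hazards model with Efron tie
handling (robust to day-granularity ties; the choice is a package default)
and a two-sided Wald p-value.

## The synthetic-cohort generator

`generate_cohort()` emulates the statistical structure the screen assumes,
not the biology of a genome:

* a small synthetic reference (~1 Mb over three contigs) with gene
  intervals scaled down proportionally, so FASTA/VCF/segment I/O is
  exercised at desk scale;
* planted gene states — biallelic samples carry one of (pathogenic variant
  + LOH), (two pathogenic variants), (deep deletion); monoallelic samples
  exactly one unaccompanied pathogenic variant; VUS carriers one
  mid-score variant — with pathogenicity scores drawn uniform on [25, 50],
  (10, 25) and [0, 10) respectively, so downstream classification is
  unambiguous by construction; the germline/somatic origin of planted
  hits follows a configurable fraction (default 0.7, in the range of the
  worked example's 14/17);
* filter fodder: low-VAF somatic, common-germline, hyper-recurrent and
  non-PASS pathogenic-looking decoys planted in wild-type samples, which
  the curation step must remove;
* feature counts drawn negative-binomial (mean/dispersion
  parameterisation, default size 2) — real mutation counts are
  overdispersed, and a Poisson generator would understate the null
  variance of every downstream statistic. Deficient (biallelic) samples
  have their means multiplied by the configured effects (default
  `del.mh` × 6; the worked-example fixture uses 7.5 over a wild-type
  baseline of 81, matching deficient-vs-wild-type medians of ~608 vs 81);
  monoallelic samples stay at baseline, reflecting that a single
  functional copy usually suffices for repair;
* exponential survival times with a configurable deficient/wild-type
  hazard ratio and uniform censoring, written in the biopsy/death/
  treatment-end date dialect so the date arithmetic is exercised;
* an illustrative per-sample SV breakpoint table for format plumbing; the
  canonical per-sample feature counts are the `features` table, and the SV
  table is not constrained to reproduce them (constructing breakpoint
  configurations that reproduce 32 planted category counts, including
  cluster runs, would add complexity without testing anything the direct
  counts do not).

What passing tests on these cohorts show: the annotation logic inverts the
planting exactly; the models recover multiplicative effects of realistic
size; the permutation machinery is calibrated. What they do not show:
robustness to miscalled copy number, subclonality and purity artefacts,
correlated features from shared mutational processes, or epigenetic
silencing — none of which the generator emulates (the last is a known
limitation of the LOF annotation itself).

## Problem sizes and numerical details

* Null-calibration runs use grids of 80-sample cohorts (6 positives) at
  200 permutations — 50 models in the test suite, 30 in the bundled
  acceptance script — and effect-recovery runs a 600-sample cohort with 20
  positives at 1,000 permutations. Sizes were chosen so the full suite
  re-runs the entire machinery, permutations included, in minutes on one
  core while keeping the positive-class counts in the screen's eligible
  range.
* The glmnet lambda path uses 100 values down to 10⁻⁴ of the data-derived
  maximum (30 values to 10⁻³ in fast mode). Signature columns must sum to
  1 within 10⁻⁶; a rank-deficient catalogue triggers a warning and the
  active-set order breaks ties deterministically. Constant features
  z-score to all zeros with a warning rather than NaN. When no lambda on
  the path satisfies the feature cap the model degrades to intercept-only
  with a warning.
* p-values are exactly (r + 1)/n (clipped to 1); with r and n integers the
  smallest attainable value at 30,000 permutations is 1/30,000 ≈ 3.3×10⁻⁵.

## Known limitations

Phasing of compound heterozygotes, SV-mediated gene disruption, promoter
methylation, tumour purity and subclonality are all outside the
annotation model. The cluster detector approximates the original
piecewise-constant rearrangement segmentation by greedy chaining. The
monoallelic effect size is assumed zero in the generator, so monoallelic
models can only be validated for calibration, not power.
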