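---
title: "Methods: genetic-model meta-analysis with snpmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetic-model meta-analysis with snpmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
```

## Scope and data model

snpmeta pools case-control SNP association studies from genotype counts.
The unit of analysis is a *record*: one (study, disease, SNP) triple with
counts of the WW / WM / MM genotypes in cases and controls (W wild-type,
M mutant allele). Published cohort tables often reuse one healthy control
panel for several rows of the same study — typically the ulcerative colitis
and Crohn's disease case groups — and `control_group_id` makes that
explicit: rows sharing it at the same SNP must carry identical control
counts. The same people genotyped at a second SNP give a *different*
genotype table, which is why the sharing constraint is scoped per SNP.

Aggregation (`count_summary()`) follows the bookkeeping of the published
cohort tables it mirrors: subject totals are summed over distinct
(study, disease) rows, so a case group genotyped at two SNPs is counted
once, while a control panel shared between a study's UC and CD rows is
counted once per row. That per-row convention reproduces the headline
totals such tables print, and deliberately double-counts shared panels;
the unique-control total is always reported alongside as the honest
denominator.

## Genetic-model contrasts

Five standard contrasts map genotypes to a 2×2 exposure table (allele,
dominant, recessive, homozygous, heterozygous). Two are worth flagging:

* The **allele model** counts chromosomes (a = 2·MM + WM, etc.), treating
  the two alleles of a person as independent. That is the convention of
  this literature; the within-person correlation it ignores mildly
  understates the variance and is documented rather than corrected.
* The **heterozygous model** here is WM vs MM — the contrast used by the
  analysis whose cohort table the package ships, where it yields ORs below
  1 because the comparison is heterozygote against the rarer homozygote.
  The textbook WM-vs-WW contrast is available as
  `"heterozygous_conventional"`. Whether the source analysis truly
  intended WM vs MM or relabelled WM vs WW cannot be decided from its
  text, so both are provided with the source's variant as the named
  default.

A contrast whose exposure arm is empty in both cases and controls (e.g.
no MM carrier anywhere, common for rare variants under the recessive
model) is degenerate; `study_effects()` drops such records with a warning
naming them, and the pipeline records every drop in its `skipped` table.

## Effect estimation and pooling

Per-table odds ratios use OR = ad/bc with Woolf log-scale standard error
√(1/a+1/b+1/c+1/d). Tables containing a zero cell get the
Haldane–Anscombe +0.5 added to all four cells of *that table only* — the
dominant convention; `correction = "all"` corrects every table for the
analyses that prefer uniform treatment. A margin of zero (no cases, or no
controls) is inestimable and errors.

Fixed-effect pooling is inverse-variance (the logit/Woolf method), matching
the default behaviour of the commercial meta-analysis software prevalent in
this literature; Mantel–Haenszel weighting is deliberately not offered
because the two differ materially only in sparse-data regimes where the
continuity correction dominates anyway. Heterogeneity is Cochran's Q with
k−1 df, I² = max(0, (Q−df)/Q)·100, and the DerSimonian–Laird τ²; the
random-effects model reuses the inverse-variance machinery with weights
1/(seᵢ²+τ²). No Knapp–Hartung adjustment and no iterative τ² estimators
(REML, Paule–Mandel) are provided: DL-only keeps the package aligned with
the software its source literature used. All 95% intervals use the
conventional critical value 1.959964; p-values are two-sided.

**Model selection.** The conventional rule — random effects when Q's
p < 0.05 or I² > 50%, fixed otherwise — is the default. The analysis this
package accompanies *states* the rule reversed, yet its results adopt
fixed effects exactly where heterogeneity is absent, i.e. they behave
conventionally; we read the stated rule as a transcription slip. The
literal reversed rule is retained as `rule = "paper"` so either reading
can be reproduced.

## Moderators

Subgroup pooling re-runs the same model-selection rule independently per
stratum. Because fixed-effect pooling is a weighted mean, re-pooling the
stratum estimates with their inverse-variance weights recovers the overall
fixed estimate exactly — a structural identity the test suite asserts to
1e-10.

Meta-regression is weighted least squares of θᵢ on an intercept plus
moderators, with weights 1/(seᵢ²+τ²) where the residual τ² comes from the
method of moments on the residual Q (the natural generalisation of
DerSimonian–Laird, to which it reduces exactly for the intercept-only
design — asserted against the random-effects pooled estimate in the
tests). Coefficients are tested with t statistics on k−p df (p = fitted
coefficients), matching the t column printed by the source literature's
tables; no small-sample variance inflation is applied. The standard
cohort moderators are encoded Caucasians = 1 / Asians = 0, CD = 1 / UC = 0,
rs4986791 = 1 / rs4986790 = 0, and sample size = cases + controls per row.
Published tables of this kind sometimes label their p-values "adjusted"
without defining the adjustment; snpmeta reports unadjusted per-moderator
p-values by default and offers an explicit Bonferroni flag, so what is
reported is always defined.

Permutation p-values re-randomise the moderator rows against the effects
(the design matrix rows are permuted jointly, and τ² is re-estimated in
every permutation) and report (1 + #{|t*| ≥ |t|})/(n_perm + 1), bounded
below by 1/(n_perm+1). The permutation stream is seeded explicitly and is
reproducible.

## Publication bias

Egger's test is the classic 1997 formulation — unweighted OLS of the
standardized effect θᵢ/seᵢ on precision 1/seᵢ, intercept tested on k−2
df — not one of the later weighted variants. Rosenthal's classic fail-safe
N uses the one-tailed criterion z = 1.644854 by default (the classic
choice, and the labelled behaviour of the prevalent software), with the
two-tailed 1.959964 as an option. Funnel exports carry per-study points
and pseudo-95% limits around the pooled estimate; a point is inside the
funnel iff |θᵢ−θ̂| ≤ 1.959964·seᵢ, which is the identity the plot data is
tested against. Rank-correlation (Begg–Mazumdar) and trim-and-fill are out
of scope.

## Hardy–Weinberg QC

`hwe_test()` is a 1-df Pearson chi-square of control genotypes against
Hardy–Weinberg expectations at the observed allele frequency, applied per
(control group, SNP) panel by `hwe_screen()`. Departure flags possible
genotyping error or stratification, but it is advisory only — no study is
excluded — because the analyses this package mirrors apply no HWE filter,
and silently changing the study set would change the science.
Monomorphic panels are reported as such with χ² = 0, p = 1.

## The synthetic-data generator

`simulate_studies()` draws, per study i: a control minor-allele frequency
qᵢ ~ Uniform(maf_range); control genotypes multinomially under HWE
((1−q)², 2q(1−q), q²); a true log OR θᵢ ~ Normal(θ, τ²); and case
genotypes from the HWE probabilities exponentially tilted by
exp(θᵢ·score(g)) with the allelic (0/1/2), dominant (0/1/1) or recessive
(0/0/1) score. The tilt is the logistic disease model conditional on
genotype under the rare-disease approximation, so the odds-ratio
parameterisation the estimators target is exactly the generative one; for
the allelic score the tilted law is again HWE at a shifted allele
frequency, making the allele-model estimator consistent for exp(θᵢ).
The default MAF range (0.02–0.05) reflects the low-frequency coding
variants of the worked example (HapMap CEU MAF 0.033 for both TLR4 SNPs);
ranges are explicit arguments everywhere else they matter. Randomness uses
one root seed that spawns a per-study substream, so extending a simulation
by another study never perturbs the data of earlier studies.

`simulate_tlr4_cohort()` instantiates the generator on the exact skeleton
of the packaged cohort table — its 13 studies, 22 (study, disease) rows,
SNP coverage (37 records), ethnicities and sample sizes — with θ =
log(1.27) and τ² = 0.01, the magnitude of the published pooled estimate,
MAF 0.05 for Caucasian and 0.03 for Asian panels (slightly above the
HapMap reference so the rarer contrasts remain estimable at the published
sample sizes), and one control group per study and SNP shared between its
UC and CD rows.

What the generator deliberately does **not** emulate: linkage
disequilibrium between the two SNPs (each is drawn independently),
covariate-dependent MAF drift, genotyping error, and — most importantly —
any correlation *adjustment* for shared controls. The generator creates
the shared-control correlation (as real cohort tables do) but the
estimators, like the published analyses they mirror, treat all rows as
independent. Passing calibration tests therefore shows the engine is
correct for its stated model, not that the independence assumption is
harmless on real data (see Limitations).

## Calibration and problem sizes

The suite calibrates the whole chain on its own generative model, at sizes
chosen to give tight Monte Carlo bands while keeping the default test run
in minutes: null coverage and spurious-heterogeneity checks use 200
replicates of k = 20 studies with 500 cases/500 controls at MAF 0.3
(fixed-effect CI coverage of OR = 1 must fall in 93–97%; mean I² ≤ 15%);
Egger's type-I error uses 200 symmetric funnels of k = 50; the permutation
test's type-I error uses 200 replicates × 1000 permutations at k = 20
(both rates must fall in [0.02, 0.10]); estimator bias uses 60 replicates
of k = 10 at n ≈ 2000 per arm (|bias| < 0.02 on the log scale). Parameter
recovery on the TLR4-shaped cohort uses 100 seeds and asserts
random-effects CI coverage of log(1.27) in [88, 100]%.

That last band is wider below than a clean nominal 95% would suggest, on
purpose: in the TLR4-shaped design the 22 effect rows come from only 13
studies (one θᵢ per study, shared by its rows) and UC/CD rows share
controls, so the effects are positively correlated and the
independence-assuming pooled SE is slightly optimistic — observed coverage
sits near 88–90%, a faithful property of the published design rather than
an estimator defect. The DerSimonian–Laird interval is used for the check
because the generator has τ² > 0.

## Numerical and degenerate-input choices

* Critical value 1.959964 everywhere a 95% interval is formed.
* k = 1: pooling is the identity (both models); heterogeneity,
  leave-one-out and meta-regression refuse with typed errors, and the
  pipeline converts those refusals into logged skips.
* Q ≤ df: I² and τ² truncate at 0 (fixed and random pooling then
  coincide, asserted exactly in the tests).
* Constant moderators are dropped with a warning; rank-deficient designs
  error rather than silently pseudo-inverting.
* Fail-safe N is floored at 0; its floor(·) keeps the "number of studies"
  reading.
* All validation failures carry the offending row and column.

## Known limitations

* No multi-level model for shared control groups: effects from the same
  study are pooled as independent, mirroring (and inheriting the mild
  anticonservatism of) the published analyses.
* The allele model's chromosome-independence assumption.
* DL-only τ²; no Knapp–Hartung; no Mantel–Haenszel option.
* Publication-bias power at small k is intrinsically low; the battery
  reports, it does not gate.
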