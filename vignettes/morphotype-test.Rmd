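---
title: "The morphotype test: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The morphotype test: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphotest)
```

## The problem

Blue mussels *Mytilus edulis* and *M. trossulus* co-occur and hybridize in
several North Atlantic and Arctic contact zones. They are cryptic: no shell
character separates them individually. One binary character — the presence
(T) or absence (E) of an uninterrupted prismatic strip under the ligament
nympha — is *semi-diagnostic*: polymorphic in both species, but much more
frequent in *trossulus*-dominated genotypes. Identification from such a
character is necessarily probabilistic, and the probability of a correct
call depends on the species composition of the population being sampled.

`morphotest` treats the character as a clinical diagnostic test for the
species-specific genotype (the reference standard being the admixture
proportion *q* from multilocus genotyping, with *q* > 0.5 called
*trossulus*). The test's operating characteristics are, in clinical terms:

* prevalence — `Ptros`, the fraction of trossulus genotypes in a sample;
* sensitivity — `P(T|tros)`, T-morphotypes among trossulus genotypes;
* specificity — `P(E|edu)`; we work with its complement, the
  false-positive rate `P(T|edu)`;
* positive/negative predictive values — `P(tros|T)` and `P(edu|E)`, the
  probabilities that a T-morphotype is trossulus and an E-morphotype is
  edulis.

## The calculators

Assuming prevalence-independent sensitivity and false-positive rate, the
predictive values follow Bayes' rule:

$$P(tros|T) = \frac{Ptros \cdot P(T|tros)}
  {Ptros \cdot P(T|tros) + (1-Ptros) \cdot P(T|edu)}$$

$$P(edu|E) = \frac{(1-Ptros)(1-P(T|edu))}
  {(1-Ptros)(1-P(T|edu)) + Ptros\,(1-P(T|tros))}$$

and the prevalence can be recovered from the observed T-morphotype
frequency `PT` by inverting the mixture identity
`PT = Ptros * P(T|tros) + (1-Ptros) * P(T|edu)`:

$$Ptros = \frac{PT - P(T|edu)}{P(T|tros) - P(T|edu)}.$$

With the pooled White Sea rates (sensitivity 0.74, false-positive rate
0.04) an equal mixture has an expected `PT` of 0.39, a PPV of 0.949 and an
NPV of 0.787:

```{r}
p <- calc_params(0.74, 0.04)
c(ppv = ppv(p, 0.5), npv = npv(p, 0.5),
  ptros = as.numeric(prevalence_from_pt(p, 0.39)))
```

A note on the NPV formula: it is sometimes written with the denominator's
second factor as `Ptros (1 - P(T|edu))`, which is not a probability
decomposition and does not reproduce the worked value 0.787. The package
implements the Bayes-consistent form with `1 - P(T|tros)`, which does.

The prevalence inversion requires an informative marker
(`P(T|tros) > P(T|edu)`) and is exact only for `PT` within
`[P(T|edu), P(T|tros)]`; outside, estimates are clamped to `[0, 1]` and
flagged, rather than silently truncated or rejected — observed frequencies
legitimately fall outside the interval by sampling error.

## Regression models

Six binomial logit models link morphotype data to taxonomic structure
(`fit_model()`, `model_spec()`):

* M1: T-morphotype indicator ~ `ptros * set` (GLM);
* M4: trossulus-genotype indicator ~ `pt * set` (GLM) — the regression
  reference for the prevalence calculator;
* M2/M5: T-morphotype indicator ~ `ptros * set * species`, with a
  sample-level random intercept (GLMM, Laplace) — measures the *drift* of
  the within-species rates with prevalence;
* M3/M6: correct-identification indicator ~ `ptros * set * morphotype`,
  with a sample-level random intercept — the reference for the predictive
  calculators.

Design choices worth stating:

* **Pseudo-R²** is the Nakagawa–Schielzeth form with the theoretical logit
  distribution variance π²/3: marginal = σ²f/(σ²f+σ²α+π²/3); conditional
  adds σ²α to the numerator. σ²f is the variance of the fixed-effect linear
  predictor over the fitting data.
* **Separation.** Samples at prevalence extremes are routinely monomorphic,
  so complete separation is a normal occurrence, not an error. A separated
  fixed-effects fit is refit by bias-reduced (Firth) logistic regression —
  penalised IRLS with the hat-value score correction — and flagged.
* **Non-convergence of a GLMM** falls back to a fixed-effects fit with
  cluster-robust (sandwich) standard errors by sample; the random factor is
  empirically weak in this system, so the fallback loses little. The
  `method` and `converged` fields always report what was actually fitted.
* **Confidence bands** (`predict_with_ci()`) are Wald intervals on the
  linear predictor mapped through the inverse logit, so bounds stay in
  [0, 1]. Predictors outside [0, 1] warn (frequencies cannot exceed them)
  but do not reject.
* **Pooling of geographic sets** (`pooling_test()`) refits the M3 structure
  under candidate relabellings of the `set` factor and selects the
  minimum-AIC partition; all candidates are fit to the identical response
  vector so AICs are comparable.
* Per-sample frequencies (`ptros`, `pt`) are derived empirically from the
  table being fitted; a table that already carries these columns (e.g.
  design values of a simulation) keeps them.

## The calibration-pair experiment

To apply the calculators in an unstudied contact zone one needs the two
rates from a few genotyped "calibration" samples. Which samples calibrate
best? Every pair of samples is scored (`evaluate_pairs()`):

* the pair's **Delta** = `p1(1-p2) + p2(1-p1)` measures taxonomic
  dissimilarity (0 = two pure conspecific samples, 0.5 = two equal
  mixtures, 1 = pure heterospecific pair);
* the pair's pooled 2×2 counts give calculator parameters, whose predicted
  curves are compared with the study's own regression reference (M4 for
  the prevalence target, M6 for the predictive target) on the grid [0, 1]
  in steps of 0.01 (endpoints included, unweighted mean);
* **Goodness** = 1/MSS; perfect agreement is reported as an infinity
  sentinel, excluded from LOESS smoothing and never fed to it.

The predictive target pools the squared differences of both species' curves
with equal weight. Degenerate pairs (pooled sensitivity not exceeding the
pooled false-positive rate, or an empty species class) are recorded as
failed evaluations rather than dropped. LOESS defaults to span 0.75 and
local quadratics; both are exposed.

`select_calibrators()` encodes the resulting practical rules: pool samples
with `Ptros` < 0.1 or > 0.8 to calibrate the prevalence calculator; pool
samples with 0.45 < `Ptros` < 0.65 to calibrate the predictive calculators.
An empty stratum is an error naming the stratum — the practical fallback
(pooling all samples) is deliberately left to the analyst. The "lazy"
calibration (`lazy_params()`) uses the extreme-`PT` samples directly, with
no genotyping, at the cost of bias when those samples are not actually pure.

## The synthetic-data generator

No individual-level genotype data are distributed with the source studies,
so the package ships a generator (`sim_config()`, `generate_study()`)
emulating the statistical structure the analysis assumes:

* **Admixture proportions.** A three-component mixture: purebred *edulis*
  `q = 0.2·Beta(1, c)`, purebred *trossulus* mirrored above 0.8, hybrids
  `0.2 + 0.6·Beta(1.2, 1.2)`. The regimes `"bimodal"` (10% intermediates at
  an equal mixture) and `"flattened"` (35%) reproduce the two observed
  kinds of contact zone. With the default `"unimodal"` hybrid profile the
  hybrid fraction of a sample scales as `4p(1-p)`, so hybrids concentrate
  where the species co-occur and vanish in pure populations; `"constant"`
  disables the scaling. The within-purebred dispersion `c` is a free
  parameter (the source histograms do not constrain it) with default 4.
* **Morphotype law.** Per-species logit intercepts and optional logit
  slopes on the sample prevalence; hybrids use the midpoint of the species
  coefficients, consistent with hybrids being intermediate in morphotype
  frequency. Defaults put sensitivity at 0.74 and the false-positive rate
  at 0.04 for an equal mixture with a moderate common drift (slope 1.5).
* **Sizes.** Log-normal lengths (median 40 mm, sdlog 0.25) with no
  morphotype–size association by default; `morph_effect` (logit per mm)
  injects one for power studies.
* **Reproducibility.** One global seed; sample *i* draws from L'Ecuyer-CMRG
  substream *i*, so any sample regenerates alone and studies are
  byte-identical under a fixed seed.

`wsbl_config()` is the preset for the reference system (White Sea plus
brackish Barents Sea): 36 samples of 18–173 mussels; a right-skewed
prevalence distribution (`qbeta(ppoints(36), 0.8, 1.6)`) reflecting an
*edulis*-dominated zone in which trossulus-dominated samples are scarce but
both calibration strata are populated; about 13% pooled intermediates; and
a positive drift of both within-class rates, steeper for the *edulis* class
(`slope 3` vs `1`), where rising T-frequencies — partly carried by
introgressed genotypes classified as *edulis* — are what erodes the test.
The drift magnitudes are not published quantities; they were fixed once, at
generator design time, as the regime in which the documented calibration
mechanics (prevalence calculators best served by dissimilar pairs,
predictive calculators by mixed pairs) emerge, and are exposed in the
configuration.

What passing tests on these synthetic data do **not** show: the generator
has no genetic linkage, no explicit multi-locus genotypes, no spatial or
salinity structure, and its drift/hybrid parameters are plausible rather
than estimated. Results about *rates of convergence* or *qualitative
mechanics* transfer to real data; exact coefficient values do not.

## Numerical choices and problem sizes

* Genotype classification is boundary-inclusive to *edulis* (`q = 0.5` is
  edulis), matching the reference-standard convention.
* Undefined diagnostic indices (zero denominators) are `NA` plus an
  explicit flag, never 0 — degenerate samples are legal data and simply
  contribute nothing to pooled regressions.
* Pooling of samples always sums 2×2 counts; frequencies are never
  averaged.
* The Hochberg screen corrects within each species' family of informative
  (morphotype-polymorphic) cells separately: the two species' screens ask
  distinct questions and form separate hypothesis families.
* Test and validation runs use deliberately modest problem sizes chosen for
  tight Monte-Carlo error at interactive cost: 10⁵–10⁶ Bernoulli draws for
  law-of-large-numbers checks, 100 replicates of 36×100-individual studies
  for coverage checks, and 20 synthetic studies for the calibration-rule
  check.

## Known limitations

* The closed-form calculators assume the two rates are transportable
  across prevalences; the drift built into the generator (and found in real data)
  violates this, which is exactly why calibration-sample choice matters.
* The correctness reference (M6) is logistic in prevalence and cannot
  represent a mid-range dip in correctness; comparisons of calculator
  curves against it inherit that restriction.
* Published coefficients are stored to their printed precision (one
  decimal); predictions from them carry rounding error of up to about
  ±0.02 on the probability scale.
* The q-threshold classification folds hybrids into the dominant-gene
  class; in heavily introgressed zones the two classes are admixture
  classes, not purebred species.
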