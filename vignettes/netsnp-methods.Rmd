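---
title: "Scoring genetic variants with a trained case/control network"
author: "netsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic variants with a trained case/control network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genome-wide association scans rank variants by single-locus case/control
asymmetry, which misses rare variants and variants whose effect is expressed
through interactions with the rest of the genotype. This package takes the
complementary route: it trains a polygenic neural-network classifier on
individual genotypes and then asks, SNP by SNP, *how much does the
classifier's output move if every holdout individual is artificially made
homozygous for this SNP's minor allele?* The shift, averaged over holdout
individuals and repetitions, is the SNP's score (mCVt): negative shifts mark
putatively protective alleles, positive shifts risk alleles, and the
magnitude acts as an importance weight. The procedure is a genotype-adapted
relative of permutation feature importance: the model is never refit when a
genotype is assigned, so the score reflects what the *trained* classifier
learned.

## The pipeline and its assumptions

**Sparse genotype store.** Diploid biallelic GT calls are encoded as 0
(hom-reference), 1 (het), 2 (hom-alternate) and -1 (missing). Because the
emulated exome data are overwhelmingly reference (>95% of minor allele
frequencies below 0.01), only non-zero codes are stored; the `.nss`
container (JSON header plus one `locus sample code` triplet per stored
call) is lossless by construction and round-trip tested byte-for-byte.
Multi-allelic records are not encodable in this scheme and are skipped with
a warning; pre-splitting with a VCF normalizer is the supported path.

**Missing genotypes.** How missing calls were handled in the original
training is not documented anywhere we could rely on; we adopt the sparse
default and map -1 to 0 when building classifier feature matrices (the
count of imputed cells is reported). Allele-frequency and association
computations, by contrast, always exclude missing calls from both margins.

**Cohort balancing.** A classifier can learn cohort identity from genotypes
(platform artifacts, population structure) and exploit cohort-level
case:control imbalance instead of disease signal; with 24 cohorts, uniform
guessing gives only ~4% cohort accuracy, so any learnable cohort signal is
a real confounder. Cohorts with fewer than 20 individuals or a minority
class under 20% of the majority are dropped, and every training set takes
an equal number of cases and controls from each retained cohort (training
prevalence exactly 0.5). Holdout sets are not forced to 0.5 unless
requested (`balancedHoldout`), because evaluation data need not share the
training prevalence; the target-SNP engine defaults to a balanced holdout
so that the baseline classifier value is centered near zero and the sign of
a shift is interpretable.

**Association and ranking.** Each SNP gets a two-sided Fisher's exact
p-value (FishP) on the 2x2 table of (minor, reference) allele counts in
cases and controls — allele-level counting, two alleles per non-missing
individual. Two-sidedness follows the point-probability convention (sum of
hypergeometric probabilities no greater than the observed table's, with a
1e-7 relative comparison tolerance); this convention is not uniquely
standard, so it is pinned by a brute-force enumeration oracle in the tests.
The implementation is a vectorized `dhyper` sum because the Q-Q calibration
needs on the order of a million exact tests. Calibration is purely
empirical: FishP quantiles under 100 label shuffles bound what chance looks
like, and the chromosome-exclusion variant reproduces the check that
association signal survives removal of the strongest locus's chromosome.

**The network.** A feed-forward pattern-recognition network (tanh hidden
layers, default 50 and 10 units; softmax output) maps the 50-SNP genotype
vector (each feature affinely scaled to [-1, 1] from training-set min/max;
values outside the range are clipped) to P(case). The classifier value is
CV = P(case) - 0.5, so -0.5 labels control and +0.5 case. The performance
function is `(1 - reg) * mean cross-entropy + reg * mean(w^2)` with
`reg = 0.1`, the regularization interpreted as a performance ratio with the
squared-weight penalty over weight entries only (biases exempt). Training
is full-batch scaled conjugate gradient (Moller): curvature along the
search direction is estimated by a forward difference of the gradient with
step `wtSigma/|p|` (`wtSigma = 5e-5`), a scale parameter `lambda`
(initial 5e-7, bounded in [1e-15, 1e15]) regulates indefiniteness via the
comparison parameter, and the direction restarts to steepest descent every
W iterations (W = number of weights) or on non-finite curvature. One SCG
iteration is one epoch; training stops at 1000 epochs, gradient norm below
1e-6, or 10 consecutive epochs of rising validation performance, returning
the best-validation weights. Weight initialization is a Nguyen-Widrow-style
scaled uniform draw from the configuration seed; given (seed, data) the
trained network is bit-reproducible. We claim equivalence with the
reference SCG formulation at the level of its tested properties (exact
gradients, monotone training loss, stopping behavior), not bitwise.

**The scoring engine.** For a target SNP, each of (by default) 20
repetitions draws a fresh ~70% balanced training subset, ranks all SNPs by
training FishP, builds the feature matrix from the 49 best-ranked SNPs plus
the target (if the target already ranks in the top 49 the 50th fills the
matrix — the target is never duplicated), trains a network, and scores the
holdout three ways: NAT (true genotypes), REF (target forced homozygous on
the reference scale) and ALT (target forced homozygous for its minor
frequency allele; when the minor allele *is* the reference allele, ALT
forces code 0 and REF code 2). mCVt is the mean ALT score over individuals
and repetitions; DIF = ALT - REF tracks the same shift per individual.
Repetition r of target t derives its seed as `childSeed(master, t, r)`, so
every target's evaluation is independently reproducible. Whether the
holdout should be redrawn per repetition is ambiguous in the source
protocol; we redraw by default and expose `fixedHoldout`.

**Significance.** mCVt values for randomly chosen target SNPs (default
1000, scored with 5 repetitions each — a deliberate tractability trade-off
recorded in the band object) form the null sample; a scored SNP is called
protective/risk when its mCVt falls outside the empirical central 95%
interval, with a rank-based two-sided empirical p. With `alpha = 1` the
band degenerates to the full sample range and nothing can be called.

**Constructed diseases.** The negative control assigns a fake disease over
real (or generated) genotypes: carriers of an e4-like allele (dominant
coding, precedence over e2) are labelled control with odds 0.30, e2-like
carriers with odds 2.41, everyone else 0.89; ages of diagnosis are ascribed
by inverse-CDF sampling from the carrier group's empirical case-age
distribution. Because such a disease depends on exactly two loci, any
burden-age correlation built from off-chromosome SNPs is spurious by
construction — the pipeline should, and in our tests does, report it as
non-significant.

## The synthetic cohort generator

Real exome-study data of this kind are access-controlled, so the package
ships a generator that emulates their structure with known ground truth.
Defaults (6,000 samples, 10,000 loci) were fixed once from the emulated
study's published characteristics:

* **MAF spectrum** — 96% of loci draw a locus MAF from U(0.001, 0.0075),
  4% from a common tail U(0.01, 0.35); after binomial genotype sampling
  this realizes >95% of loci with empirical MAF < 0.01.
* **Planted common loci** — an e4-like risk locus (MAF 0.147, per-allele
  control:case odds 0.30, -8.4 years of diagnosis age per allele) and an
  e2-like protective locus (MAF 0.076, odds 2.41, +3.8 yr/allele), plus a
  TOMM40-like companion on the same chromosome copied from the e4-like
  anchor with correlation 0.8 (so chromosome-exclusion and
  exclusion-by-gene paths are exercised against linkage).
* **Planted rare loci** — eight loci at MAF 0.02 with graded per-allele
  control:case odds {3.0, 2.41, 2.0, 1.5} (protective) and
  {0.33, 0.41, 0.5, 0.67} (risk) and +/-0.5 yr/allele age shifts. MAF 0.02
  is a deliberate choice: at 6,000 samples it yields ~240 minor alleles per
  locus, enough for the weakest planted odds to be learnable while staying
  far rarer than the common planted pair.
* **Status model** — an individual's control:case odds are the baseline
  0.89 multiplied per minor allele by the locus odds. We apply planted
  effects per allele (dosage) rather than per carrier: the APOE-genotype
  ordering (e34 below e44, e23 below e33) only exists under a dosage
  effect, and for rare loci the two codings coincide. The constructed
  -disease simulator, in contrast, keeps the three-group carrier coding of
  its source protocol exactly.
* **Cohorts** — 24 labels; half balanced, a quarter case-heavy and a
  quarter control-heavy (case fractions 0.65-0.90 and mirrored), so the
  cohort filter genuinely removes some cohorts.
* **Phenotypes** — case age of diagnosis is 75.4 + planted shifts +
  N(0, 7); control age at last visit 86.1 + N(0, 7); ages floor at 41.
  Braak stage is a monotone step function of standardized planted burden
  (weight 1.2) plus unit noise through thresholds (-1.5, -0.8, -0.2, 0.4,
  1.1), reported for a 28% autopsy fraction. Missing calls are planted at
  rate 0.002 per cell.

What the generator does *not* emulate: linkage beyond the declared
companion block, population demography and relatedness, genotyping batch
effects correlated with cohort, age-dependent ascertainment. Passing tests
therefore show that the machinery recovers effects it was pointed at under
independence-plus-one-LD-block genetics — not that it would survive the
full confounding structure of real data; the cohort-balancing and
constructed-disease checks are the in-package guards against the latter.

## Numerical choices and degenerate inputs

* Fisher p-values: vectorized exact computation chunked to bound memory;
  loci with every genotype missing in a subset have undefined MAF and are
  dropped from ranking with a message; all-zero 2x2 tables are an error.
* Ties: rank ties in FishP break by (chromosome, position); a CV of
  exactly 0 predicts control ("any positive CV" is a case); quantile type
  7 is used for band endpoints and age ascription.
* The ROC optimal operating point maximizes TPR - S*FPR with
  S = (Cost(P|N) - Cost(N|N)) / (Cost(N|P) - Cost(P|P)) * N/P, taking the
  smallest-FPR point on ties; prevalence sweeps reweight the holdout
  confusion rates analytically (a resampling mode exists for cross-checks).
* The logistic baseline is IRLS with a fixed 1e-6 ridge so complete
  separation stays finite; the GLM slope test is the closed-form
  F(1, n - 2) of the OLS slope (equal to the squared t) — the 2-df notation
  sometimes seen for such tests is not reproducible from a single-predictor
  model, so we implement the standard 1-df form and say so.
* Gradient verification compares backpropagation to central finite
  differences (step 1e-6) with the relative error floored at 1e-4 in the
  denominator, below which the oracle's own roundoff dominates.

## Problem sizes used by the test suite

The shipped checks run the full method at reduced scale, chosen once:
recovery of the eight graded planted loci uses three replicate 6,000 x
10,000 cohorts at 5 repetitions per target; sign recovery is asserted per
cohort, while the rank correlation between |log odds| and |mCVt| is
computed on the per-locus score averaged over the three cohorts (15
effective repetitions, close to the 20 used for real targets — a single
5-repetition score still carries substantial training noise). Null
calibration uses a 2,400 x 1,500 effect-free cohort with a 100-SNP random
band; the burden-uniformity check permutes ages per replicate so its 1,000
regressions are independent. The APOE-genotype assignment check trains
three networks on a 6,000-sample cohort and averages the six genotype
means.

## Known limitations

* The engine scores one SNP at a time (plus the two-locus APOE genotype
  case); no epistasis enumeration or Shapley-style attribution.
* mCVt is an importance measure relative to one trained classifier family
  and feature-selection rule; it is not an effect-size estimate on the
  odds scale.
* Exact-test p-values are conservative at rare loci; the Q-Q machinery is
  calibrated by shuffling rather than by any parametric correction.
* Full-batch SCG on 50-feature matrices is deliberate (matching the source
  environment); the trainer is not meant for large feature sets or GPUs.
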