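---
title: "Two-step allele-frequency estimation in pooled DNA: model, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step allele-frequency estimation in pooled DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolfreq)
library(dplyr)
```

## The estimation problem

A DNA bulk pools the genomes of `n` individuals from one population. On a
two-colour SNP array the bulk produces, per SNP, normalized channel
intensities `x` (allele A) and `y` (allele B), summarized by the
fluorescence intensity ratio `FIR = y / (x + y)`. Under the assumption that
each channel's signal is proportional to the amount of the corresponding
allele in the hybridized DNA, FIR is a monotone but nonlinear proxy for the
bulk's allele-B frequency `f_B`, distorted by differential hybridization of
the two probes and compressed near the ends of the scale.

The estimator in this package is deliberately split in two steps.

**Step 1: fixation testing.** Reference inbred lines genotyped on the same
array provide, per SNP, the FIR distribution of true homozygotes: an AA
cluster `(mu_AA, sd_AA, n_AA)` and a BB cluster `(mu_BB, sd_BB, n_BB)`. We
model each cluster as Gaussian and ask whether the bulk's single FIR
observation is compatible with it, using the prediction-interval Student
statistic

$$t = \frac{FIR - \hat\mu}{\hat\sigma\sqrt{1 + 1/N}}, \qquad t \sim t_{N-1},$$

two-sided at a nominal level of 5% per cluster. The four outcomes map to
calls: member of AA only (allele A fixed, `f_B = 0`), member of BB only
(`f_B = 1`), member of neither (polymorphic, passed to step 2), member of
both (ambiguous, no frequency reported). Controlling a per-test type-I
level is the point: the probability of spuriously declaring polymorphism in
a truly fixed bulk is held at about 5% per side, whereas a clustering-based
caller offers no such control.

**Step 2: one pooled calibration curve.** For polymorphic bulks, `f_B` is
predicted by inverse-logit of a linear function of FIR. The curve is a
quasi-binomial GLM (logit link, fractional responses, unit weights) fitted
by IRLS on controlled pools: bulks mixing three parental inbred lines of
known genotype in known leaf-mass proportions, so that the expected
frequency of each pool is the mass-weighted sum of parental dosages. A
single `(alpha, beta)` is shared by all SNPs. The alternative — a curve per
SNP — would require every SNP to be polymorphic in the calibration
material, silently discarding exactly the markers that differ between
isolated genetic groups; the pooled curve trades a small accuracy loss for
the absence of that ascertainment bias.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `threshold` (wd filter) | 50 | minimal cluster separation, in pooled-sd units, for a SNP to be usable; "above 50" is implemented strictly (`wd > 50`), and the boundary behaviour is configurable by passing another value. |
| `alpha` (fixation test) | 0.05 | per-side nominal type-I level of the membership tests. |
| `n_per_class` (calibration sample) | 250 | SNPs drawn per configuration class R1–R4, 1,000 in total, balancing the expected-frequency ranges in the fit. |
| `conf` (sampling bounds, concordance) | 0.95 | confidence level of Clopper–Pearson intervals and of the replicate-concordance region. |
| `n_individuals` | 15 | plants per bulk; enters only through the gamete count `2n` in sampling-error computations and simulation. |

The wd score uses the sample standard deviation (n − 1 denominator) inside
each cluster; the score's defining expression weights the variances by the
cluster counts `N`, and with `N` versus `N − 1` unresolved in its source we
chose the conventional unbiased per-cluster estimator. SNPs whose cluster
has a single line keep an undefined sd, hence an undefined wd, and fail the
filter rather than passing on a fabricated zero variance.

The membership statistic uses the `sqrt(1 + 1/N)` prediction-interval
inflation: the bulk contributes one new observation compared against an
*estimated* Gaussian, and without the inflation the test would be
anti-conservative for small reference panels. With it, the marginal type-I
rate is exact at any panel size (this is verified empirically in the test
suite at n = 100 lines).

## Configuration classes and the calibration sample

Within one series of nine pools, the three parental dosages determine the
span of expected frequencies: `(1,0,0)` spans 1–33% (R1), `(0,0,1)` or
`(0,1,0)` 33–50% (R2), `(1,0,1)` or `(1,1,0)` 51–67% (R3), and `(0,1,1)`
67–99% (R4); all-equal genotypes give monomorphic pools. The calibration
sample draws 250 SNPs per class. A SNP showing different classes in the two
series is assigned to one class by the priority order R1, R4, R2, R3: the
extreme-range classes first, which operationalizes "maximize the frequency
range" and makes the assignment deterministic. Sampling within a class is
uniform without replacement from lexicographically sorted ids under the
user's seed, so a seed fully reproduces the selection.

Whether the six parental-line samples belong in the GLM fit alongside the
18 pools is genuinely open; we include them by default in the calibration
table (flagged `is_pool = FALSE`) and let the caller restrict to pools, as
the cross-validation functions do when asked.

## The synthetic-data generator

`simulate_world()` emulates the full study design: a homozygous reference
panel (per-SNP allele-B frequency drawn from a MAF distribution, default
uniform on [0.05, 0.5]; cluster means 0.08 and 0.92 with sd 0.02, jittered
per SNP with sd 0.01 to create wd variation), two series of parental trios
with their nine-pool mixing design, and landrace bulks in which the bulk
frequency is a binomial draw of `2n` gametes around the population
frequency (n = 15 plants by default, half of the population-SNP cells fixed
and the rest uniform on [0.05, 0.95]).

The forward signal model is the inverse of the calibration curve
(`alpha = -5`, `beta = 10` by default) plus Gaussian FIR noise
(sd 0.02), with one deliberate exception: a bulk *exactly* fixed for an
allele emits FIR from the corresponding homozygous cluster, not from the
inverted curve (whose preimage of 0 and 1 is infinite). This anchoring
makes the noise-free world an exact fixed point of the estimator — fixed
cells are called fixed with probability one and polymorphic cells are
recovered to machine precision — which is the property the end-to-end
identity tests exercise.

What the generator does *not* emulate: linkage disequilibrium between
SNPs, per-SNP differential-hybridization curvature (every SNP shares one
true curve), batch and laboratory effects, DNA-mixing ("bulking") error
distinct from FIR noise, and heterozygous reference lines. Tests passing on
this generator therefore validate the statistical machinery — calibration
recovery, type-I control, error propagation, distance behaviour — not the
biology of any particular array.

## Numerical choices

* IRLS tolerance 1e-10 (relative deviance change), 50 iterations maximum;
  fits report `converged` and their deviance, and non-convergence is an
  error at prediction time.
* Allele counts for Clopper–Pearson bounds use `x = round(freq * n)` half
  away from zero; bounds at the boundary are exact (`lower = 0` at `x = 0`,
  `upper = 1` at `x = n`).
* Percentages are rounded half-up after rounding the product `100 f` to six
  decimals, so that binary float representation of exact halves (e.g.
  `0.15 + 0.425`) cannot flip a printed percent.
* The membership test treats `p >= alpha` as membership, with a 1e-12 slack
  so an observation placed exactly at the alpha quantile remains a member.
* A zero-sd cluster degenerates the membership test to exact equality with
  the mean; zero pooled deviation with distinct means yields `wd = Inf`
  (passes any threshold), and coincident means with zero deviation yield an
  undefined wd (fails).
* Mean imputation of missing frequencies happens before any SNP
  subsetting in distance computations, and replicate averaging is
  pairwise-complete (a cell missing in one replicate takes the other's
  value).
* All stochastic functions accept a `seed` and restore the caller's RNG
  state (`withr`), so identical seeds give bit-identical outputs without
  disturbing the session.

## The replicate-concordance region

To judge whether two independently sampled bulks of the same population
agree as well as sampling alone allows, each SNP's replicate pair `(f1,
f2)` is compared against the region `|f1 - f2| <= z_{0.975} sqrt(2 m (1 -
m) / 2n)` with `m = (f1 + f2)/2` — the normal approximation to the
difference of two independent binomial draws of `2n` gametes at true
frequency `m`. The exact construction of a sampling-only confidence region
for replicate scatter is not canonical; this difference-based normal form
is recorded as our choice, and simulation at `n = 15` shows its actual
coverage within half a percentage point of nominal despite the
discreteness of 30-gamete frequencies.

## Cross-validation machinery

Two complementary designs measure the calibration's robustness. SNP k-fold
CV (`snp_kfold_cv()`) refits the curve on 800 of the 1,000 calibration
SNPs and scores MAE on the held-out 200, quantifying sensitivity to the
SNP sample. Sample-removal CV (`sample_removal_cv()`) removes k of the 18
pool samples, refits, and predicts the removed pools, quantifying how
accuracy degrades as the calibration design loses frequency coverage; its
mean MAE is non-decreasing in k in expectation, and the suite asserts the
trend on noisy synthetic data. Any k below the pool count is accepted.

Problem sizes in the shipped tests are scaled to the property being
demonstrated — worlds of 80–6,000 SNPs, 40–100 lines, repeats of 40–60 for
CV and 20,000–40,000 draws for rate estimates — sizes at which the
Monte-Carlo error of each asserted quantity is comfortably below the
asserted tolerance.

## Known limitations

* One pooled curve ignores per-SNP differential hybridization; accuracy
  for balanced frequencies would improve with per-SNP curves at the cost
  of the ascertainment bias discussed above. A per-SNP extension would
  slot in behind `fit_calibration()` unchanged.
* Ambiguous fixation calls (membership in both clusters) are reported and
  excluded downstream, never resolved; with well-separated clusters they
  are rare, and fabricating a call would undo the type-I guarantee.
* The fixation test assumes Gaussian cluster FIR; heavy-tailed clusters
  inflate the realized type-I rate.
* No multiple-testing correction is applied across SNPs: the method
  controls the per-test level only, by design.
* MRD treats loci as independent; its sampling band under replicate
  bulks is driven by `2n` gametes per SNP and the FIR noise propagated
  through the curve (delta method), both of which the acceptance-style
  tests check against an analytic oracle.
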