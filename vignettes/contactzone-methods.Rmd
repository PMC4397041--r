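---
title: "Methods: quantifying divergence and hybridisation in an ecotype contact zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying divergence and hybridisation in an ecotype contact zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactzone)
```

## The problem

Where divergent ecotypes of one species meet — here, freshwater-resident
and anadromous three-spined sticklebacks sharing a tidally influenced lake
system — high phenotypic diversity can arise in two very different ways:
ongoing hybridisation and introgression between the forms, or stable
reproductive isolation between several distinct populations. The two
hypotheses leave different genetic signatures. `contactzone` implements the
quantitative toolkit needed to tell them apart from codominant
microsatellite genotypes and morphological measurements: diversity and
differentiation statistics, a phenotypic-divergence estimator compared
against neutral expectation, and a simulation-based power analysis for
hybrid detection.

The `analysis/` directory runs the full workflow on data from the
package's own synthetic generator; every computational step lives in the
package and is unit-tested, so the drivers are thin narratives. The
package's functions (plus these drivers) are the interface; no shell
wrapper is shipped.

## Data model

Genotypes are diploid allele pairs at named microsatellite loci, stored
unordered (canonicalised smaller-first) with whole-genotype missingness:
a half-missing call carries no usable information for any estimator below,
so it is demoted to missing with a warning. Each locus carries an explicit
panel tag, `neutral` or `qtl` (markers physically linked to plate-number
QTL, including the major-effect *Eda* region); panel membership is never
inferred from the data. Each individual carries exactly one group label.
Because analysis groupings (for example location crossed with plate morph)
typically cut across the files genotypes arrive in, the grouping is a
first-class sidecar table rather than a property of the GenePop file; POP
blocks only provide a fallback labelling. GenePop input accepts both the
2- and 3-digit dialects; output is always 3-digit, deterministically
ordered, so that byte-identity of outputs is a meaningful reproducibility
check.

## Differentiation statistics

`wc_theta()` implements the moment estimator of F~ST~: for every allele at
every locus, among-population (*a*), among-individual (*b*) and
within-individual (*c*) variance components are formed from the group
sizes, allele frequencies and observed heterozygote proportions, using the
weighted mean frequency, the sample-size correction *n~c~* and the
frequency variance *s²*. A locus estimate is `sum(a)/sum(a+b+c)` over its
alleles, and the multi-locus estimate is the ratio of sums over all loci
and alleles — not a mean of per-locus ratios, which would weight loci
erratically. Loci monomorphic over all groups contribute a zero
denominator and are excluded with a message. Negative estimates are
reported as computed, not clamped: clamping would distort the bootstrap
distribution. The test suite checks the estimator against an independent
transcription via nested-ANOVA mean squares on 200 random instances to
1e-12.

`jost_d()` estimates actual differentiation
`D = [(H_T - H_S)/(1 - H_S)] * n/(n - 1)`. Within-group heterozygosity uses
the small-sample correction `2*nh/(2*nh - 1)` with `nh` the harmonic mean
group size, and the total heterozygosity from unweighted mean allele
frequencies carries the matching `H_S/(2*nh*n)` correction. Two multi-locus
combinations are available: averaging the H~S~ and H~T~ components across
loci before the ratio (default, the global behaviour of the standard
R implementation of this estimator) or averaging per-locus D values
(`d_combine = "mean_of_loci"`). A monomorphic locus shared by all groups is
excluded, which makes D invariant to padding the panel with uninformative
markers.

`pairwise_matrix()` computes either statistic for every unordered group
pair with a 95% percentile bootstrap CI. The default bootstrap unit is
**loci**, resampled with replacement — the standard for multi-locus
differentiation, and cheap because the per-locus components are cached
from the point estimate. Resampling individuals within groups is provided
(`boot_unit = "individuals"`) because the underlying uncertainty target is
ambiguous in much of the applied literature; loci remain the default.

Heterozygosities use the unbiased `H_E = (2n/(2n-1)) * (1 - sum(p^2))`.
Hardy–Weinberg testing exposes both readings of "exact P-values for
chi-squared goodness-of-fit tests": a plain chi-squared test (classes with
expected count below 1 pooled; df = classes − alleles) and a Monte Carlo
exact test that permutes the 2n gene copies into random diploid pairings,
with the add-one correction `p = (1 + #{chi2* >= chi2}) / (1 + n_perm)`;
the Monte Carlo version (10,000 permutations) is the default. Monomorphic
cells return p = 1 by convention. Bonferroni correction treats all tests
computed in one call as the family.

## P~ST~ and the comparison with F~ST~

Phenotypic divergence of a heritable trait (mean lateral plate number in
the motivating system) is quantified as

$$P_{ST} = \frac{\sigma^2_{GB}}{\sigma^2_{GB} + 2\,\sigma^2_{GW}}$$

with `sigma2_GB` the among-population and `sigma2_GW` the mean
within-population trait variance. The general form of this statistic
carries a `c/h^2` multiplier on the numerator; the implementation follows
the bare factor-2 form (multiplier 1) and exposes `scalar` for sensitivity
analyses. Components come from a one-way random-intercept model fitted by
REML (lme4), with boundary estimates truncated at zero and flagged. Inside
bootstraps — 1000 replicates of resampling individuals with replacement
within groups, per group pair — the method-of-moments ANOVA solution is
used instead: it equals REML for balanced designs and makes the
100-seed coverage experiments run in seconds rather than hours. Pairwise
P~ST~ refits the components on each pair alone, matching a design where
pairwise values are reported rather than a single pooled fit.

The P~ST~–F~ST~ comparison vectorises the two pairwise matrices in
matching pair order and tests the Pearson correlation with
`t = r*sqrt(df)/sqrt(1 - r^2)`, `df = npairs - 2`, treating the pairwise
values as independent observations — exactly what a reported df of 4 over
six pairs implies. This independence assumption is knowingly optimistic
(pairs share populations); the function therefore refuses fewer than four
pairs and flags |r| = 1 rather than reporting an infinite t silently.

A note on the generator-side components: the synthetic populations have
*fixed configured* trait means, so the "true" `sigma2_GB` of a scenario is
the realised variance of those configured means (denominator n−1), not a
draw from a random-effects distribution. The coverage experiments in the
tests (95% bootstrap CI covering the analytic P~ST~ in at least 85 of 100
seeds; observed around 90) are calibrated against that fixed-means truth.

## Hybrid classes, simulation and classification

Two generations after contact, an individual belongs to one of six
genotype classes — parent A, parent B, F1, F2, backcross to A, backcross
to B — each characterised by its per-locus ancestry-pair frequencies
(phi_AA, phi_AB, phi_BB): parents (1,0,0)/(0,0,1), F1 (0,1,0), F2
(1/4,1/2,1/4), backcrosses (1/2,1/2,0)/(0,1/2,1/2).

`simulate_class()` draws cohorts mechanistically rather than from the
expected class frequencies: F2 individuals are produced by mating two
independently simulated F1 parents, each transmitting one of its two
alleles chosen uniformly at every locus independently, and backcrosses
mate a simulated F1 with a parental gamete. Marginally the two approaches
coincide, but explicit mating preserves within-individual Mendelian
sampling, which is what the classifier actually confronts. Loci are
simulated unlinked, matching the classifier's independence assumption.
`simulate_cross()` repeats the design (default 30 individuals in each of
the four hybrid classes, five repeats) under per-repeat sub-seeds drawn
deterministically from one master seed, and can append the parental
individuals to each cohort.

`classify()` is a deliberately simple plug-in-frequency re-implementation
of the genotype-class idea behind Bayesian hybrid-assignment samplers: no
MCMC over allele frequencies, no uncertainty in the baselines. Baseline
frequencies are smoothed by adding a pseudo-count of 0.5 per allele of the
observed universe (union of both baselines at a locus) and renormalising,
so no genotype has zero likelihood; the per-locus class likelihood is
`phi_AA*P_AA + phi_AB*P_AB + phi_BB*P_BB` with HWE forms for P_AA/P_BB and
the cross form `p_i*q_j + p_j*q_i` for one-copy-each ancestry. Posteriors
use a uniform class prior (configurable), are stabilised by
max-subtraction, and ties break on the fixed class order PA, PB, F1, F2,
BXA, BXB. Missing loci are simply skipped per individual. This
simplification is the package's major departure from the full Bayesian
treatment and is the reason its power surface is reported on its own
terms rather than as a reproduction of any particular MCMC sampler's
accuracy figures.

`admixture_q()` is the supervised two-population analogue of a clustering
q-value: it maximises the genotype likelihood under per-copy mixture
frequencies `x = q*p + (1-q)*q_B` over q in [0,1], by golden-section
search (tolerance 1e-6) with explicit endpoint checks so that pure
individuals return exactly 0 or 1. A hand-rolled golden section is used
instead of `stats::optimize` because the latter's parabolic-interpolation
step does not guarantee the exact boundary values the purity rule relies
on. `purity_filter()` applies the q >= 0.9 rule (the threshold reported to
maximise hybrid-assignment efficiency) to pre-labelled candidate
baselines and recomputes baseline frequencies from the survivors; it
errors, advising relaxation, if a baseline would drop below two
individuals — which necessarily happens when the baselines are
undifferentiated, so the zero-divergence power runs disable the filter.

`power_analysis()` chains purify → recompute frequencies → simulate →
classify and reports per-class correct-assignment proportions averaged
across repeats, the summed confusion matrix, and a coarse
parent-vs-hybrid dichotomy accuracy, along with the realised multi-locus
theta between the purified baselines. Two caveats documented as
properties of the plug-in design: (i) parental accuracy is optimistic
because the classified parental individuals are the same ones whose
genotypes estimated the baseline frequencies; (ii) at zero divergence the
hybrid classes collapse to near-chance (1/6) while the parental classes
keep that self-assignment bias.

## Phenotype tools

Linear traits are size-corrected with a single pooled-within-group ANCOVA
slope per trait — computed from within-group-centred covariances so group
mean differences cannot masquerade as allometry — and adjusted to the
grand mean size. Plate morphs are classified from mean plate number as
low (0–9), partial (above 9, below 29) and complete (29+); the printed
class ranges in the descriptive literature overlap at 9 and 28/29, so the
boundaries here resolve 9 to `low` and 29 upward to `complete`, preserving
the canonical exemplars (partials near 10.5, completes 29–32). The three
defensive-spine lengths are summarised by a PCA on their covariance matrix
(correlation optionally), with the first axis (PC_AP) sign-fixed toward
non-negative loadings. Genotype–phenotype association uses a one-way
fixed-effects ANOVA with `R2 = SS_between/SS_total` and optional Tukey
post-hoc contrasts; the mixed-model (nested random effects) formulation
used in some field analyses is out of scope, so mixed-model R² values are
not comparable targets. `expected_complete_fraction()` generalises the
back-of-envelope HWE calculation "what fraction of this population should
express the phenotype": given an allele frequency (or one inferred from an
observed phenotype fraction under a stated dominance model) and an
explicit penetrance map over CC/CL/LL, it returns the HWE-expected
phenotype frequency. The penetrance model is an argument, never a guess.

## The synthetic generator

`simulate_three_ecotype_scenario()` emulates the statistical structure the
analysis assumes, not any particular dataset: three populations (two
freshwater-resident, one anadromous), 9 neutral loci with 6 alleles each
at Balding–Nichols `F = 0.12` (the headline neutral differentiation of the
motivating system), 4 QTL-linked loci with 2–4 alleles at `F = 0.3`
(QTL markers are markedly less variable and more differentiated than
neutral ones), and a diallelic major plate locus (allele codes 240/172,
the fragment sizes of the classic *Eda* indel marker) fixed for the C
allele in the anadromous population and for L in both residents. The
Balding–Nichols model draws each population's frequencies from a Dirichlet
with parameters `ancestral*(1-F)/F`; it was chosen over coalescent
simulation because it matches the moment structure theta estimates and
gives closed-form expectations for the recovery tests (multi-locus theta
within [0.08, 0.16] in at least 90% of seeds at F = 0.12, 200 loci,
observed 100%).

Plate phenotypes follow the major-locus genotype with Gaussian noise —
CC 31±1 (complete), LL 5±2 in resident1 (low), and in resident2 a 50:50
mixture of 7±2 and 13±3 so that low and partially plated fish coexist in
one gene pool, reflecting the inference that plate variation among
residents is driven by loci other than the major one (modelled as noise,
not as mapped modifiers). Linear traits use population means anchored on
reported body sizes (anadromous standard length 59±2 mm versus resident
39±5 mm; gill-raker lengths 0.86/0.95/1.26 mm), an allometric slope on
size, and a shared factor giving the three spines a correlation of 0.95 so
that one PCA axis dominates. What the generator does **not** emulate:
mutation processes (no stepwise-mutation model), linkage between markers,
missing-data structure beyond uniform thinning, spatial/salinity
gradients, and the sampling imbalance of real field collections
(2–40 fish per site). Passing tests therefore demonstrate estimator
correctness and pipeline power under idealised sampling, not robustness to
those field complications.

`make_power_baselines()` generates baseline pairs on a divergence ladder
(defaults: 14 loci — the full panel size — 50 individuals, F from 0.02 to
0.5) for the power analysis; realised theta tracks the target F within
±0.05.

## Numerical and design choices

* All randomised operations take an explicit seed; the same seed yields
  byte-identical output tables. Sub-seeds for repeated crosses are drawn
  from the master seed with `sample.int`.
* Problem sizes in tests and drivers (200-locus recovery runs, 1000
  bootstrap replicates, 100-seed coverage loops, 10,000-draw Mendelian
  checks) were chosen as the smallest sizes at which the binomial/Monte
  Carlo tolerances quoted above are comfortably meaningful.
* Degenerate inputs: groups untyped at a locus give empty frequency maps
  (not errors); bootstrap replicates with zero variance everywhere record
  P~ST~ = 0; degenerate (equal-bound) bootstrap CIs are reported with a
  message; a correlation over constant vectors is an error.
* Group labels in GenePop files are taken from the sidecar when given,
  else from the shared ID prefix of each POP block, else the block index.
* The chi-squared HWE df uses the class count after pooling; with heavy
  pooling the test is conservative, which is why the Monte Carlo exact
  variant is the default.

## Limitations

The classifier's plug-in frequencies ignore baseline sampling error, so
its accuracy figures are upper bounds relative to a full Bayesian
treatment at small baseline sizes; parental accuracies additionally
benefit from self-assignment. P~ST~ inference rests on the c/h² = 1
assumption — strictly, divergent selection conclusions hold only when the
among-population additive proportion is not far below the within-
population one. The pairwise-correlation test ignores the dependence
among pairs sharing a population; a Mantel-style permutation would be the
conservative alternative and the pairwise vectors are exposed so users can
run one. No linkage disequilibrium, null-allele handling or mutation
modelling is provided.
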