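---
title: "Training-set designs for genomic prediction in unreplicated testcross trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set designs for genomic prediction in unreplicated testcross trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Early stages of a hybrid maize breeding program screen large numbers of
doubled-haploid (DH) candidate lines as testcrosses: each candidate from one
heterotic pool (Flint or Dent) is crossed to an elite tester of the opposite
pool and grown in a *single plot at a single environment* (one year x
location combination). Because nothing is replicated, a candidate's
genotypic value is confounded with genotype-by-environment interaction and
plot error, and neither BLUPs nor least-squares means of genotypes are
estimable. Genomic prediction can still rank candidates, but the accuracy
depends strongly on *which* plots are used to train the marker-effect
model: plots from the same environment, from other environments of the same
year, or from previous years. `hybridcv` implements that analysis - a
two-step adjustment + two-pool marker model + eight training-set designs
evaluated by replicated cross-validation - together with a synthetic
breeding-program generator, because programs' testcross data are
proprietary and no public dataset with this structure exists.

## The model

**Step 1 - environmental adjustment.** Raw plot values follow the
fixed-effects model

$$y = \mu + q + p(q) + e,$$

with year effects $q$ and location-within-year effects $p(q)$. Because
location is nested in year and saturates the environment cells, fitted
environment means equal observed means; sum-to-zero constraints (the
package default) merely identify the decomposition. Adjusted values are

$$y^\* = y - \hat q - \hat p(q).$$

Every environment's mean of $y^\*$ equals $\hat\mu$, so downstream
*within-environment* correlations are invariant to the constraint scheme -
any other scheme changes $y^\*$ by per-environment constants only
(`fit_environment_effects(..., constraint = "reference")` demonstrates
this). Adjustment is fitted per trait, once per dataset, not inside
cross-validation folds: it estimates environment effects, which are shared
nuisance parameters, not candidate-specific information.

**Step 2 - two-pool marker model.** For hybrids with Flint-side parental
dosages $Z_f$ and Dent-side dosages $Z_d$ (rows are hybrids, columns the
kept SNPs; dosage is on the 0/1 haplotype scale for fully homozygous DH
parents),

$$y^\* = 1\beta_0 + Z_f u_f + Z_d u_d + e, \qquad
  u = (u_f, u_d) \sim N(0, \sigma^2_{TC} I).$$

Both tester/candidate orientations enter a single model: the $Z_f$ row of a
hybrid is its Flint-side parent's dosages whether that parent is the tester
or the candidate. `fit_rrblup()` estimates the variance ratio
$\lambda = \sigma^2_e/\sigma^2_{TC}$ by REML through a spectral
decomposition of the column-centred $ZZ'$ kernel restricted to the
orthogonal complement of the intercept (a one-dimensional optimisation on
the log scale, tolerance `1e-10`), then solves the mixed-model equations
exactly in the eigenbasis. Column centring is internal and undone in the
reported intercept. The same model can be fitted by Gibbs sampling
(`fit_bayes()`): Bayesian ridge (one common shrinkage variance), Bayes A
(marker-specific scaled-inverse-$\chi^2$ variances) or Bayes B (Bayes A
plus a point mass at zero with sampled inclusion probability), with
weakly-informative defaults (prior degrees of freedom 5, scales set from
the response variance with an $R^2$ heuristic of 0.5, 10,000 iterations
with 1,000 burn-in).

Design decisions worth noting:

* One common $\sigma^2_{TC}$ is shared by $u_f$ and $u_d$.
* RR-BLUP and GBLUP with $G = ZZ'/c$ give identical predictions; the test
  suite verifies the equivalence to `1e-6`.
* For Bayes B we parameterise `prob_in` = probability that a marker effect
  is *nonzero*; `prob_in = 1` reduces the sampler to Bayes A with an
  identical random-number trajectory, which the tests check draw for draw.

**Step 3 - training-set designs.** Per replication, each environment
contributes a random *complete set* of 80 hybrids, split 3:1 into a
*training set* of 60 and a *prediction set* of 20 (proportional 3:1 scaling
when an environment has fewer hybrids). The split is a pure function of
(replication seed, environment label), so all designs share identical
splits within a replication. The designs:

| design | family | training data | predicts |
|---|---|---|---|
| CV1 | across-year | complete set, same location, previous year(s) | complete set of the location |
| CV2 | across-year | all previous-year complete sets | all current-year complete sets |
| CV3 | within-environment | own training set | own prediction set |
| CV4 | within-environment | CV3 + same-location previous-year complete set(s) | own prediction set |
| CV5 | within-environment | CV3 + all previous-year complete sets | own prediction set |
| CV6 | within-year | all current-year training sets | current-year prediction sets |
| CV7 | within-year | CV6 + same-location previous-year complete set(s) | prediction set of the location |
| CV8 | within-year | CV6 + all previous-year complete sets | current-year prediction sets |

CV2, CV6 and CV8 fit one model per target year and score it per
environment. Accuracy is always the Pearson correlation of predicted vs
observed adjusted values *within one environment* (never pooled, to avoid
stratification effects); environments with fewer than three scored hybrids
or a degenerate variance yield `NA`, which summaries count as missing
rather than zero. Hybrids appearing in a prediction set are removed from
the training assembly as a leakage safeguard.

## What the generator emulates

`simulate_dataset()` draws a complete synthetic program:

* **Genome.** 10 chromosomes, lengths uniform in 200-250 cM, 461 SNPs at
  uniform random positions allocated proportionally to chromosome length
  (mean adjacent spacing ~4.7 cM). The upper half of the plausible maize
  length range is used because a ~5-6 cM mean spacing with 461 markers
  implies a ~2300-2500 cM total map.
* **Pools.** Flint and Dent founder pools with Balding-Nichols-diverged
  allele frequencies (Fst-like 0.35), so the first principal component
  separates the pools without overlap. Founders are recombinant mosaics of
  3 ancestral haplotypes per pool (Markov segment switch rate 0.06/cM):
  founders drawn in linkage equilibrium would cap within-pool $r^2$ near
  $1/n_\text{founders}$, far below observed pool LD, whereas the mosaic
  founder structure produces $r^2 \approx 0.25$-$0.3$ at 5 cM, decaying
  with map distance.
* **Lines.** 64 founders per pool; each year (breeding cycle) creates 150
  biparental families of 3 DH lines per pool, one meiosis each under the
  Haldane model (Poisson crossovers, one expected per 100 cM) followed by
  chromosome doubling - every line is fully homozygous, full-sib DH pairs
  share half their genome at loci where the cross segregates.
* **Trials.** Every location hosts one environment per year with 89-110
  candidates (two testers per environment, the minor one on ~25% of the
  candidates, as multi-tester trial sets do). The tester pool alternates
  over locations and the pattern shifts by one location each year, so both
  orientations run in parallel every year while a given location flips
  orientation between consecutive years - the rotation typical of
  testcross networks. Sib lines are dealt round-robin over a pool-year's
  environments (families are not confounded with locations). Each
  candidate is used in exactly one environment: the trial is unreplicated.
* **Phenotypes.** $y = \mu + \text{year} + \text{location(year)} +
  g_\text{main} + g_\text{year} + g_\text{env} + e$ per trait. 150 QTL per
  trait sit at *unobserved* map positions; markers tag them only through
  LD, the regime a sparse elite-program map operates in. The interaction
  terms are year- and environment-specific QTL-effect deviations - i.e.
  genetically structured. This matters: interactions drawn i.i.d. per
  (hybrid, environment) are statistically indistinguishable from plot
  error in unreplicated data and could never transfer to unseen hybrids,
  which would make all training-set designs equivalent up to training
  size. Drawn components are rescaled so realized population variances
  match the configured ones exactly.

Default variance components (plot scale):

| trait | mean | year | loc(year) | testcross | g x year | g x env | error |
|---|---|---|---|---|---|---|---|
| yield | 100 | 1.5 | 0.8 | 0.3 | 2.0 | 0.04 | 1.2 |
| moisture | 30 | 0.8 | 0.4 | 0.4 | 2.4 | 0.04 | 0.9 |

The defaults encode the regime the study's findings identify: the
across-year transferable (testcross) variance is a minor share, the
year-level genetic interaction dominates, and location-level genetic
interaction within a year is small. Under these conditions within-year
training (CV6) beats within-environment training (CV3) through sheer
training size, both beat across-year designs, strict across-year
same-location prediction (CV1) is near useless - its training set even
carries candidates of the opposite pool after the orientation rotation -
and pooling all previous-year environments (CV2) retains a modest but real
accuracy.

What passing tests on this generator do *not* show about real data: there
is no spatial field trend, no non-genetic GxE, no dominance or epistasis,
no selection across cycles, no marker ascertainment bias, and the
interaction architecture is exactly as assumed by the analysis model. The
generator demonstrates that the pipeline recovers the qualitative design
ranking when the assumed structure holds; it cannot validate the structure
itself.

## Numerical choices and degenerate inputs

* REML: eigendecomposition is exact at these sizes; the intercept
  direction is split off by shifting the kernel with the centring
  projector, so rank-deficient kernels cause no leakage between the fixed
  and random parts. `lambda = Inf` is accepted and returns the
  total-shrinkage limit (all effects zero, predictions = training mean).
* Zero-variance responses, empty matrices, markers monomorphic in a
  training set (centred column of zeros - the effect is exactly zero) and
  environments absent from adjustment estimates raise errors or are
  handled explicitly; unavailable (design, target) pairs - e.g. CV1 in the
  first year - are recorded as missing.
* Character orderings that feed random draws use radix (C-locale) sorting,
  so results are byte-identical across locales.
* Filtering order is markers first (on the raw line set), then lines (on
  the kept markers); both filters are idempotent.
* Rogers' distance uses pairwise-complete loci rather than imputed values,
  keeping the diagnostic independent of the imputation rule; for
  per-individual biallelic frequencies the per-locus distance reduces to
  `|d_a - d_b|`.
* PCA runs on centred, unscaled dosages (biallelic dosages already share a
  scale).

## Problem sizes used by the test suite

Unit tests run on miniature programs (2-3 locations, ~20 candidates per
environment). The qualitative-reproduction experiment uses 3 years x 5
environments x 100 hybrids with 461 markers, RR-BLUP and 30
cross-validation replications; the distribution-level checks (map spacing,
LD, recombination fractions) use a few thousand Monte-Carlo draws each.
These sizes were chosen so the full suite exercises every claim at
statistically meaningful resolution while remaining a routine local run.
One caveat is recorded openly: with 30 replications the per-environment
median accuracy carries a Monte-Carlo standard error of about 0.03, while
the generator's true CV6-CV3 gap averages about 0.08-0.10. The
within-year-beats-within-environment ranking is therefore asserted at the
two-decimal precision the original figures report - and even so, an
occasional environment can tie or marginally invert; the suite treats that
strictly and the maintainers' notes document the measured margins rather
than hiding them behind a looser tolerance.

## Known limitations

* The generator produces one-tester-pair-per-environment layouts with all
  locations present every year; real networks drop and add locations.
* Bayesian samplers are single-chain; convergence diagnostics beyond
  Monte-Carlo standard errors are out of scope.
* No marker-by-environment interaction terms in the *analysis* model (the
  two-step adjustment is used instead), no GCA/SCA animal models, no
  check-based across-year correction - these follow the analysis the
  package implements, which argues unbalanced testcross data cannot
  support them.
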