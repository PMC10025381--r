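# hybridcv

Genomic prediction for **unreplicated maize testcross trials**, with a
focus on how the *training-set design* — which plots you train on —
determines prediction accuracy.

Early hybrid-breeding stages test each doubled-haploid (DH) candidate as a
single testcross plot in a single environment (year × location). With no
replication, genotype is confounded with genotype-by-environment
interaction and plot error, so the usual BLUP/LSMeans adjustments are
unavailable. `hybridcv` implements the two-step analysis used in this
setting and a cross-validation engine over eight training-set designs:

1. **Adjustment** — fixed-effects model `y = μ + q + p(q) + e` (year and
   location-within-year), adjusted values `y* = y − q̂ − p̂(q)`.
2. **Two-pool marker model** — `y* = 1β₀ + Z_f u_f + Z_d u_d + e` with
   `u ~ N(0, σ²_TC I)`, where `Z_f`/`Z_d` hold the Flint-/Dent-side
   parental SNP dosages of each hybrid. Fitted by RR-BLUP (exact REML via
   spectral decomposition; equivalent to GBLUP with `G = ZZ'/c`) or by
   Gibbs sampling (Bayesian ridge, Bayes A, Bayes B).
3. **Designs CV1–CV8** — within-environment (CV3–CV5), within-year
   (CV6–CV8) and across-year (CV1, CV2) training sets built from
   per-environment 80/60/20 complete/training/prediction splits, scored by
   per-environment Pearson correlation over replicated runs.

Because programs' testcross datasets are proprietary, the package ships a
first-class synthetic generator (`simulate_dataset()`): two diverged
heterotic pools of related DH families, 461 SNPs on 10 chromosomes with
within-pool LD r² ≈ 0.3 at 5 cM, tester×candidate trial layouts, and
phenotypes with year, location, testcross, genotype-by-year and
genotype-by-environment components. Marker/line QC (expected
heterozygosity, call rates, missingness), within-pool mean imputation,
Rogers' distance, LD-decay and PCA diagnostics round out the pipeline.

## Worked example

```r
library(hybridcv)

cfg <- sim_config(n_locations = 5, candidates_per_environment = c(100, 100),
                  master_seed = 42)
ds  <- simulate_dataset(cfg)
ds
#> Synthetic testcross dataset
#>   2708 parental lines (461 markers), 1500 hybrids in 15 environments, 3000 plot records
#>   years: 1, 2, 3; traits: yield, moisture

adj <- adjust_phenotypes(ds$plots, fit_environment_effects(ds$plots))
cv  <- run_cross_validation(adj, ds$hybrids, ds$geno,
                            designs = c("CV1", "CV2", "CV3", "CV6"),
                            n_replications = 30, seed = 142)
aggregate(r ~ design + trait, cv, median)
#>   design    trait            r
#> 1    CV1 moisture  0.050370478
#> 2    CV2 moisture  0.117933680
#> 3    CV3 moisture  0.493498627
#> 4    CV6 moisture  0.544129114
#> 5    CV1    yield -0.177950150
#> 6    CV2    yield  0.007332408
#> 7    CV3    yield  0.294548859
#> 8    CV6    yield  0.379165666
```

The medians tell the study's story: training on all environments of the
current year (CV6) predicts best; training within the target environment
alone (CV3) is clearly worse; pooling all previous-year environments (CV2)
retains little accuracy; and training on the previous year of the same
location only (CV1) is useless for selection — after the tester rotation,
that training set even carries candidates of the opposite pool.
`summarize_results(cv)` gives per-environment medians and quartiles, and
`run_pipeline()` drives simulate → QC → adjust → cross-validate end-to-end
from one (optionally YAML) configuration with deterministic TSV outputs.

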