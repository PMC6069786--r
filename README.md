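# gliomaScreen

Resampling-based ("random partitioning") screening of prognostic
gene-expression markers in high-grade glioma, with the downstream survival
workflow that turns a screened gene into a clinical claim.

## The problem

Single train/test splits produce prognostic gene lists that rarely
replicate across glioma cohorts, largely because cohorts differ in size
and clinical case mix. The screen implemented here certifies robustness
directly: draw `B` random subsets of the cohort (simple random samples
without replacement, sizes uniform on `[min_size, max_size]`, by default
500 subsets of 50 up to all 424 patients), fit a univariate Cox
proportional-hazards model of overall survival on each subset, and
aggregate. For gene *g* and subset *b* the model maximises the partial
likelihood

L(β) = ∏ᵢ:δᵢ₌₁ exp(β z_gi) / Σ_{j ∈ R(tᵢ)} exp(β z_gj),

with expression standardized to SD 1 on the full cohort (hazard ratios
are per 1 SD), Efron or Breslow tie handling, and Newton–Raphson
maximisation implemented from first principles. Per gene the screen
reports the mean and median coefficient, mean and median p-value, and the
fraction of subsets significant at α = 0.05; a robust marker is one that
is significant in nearly all subsets, not merely on the full cohort.

Around the screen the package provides: Kaplan–Meier stratification at
the median (or lower tertile) of expression with log-rank testing,
multivariate Cox adjustment (mutation status, sex, age ≥ 60), treatment
and mutation-wild-type subgroup analysis, promoter methylation–expression
association (Pearson t-test and Mann–Whitney comparison), Table-1 style
cohort summaries, cross-cohort homogeneity tests, TSV loaders/writers and
a one-call pipeline. A calibrated synthetic-cohort generator (Weibull
proportional-hazards event times; exponential censoring solved to a
target censored fraction; methylation beta values calibrated to a target
correlation) makes every stage testable without consortium data.

## Worked example

```r
library(gliomaScreen)

cfg <- SimulationConfig(n_patients = 424, n_genes = 100,
                        planted_index = 17, planted_loghr = log(1.4),
                        methylation_probes = c("cg_promoter_1", "cg_promoter_2"),
                        methylation_gene = c(17, 17),
                        methylation_r = c(-0.59, -0.33), seed = 11)
gc  <- generateCohort(cfg)
scr <- genomeScreen(gc, PartitionConfig(B = 200, seed = 11))
head(as.data.frame(scr), 3)
#>    gene   hr_full       p_full  coef_mean     p_median frac_significant
#> 1 g0017 1.3468774 1.679978e-07  0.3062610 0.0001358665            0.945
#> 2 g0021 0.8947522 3.521743e-02 -0.1140419 0.0882897421            0.345
#> 3 g0020 1.1112309 4.590285e-02  0.1122065 0.1362795192            0.290
selectRobust(scr)
#> [1] "g0017"
```

The planted gene (true per-SD HR 1.4) is recovered with a full-cohort HR
of 1.35 and is significant in 94.5% of the 200 partitions; the null genes
behind it fail the stability filter even when their full-cohort p dips
below 0.05 — the point of the screen.

```r
st <- stratifiedKM(gc, gene = "g0017")
st$median_os
#>      low     high
#> 19.02462 11.86206
st$logrank
#> Log-rank test: chisq = 14.54 on 1 df, p = 0.0001374

waldSummary(multivariateOSModel(gc, "g0017"))
#>              term    coef     se    hr lower upper      z        p
#> 1      expression  0.2921 0.0562 1.339 1.200  1.50  5.199 2.01e-07
#> 2 mutation_mutant -1.1413 0.2483 0.319 0.196  0.52 -4.597 4.28e-06
#> 3        sex_male -0.0456 0.1190 0.955 0.757  1.21 -0.384 7.01e-01
#> 4   age_ge_cutoff  0.4880 0.1108 1.629 1.311  2.02  4.405 1.06e-05
```

Median overall survival is 11.9 months in the high-expression half
against 19.0 in the low half, and the expression effect survives
adjustment for the protective mutation and for age ≥ 60. The methylation
probes calibrated to r = −0.59 and −0.33 come back at exactly those
anti-correlations:

```r
as.data.frame(methylationAssociation(gc, "g0017"))[, c("probe", "n", "r",
                                    "p_pearson", "p_mannwhitney")]
#>           probe   n     r   p_pearson p_mannwhitney
#> 1 cg_promoter_1 424 -0.59 4.05942e-41  2.209118e-18
#> 2 cg_promoter_2 424 -0.33 3.14036e-12  1.839230e-06
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch under the given seed:
it simulates a 424-patient, 200-gene cohort with one planted prognostic
gene and two calibrated promoter probes, runs the partition screen, the
median-split Kaplan–Meier stratification and the methylation association,
logs the headline numbers, and writes the results JSON to `--out`.
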