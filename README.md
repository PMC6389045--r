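# methyldyn

Longitudinal analysis of smoking-associated DNA methylation on
450K-style arrays: how big is the smoking imprint at a CpG site, and how
fast does it revert after quitting?

Smoking alters blood DNA methylation at hundreds of CpG sites. A single
cross-sectional contrast of former versus never smokers cannot separate a
site that reverts quickly from one that was barely disturbed. With two
measurements per person (baseline and a ~7-year follow-up), a
random-intercept linear mixed model can: for individual *i* at visit *j*,

```
M_ij = b0 + bC*category_i + b1*age0_i + bt*t_ij + bL*category_i*t_ij
       + confounders_ij + u_i + e_ij,     u_i ~ N(0, s2_mu), e_ij ~ N(0, s2_eps)
```

where `t_ij` is years since baseline (0 at baseline), `bC` is the
*cross-sectional* coefficient (baseline M-value difference of a smoking
category versus never-smokers) and `bL` the *longitudinal* coefficient
(difference in change per year). Former smokers are binned into 7
time-since-quitting (TSQ) categories with sample-size-matched breakpoints;
continuing smokers get their own model, plus an intensity-versus-duration
variant. The package is aimed at epigenetic epidemiologists who want the
full pipeline — array-style filtering, quantile normalization, beta→M
transform, control-probe principal-component technical adjustment, an
EWAS gate with Bonferroni correction, from-scratch REML fitting with
Satterthwaite p-values, and fine-scale reversion statistics — as tested,
composable R functions. A seeded synthetic cohort generator stands in for
individual-level cohort data, which are not redistributable.

## Worked example

```r
library(methyldyn)

cfg    <- sim_config(n_individuals = 300, n_sites = 400,
                     n_affected_sites = 20, seed = 42)
cohort <- simulate_cohort(cfg)
prep   <- preprocess_pipeline(cohort$data)
prep$data
#> methylation_set: 385 sites x 600 samples [scale: M_adjusted]
#>   visits: F4=300, S4=300
#>   control probes: 100
#>   missing entries: 692

traj <- derive_trajectories(cohort$phenos)
table(traj$trajectory)
#> CS-CS CS-FS FS-FS NS-NS
#>    49    13   100   138

ewas <- run_ewas(prep$data, cohort$phenos)
sprintf("EWAS: %d of %d sites significant at %.3g",
        sum(ewas$significant), attr(ewas, "m"), attr(ewas, "threshold"))
#> "EWAS: 20 of 385 sites significant at 0.00013"

sites <- ewas$site_id[ewas$significant]
tsq   <- run_tsq_model(prep$data, cohort$phenos, traj,
                       sites = sites, ewas = ewas)
t1 <- tsq[tsq$category == "TSQ1", ]
head(t1[, c("site_id", "beta_C", "beta_L", "p_L")], 4)
#>       site_id beta_C    beta_L    p_L
#> 1  cg00000002 -1.091  0.052629 0.0819
#> 8  cg00000005  0.537  0.055040 0.0745
#> 15 cg00000010  0.739  0.026230 0.3709
#> 22 cg00000014  0.680 -0.000103 0.9975

cr <- coefficient_correlation(t1$beta_C, t1$beta_L)
sprintf("TSQ category 1: Spearman rho = %.2f (p = %.2g, n = %d)",
        cr$rho, cr$p, cr$n)
#> "TSQ category 1: Spearman rho = -0.70 (p = 0.00065, n = 20)"
```

Reading the output: the EWAS found all 20 planted smoking-affected sites
(and nothing else) at the Bonferroni threshold 0.05/385. In the earliest
TSQ category (quit 0–4 years before follow-up) the longitudinal
coefficients oppose the cross-sectional ones — sites below never-smoker
levels at baseline are climbing back, at a rate proportional to how far
away they started. The strong negative rank correlation (ρ = −0.70) is
the signature of exponential-decay-like reversion.

`run_pipeline()` chains all stages and writes every table plus a JSON run
manifest; `render_report()` turns a run into a Markdown report with the
coefficient tables, the median-change heat-map data, and the dynamism
IQR / consistency curves. A thin command-line wrapper lives at
`inst/cli/methyldyn.R`.

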