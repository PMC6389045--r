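---
title: "Modeling smoking-associated DNA methylation dynamics across two visits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling smoking-associated DNA methylation dynamics across two visits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methyldyn)
```

## The scientific problem

Cigarette smoking leaves a broad, reproducible imprint on blood DNA
methylation. After cessation, many of the affected CpG sites drift back
toward never-smoker levels, some within a few years, others over decades.
Quantifying that reversion needs repeated measurements of the same people:
a cross-sectional contrast of former versus never smokers confounds the
rate of change with the initial size of the disturbance. `methyldyn`
implements a two-visit (baseline and ~7-years-later follow-up) analysis of
array-style methylation data that separates the two: a *cross-sectional*
coefficient for how different a smoking group was at baseline, and a
*longitudinal* coefficient for how fast that difference changes per year.

## The model

Methylation is assayed as a beta-value $\beta \in (0,1)$ and analyzed on
the M-value scale, $M = \log_2(\beta/(1-\beta))$, which unbounds the
response and stabilizes variance for regression. For each CpG site, with
individual $i$ observed at visit $j$:

$$
M_{ij} = \beta_0 + \beta_C\,\mathrm{cat}_i + \beta_1\,\mathrm{age0}_i
       + \beta_t\, t_{ij} + \beta_L\,\mathrm{cat}_i \times t_{ij}
       + \mathbf{x}_{ij}'\boldsymbol\gamma + \mu_{0i} + \varepsilon_{ij},
$$

with $\mu_{0i} \sim N(0, \sigma^2_\mu)$ a per-individual random intercept,
$\varepsilon_{ij} \sim N(0, \sigma^2_\varepsilon)$, $t_{ij}$ the
time-passed variable (0 at baseline, the years between interviews at
follow-up), $\mathrm{age0}_i$ the age at baseline, and $\mathbf{x}_{ij}$
the confounders: sex, alcohol (g/day), BMI, white-cell count and five
estimated cell-type proportions. $\beta_C$ is the expected baseline
difference of a smoking category versus the never-smoking reference;
$\beta_L$ the expected difference in change per year. One shared
time-slope $\beta_t$ is fitted for the reference, with the category
interactions as deviations from it — the literal reading of the displayed
model; an alternative with per-category slopes would be an equivalent
re-parameterization of the same fit.

Smoking categories are *trajectories* over the two visits: `NS-NS` (never
smoker at both) is always the reference; former smokers (`CS-FS`, `FS-FS`)
enter the time-since-quitting (TSQ) model binned into 7 sample-size-matched
TSQ categories; `CS-CS` enters the continued-smoking model; and the
intensity-versus-duration model regresses the `CS-CS` observations on
cigarettes/day and years smoked instead of category indicators.

### Estimation

The random-intercept model is estimated by restricted maximum likelihood.
The marginal covariance is $\sigma^2_\varepsilon (I + \lambda ZZ')$ with
$\lambda = \sigma^2_\mu/\sigma^2_\varepsilon$, block-diagonal by
individual, so generalized least squares reduces to ordinary least squares
after a per-group whitening ($y \mapsto y - d_g \bar y_g$ with
$d_g = 1 - 1/\sqrt{1+\lambda n_g}$). The restricted likelihood is profiled
over $\lambda$ ($\sigma^2_\varepsilon$ has a closed form at each
$\lambda$) and maximized on $\log\lambda \in [-12, 12]$ by a 49-point grid
scan refined with Brent's method; the $\lambda \to 0$ boundary (plain OLS)
is evaluated explicitly and wins ties. This derivative-free scheme is
reproducible and robust to the flat likelihoods two-observation groups can
produce. The test suite verifies the maximized restricted likelihood
against an independent dense-matrix Nelder–Mead optimizer over
$(\sigma^2_\mu, \sigma^2_\varepsilon)$ to $10^{-6}$, and against
`lmerTest` on a reference dataset.

P-values use a $t$ distribution with Satterthwaite degrees of freedom:
$\nu_k = 2 c_k^2 / (\mathbf{g}' A \mathbf{g})$, where $c_k$ is the
coefficient variance, $\mathbf{g}$ its finite-difference gradient in the
variance components and $A$ the inverse negative Hessian of the restricted
log-likelihood. At the $\sigma^2_\mu = 0$ boundary the OLS residual df is
used; undefined df fall back to the normal approximation with a warning.

### Multiple testing

All thresholds are Bonferroni, $\alpha/m$, with $m$ always recomputed from
the data at hand: the genome-wide EWAS uses $m$ = sites tested, and every
downstream model uses $m$ = the number of sites the EWAS carried forward —
never a hard-coded count.

## Preprocessing

Stage order is fixed and tagged on the data container so re-running on
processed input is refused:

1. SNP marker probes removed.
2. Entries set missing when detection $p \ge 0.01$ (inclusive) or bead
   count $\le 3$; samples dropped when their non-missing fraction is
   $\le 0.95$ (inclusive).
3. Quantile normalization across samples: each sample's sorted vector is
   mapped to the across-sample mean of sorted vectors; ties receive the
   mean reference value over their rank span; missing entries are excluded
   from the reference and restored as missing.
4. Sites removed if annotated to chromosome X/Y, or if their non-missing
   rate falls below 95% within *either* visit.
5. Beta to M transform.
6. Technical adjustment: principal components of the control-probe
   intensity matrix (probes mean-centered, unscaled; each component's sign
   fixed by making its largest-magnitude loading positive, for
   reproducibility) are computed sample-wise, and each site's M-values are
   replaced by residuals on an intercept, the first 20 components and a
   categorical batch indicator. Background correction is reduced to an
   optional fixed-offset subtraction: the synthetic generator does not
   model fluorescence backgrounds, so there is nothing for a
   chemistry-aware correction to estimate.

Outlier removal is per analysis, per site: OLS residuals on the pooled
(both-visit) confounder design including the time-passed variable;
entries beyond 5 residual SD are masked, at most 5 per site, largest
first, in a single pass without refitting (the residual SD uses
denominator $n - \mathrm{rank}$). The pooled design is one of two
defensible readings of the procedure; the cross-sectional alternative
differs only in replacing (age0, time) by interview age.

For the beta-scale dynamics analyses, adjusted M-values are mapped back to
beta and residualized per site on the full confounder design
("confounder residualization"); observations with incomplete covariates
are excluded and returned as missing.

## Phenotype rules

Current smokers include occasional smokers (at most 1 cigarette/day),
whose intensity is recorded as 0.5 cigarettes/day. TSQ is interview age
minus cessation age; duration is initiation to interview (CS) or to
cessation (FS). Former smokers are excluded when TSQ is missing, when the
follow-up TSQ deviates from the baseline report advanced by the visit gap
by *both* more than 20% and more than 5 years (the conjunctive reading of
the rule; a disjunctive flag exists for sensitivity analysis), or on a
quit–restart–requit history between visits. A TSQ of exactly 0 is
arithmetically valid but not categorizable, since observed TSQ is strictly
positive.

TSQ categories sit on integer-year boundaries, half-open $(lo, hi]$, with
reported years rounded half-up. The default "matched" mode chooses
boundaries greedily to equalize category counts (ties toward the earlier
boundary). Fixed mode defaults to $(0,4], (4,14], (14,21], (21,27]$ for
the first four categories — the documented category bounds — with the
remaining three boundaries ($27, 35, 45, \infty$) configurable
placeholders, not published values; matched mode is used wherever results
are computed.

## Dynamics statistics

On residualized beta-values: the per-individual change (follow-up minus
baseline) is computed per site, former smokers are binned by TSQ at
follow-up into half-open 2-year bins (or the TSQ categories), and each
site's median change per bin is summarized two ways: the across-site
interquartile range per bin ("dynamism", type-7 linear-interpolation
quantiles; bins with fewer than 4 sites return `NA`) and the fraction of
sites whose median change opposes the site's EWAS coefficient sign
("consistency", i.e. reverting toward never-smoker levels; exact-zero
medians are excluded since sign(0) is undefined). `NS-NS` and `CS-CS`
reference bins are computed alongside. Spearman correlations between
cross-sectional and longitudinal coefficients use mid-ranks and a
two-sided $t$-approximation p-value. Continued-smoking sites are labelled
diverging/converging by whether the absolute CS–NS median gap grows or
shrinks from baseline to follow-up; exact ties are labelled converging and
flagged.

One occupancy caveat: a per-site median over a handful of individuals is
noise-dominated, and the across-site IQR of such medians measures bin
sparsity rather than biology. When the package reports *where* dynamism
peaks, it therefore reads the peak off bins holding at least 10
individuals; the medians of all bins are still reported.

## The synthetic cohort generator

No individual-level cohort data are redistributable, so every analysis in
the package is exercised on a seeded generator that emulates the study's
structure. Its defaults are fixed choices, not fitted estimates:

- Baseline status proportions 280/449/615 (CS/FS/NS of 1344) — the
  reported cohort composition; visit gap uniform on $7 \pm 0.5$ years;
  current smokers quit at 4%/year between visits.
- Covariates loosely match the reported cohort: age $N(55, 9)$, BMI
  $N(27.5, 4.5)$, alcohol half-normal with scale 20 g/day, WBC
  $N(6, 1.5)$, cell proportions near typical blood fractions with a
  granulocyte remainder.
- Smoking effects: per-site $\delta_s$ on the M scale, magnitude
  $U(0.5, 1.5)$ with random sign at 50 of 1000 sites by default. Current
  smokers carry $\delta_s (1 + 0.01\,(\text{cigs} - 15))$ — linear in
  intensity, matching the linear intensity model; saturation at high
  intensity is deliberately not modeled. Former smokers carry
  $\delta_s e^{-\mathrm{TSQ}/\tau}$ at reversible sites (80% of affected
  sites) and the full $\delta_s$ at persistent ones. The exponential form
  is the simplest model consistent with a negative cross-sectional/
  longitudinal coefficient correlation; $\tau = 10$ years places peak
  reversion dynamism within the first two decades after quitting. The
  true per-site effect-size distribution is unknown — this is a free
  parameter of the generator, not an estimate.
- The random intercept is drawn per (site, individual) with SD
  $\sigma_\mu = 0.5$ M-units ($\sigma_\varepsilon = 0.5$ as well). A
  single per-individual shift shared across all sites would be a column
  shift, which quantile normalization removes exactly; the within-person
  stability the mixed model captures is a per-site quantity, so that is
  what the generator plants.
- Batch structure: each batch has a scalar score; control probes carry an
  additive probe-loading × score shift, and each site's M-values carry a
  matching per-site batch coefficient (SD 0.2 M-units) whenever batch
  shifts are enabled — so the control probes genuinely proxy a technical
  effect that is present in the methylation values, which is what the
  PC adjustment is for.
- Detection failures ($p \ge 0.01$), low bead counts and $\ge 6$-SD
  outliers are planted at configurable rates; a small fraction of former
  smokers receives inconsistent TSQ reports or restart histories to
  exercise the exclusion rules.

What the generator does **not** emulate — and hence what passing tests do
not establish about real arrays: Type I/II probe chemistry and
fluorescence background, spatial/genomic correlation between neighboring
CpGs, the real effect-size distribution, cell-composition shifts caused by
smoking itself (proportions are independent covariates here), and
nonlinear intensity saturation. Results on the generator validate the
*machinery* (estimators, filters, thresholds, summaries), not
cohort-specific effect magnitudes.

## Problem sizes

The default demonstration cohort is 600 individuals × 1000 sites with 50
affected sites — large enough that the EWAS gate, the mixed models and the
binned dynamics all operate in their intended regime, small enough to run
interactively. The test suite uses the same scale for single-cohort
properties and smaller cohorts (120–250 individuals, 50–150 sites) for
replicated calibration loops; the type-I calibration suite accumulates
1000 null site-fits and checks the rejection rate at $\alpha = 0.05$
against $[0.035, 0.065]$.

## Known limitations

- Only a random intercept is supported — no random slopes or richer
  covariance structures, and no GEE alternative.
- The intensity model is linear; heavy-smoker saturation would bias
  per-cigarette effects toward zero in real data.
- TSQ category boundaries beyond category 4 in fixed mode are
  placeholders; matched mode should be used for inference.
- The reversion timescale $\tau$ is shared across sites (an optional
  per-site multiplier exists in the generator); per-site decay-rate
  estimation is out of scope.
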