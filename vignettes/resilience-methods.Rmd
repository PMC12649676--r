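---
title: "Resilience indicators from feeder data: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resilience indicators from feeder data: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`resilio` computes deviation-based resilience indicators from automated
feeder (FIRE-type) visit logs of growing pigs, estimates their genetic
parameters under an animal model, and runs a univariate mixed-model GWAS.
This vignette is the package's account of the underlying models, the
parameters that matter, the numerical machinery, and the choices made where
the methodology left genuine freedom.

## From visits to daily series: the QC chain

Each feeder visit carries start/end timestamps (1 s), initial and final
trough weights (1 g) and a body weight (0.1 kg). `qc_feeder()` applies, in
this order:

1. **Aggregation** (`aggregate_daily`): per calendar day, feed intake is the
   sum of (initial − final) trough weights in kg, feeding duration the sum
   of visit durations in minutes, body weight the day's median of visit
   weights; age is date minus birth date. A day with no visits yields *no*
   record — gaps are never fabricated. Visits with negative consumption
   (scale noise, double-tagging) are flagged and excluded from the intake
   sum; their duration still counts, since occupancy is measured by the
   clock, not the scale.
2. **Sparse-animal exclusion** (`exclude_sparse`): animals with fewer than
   60 daily records are dropped (boundary inclusive: exactly 60 stays).
3. **Outlier masking** (`mask_outliers`): daily intake and duration values
   strictly above the animal's own mean + 4 SD are set to missing, keeping
   the pre-masking value. Two deliberate readings: the rule is **one-sided**
   (only the upper tail), because low values are the biological fasting
   signal the resilience traits exist to measure; and mean/SD are
   **per-animal**, because population-level masking would erase exactly the
   between-animal variability that is the phenotype. Both are configurable.
4. **Imputation** (`impute_rolling`): an isolated missing value becomes the
   mean of available days in a centred 5-day window (shrinking at the
   edges; the direction of a rolling average is a convention — centred
   here). For
   **runs of two or more consecutive missing days the pre-masking values
   are restored** — the only "original value" that exists for a masked day
   is the value before masking. Calendar gaps are not missing *records* and
   are never imputed.
5. **Age window** (`window_age`): only ages 90–150 d (closed interval) are
   kept, and the 60-record minimum is re-checked afterwards. Whether the
   minimum applies before or after windowing is ambiguous; the chain
   applies it both times and logs both counts.

The chain is idempotent, and every exclusion appears in the report
(`animals_in = animals_out + animals_excluded` per rule), mirroring the
accounting style of production QC pipelines.

## The six resilience indicators

For one animal with in-window daily values $y_t$ at ages $t$:

- **RMSE_FI / RMSE_FD**: fit $y_t = a + b\,t$ by OLS;
  $\mathrm{RMSE} = \sqrt{\tfrac1n \sum_t \hat e_t^2}$. The divisor is $n$
  (the literal root of the mean squared residual), not $n-2$; at $n \ge 60$
  the distinction cannot reorder animals, and the divisor is configurable.
- **RMSE_CFI / RMSE_CFD**: the same statistic applied to the cumulative sum
  of the daily values, restarted at the window start (carrying pre-window
  intake would mix in unobserved history). The baseline is the animal's own
  OLS line of the cumulative curve on age — cumulative intake is nearly
  linear in healthy animals, and illness dips flatten it.
- **QR_FI / QR_FD**: a single **population-level** quantile-regression line
  at $\tau = 0.05$ is fitted to the pooled animal-day panel per trait;
  an animal's indicator is the percentage of its days strictly below the
  line (strict inequality: a day exactly on the threshold does not count
  as fasting). Expressed in percent: at $\tau = 0.05$ the cohort mean is
  forced to ≈ 5.00 by quantile coverage. A per-breed line is available for
  sensitivity analysis but is off by default, since the threshold is
  explicitly population-level.

### Quantile regression solver

The line minimises the pinball loss
$\sum_i \rho_\tau(y_i - b_0 - b_1 x_i)$. This is a linear program whose
basic optimal solutions pass through two data points. The solver runs
iteratively reweighted least squares on a smoothed loss to get close, then
polishes exactly: it enumerates candidate lines through pairs of the 40
near-active points and keeps the smallest exact loss. On desk-scale data
this provably reaches the LP optimum (verified against full
pair-enumeration in the tests); at panel scale (tens of thousands of
points) the active set is far smaller than 40, so the polish is exact there
too. The fitted line satisfies the standard coverage bounds
(#strictly below)/N ≤ τ ≤ (#below or equal)/N.

## Production traits

ADG is the weight difference between the extreme in-window ages divided by
the age span. The 100-kg adjustments are

$$\mathrm{AGE}_{100} = \mathrm{age} + (W-100)\,\frac{\mathrm{age}-A}{W},
\qquad
\mathrm{BF}_{100} = \mathrm{bf} + (W-100)\,\frac{\mathrm{bf}}{W-B},$$

the standard swine performance-test adjustments. Both are the identity at
$W = 100$ for any coefficients — a fixed point the tests pin down. Because
the NSIF convention writes the deviation as $(100-W)$, the sign convention
is switchable. The breed- and sex-specific coefficients $A$ (days) and $B$
(kg) are population-specific and should be supplied by the caller; the
defaults ($A = 50.775$, $B = 0$) are placeholders — no validated quantity
depends on them. The measurement used
for adjustment is the last in-window weighing.

RFI is the residual of the cohort OLS regression of ADFI on ADG and MBW
(mid-window body weight, linearly interpolated, to the 0.75 power). The
regression includes an intercept: textbook definitions sometimes omit one,
but a cohort-mean RFI of exactly 0 — the defining property of the trait —
requires an intercept or centred predictors (the two give identical
residuals; both modes are provided).

## Genetic parameters: the animal model

For trait $y$: fixed effects pen×batch, breed and sex; random additive
genetic effect $a \sim N(0, \sigma_a^2 K)$ with $K$ either the pedigree
numerator matrix (Henderson's tabular method) or the VanRaden GRM; random
litter effect; residual. Heritability is
$h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_{litter}^2 + \sigma_e^2)$.

`reml_fit()` maximises the restricted likelihood by **average-information
REML**: AI updates with step halving, falling back to the EM fixed point
(which cannot leave the parameter space) when an AI step fails or the
likelihood would drop. Components are constrained non-negative with a floor
of $10^{-6}\,\mathrm{var}(y)$; a component pinned at the floor with a
negative gradient is treated as a boundary solution and removed from the AI
system (otherwise the free components crawl in ever-smaller steps and the
iteration stalls). Convergence requires a restricted-log-likelihood change
below $10^{-8}$ or a free-gradient norm below $10^{-6}$; non-convergence is
an error carrying the likelihood trajectory. Standard errors of $h^2$ come
from the delta method on the inverse AI matrix, the conventional choice.

Genetic correlations use a bivariate animal model over 2×2 additive,
litter and residual covariance blocks,
$r_g = \sigma_{a,12}/\sqrt{\sigma_{a,1}^2\sigma_{a,2}^2}$ clamped to
$[-1, 1]$. Updates that leave the PSD cone are projected back by eigenvalue
clipping (counted and reported). The bivariate fixed-effect structure is
identical to the single-trait model.

## GWAS

The association model is $y = W\alpha + x\beta + u + \varepsilon$ with
$u \sim MVN(0, \lambda\tau^{-1}K)$, $\varepsilon \sim MVN(0, \tau^{-1}I)$.
Covariates follow the GWAS model — intercept, birth year–season, breed and
the top five GRM eigenvectors — deliberately *not* the pen×batch/litter
model used for parameter estimation: the two stages use different models
and that separation is preserved. "Season" is coded as calendar quarter
(year×quarter factor); the coding is configurable.

$K$ is eigendecomposed once; for each SNP the variance ratio $\lambda$ is
re-estimated by profiling the restricted likelihood over
$\log_{10}\lambda \in [-5, 5]$ (coarse grid, then Brent refinement) — the
GEMMA's per-SNP REML convention; a faster mode
fixes $\lambda$ from the covariate-only model (EMMAX-style). Effects are
tested with a Wald chi-square on 1 df only (score/LRT omitted, matching the
reference default). Monomorphic SNPs are flagged with $\beta = 0$,
$p = 1$. Diagnostics: genomic inflation
$\lambda_{gc} = \mathrm{median}(\chi^2_{obs})/0.4549$, and the significance
threshold $P = \mathrm{FDR} \times n/m$ with $n$ the count of p-values
below 0.001 and $m$ the SNP total — a proportional rule, deliberately kept
distinct from Benjamini–Hochberg; a BH option exists for comparison but is
never the default. Genotype QC before the scan: individual call rate
≥ 0.95, SNP call rate ≥ 0.90, MAF > 0.05, HWE chi-square $p \ge 10^{-6}$
(1 df, no mid-p correction — at the $10^{-6}$ threshold and hundreds of
animals the exact test would change nothing), autosomes only.

## The synthetic-data generator

The generator exists so that every stage is testable with known ground
truth. What it emulates:

- **Trajectories**: daily feed intake and feeding duration linear in age
  (ADFI ≈ 2.5 kg, ADFD ≈ 56 min at mid-test), body weight linear with
  ADG ≈ 1.05 kg/d — matching the observed near-linearity over 90–150 d.
- **Resilience as heritable variability**: each animal carries a latent
  score $s = a + l + \epsilon$ (additive, litter, environment; variance
  fractions `h2_resilience`, `litter_var_frac`, remainder; total SD 0.30)
  and its day-to-day residual SD scales as $\mathrm{SD}_0 e^{s}$. The
  log-linear link makes RMSE-type traits heritable by construction, which
  is the premise of the whole analysis. The additive part is the sum of a
  causal-SNP component and a pedigree polygenic flow, rescaled to the
  *within-breed* variance target because the animal model treats breed as
  fixed.
- **Illness**: episodes start with per-day probability `illness_rate`
  (default 0.01), last 1 + Geometric(0.5) days, and multiply intake and
  duration by `1 − illness_depth` (default depth 0.6) — producing the
  multi-day dips that flatten cumulative curves.
- **Visits**: each daily total is split over 1–12 visits by a symmetric
  Dirichlet draw, with largest-remainder rounding so grams sum *exactly* to
  the daily total (the 1-g feeder resolution); the analysis never uses
  within-day structure beyond summation, so no richer visit model is
  warranted — the visit layer is a stand-in, not an inference target.
- **Population structure**: three breeds with Balding–Nichols founder
  allele frequencies (Fst 0.15, ancestral MAF in [0.05, 0.5]), Mendelian
  gamete transmission to offspring, litters of ~10 with **two parities per
  dam** — full sibs across parities share dam genetics but not litter
  environment, which is what identifies the litter variance separately from
  the additive variance in real nucleus herds, and here.

What it does **not** emulate: linkage disequilibrium (SNPs are independent
given ancestry), seasonal/temperature covariates, feeder hardware failure
modes beyond additive noise, selection, or genotype imputation errors.
Passing tests therefore demonstrate correctness of the *computations* under
a faithful but idealised data-generating process; they do not certify
behaviour under LD-driven confounding or structured missingness.

A single seed controls everything; stage substreams are derived from it
deterministically, and a rerun with the same configuration is bit-identical.

## Validation suite and problem sizes

The tests validate each computation against an independent oracle at desk
scale: quantile lines against full pair enumeration (≤ 12 points), the
pedigree matrix against the recursive definition (≤ 8 animals, random
pedigrees), REML against a dense grid search (n = 30), and the LMM scan
against explicit-inverse GLS (n ≤ 50, tolerance $10^{-6}$). Parameter
recovery uses n = 2000 (10 replicates) for $h^2 = 0.25$ (recovered within
±0.08), n = 2000 for $r_g = 0.5$ (±0.15), and n = 500 with m = 5000 SNPs
for null-GWAS calibration ($\lambda_{gc} \in [0.9, 1.1]$). These sizes were
chosen so the whole suite validates the estimators' sampling behaviour in
minutes on a single core while keeping standard errors small relative to
the recovery bands.

## Known limitations

- The bivariate REML is dense ($O((2n)^3)$ per iteration); cohorts beyond a
  few thousand animals would want the eigendecomposition shortcut that the
  univariate scan already uses (possible when litter is omitted).
- Boundary SEs: when a variance component sits at its floor the delta-method
  SE of $h^2$ (or $r_g$) is only indicative; profile-likelihood intervals
  are not implemented.
- The 100-kg adjustment coefficients ship as placeholders (see above).
- The FDR-proportional threshold has an inherent quirk: with no p-value
  below 0.001 the threshold is 0 and nothing is significant (a warning is
  raised).
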