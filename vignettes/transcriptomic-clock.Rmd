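---
title: "Transcriptomic aging clocks and exposure-induced age acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic aging clocks and exposure-induced age acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txclock)
```

`txclock` asks whether an inhalation exposure makes lung tissue look
transcriptionally older than it is. This vignette explains the models
behind each stage, the parameters that matter, what the built-in
simulator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The statistical model, stage by stage

### Differential expression

For a two-group contrast with groups of sizes $n_a$ and $n_b$, the
per-gene fold change is the difference of group means on the log2 scale,
$\mathrm{fc}_g = \bar x_{ga} - \bar x_{gb}$, with a pooled variance
$s_g^2$ on $d_g = n_a + n_b - 2$ degrees of freedom. Orientation is
fixed — oldest minus youngest for age contrasts, treated minus control
for exposure contrasts — and never inferred from the data.

With empirical-Bayes moderation (the default), per-gene variances are
shrunk toward a common prior: assuming
$s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_{d_g}/d_g$ and
$1/\sigma_g^2 \sim \chi^2_{d_0} / (d_0 s_0^2)$, the posterior variance
is $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the
moderated $t = \mathrm{fc}_g / \sqrt{\tilde s_g^2 (1/n_a + 1/n_b)}$
gains $d_0$ degrees of freedom. The hyperparameters $(d_0, s_0^2)$ are
estimated by the method of moments on $\log s_g^2$, using the exact mean
and variance of log-chi-square variables (digamma/trigamma, with a
Newton solve of the trigamma inverse). When the spread of log variances
does not exceed chi-square sampling noise the prior degrees of freedom
are infinite and every gene is tested against the average variance. The
test suite cross-checks both branches against limma on random data;
moderation is computed **per contrast** (whether the original analyses
moderated across all arrays jointly is unknowable from the outside; the
per-contrast choice keeps each contrast self-contained, and the
alternative would only increase shrinkage).

Benjamini–Hochberg adjustment is implemented directly from the step-up
definition $q_{(i)} = \min_{j \ge i} p_{(j)} \, n / j$, capped at 1, and
is verified against a brute-force oracle and `stats::p.adjust`.

A gene is *regulated* when $|\mathrm{fc}| > \log_2 1.5$ **and**
$\mathrm{FDR} < 0.05$ in at least one contributing contrast. The
fold-change criterion is applied two-sided: down-regulation counts.
Genes constitutively absent or knocked out in some underlying studies
(the `excluded_genes` argument, e.g. an ApoE knockout) are removed from
the entire analysis. Genes with zero variance in both groups get
$t = 0, p = 1$ (flagged, never `NaN`) so set operations stay total.

### Overlap analysis

Three views of the age-by-exposure interaction:

* **Venn counts** between the two regulated sets; the overlap percentage
  is reported relative to the *age* set, because the scientific question
  is "what share of aging-related genes does the exposure perturb?".
* **Signed maximum fold change**: per gene, the log2 fold change of
  largest absolute value across contrasts, sign retained (a plain
  maximum would hide down-regulation). Ties break toward the
  lexicographically earlier contrast id, making the statistic
  permutation-invariant up to a documented rule.
* **PC1 loadings**: the fold-change profile (genes × contrasts) is
  column-centered — each contrast is an observation of per-gene change,
  so centering per contrast keeps loadings per gene — and decomposed by
  SVD. Loadings are the unit-norm first left singular vector; *inertia*
  is $100\,\lambda_1/\sum_k \lambda_k$. Columns are **not** scaled to
  unit variance by default (contrasts share the log2-FC unit, and
  scaling would up-weight noisy contrasts); `pc1_loadings()` operates on
  whatever profile it is given, so callers wanting scaling can scale
  first. The loading sign is chosen so that the correlation with the
  gene-wise mean fold-change profile is non-negative: each profile is
  oriented by its own average direction of change, which makes the
  *comparison* of two profiles (the Pearson correlation of their
  loadings) invariant to jointly flipping the sign of all inputs.
  Consequence: negating one profile's inputs negates its reported
  loadings — the convention tracks the data's direction rather than
  hiding it.

### The clock

The age predictor is deliberately the simplest model that can read an
effective-age signal: linear in log2 expression and sparse.

1. Genes are standardized (mean 0, scale 1 with the population $1/n$
   convention) **inside selection only**.
2. The LASSO path minimizes
   $\tfrac{1}{2n}\lVert y - X\beta\rVert^2 + \lambda \lVert\beta\rVert_1$
   by cyclic coordinate descent with soft-thresholding and active-set
   iteration, warm-started along a grid of 100 log-spaced values from
   $\lambda_{\max} = \max_g |\langle \tilde x_g, \tilde y\rangle|/n$
   down to $10^{-3}\lambda_{\max}$.
3. $\lambda$ is chosen at the minimum mean validation MSE over seeded
   5-fold cross-validation (standardization re-estimated within each
   training fold). Exact ties go to the larger, sparser $\lambda$. The
   minimum-MSE rule (not the one-standard-error rule) is used because
   the clock's purpose is accurate point prediction of age, not maximal
   sparsity.
4. The genes with nonzero coefficients at $\lambda_{\min}$ are refit by
   ordinary least squares on the **raw** log2 scale, so coefficients are
   interpretable as months per log2 unit and predictions need no
   standardization parameters.

Predictions are `intercept + sum(coef * x)`. Ages are real-valued
months throughout — the clock predicts *absolute* age (animals enter the
studies at 2 months, so predicted age = 2 + predicted exposure time for
the designs simulated here), and cessation time points may be
fractional. Model genes missing from a new platform are imputed at
their training mean up to a configurable 20% of the predictor set
(beyond that, an error listing the genes); the training means are stored
in the model JSON, which carries a schema version tag and round-trips
exactly.

### Delta age and group inference

Delta age = predicted − chronological age, pooled per exposure group
(a per-time-point breakdown is also emitted, since pooling hides the
trajectory of cessation arms). Each group is compared to sham with
Welch's unequal-variance t-test — group residual variances have no
reason to be equal once an exposure perturbs part of the predictor set —
alongside a classical one-way ANOVA across all groups (which, for two
groups, reproduces the squared pooled t exactly; the suite asserts
this). Stars follow the usual thresholds (\*\*\*\* $p<10^{-4}$ … `.`
$p<0.1$, `ns` otherwise). No multiplicity correction is applied across
the handful of group comparisons: each is reported per-comparison, as is
conventional for these figures, and the number of arms is small and
fixed by design rather than data-driven.

### Validation designs

* `random_holdout_cv()`: 100 runs of a 75/25 split **stratified by
  study** (so no run accidentally trains on a single study), clock refit
  per run, MAE on both partitions; the pooled MAE is defined as the mean
  of per-run validation MAEs. Degenerate runs (fewer than two distinct
  training ages) are skipped, warned about, and *recorded* — never
  silently dropped from the denominator.
* `leave_one_study_out_cv()`: one round per study. Because batch
  offsets are per study, the held-out study's shift is never seen in
  training, so LOSO MAE is expected to exceed holdout MAE — the suite
  checks this as a median over seeds.

## The simulator

`generate_dataset()` draws
$$x_{gs} = b_g + m_g f(\mathrm{age}_s + \Delta_s) + \mathrm{step}_g e_s
          + u_{g,\mathrm{study}(s)} + \varepsilon_{gs},
  \qquad \varepsilon \sim N(0, \sigma^2),$$
with $f$ linear (default) or saturating
($f(a) = \tau(1 - e^{-a/\tau})$), per-gene per-study batch offsets
$u \sim N(0, \mathrm{batch\_sd}^2)$, and a planted acceleration
$\Delta_s$: the full `exposure_shift_months` (default 2) for
continuously smoke-exposed samples, 0 for sham, a configurable fraction
(default 0) for heated-tobacco arms, and an exponential decay with
half-life `decay_half_life` (default 1 month) after `switch_month`
(default 2) for cessation/switch arms. The decay form is a free
simulation parameter, not an inference target: the empirical observation
it mimics is only "a rapid return toward the sham range".

Acceleration is modeled as an **effective-age shift along each age
gene's own slope**, not as an independent additive effect: this is
exactly the signal a clock trained on sham aging can read, which makes
"recovered group mean delta ≈ Δ" a well-posed recovery target rather
than an approximation. For the same reason, exposure genes drawn from
the age set (the `overlap_fraction`) carry *no* separate step effect;
their exposure response *is* $\Delta m_g$. Their slopes are drawn from
a higher range (`overlap_slope_range`, default 0.35–0.6 log2/month) so
that $\Delta |m_g|$ clears the fold-change cutoff, while age-only genes
use 0.1–0.15 log2/month so that their $\Delta |m_g| \le 0.3$ stays
clearly below $\log_2 1.5 \approx 0.585$ even with estimation noise,
yet their fold change over the 7-month age span (0.7–1.05) clears it.
This separation is what makes the *recovered* overlap percentage track
the *planted* overlap fraction; biologically it mirrors the observation
that the genes most strongly up-regulated with age (immunoglobulin-like
behavior) are also the most exposure-responsive. Exposure-only genes get
a step effect of 0.8–1.5 log2 units with random sign.

The `scenario_paper_like()` preset emits 3 studies with sham time points
{1,2,3,4,6,8}, {1,2,4,6,8} and {1,4,6} months of exposure (baseline age
2 months; 8 animals per group except one group of 7), chosen so the
within-study sham pairs give exactly 28 age contrasts, the time-matched
smoke-vs-sham pairs give 14 exposure contrasts, and the sham arms total
exactly 111 samples across studies. Study 1 additionally carries
cessation and switch arms from month 3 on; studies 2 and 3 carry
heated-tobacco arms. Default noise is $\sigma = 0.25$ log2 units with
per-study batch sd 0.3, and the preset's overlap fraction is 0.62.

**What the simulator does not emulate** — and hence what passing tests
do *not* show about real data: probe-level microarray noise and
normalization artifacts; heavier-tailed and gene-correlated residuals
(noise here is i.i.d. Gaussian given the batch term); nonlinear or
heteroscedastic aging trajectories beyond the single saturating option;
sex and strain covariates; and real biological pathway structure. On
this clean generative model the clock's cross-validated MAE is far below
what any real tissue data would give; the MAE criteria used in the tests
(≤ 1.5 months) are scale analogs, not claims about real-data accuracy.

## Numerical choices

* **Solver convergence.** The exported `lasso_coordinate_descent()`
  declares convergence on the KKT subgradient conditions
  ($|x_g^\top r|/n \le \lambda + \mathrm{tol}$ for zero coefficients,
  $|x_g^\top r/n - \lambda\,\mathrm{sign}(\beta_g)| \le \mathrm{tol}$
  otherwise; default tol $10^{-8}$), and non-convergence is an error
  carrying the last iterate. Inside cross-validation, path fits
  additionally stop once a full sweep moves no coefficient by more than
  `sweep_tol` (default $10^{-4}$ on the standardized scale): with many
  strongly correlated predictors, coordinate descent's last digits
  converge slowly while the fitted values — all that MSE-based
  $\lambda$ selection consumes — are long settled. The final KKT
  violation is always recorded, and both tolerances are arguments.
* **Degenerate refits.** An empty support at $\lambda_{\min}$ falls
  back to an intercept-only model (with a warning); a singular OLS
  refit — routine when the selected support approaches the training
  sample count — is ridge-stabilized with $\epsilon = 10^{-8}$ (with a
  warning).
* **Ties.** $\lambda$ ties break sparse; signed-MFC ties break to the
  lexicographically earlier contrast; zero-variance genes get
  $t=0, p=1$.
* **Seeds.** Every stochastic operation takes an explicit seed; nothing
  reads or leaves hidden global RNG state (`with_seed` restores the
  caller's stream). The pipeline splits one root seed per stage with
  fixed offsets, and identical configs produce byte-identical artifact
  trees.
* **Monte-Carlo calibration of the group tests.** Power and type-I
  error of the vs-sham Welch test are estimated by simulating delta-age
  samples at the residual scale actually measured from a held-out
  clock fit (shift 2 months for power, 0 for the null; n = 20/group;
  200 and 1000 replicates). Re-running the full simulate-and-train
  pipeline per replicate would add nothing: the quantity under test is
  the inference machinery at the observed noise level, not the
  simulator.
* **Problem sizes.** The default test and acceptance runs use the
  full 2000-gene, 351-sample preset for single fits and the headline
  checks, and a structurally identical 600-gene preset inside loops
  over many seeds; both sizes exercise identical code paths.

## Known limitations

* The clock is strictly linear and sparse by design; saturating aging
  trajectories are only first-order captured by a linear fit.
* With the clean generative model, minimum-MSE $\lambda$ selection
  tends to keep many informative genes (support near the training
  sample count), relying on the ridge-stabilized refit; on noisier real
  data the selected sets would be smaller.
* Moderation per contrast (rather than across all arrays) re-estimates
  the variance prior 42 times on the preset; with 7–8 samples per group
  the prior is the dominant stabilizer.
* The cessation decay half-life is a simulation convention; nothing in
  the package estimates it.
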