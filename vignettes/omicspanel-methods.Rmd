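---
title: "Methods and design of omicspanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of omicspanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicspanel)
```

omicspanel turns the analyses of an interactive multi-omics biomarker
dashboard into a seedable, scriptable library. This vignette explains the
statistical machinery, the choices we made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate.

## Data model

A *study* is one metadata table (samples × clinical/demographic variables)
plus J omics matrices (samples × features) sharing one sample order, with a
categorical response and its reference level. Alignment is positional: the
files carry no mandatory sample keys, so every matrix must have exactly n
rows in metadata order. When a leading non-numeric, duplicate-free column is
present in both files it is treated as sample ids and used as a cross-check
only. Missing values are a hard error at load time — we deliberately do no
imputation, because silently imputed values leak into cross-validation folds
and bias the biomarker stage.

Metadata columns are classified automatically: non-numeric columns are
categorical, numeric columns with at most 5 distinct values are categorical
(this catches 0/1-coded clinical flags), the rest numerical. The threshold
is a parameter of `classify_variables()`.

## Cohort characteristics (Table 1)

Each metadata variable is tested against the response: numerical variables
by one-way OLS (overall F; per-group mean/SD) or the tie-corrected
Kruskal-Wallis test (per-group min/median/max), categorical variables by
Pearson chi-square with Yates continuity correction iff the table is 2×2.
These call `lm`/`anova`, `kruskal.test` and `chisq.test`; the package adds
the orchestration, summaries and the assumption validator.

`global_validate()` checks the OLS assumptions with four directional
chi-square(1) components on the residuals — skewness `n·g₁²/6` and kurtosis
`n·(g₂−3)²/24` (maximum-likelihood moments), a link-function score test
(`n·R²` of residuals on squared fitted values) and a Breusch-Pagan
heteroscedasticity test (`n·R²` of squared scaled residuals on fitted
values) — summed into a global chi-square(4). When the fitted values are
constant the last two components are undefined and the global df drops to 2.
A violated verdict (global p < 0.05) is *reported*, never acted on: both
analysis modes are user choices, and silently switching tests would make the
table irreproducible from its description. Monte-Carlo checks in the test
suite show the global test holds its nominal type-I error to within
[0.02, 0.09] at n = 200; the components are asymptotic, so at much smaller n
the verdict should be read as indicative.

## Exploratory PCA

Each dataset is decomposed by SVD (via `prcomp`) after mean-centering;
unit-variance scaling is off by default and exposed as a flag, matching the
common default for expression data where variance carries signal. Up to five
components are retained. Because singular vectors are sign-ambiguous, we fix
a convention — the largest-magnitude loading entry of each component is made
positive — so scores and loadings are identical across platforms.

Sources of variation are attributed by regressing each PC score on each
metadata variable (indicator coding for categorical variables) and reporting
the overall ANOVA F p-value per cell; the optional Benjamini-Hochberg
adjustment is applied jointly across the whole variable × component grid,
because the heatmap offers a single FDR toggle, not one per column. The
response itself appears as a heatmap row: it is a metadata variable, and its
association with early components is usually the first thing one wants to
see, redundancy notwithstanding.

## Differential expression

Three per-feature methods share one skeleton: a linear model on *all*
response levels, with the requested pairwise contrast extracted from the
coefficients and the residual df taken from the full model (n − g). The
effect is the difference of level means `a − b`. For the OLS and moderated
methods the input values are assumed to be on the log2 scale already, so
that difference *is* the log2 fold-change — the package does not transform
non-count data, and this is the single most important contract for users to
respect.

The moderated method shrinks each feature's residual variance toward a prior:
`s̃²_g = (d₀·s₀² + d·s²_g)/(d₀ + d)`, with the moderated t on d₀ + d df.
The prior is estimated by method of moments on
`e_g = log s²_g − ψ(d/2) + log(d/2)`: `ψ′(d₀/2) = var(e) − ψ′(d/2)`
inverted by Newton iteration on the trigamma function, and
`s₀² = exp(mean(e) + ψ(d₀/2) − log(d₀/2))`. When the variance spread does
not exceed what sampling alone explains, d₀ = ∞ and s₀² reduces to
`exp(mean(e))` — the geometric mean of the bias-corrected log variances.
Note a subtlety: if every `s²_g` is *identical*, this limit differs from the
common value by the chi-square log-scale bias factor
`exp(log(d/2) − ψ(d/2))`; we keep the bias-corrected form because it is what
makes the moderated t calibrated on null data (type-I error ≈ 0.05 in the
acceptance checks), which matters more than matching a degenerate input
exactly. No robust variant and no trend on s₀² is fit.

For count data, weights follow the mean-variance-trend recipe: log2 CPM with
the 0.5/+1 offsets, per-feature residual SDs square-root transformed and
smoothed against mean log2 count by lowess with span 0.5, each observation's
fitted log2 count mapped through the trend by piecewise-linear interpolation
(flat beyond the range), and weight = (trend value)⁻⁴ with the max/min ratio
capped at 10⁶ to keep single extreme observations from dominating a fit.
Library-size CPM is the only normalization — TMM-style factors are out of
scope. The test suite verifies both the weights and the downstream
moderated statistics against the established implementation of this recipe
to 10⁻⁶.

Benjamini-Hochberg adjustment is one shared implementation
(`bh_adjust()`) used by every stage, applied per dataset per contrast — not
pooled across datasets, since each dataset gets its own dashboard and its
own multiplicity burden.

## Gene sets and drug reversal

Enrichment is local over-representation analysis: GMT collections are read
from disk, and for each set the p-value is the hypergeometric upper tail
P(X ≥ k) with N = |universe|, K = |set ∩ universe|, n_q = |query|. The
universe is the set of features actually tested in the differential
analysis — using all annotated genes instead would overstate enrichment of
anything measurable. Datasets qualify for enrichment when at least half of
their feature ids look like human gene symbols (uppercase alphanumeric,
length 1–10, starting with a letter); the fraction and pattern are
configurable.

Drug-reversal scoring runs two ORAs per perturbation — DE-up genes against
the perturbation's *down* set and DE-down genes against its *up* set — and
combines them as the sum of the two −log₁₀ adjusted p-values. The sum is a
declared convention: it is symmetric in the two directions and monotone in
each, but it is one of several defensible combination rules. Perturbations
present in only one collection receive p = 1 for the missing side; ties in
the final ranking break alphabetically so output order is deterministic.

## Biomarker discovery

The elastic-net objective `(1/2n)Σ(y − b₀ − Xβ)² + λ(α‖β‖₁ + ((1−α)/2)‖β‖₂²)`
is solved by cyclic coordinate descent with active-set iteration and warm
starts along a decreasing λ path, in compiled code. The default *family* is
the 0/1-coded response under squared loss with predictions clipped to
[0, 1] — the Gaussian working model that penalized-regression biomarker
pipelines commonly default to — with penalized logistic (IRLS around the
same solver) as the option. Coefficients are reported on the standardized
scale; standardization uses the population (1/n) variance convention and is
always internal, so shifting or rescaling a feature's raw units changes
nothing downstream (a property the tests assert to 10⁻⁸).

Tuning is repeated stratified k-fold cross-validation (defaults: 5 folds, 5
repeats, α ∈ {0, 0.1, …, 1}, 50 λ values per α log-spaced from λ_max down to
10⁻³λ_max computed on the full data so the grid is common across folds).
Standardization is refit on each training fold. The winning (α, λ) maximizes
the mean out-of-fold AUC (accuracy available), with ties broken toward the
largest λ — the sparsest panel — then the largest α. The final model is
refit on all samples at the winner.

All performance surfaces are **out-of-fold**: each sample's score comes from
models that never saw it, averaged over repeats. In-sample ROC of a tuned
model is optimistically biased, so we never report it. The ensemble score is
the arithmetic mean of the member panels' out-of-fold scores; ROC curves use
the trapezoidal rule with tied scores grouped into single steps, which makes
the AUC exactly the rank concordance statistic U/(n₁n₀).

Multi-level responses are dichotomized as (chosen level) vs (reference
level), dropping other samples for this stage only. Panel overlap is
tabulated as exact-subset counts (an UpSet-style summary); sample structure
in the selected-feature space is shown by PCA and an average-linkage
(Euclidean) clustered heatmap of standardized values; and the
pathway–biomarker network connects biomarkers to significant ORA sets by
membership and biomarkers to each other when |Pearson r| clears a
user-specified cutoff (cross-dataset pairs included, since samples align).

## Synthetic data: what it shows and what it does not

The generator emulates the minimal structure each stage needs: null features
iid N(0, 1); planted features mean-shifted by ±δ/2 per group (so group means
differ by δ feature-SDs); negative-binomial counts with a log2 fold-change δ
on planted features for the count pipeline; a batch variable with an
optional additive shift to plant a dominant PCA axis; null numeric and
categorical covariates; and an optional within-block equicorrelation ρ
(blocks of 10) to stress grouped selection. Everything is a pure function of
the seed. A complementary-signal variant splits cases into two latent
subtypes, each visible to only one modality — the canonical situation where
averaging predictions beats any single modality.

The shipped study conditions are: planted-signal recovery at n = 120,
p = 400 per modality, 10 planted features, δ = 1.5; complementary-signal
averaging at n = 120, p = 200, δ = 2.5 over 20 seeds; count-pipeline
recovery at n = 12, p = 2000, 50 planted 4-fold features with dispersion
0.2; calibration checks at 200 permutations / 1000–2000 null features.
These sizes are desk-scale by design: large enough for the statistical
contracts (calibrated type-I error, recovery with margin), small enough that
the whole suite runs in minutes on one CPU.

What passing does *not* show: real omics data have correlated features,
library-composition effects, batch-by-group confounding and heavy-tailed
noise that the generator deliberately omits (only a single additive batch
shift and optional equicorrelation are modelled). The tests certify the
machinery — estimators, solvers, bookkeeping, determinism — not the
field performance of any particular panel.

## Numerical choices

- Coordinate descent converges when the largest weighted squared coefficient
  update falls below 10⁻⁹ (configurable); every active-set pass is verified
  by a full sweep before declaring convergence.
- Trigamma inversion runs Newton steps to a relative 10⁻¹⁰; the λ-grid floor
  for the ridge end (α = 0) uses the conventional α-floor of 0.001 so
  λ_max stays finite.
- The d₀ = ∞ and constant-fitted-value degeneracies are handled explicitly
  (normal reference distribution; reduced global df).
- Delimiters are sniffed from {comma, tab, semicolon} on the header line;
  the decimal point is fixed as ".".
- Study serialization writes numerics with 17 significant digits so a
  write/read round trip is bit-exact.
- All tie-breaks (importance ranks, reversal ranking, hyperparameter
  selection) are deterministic and documented on the respective functions.

## Package shape

The biomarker stage is the package's modelling core, so it follows the
classic R idiom: `fit_panel()` / `fit_ensemble()` return classed objects
(`omx_panel`, `omx_ensemble`) with `print`, `summary`, `coef`, `predict`
and `plot` methods. The surrounding stages (Table 1, PCA, differential
expression, enrichment, reporting) are plain functions over plain classed
results, orchestrated by `run_pipeline()` with a YAML config whose schema
ships in `inst/schema/config-schema.json`; a thin command-line wrapper lives
at `inst/cli/omicspanel`. Seeds live only in the config or function
arguments — there is no hidden global randomness, and two runs with the same
config and seed produce byte-identical stage outputs.

## Known limitations

- No imputation, no feature filtering, no between-sample normalization
  beyond library-size CPM; inputs are taken as given.
- The OLS/moderated DE modes trust the caller that values are log2-scale.
- Enrichment requires symbol-style feature ids and user-supplied GMT files;
  no id mapping or orthology is attempted.
- No nested cross-validation: the reported out-of-fold AUC of the *tuned*
  model carries the usual mild selection optimism.
- Survival, multinomial and longitudinal outcomes are out of scope, as are
  intermediate-integration latent-factor models.
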