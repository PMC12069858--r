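---
title: "Methods: consensus mapping of structural correlates of g"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus mapping of structural correlates of g}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `gmanifold`, the
choices the package makes where the method leaves room, and what its
synthetic cohorts do and do not establish about real data.

## The estimand and the consensus idea

The general-intelligence factor *g* is defined as the single common factor
underlying test performance across multiple cognitive domains. Its key
empirical property, the positive manifold, is that any diverse subset of a
battery produces nearly the same *g* ranking of subjects. The package
exploits this property as an error-control device: if the battery has
domains with several tests each, each one-test-per-domain combination
yields a parallel estimate of *g*, and a *real* structural correlate of
*g* should be significant against most of these estimates. An association
that appears for only a few combinations is better explained by
test-specific variance or by chance.

Formally, with domain sizes $(3, 2, 2, 2)$ the package forms all
$K = 24$ combinations, estimates factor scores $\hat g^{(k)}$ for each,
tests every ROI against every $\hat g^{(k)}$, and accepts an ROI only when
it is significant for strictly more than $K/2$ of the estimates,
i.e. at least $\lfloor K/2 \rfloor + 1 = 13$ of 24. At odd $K$ the same
formula gives $\lceil K/2 \rceil$. Counts of exactly threshold − 1 are
flagged as near misses, since a strict majority is a deliberately
conservative cut and borderline regions are worth inspecting.

## Score conditioning

Speeded tests are converted to efficiency scores, raw score divided by
completion time. "Weighting by time" admits several readings (division,
regression adjustment, a composite); division — throughput, correct output
per unit time — is the standard metric for speeded tests and is the
convention adopted. The provenance record marks every time-weighted test
so a downstream analysis can re-run under a different convention.

Each (possibly time-weighted) score vector is screened with the
Shapiro–Wilk test at $\alpha = 0.05$ (the conventional level; the screen's
only role is to decide transformation). Non-normal scores are
log-transformed as $\log(x + c)$ with $c = 1 - \min(x)$ when the support
includes values $\le 0$ and $c = 0$ otherwise; $c$ is recorded. Scores of
tests flagged as "lower is better" are negated, and every column is
z-standardized. Conditioning is idempotent up to standardization and
preserves within-test rank order.

## Parallel factor models

For each combination the package fits a one-factor model to the $4 \times
4$ correlation matrix by maximum likelihood (`stats::factanal`, no
rotation), the default behaviour of the software a practitioner would
reach for. With four indicators and one factor the model has two degrees
of freedom; no fit-quality gate is applied. Numerical choices:

* **Heywood cases.** Uniquenesses are floored at 0.005 (the `factanal`
  boundary). Fits at the boundary are flagged but retained — with four
  indicators and modest samples boundary solutions are expected
  occasionally and discarding them would bias the consensus count.
* **Degenerate correlation matrices.** When the ML fit cannot run (e.g. a
  numerically singular correlation matrix), a hand-rolled unweighted
  least-squares (minres) fit of the off-diagonal entries is used instead;
  the method is recorded in the score set.
* **Factor scores.** Regression (Thomson) scores are computed from the
  model-implied correlation matrix $\Lambda\Lambda' + \Psi$, which is
  invertible even at the uniqueness floor. Scores are re-standardized, so
  the scoring scale is immaterial. The score method is a documented choice:
  alternative methods (Bartlett) differ slightly, which is precisely the
  kind of arbitrariness the consensus design absorbs.
* **Sign convention.** Loadings and scores are flipped so the loading sum
  is positive (tie broken by the first loading), making every $\hat
  g^{(k)}$ correlate positively with performance. Negated pairs of score
  sets therefore cannot arise from fitting.

The manifold summary reports the median and range of the strictly
off-diagonal Pearson correlations among the $K$ score vectors; a low
median would warn that the battery lacks a dominant common factor and that
the consensus vote is not meaningful.

## Association and family-wise error control

ROI-level inference uses the linear model $y_r = \beta_0 + \beta_1 \hat g
+ \gamma_1\,\mathrm{gender} + \gamma_2\,\mathrm{handedness} + \varepsilon$
per ROI $r$, with handedness entering as its ordinal rank. The package
reports the slope, the covariate-adjusted (partial) Pearson correlation,
and a permutation p-value. The original inference in this design family is
vertex-wise with cluster-wise FWE; working from ROI summary tables, the
package substitutes ROI-mean values with **max-|t| permutation FWE across
the ROI family**, preserving the per-ROI, per-g-set "corrected p < 0.05"
decision structure at tabular scale. Details:

* **Freedman–Lane scheme.** The g scores are residualized on the nuisance
  covariates, permuted, and re-residualized; this respects the covariates
  under the null. The per-permutation maximum of $|t|$ across the family
  builds the null distribution.
* **Smoothing.** P-values use add-one smoothing $(b+1)/(n_\mathrm{perm}+1)$
  and are never zero; the default $n_\mathrm{perm} = 5000$ resolves
  $\alpha = 0.05$ comfortably.
* **Families.** The default-mode and task-positive node sets are corrected
  as separate families when the table's ROI labels match the built-in
  25-label set (configurable; any other table is treated as one family).
* **Contrast.** Two-sided by default; the direction of each effect is
  reported so sign consistency across g sets can be checked. The consensus
  vote itself does not require a consistent sign, but the report states
  whether the significant results agree in direction.
* Zero-variance ROI columns are excluded with a warning and never
  significant.

## The g-estimation model

Accepted ROI measures enter forward–backward stepwise OLS with partial-F
thresholds p-enter 0.05 and p-remove 0.10 (the defaults of the usual
stepwise linear-model implementation; the criteria are recorded in the
model object). Cross-validation uses K = 4 shuffled folds of near-equal
size, and **the entire stepwise selection is re-run inside each training
fold** — the only leak-free reading; a flag reproduces the leaky variant
(selection on all data, per-fold coefficient refits) for comparison only.
"Excluding outliers" is operationalized as dropping held-out predictions
with $|{\rm residual}| > 3$ robust SDs (MAD-scaled) of the pooled
residuals; both pooled and outlier-excluded MSE are always reported, and
the excluded count is part of the result. Both the in-sample adjusted
$R^2$ range and the cross-validated MSEs are reported because they answer
different questions (fit vs transportability).

## The synthetic cohort generator

The generator exists so each stage can be verified against ground truth;
it implements the minimal generative model under which the single-factor
extraction is well-specified:

$$z_{ij} = \lambda_j g_i + \delta u_{id(j)} + \sigma e_{ij}, \qquad
y_{ir} = \beta_r g_i + \gamma_{1r}\,\mathrm{gender}_i +
\gamma_{2r}\,\mathrm{hand}_i + \varepsilon_{ir},$$

with $g, u, e, \varepsilon$ independent standard normal. Defaults and
rationale:

* `n_subjects = 44`, the size of an imaged cohort this design targets;
  tests of the behavioural stages use 98, a realistic behavioural-cohort
  size. These sizes are also what the test-suite simulations use.
* loadings drawn from (0.65, 0.85), `domain_noise_sd = 0.25`,
  `test_noise_sd = 0.5`: implied correlation-scale loadings around 0.8,
  which reproduce the strong positive manifold typical of multi-domain
  batteries.
* math and logic tests are generated on an exponentiated scale and all
  speeded tests are multiplied by an independent lognormal completion time
  (median 2 minutes), so that time-weighting followed by the normality
  screen and log transform exactly recovers the latent variable — the
  conditioning path is testable end to end.
* gender is exactly balanced and independent of $g$; handedness is an
  ordinal rank 1–5 with 80% of mass at the fully right-handed maximum.
  Both enter every ROI with small default effects (0.1, 0.05) so covariate
  adjustment is always exercised.
* true effects sit on 8 of the 25 ROIs — negative CT effects on the
  inferior temporal, ventral posterior cingulate and parahippocampal
  labels, positive LGI effects on the posterior cingulate, middle temporal
  and collateral/lingual labels — with $\beta$ chosen so the population
  covariate-adjusted correlations land in the −0.25…−0.52 (CT) and
  0.22…0.41 (LGI) bands plausible for such cohorts. The closed form is
  $\rho_r = \beta_r / \sqrt{\beta_r^2 + 0.25\gamma_{1r}^2 +
  1.25\gamma_{2r}^2 + 1}$.

What the generator does **not** emulate: measurement non-linearity beyond
a log-scale skew, missing data, floor/ceiling effects, site or scanner
effects, spatial correlation among ROIs beyond what the shared $g$
induces, age structure, or any real geometry behind CT/LGI (values are on
a standardized scale, not mm). Passing tests therefore demonstrate the
pipeline's statistical correctness under its assumed model — calibration
of the permutation FWER, the consensus rule's false-positive suppression
at preserved sensitivity, leak-free cross-validation — not that real
cortical data satisfy those assumptions.

## Problem sizes in the verification suite

The statistical checks run at sizes chosen to make Monte Carlo error small
relative to the assertion margins while staying desk-scale: FWER
calibration uses 200 all-null cohorts of n = 44 with 1000 permutations
(binomial 99% CI around 0.05 is roughly 0.01–0.09); the consensus
operating characteristics use 200 replicate cohorts with 500 permutations
per g set; manifold and recovery properties use 100 seeds at n = 98 and
single fits at n = 500–10000. The acceptance script re-runs the same
computations from the installed package with a caller-supplied seed.

## Known limitations

* The consensus rule is the method's own multiplicity device; no second
  layer (FDR over counts, stability selection) is applied on top, by
  design.
* The parallel analyses share subjects, so the 24 votes are highly
  dependent; the rule trades power for specificity, and with small n the
  accepted set can be empty. The near-miss flag exists for exactly that
  case.
* Stepwise selection after a consensus screen inherits the usual
  post-selection caveats; the cross-validated MSE is the honest
  performance number, and the in-sample adjusted $R^2$ should be read as
  descriptive.
* With four indicators per factor model, boundary (Heywood) solutions are
  possible and are clamped rather than rejected.
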