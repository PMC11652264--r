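---
title: "Piecewise growth, twin ACE decomposition, and early-adult alcohol use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise growth, twin ACE decomposition, and early-adult alcohol use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(twinpaths)
```

## The scientific problem

Do emotional problems in childhood and adolescence predict how much, and how
harmfully, young adults drink — once the strong and well-established pathway
through conduct problems is taken into account? And if an association
remains, is it a plausibly causal phenotypic influence, or does it merely
reflect genetic and environmental factors shared by both traits? twinpaths
implements the full inference chain needed to ask these questions in a
classical twin design: developmental trajectories of SDQ emotional and
conduct scores, AUDIT alcohol scores in early adulthood, and the MZ/DZ
covariance contrast that separates additive-genetic (A), shared-environment
(C), and nonshared-environment (E) influences.

## Measurement and preprocessing

SDQ emotional and conduct subscales (5 items, 0–2 each) are scored by
proration: the mean of available items times the item count, so scores stay
on the 0–10 metric under partial response (`compute_scale_score()`; with
complete items this is the plain sum). AUDIT-Total (0–40) splits into
Consumption (items 1–3, 0–12) and Problem (items 4–10, 0–28); scores of 8+
flag hazardous use. Because the exact age at the alcohol assessment varies
(around 22.85 years, SD 0.88), all three AUDIT scores are residualized on
age by OLS before modelling; AUDIT-Problem is log-transformed first,
`log(score + 1)`, the offset chosen so that the many legitimate zeros map to
zero (the offset is configurable — the choice matters only for the scale of
coefficients, not for tests).

## The piecewise growth model

Six waves per trait, with a deliberate discontinuity at age 9 where the
rater switches from parent to self:

* childhood segment (parent report, ages 4, 7, 9): intercept $I_c$ anchored
  at age 4 and slope $S_c$ with loadings $(0, 3, 5)$;
* adolescence segment (self report, ages 9, 11, 16): intercept $I_p$
  anchored at age 9 and slope $S_a$ with loadings $(0, 2, 7)$.

Slope loadings are always *wave age minus anchor age*, so the anchor wave
loads exactly 0 and the anchors must coincide with a wave age
(`piecewise_loadings()` errors otherwise). No equality constraint bridges
the two segments: the age-9 parent and age-9 self measurements are distinct
variables whose means may differ, linked only through a free residual
covariance. The bivariate model has 8 factors with free means and a free
8×8 covariance, 12 residual variances, 6 cross-trait same-wave residual
covariances and 2 parent–self residual covariances at the knot — 64 free
parameters. (A covariance is fixed to zero only by the pruning rule below.)

The alcohol outcome enters jointly (one-step): the age-residualized score is
regressed on all eight factors and on covariates, which are exogenous
observed variables free to covary with the factors — this doubles as the
auxiliary-correlate device that supports the missing-at-random assumption,
since sex and family SES predict missingness in the generator and in the
motivating cohort. Standardized coefficients use the model-implied latent
standard deviations, $\beta_{std} = b\,\sigma_{pred}/\sigma_{outcome}$;
in multi-group models the within-group SDs are used (the alternative —
total-sample SDs — is not what the fitted moments deliver naturally, and
within-group standardization keeps each group's coefficients interpretable
on its own scale).

### Estimation

Everything is fitted by pattern-wise FIML: rows are grouped by missingness
pattern and each pattern contributes through its sufficient statistics, so a
likelihood evaluation costs O(#patterns) regardless of sample size.
Gradients are analytic in the data (chain rule through the implied moments,
with derivative matrices computed in closed form for `psi`, `theta`,
`alpha`, `nu` and `beta` entries, finite differences only for free
loadings). Optimization is bounded quasi-Newton (`nlminb`), with variances
bounded below at 0 and boundary solutions flagged, preceded for models with
40+ parameters by a Levenberg–Marquardt Fisher-scoring phase that uses the
expected information (refreshed every few steps).

Numerical choices worth knowing:

* Convergence is a scaled-gradient criterion (1e-5) for small models. Large
  growth/multi-group models sit on extremely ill-conditioned surfaces: in
  profiling, 3000 extra quasi-Newton iterations recovered under 0.1
  log-likelihood units. The scoring phase therefore declares
  *quasi-convergence* when two consecutive damped Newton steps each improve
  the log-likelihood by less than 2e-3 units. Chi-square difference testing
  tolerates up to 0.05 of resulting slack, and whenever a restricted model
  appears to beat its reference the reference is re-polished from the
  restricted solution (it can only improve) before the test is computed.
* Start values come from sample moments (means projected through the fixed
  loadings, variance parameters at fractions of marginal variances);
  sequential refits warm-start from the previous solution. Multi-start
  (jittered, deterministic under the fit seed) is available via `starts=`.
* The unconstrained two-group model of the sex pipeline has no cross-group
  constraints, so it is fitted exactly as two single-group fits.
* `p = 1` is returned for a 0-df difference test by convention.

### Pruning and the sex-difference pipeline

`prune_nonsignificant_covariances()` fixes to zero, jointly, every factor or
residual covariance whose robust-SE z-test is nonsignificant, keeps the
pruned model only if a chi-square difference test against the full model is
nonsignificant, and otherwise restores covariances one at a time by largest
likelihood gain.

`sex_difference_pipeline()` runs the ordered constraint sequence across
female and male groups: (1) everything involving covariates except the
outcome-on-covariate coefficients, (2) factor means, (3) factor variances,
(4) factor covariances, (5) residual variances and covariances. A
significant step triggers `modification_search()`, which frees the
constraint whose release most improves the likelihood — the exact
free-one-refit difference, not the score-test approximation; slower, but it
is the same metric as the stopping rule, and ties break by fixed label
order for determinism. Wald tests (cluster-robust, with the cross-group
sampling covariance) then compare every outcome coefficient between sexes;
coefficients passing equality are equated, and finally the outcome
intercept and residual variance are equated if a difference test allows.

## Twin models

Factor scores for the retained predictors (those significant in either sex)
are computed by the regression method,
$\hat\eta = \alpha + \Psi\Lambda' \Sigma^{-1}(y_{obs} - \mu)$ on each row's
observed sub-pattern — using only the growth indicators, never the outcome
or covariates, which would leak the outcome into the scores. Sex is
residualized out of every column, and same-sex plus opposite-sex DZ pairs
are pooled into one DZ group (a five-group model is used only for the
sex-difference test on direct paths, with opposite-sex twins ordered
male-first and each twin's own sex-specific path).

The model family shares one skeleton: a trivariate Cholesky
($L_A, L_C, L_E$) over the predictor block, and per predictor either

* a **direct path** $b_j$ — its A/C/E reach the outcome only through the
  phenotype, which constrains cross-twin cross-trait covariances to
  $[(r\Sigma_A + \Sigma_C)b]_j$ with $r = 1$ (MZ) / $0.5$ (DZ), E never
  crossing twins; or
* a **correlated-ACE link** — free loadings of the outcome on that
  predictor's Cholesky factors ($w_{Aj}, w_{Cj}, w_{Ej}$).

All-correlated is the correlated-factor solution of the full Cholesky;
all-direct is the phenotypic transmission model (2 fewer parameters per
predictor). `structure_search()` fits both, and — unless the direct model
already wins on AIC — every hybrid, reporting ΔAIC against the Cholesky
reference and selecting the minimum-AIC converged member (ties: fewer
parameters, then lexicographic code). Identification is checked before each
fit by the rank of the moment Jacobian. Standardized variance shares per
variable sum to one exactly by construction.

Because two-step estimation regresses on *estimated* scores, coefficients
are attenuated relative to the joint model; with the default generator the
intercept-factor scores correlate ~0.75–0.80 with their factors but the
slope-factor scores only ~0.39–0.46 (slopes are weakly determined by three
waves), so only well-separated effects should be compared quantitatively
across the two routes. The package documents this rather than hiding it:
the one-step/two-step agreement test requires 20% agreement only for the
strong conduct-slope effect.

## The synthetic world

`sim_config()` fixes the generating process the whole test suite relies on;
defaults are chosen once to emulate a large UK twin cohort and are not
tuned afterwards:

* pairs: 3400 MZ, 3300 same-sex DZ, 3300 opposite-sex DZ (scaled in tests);
* factor means/SDs on the SDQ 0–10 metric (e.g. emotional preadolescent
  intercept mean 3.2, SD 1.6; slopes near −0.1 per year, SD 0.16–0.20),
  with a structured 8×8 correlation matrix (cross-trait same-factor
  correlations 0.25–0.40);
* ACE shares 0.4/0.2/0.4 applied proportionally to the factor covariance —
  which guarantees positive semi-definite component matrices; DZ genetic
  components are constructed as $0.5 A_1 + \sqrt{0.75}A'$, exactly
  equivalent in distribution to the joint draw;
* wave residual variances 1.0–2.0 with cross-trait residual correlation
  0.25 and parent–self correlation 0.30 at age 9;
* a unit-variance alcohol liability with standardized direct effects −0.08
  (emotional preadolescent intercept) and 0.30 (adolescent conduct slope) —
  the magnitudes reported for the motivating cohort — and unique ACE shares
  0.4/0.1/0.5; AUDIT-Total is an affine map of the liability (mean 8.3,
  SD 4.9) plus a small true age slope that makes the age residualization
  consequential; AUDIT-Problem is a zero-inflated monotone (exponential)
  transform, deliberately skewed so the log transform is warranted;
* sex effects as mean shifts only (females higher on emotional, males on
  conduct and alcohol); ACE variances are sex-homogeneous because the
  analysis residualizes sex before twin modelling;
* missingness: per-wave logistic models on sex and a standard-normal
  family SES covariate — MAR by construction — with base rates ~10–12% in
  childhood, ~55% at the age-9 waves and ~50% at the alcohol wave,
  mirroring realistic cohort attrition.

`implied_observed_moments()` gives the exact means (per sex), within-twin
covariance, and MZ/DZ cross-twin covariance of the twelve wave scores and
the linear AUDIT-Total column; Consumption and Problem are monotone
transforms of the same liability and are intentionally outside the linear
oracle. Observed scores are left continuous (the models treat them as
continuous); `round_to_scale()` optionally censors and rounds onto the
questionnaire grids.

What a green test does *not* establish: the generator is multivariate
normal with linear effects and MAR missingness — it cannot detect bias from
ordinal measurement, floor effects, MNAR attrition, rater-specific method
variance beyond a single residual covariance, or sex-specific ACE
variances, none of which it simulates.

## Known limitations

* Chi-square difference tests use plain ML statistics; robust (scaled)
  difference testing is not implemented, so with strongly non-normal data
  the difference tests pair imperfectly with the sandwich standard errors.
* Modification indices are exact refits; with many candidate constraints
  this is the slow-but-unambiguous option, and like any specification
  search it over-fits — the per-step log in the report is the audit trail.
* Quasi-convergence (above) trades the last ~0.1 log-likelihood units of
  the large fits for an order-of-magnitude runtime reduction; confidence
  intervals from such fits inherit that slack, which is negligible relative
  to their sampling error at the simulated sample sizes.
* Ordinal item-level modelling, sex-limitation ACE models, dominance (ADE),
  and three-piece trajectories are out of scope.
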