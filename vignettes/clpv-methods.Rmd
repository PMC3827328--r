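---
title: "Estimating construct-level predictive validity from censored, range-restricted selection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating construct-level predictive validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpv)
```

## The problem

A medical school (or any selective programme) validates its selection
measures on the students it admitted, but needs to know how those measures
would predict across everyone who applied. The observed entrant correlation
understates the true predictor–outcome relationship for three reasons that
`clpv` models explicitly: range restriction from selection, attenuation from
measurement error, and right-censorship of the predictor at a grade ceiling.
The target of inference is the construct-level predictive validity
$\rho_{TP}$ — the correlation between the latent traits underlying predictor
and outcome, in the applicant pool.

## The observation model

Seven parameters describe the data: $(\mu_a, \sigma_a)$ for the predictor in
applicants, $(\mu_i, \sigma_i)$ for the predictor in entrants, $(\mu_y,
\sigma_y)$ for the outcome in entrants, and the entrant correlation $r_i$.
The likelihood has three kinds of contribution:

* **Applicants** (predictor only): a Tobit likelihood — normal density for
  uncensored scores, upper-tail probability $1 - \Phi((c-\mu_a)/\sigma_a)$
  for each score at the ceiling $c$.
* **Entrants, continuous outcome**: bivariate-normal density for uncensored
  pairs; for a pair with the predictor at the ceiling, the outcome's
  marginal density times the conditional upper tail
  $P(X \ge c \mid y)$.
* **Entrants, ordinal or binary outcome**: the latent outcome is standard
  normal ($\mu_y, \sigma_y$ fixed at 0, 1 — they are not identified from
  category labels) and category $j$ corresponds to the interval
  $(\tau_{j-1}, \tau_j]$. Uncensored pairs contribute
  $\phi(x)\,P(\tau_{j-1} < Y^* \le \tau_j \mid x)$; censored pairs the
  bivariate-normal rectangle $P(X \ge c,\ \tau_{j-1} < Y^* \le \tau_j)$.

Entrants are treated as a subset of applicants produced by indirect
selection; no explicit selection term enters the likelihood, because the
Hunter–Schmidt–Le machinery corrects for selection afterwards. A value
tied at the ceiling *is* the censorship signal: any observation
$\ge c$ is treated as censored, which also covers data reported simply as
"maximum points".

**Thresholds are two-step.** $\tau_j$ is fixed at
$\Phi^{-1}(\text{cumulative proportion through category } j)$ from the
marginal frequencies, the standard two-step device in polychoric
estimation, rather than sampled jointly. Two-step thresholds are stable,
make the ordinal likelihood a function of $(\mu_i,\sigma_i,r_i)$ only, and
are validated against a quadrature oracle in the test suite.

**Numerical choices.** Rectangle probabilities use the high-accuracy
bivariate-normal CDF (`mvtnorm`'s TVPACK algorithm, absolute tolerance
$10^{-12}$, comfortably under the $10^{-7}$ design target). Likelihood
evaluations inside the samplers use sufficient statistics for the
uncensored blocks, so cost scales with the number of *censored*
observations. Out-of-range proposals ($|r_i|\ge 1$, non-positive SDs)
return $-\infty$ rather than erroring, so the sampler can propose freely.

## Maximum likelihood and the DRAM posterior

`fit_seven_parameter_mle()` maximizes the joint likelihood on a transformed
scale ($\log\sigma$, $\operatorname{atanh} r$), Nelder–Mead followed by a
BFGS polish, starting from decensored moment estimates. When nothing is
censored and the outcome is continuous, the MLE is returned in closed form
(sample moments and the Pearson correlation) — this limiting identity is one
of the test suite's oracles.

The posterior is sampled by `run_dram()`, a delayed-rejection adaptive
Metropolis chain:

* proposal covariance re-estimated from the chain history every
  `adapt_interval` (default 100) iterations from iteration `adapt_start`
  (default 200), scaled by the usual $2.38^2/d$;
* one delayed-rejection stage on rejection, retrying from a proposal
  shrunk by `dr_shrink` (default 5) and accepted with the two-stage
  probability that preserves the target;
* the chain is started at the MLE with a proposal covariance from the
  inverse observed information, so adaptation starts close to the target
  geometry. The reported `acceptance` is the first-stage rate (the
  standard random-walk diagnostic, typically .2–.4 here); the combined
  rate including delayed-rejection accepts is reported separately, since
  the shrunken second stage accepts small moves often by design.

Because no prior information usually exists for these parameters, priors
are weakly informative: flat on the means, $1/\sigma$ on the SDs
(flat on $\log\sigma$), uniform on $r_i \in (-1,1)$ (a $\log(1-r_i^2)$
Jacobian term on the sampling scale). Users who need different priors can
call `run_dram()` with their own log-posterior.

Chains default to 5,000 iterations with summaries from the final 2,000
(`chain_control()`); burn-in is exactly `length - use_last`, not a separate
knob. Summaries are posterior mean (estimate), SD (standard error) and
2.5th/97.5th percentiles (interval). Equilibrium is checked automatically:
each retained trace is regressed on iteration number and a slope with
$p < .01$ flags the parameter, replacing an unreproducible visual
inspection.

## The correction, per draw

For each retained draw the selection ratio $u = \sigma_i/\sigma_a$ is formed
from that draw's **latent (decensored) SDs** — censorship shrinks observed
SDs, so using observed ones would overstate selection — and pushed through
the Hunter–Schmidt–Le correction for indirect range restriction
(`hsl_case_iv()`):

$$r_{XXi} = 1 - \frac{1 - r_{XXa}}{u^2}, \qquad
  u_T = \sqrt{\frac{u^2 - (1 - r_{XXa})}{r_{XXa}}}, \qquad
  r_{TPi} = \frac{r_i}{\sqrt{r_{XXi}\, r_{YYi}}},$$
$$\rho = \frac{r_{TPi}/u_T}{\sqrt{1 + r_{TPi}^2\,(1/u_T^2 - 1)}}.$$

Two reliabilities are inputs, not estimates: the predictor's in the
*applicant* pool ($r_{XXa}$) and the outcome's in *entrants* ($r_{YYi}$).
When unknown, defaults of .815 and .834 — field averages — are used and
logged. The correction is the identity when both reliabilities and $u$
are 1, and can only increase the magnitude otherwise; both laws are
enforced by tests.

Per-draw propagation can occasionally step outside the correction's domain
(e.g. a draw with $u^2 \le 1 - r_{XXa}$). Such draws are dropped and
counted — more than 5% flags the estimate as unreliable — and corrected
values that overshoot $\pm 1$ are clipped with a warning rather than
discarded, so a long chain survives a few extreme draws. The standard
error is converted to an equivalent N by inverting
$SE(r) = (1-r^2)/\sqrt{n-1}$, which is how corrected validities re-enter
correlation-based meta-analysis.

## The synthetic cohort generator

`simulate_cohort()` draws latent true scores $(T, P)$ bivariate normal with
correlation `rho_true`, forms observed scores with the stated
reliabilities, admits the top `selection_fraction` on a selection composite
$S = wZ + \sqrt{1-w^2}\,\varepsilon$, and censors the observed predictor at
the `ceiling_quantile` of the applicant pool. Defaults (20,000 applicants,
$\rho = .65$, reliabilities .815/.834, fraction .25, $w = .8$, ceiling at
the 90th percentile) produce realized selection ratios around .72–.78 and
roughly a third of entrants at the ceiling — the geometry of large recent
UK cohorts.

**What the composite selects on is a modelling decision.** The correction
being tested assumes *indirect* selection: whatever drives admission
affects the observed predictor only through its true score
($S \perp X \mid T$). The generator therefore defaults to
`selection_on = "true_score"` ($Z = T$), under which the corrected
estimate is consistent — an analytic Pearson–Lawley calculation under the
default conditions gives a population-level corrected value of .650
exactly. Setting `selection_on = "observed"` ($Z = X$) instead lets the
composite ride on the predictor's measurement error; its $w = 1$ limit is
classical *direct* selection, which is the regime for the Thorndike
Case II cross-check in the tests. Under observed-score selection with
$w < 1$ the indirect-selection correction genuinely overcorrects (by about
+.09 at the defaults — the constant-error-variance step underestimates
$u_T$ when the error itself is range-restricted); the generator exposes
this regime deliberately, but recovery guarantees apply to the
true-score default only.

Every cohort records a `truth` block (realized $u$, restricted
reliabilities, entrant correlation) so recovery tests assert against the
realized generative values, and all randomness flows from one seed, making
every fixture bit-regenerable.

The cohort's unrestricted outcome reliability differs from the restricted
value realized after selection; the generator generates with the
unrestricted value and reports the realized restricted one
(`truth$r_YYi`), which is what the correction consumes.

## Meta-analysis of validities

`pool_random_effects()` and `meta_regress()` follow the Hedges–Olkin
random-effects route: Fisher-z transform, within-study variance
$1/(n-3)$ (or variances supplied directly as z-scale SEs or derived from
printed CIs), DerSimonian–Laird $\tau^2$, inverse-variance weights,
back-transform of the pooled mean. The machinery is delegated to
`metafor::rma(method = "DL")` behind this interface; a hand-computed
DerSimonian–Laird oracle cross-checks it in the tests. `Q_B` is the omnibus
moderator chi-square (`QM`), `Q_E` residual heterogeneity. Moderator
p-values are two-tailed by default. A raw-r, n-weighted Hunter–Schmidt
pooling mode is available behind `method = "raw-r"` for sensitivity
analysis. Corrected validities enter with their equivalent N — the device
that lets chain-derived standard errors flow into correlation
meta-analysis.

## Closed-form predictions

The prediction module works entirely from published or fitted summary
numbers: `attenuate()` maps a construct-level validity back to the observed
scale ($\rho\sqrt{r_{XX} r_{YY}}$); `predictor_z()` places a grade profile
in the decensored applicant pool; `expected_outcome_z()` is the regression
prediction $r_{att} z$; `tail_rate()` converts a baseline failure or retake
rate into a predicted rate for out-of-range entrants; and
`grade_increment_effect()` projects the value of an extra grade step.

Two conventions deserve note. First, `tail_rate()` models the outcome of a
student at predictor $z$ as normal with mean $r_{att}z$ and **unit** SD:
$\Phi(z_{cut} - r_{att}z)$. Only this convention reproduces the full set of
published failure/retake rates this module is validated against; the
conditional-SD variant ($\sqrt{1-r_{att}^2}$) is available via
`conditional_sd = TRUE`. Second, golden tests follow print precision:
z-scores are reported to 2 decimals and the expected-outcome products in
the worked example are taken from those 2-dp values (which is how such
tables are built by hand), while tail rates are computed from
full-precision z. Published sources occasionally truncate rather than
round (e.g. an attenuated correlation of .5536 printed as .553, a cutoff
of −1.036 printed as −1.03); the package always reports the computed
value. `sample_size_for_power()` uses the Fisher-z approximation
$n = ((z_{\alpha} + z_{power})/\operatorname{atanh} r)^2 + 3$ rounded to
the nearest integer, which reproduces the canonical 290-student
requirement for detecting $r = .171$ one-tailed at 90% power.

## Grade scoring and composites

Tariffs are data, not code: the shipped defaults are the standard UK
scorings, and variants (an A* = 12 A-level extension, the SQA band
scorings) are additions loaded from config. `score_best_k()` sums the best
$k$ mapped grades, summing and flagging (rather than rejecting) profiles
with fewer than $k$ grades, because real cohorts contain such students.
`zscore_by_group()` uses the sample ($n-1$) SD — the convention is stated
here because sources rarely say. `composite_attainment()` standardizes the
columns, imputes missing cells by EM under a multivariate-normal
missing-at-random model (convergence when the largest parameter change
drops below $10^{-6}$; non-convergence is an error reporting the iteration
count), and extracts the first principal component of the completed table
from the **correlation** matrix, since qualifications sit on mixed scales;
the component sign is fixed to correlate positively with the column mean.

## Problem sizes and runtime

The test suite exercises the full pipeline at desk scale: ten full-size
cohorts (20,000 applicants, chains of 5,000) for bias and RMSE, and one
hundred reduced cohorts (5,000 applicants, chains of 2,500 with summaries
from the final 1,000) for interval coverage. These sizes were chosen so
the whole suite runs in a couple of minutes on one core while leaving the
Monte-Carlo error of each check well inside its assertion margin.

## Limitations

* The generator emulates the generative structure the model assumes —
  bivariate-normal latent traits, normal errors, a sharp top-fraction
  selection rule. Real cohorts add non-normal grade distributions,
  lumpy tariff scales, school-level clustering and drifting selection
  policies; passing recovery tests demonstrates correctness of the
  machinery under its assumptions, not robustness to their violation.
* Left-censoring, interval-censored outcomes and non-normal latent
  families are out of scope.
* Outcome reliability in entrants is an input; the package does not
  estimate it from raw data, and results inherit its uncertainty
  (the per-draw propagation covers parameter uncertainty, not
  reliability-input uncertainty).
* Direct-selection regimes (selection on the observed, error-laden score)
  violate the indirect-selection assumption of the correction; the
  generator can produce them, and the package deliberately reports the
  overcorrected value rather than silently switching formulas.
* Single-chain DRAM with a trend-test equilibrium check is the designed
  scope; multi-chain convergence diagnostics are not provided.
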