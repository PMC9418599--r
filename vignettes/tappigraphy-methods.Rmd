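---
title: "Joint-interval distributions and cluster-corrected regression for smartphone touchscreen dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-interval distributions and cluster-corrected regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapjid)
```

## The behavioral representation

Smartphone touchscreen logs are a stream of discrete events: a timestamp
per touch, the foreground app, and screen on/off episodes. The package's
core representation is the *joint-interval distribution* (JID): the
2-D probability distribution of a within-session inter-touch interval
$k$ against its successor $k{+}1$, both on a $\log_{10}$ millisecond
axis. Intervals never span usage sessions (screen-on to screen-off), so
the long gaps between sessions do not enter the distribution.

Concretely, all consecutive interval pairs $(k, k{+}1)$ of a participant
are pooled, $\log_{10}$-transformed, smoothed with an isotropic Gaussian
kernel of bandwidth $h = 0.1$ (log10 units), evaluated at the centers of
a fixed $50 \times 50$ grid spanning $[10^{0.5}, 10^{5}]$ ms, converted
to bin masses (density $\times$ bin area) and renormalized to sum to 1.
The result is a 2500-dimensional feature vector per participant. Because
it is a normalized distribution, the JID is invariant to the *amount* of
usage in expectation — two people with very different touch counts but
the same interval dynamics converge to the same grid.

Three variants restrict which pairs enter the grid:

* **Full** — every consecutive pair within a session;
* **Social** — pairs whose three bounding touches all fall on a
  configured list of social-networking/browser apps (the strictest
  reading of "intervals accumulated while on" those apps);
* **Transition** — the subsequence of intervals whose bounding touches
  differ in app, re-paired consecutively within the session.

Numerical choices worth knowing:

* KDE is evaluated at bin centers only; kernel mass falling outside the
  grid range is recovered by the final renormalization rather than by a
  boundary-corrected kernel. This keeps the estimator simple and makes
  the normalization invariant exactly testable.
* Duplicate timestamps (simultaneous multi-finger touches) are collapsed
  before interval extraction — a zero interval has no $\log$.
* Duplicate $(k, k{+}1)$ pairs are aggregated into multiplicities before
  the kernel sums. This changes nothing mathematically but makes the
  grid *bit-identical* under duplication of the whole pair set, which is
  the sharpest form of the amount-invariance contract and is asserted in
  the tests.
* Intervals beyond $10^5$ ms stay in the pair sequence (they influence
  pairing) but contribute negligible in-range mass.

JID entropy is the Shannon entropy $H = -\sum_i p_i \log_2 p_i$ over
positive-mass bins (bounded by $\log_2 2500 \approx 11.29$ bits), and
daily usage is the $\log_{10}$ median touch count over days with at
least one touch.

## Cognitive scoring

Trial-level records from five online tasks are reduced to
per-participant scores: median correct-trial reaction time (simple and
choice), task-switch costs, Corsi span, and 2-back $d'$. Scores carry a
validity flag enforcing the minimum of successfully executed trials per
task: 12 (simple RT), 24 (choice RT), 12 (switching), 2 (Corsi), 30
(2-back). Conventions the underlying method description leaves open, and
which this package declares explicitly:

* a trial counts as "successfully executed" when a response was
  recorded within 3 s; correctness is required for the medians, not for
  the minima;
* global cost $= (\tilde{RT}_{mixed} - \tilde{RT}_{pure}) /
  \tilde{RT}_{pure}$ and local cost $= (\tilde{RT}_{switch} -
  \tilde{RT}_{nonswitch}) / \tilde{RT}_{nonswitch}$ (ratio-normalized
  differences of medians);
* $d' = z(\text{hit rate}) - z(\text{false-alarm rate})$ with rates
  clipped to $[1/2N, 1 - 1/2N]$ so extreme performance stays finite;
* finger-preference ranks (a permutation of eight posture images) map to
  the two 0-1 scales via $(8 - r^*)/7$, $r^*$ the best rank in the
  thumb set and in the both-thumbs set respectively — the published
  description fixes only the endpoints.

## Bin-wise robust regression

Each of the 2500 bins is regressed on a participant-level predictor
(age, or a cognitive score) plus a gender term, after a $\log_{10}$
transform of the masses in which zeros are replaced by the minimum
positive mass observed anywhere in the cohort. The fit is iteratively
reweighted least squares with Tukey bisquare weights (tuning constant
4.685, 95% Gaussian efficiency), residual scale re-estimated every
iteration as $\mathrm{median}|r|/0.6745$, at most 50 iterations,
convergence at $10^{-8}$ relative change in coefficients. The solver
lives in C++ because the correction below refits all bins hundreds of
times.

Two estimator details matter for calibration and were chosen after
measuring the alternatives:

* **Coefficient covariance.** The naive weighted-least-squares
  covariance at the converged weights is anti-conservative (empirical
  type-I error 0.083 at nominal 0.05, $n = 200$). The package uses the
  standard M-estimator covariance with Huber's small-sample correction
  — $\hat\sigma^2 = K^2 \frac{\sum \psi(r_i)^2/(n-p)}{(\overline{\psi'})^2}$,
  $\mathrm{Cov}(\hat\beta) = \hat\sigma^2 (X'X)^{-1}$ — which measures
  at 0.050.
* **A note on IRLS vs OLS.** A bisquare M-estimator differs from OLS by
  a random amount of the order of a few percent of a standard error on
  *any* noisy Gaussian sample; the two only coincide when downweighting
  is inactive. The tests therefore validate the solver against the
  closed-form weighted normal equations (an independent one-step oracle
  in base R) and against closed-form OLS with the tuning constant sent
  to infinity, rather than asserting a false equivalence.

$R^2$ and the omnibus $F$ are reported from the unweighted residuals at
the robust coefficients ($R^2$ clamped to $[0,1]$; a robust $R^2$ is not
uniquely defined and this is the declared convention).

## Cluster-based correction across the grid

With 2500 correlated tests, single-bin thresholds are meaningless; the
package adapts the neuroimaging cluster approach. Bins with two-sided
$p < 0.05$ for the predictor of interest are grouped into 8-connected
clusters; each cluster's mass is the sum of squared predictor $t$
values over its bins (the regressor-specific 1-df $F$ — chosen over the
omnibus model $F$, which mixes in the nuisance terms and is
miscalibrated under resampling with a robust fit).

The null distribution of the *maximum* cluster mass is built by a
Freedman-Lane-style scheme: remove the fitted effect of the predictor
of interest (keeping the nuisance fits), refit the reduced model, and in
each of `n_boot` resamples reattach row-resampled reduced-model
residuals to the nuisance fit — one shared index vector across all bins,
which preserves the spatial correlation of the grid — then refit the
full robust model and cluster as above. A cluster is significant when
its corrected $p$ (the fraction of null maxima at or above its mass) is
at most $\alpha$; the reference analysis scale is 1000 resamples at
$\alpha = 0.05$.

Rows are **permuted** by default rather than drawn with replacement.
This was a measured decision, not a stylistic one: with a shared
with-replacement index, duplicated rows reduce the effective degrees of
freedom of *every* bin simultaneously, inflating all robust $t$
statistics together; the resulting max-mass null is stochastically far
above the true sampling distribution and drives the family-wise error
rate to zero. The permutation variant of the same H0 construction
measures at the nominal rate (the acceptance suite simulates 200
global-null cohorts and requires the FWER in $[0.02, 0.08]$). The
with-replacement draw remains available via `resample = "bootstrap"`
with its conservatism documented.

Pairwise residual correlations across far-apart bins (the
pace-of-aging analysis) are instead corrected with Benjamini-Hochberg
FDR at $\alpha = 0.001$.

## Accelerated and decelerated aging

For bins surviving the age-model cluster correction, responses are
residualized in two steps — gender first, then age (plain least squares;
with correlated covariates this is deliberately *not* identical to the
joint-model residual) — keeping each bin's age-slope sign. A
participant displaced from the cohort age trend *in the direction* of
the trend is read as behaviorally accelerated at that bin. For every
pair of significant bins more than 5 bins apart (Chebyshev distance by
default, Euclidean available), the residual correlation is computed;
pairs passing FDR and $R^2 > 0.1$ are labelled **consistent** when
$\mathrm{sign}(r)\,\mathrm{sign}(\beta_i)\,\mathrm{sign}(\beta_j) = +1$
(the same individuals are accelerated at both bins) and
**inconsistent** otherwise. The triple product makes the label invariant
to flipping the sign of either bin's response, which the tests assert.

## The synthetic cohort: what it emulates, and what a green test means

No participant data ships with the package; every pipeline stage is
exercised on a generator whose defaults state the world the analyses
expect:

* ages from a bimodal mixture with modes at 25 and 63 years (sd 7 and
  8, equal weights), truncated to 16-86; 62.5% female (coded 2);
* 14 recording days; expected sessions/day 20 at age 16, declining 0.1
  per year (so a usage-age effect exists for the covariate models);
  touches per session $2 + \mathrm{NB}(\mu = 15, \text{size} = 2)$;
* within-session intervals from a two-component log-normal mixture
  anchored at the two headline time scales, $\log_{10}$ means 2.0
  (~100 ms) and 3.6 (~4 s), sds 0.25 and 0.35; the fast-component
  weight is $w(\text{age}) = \mathrm{clip}(0.75 - 0.006\,(\text{age} -
  16),\ 0.05,\ 0.95)$, so older participants lose mass at short
  intervals and gain it at long ones;
* a latent standard-normal pace factor per participant loads
  $+\lambda$ on the fast weight and $-\lambda$ on the slow-component
  mean ($\lambda = 0.05$), planting correlated residual structure with
  both consistent and inconsistent far pairs;
* app labels follow a two-state social/non-social Markov chain (switch
  probability 0.1) over small app pools, giving the Social and
  Transition variants something to select;
* cognitive trial records carry linear age effects (e.g. choice RT
  450 ms + 2 ms/year, $d'$ 2.8 − 0.015/year) with log-normal trial
  noise.

`planted_truth()` derives the expected per-bin age-effect and
pace-loading signs analytically: consecutive intervals are independent
draws, so the expected grid is the outer product of the KDE-smoothed
mixture marginal with itself, and signs come from numeric
differentiation. Expected pair labels follow the same triple-product
rule as the estimator.

What the generator does **not** emulate: circadian and weekly rhythm,
app-specific interval signatures, heavy-tailed session lengths,
autocorrelated intervals within a session, missing data, or any attempt
to match the real cohort's coefficient values. A green acceptance run
establishes that the pipeline recovers effects *of the planted form at
realistic sizes* — not that it reproduces any published cohort-level
estimate, which would require the original data.

## Scales, budgets, and degenerate inputs

* The family-wise error simulation runs 200 null cohorts with 200
  resamples each (the reference analysis uses 1000 resamples; the
  criterion scale is stated by the build contract and keeps the suite
  inside its runtime budget).
* Parameter recovery runs one fixed-seed cohort of $n = 150$; pair-label
  recovery runs 20 seeds of $n = 50$ with 100 resamples.
* Degenerate inputs are contracts, not crashes: single-touch sessions
  yield empty interval sequences; zero eligible pairs is an explicit
  error at `compute_jid` but a skip-with-audit in the pipeline; an empty
  significance mask yields an empty residual matrix and pair table; a
  cohort below `min_n = 20` refuses to run a regression.

## Known limitations

* The cluster-forming threshold ($p < 0.05$ per bin), connectivity (8),
  and cluster statistic (sum of $t^2$) are declared defaults; the
  published description defers to a toolbox whose exact settings are
  not printed, so exact numerical agreement with it is not claimed.
* Two-step residualization is kept faithful to the described procedure
  even where a joint fit would be statistically cleaner.
* The robust $t$ relies on an asymptotic covariance; at $n \ll 60$ its
  calibration degrades (the package guards regressions at $n \ge 20$).
* Cross-sectional residual pairs say nothing about longitudinal
  within-person aging rates.
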