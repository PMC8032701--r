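---
title: "Modeling minute-epoch activity counts with zero-inflated Poisson hidden semi-Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling minute-epoch activity counts with zero-inflated Poisson hidden semi-Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actihsmm)
```

## The problem

Collar- or wrist-worn accelerometers integrate movement into one
nonnegative integer count per epoch (one minute here), producing more than
one hundred thousand observations per subject over a multi-week trial. In
sedentary animals such as domestic cats with osteoarthritis-associated
pain, these series are dominated by zeros (often more than 70% of minutes)
with a heavy right tail from short bursts of intense activity, and activity
patterns vary widely between subjects. Averaging counts within treatment
periods throws away exactly the structure in which a treatment effect may
live: an analgesic can increase high-intensity activity and improve rest at
the same time, leaving the mean almost unchanged.

`actihsmm` models the minute-by-minute counts directly. Latent states
represent unobserved activity types (resting, walking, running, ...),
ordered by mean count intensity; the time spent in a state follows an
explicit dwell-time distribution rather than the geometric dwell implied by
an ordinary hidden Markov chain; and treatment and environment covariates
act on the emission intensities, the dwell lengths, and the between-state
transition preferences. Each subject gets its own maximum-likelihood fit;
a second least-squares stage turns the subject-level coefficients into
population-level treatment-effect estimates with
heteroskedasticity-robust standard errors.

## The model

For subject $i$ at minute $t$, let $S^t \in \{1,\dots,M\}$ be the latent
state, $Y^t$ the count, $X^t \in \mathbb{R}^q$ the treatment covariates and
$Z^t \in \mathbb{R}^p$ the environmental covariates (night and weekend
indicators in the motivating crossover design).

**Emissions.** State 1, the resting state, emits zero-inflated Poisson
counts; states $2,\dots,M$ emit plain Poisson counts:
$$\log\frac{p(z,x)}{1-p(z,x)} = b_{0,0} + b_{1,0}'x + \gamma_0' z,\qquad
\log \lambda(m,z,x) = b_{0,m} + b_{1,m}'x + \gamma_m' z .$$
The constraints $b_{0,m+1} > b_{0,m}$, $b_{1,m+1} \ge b_{1,m}$,
$\gamma_{m+1} \ge \gamma_m$ (componentwise) make
$\lambda(m+1,z,x) > \lambda(m,z,x)$ for every binary covariate pattern,
so states are intensity-ordered within a subject and comparable by rank
across subjects. The displayed Poisson factor is $e^{-\lambda}$; the
likelihood would not normalize otherwise.

**Dwell times.** The dwell in state $m$ follows a discretized accelerated
failure time model: with base distribution function $F_m$ (Weibull by
default, gamma selectable; both closed under time rescaling) and
acceleration $a = \exp(c_m'x + \eta_m'z)$, the probability of an
integer dwell $v$ is proportional to $F_m(a(v{+}1)) - F_m(av)$,
truncation-renormalized to $v \in \{1,\dots,D_{\max}\}$. The finite
support cap `D_max` (default 360 minutes) realizes the finite-support
assumption of the asymptotic theory while comfortably exceeding plausible
single-behaviour bouts at minute resolution. The AFT regression carries no
intercept — it is absorbed by the free scale parameter. Covariates are
evaluated at the minute the dwell begins.

**Transitions.** Conditional on leaving state $m$, the destination
$l \neq m$ follows a multinomial logit with logits $d_{m,l}'x +
\varrho_{m,l}'z$. Self-transitions are structurally excluded — state
persistence belongs to the dwell model — and the lowest-index allowed
destination is the reference category with coefficients fixed at zero,
which makes the softmax identifiable. Note the model has no transition
intercepts: under $x = z = 0$ the destination distribution is uniform over
the allowed states, so long-run occupancy under a null covariate pattern
is governed by the mean dwell lengths.

**Initial distribution.** $\delta$ is held fixed at uniform during
optimization: with a single sequence per subject it contributes one dwell's
worth of information and estimating it from decoded state frequencies would
be circular. An optional one-step re-estimation from the decoded path is
available after fitting (`fit_subject(..., reestimate_delta = TRUE)`).

**Censoring.** The final dwell of a series is right-censored through the
dwell survivor function $S_m(v) = \sum_{u \ge v} r_m(u)$; ignoring this
biases the duration parameters near the end of the observation window.

## Likelihood, fitting, decoding

The exact likelihood is computed by an explicit-duration forward recursion
over dwell segmentations, entirely in log space with streaming
log-sum-exp, at cost $O(T \cdot M \cdot (M + D_{\max}))$. Quantities that
depend only on the covariate pattern — dwell pmfs, transition rows,
emission intensities — are computed once per unique $(x, z)$ pattern,
which is what makes minute-resolution fitting cheap for categorical
designs. The recursion is verified in the test suite against a brute-force
enumeration of every dwell segmentation on small instances.

Subject fitting maximizes this likelihood directly (no EM) with BFGS over
an unconstrained reparameterization: centered log-ratios for $\delta$,
a first value plus exponential-map increments for the strictly increasing
intercepts, squared increments for the nondecreasing slope columns
(equality representable, matching the $>$ versus $\ge$ in the constraints),
and log maps for shapes and scales. The exact gradient is computed by
reverse-mode differentiation of the recursion — the adjoint weights are the
posterior expectations of the dwell, transition, and emission sufficient
statistics — and is checked against finite differences in the tests. Two
numerical details matter in practice: per-minute log emission
probabilities are floored at a finite sentinel so that cumulative sums
remain well-defined when a probability underflows, and the squared-increment
coordinates are initialized slightly off zero because their gradient
vanishes identically at zero (the states' slopes could otherwise never
separate). Multiple seeded restarts (default 5; the first start is a
moment-based initialization from the zero fraction and positive-count
quantiles) guard against local optima; relative tolerance `1e-6`, at most
2000 iterations, all configurable through `fit_control()`. For $M = 1$ the
dwell and transition blocks drop out of the likelihood and are excluded
from optimization (they would be flat directions). The number of states is
chosen by BIC ($-2\ell + j\log T$), ties toward the smaller model.

Viterbi decoding is the max-product analogue of the same recursion, with
ties broken toward the lower state index and then the shorter dwell.
Model adequacy is checked by simulating a long trajectory from the fitted
model (observed covariate schedule recycled, default ten times the series
length) and comparing marginal count quantiles with the data — under a
sparse regime both are zero up to high percentiles, so the informative
comparison is in the upper tail.

## Two-stage population inference

Subject-level coefficient estimates (treatment effects on log intensity,
zero-inflation odds, log dwell acceleration, transition logits) are
regressed on baseline covariates $W$ by ordinary least squares. Because the
stacked design is $I \otimes [1, W]$, the regression decomposes
componentwise. The covariance uses the raw-residual sandwich
$(X'X)^{-1} X'\mathrm{diag}(e^2) X (X'X)^{-1}$ (HC0), matching the
asymptotic form of the two-stage estimator in the regime $n/T \to 0$ where
first-stage estimation error is asymptotically negligible but residual
heteroskedasticity is not; no small-sample correction is applied by
default. Baseline covariates are centered so that each intercept estimates
the average treatment effect over the sample; centering changes only the
intercept, never slopes or their standard errors (a tested invariant).
Wald $z$ tests against the standard normal give the reported p-values,
unadjusted across states. Percent effect sizes are reported as
$100\times$ the log-scale coefficient by default (the small-coefficient
convention); the exact $100(e^{\beta}-1)$ form is available behind an
explicit flag and never silently substituted.

Cross-subject state alignment relies entirely on the monotone-intensity
constraint — states are comparable by rank — with no post-hoc label
matching.

## The synthetic crossover generator

No public minute-epoch crossover dataset of this kind exists, so the
package ships a generator that produces data with the statistical
structure the model assumes: an 11-week two-period crossover (2-week
baseline, 3-week blinded period, 3-week washout, 3-week crossed period) at
1440 one-minute epochs per day, a night window of 18:00–06:00 (the night
definition is a convention, configurable), weekends on days 6–7 of each
week, alternating treatment sequences, and subject-specific parameters
drawn around population truths. Treatment-effect heterogeneity uses
additive noise on the first state plus mean-corrected squared-increment
innovations above it, so $E(b_{1,m}\,|\,W)$ is exactly linear in $W$ while
every draw respects the ordering constraint; remaining heterogeneity is
applied on the unconstrained scale and mapped back, which guarantees
validity by construction. Per-subject seeds are derived as master seed plus
subject index.

The shipped six-state truth (`default_paper_like_truth()`) is calibrated to
the qualitative fingerprints of sparse animal actigraphy: about 79% zero
minutes at the default seed (so the marginal 75th percentile is zero),
decoded resting-state occupancy near 84%, intensities spanning three orders
of magnitude (0.25 to 100 expected counts per minute), long rests (mean
dwell near an hour, longer at night) against short active bouts, and a
night/day contrast in zeros, intensities, dwell lengths, and
return-to-rest transitions. Because the transition model has no intercepts,
the day-time embedded chain is uniform and occupancy shares are driven by
mean dwells; with minute-resolution dwells bounded below by one minute, the
rarest states cannot be pushed below roughly 2% occupancy — the generator
reproduces the dominant-resting pattern, not any specific published
occupancy table. What the generator deliberately does not emulate:
accelerometer hardware artifacts (saturation, non-wear), behavioural
autocorrelation beyond the semi-Markov structure, or treatment-by-night
interactions. Tests passing on these data validate the estimation
machinery under the model's own assumptions; they cannot certify fit to
any particular real population.

## Validation studies shipped with the package

The acceptance suite (and `scripts/acceptance.R`) runs four simulation
studies whose sizes were chosen to give informative checks at desk scale:

* **Recovery** — a two-state fit at $T = 50{,}000$ minutes with intensities
  $(e^0, e^{\ln 5})$ recovers both intensity intercepts within three
  Monte-Carlo standard errors over six replicates, and the intercept RMSE
  decreases monotonically over $T \in \{5{,}000;\, 20{,}000;\, 80{,}000\}$.
* **BIC selection** — on well-separated two-state data (intensity ratio 10,
  $T = 20{,}000$), BIC over candidates $\{1,2,3\}$ picks $M = 2$ in at
  least 80% of 20 seeded replicates.
* **Two-stage coverage** — `coverage_simulation()`: $n = 40$ subjects,
  $T = 5{,}000$ minutes, 100 replicates; nominal 95% Wald intervals for the
  average treatment effect cover the truth with empirical coverage in
  $[0.88, 0.99]$. The truth places the state-2 effect increment
  (`Omega0 = (0.05, 0.20)`) far from the monotonicity boundary relative to
  first-stage noise and separates the intensities $(0.8, 15)$ well. Both
  choices matter: when the increment is comparable to the first-stage
  sampling noise the constrained MLE truncates at the boundary, and when
  states overlap, minutes leak between them and bias the smaller state's
  effect toward the larger one — both are finite-sample departures from
  the interior-point asymptotic regime the intervals are derived in, and
  both were visible in coverage when the study was designed. Within a
  replicate, later subjects are warm-started from the first subject's
  optimum; the start point does not change the maximizer and cuts compute.
* **Calibration** — the shipped six-state truth, ten subjects over two
  weeks, reproduces the sparse-activity fingerprints listed above at a
  fixed seed.

## Known limitations

* Transition covariate effects are weakly identified when jumps are rare
  (long dwells); the generator's defaults keep dwell means modest in the
  studies that estimate them.
* The squared-increment parameterization makes slope equality
  representable but puts a curvature zero at exact equality; the fitter's
  off-zero initialization handles this, yet data truly at the boundary
  will converge slowly along those coordinates.
* With a single sequence per subject, $\delta$ is essentially
  unidentified; it is fixed uniform (see above) and its one-dwell
  contribution is absorbed by the censored-likelihood structure.
* Continuous covariates are supported but defeat the per-pattern
  precomputation (every minute becomes its own pattern); the engine is
  designed for categorical designs such as treatment/night/weekend
  indicators.
* p-values are reported unadjusted across states, matching the reporting
  convention of the motivating analysis.
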