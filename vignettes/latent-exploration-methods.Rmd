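---
title: "Methods: latent reinforcement learning for vocal pitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent reinforcement learning for vocal pitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`latentRL` decomposes a trial-by-trial vocal pitch series
$p_t$ (one value per rendition of a target syllable or utterance) into

$$p_t = \epsilon_t + b_t + V_t,$$

where

* $\epsilon_t \sim \mathcal N(0, \sigma_\epsilon^2)$ is **motor
  exploration** — the ideal, iid Gaussian component injected by a latent
  learner (biologically, the songbird anterior forebrain pathway);
* $b_t$ is the **learned pitch bias**, updated by a leaky correlation of
  exploration with reward,
  $$b_t = (1-\delta)\,b_{t-1} + \alpha R_{t-1}\epsilon_{t-1} + \eta_t,$$
  with learning rate $\alpha$, leak $\delta \in (0,1)$, reward $R_t$
  ($0$ on escapes, $-1$ on white-noise hits by default) and a small iid
  noise $\eta_t$ that makes the bias a proper stochastic state;
* $V_t = p^* + c_t + d_t + o_t$ collects the **non-reinforced repertoire**:
  a stable target pitch $p^*$, a slow colored drift
  $c_t = (1-\tau)c_{t-1} + \varepsilon_t$, a piecewise-linear circadian
  pattern $d_t$ on equal-count time-of-day nodes, and singing-history
  offsets $o_t = O_{1+n_h(t)}$ indexed by the number of renditions in the
  preceding $x$ seconds (clipped at $N_h - 1$).

The update rule is the policy-gradient ascent direction of an expected
reward penalized by a quadratic bias cost, so the learner is a
policy-gradient reinforcement learner that exploits only its own
exploration — not the repertoire fluctuations. The deliberate
non-optimality of $V_t$ is the scientific point: if the decomposition is
right, the estimated explorations should look like ideal white Gaussian
noise (self-consistency), and removing the exploration channel should
mimic lesions of the motor-learning pathway.

## State-space formulation and fitting

Both fitting stages are linear Gaussian state-space models
$y_t = H x_t + g_t$, $x_t = A_t x_{t-1} + a_t + q_t$ with scalar
observation, diagonal process covariance and a fixed, very small
observation variance $G = 10^{-4}\,\mathrm{Hz}^2$; the exploration is
estimated as the smoothed disturbance of its process-noise channel, not
as observation noise.

* **Baseline** (no feedback): bias clamped at zero, state
  $[c_t,\; p^* + d_t + o_t + \epsilon_t]$, with the structural
  coefficients $(p^* + D_j)$ and $O_k$ multiplying a known input vector
  of circadian hat weights and history indicators.
* **Feedback**: state $[b_t,\; c_t,\; p^* + d_t + o_t + \epsilon_t]$,
  repertoire frozen at the baseline estimates, and a time-varying
  transition whose reward-dependent entries recover
  $\epsilon_{t-1} = (x_{t-1})_3 - (p^* + d_{t-1} + o_{t-1})$ so the bias
  row implements $\alpha R_{t-1}\epsilon_{t-1}$ exactly. The lagged
  deterministic repertoire value enters as a known input; this is the
  only construction in which the printed transition entries reproduce
  the scalar learning rule, which the test suite verifies sample-path
  exactly.

Fitting is EM (E-step: fixed-interval smoothing with exact lag-one
cross-covariances from $\mathrm{Cov}(x_{t-1}, x_t \mid y) = J_{t-1}P^s_t$;
M-step: closed-form expected-complete-data updates, with minimum-norm
least squares for the structural coefficients, whose hat-weight and
indicator blocks are each partitions of unity and hence exactly
collinear by one dimension). Two numerical choices matter:

* **Fixed priors.** The state prior at the first rendition is held fixed
  across EM iterations (diffuse for the baseline; for feedback, the bias
  prior variance $\sigma_\eta^2/(1-(1-\delta)^2)$ is evaluated at the
  initial guess and then frozen). This keeps the EM likelihood trace
  exactly non-decreasing, which the tests assert at tolerance $10^{-8}$.
* **Direct-likelihood polish.** EM approaches the optimum along a very
  flat ridge in $(\alpha, \delta)$ (likelihood gains of order
  $10^{-4}$ nats per iteration), so a relative-tolerance stop leaves the
  learning rate near its initialization. After EM stops, the package
  therefore maximizes the exact filter likelihood directly
  (Nelder–Mead over $\log\delta, \log\alpha, \log\sigma_\eta^2,
  \log\sigma_\epsilon^2$, and analogously over the baseline noise
  parameters with the structural coefficients held fixed), starting from
  the EM point so the likelihood can only improve.

Pitch is mean-centered internally (no rescaling: with $G$ fixed in
$\mathrm{Hz}^2$, dividing by $p^*$ would silently change the assumed
observation noise); parameters are reported in Hz. The zero-average
constraint on the circadian pattern is applied by re-centering after the
fit, and the same constraint is applied to the history offsets — both
blocks are confounded with $p^*$ by exactly one dimension, so the
rendition-weighted means of $d_t$ and $o_t$ are absorbed into $p^*$.

Model selection for the history horizon $x$ and quantization $N_h$ uses
BIC with $k = 3 + (N_D + 1) + N_h - 1$ effective parameters (the $-1$
removes the exact collinearity). Defaults $N_D = 6$, $x = 2$ s,
$N_h = 5$; birds that never produce more than $k$ renditions in the
window get $N_h = k + 1$.

## Diagnostics

Self-consistency is checked on the estimated explorations
$\hat\epsilon_t$ with two surrogate-calibrated components:

* **Whiteness**: mutual average information (MAI) between the series and
  its lag-$k$ copy over 50 log-spaced integer lags in $[1, 1000]$
  (deduplicated, lags above $T/2$ dropped). The estimator is an
  equal-frequency histogram on rank-transformed pairs with
  $\lceil T^{1/3}\rceil$ bins per axis, making the profile invariant to
  monotone transforms. The reference level is the mean MAI of three
  Gaussian iid surrogates of the same length; the band is $\pm 3$
  surrogate SDs. Note that with $\sim 41$ distinct lags a perfectly
  white series trips a 3-SD band at one lag in roughly 10% of
  realizations — single-lag excursions at that rate are chance, not
  structure. Normalized profiles map the reference to 0 and the pitch
  series' own lag-1 MAI to 1.
* **Gaussianity**: skewness and excess kurtosis of $\hat\epsilon_t$
  against their analytic standard errors ($\sqrt{6/T}$, $\sqrt{24/T}$).
  A lag-MAI statistic cannot, even in principle, flag exploration that
  is iid but non-Gaussian (the lagged dependence structure is unchanged
  by the marginal), so this component carries that half of the
  self-consistency argument.

Further diagnostics: MS2D (mean squared second difference of the
per-day-resampled bias; smoothness of the learned policy), smoothed
RMSE between simulated and observed trajectories (trailing 50-rendition
running means), normalized final pitch (last feedback day's mean pitch
on a scale where the first-day threshold is 0 and the last-day threshold
is 1 — always normalized by the *observed* experiment's thresholds when
scoring model simulations), and a pooled-SD standardized mean difference
(`dprime`; the pooled-SD convention is a documented choice).

## The simulator and the synthetic-bird generator

`simulate_experiment()` iterates the generative recursions forward with
hit determination against an adaptive threshold and supports the
threshold policies `daily_quantile(q)` (previous day's $q$-quantile,
linear-interpolation convention), `running_median(w)` and `human_auto`
(running median re-adjusted when the escape rate over the last $w$
renditions leaves $[0.05, 0.80]$). All replicates reuse the singing
schedule, as when emulating a real bird's timestamps.

The synthetic-bird presets emulate the structure of real conditioning
data at study scale. Defaults, chosen once:

* target pitch $p^* = 1000$ Hz; exploration SD 1% of $p^*$
  ($\sigma_\epsilon^2 = 100\,\mathrm{Hz}^2$); $\alpha = 0.003$,
  $\delta = 3\times 10^{-4}$ (typical best-fit values);
* $\sigma_\eta^2 = 10^{-4}\,\mathrm{Hz}^2$: small enough that the
  baseline bias wander (stationary SD
  $\sqrt{\sigma_\eta^2 / (2\delta)} \approx 0.4$ Hz) is negligible,
  which is required for consistency with clamping $b_t = 0$ when
  fitting baseline data. (A larger value — e.g. wander of several Hz —
  would rival the daily learning signal and make
  $(\alpha, \delta, \sigma_\eta)$ jointly unidentifiable.)
* colored drift $\tau = 0.01$,
  $\sigma_\varepsilon^2 = 0.46\,\mathrm{Hz}^2$ (stationary variance
  $\approx 23\,\mathrm{Hz}^2$); circadian amplitude and history offsets
  calibrated so the realized variance shares of colored, circadian and
  history components sit near the reported cohort averages
  (roughly 14%, 11% and 15% of baseline variance, with exploration
  around 61%); the first-to-second-motif history drop is 5.3 Hz;
* morning-heavy singing: per-day rendition counts uniform on
  [300, 1500], song-bout onsets Beta(1.3, 2.0) over a 14-h day, bouts
  of $1 + \mathrm{Poisson}(3)$ renditions at 0.4–1.1 s gaps (so history
  counts in a 2-s window actually span their range);
* the true circadian pattern is piecewise-linear on the equal-count
  nodes of the generated schedule — i.e., the generative model lives in
  the same basis class the fit uses, exactly as when simulating from
  fitted parameters.

Falsification presets replace the exploration sampler with a bimodal
Gaussian mixture (`non_gaussian_exploration`; components at
$\pm 0.9\sigma$) or an AR(1) process with coefficient 0.9
(`non_iid_exploration`), both variance-matched; `lesion_pair` emits a
baseline pair in which the "post-lesion" trajectory is generated with
the exploration channel deleted.

What the generator does **not** emulate: multi-timescale or non-AR(1)
drift, overnight consolidation of the bias into the repertoire,
social-context modulation of variability, measurement artifacts of
pitch extraction. Two consequences observed in testing are worth
recording as genuine limitations of desk-scale validation rather than
implementation defects:

* **Learning-rate recovery is plug-in limited.** With the repertoire
  (or even just $\tau, \sigma_\varepsilon^2$) fixed at the truth, the
  feedback stage recovers $\alpha$ to within ~10%. With $\tau$ frozen
  at a 3-day baseline estimate — whose error is irreducibly large,
  since a drift with 100-rendition correlation time offers only a few
  dozen effective samples per day — the mismatch in the colored channel
  is absorbed by the reward-driven bias (closed-loop rewards correlate
  with the drift) and $\alpha$, $\delta$ inflate together at a
  near-constant ratio, by up to a factor ~3 in unlucky seeds.
  $\sigma_\epsilon$ and the exploration fraction are unaffected
  (recovered within ±10% and ±0.1 in every seed tested).
* **A classical fit whitens AR(1) worlds.** When all repertoire
  structure beyond $p^*$ is exactly AR(1), the classical model's freely
  refitted bias channel (itself AR(1)) absorbs the drift, so its
  residual explorations are nearly as white at lag 1 as the latent
  fit's. The classical model still fails in the two robust ways: its
  bias is an order of magnitude rougher (MS2D), and simulations from
  its fitted parameters undershoot the learned pitch shift.

## Problem sizes

Tests and the acceptance script run on simulated experiments of 2–5
baseline days and 6–22 feedback days at 300–1500 renditions/day
(up to ~20,000 feedback renditions for parameter recovery; ~7,000–11,000
for diagnostics and model comparisons), with 6–20 synthetic birds per
claim and 6–8 simulation replicates per bird where trajectories are
scored against observations. These sizes were chosen so each claim is
measured at the scale where its effect is expected to be resolvable.

## Known limitations

* Contingency reversals are fitted per contiguous block; no
  cross-reversal coupling.
* The history window does not cross midnight, and its left endpoint is
  open — conventions documented at the function level.
* The colored-noise recursion runs per rendition with no overnight
  rescaling of $\tau$.
* $\sigma_\eta^2$ recovery is reported but not asserted anywhere; it is
  weakly identified jointly with $(\alpha, \delta)$.
* The MAI estimator is a histogram estimator chosen for robustness and
  transform-invariance; absolute MAI values are estimator-specific, and
  all conclusions are drawn relative to the surrogate reference.
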