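---
title: "Continuous-time GLMs for submillisecond neural coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time GLMs for submillisecond neural coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppglm)
```

## The model

`ppglm` infers functional coupling between spiking neurons at the timescale of
synaptic dynamics (well below one millisecond). One postsynaptic neuron's
spike train is modelled as an inhomogeneous Poisson process whose conditional
intensity at time $t$ is

$$\lambda(t) = \Phi\Big(w_0 + \sum_{x_s \in X(t,H)} w_{n_s}^\top
\phi(t - t_s)\Big),$$

where $X(t,H)$ is the set of population spikes in the history window
$[t-H, t)$ (default $H = 5$ ms), $\phi$ maps a lag onto $J$ temporal basis
functions, $w_n \in \mathbb{R}^J$ is the coupling-weight block for
presynaptic neuron $n$, $w_0$ is an intercept on the log-rate scale, and
$\Phi$ is a nonnegative, increasing, convex inverse link (exponential by
default; softplus is supported on the Monte Carlo path). The coupling filter
of neuron $n$ is $f_n(\tau) = w_n^\top \phi(\tau)$, a log-rate modulation as
a function of lag.

The continuous-time log-likelihood is

$$\log p(y \mid X, w) = \sum_{k=1}^{K} \log \lambda(y_k) -
\int_0^T \lambda(t)\,dt .$$

The first (spike) term is always computed exactly from the spike times. The
second term, the cumulative intensity function (CIF), is analytically
intractable under a nonlinearity, and the package's two estimators differ
only in how they treat it:

* **MC** (`fit_mc()`): stratified Monte Carlo. $[0,T]$ is split into $M$
  equal strata with one uniform draw per stratum, and
  $(T/M)\sum_m \lambda(\tau_m)$ is an unbiased CIF estimate with lower
  variance than plain uniform sampling. A fresh sample is drawn at every
  Adam iteration.
* **PA-c** (`fit_pa_c()`): a second-order polynomial
  $a_2 x^2 + a_1 x + a_0$ is fitted to $\Phi$ over a data-driven range, which
  makes the CIF quadratic in $w$:
  $a_2 w^\top M w + a_1 m^\top w + T a_0$. The sufficient statistics $k$
  (spike features), $m$ (single basis integrals scaled by spike counts) and
  $M$ (pairwise basis integrals accumulated over all spike pairs within the
  interaction window) are computed once, and the penalized maximizer
  $w^* = (2 a_2 M + 2\beta I)^{-1}(k - a_1 m)$ is a single linear solve.
* **hybrid** (`fit_hybrid()`): PA-c provides the closed-form warm start, MC
  refines it — the closed form's speed with the sampler's accuracy.

Two binned baselines are included for comparison: a full-gradient Newton fit
of the classical discrete GLM (`fit_discrete_full()`), its mini-batch
stochastic-gradient variant (`fit_discrete_batched()`), and the discrete
polynomial approximation PA-d (`fit_pa_d()`), which accumulates
$\sum_t x_t$, $\sum_t y_t x_t$, $\sum_t x_t x_t^\top$ in streaming chunks so
the design matrix is never materialized.

## The temporal basis

The default basis (`gl_basis()`) is a set of generalized Laguerre polynomials
under a gamma-like envelope,

$$\phi_n(\tau) = L_n^{(\alpha)}(c\,\tau_{ms})\,(c\,\tau_{ms})^{\alpha/2}
e^{-c\,\tau_{ms}/2},$$

with shape $\alpha = 2$ and scale $c = 1.5$ per millisecond. The lag variable
is measured in milliseconds internally — that is the scale on which these
parameter values are meaningful — and converted at the module boundary; all
public interfaces use seconds. These functions rise fast and decay slowly
like postsynaptic potentials, are orthogonal on $[0,\infty)$ under the
induced weight (`gl_orthogonality_check()` verifies the Gram matrix is
diagonal with entries $\Gamma(n+\alpha+1)/n!/c$), and — the property the PA
estimator exploits — their single and pairwise integrals reduce to lower
incomplete gamma evaluations when $\alpha$ is a nonnegative even integer.
For other $\alpha$, and for the raised cosine comparison basis
(`rc_basis()`), integrals fall back to adaptive quadrature with absolute
tolerance below 1e-10; the closed forms are tested against that same
quadrature to 1e-8 across $J \le 7$ and a 50-point lag grid.

```{r basis, fig.width = 6, fig.height = 3}
autoplot(gl_basis(3, window = 0.005))
```

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `window` ($H$) | 0.005 | s | history window; synaptic effects at 4–6 ms |
| `n_basis` ($J$) | 3 | — | GL basis size; configurable 2–7 |
| `alpha`, `scale` | 2, 1.5 | —, 1/ms | GL shape and rise-time scale |
| `M` | `ceiling(100 T)` | — | one stratum per 10 ms of recording |
| `n_iter`, `learning_rate` | 2000, 0.01 | — | Adam settings for MC |
| `ridge` ($\beta$) | 0 (simulation), 1000 (screening) | — | excludes the intercept |
| approximation range | 2.5–97.5 pctl (sim) or mean ± width/2 (data) | Hz | `select_range()` |

The intercept $w_0$ is carried as an explicit extra covariate (the
sufficient statistics gain one slot holding $T$, $K$ and the cross terms
$S_n \bar\phi$): without it the model cannot represent a baseline rate.
The history window is half-open — a spike begins to influence the rate
strictly after its own time — so self-history is causal and $\phi(0)$ never
enters a neuron's own spike term.

## The synthetic-data generator

`simulate_all_to_one()` reproduces the package's reference protocol: seven
presynaptic neurons fire as independent homogeneous Poisson processes (5 Hz
each; a package choice, exposed in the arguments) and one postsynaptic
neuron (3 Hz baseline) receives them through ground-truth coupling filters.
Ground truth is deliberately *outside* the fitting span: each filter is a
mixture of 100 log-spaced raised cosine bumps (`make_filters()`), with a
unimodal gamma-like coefficient profile peaking at a random monosynaptic
latency plus 15% smooth variability, a random sign, and a sup-norm drawn
from [0.5, 2] (bounded well under 3 to keep simulated rates stable). Because
the postsynaptic neuron has no self-coupling, its intensity is a
deterministic function of the presynaptic spikes, and the sampler is *exact*:
thinning with piecewise-constant upper bounds computed from the positive
parts of the active filters on segments delimited by filter onsets/offsets.
A fine-grid Bernoulli sampler (`method = "grid"`) is retained purely as a
cross-check; the two agree on target rates within sampling error, and
time-rescaled inter-spike intervals under the true intensity pass
Kolmogorov–Smirnov tests against Exp(1) across seeds.

`simulate_network()` extends this to a sparsely connected population
(directed Erdős–Rényi mask, 10% by default, no self-edges) simulated jointly
by Ogata thinning on the superposed process. Stability is guarded by scaling
each neuron's incoming filters so the excitatory mass proxy (baseline rate
times positive filter integral, summed over inputs) stays below 0.8.

What the generator does *not* emulate: refractoriness and self-history
dynamics, common-input correlations from unobserved neurons, non-Poisson
count dispersion, and nonstationary baselines. Tests passing on this
generator therefore demonstrate estimator correctness under the model class,
not robustness to those real-data features.

## Numerical choices

* **Linear-predictor cap.** $u$ is capped at 30 before the exp link during
  optimization (a rate of $10^{13}$ Hz); `pp_rate()` warns when the cap is
  active.
* **Degenerate likelihood directions.** With the exp link, weight directions
  whose features never coincide with target spikes have their maximum at
  infinity (the likelihood is monotone but flat in the tail). Convergence
  comparisons between estimators are therefore run with a small common ridge,
  which makes the optimum unique; `solve_map()` reports rank deficiency at
  $\beta = 0$ and suggests a positive ridge.
* **Right-edge truncation.** The statistics $m$ and $M$ integrate each
  spike's basis functions over the full window even when it extends past
  $T$, exactly as their defining integrals are written. The exact-identity
  tests use edge-free instances (no spikes within $H$ of $T$); on real data
  the effect is $O(\text{rate} \cdot H / T)$.
* **Bin-center convention.** The discrete designs evaluate the basis at
  bin-center lags. The resulting $O(\Delta)$ error is deliberately left in
  place — it is the discretization effect the continuous estimators remove —
  and shows up as the monotone convergence of binned fits to the continuous
  reference at $\Delta \in \{1, 0.5, 0.1\}$ ms.
* **Deterministic continuous reference.** `fit_continuous_ref()` maximizes
  the exact-spike-term likelihood with a midpoint-rule CIF (0.02–0.05 ms) by
  damped Newton iterations; it is the converged continuous optimum that the
  binned fits approach, and the gradient oracle for the gradient-variance
  experiment uses the same midpoint construction (its $O(dt^2)$ bias is
  orders below the stochastic errors being measured).
* **"Chebyshev" coefficients.** The quadratic surrogate minimizes mean
  squared error on a dense grid (10^4 points), which is the stated criterion;
  a Chebyshev-weighted projection differs negligibly over these ranges.
* **Degenerate approximation ranges.** A percentile range narrower than 0.1
  on the linear-predictor scale (e.g. a constant-rate simulation) is widened
  symmetrically to width 0.1.
* **Ties and self-pairs in $M$.** The symmetric quadratic form counts each
  unordered spike pair twice off-diagonal and same-spike pairs once on the
  diagonal; pair enumeration is a two-pointer sweep over the globally
  time-sorted spikes, linear in the number of in-window pairs.

## Design choices that were genuinely open

* **Range-width cross-validation.** For recorded data the approximation
  width is chosen from {3,…,7} Hz by held-out log-likelihood on a time
  split (first 80% fit, last 20% scored with a fixed stratified sample);
  `select_range_cv()`.
* **CCG normalization.** Cross-correlograms are compared to filters as
  empirical log-rate modulations,
  $\log(\text{count}/(S_{pre} \cdot \text{bin} \cdot \bar r_{post}))$, so
  both live on the linear-predictor scale; empty bins are floored at half a
  count. Raw counts remain available on the `ccg` object.
* **Onset definition.** Filter onset for the screening delay is the earliest
  lag exceeding 10% of the peak (configurable); the peak window for putative
  excitatory connections is 0.3–2.5 ms, the monosynaptic latency range.
* **Amplitude threshold.** Default is twice the median absolute filter value
  across all screened pairs — a robust null scale — since no principled
  amplitude rule exists without calibration data.
* **Mini-batch baseline.** The batched discrete comparator is plain
  mini-batch SGD with unbiased scaling, not a variance-reduced optimizer:
  the gradient-variance comparison needs a representative stochastic
  baseline, not a faithful reimplementation of any particular one.

## Problem sizes used by the tests and the acceptance script

Unit tests run on 2–4 presynaptic neurons and 2–40 s recordings. The
recovery protocol uses the 8-neuron all-to-one simulation at $T = 10$ and
$T = 1000$ s with 400 MC iterations; the gradient-variance experiment uses
$T = 100$ s with a budget of $10^4$ sample points or bins and 100 resamples
per checkpoint; the unbiasedness check uses $10^4$ resamples. These sizes
were chosen so the full suite completes in a few minutes while leaving each
comparison with a comfortable signal margin.

## Known limitations

* The PA path is derived for the exponential link only; `link = "softplus"`
  is accepted by the MC estimator alone and rejected at configuration time
  for PA.
* Pure R inner loops put the practical ceiling around a few hundred
  thousand spikes per fit; the design favours vectorized window queries
  (binary search plus pair expansion) over per-spike loops.
* The sequential network simulator is meant for moderate populations
  (tens of neurons at tens of seconds) — its event loop is exact but not
  vectorizable.
* No external stimulus covariates: the model is restricted to spike
  history.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
sim <- simulate_all_to_one(duration = 100, seed = 1)
pop <- sim$population
pop

b <- gl_basis(3, window = 0.005)
fit <- fit_hybrid(pop, sim$truth$target, b,
                  range = list(mode = "mean_centered", width_hz = 4),
                  control = mc_control(n_iter = 200, seed = 1))
glance(fit)
filter_mse(coupling_filters(fit), coupling_filters(sim))
autoplot(fit)
```
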