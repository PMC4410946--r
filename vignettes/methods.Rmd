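---
title: "Models and methods behind nmminvert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmminvert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nmminvert simulates a single-node neural mass model and infers its
parameters from a noisy voltage trace with four gradient-free MCMC
samplers. This vignette records the model, the numerical choices, the
design decisions that were genuinely open, and the limitations we know
about. Everything quantitative stated here is computed by the package's
test suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The forward model

Three coupled neural populations — spiny-stellate cells (`x1`), inhibitory
interneurons (`x7`) and pyramidal cells (`x9`, the observable voltage) —
interact through four connection strengths `g1..g4`. Each population's
membrane behaves as a critically damped second-order filter with rate
constant `tau_e` or `tau_i` (ms) and maximum post-synaptic amplitude `h_e`
or `h_i` (mV); `x4, x5, x6, x8` are the corresponding velocity states, and
`x2, x3` accumulate the excitatory and inhibitory drive to the pyramidal
population, whose voltage integrates their difference: `x9' = x5 - x6`.
Population output passes through the centred firing-rate sigmoid
`S(v) = 1/(1 + exp(-0.56 v)) - 0.5`, and a Heaviside step of magnitude `u`
(switched on at `t = 0`, right-continuous) drives the spiny-stellate
population. Simulations start from the zero (resting) state, the natural
initial condition of the input-free system.

**Delays.** The coupling terms involve delayed states `x(t - delta)` with a
single intrinsic delay `delta` (ms). The model treats these with a
first-order expansion, `x(t - delta) ~ x(t) - delta * x'(t)`, where the
derivative of each delayed state (`x1`, `x7`, `x9`) is available exactly
from the position/velocity structure (`x1' = x4`, `x7' = x8`,
`x9' = x5 - x6`), so the right-hand side stays an explicit nine-state ODE
and fixed points are unaffected (velocities vanish there). A
`delay_mode = "none"` switch exists for sensitivity analysis; the two modes
agree as `delta -> 0` (tested). A genuine delay-differential treatment is
out of scope; for the reference delay (`delta ~ 12` ms, twice `tau_e`) the
expansion is a modelling choice, not an approximation guarantee, and it is
the *destabilising* reading: a pseudospectral analysis of the true delay
characteristic equation classifies fewer prior draws unstable than the
expansion does.

**Integration.** deSolve's `"bdf"` method (implicit
backward-differentiation formulas with dense Newton solves), absolute and
relative tolerances both `1e-3`. Solver failures, non-finite output, or any
state exceeding `1e6` are reported as an integration failure, which the
likelihood maps to `-Inf`. In practice failures are rare: every drive on
the right-hand side is a bounded sigmoid plus stable linear damping, so
trajectories cannot blow up — dynamical instability manifests as a
sustained oscillation, not divergence. Halving the tolerances moves the
endpoint by less than the coarser tolerance (tested). The default output
grid is 100 equally spaced points on [0, 100] ms, long enough to capture
the step response given `tau_e ~ 5.8` ms and `tau_i ~ 7.8` ms; both window
and grid are `sim_control()` fields.

## Priors, likelihood and tempering

Each of the ten parameters carries an independent Gamma prior with the
shapes and scales of `nmm_prior()`; the log joint is the sum of the
Gaussian log likelihood of the observed voltage (noise covariance
`sigma^2 I`) and the ten Gamma log densities, with `-Inf` outside the
positive orthant or on integration failure. The noise level is never part
of the model spec: synthetic datasets default to
`sigma = 0.1 * sd(noiseless x9)` — an SNR-matched rule that keeps inference
comparably hard at any window length — and record the value used in their
JSON sidecar. The tempered density at inverse temperature `beta` is
`beta * log_lik + log_prior`, affine in `beta`, recovering the prior at
`beta = 0` and the posterior at `beta = 1`.

## Stability analysis and the prior census

Because `x9` purely integrates `x5 - x6`, the combination `x9 - x2 + x3` is
conserved along every trajectory. Two consequences shape the stability
module:

* fixed points form a one-dimensional family, so the solver replaces the
  (identically satisfied) ninth steady-state equation with the conservation
  constraint pinned at its zero-initial-state value, making the system
  square and regular; it is solved by Levenberg–Marquardt (a trust-region
  method, `minpack.lm`) with the analytic Jacobian, from the origin with up
  to five deterministic perturbed restarts;
* the Jacobian at any fixed point has one *exact* zero eigenvalue (the
  tangent of that family). Classifying stability on the full 9x9 spectrum
  would amount to reading the sign of floating-point noise. The package
  therefore reduces to the flow on the invariant 8-dimensional subspace
  (an exact elimination, not a tolerance) and calls the model stable
  exactly when the largest real part of the reduced spectrum is negative.

The classification is validated against an integration oracle: integrate to
2000 ms and ask whether the trajectory settles onto the fixed point or
keeps oscillating (late-window amplitude above 0.05). Agreement is 95%+
over 200 prior draws, with disagreements confined to eigenvalues within
about 2e-3 of the imaginary axis, where a 2000 ms window simply cannot
tell a slow decay from a slow growth.

`instability_census()` draws from the prior and reports the unstable
fraction under the sustained input `u` (the regime in which data are
observed; an `input = "off"` switch exists). At the reference prior the
census gives roughly 24% unstable — substantial, and enough to exercise
every sampler's handling of hostile parameter regions, though we note that
alternative readings of the delay operator move this figure anywhere from
0% to 26%, so it should be read as a property of this package's delay
convention rather than of "the" model.

## The samplers

All four samplers share one target contract (log joint, with the
likelihood and prior parts cached separately for tempering) and treat
out-of-support or failed-integration proposals as density zero. Chains are
initialised from prior draws, redrawn until the log joint is finite.

**Random-walk Metropolis** proposes from a diagonal Gaussian with
per-parameter standard deviation `0.1 *` the prior standard deviation
(`sqrt(shape) * scale`) — the prior supplies the only scale information
available before sampling — and accepts with probability
`min(1, exp(delta log density))`.

**Slice sampling** performs one univariate stepping-out/shrinkage update
per coordinate per sweep, in canonical parameter order; one sweep is one
recorded sample. Levels are drawn in log space
(`log f(theta) + log U(0,1)`), brackets start at one prior standard
deviation and expand at most 20 times (budget split uniformly between the
two directions), and shrinkage contracts toward the current point, which
always remains in the slice — the update cannot stall.

**Adaptive Metropolis** proposes from `N(theta, lambda * Sigma)` and tunes
`lambda` (scalar scale), `mu` and `Sigma` by stochastic approximation
during the first `n_adapt` iterations only, then freezes — continued
adaptation would use the past infinitely often and break the Markov
property. The mean and covariance use the equal-weight schedule
`gamma_i = 1/i` (they are the running mean and covariance of the visited
states, with `Sigma` using the pre-update mean), and the covariance update
engages after a 100-iteration settling window so that the initial
barely-moving chain cannot collapse `Sigma` toward a rank-one matrix. The
scale uses the faster schedule `gamma = 1/sqrt(i)` on
`log lambda <- log lambda + gamma * (alpha - 0.23)` with the *realized*
acceptance probability `alpha = min(1, ratio)` (lower variance than the
0/1 indicator). This two-timescale split is the standard stochastic
approximation remedy for the scale/covariance coupling: with a single
`1/i` schedule the scale can only relax like `k^-0.1` after the early
transient and the acceptance rate is still near 12% after tens of
thousands of iterations, whereas the split settles at the 23% target
within about 2000 iterations (tested). Proposals are centred at the
current state — centring at the running mean would break Metropolis
symmetry — with a `center = "mean"` switch retained for sensitivity
analysis. On the neural-mass posterior the initial `Sigma` is the identity
in prior-standardised coordinates (`diag(prior sd^2)`), consistent with the
other samplers' prior-scaled defaults; a raw-unit identity is
incommensurate with parameter scales spanning two orders of magnitude.

**Population MCMC** runs `N = 4` chains against tempered targets with
inverse temperatures `beta_i = (1 - i/N)^p`, `i = 0..N-1` (power schedule,
`p = 5`) or `beta_i = 1 - i/N` (uniform). Indexing from zero keeps the
`beta = 1` cold chain — the only chain whose samples are retained — in both
schedules; the hottest chain sits near (not at) the prior. Every
`k_swap = 10` iterations one pair of chains is chosen uniformly at random
among all pairs and their states are exchanged with probability
`min(1, exp((beta_i - beta_j) (loglik_j - loglik_i)))`; cached likelihood
values travel with the states. Each chain owns an RNG stream derived from
the master seed (swap decisions use a separate stream), so results are
independent of how chain updates are interleaved and adding a chain never
perturbs another; with `N = 1` the sampler is bitwise identical to plain
random-walk Metropolis (tested).

**Run protocol.** The reference protocol collects 2000 samples, discards
the first 600 as burn-in, and (for the adaptive sampler) adapts during the
first 300; retained draws are samples 601–2000, i.e. 1400 posterior
samples. Each sampler in a benchmark gets a seed derived by stable string
hashing from the master seed, so the set of configurations can change
without perturbing any individual run.

## Diagnostics

Autocorrelations use the biased `1/R` normalisation, computed by FFT so
full-lag-range estimates on long chains stay affordable. The effective
sample size truncates `ESS = R / (1 + 2 sum rho_q)` by the initial
monotone sequence rule: adjacent-lag pair sums are kept while positive and
forced non-increasing by running minima; the estimate is clamped to
`[1, R]`, and a direct enumeration oracle checks the truncation logic on
short series. The efficiency report gives per-parameter ESS on retained
draws, the wall time of the sampling loop only, `wall time / min ESS` (the
cost of the worst-mixing parameter, the headline comparison metric), and
the l2 error — the Euclidean norm of (prediction at the posterior-mean
parameters minus the *observed* data), since all samplers are compared on
one fixed dataset; a `reference = "truth"` flag switches to the noiseless
trajectory for simulation studies. Degenerate (stuck) parameter series are
reported with ESS 1.

## Identifiability: what inversion can and cannot recover

The likelihood is *exactly* invariant under two scaling families:
`(g1, g2, g3, u) -> (g1, g2, g3, u)/c` with `h_e -> c h_e`, and
`g4 -> g4/k` with `h_i -> k h_i` — the amplitudes enter the equations only
through these products. Individual parameters in those groups are
therefore located along the ridges by the prior alone. Consequences,
verified by the test suite: predicted voltage is recovered well (small l2
error) and most parameters lie within three posterior standard deviations
of the generating values, but the amplitude-group parameters can sit
beyond that — the reference truth's `h_i` lies 1.9 prior standard
deviations above the prior mean, and shrinking the noise makes
per-parameter recovery *worse*, because the posterior collapses onto the
prior-anchored ridge. Function-space recovery, not per-parameter recovery,
is the meaningful criterion for this model.

## Problem sizes and what the tests show

The test suite runs the analytic-target checks at 6,000–30,000 iterations
(moment recovery within three conservative Monte-Carlo standard errors
computed from the worst-parameter ESS), the census at 10,000 draws, the
oracle comparison at 200 draws, and the sampler benchmark at the full
2000/600/300 protocol aggregated over five seeds. These sizes are the
package's reference study; all are arguments, so larger replications are
one call away. The synthetic generator emulates the reference experiment —
a step-driven deterministic trajectory plus i.i.d. Gaussian observation
noise on the pyramidal voltage only. It does not emulate coloured or
state-dependent noise, model mismatch (data generated by a different
model), multi-node coupling, or real EEG/MEG preprocessing, so passing
tests demonstrate correctness of the machinery under the stated model, not
robustness to the ways real recordings violate it.

## Known limitations

* The delay expansion is first-order in a delay that is not small; its
  stability census differs materially from a true delay-system analysis.
* The uniform temperature ladder outperforms the power-law ladder on this
  unimodal posterior (the power ladder's hottest chains wander the prior
  and their states rarely survive a swap into the cold chain); the power
  ladder's advantages are expected on multimodal targets and for model
  evidence work, which is out of scope here.
* Wall-time comparisons depend on hardware and are reported but never
  asserted.
* The noise covariance is `sigma^2 I` with known `sigma`; estimating
  `sigma` or structured noise is out of scope.
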