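---
title: "Competition dynamics of balanced spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition dynamics of balanced spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Cortical networks in the balanced state keep excitation and inhibition in
close register: the mean input to a neuron stays below threshold and spiking
is driven by fluctuations. When such a network contains two structurally
identical subnetworks whose *within*-population synapses are scaled by a
factor `w` relative to the *across*-population synapses, the two populations
compete. Depending on `w`, the network shows three collective regimes:

* **ER (equal rate)** — both populations fire at the same stationary rate;
* **WLC (winnerless competition)** — activity alternates stochastically
  between the populations, with nearly instantaneous switches;
* **WTA (winner-take-all)** — one population permanently dominates.

`lvcomp` implements the whole chain from microscopic simulation to the
low-dimensional model that explains this behaviour: a generalized
Lotka-Volterra competition system driven by the network's own
(multiplicative) intrinsic noise.

## Network model

Two scenarios of three subnetworks are built (`network_spec()`,
`assemble_network()`):

* **EEI** — two excitatory populations of 2000 neurons each plus one shared
  inhibitory population of 1000; within-population EPSPs are `w*J` with
  `w >= 1`, all other EPSPs `J = 0.1` mV, IPSPs `-g*J` with `g = 6`.
* **EII** — one excitatory population of 4000 neurons plus two competing
  inhibitory populations of 500; within-population IPSPs are `-w*g*J` with
  `0 <= w <= 1` (weaker self-inhibition means stronger effective
  cooperation), all other IPSPs `-g*J`.

Excitatory-pathway connection fractions are `eps = 0.1` of the target or
source population; inhibitory-related pathways use `p*eps = 0.3`. All
degrees are **exact**: every neuron has precisely the same in- and
out-degree per block. The graph is drawn with a fixed-degree variant of the
configuration model — each of the nine blocks starts from a deterministic
circulant pattern meeting the margins and is then randomized by
margin-preserving checkerboard swaps (10 successful swaps per edge), with no
self- or multi-edges. Swap randomization approximates, but does not
guarantee, a uniform draw over all margin-satisfying matrices; exactness of
the margins is asserted for every seed, uniformity only in distributional
Monte-Carlo checks.

Neurons are leaky integrate-and-fire units (`simulate_lif()`):
membrane time constant 20 ms, threshold 20 mV, reset 10 mV, delta synapses
with a one-step delay (`t_d = dt = 0.1` ms) and a constant DC drive. The
membrane equation is linear between spikes, so each step uses the exact
exponential propagator; all threshold crossings within a step fire together.
The 270 pA drive is converted to millivolts with an assumed capacitance of
250 pF (the standard value of the simulators used in this field), giving
21.6 mV — deliberately suprathreshold, so the network is active, while
recurrent inhibition keeps the mean potential below threshold
(fluctuation-driven regime). The DC drive is noiseless by design: every
stochastic feature of the rates is then *intrinsic* network noise.

Three parameters are not dictated by the physics and are explicit knobs:

| parameter | default | why |
|---|---|---|
| `t_ref` | 2 ms | the standard integrate-and-fire refractory period of NEST-family simulators; irrelevant at the few-Hz balanced rates, but it bounds the winner's rate in the WTA regime (with `t_ref = 0` the winner population has no rate ceiling and the strong-coupling regime degenerates into pathological fast alternation) |
| `C_m` | 250 pF | only used for the pA-to-mV conversion; the drive can be set directly in mV |
| initial potentials | uniform on `[0, theta)` | symmetric deterministic initialization would freeze the rate difference at zero; a uniform draw breaks symmetry while remaining agnostic |

Because random initial potentials are partially synchronous, every spiking
run begins with a population transient; `run_pipeline()` discards the first
second (`burn_in_ms = 1000`) before analysis.

## Dimensionality reduction

Population spike counts in 10 ms bins give the population rates `X1`,
`X2`, `Y` in spikes/ms (kHz), where `X1`, `X2` are the competing pair and
`Y` the shared population (`bin_rates()`). Too-small bins distort the
statistics, too-large bins the dynamics; 10 ms resolves the switches while
keeping per-bin counts in the tens. The series are smoothed with a
Savitzky-Golay filter of window 21 samples and polynomial order 4
(`savgol_smooth()`), which preserves local extrema; at the boundaries the
filter's own transient rows (a polynomial fit to the partial window) are
used, so output length equals input length and the edge treatment is
deterministic. The sum/difference coordinates are

```
C = (X1 + X2)/2,   D = (X1 - X2)/2
```

an exactly invertible rotation (`to_cd()`): `C` is the joint activity level,
`D` the competition coordinate.

## The Lotka-Volterra reduction

A first-order perturbation of the stationary low-rate response
`r = ((theta - mu)/(sigma tau sqrt(pi))) exp(-(theta - mu)^2 / sigma^2)`
(`stationary_rate()`) around an operating point yields rate dynamics of
generalized Lotka-Volterra form with an additive constant
(`lv_rhs()`):

```
dX1/dt = k X1 (w X1 + X2 + k1 Y + k0) + h0     (and symmetrically for X2)
```

with `k1 = -p*g` for the EEI scenario and all signs flipped (negative `k`)
for EII. The bracket is the mean-field drive of `coupling_matrix()`;
`k0` collects effective couplings and the DC drive, and `h0` is a small
floor term that lets an extinguished population recover. The defaults
`k = 1 ms`, `k0 = 22 kHz`, `h0 = 0.5 kHz` are the mean-field operating
point used throughout; they are configurable, and how they emerge from the
derivation is not re-derived here — they are treated as given constants.
The exponent of the stationary-rate formula is implemented exactly as the
derivation states it; the textbook diffusion result has an additional
factor 2 in the denominator, and a `variant = "diffusion"` flag exposes it
for sensitivity checks. Note that `r0` (the Poisson-equivalent external
rate) enters the mean input only, never the variance: a DC current carries
no shot noise.

In sum/difference coordinates (`cd_rhs()`):

```
dC/dt = k C ((w+1) C + k1 Y + k0) + k (w-1) D^2 + h0
dD/dt = k D (2 w C + k1 Y + k0)
```

Two algebraic points deserve emphasis, both covered by exact tests:

* the cross-term in `dC/dt` is quadratic, `k (w-1) D^2`; a linear `D` term
  is inconsistent with the coordinate substitution (direct expansion shows
  the `D`-linear parts cancel);
* `k0` sits inside the `k(...)` bracket. With the default `k = 1 ms` the
  alternative placement outside the bracket is numerically identical.

`D = 0` is always an invariant manifold: equal rates are always a solution;
the question is their stability.

The shared rate is *slaved* to the competing pair. Empirically (and this is
the package's central fit, `fit_Y()` / `fit_competition()`):

```
Y = a + b C + f D^2
```

with `a` in kHz, `b` dimensionless, `f` in ms. Ordinary least squares on
the smoothed series estimates `(a, b, f)`; a chi-square goodness-of-fit
statistic on the standardized residuals (20 equal-probability normal bins,
17 degrees of freedom) accompanies the fit. When `D` carries no variance
(a perfectly homogeneous run), `f` is unidentifiable and reported as `NA`
rather than a number. Identifiability is worth knowing about even away from
that corner: during dwells `D^2` and `C` move together, so the standard
error of `f` is an order of magnitude larger than that of `b` at equal
sample size — the homogeneous `w = 1` point, where `|D|` is small, needs
longer runs (60 s rather than 20 s) for a stable `f`.

## Fixed points, stability, energy

Substituting the linear part of the slaved rate (`f ≈ 0`) closes the system
in two dimensions (`simplified2d_rhs()`, with `pg = -k1`):

* interior equilibrium `((pg a - k0)/(w + 1 - pg b)) (1, 1)` — the saddle
  in the switching regime;
* axis equilibria `(0, (pg a - k0)/(w - pg b/2))` and its mirror — the two
  attractors.

`fixed_points()` evaluates the closed forms, polishes them by Newton
iteration and classifies each point by the eigenvalues of the analytic
Jacobian; eigenvalues below `1e-9` in magnitude are reported as *marginal*,
never silently classified. At `w = 1` the two bracket functions coincide
and the field degenerates to an entire line of equilibria,
`(1 - pg b/2)(X1 + X2) = pg a - k0`: the function then returns the single
diagonal representative, labelled marginal — this is the unique equal-rate
state of the homogeneous network, and `w` is revealed as a genuine
bifurcation parameter.

For the pure competition system (`h0 = 0`, `f = 0`) an energy-like
Lyapunov function exists (`lyapunov_spec()`, `V()`, `Vdot()`):

```
V = (pg a - k0)(X1 + X2) + ((pg b)/2 - w)(X1^2 + X2^2)/2 + ((pg b)/2 - 1) X1 X2
```

Its derivative along the flow is exactly
`-k X1 B1^2 - k X2 B2^2 <= 0`, where `B_i` are the field brackets. The
factor 1/2 on the diagonal quadratic terms is essential: it is what makes
the chain-rule derivative collapse to the negative-semidefinite form (it
follows from the generic Lotka-Volterra energy recipe with identity
response functions), and without it the attractor-saddle energy difference
would come out negative at the standard operating point. The constructors
refuse nonzero `h0` or `f` instead of ignoring them. `energy_barrier()`
sweeps `w` at fixed `(a, b)` — the fit coefficients are in reality weak
functions of `w`, but the sweep isolates the geometric effect — and
reports `V(saddle) - V(attractor)`; where the two-attractor configuration
does not exist (e.g. `w = 1`) the barrier is undefined (`NA`), not zero.
The barrier grows quickly with `w`, which is the qualitative explanation
for dwell times growing faster than exponentially and for the eventual
WTA regime.

## Empirical state-space reconstruction

From the smoothed series, normalized first-order differences (forward
difference over one bin; a centered variant is available) estimate the
rate derivatives (`estimate_derivatives()`). Binning the states on a 30x30
grid over the occupied range and averaging the derivatives per bin gives
the empirical flow (`estimate_flow()`); bins with fewer than 5 samples are
flagged unusable and never interpolated. Zero contours of the binned mean
derivatives (marching squares, `empirical_nullclines()`) are the empirical
nullclines; on surrogate data from the closed two-dimensional system they
lie within one grid cell of the analytic nullclines.

The *noise* analysis (`noise_variance()`) computes the per-bin variance of
the residual (derivative minus local mean drift). Samples with
`|X1 - X2| <= 1` kHz (twice the 0.5 kHz exclusion threshold) are excluded:
switch transits pass near the saddle and inflate the local variance there.
A multiplicative-noise system shows residual variance growing with the
rate itself; an additive one is flat. `noise_state_correlation()`
summarizes this as the Spearman rank correlation between bin coordinate
and bin variance. Two estimator properties matter when interpreting it on
surrogates and are deliberate design points rather than defects:

* at 10 ms sampling of a millisecond-scale field, forward differences mix
  within-bin drift curvature into the residual; the discrimination test
  therefore samples the surrogate at its native integration step;
* the reflecting boundary at rate zero makes even planted *additive* noise
  effectively state-dependent near the axes, so the additive-flatness
  check is run at an interior (equal-rate) operating point where the
  boundary is never touched. Because a single realization's Spearman rho
  over ~500 usable bins has sampling deviation ~0.05, flatness is asserted
  on the mean over three seeded realizations.

## Switching statistics

`detect_switches()` uses a hysteresis rule on the smoothed competition
coordinate: having exceeded `+h`, a switch is counted when `D` next falls
below `-h` (and vice versa), with `h = 0.5` kHz — the same scale as the
saddle-exclusion threshold. Chatter inside the band produces no events,
and the censored first and last epochs are excluded from dwell statistics.
The empirical survivor function, its log-linear regression `R^2` and the
maximum-likelihood exponential fit (`survivor()`, `fit_exponential()`)
quantify how memoryless the switching is; in the WLC regime the dwell
times are exponential to good approximation, the signature of
noise-driven barrier escape. `classify_regime()` maps a run to ER (never
leaves the band), WTA (leaves it, never switches) or WLC (switches); the
label is necessarily duration-dependent — a WLC process observed for less
than one mean dwell looks like WTA — so the observation time is reported
with it, and `sweep_w()` takes a majority over seeds.

## The surrogate generator

`integrate_sde()` integrates the reduction as a stochastic differential
equation (Euler-Maruyama, step 0.1 ms, output subsampled to the 10 ms
analysis grid by default) with the shared rate slaved through the
quadratic relation. Noise is independent per dimension, either additive
(`sigma = eta`) or multiplicative (`sigma = eta X`); rates reflect at
zero, keeping the generator in the meaningful domain (absorption would
kill the competition). Deterministic runs switch to a classical RK4 step
so they double as reference trajectories (agreement with an adaptive
solver to better than `1e-6`). `generate_dataset()` plants parameter sets
for each regime: the standard two-attractor point `w = 2.5` with
multiplicative `eta = 0.42` for WLC — the amplitude was fixed once so the
surrogate dwell-time scale (~1.2 s) matches the spiking network at the
same operating point — `w = 0.8` (single interior attractor) with weak
noise for ER, and `w = 3.0` with weak noise for WTA. The slaved `Y` is
exact up to a small observation noise (default 0.01 kHz).

What the surrogates emulate: metastable switching between two attractors,
state-dependent noise, the quadratic slaved-rate relation, the 10-ms
sampling of the analysis pipeline. What they do not emulate: spike-count
(shot) noise in the binned rates, the correlation structure the
Savitzky-Golay filter leaves behind, finite-size effects that couple the
noise across populations, or any dependence of `(a, b, f)` on `w`. A test
passing on surrogates therefore validates the estimator machinery, not
the biological realism of the network model; the spiking pipeline is
checked separately against its own operating points.

## Problem sizes and numerical choices

The packaged analyses use full-size networks (5000 neurons, 4.3 million
synapses) simulated for 20 s at the standard switching points; the
homogeneous `w = 1` fit is pooled over five independent 60 s realizations
and the EII fit over three 20 s realizations, because the weakly
identified `f` needs far more data than `a` and `b` (its seed-to-seed
scatter in a single short equal-rate run is of the same order as the
coefficient itself); surrogate checks use 100-400 s of SDE time. Key numerical
choices, in one place:

* exact exponential propagator per 0.1 ms step; delays as a one-step ring
  buffer; simultaneous crossings fire together;
* degrees from connection fractions must be integers — fractional degrees
  are an error, never silently rounded;
* one master seed per run; child seeds for the nine blocks and the
  initial potentials are derived deterministically from it, so every
  number in a result bundle is a pure function of the configuration;
* Newton polishing tolerance `1e-12`; marginal-eigenvalue threshold
  `1e-9`; flow bins need 5 samples, variance bins 2 residuals;
* the chi-square fit diagnostic uses 20 equal-probability bins of the
  standardized residuals — the exact binning convention behind the
  original analysis is not recoverable, so the statistic is a diagnostic,
  not a reproduction target.

## Known limitations

* The Lyapunov function is not unique; only the quoted quadratic form is
  implemented, and no quantitative (Kramers-type) escape-rate prediction
  is attempted — the noise is multiplicative, so the barrier picture is
  qualitative.
* The `Y`-dynamics coefficients of the three-dimensional system are never
  assigned: the shared rate is always slaved through its fitted quadratic.
* Uniformity of the configuration-model sampler is approximate (swap
  randomization), though margin exactness is guaranteed.
* The regime boundaries in `w` are sharp in the reduced model but
  duration- and size-dependent in spiking simulations; classification
  near the boundaries is inherently stochastic.
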