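---
title: "Models of gut bacterial load variance in C. elegans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of gut bacterial load variance in C. elegans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
set.seed(1)
```

```{r}
library(gutload)
library(dplyr)
```

Populations of isogenic, age-synchronized *C. elegans* mono-colonized from a
shared inoculum nonetheless show bacterial loads spanning orders of
magnitude across individual worms. `gutload` implements the ladder of
models a quantitative microbiome ecologist would walk through to dissect
that variance: a demographic-noise null model, stationary host
heterogeneity, and two classes of genuinely multistable dynamics, together
with the measurement model needed to compare them against sorter
fluorescence data. Every stage runs on synthetic data with known ground
truth, so the whole pipeline is exercisable — and falsifiable — at desk
scale.

## The null model: colonization, birth, death on a finite gut

The gut offers `V` colonizable sites. With `N` bacteria present and
`E = V - N` sites empty, three reactions fire:

* colonization: an empty site gains a colonist from the environment at
  propensity `c * E` (so `c` is a per-empty-site rate; the per-worm arrival
  rate in an empty gut is `c * V`);
* birth: `b * N * E / V` — division into an empty site, scaled by the empty
  fraction so the deterministic limit is exact;
* death: `d * N`.

The mean occupancy fraction `phi = <N/V>` then obeys

```
dphi/dt = (1 - phi) (b phi + c) - d phi,
```

with migration-free steady state `N* = V (1 - d/b)` when `b > d`. The
package integrates this with a stiff-capable adaptive solver (`lsoda`,
relative tolerance 1e-8, absolute 1e-10 — tight enough that solver error is
negligible against any data considered here), and simulates the reactions
exactly with the Gillespie algorithm in compiled code.

```{r}
rates <- logistic_rates(b = 0.4, c = 0.005, d = 0.1, V = 1000)
snap <- gen_logistic_snapshot(rates, n_worms = 24,
                              times = c(3, 12, 18, 24, 36, 42, 48), seed = 1)
fit <- fit_meanfield(snap, V_fixed = 1000)
tidy(fit)
```

**Fitting and identifiability.** `fit_meanfield()` least-squares the log10
of the integrated mean trajectory against log10 per-time mean loads (means
are taken on raw loads before logging; all-zero time points are dropped;
fluctuations are empirically more symmetric on the log scale, which is why
the fit lives there). Means rather than medians of log load are the fitting
target; medians would discard the information in the heavy upper tail that
dominates CFU counts. Birth and death compensate each other strongly — the
saturation level pins down only `d/b`, and the early rise constrains
`b - d` jointly with `c` — so fits report `b - d` alongside the raw rates,
and the three rates are individually trustworthy only when the sampling
window straddles the growth phase. `V` defaults to the maximum observed
load unless supplied.

**Finite-size caveat.** The mean-field ODE describes the `V -> infinity`
limit. At `V = 1000` the ensemble mean of the stochastic model sits a few
cells *below* the ODE solution in the steepest part of the growth curve (a
standard 1/V fluctuation correction, largest where the variance is
amplified through the logistic nonlinearity). Oracle comparisons between
simulation and ODE are therefore made at time points where that correction
is smaller than the Monte-Carlo standard error of the comparison.

## Host heterogeneity and the three-level likelihood

Stationary host-to-host differences are expressed through
`heterogeneity_spec()`: per-worm birth and colonization rates drawn from
normal distributions truncated at zero (negative draws are rejected and
redrawn, not clipped, to avoid an atom at zero), and optionally a per-worm
carrying capacity resampled with replacement from an empirical pool —
typically the 48-hour loads of the highest-inoculum condition, which is the
closest available estimate of the distribution of realized capacities.

Because the stochastic model has no tractable likelihood, fitting is
simulation-based: loads are discretized into three levels (low / medium /
high, with boundaries assigned to the lower level — the conservative
tie-break when a load lands exactly on a published cut point), per-level
probabilities are estimated from a simulated ensemble, and candidates are
scored by the multinomial negative log-likelihood
`-sum_ij n_ij log P_ij` (natural log). Probability cells the finite
simulation missed are floored at `1 / (2 n_sim)` — a continuity-correction
pseudocount without which a single unvisited level makes the score
infinite — and renormalized per time point. `grid_search_heterogeneous()`
scans a candidate grid, and at the winner simulates `n_rep` datasets of the
data's own size so the data's score can be referred to the model's own
score distribution; a data score above the 97.5th percentile flags the
model as rejected. This absolute goodness-of-fit check is what lets the
heterogeneity model fail honestly rather than merely rank candidates.

## Measurement: the saturating fluorescence map

Sorter fluorescence is a floor- and ceiling-limited proxy for load. The
calibration is `y = a tanh((x - b) / c)` with `x = log10 CFU` and
`y = log10 GFP` (both axes base 10; the `ln` inside the analytic inverse is
just the inverse of tanh). The fitted constants used as synthetic defaults
are `a = 4.00`, `b = 0.884`, `c = 3.064`. The inverse map is defined only
for `|y| < a`; measured fluorescence can exceed the fitted asymptote, so
the inverse clips to `a - 1e-9` with a warning by default. Densities
transform with the Jacobian `(c/a) / (1 - (y/a)^2)`, which compresses the
right-hand side of fluorescence histograms — the mechanism behind their
left skew.

```{r}
map <- calibration_map(a = 4.00, b = 0.884, c = 3.064)
x <- runif(200, 0, 6)
pairs <- data.frame(log_cfu = x,
                    log_gfp = logcfu_to_loggfp(x, map) + rnorm(200, 0, 0.1))
tidy(fit_calibration(pairs))
```

The synthetic measurement model adds what calibration alone does not carry:
an autofluorescence floor (loads under ~100 cells are indistinguishable
from background) and a background draw whose maximum with the mapped signal
gives the reading — autofluorescence masks weak signal rather than adding
to it in log space. The background level (1.4 log-GFP, the map evaluated at
the detection threshold) and its spread (0.2) are fixture choices: the
real autofluorescence distribution is not published, and nothing downstream
is sensitive to it beyond the existence of the floor.

## Mixture summaries and the occupancy proxy

Bimodal log-load distributions are summarized by a two-component Gaussian
mixture fitted in log10-CFU space (`fit_gmm2()`, EM via mclust with
unequal variances, components always reported low/high by mean, variance
floored at 1e-4 to survive duplicated values). The mixture is a summary
statistic, not a partition of worms; the only quantity carried downstream
is the weight of the high mode, tracked over time by `weight_series()` as
the proxy for the probability of occupying the high-load state. Worms with
zero load are excluded by default before logging; an option maps them to
log10(100), the detection-threshold value, and both behaviors are tested.
When every worm sits at one value (e.g. a deterministic initial condition)
the fit is flagged degenerate instead of hanging or inventing structure.

## Two models of multistability

**Explicit state switching.** Each worm-microbe system occupies a low or
high growth state; within a state, log10 load follows a logistic SDE
`dphi = r_s phi (C_s - phi) dt + sqrt(2 D_s) dW`, and the state flips as a
telegraph process with rates `alpha_h` (low to high) and `alpha_l` (high to
low). The master equation gives the closed-form occupancy relaxation

```
P(high, t) = (p0 - p*) exp(-(alpha_h + alpha_l) t) + p*,   p* = alpha_h / (alpha_h + alpha_l),
```

which `fit_switching_rates()` inverts from an occupancy curve by bounded
nonlinear least squares (initial occupancy free by default, since observed
weight series typically include the transient; a flat curve identifies only
the rate ratio and is flagged as such). When switching is slow compared to
within-state relaxation, the stationary load density is the
occupancy-weighted mixture of the two per-state Boltzmann densities
(`switching_stationary_pdf()`, each component normalized by quadrature on
`[0, C_high + 4 sqrt(D_high / r_high)]`).

```{r}
occ <- simulate_telegraph(0.08, 0.02, p0 = 0, n = 5000,
                          times = c(0, 6, 24, 48, 72), seed = 2)
tidy(fit_switching_rates(occ))
```

**Noise convention.** Throughout the package `D` is the Fokker-Planck
diffusion coefficient: the noise term integrates as `sqrt(2 D dt)` per
Euler-Maruyama step, so that the stationary density is exactly
`exp(-U/D)`, the Kramers prefactors take their textbook form, and the
curvature-variance relation `K = D / sigma^2` holds. This is the unique
convention under which the stationary-density, escape-rate and
noise-estimation formulas are mutually consistent, and it is enforced by
the package's round-trip and histogram tests rather than by notation.

**Switching discretization.** State flips are per-step Bernoulli events
with probability `alpha * dt` (the first-order discretization); an
`"exact"` mode uses `1 - exp(-alpha dt)`, the exact per-step marginal, and
an exact interval-transition sampler (`simulate_telegraph()`) serves as the
oracle for occupancy statistics. A guard rejects `dt` with
`max(alpha) * dt > 0.1`. Log-load is reflected at zero: loads below one
cell are not meaningful on the log scale, and reflection implements a
zero-flux boundary consistent with the truncated stationary density.

**Multiwell potential.** Alternatively, multistability is intrinsic to the
load dynamics: `dphi = -U'(phi) dt + sqrt(2 D) dW` with a polynomial `U`.
Two modes require order >= 4; order 6 additionally captures unequal well
widths, and on the same data the order-6 fit can never have a larger
weighted residual than the nested order-4 fit. The empirical landscape is
`R(phi) = -ln P(phi)` from a histogram (40 equal-width bins by default;
empty bins are excluded, not imputed — imputation would fabricate barrier
heights exactly where data are absent). Polynomials are fitted to `R` by
count-weighted least squares so sparse tails do not dominate. Since the
histogram determines only `U/D`, the noise amplitude comes from an
independently measured escape rate via the inverted Kramers relation

```
D = 2 pi alpha_l exp(R(C_M) - R(C_H)) / sqrt(R''(C_H) R''(C_M)),
```

after which `U = D * R`. This inversion is exact by construction and is
pinned by a round-trip property test (`kramers_rates()` then
`estimate_noise_D()` returns `D` to 1e-8). Escape rates themselves follow
the overdamped Kramers form `sqrt(K_well K_barrier) / (2 pi) *
exp(-barrier/D)`, an asymptotic result: the package's own first-passage
simulations agree within a factor of two once the barrier exceeds about
3 D, and the formula should not be trusted below that.

```{r}
pot <- poly_potential(c(0.25, 0, -0.5, 0, 0.25), D = 0.0625)  # (phi^2-1)^2/4
fp <- find_fixed_points(pot, support = c(-2, 2))
kramers_rates(pot, fp)
```

Root finding for fixed points uses `polyroot()` on `U'` restricted to the
working support `[min(data) - 1, max(data) + 1]`; a potential is accepted
as bistable only with exactly two minima flanking one interior maximum
there, and a non-confining fitted leading coefficient triggers a warning
rather than silent use.

## What the synthetic data do and do not emulate

The generators reproduce the two experimental designs: destructive CFU
sampling (`gen_logistic_snapshot()`, an independent cohort per time point,
24 worms at 3-48 h matching the published design shape) and longitudinal
fluorescence measurement (`gen_switching_population()`, the same worms
re-measured, including the 150-worm sorted-bin layout), plus the sorter
gates themselves (`gen_sorted_bins()`, low 45-620, high 850-3950
fluorescence units with the gap discarded). Defaults are the study
conditions where stated; the test colonizer (`b = 0.4`, `c = 0.005` per
site, `d = 0.1`, `V = 1000`) is chosen so its growth phase spans the
sampling window, and the switching defaults (`C_low = 2`, `C_high = 5.5`
log10 CFU, `D = 0.2`, `alpha_h = 0.08`, `alpha_l = 0.02` per hour) place
the two states at the observed mode locations with the published transition
rates.

Not emulated: worm loss during handling, sorter optics beyond the
background model, inter-species interactions, host demography, and any
time- or load-dependence of the switching rates. Passing tests therefore
demonstrate that the estimators recover known ground truth under the
models' own assumptions — they cannot certify those assumptions against
real worms, and the snapshot designs simulated here are intrinsically
unable to distinguish the switching model from a high-order potential
model, which is precisely why both are provided.

## Numerical choices, in one place

* ODE: `lsoda`, rtol 1e-8, atol 1e-10; trajectories clamped to [0, 1] only
  against round-off.
* SSA: event cap 1e7 per trajectory; per-worm seeds derived once from the
  master seed so ensembles are order-independent and reproducible.
* Euler-Maruyama: default `dt = 0.01` h; halving `dt` moves stationary
  moments by well under the Monte-Carlo error of any test here; blow-up
  guard at ten support-widths for the potential model.
* Mixture EM: deterministic initialization (so repeated fits agree to
  machine precision); variance floor 1e-4; degenerate fits flagged, never
  silently returned.
* Quadrature: stationary densities normalized with `integrate()` to
  rel.tol 1e-10 after shifting the exponent by the well minimum to avoid
  overflow.
* Problem sizes used by the test-suite oracles: 300-500 Gillespie runs for
  ODE comparisons, 1e5 retained Langevin samples (recorded every 10 h of a
  1e6 h run so basin occupancy is well averaged) for histogram tests,
  200-500 first-passage runs, a 5x5 grid with 240 simulated worms per
  evaluation for the likelihood search.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates the parameter-recovery results from
scratch: it simulates 5,000 two-state chains at the published switching
rates and refits the occupancy relaxation (recovering `alpha_h` and
`alpha_l`), and refits the tanh calibration to 200 noisy synthetic pairs
generated at the published constants (recovering `a`, `b`, `c`). See the
README for the exact invocation.
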