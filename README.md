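# gutload

Stochastic models of gut bacterial load variance in *C. elegans*.

Even isogenic, age-synchronized worms colonized by a single bacterial
isolate from a shared inoculum end up carrying bacterial loads that differ
by orders of magnitude. `gutload` is for quantitative microbiome ecologists
who want to ask *why*, by walking the standard model ladder against
per-worm load data:

1. **Demographic-noise null model** — colonization/birth/death on `V` gut
   sites: reactions `E -> N` at rate `c E`, `N + E -> 2N` at `b N E / V`,
   `N -> E` at `d N`, with mean-field limit
   `dphi/dt = (1 - phi)(b phi + c) - d phi` and migration-free steady state
   `N* = V (1 - d/b)`. Exact Gillespie simulation (Rcpp) plus log-space
   least-squares fitting of the rates to snapshot means.
2. **Stationary host heterogeneity** — per-worm rates drawn from truncated
   normals and/or carrying capacities resampled from data, scored by a
   discretized three-level likelihood `L = -sum n_ij log P_ij` with
   simulation-estimated probabilities, grid search, and an absolute
   goodness-of-fit test (is the data's score inside the model's own score
   distribution?).
3. **Fluorescence calibration** — the saturating sorter map
   `y = a tanh((x - b)/c)` between log10 CFU and log10 GFP, its exact
   inverse, nonlinear least-squares fitting, and the Jacobian change of
   variables for densities.
4. **Mixture summaries** — two-component Gaussian mixtures in log-load
   space; the high-mode weight over time is the occupancy proxy.
5. **Two-state switching model** — per-state logistic SDEs with telegraph
   switching at rates `alpha_h`, `alpha_l`; closed-form occupancy
   relaxation `P(high,t) = (p0 - p*) e^{-(alpha_h+alpha_l) t} + p*` with
   `p* = alpha_h/(alpha_h+alpha_l)`, rate fitting, Euler–Maruyama
   simulation, and the fast-switching stationary density.
6. **Multiwell potential model** — `dphi = -U'(phi) dt + sqrt(2D) dW` with
   polynomial `U` (orders 4/6) fitted to the empirical landscape
   `R = -ln P(phi)`, fixed-point analysis, Kramers escape rates
   `sqrt(K_w K_b)/(2 pi) exp(-dU/D)`, and noise estimation by inverting the
   Kramers relation.

A synthetic-data module generates both experimental designs (destructive
CFU sampling; longitudinal GFP with sorter binning) with known ground
truth, so every estimator in the package is validated against data whose
answer is known.

## Worked example

Simulate a longitudinal population that starts in the low-load state,
summarize each time point with a mixture fit, and recover the switching
rates from the high-mode weights:

```r
library(gutload)

model <- switching_model(r_low = 1, C_low = 2, D_low = 0.2,
                         r_high = 1, C_high = 5.5, D_high = 0.2,
                         alpha_h = 0.08, alpha_l = 0.02)
pop <- gen_switching_population(model, n_worms = 150,
                                times = c(6, 12, 24, 48, 72),
                                p0_high = 0, seed = 7)
ws <- weight_series(pop, seed = 1)
ws[, c("time_h", "p_high", "mu_low", "mu_high")]
#> # A tibble: 5 × 4
#>   time_h p_high mu_low mu_high
#>    <dbl>  <dbl>  <dbl>   <dbl>
#> 1      6  0.433   1.92    5.37
#> 2     12  0.567   2.00    5.51
#> 3     24  0.733   2.12    5.50
#> 4     48  0.78    1.98    5.47
#> 5     72  0.760   2.09    5.50

fit_switching_rates(ws)
#> <switching_fit> alpha_h = 0.07664 /h, alpha_l = 0.02211 /h, p0 = 0.145 (SSE 0.000903)
```

The mixture means sit at the two state capacities (about 2 and 5.5 log10
CFU), the high-mode weight relaxes toward the stationary occupancy
`alpha_h/(alpha_h + alpha_l) = 0.8`, and refitting the occupancy relaxation
recovers the generating rates (0.08 and 0.02 per hour) within the
mixture-estimation noise of a 150-worm population.

Fitted objects have `tidy()`/`glance()` methods, result types have
`autoplot()` methods, and `run_pipeline()` drives the same stages from a
YAML/list config with seed-stamped run logs. See the vignette
(`vignettes/gut-load-models.Rmd`) for the full methods account.

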