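---
title: "Inferring division control from population-level cell-size dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring division control from population-level cell-size dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizedyn)
```

## The problem

Rod-shaped bacteria such as *E. coli* regulate their volume by balancing
elongation against division. Along a batch growth curve the balance shifts:
cells leaving stationary phase swell several-fold within ~2 h, then shrink
back as nutrients deplete. Single-cell tracking can resolve the underlying
division control directly, but many experiments only yield *population*
snapshots: per-cell segmentation measurements at sampling times, OD600
readings, and CFU counts. `sizedyn` implements an inference chain that works
from exactly these population-level observables.

The chain has four stages:

1. **Geometry.** Segmented cells are treated as sphero-cylinders (capsules).
   From projected area $A_p$ and length $L$, the width solves
   $A_p = w(L-w) + \pi (w/2)^2$; then $A = \pi L w$ and
   $V = \pi L w^2/4 - \pi w^3/12$. Artefacts are removed by four strict
   thresholds (width > 0.35 µm, 1.05 µm < L < 10 µm, 1 < L/w < 7,
   $A_p$ > 0.73 µm²) and a per-time-point filter discarding cells more than
   3 log-standard-deviations from the mean log-volume (≈ 99.7 % retained
   under a log-normal size distribution).
2. **Growth.** OD600 curves are fitted in log space to the logistic solution
   $B(t) = B_\max / (1 + e^{-\mu_\max (t - t_s)})$, giving the time-varying
   specific growth rate $\mu(t) = \mu_\max/(1+e^{\mu_\max(t-t_s)})$; a
   Gompertz alternative is provided. During continuous-dilution
   (sustained-growth) windows the rate is frozen at its pre-dilution value.
3. **Size model.** Division is modelled as a jump $s \to s/2$ with hazard
   $k(t)\,\mu(t)\,s$ — an adder-type rule: the hazard per unit of *added*
   volume is exactly $k(t)$. Averaging and closing the moment hierarchy with
   $\langle s^2\rangle \approx \langle s\rangle^2$ gives the mean-size
   equation
   $$\frac{d\langle s\rangle}{dt} = \mu(t)\langle s\rangle -
     k(t)\,\mu(t)\,\frac{\langle s\rangle^2}{2},$$
   a Riccati equation whose fixed point under constant rates is
   $\langle s\rangle = 2/k$.
4. **Inference.** The division coefficient follows a double sigmoid
   $k(t) = k_0 + (k_\max - k_0)\left[\sigma(\lambda(t-t_1^*)) -
   \sigma(\lambda(t-t_2^*))\right]$ with five free parameters, so that $k$
   returns to its basal stationary-phase value at both ends. Parameters are
   fitted by minimising the summed squared *relative* residuals of the
   predicted versus observed mean sizes. A model-free diagnostic,
   `pointwise_k()`, inverts the mean-size equation algebraically:
   $k = 2(\mu\langle s\rangle - d\langle s\rangle/dt)/(\mu\langle s\rangle^2)$.

A companion uncertainty module smooths replicated OD and CFU series on the
log scale and propagates 95 % half-widths into the OD/CFU ratio by the
first-order absolute-sum rule $\Delta z = |\Delta x / y| + |x\,\Delta y/y^2|$,
which is conservative by at most $\sqrt 2$ relative to quadrature.

## Worked example

```{r example, eval = FALSE}
sched <- division_schedule(k0_per_um3 = 2, kmax_per_um3 = 6,
                           lambda_per_h = 3, t1_star_h = 2, t2_star_h = 8)
# overnight (stationary) cells carry the frozen post-plateau size ~2/kmax:
# k relaxes back to k0 only after growth stops, when sizes no longer move
cfg <- sim_config(mu = function(t) logistic_rate(t, t_s = 4, mu_max = 2),
                  schedule = sched, n0 = 300, t_end_h = 10, seed = 1,
                  s0_median_um3 = 0.28, noise_log_sd = 0.05)
sim <- simulate_population(cfg)
obs <- observe(sim)

gf <- fit_growth(growth_curve(obs$od$time_h, obs$od$od600_corrected))
cells <- derive_dimensions(obs$cells)$cells
summ <- summarize_cells(filter_cells(cells)$kept, seed = 1)
fit <- infer_division_dynamics(summ, gf, seed = 1)
fit$schedule
```

## The synthetic-data generator

`simulate_population()` is an exact, event-driven sampler of the
growth-division process: between divisions sizes follow
$s(t) = s(t_0)\,e^{\int\mu}$, and division times are drawn by inverting the
per-cell cumulative hazard against precomputed tables of
$M = \int \mu\,dt$, $v = e^M$ and $K = \int k\,dv$ (the cumulative hazard of
a cell of size $s_0$ at $t_0$ is $(s_0/v(t_0))\,[K(t)-K(t_0)]$). There is no
thinning or time-discretisation error in the division law: under constant
rates the sampled added volumes are *exactly* exponential with mean $1/k$.

Two ensembles are available, and the distinction matters:

* **Lineage mode** (default) follows `n0` independent cells through
  divisions, keeping one daughter each time. This is precisely the jump
  process whose expectation the mean-size equation describes, so it is the
  right oracle for the inference stage. Each lineage carries a weight
  $2^{\text{divisions}}$; weighted totals are unbiased estimators of
  population biomass and count (the many-to-one property).
* **Tree mode** keeps both daughters: the cell count equals `n0` plus the
  number of divisions, total volume is continuous across divisions, and the
  OD-like (total volume) and CFU-like (count) channels are exact. Tree mode
  feeds the OD/CFU ratio analysis, where the ratio is by construction the
  population mean size.

The two ensembles have *different* mean sizes. For binary fission the
snapshot mean converges exactly to $1/k$ (because the population count obeys
$dN/dt = k\mu V$ while $dV/dt = \mu V$), whereas the lineage-ensemble mean
converges to $\approx 1.45/k$. Neither equals the closed-equation fixed
point $2/k$: with a size-proportional hazard the added volumes are
exponential, the stationary size CV is ≈ 0.62, and the closure
$\langle s^2\rangle \approx \langle s\rangle^2$ under-counts division by the
factor $1 + \mathrm{CV}^2 \approx 1.4$. We verified the *exact* stationarity
identity $\langle s^2\rangle = (2/k)\langle s\rangle$ to well under 1 % in
simulation, which pins the blame on the closure, not the sampler.

Consequences worth knowing before trusting a fit:

* Fitting the closed mean-size equation to simulated (or real) snapshot
  means yields an **effective** coefficient
  $\hat k(t) \approx k(t)\,[1 + \mathrm{CV}^2(t)]$, biased upward by
  ~25–40 % relative to the generating hazard coefficient. The *shape* of
  $\hat k(t)$ — when division control tightens and relaxes — is recovered
  well; its absolute scale inherits the closure bias. Comparisons between
  conditions analysed the same way remain meaningful.
* Once growth arrests ($\mu \approx 0$), sizes freeze and the data carry no
  information about $k(t)$; the fitted curve there is an extrapolation of
  the double-sigmoid family. `fit_division_schedule()` flags an
  unidentified $t_2^*$ when it falls beyond the data window, and
  `pointwise_k()` refuses to report values where $\mu$ is below 0.02 h⁻¹
  (configurable), since the algebraic inversion degenerates to 0/0.

What the generator does **not** emulate: proliferation-biased sampling of a
real microscope snapshot (a random field of view over-represents
fast-dividing clones; the lineage ensemble samples lineages uniformly),
asymmetric division, cell death and lysis, OD saturation and scattering
non-linearity, and diauxic multi-phase growth. Passing the recovery tests
therefore shows the chain is internally consistent for the stated process,
not that these real-data effects are harmless.

## Numerical choices

* **ODE integration**: `deSolve::lsoda`, relative tolerance 1e-8 (1e-6
  inside the schedule-fit loop, where accuracy is noise-limited); halving
  tolerances moves solutions by < 1e-6 relative.
* **Curve fitting**: Nelder–Mead with deterministic multi-starts — 8
  data-driven heuristic starts for the 3-parameter growth fits, 16
  Latin-hypercube starts (seeded) for the 5-parameter schedule fit. Box
  constraints are imposed by smooth reparametrisation, with
  $t_2^* = t_1^* + \delta,\ \delta \ge 0$ enforcing the ordering. Default
  bounds: $k_0, k_\max \in [0.05, 50]$ µm⁻³ (log-uniform),
  $\lambda \in [0.1, 20]$ h⁻¹, $t_1^*$ in the data window ± 5 h.
* **Width root**: the quadratic $(\pi/4-1)w^2 + Lw - A_p$ has a negative
  leading coefficient; only its smaller positive root can satisfy
  $0 < w \le L$, and measurements admitting no such root are rejected with
  a diagnostic rather than silently dropped.
* **Filters**: strict inequalities, applied in the documented order only
  for attributing a rejection reason (the kept set is order-independent);
  the 3σ log filter is single-pass, with mean and SD taken from the
  pre-removal data. The area threshold is read as *projected* area, the
  quantity defined before surface area; both readings are configurable.
* **Mask measurement**: area is pixel count × pixel area; length is the
  longest side of the *minimum-area* bounding rectangle (rotating calipers
  over the convex hull, plus one pixel), chosen over the axis-aligned box
  because it is rotation-invariant up to rasterisation. Rendered masks use
  a half-pixel-offset grid, which keeps pixel-count areas within ~2 % of
  the analytic capsule area for cells ≥ 10 pixels long.
* **Trend smoothing**: penalised regression splines on log-values
  (`mgcv::gam`, REML), the standard empirical-Bayes equivalent of the
  Gaussian-process smoothers used for growth-curve inference; the 95 %
  band is the back-transformed pointwise interval. Constant series
  short-circuit to an exact constant with zero band.
* **Moment hierarchy**: closed at the top order by
  $\langle s^{n+1}\rangle \approx \langle s^n\rangle\langle s\rangle$.
  Order 1 reproduces the mean-size equation exactly (same code path). The
  order-2 closure has a saddle fixed point and blows up on long horizons —
  it is useful only as a short-horizon diagnostic, and the integrator warns
  when positivity is lost.
* **Confidence intervals** for per-time mean volumes use a seeded
  percentile bootstrap (default 1000 resamples), a reproducible,
  assumption-light replacement for Bayesian machinery.
* **Population cap**: tree-mode simulations refuse to outgrow `pop_cap`
  (bounded memory) unless `on_cap = "subsample"`, which halves the
  population uniformly and doubles the per-cell weight, keeping population
  observables unbiased; snapshots are recorded before reweighting.

## Problem sizes used in the test-suite studies

Simulation studies in the tests use sizes chosen to make sampling error
comfortably smaller than the effects being checked while keeping the suite
quick: 100-repetition coverage checks for the bootstrap and the smoother
bands, a 12-repetition noisy-recovery study for the schedule fit (median
sup-norm criterion), 50 pipeline replicates for the end-to-end recovery
study, and ≥ 5000 tracked divisions for the added-size distribution test.

## Known limitations

* The mean-field closure bias (above) makes the absolute scale of $k(t)$ an
  effective quantity; only a fluctuation-aware likelihood (beyond scope)
  would remove it.
* The double-sigmoid family assumes one rise and one fall of $k(t)$;
  multi-phase media shifts would need a richer schedule.
* The Gompertz growth alternative uses the standard
  $B_\max e^{-e^{-r(t-t_m)}}$ parametrisation fitted with the same
  log-space objective; it fits late growth better but represents the
  exponential phase — where most size dynamics happen — less well, so the
  logistic form remains the default.
* OD is taken as proportional to total cell volume; biomass-density
  changes along the curve would bend that proportionality.
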