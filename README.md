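# sizedyn

Bacterial cell volume is not constant along a batch growth curve: cells
leaving stationary phase swell several-fold within a couple of hours, then
shrink back as nutrients run out. `sizedyn` is an R package for researchers
who want to quantify the division control behind those dynamics **without
single-cell tracking**, using only population-level measurements: per-cell
segmentation snapshots, OD600 time series, and CFU counts.

## The model

Cells are sphero-cylinders. From a cell's projected area *A<sub>p</sub>* and
length *L*, the width *w* solves *A<sub>p</sub> = w(L−w) + π(w/2)²*, and
volume follows as *V = πLw²/4 − πw³/12*. Each cell grows exponentially at
the population growth rate, *ds/dt = μ(t)s*, with *μ(t)* extracted from a
log-space logistic fit to OD600,

&nbsp;&nbsp;μ(t) = μ<sub>max</sub> / (1 + e^{μ<sub>max</sub>(t − t<sub>s</sub>)}),

and divides in half with hazard *k(t)·μ(t)·s* — an adder-type rule (the
hazard per unit of added volume is exactly *k(t)*). The mean-field equation
for the mean size,

&nbsp;&nbsp;d⟨s⟩/dt = μ(t)⟨s⟩ − k(t)·μ(t)·⟨s⟩²/2,

has the homeostatic fixed point ⟨s⟩ = 2/k under constant rates. The
time-varying division coefficient is parametrised as a double sigmoid
*k(t) = k₀ + (k<sub>max</sub> − k₀)[σ(λ(t−t₁\*)) − σ(λ(t−t₂\*))]* and fitted
by minimising the summed squared relative residuals between predicted and
observed mean volumes. A stochastic single-cell simulator with exact
division-time sampling serves as synthetic-data generator and oracle, and a
ratio module turns replicated OD and CFU series into a smoothed OD/CFU
trend with propagated 95% bands (Δz = |Δx/y| + |x·Δy/y²|).

## Worked example

Simulate a growth curve whose division coefficient rises from 2 to
6 µm⁻³ around t = 2 h (logistic growth, μ_max = 2 h⁻¹), observe it through
noisy OD and microscopy channels, and run the full inference chain:

```r
library(sizedyn)

sched <- division_schedule(k0_per_um3 = 2, kmax_per_um3 = 6,
                           lambda_per_h = 3, t1_star_h = 2, t2_star_h = 8)
# overnight cells carry the small frozen stationary size (~2/kmax)
cfg <- sim_config(mu = function(t) logistic_rate(t, t_s = 4, mu_max = 2),
                  schedule = sched, n0 = 300, t_end_h = 10, seed = 1,
                  s0_median_um3 = 0.28, noise_log_sd = 0.05)
obs <- observe(simulate_population(cfg))

gf <- fit_growth(growth_curve(obs$od$time_h, obs$od$od600_corrected))
gf
#> Logistic fit: mu_max = 2 /h, B_max = 0.0002638, t_s = 4 h (sse_log = 5.81e-15)

cells <- derive_dimensions(obs$cells)$cells
summ <- summarize_cells(filter_cells(cells)$kept, seed = 1)
summ[c(1, 3, 5, 21), c("time_h", "n_cells", "mean_volume_um3")]
#>    time_h n_cells mean_volume_um3
#> 1       0     105       0.3669867
#> 3       1     157       0.7153840
#> 5       2     142       0.5658811
#> 21     10      64       0.4347819

fit <- infer_division_dynamics(summ, gf, seed = 1)
round(rbind(truth  = k_of_t(sched, 0:6),
            fitted = k_of_t(fit$schedule, 0:6)), 2)
#>        [,1] [,2] [,3] [,4] [,5] [,6] [,7]
#> truth  2.01 2.19 4.00 5.81 5.99 6.00 5.99
#> fitted 1.86 2.71 3.81 4.76 4.99 4.34 3.24
```

The growth stage recovers μ_max and t_s essentially exactly; the mean
volume shows the resuspension peak (0.37 → 0.72 µm³ in the first hour,
then decline). The fitted k(t) *curve* tracks the generating schedule —
when division control tightens and by how much — even though the five raw
parameters are individually degenerate (several parameter combinations
produce nearly the same bump; compare curves, not parameters). Its
absolute scale is an effective value: fitting the closed mean-size
equation to stochastic data inflates k by roughly 1 + CV² of the size
distribution, while the hard morphometric filters truncate the smallest
cells and pull it down; and once growth arrests (here t ≳ 6 h) the data no
longer constrain k(t) at all. The methods vignette
(`vignettes/cell-size-dynamics.Rmd`) quantifies these effects and the
design choices behind every stage.

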