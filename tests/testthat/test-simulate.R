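test_that("without division every size follows the exact growth law", {
  cfg <- sim_config(mu = 1, schedule = 0, n0 = 50, t_end_h = 3,
                    snapshot_times_h = c(0, 1.5, 3), seed = 2)
  sim <- simulate_population(cfg)
  s0 <- sim$states[[1]]$sizes_um3
  expect_equal(sim$states[[2]]$sizes_um3, s0 * exp(1.5), tolerance = 1e-8)
  expect_equal(sim$states[[3]]$sizes_um3, s0 * exp(3), tolerance = 1e-8)
  expect_equal(sim$states[[3]]$cumulative_divisions, 0)
  expect_equal(sim$states[[3]]$n_alive, 50)
})

test_that("tree mode conserves counts and biomass across divisions", {
  cfg <- sim_config(mu = 1, schedule = 2, n0 = 100, t_end_h = 3,
                    snapshot_times_h = seq(0, 3, 0.5), division = "tree",
                    seed = 4)
  sim <- simulate_population(cfg, track_divisions = TRUE)
  last <- sim$states[[length(sim$states)]]
  expect_equal(last$n_alive, 100 + last$cumulative_divisions)
  expect_gt(last$cumulative_divisions, 0)
  # total volume equals the deterministic biomass at every snapshot
  ps <- population_summary(sim)
  # equality up to hazard-table interpolation error
  expect_equal(ps$total_volume_um3, ps$biomass_um3, tolerance = 1e-5)
  # division log is self-consistent
  d <- sim$divisions
  expect_true(all(d$added_size_um3 > 0))
  expect_equal(d$division_size_um3 - d$birth_size_um3, d$added_size_um3)
})

test_that("identical configurations and seeds reproduce runs exactly", {
  cfg <- sim_config(mu = logistic_mu(), schedule = peaked_schedule(),
                    n0 = 60, t_end_h = 6, seed = 31)
  a <- simulate_population(cfg, track_divisions = TRUE)
  b <- simulate_population(cfg, track_divisions = TRUE)
  expect_identical(a$states, b$states)
  expect_identical(a$divisions, b$divisions)
})

test_that("added sizes between birth and division are exponential", {
  cfg <- sim_config(mu = 1, schedule = 2, n0 = 600, t_end_h = 12,
                    snapshot_times_h = c(0, 12), seed = 17)
  sim <- simulate_population(cfg, track_divisions = TRUE)
  # censor-free subset: cells born early enough that an added size in the
  # far exponential tail would still divide before the horizon
  d <- sim$divisions[sim$divisions$birth_time_h < 8, ]
  expect_gt(nrow(d), 5000)
  expect_equal(mean(d$added_size_um3), 0.5, tolerance = 0.05)
  ks <- suppressWarnings(stats::ks.test(d$added_size_um3, "pexp", 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("the lineage ensemble reaches a drift-free steady state", {
  cfg <- sim_config(mu = 1, schedule = 2, n0 = 800, t_end_h = 20,
                    snapshot_times_h = seq(0, 20, 0.5), seed = 23)
  sim <- simulate_population(cfg)
  ps <- population_summary(sim)
  late <- ps[ps$time_h >= 15, ]
  fit <- stats::lm(mean_size_um3 ~ time_h, data = late)
  slope <- summary(fit)$coefficients["time_h", ]
  expect_gt(slope["Pr(>|t|)"], 0.05)       # no detectable trend
  # the exact stationarity identity <s^2> = (2/k) <s>
  sizes <- sim$states[[length(sim$states)]]$sizes_um3
  expect_equal(mean(sizes^2) / mean(sizes), 2 / 2, tolerance = 0.05)
})

test_that("ensemble means track the mean-field solution up to closure error", {
  # the closed equation neglects size fluctuations; with exponential added
  # sizes the stationary size CV is ~0.6, so the ensemble mean sits up to
  # ~30% below the mean-field path (quantified in the vignette)
  cfg <- sim_config(mu = logistic_mu(), schedule = peaked_schedule(),
                    n0 = 600, t_end_h = 10, seed = 41)
  ps <- population_summary(simulate_population(cfg))
  mf <- integrate_mean_size(logistic_mu(), peaked_schedule(),
                            ps$mean_size_um3[1], ps$time_h)
  ratio <- ps$mean_size_um3 / mf$mean_size_um3
  expect_true(all(ratio > 0.65 & ratio < 1.1))
})

test_that("population-level observables are unbiased in lineage mode", {
  # weighted count estimate ~ true population growth: V/N -> 1/k
  cfg <- sim_config(mu = 1, schedule = 2, n0 = 2000, t_end_h = 10,
                    snapshot_times_h = seq(0, 10, 1), seed = 7)
  ps <- population_summary(simulate_population(cfg))
  expect_lt(abs(ps$pop_mean_size_um3[11] - 0.5) / 0.5, 0.15)
})

test_that("observed tables mirror the simulation without noise", {
  cfg <- sim_config(mu = 1, schedule = 1.5, n0 = 150, t_end_h = 4,
                    snapshot_times_h = seq(0, 4, 1), seed = 3,
                    noise_log_sd = 0, subsample = 1e6)
  sim <- simulate_population(cfg)
  obs <- observe(sim)
  ps <- population_summary(sim)
  # measured volumes invert exactly back through the capsule geometry
  dd <- derive_dimensions(obs$cells)
  expect_equal(nrow(dd$rejected), 0)
  expect_equal(dd$cells$volume_um3, dd$cells$true_volume_um3,
               tolerance = 1e-8)
  by_t <- tapply(dd$cells$volume_um3, dd$cells$time_h, mean)
  expect_equal(as.numeric(by_t), ps$mean_size_um3, tolerance = 1e-8)
  # OD/CFU ratio is proportional to the population mean size by construction
  expect_equal(obs$od$od600_corrected / obs$cfu$cfu_per_ml / cfg$od_per_um3,
               ps$biomass_um3 / ps$total_weight, tolerance = 1e-12)
})

test_that("the population cap errors or reweights as configured", {
  cfg_err <- sim_config(mu = 1, schedule = 1, n0 = 50, t_end_h = 8,
                        snapshot_times_h = c(0, 8), division = "tree",
                        pop_cap = 200, seed = 5)
  expect_error(simulate_population(cfg_err), "pop_cap")
  cfg_sub <- sim_config(mu = 1, schedule = 1, n0 = 50, t_end_h = 8,
                        snapshot_times_h = seq(0, 8, 0.5), division = "tree",
                        pop_cap = 500, on_cap = "subsample", seed = 5)
  sim <- simulate_population(cfg_sub)
  expect_true(sim$subsampled)
  # snapshots are taken before reweighting; between control points the
  # population can overshoot the cap by at most one doubling
  expect_true(all(vapply(sim$states, `[[`, numeric(1), "n_alive") <= 1000))
  last <- sim$states[[length(sim$states)]]
  # weighted count still tracks the deterministic expectation N ~ k V
  expect_lt(abs(sum(last$weights) * 1 -
                  (50 * mean(sim$states[[1]]$sizes_um3) * exp(8) * 1)) /
              (50 * mean(sim$states[[1]]$sizes_um3) * exp(8)), 0.5)
})
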