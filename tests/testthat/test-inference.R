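test_that("objective vanishes on self-generated data and at steady state", {
  mu_fn <- logistic_mu()
  sc <- peaked_schedule()
  times <- seq(0, 10, 0.5)
  obs <- integrate_mean_size(mu_fn, sc, 1, times)$mean_size_um3
  expect_lt(size_objective(sc, mu_fn, obs[1], times, obs), 1e-10)
  # constant observations at 2/k under matching constant schedule
  kconst <- division_schedule(1.5, 1.5, 1, 0, 0)
  times2 <- seq(0, 6, 1)
  obs2 <- rep(2 / 1.5, length(times2))
  expect_lt(size_objective(kconst, mu_function(1), 2 / 1.5, times2, obs2),
            1e-12)
})

test_that("objective arithmetic matches hand computation and ignores order", {
  mu_fn <- mu_function(1)
  times <- c(0, 1, 2)
  pred <- integrate_mean_size(mu_fn, 1.5, 0.5, times)$mean_size_um3
  obs <- c(0.6, 0.9, 1.1)
  expect_equal(size_objective(1.5, mu_fn, 0.5, times, obs),
               sum(((obs - pred) / obs)^2), tolerance = 1e-9)
  # doubling the observations: each term becomes (1 - p/(2 o))^2
  expect_equal(size_objective(1.5, mu_fn, 0.5, times, 2 * obs),
               sum((1 - pred / (2 * obs))^2), tolerance = 1e-9)
  # permutation invariance
  p <- c(3, 1, 2)
  expect_equal(size_objective(1.5, mu_fn, 0.5, times[p], obs[p]),
               size_objective(1.5, mu_fn, 0.5, times, obs), tolerance = 1e-12)
})

test_that("noiseless data pins the k(t) curve where growth is informative", {
  mu_fn <- logistic_mu()
  sc <- peaked_schedule()
  times <- seq(0, 10, 0.5)
  obs <- integrate_mean_size(mu_fn, sc, 1, times)$mean_size_um3
  fit <- fit_division_schedule(mu_fn, obs[1], times, obs,
                               n_starts = 12, seed = 3)
  expect_lt(fit$objective, 1e-6)
  # identifiability holds only while mu(t) is appreciably positive: past
  # growth arrest the data no longer constrain k(t)
  tt <- seq(0, 10, 0.1)
  tt <- tt[mu_fn(tt) > 0.02]
  expect_lt(k_supnorm(fit$schedule, sc, tt), 0.05)
})

test_that("schedule fitting is deterministic given the seed", {
  mu_fn <- mu_function(1)
  times <- seq(0, 8, 1)
  obs <- integrate_mean_size(mu_fn, 1.5, 0.5, times)$mean_size_um3 *
    exp(c(0.01, -0.02, 0.015, 0, 0.01, -0.01, 0.02, -0.015, 0))
  f1 <- fit_division_schedule(mu_fn, obs[1], times, obs, n_starts = 6, seed = 9)
  f2 <- fit_division_schedule(mu_fn, obs[1], times, obs, n_starts = 6, seed = 9)
  expect_identical(f1$schedule, f2$schedule)
  expect_equal(f1$n_starts_converged, 6)
})

test_that("constant-size data under constant growth yield a flat k near k0", {
  mu_fn <- mu_function(1)
  times <- seq(0, 8, 0.5)
  obs <- rep(2 / 2.5, length(times))       # steady state of k0 = 2.5
  fit <- fit_division_schedule(mu_fn, obs[1], times, obs,
                               n_starts = 10, seed = 4)
  kk <- k_of_t(fit$schedule, times)
  expect_lt(max(abs(kk - 2.5) / 2.5), 0.05)
})

test_that("noisy observations still recover k(t) in the data window", {
  mu_fn <- logistic_mu()
  sc <- peaked_schedule()
  times <- seq(0, 10, 0.5)
  truth <- integrate_mean_size(mu_fn, sc, 1, times)$mean_size_um3
  tt <- seq(0, 10, 0.1)
  tt <- tt[mu_fn(tt) > 0.02]
  errs <- vapply(1:12, function(r) {
    set.seed(300 + r)
    obs <- truth * exp(rnorm(length(truth), 0, 0.05))
    fit <- fit_division_schedule(mu_fn, obs[1], times, obs,
                                 n_starts = 10, seed = r, maxit = 500)
    k_supnorm(fit$schedule, sc, tt)
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("pointwise inversion undoes the forward model", {
  mu_fn <- mu_function(1)
  # steady state: k = 2/<s>
  flat <- list(value = function(t) rep(4 / 3, length(t)),
               deriv = function(t) rep(0, length(t)))
  expect_equal(pointwise_k(mu_fn, flat, c(1, 5)), c(1.5, 1.5))
  # pure growth (d<s>/dt = mu <s>) has no division: k = 0
  growing <- list(value = function(t) 0.5 * exp(t),
                  deriv = function(t) 0.5 * exp(t))
  expect_equal(pointwise_k(mu_fn, growing, c(0, 2)), c(0, 0),
               tolerance = 1e-12)
  # forward-then-invert with constant k along a relaxing trajectory
  grid <- seq(0, 10, 0.05)
  traj <- integrate_mean_size(mu_fn, 1.5, 0.3, grid)
  sp <- smooth_size_spline(traj$time_h, traj$mean_size_um3, spar = 0.3)
  kk <- pointwise_k(mu_fn, sp, seq(0.5, 9.5, 0.25))
  expect_lt(max(abs(kk - 1.5)), 1e-3)
})

test_that("inversion is refused where the growth rate is too small", {
  mu_fn <- logistic_mu()                    # mu ~ 0 past t = 7
  flat <- list(value = function(t) rep(1, length(t)),
               deriv = function(t) rep(0, length(t)))
  kk <- pointwise_k(mu_fn, flat, c(1, 9))
  expect_false(is.na(kk[1]))
  expect_true(is.na(kk[2]))
})

test_that("weighted spline interpolates means with usable derivatives", {
  tt <- seq(0, 6, 0.5)
  y <- 1 + 0.5 * sin(tt)
  sp <- smooth_size_spline(tt, y, halfwidths = rep(0.05, length(tt)),
                           spar = 0.2)
  expect_equal(sp$value(3), 1 + 0.5 * sin(3), tolerance = 0.02)
  expect_equal(sp$deriv(3), 0.5 * cos(3), tolerance = 0.05)
})
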