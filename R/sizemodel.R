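#' Time-varying division coefficient schedule
#'
#' The division coefficient k(t) (per cubic micrometre) multiplies
#' `mu(t) s` to give the per-cell division hazard. Its time course is a
#' double sigmoid,
#' `k(t) = k0 + (kmax - k0) [logis(lambda (t - t1)) - logis(lambda (t - t2))]`,
#' rising from the basal value `k0` around `t1_star`, plateauing near `kmax`,
#' and returning to `k0` around `t2_star` — so the schedule starts and ends
#' at the stationary-phase value.
#'
#' @param k0_per_um3 basal coefficient, per um^3.
#' @param kmax_per_um3 plateau coefficient, per um^3 (may be below `k0`).
#' @param lambda_per_h steepness of both transitions, per hour.
#' @param t1_star_h rise midpoint, hours.
#' @param t2_star_h fall midpoint, hours; `t1_star_h <= t2_star_h`.
#' @return object of class `division_schedule`.
#' @export
division_schedule <- function(k0_per_um3, kmax_per_um3, lambda_per_h,
                              t1_star_h, t2_star_h) {
  stopifnot(k0_per_um3 > 0, kmax_per_um3 > 0, lambda_per_h > 0,
            t1_star_h <= t2_star_h)
  structure(list(k0_per_um3 = k0_per_um3, kmax_per_um3 = kmax_per_um3,
                 lambda_per_h = lambda_per_h, t1_star_h = t1_star_h,
                 t2_star_h = t2_star_h),
            class = "division_schedule")
}

#' @export
print.division_schedule <- function(x, ...) {
  cat(sprintf(
    "Division schedule: k0 = %.4g, kmax = %.4g /um^3; lambda = %.4g /h; t1* = %.4g h, t2* = %.4g h\n",
    x$k0_per_um3, x$kmax_per_um3, x$lambda_per_h, x$t1_star_h, x$t2_star_h))
  invisible(x)
}

#' Evaluate the division coefficient at given times
#'
#' @param schedule a [division_schedule()].
#' @param t times in hours (vectorised).
#' @return k(t), per cubic micrometre; tends to `k0` as `t -> +/- Inf`.
#' @export
k_of_t <- function(schedule, t) {
  stopifnot(inherits(schedule, "division_schedule"))
  with(schedule, {
    k0_per_um3 + (kmax_per_um3 - k0_per_um3) *
      (stats::plogis(lambda_per_h * (t - t1_star_h)) -
         stats::plogis(lambda_per_h * (t - t2_star_h)))
  })
}

#' Division-coefficient function factory
#'
#' @param schedule a [division_schedule()] or a single positive number for a
#'   constant coefficient.
#' @return a function of time returning k per cubic micrometre.
#' @export
k_function <- function(schedule) {
  if (is.numeric(schedule) && length(schedule) == 1) {
    stopifnot(schedule >= 0)
    force(schedule)
    return(function(t) rep_len(schedule, length(t)))
  }
  stopifnot(inherits(schedule, "division_schedule"))
  function(t) k_of_t(schedule, t)
}

# Moment-hierarchy right-hand side with mean-field closure:
#   d<s^n>/dt = n mu <s^n> - k mu (1 - 2^-n) <s^(n+1)>,  n = 1..N,
# closing the top moment as <s^(N+1)> ~ <s^N> <s>.
moment_rhs <- function(t, m, parms) {
  mu <- parms$mu_fn(t)
  k <- parms$k_fn(t)
  n <- seq_along(m)
  m_up <- c(m[-1], m[length(m)] * m[1])
  list(n * mu * m - k * mu * (1 - 2^(-n)) * m_up)
}

#' Integrate the moment hierarchy of the growth-division process
#'
#' The population-balance model — exponential single-cell growth
#' `ds/dt = mu(t) s` plus binary division `s -> s/2` at hazard
#' `k(t) mu(t) s` — yields for the raw size moments
#' `d<s^n>/dt = n mu <s^n> - k mu (1 - 2^-n) <s^(n+1)>`.
#' The hierarchy is unclosed; here the top moment is closed mean-field
#' style as `<s^(N+1)> ~ <s^N><s>`. At `closure_order = 1` this is exactly
#' the mean-size equation
#' `d<s>/dt = mu <s> - k mu <s>^2 / 2`.
#'
#' @param mu_fn growth-rate function of time (see [mu_function()]).
#' @param schedule a [division_schedule()], constant, or k(t) function.
#' @param closure_order number of moments carried (>= 1).
#' @param initial_moments numeric vector of length `closure_order`,
#'   `(<s>, <s^2>, ...)` at the first grid time.
#' @param t_grid output times (hours), first element is the initial time.
#' @param rtol,atol solver tolerances (lsoda).
#' @return data.frame with `time_h` and columns `m1 ... m<order>`.
#' @export
integrate_moments <- function(mu_fn, schedule, closure_order = 1,
                              initial_moments, t_grid,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.function(mu_fn), closure_order >= 1,
            length(initial_moments) == closure_order,
            all(initial_moments > 0), length(t_grid) >= 2)
  k_fn <- if (is.function(schedule)) schedule else k_function(schedule)
  sol <- deSolve::ode(y = as.numeric(initial_moments), times = t_grid,
                      func = moment_rhs,
                      parms = list(mu_fn = mu_fn, k_fn = k_fn),
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("moment integration failed; final state: ",
         paste(signif(sol[nrow(sol), ], 6), collapse = ", "))
  out <- as.data.frame(sol)
  names(out) <- c("time_h", paste0("m", seq_len(closure_order)))
  if (any(out[, -1] <= 0))
    warning("moment trajectories lost positivity: the top-moment closure ",
            "is unstable at order >= 2; shorten the horizon")
  out
}

#' Integrate the mean-field mean cell size
#'
#' Solves the closed mean-size equation
#' `d<s>/dt = mu(t) <s> - k(t) mu(t) <s>^2 / 2` on a time grid. This is a
#' Riccati equation: for constant `mu > 0` and constant `k` the mean size
#' relaxes monotonically to the homeostatic fixed point `<s> = 2/k`.
#'
#' @inheritParams integrate_moments
#' @param s0 initial mean size in cubic micrometres (at `t_grid[1]`).
#' @return object of class `mean_size_trajectory`: data.frame with `time_h`
#'   and `mean_size_um3`.
#' @export
integrate_mean_size <- function(mu_fn, schedule, s0, t_grid,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(s0 > 0)
  m <- integrate_moments(mu_fn, schedule, closure_order = 1,
                         initial_moments = s0, t_grid = t_grid,
                         rtol = rtol, atol = atol)
  out <- data.frame(time_h = m$time_h, mean_size_um3 = m$m1)
  class(out) <- c("mean_size_trajectory", "data.frame")
  out
}

#' @export
print.mean_size_trajectory <- function(x, ...) {
  cat(sprintf("Mean-size trajectory: %d times on [%g, %g] h, <s> in [%.4g, %.4g] um^3\n",
              nrow(x), min(x$time_h), max(x$time_h),
              min(x$mean_size_um3), max(x$mean_size_um3)))
  invisible(x)
}
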