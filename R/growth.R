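#' Logistic biomass curve
#'
#' Closed-form solution of the logistic equation
#' `dB/dt = mu_max B (1 - B/B_max)`:
#' `B(t) = B_max / (1 + exp(-mu_max (t - t_s)))`, where `t_s` is the
#' half-capacity crossing and can be read as the time of entry into
#' stationary phase. Evaluated through `plogis()` so that extreme arguments
#' cannot overflow.
#'
#' @param t time in hours (vectorised).
#' @param t_s half-capacity time in hours.
#' @param B_max carrying capacity (OD units).
#' @param mu_max maximum specific growth rate, per hour.
#' @return biomass at `t`, strictly inside `(0, B_max)`.
#' @export
logistic_solution <- function(t, t_s, B_max, mu_max) {
  stopifnot(B_max > 0, mu_max > 0)
  B_max * stats::plogis(mu_max * (t - t_s))
}

#' @rdname logistic_solution
#' @details `logistic_rate()` is the specific growth rate
#'   `mu(t) = (1/B) dB/dt = mu_max / (1 + exp(mu_max (t - t_s)))`, which
#'   decreases monotonically from `mu_max` in early exponential phase to 0
#'   in stationary phase, passing `mu_max / 2` at `t_s`.
#' @export
logistic_rate <- function(t, t_s, mu_max) {
  stopifnot(mu_max > 0)
  mu_max * stats::plogis(-mu_max * (t - t_s))
}

#' Gompertz biomass curve
#'
#' Standard two-shape-parameter Gompertz form
#' `B(t) = B_max exp(-exp(-r (t - t_m)))`, with inflection at `t_m` where
#' `B = B_max / e`, and specific growth rate
#' `mu(t) = d log B / dt = r exp(-r (t - t_m))`.
#'
#' @param t time in hours (vectorised).
#' @param t_m inflection time in hours.
#' @param B_max carrying capacity.
#' @param r shape rate, per hour.
#' @export
gompertz_solution <- function(t, t_m, B_max, r) {
  stopifnot(B_max > 0, r > 0)
  B_max * exp(-exp(-r * (t - t_m)))
}

#' @rdname gompertz_solution
#' @export
gompertz_rate <- function(t, t_m, r) {
  stopifnot(r > 0)
  r * exp(-r * (t - t_m))
}

#' OD600 growth curve container
#'
#' Holds a dilution-corrected OD600 time series for one condition. OD values
#' must already be multiplied by their dilution factors. An optional
#' `dilution_window = c(t_start, t_end)` marks a period of repeated 1:2
#' dilutions that held the culture in sustained exponential growth; points
#' inside the window are excluded from curve fitting and the growth rate is
#' frozen at its window-start value.
#'
#' @param times_h strictly increasing sampling times, hours.
#' @param od600 positive dilution-corrected OD600 values.
#' @param dilution_window optional length-2 numeric within the time range.
#' @param condition label.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(times_h, od600, dilution_window = NULL,
                         condition = "") {
  stopifnot(is.numeric(times_h), is.numeric(od600),
            length(times_h) == length(od600),
            all(diff(times_h) > 0), all(od600 > 0))
  if (!is.null(dilution_window)) {
    stopifnot(length(dilution_window) == 2,
              dilution_window[1] <= dilution_window[2],
              dilution_window[1] >= min(times_h),
              dilution_window[2] <= max(times_h))
  }
  structure(list(times_h = as.numeric(times_h), od600 = as.numeric(od600),
                 dilution_window = dilution_window,
                 condition = condition),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("OD600 growth curve '%s': %d points on [%g, %g] h\n",
              x$condition, length(x$times_h), min(x$times_h), max(x$times_h)))
  if (!is.null(x$dilution_window))
    cat(sprintf("  dilution window: [%g, %g] h\n",
                x$dilution_window[1], x$dilution_window[2]))
  invisible(x)
}

in_window <- function(t, window) {
  if (is.null(window)) rep.int(FALSE, length(t))
  else t >= window[1] & t <= window[2]
}

#' Fit a logistic or Gompertz curve to an OD600 series in log space
#'
#' Minimises the log-space sum of squares
#' `sum_i (log B_i - log B(t_i; theta))^2` over the three curve parameters,
#' using Nelder-Mead simplex restarts from deterministic data-driven
#' starting points (carrying capacity near the maximum OD, rate from the
#' steepest log-slope, midpoint at the half-maximum crossing, each jittered
#' reproducibly). Points inside the curve's dilution window do not enter
#' the objective.
#'
#' @param curve a [growth_curve()].
#' @param model `"logistic"` or `"gompertz"`.
#' @param n_starts number of simplex restarts.
#' @param seed integer seed for the (deterministic) start jitter.
#' @return object of class `growth_fit` with elements `mu_max_per_h`
#'   (for Gompertz: the shape rate `r`), `B_max`, `t_s_h` (for Gompertz:
#'   `t_m`), `sse_log`, `model`, `dilution_window`, `n_starts_converged`.
#' @export
fit_growth <- function(curve, model = c("logistic", "gompertz"),
                       n_starts = 8, seed = 1) {
  stopifnot(inherits(curve, "growth_curve"))
  model <- match.arg(model)
  use <- !in_window(curve$times_h, curve$dilution_window)
  t_i <- curve$times_h[use]
  b_i <- curve$od600[use]
  if (length(t_i) < 4) stop("need at least 4 time points outside the dilution window")
  if (stats::sd(log(b_i)) == 0) stop("degenerate data: OD is constant")

  fn <- function(par) {  # par = (log B_max, log rate, midpoint)
    bmax <- exp(par[1]); rate <- exp(par[2]); tm <- par[3]
    pred <- if (model == "logistic") {
      log(bmax) + stats::plogis(rate * (t_i - tm), log.p = TRUE)
    } else {
      log(bmax) - exp(-rate * (t_i - tm))
    }
    sum((log(b_i) - pred)^2)
  }

  # data-driven heuristics
  bmax0 <- max(b_i)
  slopes <- diff(log(b_i)) / diff(t_i)
  rate0 <- max(max(slopes), 1e-3)
  half_idx <- which(b_i >= bmax0 / 2)[1]
  tm0 <- t_i[half_idx]
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    jit <- if (i == 1) c(0, 0, 0) else stats::rnorm(3, 0, c(0.3, 0.5, 1))
    c(log(bmax0 * 1.05) + jit[1], log(rate0) + jit[2], tm0 + jit[3])
  })

  fits <- lapply(starts, function(p0) {
    tryCatch(stats::optim(p0, fn, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
             error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits)) stop("growth-curve fit failed to converge from any start")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  # polish the winner
  best <- stats::optim(best$par, fn, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-14))
  structure(list(
    mu_max_per_h = exp(best$par[2]),
    B_max = exp(best$par[1]),
    t_s_h = best$par[3],
    sse_log = best$value,
    model = model,
    dilution_window = curve$dilution_window,
    n_starts_converged = length(fits)
  ), class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$model == "logistic") {
    cat(sprintf("Logistic fit: mu_max = %.4g /h, B_max = %.4g, t_s = %.4g h (sse_log = %.3g)\n",
                x$mu_max_per_h, x$B_max, x$t_s_h, x$sse_log))
  } else {
    cat(sprintf("Gompertz fit: r = %.4g /h, B_max = %.4g, t_m = %.4g h (sse_log = %.3g)\n",
                x$mu_max_per_h, x$B_max, x$t_s_h, x$sse_log))
  }
  invisible(x)
}

#' Time-varying growth rate from a fitted curve
#'
#' Evaluates `mu(t)` for a [fit_growth()] result. Inside the fit's dilution
#' window the growth rate is held constant at its value just before the
#' dilutions started.
#'
#' @param fit a `growth_fit`.
#' @param t times in hours (vectorised).
#' @return growth rate per hour.
#' @export
growth_rate <- function(fit, t) {
  stopifnot(inherits(fit, "growth_fit"))
  t_eff <- t
  if (!is.null(fit$dilution_window)) {
    w <- in_window(t, fit$dilution_window)
    t_eff[w] <- fit$dilution_window[1]
  }
  if (fit$model == "logistic") {
    logistic_rate(t_eff, fit$t_s_h, fit$mu_max_per_h)
  } else {
    gompertz_rate(t_eff, fit$t_s_h, fit$mu_max_per_h)
  }
}

#' Fitted biomass values
#'
#' @param object a `growth_fit`.
#' @param t times in hours.
#' @param ... unused.
#' @return predicted biomass (OD units) at `t`.
#' @export
predict.growth_fit <- function(object, t, ...) {
  if (object$model == "logistic") {
    logistic_solution(t, object$t_s_h, object$B_max, object$mu_max_per_h)
  } else {
    gompertz_solution(t, object$t_s_h, object$B_max, object$mu_max_per_h)
  }
}

#' Growth-rate function factory
#'
#' Wraps a fit (or constant) into the `mu(t)` callable consumed by the
#' size-dynamics and simulation modules.
#'
#' @param fit a `growth_fit`, or a single positive number for a constant
#'   growth rate.
#' @return a function of time returning the growth rate per hour.
#' @export
mu_function <- function(fit) {
  if (is.numeric(fit) && length(fit) == 1) {
    stopifnot(fit >= 0)
    force(fit)
    return(function(t) rep_len(fit, length(t)))
  }
  stopifnot(inherits(fit, "growth_fit"))
  function(t) growth_rate(fit, t)
}
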