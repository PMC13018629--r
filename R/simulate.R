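#' Configuration of a stochastic growth-division simulation
#'
#' Describes cells that each grow exponentially, `ds/dt = mu(t) s`, and
#' halve their size (`s -> s/2`) with per-cell hazard `k(t) mu(t) s`. The
#' hazard per unit of *added* size is then exactly `k(t)` (divide the
#' per-time hazard by `ds/dt`), which is the adder division rule: under
#' constant rates the size added between birth and division is exponential
#' with mean `1/k`.
#'
#' Two ensembles can be simulated (see [simulate_population()]):
#' `division = "lineage"` follows `n0` independent single-cell lineages of
#' the jump process — the ensemble whose mean the mean-field equation
#' ([integrate_mean_size()]) describes — carrying a statistical weight
#' `2^divisions` per lineage so that population totals (biomass, count)
#' remain unbiased; `division = "tree"` simulates full symmetric binary
#' fission, where each division adds a cell and the final count equals
#' `n0` plus the number of divisions.
#'
#' @param mu growth rate: a `growth_fit`, a constant (per hour), or a
#'   function of time.
#' @param schedule division coefficient: a [division_schedule()], a
#'   constant (per um^3), or a function of time.
#' @param n0 initial number of cells (lineages).
#' @param t_end_h simulation horizon, hours.
#' @param snapshot_times_h times at which population states are recorded
#'   (within `[0, t_end_h]`).
#' @param division `"lineage"` or `"tree"` (see above).
#' @param s0_median_um3,s0_log_sd initial sizes are log-normal with this
#'   median and log-sd (stationary-phase cells are around 1 um^3).
#' @param seed integer seed; identical configs and seeds reproduce runs
#'   byte for byte.
#' @param noise_log_sd multiplicative log-normal measurement noise applied
#'   independently to length and width by [observe()].
#' @param subsample cells measured per snapshot by [observe()].
#' @param width_model how simulated volumes map to (length, width) pairs in
#'   [observe()]: `"isometric"` keeps the aspect ratio fixed (width grows as
#'   the cube root of volume, mirroring the observation that cells widen as
#'   well as lengthen along the growth curve), `"fixed"` keeps width at
#'   `width_um` and solves the capsule volume for length (cells below the
#'   sphere volume become spheres).
#' @param aspect aspect ratio L/w used by the isometric width model.
#' @param width_um fixed cell width for `width_model = "fixed"`,
#'   micrometres.
#' @param od_per_um3 OD600 units per cubic micrometre of total cell volume
#'   (arbitrary proportionality; only ratios matter downstream).
#' @param cfu_scale CFU/ml per (weighted) cell.
#' @param pop_cap maximum live population (tree mode) before the `on_cap`
#'   policy applies.
#' @param on_cap `"error"` (bounded-memory contract) or `"subsample"`
#'   (uniformly halve the population and double the per-cell statistical
#'   weight, keeping population observables unbiased).
#' @param grid_dt_h resolution of the precomputed hazard tables, hours.
#' @param condition label stamped onto observed tables.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(mu, schedule, n0 = 100, t_end_h = 10,
                       snapshot_times_h = seq(0, t_end_h, by = 0.5),
                       division = c("lineage", "tree"),
                       s0_median_um3 = 1, s0_log_sd = 0.3, seed = 1,
                       noise_log_sd = 0.03, subsample = 200,
                       width_model = c("isometric", "fixed"), aspect = 3,
                       width_um = 1,
                       od_per_um3 = 1e-9, cfu_scale = 1, pop_cap = 1e6,
                       on_cap = c("error", "subsample"), grid_dt_h = 1e-3,
                       condition = "sim") {
  division <- match.arg(division)
  width_model <- match.arg(width_model)
  on_cap <- match.arg(on_cap)
  stopifnot(aspect > 1)
  stopifnot(n0 >= 1, t_end_h > 0, s0_median_um3 > 0, s0_log_sd >= 0,
            noise_log_sd >= 0, width_um > 0, od_per_um3 > 0, cfu_scale > 0,
            pop_cap >= 2, grid_dt_h > 0,
            all(snapshot_times_h >= 0), all(snapshot_times_h <= t_end_h))
  mu_fn <- if (is.function(mu)) mu else mu_function(mu)
  k_fn <- if (is.function(schedule)) schedule else k_function(schedule)
  structure(list(mu_fn = mu_fn, k_fn = k_fn, n0 = as.integer(n0),
                 t_end_h = t_end_h,
                 snapshot_times_h = sort(unique(snapshot_times_h)),
                 division = division,
                 s0_median_um3 = s0_median_um3, s0_log_sd = s0_log_sd,
                 seed = seed, noise_log_sd = noise_log_sd,
                 subsample = subsample, width_model = width_model,
                 aspect = aspect, width_um = width_um,
                 od_per_um3 = od_per_um3, cfu_scale = cfu_scale,
                 pop_cap = pop_cap, on_cap = on_cap, grid_dt_h = grid_dt_h,
                 condition = condition),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config '%s' (%s): n0 = %d, t_end = %g h, %d snapshots\n",
              x$condition, x$division, x$n0, x$t_end_h,
              length(x$snapshot_times_h)))
  invisible(x)
}

# Hazard tables on a fine time grid:
#   M(t) = int_0^t mu  (trapezoid), v = exp(M),
#   K(t) = int_0^t k dv (trapezoid in v; exact for constant k).
# A cell of size s0 at time t0 divides when
#   K(t) = K(t0) + E * v(t0) / s0,   E ~ Exp(1),
# because its cumulative hazard is (s0/v(t0)) (K(t) - K(t0)).
hazard_tables <- function(mu_fn, k_fn, t_end, dt) {
  tg <- seq(0, t_end, by = dt)
  if (tg[length(tg)] < t_end) tg <- c(tg, t_end)
  mu <- mu_fn(tg)
  if (any(mu < 0)) stop("growth rate must be non-negative")
  M <- c(0, cumsum((mu[-1] + mu[-length(mu)]) / 2 * diff(tg)))
  v <- exp(M)
  kg <- k_fn(tg)
  if (any(kg < 0)) stop("division coefficient must be non-negative")
  K <- c(0, cumsum((kg[-1] + kg[-length(kg)]) / 2 * diff(v)))
  list(t = tg, M = M, v = v, K = K)
}

# linear interpolation on a table
tab_interp <- function(x, xs, ys) {
  i <- findInterval(x, xs, all.inside = TRUE)
  frac <- (x - xs[i]) / (xs[i + 1] - xs[i])
  ys[i] + frac * (ys[i + 1] - ys[i])
}

# invert the cumulative-hazard table: given target K value, return
# (v*, t*). K is non-decreasing and piecewise linear in v.
invert_hazard <- function(target, tab) {
  j <- findInterval(target, tab$K, all.inside = TRUE)
  dK <- tab$K[j + 1] - tab$K[j]
  v_star <- if (dK > 0) {
    tab$v[j] + (target - tab$K[j]) / dK * (tab$v[j + 1] - tab$v[j])
  } else tab$v[j + 1]
  m_star <- log(v_star)
  dM <- tab$M[j + 1] - tab$M[j]
  t_star <- if (dM > 0) {
    tab$t[j] + (m_star - tab$M[j]) / dM * (tab$t[j + 1] - tab$t[j])
  } else tab$t[j + 1]
  c(v_star, t_star)
}

#' Simulate a growing and dividing cell population
#'
#' Event-driven, exact-in-distribution simulation of the growth-division
#' process of a [sim_config()]. Between divisions each cell's size follows
#' the deterministic growth law `s(t) = s(t0) exp(int_{t0}^{t} mu)`;
#' division times are sampled by inverting the per-cell cumulative hazard
#' against a precomputed integral table (no thinning error; for constant
#' rates the sampled added sizes are exactly exponential).
#'
#' In `"lineage"` mode the `n0` cells are followed through divisions
#' (`s -> s/2`, count fixed), each carrying weight `2^divisions`; in
#' `"tree"` mode both half-size daughters are kept, so total volume is
#' continuous across divisions and the count equals `n0` plus the number
#' of divisions.
#'
#' @param config a [sim_config()].
#' @param track_divisions if `TRUE`, return the per-division log
#'   (birth size, division size, added size, times) needed for hazard
#'   diagnostics.
#' @return object of class `sim_result`: list with `states` (one entry per
#'   snapshot: `time_h`, `sizes_um3`, `weights`, `n_alive`,
#'   `cumulative_divisions`, `biomass_um3` — the exact total population
#'   volume `sum(s_init) exp(int mu)`), `divisions` (data.frame or NULL),
#'   `config`, `subsampled`.
#' @export
simulate_population <- function(config, track_divisions = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tab <- hazard_tables(config$mu_fn, config$k_fn, config$t_end_h,
                       config$grid_dt_h)
  s_init <- stats::rlnorm(config$n0, log(config$s0_median_um3),
                          config$s0_log_sd)
  res <- if (config$division == "lineage") {
    simulate_lineages(config, tab, s_init, track_divisions)
  } else {
    simulate_tree(config, tab, s_init, track_divisions)
  }
  v_snap <- tab_interp(config$snapshot_times_h, tab$t, tab$v)
  biomass <- sum(s_init) * v_snap
  for (i in seq_along(res$states)) res$states[[i]]$biomass_um3 <- biomass[i]
  structure(c(res, list(config = config)), class = "sim_result")
}

simulate_lineages <- function(config, tab, s_init, track_divisions) {
  snaps <- config$snapshot_times_h
  n0 <- config$n0
  K_end <- tab$K[length(tab$K)]
  S <- matrix(NA_real_, n0, length(snaps))   # size at each snapshot
  D <- matrix(0L, n0, length(snaps))         # divisions so far
  n_div <- 0L
  div_t <- numeric(1024); div_birth <- numeric(1024); div_size <- numeric(1024)
  div_bt <- numeric(1024)
  for (i in seq_len(n0)) {
    t0 <- 0; s0 <- s_init[i]; d <- 0L
    v0 <- 1
    j <- 1L                                   # next snapshot index
    K0 <- 0
    repeat {
      target <- K0 + stats::rexp(1) * v0 / s0
      if (target >= K_end) {                  # no further division
        while (j <= length(snaps)) {
          S[i, j] <- s0 * tab_interp(snaps[j], tab$t, tab$v) / v0
          D[i, j] <- d
          j <- j + 1L
        }
        break
      }
      vt <- invert_hazard(target, tab)
      while (j <= length(snaps) && snaps[j] < vt[2]) {
        S[i, j] <- s0 * tab_interp(snaps[j], tab$t, tab$v) / v0
        D[i, j] <- d
        j <- j + 1L
      }
      s_star <- s0 * vt[1] / v0
      n_div <- n_div + 1L
      if (track_divisions) {
        if (n_div > length(div_t)) {
          div_t <- c(div_t, numeric(length(div_t)))
          div_birth <- c(div_birth, numeric(length(div_birth)))
          div_size <- c(div_size, numeric(length(div_size)))
          div_bt <- c(div_bt, numeric(length(div_bt)))
        }
        div_t[n_div] <- vt[2]; div_birth[n_div] <- s0
        div_size[n_div] <- s_star; div_bt[n_div] <- t0
      }
      t0 <- vt[2]
      s0 <- s_star / 2; v0 <- vt[1]; K0 <- target; d <- d + 1L
      if (j > length(snaps)) break
    }
  }
  states <- lapply(seq_along(snaps), function(j) {
    structure(list(time_h = snaps[j], sizes_um3 = S[, j],
                   weights = 2^as.numeric(D[, j]), n_alive = n0,
                   cumulative_divisions = sum(D[, j])),
              class = "population_state")
  })
  names(states) <- format(snaps)
  divisions <- make_division_log(track_divisions, n_div, div_t, div_birth,
                                 div_size, div_bt)
  list(states = states, divisions = divisions, subsampled = FALSE)
}

make_division_log <- function(track, n_div, div_t, div_birth, div_size,
                              div_bt) {
  if (!track || n_div == 0L) return(NULL)
  keep <- seq_len(n_div)
  df <- data.frame(time_h = div_t[keep], birth_time_h = div_bt[keep],
                   birth_size_um3 = div_birth[keep],
                   division_size_um3 = div_size[keep],
                   added_size_um3 = div_size[keep] - div_birth[keep])
  df[order(df$time_h), , drop = FALSE]
}

simulate_tree <- function(config, tab, s_init, track_divisions) {
  snaps <- config$snapshot_times_h
  controls <- sort(unique(c(0, snaps, config$t_end_h)))
  K_at <- function(x) tab_interp(x, tab$t, tab$K)
  v_at <- function(x) tab_interp(x, tab$t, tab$v)
  cur_s <- s_init
  cur_birth_s <- cur_s          # size at (actual) birth, for added-size log
  cur_birth_t <- rep.int(0, config$n0)
  cur_w <- rep.int(1, config$n0)
  n_div <- 0L
  div_t <- numeric(1024); div_birth <- numeric(1024); div_size <- numeric(1024)
  div_bt <- numeric(1024)
  subsampled <- FALSE
  states <- vector("list", length(snaps))
  names(states) <- format(snaps)
  record <- function(ts) {
    structure(list(time_h = ts, sizes_um3 = cur_s, weights = cur_w,
                   n_alive = length(cur_s),
                   cumulative_divisions = n_div),
              class = "population_state")
  }
  si <- match(controls[1], snaps, nomatch = 0L)
  if (si > 0) states[[si]] <- record(controls[1])

  for (ci in seq_len(length(controls) - 1L)) {
    t0c <- controls[ci]; t1c <- controls[ci + 1L]
    K_end <- K_at(t1c)
    cap0 <- 2L * max(length(cur_s), 64L)
    st_t <- numeric(cap0); st_s <- numeric(cap0); st_b <- numeric(cap0)
    st_w <- numeric(cap0); st_bt <- numeric(cap0)
    top <- length(cur_s)
    st_t[seq_len(top)] <- t0c
    st_s[seq_len(top)] <- cur_s
    st_b[seq_len(top)] <- cur_birth_s
    st_bt[seq_len(top)] <- cur_birth_t
    st_w[seq_len(top)] <- cur_w
    out_s <- numeric(cap0); out_b <- numeric(cap0); out_w <- numeric(cap0)
    out_bt <- numeric(cap0)
    n_out <- 0L
    v_t1 <- v_at(t1c)
    hard_cap <- if (config$on_cap == "error") config$pop_cap
                else 8L * config$pop_cap
    while (top > 0L) {
      t0 <- st_t[top]; s0 <- st_s[top]; b0 <- st_b[top]; w0 <- st_w[top]
      bt0 <- st_bt[top]
      top <- top - 1L
      target <- K_at(t0) + stats::rexp(1) * v_at(t0) / s0
      if (target >= K_end) {             # survives this chunk
        n_out <- n_out + 1L
        if (n_out > length(out_s)) {     # grow survivor store
          out_s <- c(out_s, numeric(length(out_s)))
          out_b <- c(out_b, numeric(length(out_b)))
          out_w <- c(out_w, numeric(length(out_w)))
          out_bt <- c(out_bt, numeric(length(out_bt)))
        }
        out_s[n_out] <- s0 * v_t1 / v_at(t0)
        out_b[n_out] <- b0
        out_bt[n_out] <- bt0
        out_w[n_out] <- w0
        next
      }
      vt <- invert_hazard(target, tab)
      t_star <- vt[2]
      s_star <- s0 * vt[1] / v_at(t0)
      n_div <- n_div + 1L
      if (track_divisions) {
        if (n_div > length(div_t)) {
          div_t <- c(div_t, numeric(length(div_t)))
          div_birth <- c(div_birth, numeric(length(div_birth)))
          div_size <- c(div_size, numeric(length(div_size)))
          div_bt <- c(div_bt, numeric(length(div_bt)))
        }
        div_t[n_div] <- t_star; div_birth[n_div] <- b0
        div_size[n_div] <- s_star; div_bt[n_div] <- bt0
      }
      if (n_out + top + 2L > hard_cap)
        stop("population exceeded pop_cap (", config$pop_cap,
             "); rerun with on_cap = \"subsample\" or a larger cap")
      if (top + 2L > length(st_t)) {      # grow the stack
        st_t <- c(st_t, numeric(length(st_t)))
        st_s <- c(st_s, numeric(length(st_s)))
        st_b <- c(st_b, numeric(length(st_b)))
        st_bt <- c(st_bt, numeric(length(st_bt)))
        st_w <- c(st_w, numeric(length(st_w)))
      }
      half <- s_star / 2
      st_t[top + 1L] <- t_star; st_s[top + 1L] <- half
      st_b[top + 1L] <- half; st_w[top + 1L] <- w0
      st_bt[top + 1L] <- t_star
      st_t[top + 2L] <- t_star; st_s[top + 2L] <- half
      st_b[top + 2L] <- half; st_w[top + 2L] <- w0
      st_bt[top + 2L] <- t_star
      top <- top + 2L
    }
    cur_s <- out_s[seq_len(n_out)]
    cur_birth_s <- out_b[seq_len(n_out)]
    cur_birth_t <- out_bt[seq_len(n_out)]
    cur_w <- out_w[seq_len(n_out)]
    si <- match(t1c, snaps, nomatch = 0L)
    if (si > 0) states[[si]] <- record(t1c)
    # population-cap policy (applied after recording the snapshot)
    while (length(cur_s) > config$pop_cap) {
      if (config$on_cap == "error")
        stop("population exceeded pop_cap (", config$pop_cap,
             "); rerun with on_cap = \"subsample\" or a larger cap")
      subsampled <- TRUE
      keep <- sample.int(length(cur_s), ceiling(length(cur_s) / 2))
      cur_s <- cur_s[keep]; cur_birth_s <- cur_birth_s[keep]
      cur_birth_t <- cur_birth_t[keep]
      cur_w <- 2 * cur_w[keep]
    }
  }
  divisions <- make_division_log(track_divisions, n_div, div_t, div_birth,
                                 div_size, div_bt)
  list(states = states, divisions = divisions, subsampled = subsampled)
}

#' @export
print.sim_result <- function(x, ...) {
  last <- x$states[[length(x$states)]]
  cat(sprintf(
    "Stochastic growth-division run (%s): %d snapshots, final n = %d (sum w = %g), %d divisions%s\n",
    x$config$division, length(x$states), last$n_alive, sum(last$weights),
    last$cumulative_divisions,
    if (x$subsampled) ", population reweighted at cap" else ""))
  invisible(x)
}

#' Per-snapshot population summaries of a simulation
#'
#' `mean_size_um3` is the unweighted mean over tracked cells: in lineage
#' mode this is the ensemble mean described by the mean-field equation; in
#' tree mode it coincides with the population snapshot mean.
#' `pop_mean_size_um3` is the weight-corrected population mean
#' (total volume / total count estimate), which in lineage mode carries the
#' proliferation bias of a real population snapshot.
#'
#' @param sim a `sim_result`.
#' @return data.frame with one row per snapshot: `time_h`, `n_alive`,
#'   `total_weight` (population-count estimate), `total_volume_um3`
#'   (weighted), `biomass_um3` (exact), `mean_size_um3`,
#'   `pop_mean_size_um3`, `cumulative_divisions`.
#' @export
population_summary <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  rows <- lapply(sim$states, function(st) {
    tw <- sum(st$weights)
    data.frame(time_h = st$time_h, n_alive = st$n_alive, total_weight = tw,
               total_volume_um3 = sum(st$weights * st$sizes_um3),
               biomass_um3 = st$biomass_um3,
               mean_size_um3 = mean(st$sizes_um3),
               pop_mean_size_um3 = sum(st$weights * st$sizes_um3) / tw,
               cumulative_divisions = st$cumulative_divisions)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observe a simulation through OD-, CFU- and microscopy-like channels
#'
#' Converts snapshots into the three measurement tables the analysis
#' pipeline consumes: an OD600-like series proportional to the total
#' population volume (exact biomass; growth is deterministic and division
#' conserves volume), a CFU-like series proportional to the population
#' count (exact in tree mode; the weighted estimate `sum(2^divisions)` in
#' lineage mode), and a per-cell table in which a uniform subsample of
#' tracked cells is mapped to sphero-cylinder (length, width) pairs —
#' fixed width, length solved from the capsule volume; cells below the
#' sphere volume are rendered as spheres — and corrupted by independent
#' multiplicative log-normal noise on length and width before the
#' projected area is recomputed.
#'
#' @param sim a `sim_result` from [simulate_population()].
#' @param n_replicates replicate series generated for OD and CFU.
#' @param series_noise_log_sd multiplicative log-normal noise applied to
#'   each OD/CFU replicate measurement.
#' @param seed seed for measurement noise and subsampling.
#' @return list with `od` (condition, time_h, od600_corrected,
#'   in_dilution_window, replicate), `cfu` (time_h, bio_rep, tech_rep,
#'   cfu_per_ml), and `cells` (cell_id, condition, time_h,
#'   projected_area_um2, length_um, true_volume_um3).
#' @export
observe <- function(sim, n_replicates = 1, series_noise_log_sd = 0,
                    seed = sim$config$seed + 1) {
  stopifnot(inherits(sim, "sim_result"))
  cfg <- sim$config
  set.seed(seed)
  summ <- population_summary(sim)
  reps <- lapply(seq_len(n_replicates), function(r) {
    noise_od <- exp(stats::rnorm(nrow(summ), 0, series_noise_log_sd))
    noise_cfu <- exp(stats::rnorm(nrow(summ), 0, series_noise_log_sd))
    list(od = data.frame(condition = cfg$condition, time_h = summ$time_h,
                         od600_corrected = cfg$od_per_um3 *
                           summ$biomass_um3 * noise_od,
                         in_dilution_window = 0L, replicate = r),
         cfu = data.frame(time_h = summ$time_h, bio_rep = r, tech_rep = 1L,
                          cfu_per_ml = cfg$cfu_scale * summ$total_weight *
                            noise_cfu))
  })
  od <- do.call(rbind, lapply(reps, `[[`, "od"))
  cfu <- do.call(rbind, lapply(reps, `[[`, "cfu"))

  cells <- do.call(rbind, lapply(sim$states, function(st) {
    n <- length(st$sizes_um3)
    m <- min(cfg$subsample, n)
    idx <- if (m < n) sample.int(n, m) else seq_len(n)
    v <- st$sizes_um3[idx]
    if (cfg$width_model == "isometric") {
      # capsule volume at fixed aspect a: V = pi (a/4 - 1/12) w^3
      w <- (v / (pi * (cfg$aspect / 4 - 1 / 12)))^(1 / 3)
      l <- cfg$aspect * w
    } else {
      w0 <- cfg$width_um
      sphere <- v < pi * w0^3 / 6
      w <- ifelse(sphere, (6 * v / pi)^(1 / 3), w0)
      l <- ifelse(sphere, w, 4 * v / (pi * w0^2) + w0 / 3)
    }
    l <- l * exp(stats::rnorm(m, 0, cfg$noise_log_sd))
    w <- pmin(w * exp(stats::rnorm(m, 0, cfg$noise_log_sd)), l)
    data.frame(cell_id = sprintf("t%g_c%04d", st$time_h, seq_len(m)),
               condition = cfg$condition, time_h = st$time_h,
               projected_area_um2 = capsule_area(l, w), length_um = l,
               true_volume_um3 = v)
  }))
  rownames(cells) <- NULL
  list(od = od, cfu = cfu, cells = cells)
}

#' Rasterise a sphero-cylinder into a binary pixel mask
#'
#' Renders a capsule of length `length_um` and width `width_um`, rotated by
#' `angle_deg`, onto a square pixel grid centred on the cell (a pixel is
#' foreground when its centre lies within `width/2` of the capsule's axis
#' segment). Useful as a ground-truth fixture for [measure_mask()].
#'
#' @param length_um,width_um capsule dimensions, micrometres (`w <= L`).
#' @param angle_deg orientation of the long axis, degrees.
#' @param pixel_area_um2 pixel area; pixel side is its square root.
#' @return logical matrix.
#' @export
render_mask <- function(length_um, width_um, angle_deg = 0,
                        pixel_area_um2 = 0.005) {
  stopifnot(length_um > 0, width_um > 0, width_um <= length_um,
            pixel_area_um2 > 0)
  p <- sqrt(pixel_area_um2)
  if (width_um / 2 < p)
    stop("degenerate sub-pixel shape: width must span at least 2 pixels")
  half_axis <- (length_um - width_um) / 2
  r <- width_um / 2
  n <- ceiling((length_um / 2 + p) / p)
  # half-pixel offset: an aligned lattice systematically over-covers the
  # boundary; the offset grid keeps pixel-count area unbiased and preserves
  # the quarter-turn symmetry
  centers <- (seq(-n, n - 1) + 0.5) * p
  theta <- angle_deg * pi / 180
  u <- c(cos(theta), sin(theta))
  xx <- matrix(centers, length(centers), length(centers))
  yy <- t(xx)
  proj <- xx * u[1] + yy * u[2]
  proj <- pmin(pmax(proj, -half_axis), half_axis)
  dx <- xx - proj * u[1]
  dy <- yy - proj * u[2]
  dx * dx + dy * dy <= r * r
}
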