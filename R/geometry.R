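#' Projected area of a sphero-cylinder (capsule)
#'
#' A rod-shaped bacterium is modelled as a capsule: a cylinder of length
#' `L - w` capped by two hemispheres of diameter `w`. Its projection onto the
#' image plane is a rectangle of sides `L - w` and `w` plus two half-disks,
#' giving area `w (L - w) + pi (w/2)^2`.
#'
#' @param length_um cell length L in micrometres (the long axis, caps
#'   included).
#' @param width_um cell width w in micrometres; must satisfy `0 < w <= L`.
#' @return projected area in square micrometres.
#' @seealso [width_from_area_length()] for the inverse.
#' @export
capsule_area <- function(length_um, width_um) {
  stopifnot(all(width_um > 0), all(length_um > 0))
  if (any(width_um > length_um * (1 + 1e-12)))
    stop("capsule geometry requires width <= length")
  width_um * (length_um - width_um) + pi * (width_um / 2)^2
}

#' Recover cell width from projected area and length
#'
#' Inverts the capsule projected-area relation
#' `A_p = w (L - w) + pi (w/2)^2` for the width. Rearranged, w is a root of
#' the quadratic `(pi/4 - 1) w^2 + L w - A_p = 0`, whose leading coefficient
#' is negative; only the smaller positive root can satisfy `0 < w <= L`, so
#' that root is returned.
#'
#' @param projected_area_um2 projected area A_p in square micrometres.
#' @param length_um cell length L in micrometres.
#' @return width in micrometres; `NA_real_` where no admissible real root in
#'   `(0, L]` exists (the record should be rejected upstream). Vectorised.
#' @examples
#' width_from_area_length(capsule_area(4, 1), 4)  # 1
#' @export
width_from_area_length <- function(projected_area_um2, length_um) {
  n <- max(length(projected_area_um2), length(length_um))
  a_p <- rep_len(as.numeric(projected_area_um2), n)
  l <- rep_len(as.numeric(length_um), n)
  w <- rep.int(NA_real_, n)
  ok <- !is.na(a_p) & !is.na(l) & a_p > 0 & l > 0
  cc <- pi / 4 - 1                       # < 0
  disc <- l^2 + 4 * cc * a_p
  ok <- ok & disc >= 0
  # smaller positive root of cc*w^2 + l*w - a_p
  root <- (-l[ok] + sqrt(disc[ok])) / (2 * cc)
  # admissible only in (0, L]; allow a whisker of rounding above L
  adm <- root > 0 & root <= l[ok] * (1 + 1e-9)
  root[!adm] <- NA_real_
  w[ok] <- pmin(root, l[ok])
  w
}

#' Surface area and volume of a sphero-cylinder
#'
#' For a capsule of length L and width w: surface `A = pi L w` and volume
#' `V = pi L w^2 / 4 - pi w^3 / 12` (cylinder plus two hemispherical caps).
#' At `L = w` these reduce to the sphere values `pi w^2` and `pi w^3 / 6`.
#'
#' @param length_um,width_um capsule dimensions in micrometres, `0 < w <= L`.
#' @return a list with numeric components `surface_um2` and `volume_um3`.
#' @export
surface_and_volume <- function(length_um, width_um) {
  stopifnot(all(width_um > 0), all(length_um > 0))
  if (any(width_um > length_um * (1 + 1e-9)))
    stop("inconsistent geometry: width exceeds length")
  list(
    surface_um2 = pi * length_um * width_um,
    volume_um3  = pi * length_um * width_um^2 / 4 - pi * width_um^3 / 12
  )
}

#' Derive width, volume and surface for a table of segmented cells
#'
#' Takes one row per cell with columns `projected_area_um2` and `length_um`
#' (plus any id/label columns, conventionally `cell_id`, `condition`,
#' `time_h`) and appends `width_um`, `volume_um3`, `surface_um2` and
#' `sv_ratio` (surface-to-volume, per micrometre). Rows whose measurements
#' admit no capsule geometry are split off rather than silently dropped.
#'
#' @param cells data.frame of per-cell measurements.
#' @return list with `cells` (rows with valid derived geometry) and
#'   `rejected` (rows with no admissible width, with a `reason` column).
#' @export
derive_dimensions <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("projected_area_um2", "length_um") %in% names(cells)))
  w <- width_from_area_length(cells$projected_area_um2, cells$length_um)
  bad <- is.na(w)
  out <- cells[!bad, , drop = FALSE]
  out$width_um <- w[!bad]
  sv <- surface_and_volume(out$length_um, out$width_um)
  out$volume_um3 <- sv$volume_um3
  out$surface_um2 <- sv$surface_um2
  out$sv_ratio <- sv$surface_um2 / sv$volume_um3
  rej <- cells[bad, , drop = FALSE]
  if (nrow(rej)) rej$reason <- "no_admissible_width"
  list(cells = out, rejected = rej)
}

#' Morphometric filter thresholds
#'
#' Bundle of hard thresholds used to discard segmentation artefacts. The
#' defaults keep cells with width above 0.35 um, length strictly between
#' 1.05 and 10 um, aspect ratio (L/w) strictly between 1 and 7, and
#' projected area above 0.73 um^2 — plus a per-time-point filter removing
#' cells whose log-volume deviates from the group mean by more than
#' `log_sigma_mult` log-standard-deviations.
#'
#' @param min_width_um,min_length_um,max_length_um,min_aspect,max_aspect,min_area_um2
#'   hard thresholds (micrometre units; all strict inequalities).
#' @param log_sigma_mult multiplier for the log-space volume filter.
#' @return an object of class `filter_criteria`.
#' @export
filter_criteria <- function(min_width_um = 0.35, min_length_um = 1.05,
                            max_length_um = 10, min_aspect = 1,
                            max_aspect = 7, min_area_um2 = 0.73,
                            log_sigma_mult = 3) {
  stopifnot(min_width_um > 0, min_length_um > 0, min_area_um2 > 0,
            min_length_um < max_length_um, min_aspect < max_aspect,
            log_sigma_mult > 0)
  structure(list(min_width_um = min_width_um, min_length_um = min_length_um,
                 max_length_um = max_length_um, min_aspect = min_aspect,
                 max_aspect = max_aspect, min_area_um2 = min_area_um2,
                 log_sigma_mult = log_sigma_mult),
            class = "filter_criteria")
}

#' @export
print.filter_criteria <- function(x, ...) {
  cat("Morphometric filter criteria (strict inequalities):\n")
  cat(sprintf("  width      > %g um\n", x$min_width_um))
  cat(sprintf("  length     in (%g, %g) um\n", x$min_length_um, x$max_length_um))
  cat(sprintf("  aspect L/w in (%g, %g)\n", x$min_aspect, x$max_aspect))
  cat(sprintf("  area       > %g um^2\n", x$min_area_um2))
  cat(sprintf("  log-volume within %g sigma of group mean\n", x$log_sigma_mult))
  invisible(x)
}

#' Apply the hard morphometric filters
#'
#' Keeps cells satisfying, simultaneously and strictly:
#' `w > min_width`, `min_length < L < max_length`,
#' `min_aspect < L/w < max_aspect` and `A_p > min_area`.
#' The rejection log records the first criterion each discarded cell failed,
#' checked in that order; the kept set itself is order-independent.
#'
#' @param cells data.frame with derived `width_um` (see
#'   [derive_dimensions()]), `length_um` and `projected_area_um2`.
#' @param criteria a [filter_criteria()] object.
#' @return list with `kept` (data.frame) and `rejection_log` (data.frame of
#'   rejected rows plus a `criterion` column).
#' @export
apply_hard_filters <- function(cells, criteria = filter_criteria()) {
  stopifnot(is.data.frame(cells), inherits(criteria, "filter_criteria"),
            all(c("width_um", "length_um", "projected_area_um2") %in% names(cells)))
  w <- cells$width_um; l <- cells$length_um; a <- cells$projected_area_um2
  asp <- l / w
  fail_width  <- !(w > criteria$min_width_um)
  fail_length <- !(l > criteria$min_length_um & l < criteria$max_length_um)
  fail_aspect <- !(asp > criteria$min_aspect & asp < criteria$max_aspect)
  fail_area   <- !(a > criteria$min_area_um2)
  keep <- !(fail_width | fail_length | fail_aspect | fail_area)
  criterion <- rep.int(NA_character_, nrow(cells))
  criterion[fail_area]   <- "area"
  criterion[fail_aspect] <- "aspect"
  criterion[fail_length] <- "length"
  criterion[fail_width]  <- "width"   # listed order: first failure wins
  log_df <- cells[!keep, , drop = FALSE]
  if (nrow(log_df)) log_df$criterion <- criterion[!keep]
  list(kept = cells[keep, , drop = FALSE], rejection_log = log_df)
}

#' Per-time-point log-space volume outlier filter
#'
#' Within one group of cells (a single sampling time), discards cells whose
#' log-transformed volume deviates from the group mean log-volume by more
#' than `log_sigma_mult` times the group log-standard-deviation. Mean and sd
#' are computed once on the pre-removal data (a single pass, not iterated).
#' Under a log-normal size distribution the default multiplier of 3 retains
#' approximately 99.7% of cells.
#'
#' @param cells data.frame with a `volume_um3` column, all from one time
#'   point. Groups with fewer than 3 cells pass through unfiltered.
#' @param log_sigma_mult deviation threshold in units of log-sd.
#' @return the kept subset of `cells`.
#' @export
log_sigma_filter <- function(cells, log_sigma_mult = 3) {
  stopifnot(is.data.frame(cells), "volume_um3" %in% names(cells),
            all(cells$volume_um3 > 0))
  if (nrow(cells) < 3) return(cells)
  lv <- log(cells$volume_um3)
  m <- mean(lv)
  s <- stats::sd(lv)
  if (s == 0) return(cells)
  cells[abs(lv - m) <= log_sigma_mult * s, , drop = FALSE]
}

#' Full outlier filtering for a multi-time-point cell table
#'
#' Applies [apply_hard_filters()] to the whole table, then
#' [log_sigma_filter()] within each `(condition, time_h)` group.
#'
#' @param cells data.frame with derived geometry and `condition`, `time_h`.
#' @param criteria a [filter_criteria()] object.
#' @return list with `kept` and `rejection_log` (hard-filter rejections).
#' @export
filter_cells <- function(cells, criteria = filter_criteria()) {
  hard <- apply_hard_filters(cells, criteria)
  kept <- hard$kept
  if (nrow(kept)) {
    key <- interaction(kept$condition, kept$time_h, drop = TRUE)
    pieces <- lapply(split(kept, key), log_sigma_filter,
                     log_sigma_mult = criteria$log_sigma_mult)
    kept <- do.call(rbind, pieces)
    rownames(kept) <- NULL
  }
  list(kept = kept, rejection_log = hard$rejection_log)
}

#' Per-group size summaries with bootstrap confidence half-widths
#'
#' For each `(condition, time_h)` group of filtered cells, computes the cell
#' count, mean and sd of volume, mean length, width and surface-to-volume
#' ratio, and a percentile-bootstrap 95% half-width for the mean volume.
#'
#' @param cells filtered data.frame with derived geometry.
#' @param bootstrap_reps bootstrap resamples for the mean-volume CI.
#' @param seed integer seed making the bootstrap reproducible.
#' @param conf confidence level for the bootstrap interval.
#' @return data.frame, one row per group, ordered by condition then time.
#' @export
summarize_cells <- function(cells, bootstrap_reps = 1000, seed = 1,
                            conf = 0.95) {
  stopifnot(is.data.frame(cells),
            all(c("condition", "time_h", "volume_um3", "length_um",
                  "width_um", "sv_ratio") %in% names(cells)))
  if (nrow(cells) == 0) {
    return(data.frame(condition = character(), time_h = numeric(),
                      n_cells = integer(), mean_volume_um3 = numeric(),
                      sd_volume_um3 = numeric(), mean_length_um = numeric(),
                      mean_width_um = numeric(),
                      mean_sv_ratio_per_um = numeric(),
                      ci_halfwidth_volume = numeric()))
  }
  key <- interaction(cells$condition, cells$time_h, drop = TRUE)
  groups <- split(cells, key)
  alpha <- (1 - conf) / 2
  rows <- lapply(groups, function(g) {
    v <- g$volume_um3
    set.seed(seed)  # per-group reset: summaries independent of group order
    hw <- 0
    if (length(v) > 1) {
      boot_means <- vapply(seq_len(bootstrap_reps), function(i)
        mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
      q <- stats::quantile(boot_means, c(alpha, 1 - alpha), names = FALSE)
      hw <- (q[2] - q[1]) / 2
    }
    data.frame(condition = g$condition[1], time_h = g$time_h[1],
               n_cells = length(v), mean_volume_um3 = mean(v),
               sd_volume_um3 = if (length(v) > 1) stats::sd(v) else 0,
               mean_length_um = mean(g$length_um),
               mean_width_um = mean(g$width_um),
               mean_sv_ratio_per_um = mean(g$sv_ratio),
               ci_halfwidth_volume = hw)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}
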