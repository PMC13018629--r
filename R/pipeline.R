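#' Infer division dynamics from size summaries and a growth fit
#'
#' Convenience wrapper tying the pipeline together: takes the per-time
#' summary table from [summarize_cells()] (or any table with `time_h` and
#' `mean_volume_um3`) and a fitted growth curve, and fits the
#' division-coefficient schedule by [fit_division_schedule()]. The initial
#' mean size is the first observed mean (overnight culture).
#'
#' @param size_summary data.frame with `time_h`, `mean_volume_um3` and
#'   optionally `ci_halfwidth_volume`.
#' @param growth_fit a [fit_growth()] result (or constant growth rate).
#' @param ... passed to [fit_division_schedule()] (`n_starts`, `seed`,
#'   `bounds`, ...).
#' @return a `schedule_fit`.
#' @export
infer_division_dynamics <- function(size_summary, growth_fit, ...) {
  stopifnot(is.data.frame(size_summary),
            all(c("time_h", "mean_volume_um3") %in% names(size_summary)))
  ord <- order(size_summary$time_h)
  times <- size_summary$time_h[ord]
  obs <- size_summary$mean_volume_um3[ord]
  fit_division_schedule(mu_fn = mu_function(growth_fit),
                        s0 = obs[1], times = times, observed = obs, ...)
}

#' Read a per-cell measurement table
#'
#' Expects columns `cell_id`, `condition`, `time_h`, `projected_area_um2`,
#' `length_um` (extra columns are kept).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "condition", "time_h", "projected_area_um2", "length_um")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cell table is missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Read an OD600 table into growth curves
#'
#' Expects columns `condition`, `time_h`, `od600_corrected` (already
#' multiplied by dilution factors) and optionally `in_dilution_window`
#' (0/1); returns one [growth_curve()] per condition, averaging replicate
#' rows at identical times.
#'
#' @param path CSV file path.
#' @return named list of `growth_curve` objects.
#' @export
read_od_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "time_h", "od600_corrected")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("OD table is missing columns: ", paste(missing, collapse = ", "))
  lapply(split(df, df$condition), function(d) {
    agg <- stats::aggregate(d$od600_corrected, by = list(time_h = d$time_h),
                            FUN = mean)
    window <- NULL
    if ("in_dilution_window" %in% names(d) && any(d$in_dilution_window > 0)) {
      tw <- d$time_h[d$in_dilution_window > 0]
      window <- range(tw)
    }
    growth_curve(agg$time_h, agg$x, dilution_window = window,
                 condition = d$condition[1])
  })
}

#' Read a replicated CFU table
#'
#' Expects columns `time_h`, `bio_rep`, `tech_rep`, `cfu_per_ml`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_cfu_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "bio_rep", "tech_rep", "cfu_per_ml")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CFU table is missing columns: ", paste(missing, collapse = ", "))
  df
}
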