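# Thermal-regime covariates from Lagrangian drift trajectories and origin
# sea-surface-temperature series: per-replicate medians and interquartile
# ranges, then a trajectory-length-weighted average across replicates.

#' Summarize drift trajectories for one location/depth
#'
#' For each replicate trajectory, the median and interquartile range of
#' temperature and latitude are computed over the first `duration` days (or
#' the full record when shorter); the per-replicate statistics are then
#' averaged across replicates weighted by the number of days each replicate
#' actually contributed.  Statistics are computed per trajectory *first* —
#' pooling all days before summarizing gives different (wrong) answers.
#' Quantiles use linear interpolation between order statistics (R's default
#' type 7 rule).
#'
#' @param trajs Data frame with columns `replicate_id`, `day`,
#'   `temperature_C`, `latitude_deg` (a single location/depth; see
#'   [env_summaries()] for the grouped version).
#' @param duration Days to use: one of 50, 150, 250, 350, 500.
#' @return One-row data frame: `t_med`, `lat_med`, `t_iqr`, `lat_iqr`,
#'   `duration`, `n_replicates`.
#' @export
summarize_trajectories <- function(trajs, duration) {
  if (!duration %in% c(50, 150, 250, 350, 500))
    stop("duration must be one of 50, 150, 250, 350, 500")
  reps <- split(trajs, trajs$replicate_id)
  stats <- lapply(reps, function(r) {
    r <- r[order(r$day), , drop = FALSE]
    r <- r[r$day <= duration, , drop = FALSE]
    if (!nrow(r)) {
      message("empty replicate skipped")
      return(NULL)
    }
    c(t_med = median(r$temperature_C), lat_med = median(r$latitude_deg),
      t_iqr = IQR(r$temperature_C), lat_iqr = IQR(r$latitude_deg),
      w = nrow(r))
  })
  stats <- do.call(rbind, stats[!vapply(stats, is.null, logical(1))])
  if (is.null(stats) || !nrow(stats)) stop("no usable replicates")
  w <- stats[, "w"]
  wmean <- function(x) sum(w * x) / sum(w)
  data.frame(t_med = wmean(stats[, "t_med"]),
             lat_med = wmean(stats[, "lat_med"]),
             t_iqr = wmean(stats[, "t_iqr"]),
             lat_iqr = wmean(stats[, "lat_iqr"]),
             duration = duration, n_replicates = nrow(stats))
}

#' Median and interquartile range of an origin SST series
#'
#' @param daily_sst Numeric vector of daily sea surface temperatures (degC).
#' @return c(t_med_orig, t_iqr_orig).
#' @export
summarize_origin <- function(daily_sst) {
  daily_sst <- daily_sst[is.finite(daily_sst)]
  if (!length(daily_sst)) stop("empty SST series")
  c(t_med_orig = median(daily_sst), t_iqr_orig = IQR(daily_sst))
}

#' Environmental summary table over locations, depths and durations
#'
#' @param trajs Data frame with `location_id`, `depth_m`, `replicate_id`,
#'   `day`, `temperature_C`, `latitude_deg`.
#' @param durations Durations (days) to evaluate.
#' @param sst Optional data frame `location_id`, `sst_C` with origin daily
#'   SST series; adds `t_med_orig`/`t_iqr_orig` columns.
#' @return Data frame with one row per location x depth x duration.
#' @export
env_summaries <- function(trajs, durations = c(50, 150, 250, 350, 500),
                          sst = NULL) {
  groups <- split(trajs, list(trajs$location_id, trajs$depth_m), drop = TRUE)
  rows <- list()
  for (g in groups) {
    for (dur in durations) {
      r <- summarize_trajectories(g, dur)
      r$location_id <- g$location_id[[1]]
      r$depth_m <- g$depth_m[[1]]
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(sst)) {
    per_loc <- lapply(split(sst$sst_C, sst$location_id), summarize_origin)
    out$t_med_orig <- vapply(as.character(out$location_id),
                             function(l) per_loc[[l]][["t_med_orig"]],
                             numeric(1))
    out$t_iqr_orig <- vapply(as.character(out$location_id),
                             function(l) per_loc[[l]][["t_iqr_orig"]],
                             numeric(1))
  }
  rownames(out) <- NULL
  out
}
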