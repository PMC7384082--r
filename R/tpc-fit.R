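# Per-curve model fitting: preprocessing, multi-start Levenberg-Marquardt
# least squares, quality filtering and data-coverage reliability flags.

trait_names <- function() c("b0_qrt", "ln_e", "tpk_sq", "ln_bpk", "ln_ed", "ln_wop")

#' Construct a growth-rate-versus-temperature series
#'
#' @param taxon_id Character scalar identifying the species/strain.
#' @param temperature Temperatures in kelvin (use `celsius = TRUE` for deg C
#'   input, converted by +273.15).
#' @param rate Growth rates (time^-1); nonpositive values are allowed here
#'   and removed by [preprocess_series()].
#' @param habitat One of `"marine"`, `"freshwater"`, `"unknown"`.
#' @param latitude,longitude Isolation location in degrees (optional).
#' @param cell_volume Cell volume in cubic micrometres (optional).
#' @param celsius If `TRUE`, `temperature` is given in Celsius.
#'
#' @return An object of class `growth_series`.
#' @export
growth_series <- function(taxon_id, temperature, rate,
                          habitat = "unknown", latitude = NA_real_,
                          longitude = NA_real_, cell_volume = NA_real_,
                          celsius = FALSE) {
  stopifnot(length(temperature) == length(rate), length(temperature) >= 1L)
  habitat <- match.arg(habitat, c("marine", "freshwater", "unknown"))
  if (celsius) temperature <- temperature + 273.15
  structure(list(taxon_id = as.character(taxon_id),
                 temperature = as.numeric(temperature),
                 rate = as.numeric(rate),
                 habitat = habitat, latitude = latitude,
                 longitude = longitude, cell_volume = cell_volume),
            class = "growth_series")
}

#' Remove nonpositive rates and sort a series by temperature
#'
#' The Sharpe-Schoolfield model is strictly positive (its numerator is an
#' exponential), so zero or negative growth-rate measurements cannot be
#' described by it and are removed before fitting.
#'
#' @param series A [growth_series()].
#' @return The cleaned series, with attribute `n_removed` giving the count
#'   of discarded points.  Fewer than 4 surviving points (the number of free
#'   parameters) raises an "insufficient data" error.
#' @export
preprocess_series <- function(series) {
  stopifnot(inherits(series, "growth_series"))
  keep <- is.finite(series$rate) & series$rate > 0 & is.finite(series$temperature)
  n_removed <- sum(!keep)
  if (sum(keep) < 4L)
    stop(sprintf("insufficient data: %d positive points after removing %d (need >= 4)",
                 sum(keep), n_removed))
  ord <- order(series$temperature[keep])
  out <- series
  out$temperature <- series$temperature[keep][ord]
  out$rate <- series$rate[keep][ord]
  attr(out, "n_removed") <- n_removed
  out
}

ss_curve <- function(b0, e_act, t_pk, d_ed, t_ref, temp) {
  k <- boltzmann_k
  e_d <- e_act + d_ed
  b0 * exp(-e_act / k * (1 / temp - 1 / t_ref)) /
    (1 + e_act / d_ed * exp(e_d / k * (1 / t_pk - 1 / temp)))
}

#' Fit the Sharpe-Schoolfield model to one series
#'
#' Nonlinear least squares via the Levenberg-Marquardt algorithm
#' (`minpack.lm::nlsLM`) over bounded parameters, with a multi-start
#' schedule: activation-energy starts \{0.3, 0.65, 1.2\} eV crossed with peak
#' starts at the temperature of the observed maximum rate and +/- 3 K.  The
#' deactivation energy is optimized as the positive offset `d_ed = e_d -
#' e_act` so the constraint `e_d > e_act` holds structurally; the reported
#' 4x4 estimate covariance is mapped back to (b0, e_act, t_pk, e_d).  The
#' start with the lowest residual sum of squares wins; exact ties go to the
#' lower activation energy.
#'
#' @param series A preprocessed [growth_series()] (all rates positive).
#' @param t_ref Reference temperature in kelvin (273.15 or 283.15 in the
#'   standard analyses).
#'
#' @return A `tpc_fit` object: `params` ([tpc_params()]), `derived` (Bpk,
#'   Wop, B(Tref)), `param_covariance` (4x4, possibly NA for saturated
#'   fits), `r_squared`, `n_points`, `missing_mask` (six named flags, filled
#'   by [mark_uncertain_params()]), `converged`.
#' @export
fit_sharpe_schoolfield <- function(series, t_ref = 273.15) {
  stopifnot(inherits(series, "growth_series"))
  temp <- series$temperature
  rate <- series$rate
  if (any(rate <= 0)) series <- preprocess_series(series)
  temp <- series$temperature; rate <- series$rate
  n <- length(rate)
  if (n < 4L) stop("insufficient data: need >= 4 positive points")

  lower <- c(b0 = 1e-10, e_act = 1e-2, t_pk = min(temp) - 10, d_ed = 1e-3)
  upper <- c(b0 = 1e3, e_act = 10, t_pk = max(temp) + 10, d_ed = 50)
  t_at_max <- temp[which.max(rate)]
  e_starts <- c(0.3, 0.65, 1.2)
  tpk_starts <- pmin(pmax(t_at_max + c(0, 3, -3), lower["t_pk"]), upper["t_pk"])

  dat <- data.frame(temp = temp, rate = rate)
  best <- NULL
  best_ssr <- Inf
  best_e <- Inf
  for (e0 in e_starts) {
    # b0 start: observed rate nearest Tref, pulled back by the Arrhenius factor
    i_near <- which.min(abs(temp - t_ref))
    b0_start <- rate[i_near] *
      exp(e0 / boltzmann_k * (1 / temp[i_near] - 1 / t_ref))
    b0_start <- min(max(b0_start, lower["b0"] * 10), upper["b0"] / 10)
    for (tp0 in tpk_starts) {
      start <- c(b0 = unname(b0_start), e_act = e0, t_pk = unname(tp0),
                 d_ed = unname(2 * e0))
      fit <- tryCatch(
        suppressWarnings(minpack.lm::nlsLM(
          rate ~ ss_curve(b0, e_act, t_pk, d_ed, t_ref, temp),
          data = dat, start = as.list(start),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                               ptol = 1e-14))),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- sum(residuals(fit)^2)
      e_hat <- coef(fit)[["e_act"]]
      if (ssr < best_ssr - 1e-15 * (1 + best_ssr) ||
          (abs(ssr - best_ssr) <= 1e-15 * (1 + best_ssr) && e_hat < best_e)) {
        best <- fit; best_ssr <- ssr; best_e <- e_hat
      }
    }
  }

  mask <- setNames(rep(TRUE, 6L), trait_names())
  if (is.null(best)) {
    return(structure(list(params = NULL, derived = NULL,
                          param_covariance = matrix(NA_real_, 4, 4),
                          r_squared = NA_real_, n_points = n,
                          missing_mask = mask, converged = FALSE,
                          series = series, t_ref = t_ref),
                     class = "tpc_fit"))
  }

  cf <- coef(best)
  params <- tpc_params(b0 = cf[["b0"]], e_act = cf[["e_act"]],
                       t_pk = cf[["t_pk"]], e_d = cf[["e_act"]] + cf[["d_ed"]],
                       t_ref = t_ref)
  sst <- sum((rate - mean(rate))^2)
  r2 <- if (sst > 0) 1 - best_ssr / sst else NA_real_
  if (n == 4L)
    warning("saturated fit: exactly 4 points for 4 free parameters")
  vc <- tryCatch(vcov(best), error = function(e) matrix(NA_real_, 4, 4))
  if (!all(is.finite(vc))) vc <- matrix(NA_real_, 4, 4)
  # map (b0, e_act, t_pk, d_ed) -> (b0, e_act, t_pk, e_d): e_d = e_act + d_ed
  J <- diag(4); J[4, 2] <- 1
  vc4 <- J %*% vc %*% t(J)
  dimnames(vc4) <- list(c("b0", "e_act", "t_pk", "e_d"),
                        c("b0", "e_act", "t_pk", "e_d"))

  res <- structure(list(params = params, derived = derive_tpc(params),
                        param_covariance = vc4, r_squared = r2,
                        n_points = n, missing_mask = mask, converged = TRUE,
                        series = series, t_ref = t_ref),
                   class = "tpc_fit")
  mark_uncertain_params(res, series)
}

#' @export
print.tpc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Sharpe-Schoolfield fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("Sharpe-Schoolfield fit (%s): R^2 = %.3f, n = %d\n",
              x$series$taxon_id, x$r_squared, x$n_points))
  print(x$params)
  cat(sprintf("  Bpk = %.4g  Wop = %.2f K  B(Tref) = %.4g\n",
              x$derived$b_pk, x$derived$w_op, x$derived$b_at_ref))
  invisible(x)
}

#' Flag parameters whose supporting data region is absent
#'
#' Coverage-based reliability heuristics: the activation energy needs the
#' rising branch (at least 3 points below the fitted peak); the peak
#' temperature and the deactivation energy need the falling branch (at least
#' 2 points above the fitted peak).  B0 inherits missingness from the
#' activation energy, Bpk from the peak temperature, and Wop from either.
#' Unconverged fits have all six traits missing.
#'
#' @param result A `tpc_fit`.
#' @param series The series the fit was computed from (defaults to the one
#'   stored in the fit).
#' @return The fit with its `missing_mask` updated (TRUE = missing).
#' @export
mark_uncertain_params <- function(result, series = result$series) {
  stopifnot(inherits(result, "tpc_fit"))
  mask <- setNames(rep(FALSE, 6L), trait_names())
  if (!result$converged) {
    result$missing_mask <- setNames(rep(TRUE, 6L), trait_names())
    return(result)
  }
  tpk <- result$params$t_pk
  n_below <- sum(series$temperature < tpk)
  n_above <- sum(series$temperature > tpk)
  e_missing <- n_below < 3L
  fall_missing <- n_above < 2L
  mask["ln_e"] <- e_missing
  mask["tpk_sq"] <- fall_missing
  mask["ln_ed"] <- fall_missing
  mask["b0_qrt"] <- e_missing
  mask["ln_bpk"] <- fall_missing
  mask["ln_wop"] <- e_missing || fall_missing || !is.finite(result$derived$w_op)
  result$missing_mask <- mask
  result
}

#' Quality-filter a list of fits
#'
#' Drops fits with R^2 below `min_r2` (0.5 in the standard analysis).  When
#' the reference temperature is 10 degC (283.15 K) the B0 comparison is only
#' meaningful for curves peaking above it, so fits with `t_pk` < 283.15 K
#' are additionally dropped.
#'
#' @param results List of `tpc_fit` objects.
#' @param t_ref Reference temperature the fits were computed at (K).
#' @param min_r2 Minimum R^2 to keep.
#' @return The surviving fits, with attribute `dropped` giving counts
#'   removed by each rule (also reported via `message`).
#' @export
filter_fits <- function(results, t_ref = 273.15, min_r2 = 0.5) {
  if (length(results) == 0L) return(results)
  conv <- vapply(results, function(f) isTRUE(f$converged), logical(1))
  r2 <- vapply(results, function(f)
    if (isTRUE(f$converged)) f$r_squared else -Inf, numeric(1))
  keep_r2 <- conv & is.finite(r2) & r2 >= min_r2
  keep_tpk <- rep(TRUE, length(results))
  if (isTRUE(all.equal(t_ref, 283.15))) {
    keep_tpk <- vapply(results, function(f)
      !isTRUE(f$converged) || f$params$t_pk >= 283.15, logical(1))
  }
  keep <- keep_r2 & keep_tpk
  dropped <- c(not_converged = sum(!conv),
               low_r2 = sum(conv & !keep_r2),
               low_tpk = sum(conv & keep_r2 & !keep_tpk))
  message(sprintf(
    "filter_fits: kept %d/%d (dropped: %d unconverged, %d with R^2 < %g, %d with Tpk below Tref)",
    sum(keep), length(results), dropped[["not_converged"]],
    dropped[["low_r2"]], min_r2, dropped[["low_tpk"]]))
  out <- results[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Read a growth-rate CSV into a list of series
#'
#' Expected columns: `taxon_id`, `temperature_C`, `rate`, `rate_unit`
#' (`"per_day"` or `"per_second"`; per-day values are divided by 86400),
#' `habitat`, `latitude`, `longitude`, `cell_volume_um3`.
#'
#' @param path CSV file path.
#' @return A list of [growth_series()] objects, one per taxon id.
#' @export
read_rates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", "temperature_C", "rate")
  if (!all(need %in% names(df)))
    stop("rates CSV must contain columns: ", paste(need, collapse = ", "))
  if (is.null(df$rate_unit)) df$rate_unit <- "per_second"
  df$rate <- ifelse(df$rate_unit == "per_day", df$rate / 86400, df$rate)
  first_or_na <- function(x) if (length(x)) x[[1]] else NA
  lapply(split(df, df$taxon_id), function(d)
    growth_series(taxon_id = d$taxon_id[[1]],
                  temperature = d$temperature_C, rate = d$rate,
                  habitat = if (!is.null(d$habitat)) d$habitat[[1]] else "unknown",
                  latitude = if (!is.null(d$latitude)) first_or_na(d$latitude) else NA_real_,
                  longitude = if (!is.null(d$longitude)) first_or_na(d$longitude) else NA_real_,
                  cell_volume = if (!is.null(d$cell_volume_um3)) first_or_na(d$cell_volume_um3) else NA_real_,
                  celsius = TRUE))
}
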