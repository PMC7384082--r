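# Transformations of the six TPC traits toward normality and first-order
# (delta-method) propagation of the least-squares estimate covariance;
# the niche width gets a nonparametric bootstrap instead because it has no
# closed form in the fitted parameters.

num_gradient <- function(f, x, rel_h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- rel_h * max(abs(x[i]), 1)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

tpc_from_vec <- function(v, t_ref) {
  tpc_params(b0 = v[1], e_act = v[2], t_pk = v[3], e_d = v[4], t_ref = t_ref)
}

#' Transform a fitted TPC into the six-trait vector with delta-method errors
#'
#' The six traits are `B(Tref)^(1/4)`, `ln E`, `Tpk^2`, `ln Bpk`, `ln ED`
#' and `ln Wop` (each transformation chosen so the trait is approximately
#' Gaussian across taxa).  Error variances of the transformed estimates are
#' obtained by the first-order delta method through the gradient of the
#' transformed quantity with respect to the four fitted parameters, using
#' the fit's estimate covariance.  `ln Wop` has no analytic gradient path
#' and is left `NA` unless a bootstrap variance ([bootstrap_wop_variance()])
#' is supplied via `wop_variance`.
#'
#' @param fit A converged `tpc_fit`.
#' @param wop_variance Optional variance of `ln Wop` from the bootstrap.
#' @return A list of class `trait_vector`: `values` and `se_variances`
#'   (named 6-vectors) and `missing_mask` (from the fit).
#' @export
transform_traits <- function(fit, wop_variance = NA_real_) {
  stopifnot(inherits(fit, "tpc_fit"))
  if (!fit$converged) stop("cannot transform an unconverged fit")
  p <- fit$params
  th <- c(p$b0, p$e_act, p$t_pk, p$e_d)
  vals <- setNames(c(
    compute_b_at_ref(p)^0.25,
    log(p$e_act),
    p$t_pk^2,
    log(fit$derived$b_pk),
    log(p$e_d),
    if (is.finite(fit$derived$w_op)) log(fit$derived$w_op) else NA_real_
  ), trait_names())

  vc <- fit$param_covariance
  vars <- setNames(rep(NA_real_, 6L), trait_names())
  if (all(is.finite(vc))) {
    g_b0q <- num_gradient(function(v)
      compute_b_at_ref(tpc_from_vec(v, p$t_ref))^0.25, th)
    g_lnbpk <- num_gradient(function(v)
      log(compute_bpk(tpc_from_vec(v, p$t_ref))), th)
    delta <- function(g) drop(t(g) %*% vc %*% g)
    vars["b0_qrt"] <- delta(g_b0q)
    vars["ln_e"] <- vc[2, 2] / p$e_act^2
    vars["tpk_sq"] <- (2 * p$t_pk)^2 * vc[3, 3]
    vars["ln_bpk"] <- delta(g_lnbpk)
    vars["ln_ed"] <- vc[4, 4] / p$e_d^2
  }
  vars["ln_wop"] <- wop_variance
  vars[!is.finite(vars)] <- NA_real_
  vars[is.finite(vars) & vars < 0] <- NA_real_
  structure(list(values = vals, se_variances = vars,
                 missing_mask = fit$missing_mask),
            class = "trait_vector")
}

#' Back-transform the four core traits to Sharpe-Schoolfield parameters
#'
#' Inverse of the trait transformations for the four fitted parameters:
#' `b0 = b0_qrt^4`, `e_act = exp(ln_e)`, `t_pk = sqrt(tpk_sq)`,
#' `e_d = exp(ln_ed)`.  Rows violating `e_d > e_act + 1e-3` or falling
#' outside a physically sensible peak-temperature range are marked invalid
#' so generators can reject and redraw them.
#'
#' @param traits Matrix (or vector) with columns `b0_qrt`, `ln_e`, `tpk_sq`,
#'   `ln_ed`.
#' @param t_ref Reference temperature (K).
#' @param t_pk_range Acceptable peak-temperature range (K).
#' @return A data frame with columns `b0`, `e_act`, `t_pk`, `e_d`, `valid`.
#' @export
back_transform_to_tpc <- function(traits, t_ref = 273.15,
                                  t_pk_range = c(250, 340)) {
  if (is.null(dim(traits))) traits <- matrix(traits, nrow = 1,
                                             dimnames = list(NULL, names(traits)))
  need <- c("b0_qrt", "ln_e", "tpk_sq", "ln_ed")
  if (!all(need %in% colnames(traits)))
    stop("traits must have columns: ", paste(need, collapse = ", "))
  b0 <- traits[, "b0_qrt"]^4
  e_act <- exp(traits[, "ln_e"])
  t_pk <- suppressWarnings(sqrt(traits[, "tpk_sq"]))
  e_d <- exp(traits[, "ln_ed"])
  valid <- is.finite(b0) & b0 > 0 & is.finite(e_act) & e_act > 0 &
    is.finite(t_pk) & t_pk >= t_pk_range[1] & t_pk <= t_pk_range[2] &
    is.finite(e_d) & (e_d - e_act) > 1e-3
  data.frame(b0 = b0, e_act = e_act, t_pk = t_pk, e_d = e_d,
             t_ref = t_ref, valid = valid)
}

#' Bootstrap variance of the log operational niche width
#'
#' Nonparametric case resampling: (temperature, rate) pairs are resampled
#' with replacement, the curve refitted from the original estimates as
#' starting values, and `ln Wop` recomputed per replicate.  Case resampling
#' (rather than residual resampling) is used because residual variance is
#' expected to change along the curve.
#'
#' @param series The preprocessed [growth_series()] behind the fit.
#' @param fit The converged `tpc_fit` (must have an estimable Wop).
#' @param n_boot Number of bootstrap replicates (>= 50).
#' @param seed Integer seed; the same seed reproduces the same variance.
#' @return The sample variance of `ln Wop` across converging replicates,
#'   with attribute `convergence_fraction`.  If fewer than half of the
#'   replicates converge the variance is `NA` with a warning.
#' @export
bootstrap_wop_variance <- function(series, fit, n_boot = 100, seed = 1) {
  stopifnot(inherits(series, "growth_series"), inherits(fit, "tpc_fit"),
            n_boot >= 50)
  if (!fit$converged || !is.finite(fit$derived$w_op))
    stop("fit must be converged with an estimable Wop")
  set.seed(seed)
  n <- length(series$rate)
  p <- fit$params
  start <- list(b0 = p$b0, e_act = p$e_act, t_pk = p$t_pk,
                d_ed = p$e_d - p$e_act)
  lower <- c(b0 = 1e-10, e_act = 1e-2,
             t_pk = min(series$temperature) - 10, d_ed = 1e-3)
  upper <- c(b0 = 1e3, e_act = 10, t_pk = max(series$temperature) + 10,
             d_ed = 50)
  ln_wops <- rep(NA_real_, n_boot)
  t_ref_val <- fit$t_ref
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    dat <- data.frame(temp = series$temperature[idx], rate = series$rate[idx])
    bf <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        rate ~ ss_curve(b0, e_act, t_pk, d_ed, t_ref_val, temp),
        data = dat, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (is.null(bf)) next
    cf <- coef(bf)
    pp <- tryCatch(tpc_params(cf[["b0"]], cf[["e_act"]], cf[["t_pk"]],
                              cf[["e_act"]] + cf[["d_ed"]], fit$t_ref),
                   error = function(e) NULL)
    if (is.null(pp)) next
    w <- tryCatch(compute_wop(pp), error = function(e) NA_real_)
    if (is.finite(w) && w > 0) ln_wops[b] <- log(w)
  }
  ok <- is.finite(ln_wops)
  frac <- mean(ok)
  if (frac < 0.5) {
    warning(sprintf("only %.0f%% of bootstrap replicates converged; variance unreliable",
                    100 * frac))
    out <- NA_real_
  } else {
    out <- var(ln_wops[ok])
  }
  attr(out, "convergence_fraction") <- frac
  out
}

#' Assemble a traits table from a list of fits
#'
#' One row per TPC: taxon id, the six transformed trait values, their
#' measurement-error variances, and series metadata.  Values flagged missing
#' by the coverage heuristics are set to `NA` (the mixed model imputes them
#' as Missing At Random).
#'
#' @param fits List of converged `tpc_fit` objects.
#' @param wop_variances Optional numeric vector of `ln Wop` bootstrap
#'   variances, one per fit.
#' @return A data frame with columns `taxon_id`, the traits, `var.<trait>`
#'   columns, `habitat`, `latitude`, `longitude`, `cell_volume`.
#' @export
fits_to_traits <- function(fits, wop_variances = NULL) {
  if (is.null(wop_variances)) wop_variances <- rep(NA_real_, length(fits))
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    tv <- transform_traits(f, wop_variance = wop_variances[i])
    vals <- tv$values
    vals[tv$missing_mask] <- NA_real_
    vars <- tv$se_variances
    vars[tv$missing_mask] <- NA_real_
    out <- data.frame(taxon_id = f$series$taxon_id)
    for (nm in trait_names()) out[[nm]] <- vals[[nm]]
    for (nm in trait_names()) out[[paste0("var.", nm)]] <- vars[[nm]]
    out$habitat <- f$series$habitat
    out$latitude <- f$series$latitude
    out$longitude <- f$series$longitude
    out$cell_volume <- f$series$cell_volume
    out
  })
  do.call(rbind, rows)
}
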