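test_that("transforms and back-transforms are mutually inverse", {
  p <- tpc_params(0.013, 0.7, 295.2, 2.4, 273.15)
  tv <- transform_traits(fake_fit(p))
  bt <- back_transform_to_tpc(tv$values[c("b0_qrt", "ln_e", "tpk_sq", "ln_ed")])
  expect_true(bt$valid)
  expect_equal(bt$e_act, p$e_act, tolerance = 1e-12)
  expect_equal(bt$t_pk, p$t_pk, tolerance = 1e-12)
  expect_equal(bt$e_d, p$e_d, tolerance = 1e-12)
  # the B0 trait is the curve value at Tref, not the raw b0 parameter
  expect_equal(bt$b0, compute_b_at_ref(p), tolerance = 1e-12)

  # a draw with ln(ED) below ln(E) is flagged invalid
  bad <- tv$values[c("b0_qrt", "ln_e", "tpk_sq", "ln_ed")]
  bad["ln_ed"] <- bad["ln_e"] - 0.5
  expect_false(back_transform_to_tpc(bad)$valid)
})

test_that("delta-method variances follow the standard first-order formulas", {
  p <- tpc_params(0.01, 0.65, 300, 3.0, 273.15)
  vc <- diag(c(1e-8, 1e-4, 1, 1e-2))
  tv <- transform_traits(fake_fit(p, vc = vc))
  # var(ln E) = var(E)/E^2 and var(Tpk^2) = (2 Tpk)^2 var(Tpk)
  expect_equal(tv$se_variances[["ln_e"]], 1e-4 / 0.65^2, tolerance = 1e-10)
  expect_equal(tv$se_variances[["tpk_sq"]], (2 * 300)^2 * 1, tolerance = 1e-10)
  expect_equal(tv$se_variances[["ln_ed"]], 1e-2 / 9, tolerance = 1e-10)
  expect_true(is.na(tv$se_variances[["ln_wop"]]))

  # a fit without a usable covariance keeps values but drops variances
  tv2 <- transform_traits(fake_fit(p))
  expect_true(all(is.finite(tv2$values[1:5])))
  expect_true(all(is.na(tv2$se_variances[1:5])))
})

test_that("delta-method variances converge to Monte-Carlo truth at small CV", {
  p <- tpc_params(0.01, 0.65, 293.15, 3.0, 273.15)
  th <- c(p$b0, p$e_act, p$t_pk, p$e_d)
  sds <- abs(th) * c(0.01, 0.01, 0.0005, 0.01)
  tv <- transform_traits(fake_fit(p, vc = diag(sds^2)))
  set.seed(11)
  n <- 2e5
  draws <- sapply(1:4, function(j) rnorm(n, th[j], sds[j]))
  mc_lnbpk <- var(log(ss_grid(
    list(b0 = draws[, 1], e_act = draws[, 2], t_pk = draws[, 3],
         e_d = draws[, 4], t_ref = p$t_ref), draws[, 3])))
  expect_equal(tv$se_variances[["ln_bpk"]], mc_lnbpk, tolerance = 0.02)
})

test_that("the Wop bootstrap is deterministic, degenerate on noise-free data, and calibrated", {
  p <- tpc_params(0.01, 0.65, 293.15, 3.0, 273.15)
  s0 <- simulate_growth_curves(p, noise_sd = 0, seed = 6)
  f0 <- fit_sharpe_schoolfield(s0, 273.15)
  v0 <- bootstrap_wop_variance(s0, f0, n_boot = 60, seed = 3)
  expect_lt(v0, 1e-6)
  v0b <- bootstrap_wop_variance(s0, f0, n_boot = 60, seed = 3)
  expect_identical(as.numeric(v0), as.numeric(v0b))

  # bootstrap SD within a factor of 2 of the across-dataset SD of ln Wop
  s1 <- preprocess_series(simulate_growth_curves(p, noise_sd = 0.05, seed = 7))
  f1 <- fit_sharpe_schoolfield(s1, 273.15)
  vb <- bootstrap_wop_variance(s1, f1, n_boot = 80, seed = 4)
  lw <- sapply(1:80, function(i) {
    si <- tryCatch(preprocess_series(
      simulate_growth_curves(p, noise_sd = 0.05, seed = 5000 + i)),
      error = function(e) NULL)
    if (is.null(si)) return(NA_real_)
    fi <- fit_sharpe_schoolfield(si, 273.15)
    if (fi$converged && is.finite(fi$derived$w_op)) log(fi$derived$w_op)
    else NA_real_
  })
  ratio <- sqrt(vb) / sd(lw, na.rm = TRUE)
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("the traits table propagates values, variances and missingness", {
  p <- tpc_params(0.01, 0.65, 293.15, 3.0, 273.15)
  s_full <- simulate_growth_curves(p, noise_sd = 0.02, seed = 21,
                                   taxon_id = "sp1")
  s_rise <- simulate_growth_curves(p, noise_sd = 0.02, design = "rise_only",
                                   seed = 22, taxon_id = "sp2")
  fits <- list(fit_sharpe_schoolfield(preprocess_series(s_full), 273.15),
               fit_sharpe_schoolfield(preprocess_series(s_rise), 273.15))
  tab <- fits_to_traits(fits)
  expect_identical(nrow(tab), 2L)
  expect_true(all(is.finite(unlist(tab[1, trait_names <- c("b0_qrt", "ln_e",
    "tpk_sq", "ln_bpk", "ln_ed", "ln_wop")]))))
  expect_true(is.na(tab[2, "tpk_sq"]))
  expect_true(is.na(tab[2, "ln_ed"]))
  expect_false(is.na(tab[2, "ln_e"]))
})
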