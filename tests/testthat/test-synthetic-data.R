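test_that("pure-birth trees are ultrametric, unit height and reproducible", {
  tr2 <- simulate_tree(2, seed = 1)
  d2 <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(d2, c(1, 1))

  expect_identical(ape::write.tree(simulate_tree(12, seed = 5)),
                   ape::write.tree(simulate_tree(12, seed = 5)))

  tr <- simulate_tree(50, seed = 2)
  depths <- ape::node.depth.edgelength(tr)[1:50]
  expect_lt(max(depths) - min(depths), 1e-10)
  expect_equal(max(depths), 1)
})

test_that("trait simulation reproduces the Brownian covariance structure", {
  pc <- phylo_covariance(simulate_tree(6, seed = 3))
  tips <- sapply(1:1500, function(i)
    simulate_traits(pc, matrix(1), matrix(0), seed = i,
                    trait_cols = "x")$traits$x)
  emp <- cov(t(tips))
  expect_lt(max(abs(emp - pc$A)), 0.12)

  # G = 0: trait distances unrelated to phylogenetic relatedness
  pc2 <- phylo_covariance(simulate_tree(80, seed = 4))
  tt <- simulate_traits(pc2, matrix(0), matrix(1), seed = 5,
                        trait_cols = "x")$traits$x
  dis <- as.vector(dist(tt)^2)
  rel <- as.vector(as.dist(pc2$A))
  expect_lt(abs(cor(dis, rel)), 0.1)

  # a fixed-effect slope is visible to plain least squares
  pc3 <- phylo_covariance(simulate_tree(80, seed = 6))
  set.seed(7)
  z <- rnorm(80)
  sim <- simulate_traits(pc3, matrix(0.05), matrix(0.05),
                         beta_true = rbind(0, 0.5), X = cbind(1, z),
                         seed = 8, trait_cols = "y")
  ols <- coef(lm(sim$traits$y ~ z))[2]
  expect_equal(unname(ols), 0.5, tolerance = 0.15)
})

test_that("parameter-bank draws respect the constraints with logged rejections", {
  bank <- simulate_tpc_bank(200, seed = 9)
  expect_length(bank, 200)
  for (p in bank[1:20]) {
    expect_gt(p$e_d, p$e_act + 1e-3)
    expect_gt(p$t_pk, 250); expect_lt(p$t_pk, 340)
  }
  expect_true(is.numeric(attr(bank, "n_rejected")))
})

test_that("growth-curve plans cover the peak, only the rise, or neither noise", {
  p <- tpc_params(0.01, 0.65, 293.15, 3.0, 273.15)
  s0 <- simulate_growth_curves(p, noise_sd = 0, seed = 10)
  expect_equal(s0$rate, evaluate_tpc(p, s0$temperature), tolerance = 1e-12)

  s_rise <- simulate_growth_curves(p, noise_sd = 0.05, design = "rise_only",
                                   seed = 11)
  expect_true(all(s_rise$temperature <= p$t_pk))

  s_sparse <- simulate_growth_curves(p, noise_sd = 0, design = "sparse",
                                     seed = 12)
  expect_lt(length(s_sparse$rate), length(s0$rate))
})

test_that("trajectory walks are reproducible with calibrated autocorrelation", {
  t0 <- simulate_trajectories(3, 100, rho = 0.9, sd = 0, seed = 13)
  expect_equal(IQR(t0$temperature_C[t0$replicate_id == "rep1"]), 0)

  expect_identical(simulate_trajectories(4, 200, seed = 14),
                   simulate_trajectories(4, 200, seed = 14))

  tt <- simulate_trajectories(100, 500, rho = 0.95, sd = 0.5, seed = 15)
  ac1 <- sapply(split(tt$temperature_C, tt$replicate_id), function(x)
    acf(x, lag.max = 1, plot = FALSE)$acf[2])
  expect_lt(abs(mean(ac1) - 0.95), 0.05)
})

test_that("curves built from back-transformed traits survive the whole pipeline", {
  # master integration check: inject a heritable correlation between the
  # peak-height and peak-temperature traits, push everything through curve
  # simulation, fitting, transformation and the mixed model, and ask for
  # the correlation back
  n_sp <- 30
  pc <- phylo_covariance(simulate_tree(n_sp, seed = 16))
  G <- diag(c(0.004, 0.02))            # ln_bpk, tpk scaled variances
  G[1, 2] <- G[2, 1] <- 0.75 * sqrt(G[1, 1] * G[2, 2])
  sim <- simulate_traits(pc, G, diag(c(1e-4, 1e-4)), seed = 17,
                         trait_cols = c("d_lnbpk", "d_tpk"))
  set.seed(18)
  fits <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    pars <- tpc_params(b0 = 0.01 * exp(sim$traits$d_lnbpk[i]),
                       e_act = 0.65,
                       t_pk = 293.15 + 40 * sim$traits$d_tpk[i],
                       e_d = 3, t_ref = 273.15)
    s <- simulate_growth_curves(pars, noise_sd = 0.02, seed = 1800 + i,
                                taxon_id = sim$traits$taxon_id[i])
    s <- preprocess_series(s)
    fits[[i]] <- fit_sharpe_schoolfield(s, 273.15)
  }
  keep <- suppressMessages(filter_fits(fits, 273.15))
  traits <- fits_to_traits(keep)
  fit <- pmm_fit(build_design(traits, pc, "intercepts",
                              responses = c("tpk_sq", "ln_bpk")),
                 n_iter = 4000, burn_in = 1000, thin = 3, n_chains = 1,
                 seed = 19)
  co <- decompose_correlations(fit)
  # the injected positive heritable association is recovered in sign and
  # rough magnitude at the phenotypic level
  expect_gt(co$r_phe_mean, 0.3)
})
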