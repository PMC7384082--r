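make_summary_stub <- function(terms, responses, lower, upper, dic,
                              n_cols = length(terms) * length(responses)) {
  co <- expand.grid(term = terms, response = responses,
                    stringsAsFactors = FALSE)[, c(2, 1)]
  co$mean <- (lower + upper) / 2
  co$lower <- lower
  co$upper <- upper
  structure(list(coefficients = co, terms = terms,
                 dic = list(dic = dic), n_fixed_columns = n_cols),
            class = "pmm_summary")
}

test_that("the fixed design has one coefficient per response per term", {
  pc <- star_cov(paste0("t", 1:10))
  set.seed(1)
  traits <- data.frame(taxon_id = pc$taxa,
                       matrix(rnorm(60), 10, 6,
                              dimnames = list(NULL, phylotpc:::trait_names())),
                       latitude = runif(10, -60, 60), check.names = FALSE)
  d1 <- build_design(traits, pc, "intercepts")
  expect_identical(ncol(d1$X), 1L)            # x 6 responses = 6 coefficients
  expect_identical(ncol(d1$X) * ncol(d1$Y), 6L)
  d2 <- build_design(traits, pc, "latitude_poly2")
  expect_identical(ncol(d2$X), 3L)            # x 6 responses = 18
  expect_identical(ncol(d2$X) * ncol(d2$Y), 18L)

  # two TPCs of one species map to the same species index
  traits2 <- rbind(traits[c(1, 1, 2, 3), ])
  traits2$taxon_id <- c("t1", "t1", "t2", "t3")
  d3 <- build_design(traits2, pc, "intercepts")
  expect_identical(d3$sp[1], d3$sp[2])
  expect_false(d3$sp[1] == d3$sp[3])

  # a missing covariate drops the observation with a log entry
  traits$latitude[4] <- NA
  expect_message(d4 <- build_design(traits, pc, "abs_latitude"), "dropped 1")
  expect_identical(nrow(d4$Y), 9L)
})

test_that("PSRF matches its formula in degenerate and separated cases", {
  set.seed(2)
  a <- matrix(rnorm(1000), ncol = 1)
  n <- nrow(a)
  # two copies of one stream: between-chain variance is zero
  expect_equal(unname(compute_psrf(list(a, a))), sqrt((n - 1) / n),
               tolerance = 1e-12)
  # chains centred 5 sigma apart are flagged hard
  expect_gt(compute_psrf(list(a, a + 5)), 1.5)
  expect_error(compute_psrf(list(a)), "2 chains")
})

test_that("ESS is calibrated on independent and AR(1) draws", {
  set.seed(3)
  expect_true(abs(compute_ess(rnorm(1000)) - 1000) < 200)
  rho <- 0.9
  x <- as.numeric(arima.sim(list(ar = rho), 20000))
  target <- 20000 * (1 - rho) / (1 + rho)
  ess <- compute_ess(x)
  expect_gt(ess, target / 1.5)
  expect_lt(ess, target * 1.5)
  expect_warning(e0 <- compute_ess(rep(1, 100)), "constant")
  expect_identical(e0, 0)
  expect_error(compute_ess(rnorm(5)), "at least 10")
})

test_that("identical chains average to the per-chain DIC and sampling is deterministic", {
  pc <- star_cov(paste0("t", 1:12))
  set.seed(4)
  traits <- data.frame(taxon_id = rep(pc$taxa, each = 2),
                       a = rnorm(24), b = rnorm(24))
  d <- build_design(traits, pc, "intercepts", responses = c("a", "b"))
  f1 <- pmm_fit(d, n_iter = 600, burn_in = 100, thin = 2, n_chains = 1,
                seed = 99)
  f2 <- pmm_fit(d, n_iter = 600, burn_in = 100, thin = 2, n_chains = 1,
                seed = 99)
  # same seed, same data: bit-identical sample streams
  expect_identical(f1$chains[[1]]$beta, f2$chains[[1]]$beta)
  expect_identical(f1$chains[[1]]$G, f2$chains[[1]]$G)

  fcopy <- f1
  fcopy$chains <- list(f1$chains[[1]], f1$chains[[1]])
  dic <- compute_dic(fcopy)
  expect_equal(dic$dic, dic$per_chain[1])
  expect_equal(dic$per_chain[1], dic$per_chain[2])
})

test_that("HPD intervals are shortest and ordered", {
  set.seed(5)
  x <- c(rnorm(2000), rnorm(500, 10))
  h <- hpd_interval(x, 0.5)
  expect_lt(h[1], h[2])
  # a 50% interval on this mixture should sit inside the dominant mode
  expect_gt(h[1], -3); expect_lt(h[2], 3)
  q <- hpd_interval(rnorm(5000), 0.95)
  expect_equal(unname(q), c(-1.96, 1.96), tolerance = 0.15)
})

test_that("model selection honours the HPD-exclusion rule before DIC", {
  s_int <- make_summary_stub("intercept", c("a", "b"), -1, 1, dic = 100)
  # covariate null on every response: excluded no matter how good its DIC
  s_null <- make_summary_stub(c("intercept", "z"), c("a", "b"),
                              lower = -1, upper = 1, dic = 50)
  sel <- select_model(list(s_int, s_null))
  expect_identical(sel$best, 1L)
  expect_true(sel$excluded[2])

  # effect on a single response is enough to survive the rule
  s_one <- make_summary_stub(c("intercept", "z"), c("a", "b"),
                             lower = -1, upper = 1, dic = 50)
  s_one$coefficients$lower[s_one$coefficients$response == "a" &
                             s_one$coefficients$term == "z"] <- 0.2
  sel2 <- select_model(list(s_int, s_one))
  expect_identical(sel2$best, 2L)
  expect_false(sel2$excluded[2])

  # single candidate passes through; DIC ties go to the simpler model
  expect_identical(select_model(list(s_int))$best, 1L)
  s_tie <- s_one; s_tie$dic <- list(dic = 100.3)
  expect_identical(select_model(list(s_int, s_tie))$best, 1L)
})

test_that("weak data leave the variance posterior near the prior", {
  # 3 observations of 1 trait: the likelihood barely constrains G and R
  pc <- star_cov(c("t1", "t2", "t3"))
  traits <- data.frame(taxon_id = pc$taxa, a = c(-0.1, 0.05, 0.12))
  d <- build_design(traits, pc, "intercepts", responses = "a")
  f <- pmm_fit(d, n_iter = 4000, burn_in = 1000, thin = 2, n_chains = 1,
               seed = 7)
  post_med <- median(f$chains[[1]]$R[, 1])
  # prior median of the residual variance: IW(0.002, 1.002) marginal
  prior_draws <- 0.002 / rchisq(20000, df = 1.002)
  expect_lt(abs(log10(post_med) - log10(median(prior_draws))), 1.2)
})

test_that("per-draw covariance matrices stay symmetric positive-definite", {
  pc <- star_cov(paste0("t", 1:15))
  set.seed(8)
  traits <- data.frame(taxon_id = rep(pc$taxa, 2), a = rnorm(30),
                       b = rnorm(30))
  f <- pmm_fit(build_design(traits, pc, "intercepts",
                            responses = c("a", "b")),
               n_iter = 800, burn_in = 200, thin = 4, n_chains = 1, seed = 12)
  for (r in seq_len(nrow(f$chains[[1]]$G))) {
    G <- matrix(f$chains[[1]]$G[r, ], 2, 2)
    R <- matrix(f$chains[[1]]$R[r, ], 2, 2)
    expect_equal(G[1, 2], G[2, 1], tolerance = 1e-10)
    expect_true(all(eigen(G, symmetric = TRUE)$values > 0))
    expect_true(all(eigen(R, symmetric = TRUE)$values > 0))
  }
})
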