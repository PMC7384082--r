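# Synthetic-data generators: pure-birth trees, multivariate trait evolution
# with known heritable (G) and residual (R) covariance plus fixed effects,
# noisy unimodal growth curves with configurable temperature coverage, and
# AR(1) drift trajectories.  These provide parameter-recovery ground truth
# for every pipeline stage without any external downloads.

#' Simulate a pure-birth ultrametric tree scaled to unit height
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed (same seed, same Newick string).
#' @return An `ape::phylo` tree with tip labels `t1..tn` and height 1.
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  stopifnot(n_taxa >= 2)
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depths <- ape::node.depth.edgelength(tr)[seq_len(n_taxa)]
  tr$edge.length <- tr$edge.length / max(depths)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

#' Simulate multivariate trait evolution on a tree
#'
#' Species effects are drawn matrix-normal with among-species covariance
#' `G_true` across traits and the relatedness matrix `A` across species
#' (Brownian motion on the tree); each observation adds an independent
#' residual with covariance `R_true` and a fixed-effect part `X beta_true`.
#'
#' @param tree A `phylo` tree or [phylo_covariance()].
#' @param G_true,R_true k x k heritable and residual covariance matrices
#'   (symmetric PSD; `R_true` may be 0 for pure-Brownian tips).
#' @param beta_true p x k fixed-effect matrix (default: zero intercept
#'   only).
#' @param X n x p covariate matrix (default a column of ones); `n` defaults
#'   to `tpcs_per_species` observations per species.
#' @param tpcs_per_species Integer (scalar or per-species vector) number of
#'   observations per species.
#' @param seed Integer seed.
#' @param trait_cols Column names for the traits (default the six TPC
#'   traits when k = 6, else `trait1..k`).
#' @return List: `traits` (data frame `taxon_id` + trait columns + any
#'   covariates as `x1..xp`), `species_effects` (N x k truth), `G_true`,
#'   `R_true`, `beta_true`.
#' @export
simulate_traits <- function(tree, G_true, R_true, beta_true = NULL,
                            X = NULL, tpcs_per_species = 1, seed = 1,
                            trait_cols = NULL) {
  pc <- if (inherits(tree, "phylo_cov")) tree else phylo_covariance(tree)
  A <- pc$A
  N <- nrow(A)
  k <- nrow(as.matrix(G_true))
  G_true <- as.matrix(G_true); R_true <- as.matrix(R_true)
  set.seed(seed)

  chol_psd <- function(M) {
    ev <- eigen(M, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(M)) %*% t(ev$vectors)
  }
  U <- chol_psd(A) %*% matrix(rnorm(N * k), N, k) %*% chol_psd(G_true)
  rownames(U) <- pc$taxa

  reps <- rep(tpcs_per_species, length.out = N)
  sp <- rep(seq_len(N), times = reps)
  n <- length(sp)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(beta_true)) beta_true <- matrix(0, ncol(X), k)
  E <- matrix(rnorm(n * k), n, k) %*% chol_psd(R_true)
  Y <- X %*% beta_true + U[sp, , drop = FALSE] + E

  if (is.null(trait_cols))
    trait_cols <- if (k == 6) trait_names() else paste0("trait", seq_len(k))
  colnames(Y) <- trait_cols
  traits <- data.frame(taxon_id = pc$taxa[sp], Y, check.names = FALSE)
  if (ncol(X) > 1 || any(X != 1))
    for (j in seq_len(ncol(X))) traits[[paste0("x", j)]] <- X[, j]
  list(traits = traits, species_effects = U, G_true = G_true,
       R_true = R_true, beta_true = beta_true)
}

#' Draw realistic Sharpe-Schoolfield parameter sets
#'
#' Samples the four core traits on their transformed scales from realistic
#' phytoplankton ranges — activation energy lognormal around 0.65 eV, peak
#' temperature normal around 293 K, deactivation energy 3-6 times the
#' activation energy, B0 lognormal around 1 per day — and back-transforms
#' them, rejecting and redrawing draws that violate `e_d > e_act` or leave
#' the physical peak-temperature range.  Rejection beyond 50% of attempts
#' aborts with advice to widen the ranges.
#'
#' @param n Number of parameter sets.
#' @param t_ref Reference temperature (K).
#' @param seed Integer seed.
#' @param e_meanlog,e_sdlog Lognormal parameters for E (eV).
#' @param tpk_mean,tpk_sd Normal parameters for Tpk (K).
#' @param ed_factor_range ED is uniform in `ed_factor_range * E`.
#' @param b0_meanlog,b0_sdlog Lognormal parameters for B0 (s^-1).
#' @return List of [tpc_params()] objects; attribute `n_rejected`.
#' @export
simulate_tpc_bank <- function(n, t_ref = 273.15, seed = 1,
                              e_meanlog = log(0.65), e_sdlog = 0.3,
                              tpk_mean = 293, tpk_sd = 5,
                              ed_factor_range = c(3, 6),
                              b0_meanlog = log(1 / 86400), b0_sdlog = 0.5) {
  set.seed(seed)
  out <- vector("list", n)
  n_rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      if (n_rejected > 50L * max(n, 10L))
        stop("rejection rate above 50%; widen the parameter ranges")
      tr <- c(b0_qrt = rlnorm(1, b0_meanlog, b0_sdlog)^0.25,
              ln_e = rnorm(1, e_meanlog, e_sdlog),
              tpk_sq = rnorm(1, tpk_mean, tpk_sd)^2,
              ln_ed = NA_real_)
      e <- exp(tr["ln_e"])
      tr["ln_ed"] <- log(runif(1, ed_factor_range[1], ed_factor_range[2]) * e)
      bt <- back_transform_to_tpc(tr, t_ref = t_ref)
      if (bt$valid) break
      n_rejected <- n_rejected + 1L
    }
    out[[i]] <- tpc_params(bt$b0, bt$e_act, bt$t_pk, bt$e_d, t_ref)
  }
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Simulate a noisy growth-rate series from known parameters
#'
#' Rates are the Sharpe-Schoolfield curve plus additive Gaussian noise with
#' standard deviation `noise_sd * Bpk`.  Additive (not multiplicative)
#' noise is deliberate: it produces nonpositive rates at the curve tails,
#' which exercises the preprocessing removal rule.  Coverage plans:
#' `"full"` keeps the whole grid, `"rise_only"` keeps temperatures at or
#' below the peak (so deactivation-side parameters become unidentifiable,
#' exercising the Missing-At-Random flags), `"sparse"` keeps every other
#' point.
#'
#' @param params A [tpc_params()] object.
#' @param temp_grid Temperatures (K); default 15 points spanning the curve.
#' @param noise_sd Noise standard deviation as a fraction of Bpk.
#' @param design Coverage plan.
#' @param seed Integer seed.
#' @param taxon_id Label for the series.
#' @return A [growth_series()] (negatives retained).
#' @export
simulate_growth_curves <- function(params, temp_grid = NULL, noise_sd = 0.05,
                                   design = c("full", "rise_only", "sparse"),
                                   seed = 1, taxon_id = "sim") {
  design <- match.arg(design)
  stopifnot(inherits(params, "tpc_params"))
  if (is.null(temp_grid))
    temp_grid <- seq(params$t_pk - 20, params$t_pk + 8, length.out = 15)
  temp_grid <- switch(design,
                      full = temp_grid,
                      rise_only = temp_grid[temp_grid <= params$t_pk],
                      sparse = temp_grid[seq(1, length(temp_grid), by = 2)])
  set.seed(seed)
  bpk <- compute_bpk(params)
  rates <- evaluate_tpc(params, temp_grid) +
    rnorm(length(temp_grid), 0, noise_sd * bpk)
  growth_series(taxon_id, temp_grid, rates)
}

#' Simulate AR(1) drift trajectories
#'
#' Daily temperature and latitude follow independent stationary AR(1)
#' processes \eqn{x_t = \mu + \rho (x_{t-1} - \mu) + \epsilon_t} per
#' replicate, emulating the autocorrelated thermal exposure of passively
#' drifting plankton.
#'
#' @param n_replicates Number of replicate trajectories.
#' @param n_days Days per replicate (<= 500); may be a vector per replicate.
#' @param rho AR(1) coefficient.
#' @param sd Innovation standard deviation (same for T and latitude).
#' @param mu_temp,mu_lat Process means (degC, degrees).
#' @param seed Integer seed.
#' @param location_id,depth_m Identifiers copied into the table.
#' @return Data frame `location_id`, `depth_m`, `replicate_id`, `day`,
#'   `temperature_C`, `latitude_deg`.
#' @export
simulate_trajectories <- function(n_replicates, n_days = 500, rho = 0.95,
                                  sd = 0.5, mu_temp = 15, mu_lat = 40,
                                  seed = 1, location_id = "loc1",
                                  depth_m = 50) {
  stopifnot(all(n_days <= 500), all(n_days >= 1))
  set.seed(seed)
  n_days <- rep(n_days, length.out = n_replicates)
  ar1 <- function(nd, mu) {
    x <- numeric(nd)
    # stationary start
    x[1] <- mu + rnorm(1, 0, if (abs(rho) < 1) sd / sqrt(1 - rho^2) else sd)
    if (nd > 1) for (t in 2:nd)
      x[t] <- mu + rho * (x[t - 1] - mu) + rnorm(1, 0, sd)
    x
  }
  rows <- lapply(seq_len(n_replicates), function(r) {
    nd <- n_days[r]
    data.frame(location_id = location_id, depth_m = depth_m,
               replicate_id = paste0("rep", r), day = seq_len(nd),
               temperature_C = ar1(nd, mu_temp),
               latitude_deg = ar1(nd, mu_lat))
  })
  do.call(rbind, rows)
}
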