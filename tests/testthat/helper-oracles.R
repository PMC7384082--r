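# Independent oracles and small fixture builders shared across tests.

# Line-by-line transcription of the Sharpe-Schoolfield equation, written
# directly from the formula and kept independent of the package's
# evaluator (term-by-term, scalar, no reuse of package helpers).
ss_transcription <- function(b0, e, tpk, ed, tref, temp) {
  kB <- 8.617e-5
  numerator <- b0 * exp((-e / kB) * ((1 / temp) - (1 / tref)))
  inner <- (ed / kB) * ((1 / tpk) - (1 / temp))
  denominator <- 1 + (e / (ed - e)) * exp(inner)
  numerator / denominator
}

# random valid parameter sets from realistic ranges
random_params <- function(n, seed = 1, t_ref = 273.15) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    e <- runif(1, 0.2, 1.5)
    tpc_params(b0 = exp(runif(1, log(1e-6), log(1e-3))),
               e_act = e,
               t_pk = runif(1, 280, 310),
               e_d = e * runif(1, 2, 8),
               t_ref = t_ref)
  })
}

# star "phylogeny" covariance (independent species)
star_cov <- function(taxa) {
  A <- diag(length(taxa))
  dimnames(A) <- list(taxa, taxa)
  structure(list(taxa = taxa, A = A, A_inv = A, height = 1),
            class = "phylo_cov")
}

# within-species TPC replication mix matching the compiled dataset:
# ~56% of species one curve, ~37% two to five, the rest six to twelve
draw_replication <- function(n_species) {
  u <- runif(n_species)
  ifelse(u < 0.56, 1L,
         ifelse(u < 0.93, sample(2:5, n_species, replace = TRUE),
                sample(6:12, n_species, replace = TRUE)))
}

# minimal converged tpc_fit wrapper around known parameters + covariance
fake_fit <- function(params, vc = diag(4) * NA_real_, r2 = 1) {
  structure(list(params = params, derived = derive_tpc(params),
                 param_covariance = vc, r_squared = r2, n_points = 10,
                 missing_mask = setNames(rep(FALSE, 6),
                                         c("b0_qrt", "ln_e", "tpk_sq",
                                           "ln_bpk", "ln_ed", "ln_wop")),
                 converged = TRUE, series = NULL, t_ref = params$t_ref),
            class = "tpc_fit")
}

# vectorized curve evaluation over a temperature grid (for grid oracles)
ss_grid <- function(p, temps) {
  kB <- 8.617e-5
  p$b0 * exp(-p$e_act / kB * (1 / temps - 1 / p$t_ref)) /
    (1 + p$e_act / (p$e_d - p$e_act) *
       exp(p$e_d / kB * (1 / p$t_pk - 1 / temps)))
}
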