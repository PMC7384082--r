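# phylotpc

Phylogenetic analysis of thermal performance curve (TPC) evolution in
phytoplankton — for comparative physiologists and evolutionary ecologists
who want to ask whether the shape of the growth-rate-versus-temperature
curve is thermodynamically constrained or free to adapt across a phylogeny.

The pipeline has three layers:

1. **Per-curve fitting.** Each species/strain's growth-rate series is
   described by the four-parameter Sharpe–Schoolfield model with the peak
   temperature explicit,

   B(T) = B₀ · exp(−E/k · (1/T − 1/T_ref)) / (1 + E/(E_D − E) ·
   exp(E_D/k · (1/T_pk − 1/T))),

   fitted by bounded multi-start Levenberg–Marquardt least squares after
   removing nonpositive rates. Two derived traits complete the description:
   the maximum height B_pk = B(T_pk) and the operational niche width W_op
   (kelvin from the peak down the rising branch to half height). Fits with
   R² < 0.5 are discarded; parameters whose supporting temperature range was
   never sampled are flagged missing.

2. **Trait transforms with known errors.** The six traits are transformed
   toward normality (B₀^¼, ln E, T_pk², ln B_pk, ln E_D, ln W_op); estimate
   variances follow by the delta method through the curve formula, and by a
   case-resampling bootstrap for W_op.

3. **The phylogenetic mixed model.** A multi-response animal model,
   y = Xβ + u + e with vec(u) ~ N(0, G ⊗ A), partitions trait covariance
   into a phylogenetically heritable matrix G and a residual matrix R, given
   the relatedness matrix A from an ultrametric tree scaled to unit height.
   A blocked Gibbs sampler (RcppArmadillo) with inverse-Wishart priors
   handles known measurement-error variances and imputes missing traits as
   Missing At Random. On top of the posterior: Gelman–Rubin and effective
   sample size diagnostics, DIC model selection with an HPD-exclusion rule
   for fixed effects, phylogenetic heritability h² = G_ii/(G_ii + R_ii)
   (Pagel's λ), and the r_her / r_res / r_phe correlation decomposition.
   Single-response variants regress curve-height traits on log cell volume
   with marginal/conditional R². A small environmental module summarizes
   drift-trajectory tables (median/IQR of temperature and latitude,
   trajectory-length weighted). A synthetic-data module generates trees,
   traits, curves and trajectories with known ground truth.

## Worked example

Simulate a curve from known parameters, fit it back, and transform:

```r
library(phylotpc)

truth <- tpc_params(b0 = 0.01, e_act = 0.65, t_pk = 293.15, e_d = 3.0,
                    t_ref = 273.15)
series <- simulate_growth_curves(truth, noise_sd = 0.03, seed = 1)
fit <- fit_sharpe_schoolfield(preprocess_series(series), t_ref = 273.15)
fit
#> Sharpe-Schoolfield fit (sim): R^2 = 0.990, n = 15
#> Sharpe-Schoolfield parameters (Tref = 273.15 K):
#>   B0 = 0.009784  E = 0.6721 eV  Tpk = 292.96 K  ED = 3.005 eV
#>   Bpk = 0.05236  Wop = 10.01 K  B(Tref) = 0.009784
```

The fitted peak sits within 0.2 K of the generating value, and the derived
traits (maximum height ~0.052 s⁻¹, niche width ~10 K) match the truth
(0.0515 s⁻¹, 10.26 K) to a few percent at 3% noise.

Now the comparative layer: traits evolved on a tree with a known heritable
correlation, recovered by the mixed model:

```r
tree <- simulate_tree(100, seed = 2)
pc <- phylo_covariance(tree)
G <- matrix(c(1, 0.7, 0.7, 1), 2)        # heritable covariance, r = 0.7
R <- diag(2) * 0.3                        # residual covariance
sim <- simulate_traits(pc, G, R, tpcs_per_species = 3, seed = 3,
                       trait_cols = c("tpk_sq", "ln_bpk"))
fit <- pmm_fit(build_design(sim$traits, pc, "intercepts",
                            responses = c("tpk_sq", "ln_bpk")),
               n_iter = 8000, burn_in = 2000, thin = 5, n_chains = 2,
               seed = 4)
phylogenetic_heritability(fit)
#>             mean     lower     upper
#> tpk_sq 0.6102699 0.4778224 0.7295383
#> ln_bpk 0.8250333 0.7608929 0.8865882
decompose_correlations(fit)[, c("trait_i", "trait_j", "r_her_mean",
                                "r_her_lower", "r_her_upper")]
#>   trait_i trait_j r_her_mean r_her_lower r_her_upper
#> 1  tpk_sq  ln_bpk  0.7327194   0.5701347   0.8854606
```

True heritability here is 1/(1+0.3) ≈ 0.77 per trait and the injected
heritable correlation is 0.7. The posterior means track both — the spread
of the per-trait heritability estimates around the truth is what a single
Brownian draw on a 100-taxon tree genuinely leaves unresolved (the methods
vignette quantifies this).

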