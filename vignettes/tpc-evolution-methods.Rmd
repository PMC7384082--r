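---
title: "Methods: thermal performance curve evolution with phylotpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal performance curve evolution with phylotpc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ectotherm fitness-related rates respond to temperature through a unimodal
thermal performance curve (TPC).  Whether the shape of that curve is pinned
by thermodynamic constraints on enzyme kinetics or free to adapt is an open
question; answering it requires (i) describing each species' curve by a
small set of parameters, and (ii) asking how those parameters covary across
a phylogeny once environmental covariates are controlled for.  `phylotpc`
implements that pipeline for phytoplankton growth-rate data: per-curve model
fitting, uncertainty propagation, and a multi-response phylogenetic mixed
model that partitions trait covariance into phylogenetically heritable and
residual components.

# The curve model

The package uses the four-parameter Sharpe–Schoolfield model with the peak
temperature as an explicit parameter:

$$B(T) = \frac{B_0\, e^{-\frac{E}{k}\left(\frac{1}{T} - \frac{1}{T_{ref}}\right)}}
{1 + \frac{E}{E_D - E}\, e^{\frac{E_D}{k}\left(\frac{1}{T_{pk}} - \frac{1}{T}\right)}}$$

with $k = 8.617\times10^{-5}$ eV/K.  $B_0$ (time$^{-1}$) sets the vertical
offset and approximates the rate at the reference temperature $T_{ref}$;
$E$ (eV) is the thermal sensitivity of the rising branch; $T_{pk}$ (K) is
the exact argmax of the curve under this parameterization; $E_D > E$ (eV)
controls the fall beyond the peak.  Two derived descriptors complete the
six-trait vector: the maximum height $B_{pk} = B(T_{pk})$ and the
operational niche width $W_{op}$, the distance in kelvin from $T_{pk}$ down
the *rising* branch to where the rate is half of $B_{pk}$.  $W_{op}$ is
found by bisection on a verified bracket to $10^{-6}$ K; if the half-height
is not reached within 150 K below the peak (an unphysical situation) the
trait is recorded missing rather than extrapolated.  Because the model's
numerator is an exponential, fitted rates are strictly positive;
nonpositive growth-rate measurements therefore cannot be described by the
model and are removed before fitting.

The model's core assumption — a single rate-limiting enzyme deactivating at
high temperature — is debated, but the functional form is the field's
workhorse for metabolic TPCs and is the one this package commits to.
Alternative forms that admit nonpositive rates are out of scope.

# Per-curve fitting

Each species/strain series is fitted separately (replicate strains are
never averaged) by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) under box constraints: $B_0 \in (10^{-10}, 10^3)$,
$E \in (0.01, 10)$ eV, $T_{pk}$ within the observed range $\pm 10$ K, and
$E_D - E \in (10^{-3}, 50)$ eV.  The constraint $E_D > E$ is enforced
structurally by optimizing over the offset $E_D - E$; the reported
covariance is mapped back by the (linear) Jacobian.  A multi-start schedule
guards against local optima: $E$ starts at $\{0.3, 0.65, 1.2\}$ eV crossed
with peak starts at the temperature of the observed maximum and $\pm 3$ K;
$E_D$ starts at $3E$ and $B_0$ at the observed rate nearest $T_{ref}$
pulled back by the Arrhenius factor.  The lowest residual sum of squares
wins, ties to the lower $E$.  Fits with $R^2 < 0.5$ are discarded.  Two
reference temperatures are supported (0 °C and 10 °C); at
$T_{ref} = 10$ °C, fits with $T_{pk} < 10$ °C are additionally excluded
because their "low-temperature" trait would be read off the falling branch.
Because the fitted $B_0$ parameter only approximates the curve value at
$T_{ref}$, the trait used downstream is $B(T_{ref})$ computed from the full
fitted curve.

Reliability flags: many experimental curves sample only part of the
temperature range, leaving some parameters unidentified.  The package flags
a parameter missing by data coverage relative to the *fitted* peak — $E$
(and hence $B_0$) when fewer than 3 points lie below $T_{pk}$; $T_{pk}$,
$E_D$ (and hence $B_{pk}$) when fewer than 2 points lie above it; $W_{op}$
when either side fails.  These coverage thresholds are the package's own
operationalization of "not estimable with certainty"; simulation with
rise-only designs confirms they fire exactly when the deactivation branch
is unsampled.  Flagged values are not dropped: they enter the mixed model
as missing responses and are imputed under a Missing-At-Random assumption,
which retains partly-sampled curves and their information about the
observed traits.

# Trait transformations and measurement error

To bring each trait close to normality the model works on transformed
scales: $B_0^{1/4}$, $\ln E$, $T_{pk}^2$, $\ln B_{pk}$, $\ln E_D$,
$\ln W_{op}$.  Estimate variances on those scales come from the first-order
delta method, with the gradients of $B(T_{ref})$ and $B_{pk}$ taken through
the full curve formula with respect to all four fitted parameters (central
differences; at coefficients of variation of a few percent the delta
variances agree with $10^6$-draw Monte-Carlo propagation to well under 5%,
which the test suite asserts).  $W_{op}$ has no analytic path, so its
variance comes from a nonparametric bootstrap: (temperature, rate) pairs
are resampled with replacement and the curve refitted per replicate.  Case
resampling was chosen over residual resampling because residual variance is
expected to vary along the curve; the variance is computed directly on the
$\ln W_{op}$ replicates with no additional delta step.  The quartic-root
transform needs no sign handling because retained rates are positive.

# The phylogenetic mixed model

The heart of the package is a multi-response mixed model ("animal model")
over the $k$ transformed traits.  For observation $i$ of species $s$:

$$w_i = y_i + m_i, \quad m_i \sim N(0, \mathrm{diag}(V_i)) \qquad
y_i = B^\top x_i + u_{s} + e_i, \quad e_i \sim N(0, R)$$

$$\mathrm{vec}(u) \sim N(0,\; G \otimes A)$$

where $V_i$ holds the known measurement-error variances from the delta
method/bootstrap (zero where unknown), $G$ and $R$ are the $k \times k$
phylogenetically heritable and residual covariance matrices, and $A$ is the
species relatedness matrix: $A_{ij}$ is the depth of the most recent common
ancestor of species $i$ and $j$ on the ultrametric tree scaled to unit
height, so heritable and residual variances are directly comparable (the
tree's time calibration is relative, not absolute).  Every fixed-effect
column receives a distinct coefficient per response, so e.g. a latitude
model estimates one latitude slope for each trait.  Numeric covariates are
centered and scaled (recorded for back-transforming coefficients);
quadratic latitude terms are powers of the standardized covariate.

Sampling is by a blocked Gibbs sweep written in C++ (RcppArmadillo), the
same design decision the established mixed-model MCMC packages make:

1. fixed effects from their matrix-normal full conditional (flat prior;
   with a design shared across responses the conditional mean is the
   per-response least-squares fit);
2. species effects jointly per species, single-site over species, using
   $A^{-1}$ and the current $G$;
3. $G$ from its conjugate inverse-Wishart full conditional given the
   species effects;
4. $R$ likewise given the residuals;
5. latent true trait values given the observations and their known error
   variances (exactly-observed components are conditioned on, not
   sampled);
6. missing responses from their conditional normals (MAR imputation).

All randomness flows through R's RNG, so a seed makes chains bit-identical.
Priors on $G$ and $R$ are inverse-Wishart with scale $0.002\,I_k$ and
$k + 0.002$ degrees of freedom — the package's multivariate rendering of a
weak inverse-Gamma(0.001, 0.001) variance prior; each variance keeps a
heavy-tailed near-flat marginal and the prior stays proper for every $k$.
A prior-dominance test (3 observations) confirms the posterior variance
stays within about an order of magnitude of the prior median when data are
this weak.  Non-positive-definite conditionals are retried once with a
small diagonal jitter and then abort loudly.

Diagnostics follow standard practice: the Gelman–Rubin potential scale
reduction factor over $\ge 2$ chains (target $< 1.1$ for every fixed effect
and covariance element) and autocorrelation-time effective sample sizes
with Geyer initial-positive-sequence truncation (target $> 200$ after
pooling chains).  Default chain settings (6,000 iterations, 1,000 burn-in,
thin 5, 2 chains) are deliberately desk-scale and fully configurable; the
recovery studies in the test suite use 20,000-iteration chains.

## Model selection, heritability, correlations

Candidate fixed-effect structures (intercepts-only; absolute latitude;
quadratic latitude; habitat; latitude plus habitat; or arbitrary covariate
columns for drift-regime models) are compared by DIC, averaged across
chains, after an HPD-exclusion step: a model is removed when some
non-intercept fixed effect has a 95% HPD interval containing zero for
every single response.  DIC differences under 0.5 are ties resolved toward
the simpler model.  Deviance is conditional on the species effects and
latent/imputed values (the convention of the mixed-model MCMC packages this
design follows), with the plug-in deviance evaluated at the posterior means
of the fixed effects, species effects and latent values and the posterior
mean of $R$; a marginal-likelihood DIC is not available in closed form
here.  Note one structural consequence of the exclusion rule: a truly null
covariate is excluded only when all $k$ per-response intervals contain
zero, which happens with probability near $0.95^k$ — the rule is
deliberately conservative about discarding predictors, and power studies
should account for that.

Phylogenetic heritability per trait is $G_{ii}/(G_{ii} + R_{ii})$ per draw
(equivalent to Pagel's $\lambda$ in this model class); known
measurement-error variance sits in its own observation layer and never
enters the denominator.  Heritability is reported from the intercepts-only
model because fixed effects absorb residual variance and inflate the
ratio.  Pairwise trait correlations are decomposed per draw into
$r_{her} = G_{ij}/\sqrt{G_{ii}G_{jj}}$,
$r_{res} = R_{ij}/\sqrt{R_{ii}R_{jj}}$ and the phenotypic
$r_{phe} = (G_{ij}+R_{ij})/\sqrt{(G_{ii}+R_{ii})(G_{jj}+R_{jj})}$, each
summarized by the posterior mean and the shortest 95% interval.

## Size scaling

Single-response variants of the same machinery regress $B_0^{1/4}$ (at
either reference temperature), $\ln B_{pk}$ or $\ln B_0$ on log cell
volume, with the species effect on the intercept, the slope, or both, and
with the relatedness matrix either from the tree or the identity (no
phylogenetic correction).  Marginal and conditional coefficients of
determination follow the variance-components convention: the fixed-effect
variance is the variance of the fixed linear predictor over the data, the
random-effect variance the variance of the realized random predictor, and
$R_m^2$, $R_c^2$ are the corresponding shares of the total.  A
$\ln B_0$ response emits a warning: the log of a quartic-root-scaled trait
strains the Gaussian response assumption, and results there are
qualitative.

# Environmental summaries

For drifting marine plankton, thermal exposure is summarized from
precomputed Lagrangian trajectory tables: per replicate trajectory, the
median and interquartile range of temperature and latitude over the first
50/150/250/350/500 days (or the full shorter record); then the weighted
mean across replicates with weight equal to the days each replicate
actually contributed.  The per-replicate-then-weight order matters — pooling
all days first gives different answers, and the test suite pins the order
with a brute-force oracle.  Quantiles use linear interpolation between
order statistics (R's default type-7 rule; the choice is fixed and
documented because different quantile conventions shift IQRs by fractions
of a degree).  Origin-location summaries are the plain median and IQR of
the daily sea-surface-temperature series.

# Synthetic data: what it emulates and what it does not

The generator provides ground truth for every stage: pure-birth trees
scaled to unit height; matrix-normal species effects with row covariance
$A$ and column covariance $G$ plus per-observation residuals with
covariance $R$ and arbitrary fixed effects; noisy growth curves
$B(T) + \varepsilon$, $\varepsilon \sim N(0, (\text{noise\_sd} \cdot
B_{pk})^2)$ with full, rise-only and sparse coverage plans; and AR(1)
temperature/latitude drift walks.  Additive (not multiplicative) curve
noise is deliberate: it produces nonpositive rates at the tails, so the
preprocessing rule has real work in every simulation.  Parameter banks draw
$E$ lognormal around 0.65 eV, $T_{pk}$ normal around 293 K ($\sigma$ = 5 K),
$E_D$ uniform at 3–6 times $E$, and $B_0$ lognormal around one doubling per
day, with constraint-violating draws rejected and redrawn.  Default
within-species replication follows the compiled dataset's structure:
roughly 56% of species with a single curve, 37% with two to five, the rest
with up to twelve.

What passing recovery tests on these data do *not* show: real growth-rate
series have heteroscedastic, non-Gaussian errors, temperature grids chosen
by experimenters rather than centered on the peak, taxon sampling that is
geographically and phylogenetically uneven, and trees estimated with error.
The synthetic studies validate the estimators under the model's own
assumptions, nothing stronger.

# Numerical choices and problem sizes

Recovery studies in the tests and the acceptance script run at desk scale,
as their own design choice: heritability recovery uses 60-taxon trees with
two traits, 10 replicate datasets per heritability level and
20,000-iteration chains; correlation recovery uses 80 taxa with two curves
per species; model-selection studies use 50 taxa and two traits; scaling
studies 50 species with cell volumes spanning seven orders of magnitude.
Two behaviours of these estimators are worth knowing about, and both are
properties of the statistics rather than of the implementation (each was
cross-checked against independent maximum-likelihood $\lambda$ estimates on
identical data):

* point estimates of intermediate phylogenetic heritability at these sample
  sizes carry a downward finite-sample bias of roughly 0.05–0.15, because
  the estimator is bounded at zero and singleton-heavy replication leaves
  the heritable/residual split weakly identified;
* a single Brownian draw on an 80-taxon tree realizes a species-effect
  correlation that can sit 0.1–0.3 away from the generating value (a tree
  supports far fewer independent contrasts than its tip count), and a
  correctly working sampler tracks the *realized* draw — recovery is
  therefore judged on averages over replicate datasets, and heritable
  correlations are only meaningfully estimated when the heritable variances
  themselves are well identified.

Other fixed choices: bisection tolerance $10^{-6}$ K for $W_{op}$;
rejection of $E_D - E < 10^{-6}$ eV as numerically singular; dense
inversion of $A$ with a $10^{-10}$ jitter fallback (the sparse
ancestral-node formulation used at scale is unnecessary for hundreds of
taxa); HPD intervals as the shortest interval containing 95% of draws;
rate units converted to s$^{-1}$ on read (86,400 s/day).  No command-line
wrapper is shipped: the package's users work in R, and the exported
functions plus `scripts/acceptance.R` are the interface.

# Known limitations

The sampler supports one random-effect term (species) — reduced animal
models and additional variance strata are out of scope.  Responses are
Gaussian-only, hence the transform-first design.  DIC is conditional on
latent variables and therefore rewards models that shift fixed-effect
signal into species effects less than a marginal criterion would; with
species-level covariates and all-singleton data the intercepts-only model
additionally has a near-degenerate high-$G$/low-$R$ mode, which
within-species replication (present in the real data and in the default
generator) suppresses.  Tree uncertainty is not propagated; the tree is an
input.
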