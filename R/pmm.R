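# Multi-response phylogenetic mixed model: design construction, the Gibbs
# sampler front end, convergence diagnostics, DIC model selection, and the
# heritability / correlation decompositions read off the G and R draws.

#' Default inverse-Wishart prior for a covariance block
#'
#' Translation of a weak univariate inverse-Gamma(0.001, 0.001) variance
#' prior to the multivariate case: scale `0.002 * I_k` and `k + 0.002`
#' degrees of freedom, so each variance has a heavy-tailed, near-flat
#' marginal while the prior stays proper for any dimension.
#'
#' @param k Block dimension.
#' @return List with `Psi` (k x k) and `nu`.
#' @export
default_iw_prior <- function(k) {
  list(Psi = diag(0.002, k), nu = k + 0.002)
}

#' Build the multi-response design for the mixed model
#'
#' Stacks the traits into an n x k response matrix, attaches the known
#' measurement-error variances (0 where unknown), builds the fixed-effect
#' design (each column gets a distinct coefficient per response, so the
#' effective coefficient count is `ncol(X) * k`), and maps observations to
#' tips of the pruned tree.  Numeric covariates are centered and scaled
#' (recorded in `x_center`/`x_scale` for back-transforming coefficients);
#' polynomial terms are powers of the standardized covariate.
#'
#' @param traits Data frame from [fits_to_traits()] (or the synthetic
#'   generator): `taxon_id`, trait columns, `var.<trait>` columns, plus any
#'   covariates (`latitude`, `habitat`, ...).
#' @param phylo A [phylo_covariance()] object (its `taxa` fixes species
#'   order).  Observations whose taxon is not a tip raise an error.
#' @param fixed One of `"intercepts"`, `"abs_latitude"`, `"latitude_poly2"`,
#'   `"habitat"`, `"latitude_plus_habitat"`, or a character vector of
#'   numeric covariate column names (marine-variant models).
#' @param responses Trait column names to model (default the six TPC
#'   traits present in `traits`).
#' @return A list of class `pmm_design` with `Y`, `V`, `X`, `sp` (1-based
#'   species index), `taxa`, `term_labels`, `x_center`, `x_scale`,
#'   `n_dropped`.
#' @export
build_design <- function(traits, phylo, fixed = "intercepts",
                         responses = NULL) {
  stopifnot(inherits(phylo, "phylo_cov"))
  if (is.null(responses))
    responses <- intersect(trait_names(), names(traits))
  if (!length(responses)) stop("no response columns found in traits")
  bad <- setdiff(unique(traits$taxon_id), phylo$taxa)
  if (length(bad))
    stop("taxa absent from the pruned tree: ", paste(bad, collapse = ", "))

  named_mode <- length(fixed) > 1L ||
    !fixed[1] %in% c("intercepts", "abs_latitude", "latitude_poly2",
                     "habitat", "latitude_plus_habitat")
  covar_cols <- character(0)
  if (named_mode) {
    covar_cols <- fixed
    miss <- setdiff(covar_cols, names(traits))
    if (length(miss)) stop("covariate columns not found: ",
                           paste(miss, collapse = ", "))
  }

  # rows lacking a needed covariate are dropped (logged)
  need <- switch(if (named_mode) "covars" else fixed,
                 intercepts = character(0),
                 abs_latitude = "latitude",
                 latitude_poly2 = "latitude",
                 habitat = "habitat",
                 latitude_plus_habitat = c("latitude", "habitat"),
                 covars = covar_cols)
  ok <- rep(TRUE, nrow(traits))
  for (nm in need) {
    v <- traits[[nm]]
    ok <- ok & !(is.na(v) | (is.character(v) & v == "unknown"))
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("build_design: dropped %d observation(s) lacking a required covariate",
                    n_dropped))
  traits <- traits[ok, , drop = FALSE]
  n <- nrow(traits)
  if (n < 3L) stop("fewer than 3 usable observations")

  k <- length(responses)
  Y <- as.matrix(traits[, responses, drop = FALSE])
  V <- matrix(0, n, k, dimnames = list(NULL, responses))
  for (j in seq_len(k)) {
    vc <- paste0("var.", responses[j])
    if (vc %in% names(traits)) {
      vv <- traits[[vc]]
      V[, j] <- ifelse(is.finite(vv) & vv > 0, vv, 0)
    }
  }
  V[is.na(Y)] <- 0

  std <- function(x) {
    ct <- mean(x); sc <- sd(x); if (!is.finite(sc) || sc == 0) sc <- 1
    list(z = (x - ct) / sc, center = ct, scale = sc)
  }
  X <- matrix(1, n, 1); labs <- "intercept"
  x_center <- c(intercept = 0); x_scale <- c(intercept = 1)
  add_col <- function(x, lab, center, scale_) {
    X <<- cbind(X, x); labs <<- c(labs, lab)
    x_center <<- c(x_center, setNames(center, lab))
    x_scale <<- c(x_scale, setNames(scale_, lab))
  }
  if (named_mode) {
    for (nm in covar_cols) {
      s <- std(as.numeric(traits[[nm]]))
      add_col(s$z, nm, s$center, s$scale)
    }
  } else if (fixed == "abs_latitude") {
    s <- std(abs(traits$latitude))
    add_col(s$z, "abs_latitude", s$center, s$scale)
  } else if (fixed == "latitude_poly2") {
    s <- std(traits$latitude)
    add_col(s$z, "latitude", s$center, s$scale)
    add_col(s$z^2, "latitude_sq", s$center, s$scale)
  } else if (fixed == "habitat") {
    add_col(as.numeric(traits$habitat == "marine"), "habitat_marine", 0, 1)
  } else if (fixed == "latitude_plus_habitat") {
    s <- std(abs(traits$latitude))
    add_col(s$z, "abs_latitude", s$center, s$scale)
    add_col(as.numeric(traits$habitat == "marine"), "habitat_marine", 0, 1)
  }
  colnames(X) <- labs

  sp <- match(traits$taxon_id, phylo$taxa)
  structure(list(Y = Y, V = V, X = X, sp = sp, taxa = phylo$taxa,
                 phylo = phylo, responses = responses, term_labels = labs,
                 x_center = x_center, x_scale = x_scale,
                 n_dropped = n_dropped, fixed = fixed),
            class = "pmm_design")
}

#' Fit the multi-response phylogenetic mixed model by Gibbs sampling
#'
#' Runs `n_chains` independent chains of the blocked Gibbs sampler.  Each
#' sweep updates, in order: the fixed effects from their matrix-normal full
#' conditional; the species effects jointly per species (single-site over
#' species, using the relatedness-matrix inverse and the current heritable
#' covariance G); G and the residual covariance R from their conjugate
#' inverse-Wishart full conditionals; the latent true trait values given the
#' observations and their known error variances; and any missing responses
#' from their conditional normals (Missing At Random).
#'
#' @param design A [build_design()] object (or arguments to build one via
#'   `traits`, `phylo`, `fixed`).
#' @param prior List with `G` and `R` elements, each `list(Psi, nu)`;
#'   defaults to [default_iw_prior()] for each block.
#' @param n_iter,burn_in,thin Chain length controls (draws are stored every
#'   `thin` sweeps after `burn_in`).
#' @param n_chains Number of chains (>= 2 needed for PSRF).
#' @param seed Integer master seed; chain c uses `seed + c - 1`.
#' @param fix_g_zero Degenerate test mode: species effects are pinned to
#'   zero so the fixed-effect posterior can be checked against generalized
#'   least squares.
#' @param random_design Optional n x q matrix replacing the default random
#'   intercept column (used by the size-scaling module for random slopes).
#' @return A `pmm_fit` object: `chains` (per-chain draw matrices), `design`,
#'   `settings`.
#' @export
pmm_fit <- function(design, prior = NULL, n_iter = 6000, burn_in = 1000,
                    thin = 5, n_chains = 2, seed = 1, fix_g_zero = FALSE,
                    random_design = NULL) {
  stopifnot(inherits(design, "pmm_design"))
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  k <- ncol(design$Y)
  Zr <- if (is.null(random_design)) matrix(1, nrow(design$Y), 1)
        else as.matrix(random_design)
  d <- ncol(Zr) * k
  if (is.null(prior)) prior <- list(G = default_iw_prior(d),
                                    R = default_iw_prior(k))
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    chains[[ch]] <- pmm_gibbs_cpp(
      W = design$Y, X = design$X, sp = design$sp - 1L, Zr = Zr,
      Ainv = design$phylo$A_inv, V = design$V,
      PsiG = prior$G$Psi, nuG = prior$G$nu,
      PsiR = prior$R$Psi, nuR = prior$R$nu,
      n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
      thin = as.integer(thin), fix_g_zero = fix_g_zero)
  }
  structure(list(chains = chains, design = design, k = k, q = ncol(Zr),
                 prior = prior,
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, n_chains = n_chains,
                                 seed = seed, fix_g_zero = fix_g_zero)),
            class = "pmm_fit")
}

merged_draws <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, function(ch) ch[[what]]))
}

#' Shortest interval containing a given posterior mass
#'
#' @param x Numeric draws.
#' @param prob Coverage probability.
#' @return c(lower, upper).
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(lower = x[1], upper = x[1]))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed per scalar parameter from >= 2 chains of equal length:
#' \eqn{\sqrt{((n-1)/n \, W + B/n) / W}} with W the mean within-chain
#' variance and B the between-chain variance of the means (times n).
#' Parameters constant in every chain get PSRF 1.
#'
#' @param chains List of draw matrices (iterations x parameters).
#' @return Named vector of PSRF values.
#' @export
compute_psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("at least 2 chains are required for the PSRF")
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]])
  stopifnot(all(vapply(chains, nrow, 1L) == n))
  means <- sapply(chains, colMeans)
  vars <- sapply(chains, function(ch) apply(ch, 2, var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  out <- sqrt(((n - 1) / n * W + B / n) / W)
  out[W == 0 & B == 0] <- 1
  out
}

#' Effective sample size of one parameter's draws
#'
#' Autocorrelation-time ESS with Geyer's initial-positive-sequence
#' truncation: the integrated autocorrelation time sums consecutive
#' lag-pair autocorrelations until a pair sum turns negative.
#'
#' @param x Numeric vector of draws (a matrix is handled column-wise).
#' @return ESS (scalar, or vector per column).  A constant chain returns 0
#'   with a warning.
#' @export
compute_ess <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, compute_ess))
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples for an ESS estimate")
  if (var(x) == 0) {
    warning("constant chain: ESS undefined, reporting 0")
    return(0)
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)      # rho[1] = lag 0
  n_pairs <- floor(length(rho) / 2)
  tau <- 0
  for (m in seq_len(n_pairs)) {
    g <- rho[2 * m - 1] + rho[2 * m]       # lags 2(m-1) and 2m-1
    if (g < 0) break
    tau <- tau + 2 * g
  }
  tau <- max(tau - 1, 1 / n)               # subtract double-counted rho_0
  n / tau
}

#' Deviance information criterion of a fitted model
#'
#' DIC = mean deviance + pD, with pD the mean deviance minus the plug-in
#' deviance at posterior means of the fixed effects, species effects and
#' latent/imputed trait values (and the posterior-mean residual covariance).
#' Reported per chain and averaged across chains.
#'
#' @param fit A `pmm_fit`.
#' @return List with `per_chain` (vector), `dic` (average), `pd_per_chain`.
#' @export
compute_dic <- function(fit) {
  per <- vapply(fit$chains, function(ch) {
    2 * mean(ch$deviance) - ch$dev_hat
  }, numeric(1))
  pd <- vapply(fit$chains, function(ch) {
    mean(ch$deviance) - ch$dev_hat
  }, numeric(1))
  list(per_chain = per, dic = mean(per), pd_per_chain = pd)
}

#' Posterior summary of a multi-response mixed model
#'
#' @param object A `pmm_fit`.
#' @param prob HPD coverage.
#' @param ... Unused.
#' @return A list of class `pmm_summary`: `dic`, `psrf` (fixed effects and
#'   covariance elements; `NA` if a single chain), `ess` (summed over
#'   chains), `coefficients` (posterior mean and HPD per response x term),
#'   `heritability` (if the model is intercepts-only), `correlations`, plus
#'   bookkeeping fields used by [select_model()].
#' @export
summary.pmm_fit <- function(object, prob = 0.95, ...) {
  fit <- object
  k <- fit$k
  responses <- fit$design$responses
  terms <- fit$design$term_labels
  p <- length(terms)

  beta <- merged_draws(fit, "beta")  # draws x (p*k), column-major over (p,k)
  colnames(beta) <- as.vector(outer(terms, responses,
                                    function(a, b) paste(b, a, sep = ":")))
  G <- merged_draws(fit, "G")
  R <- merged_draws(fit, "R")

  par_mat <- cbind(beta,
                   `colnames<-`(G, paste0("G", seq_len(ncol(G)))),
                   `colnames<-`(R, paste0("R", seq_len(ncol(R)))))
  psrf <- if (length(fit$chains) >= 2) {
    chs <- lapply(fit$chains, function(ch) cbind(ch$beta, ch$G, ch$R))
    setNames(compute_psrf(chs), colnames(par_mat))
  } else NULL
  ess <- vapply(seq_len(ncol(par_mat)), function(j) {
    sum(vapply(fit$chains, function(ch) {
      v <- cbind(ch$beta, ch$G, ch$R)[, j]
      if (var(v) == 0) 0 else compute_ess(v)
    }, numeric(1)))
  }, numeric(1))
  names(ess) <- colnames(par_mat)

  coefs <- data.frame(response = rep(responses, each = p),
                      term = rep(terms, times = k),
                      mean = NA_real_, lower = NA_real_, upper = NA_real_)
  for (j in seq_len(k)) for (t in seq_len(p)) {
    col <- (j - 1) * p + t
    hpd <- hpd_interval(beta[, col], prob)
    row <- (j - 1) * p + t
    coefs$mean[row] <- mean(beta[, col])
    coefs$lower[row] <- hpd[1]
    coefs$upper[row] <- hpd[2]
  }

  # heritability is only reported for the intercepts-only model: fixed
  # effects absorb residual variance and bias the ratio upward
  herit <- NULL
  if (fit$q == 1L && !fit$settings$fix_g_zero && p == 1L)
    herit <- phylogenetic_heritability(fit, prob = prob, warn_fixed = FALSE)
  corrs <- if (fit$q == 1L && k >= 2L && !fit$settings$fix_g_zero)
    decompose_correlations(fit, prob = prob) else NULL

  structure(list(dic = compute_dic(fit), psrf = psrf, ess = ess,
                 coefficients = coefs, heritability = herit,
                 correlations = corrs, responses = responses,
                 terms = terms, fixed = fit$design$fixed,
                 n_fixed_columns = p * k, prob = prob),
            class = "pmm_summary")
}

#' @export
print.pmm_summary <- function(x, ...) {
  cat(sprintf("Multi-response phylogenetic mixed model (%s)\n",
              paste(x$fixed, collapse = "+")))
  cat(sprintf("  DIC (chain average): %.2f\n", x$dic$dic))
  if (!is.null(x$psrf))
    cat(sprintf("  max PSRF: %.3f   min ESS: %.0f\n",
                max(x$psrf, na.rm = TRUE), min(x$ess)))
  if (!is.null(x$heritability)) {
    cat("  phylogenetic heritability:\n")
    print(round(x$heritability, 3))
  }
  invisible(x)
}

#' HPD-exclusion rule plus DIC minimization over candidate models
#'
#' A candidate is excluded when any non-intercept fixed effect has a 95%
#' HPD interval containing zero for every single response variable.  Among
#' the survivors (always including the intercepts-only model if present)
#' the smallest chain-averaged DIC wins; DIC differences below `dic_tie`
#' are ties, resolved toward the model with fewer fixed-effect columns.
#'
#' @param summaries List of `pmm_summary` objects.
#' @param dic_tie DIC difference treated as a tie.
#' @return List: `best` (index into `summaries`), `excluded` (logical),
#'   `dic` (vector).
#' @export
select_model <- function(summaries, dic_tie = 0.5) {
  stopifnot(length(summaries) >= 1L)
  excluded <- vapply(summaries, function(s) {
    co <- s$coefficients
    nonint <- setdiff(unique(co$term), "intercept")
    for (term in nonint) {
      rows <- co[co$term == term, ]
      if (all(rows$lower <= 0 & rows$upper >= 0)) return(TRUE)
    }
    FALSE
  }, logical(1))
  is_int <- vapply(summaries, function(s)
    identical(s$terms, "intercept"), logical(1))
  excluded[is_int] <- FALSE   # the intercepts-only model is never excluded
  dic <- vapply(summaries, function(s) s$dic$dic, numeric(1))
  ncols <- vapply(summaries, function(s) s$n_fixed_columns, numeric(1))
  cand <- which(!excluded)
  if (!length(cand)) cand <- which(is_int)
  if (!length(cand)) cand <- seq_along(summaries)
  best_dic <- min(dic[cand])
  tied <- cand[dic[cand] <= best_dic + dic_tie]
  best <- tied[which.min(ncols[tied])]
  list(best = best, excluded = excluded, dic = dic)
}

#' Heritable / residual / phenotypic correlation decomposition
#'
#' Per posterior draw, the correlation between traits i and j is the
#' covariance divided by the geometric mean of the variances, computed from
#' the heritable matrix G (r_her), the residual matrix R (r_res), and their
#' sum (r_phe).  Summaries are posterior means with HPD intervals.
#'
#' @param fit A `pmm_fit` with k >= 2 responses.
#' @param prob HPD coverage.
#' @return Data frame with one row per trait pair and columns
#'   `<comp>_mean`, `<comp>_lower`, `<comp>_upper` for her/res/phe.
#' @export
decompose_correlations <- function(fit, prob = 0.95) {
  k <- fit$k
  stopifnot(k >= 2L, fit$q == 1L)
  responses <- fit$design$responses
  G <- merged_draws(fit, "G")
  R <- merged_draws(fit, "R")
  pairs <- utils::combn(k, 2)
  out <- data.frame(trait_i = responses[pairs[1, ]],
                    trait_j = responses[pairs[2, ]])
  at <- function(M, i, j) M[, (j - 1) * k + i]
  for (comp in c("her", "res", "phe")) {
    m <- lo <- hi <- numeric(ncol(pairs))
    for (pp in seq_len(ncol(pairs))) {
      i <- pairs[1, pp]; j <- pairs[2, pp]
      r <- switch(comp,
        her = at(G, i, j) / sqrt(at(G, i, i) * at(G, j, j)),
        res = at(R, i, j) / sqrt(at(R, i, i) * at(R, j, j)),
        phe = (at(G, i, j) + at(R, i, j)) /
          sqrt((at(G, i, i) + at(R, i, i)) * (at(G, j, j) + at(R, j, j))))
      h <- hpd_interval(r, prob)
      m[pp] <- mean(r); lo[pp] <- h[1]; hi[pp] <- h[2]
    }
    out[[paste0("r_", comp, "_mean")]] <- m
    out[[paste0("r_", comp, "_lower")]] <- lo
    out[[paste0("r_", comp, "_upper")]] <- hi
  }
  out
}

#' Phylogenetic heritability per trait
#'
#' The ratio of heritable to total (heritable + residual) variance,
#' equivalent to Pagel's lambda in this model class.  Known
#' measurement-error variance is excluded from the denominator by
#' construction (it lives in a separate observation layer).  Estimates
#' should come from the intercepts-only model: fixed effects absorb
#' residual variance and bias heritability upward.
#'
#' @param fit A `pmm_fit`.
#' @param prob HPD coverage.
#' @param warn_fixed Warn when the model has non-intercept fixed effects.
#' @return Matrix with rows per trait and columns `mean`, `lower`, `upper`.
#' @export
phylogenetic_heritability <- function(fit, prob = 0.95, warn_fixed = TRUE) {
  stopifnot(fit$q == 1L)
  if (warn_fixed && length(fit$design$term_labels) > 1L)
    warning("heritability requested from a model with fixed effects; ",
            "the intercepts-only model gives unbiased estimates")
  k <- fit$k
  G <- merged_draws(fit, "G")
  R <- merged_draws(fit, "R")
  out <- matrix(NA_real_, k, 3,
                dimnames = list(fit$design$responses,
                                c("mean", "lower", "upper")))
  for (i in seq_len(k)) {
    gi <- G[, (i - 1) * k + i]
    ri <- R[, (i - 1) * k + i]
    h2 <- gi / (gi + ri)
    hpd <- hpd_interval(h2, prob)
    out[i, ] <- c(mean(h2), hpd[1], hpd[2])
  }
  out
}
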