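# Size-scaling of the curve height traits: single-response mixed
# regressions on log cell volume, with species identity random on the
# intercept, the slope, or both, fitted with and without the phylogenetic
# covariance, plus Nakagawa-Schielzeth marginal/conditional R-squared.

#' Single-response size-scaling regression
#'
#' Regresses one curve-height trait (`B0^(1/4)` at either reference
#' temperature, `ln Bpk`, or `ln B0`) on the natural log of cell volume
#' with the same Gibbs machinery as the multi-response model, restricted to
#' one response.  The covariate is centered and scaled internally; the
#' reported slope and intercept are back-transformed to the raw
#' `ln(volume)` scale.  `ln B0` responses trigger a warning: a log
#' transform of a fourth-root-scaled trait is known to strain the Gaussian
#' response assumption.
#'
#' @param data Data frame with `taxon_id`, `ln_volume`, and the response
#'   column; an optional `var.<response>` column supplies known
#'   measurement-error variances.
#' @param response Name of the response column.  One of the conventional
#'   names `b0_qrt_tref0`, `b0_qrt_tref10`, `ln_bpk`, `ln_b0` or any column
#'   present in `data`.
#' @param random Which coefficient(s) the species effect acts on.
#' @param use_phylogeny If `TRUE`, species effects covary as the
#'   relatedness matrix from `tree`; otherwise an identity matrix (a star
#'   phylogeny) is used.
#' @param tree Tree or [phylo_covariance()] (required when
#'   `use_phylogeny = TRUE`; optional otherwise, used for taxon ordering).
#' @param n_iter,burn_in,thin,n_chains,seed Chain settings, as in
#'   [pmm_fit()].
#' @return A list of class `scaling_summary`: `slope`, `intercept`
#'   (posterior mean + HPD, raw scale), `dic`, `r2_marginal`,
#'   `r2_conditional`, `var_components` (posterior means of
#'   sigma2_fixed/random/resid), and the underlying `fit`.
#' @export
fit_size_scaling <- function(data, response,
                             random = c("intercept", "slope", "both"),
                             use_phylogeny = TRUE, tree = NULL,
                             n_iter = 4000, burn_in = 1000, thin = 3,
                             n_chains = 2, seed = 1) {
  random <- match.arg(random)
  stopifnot(all(c("taxon_id", "ln_volume", response) %in% names(data)))
  data <- data[is.finite(data$ln_volume) & is.finite(data[[response]]), ,
               drop = FALSE]
  taxa <- unique(data$taxon_id)
  if (length(taxa) < 3L) stop("fewer than 3 species with usable data")
  if (grepl("ln_b0", response))
    warning("ln(B0) response: the Gaussian response assumption is strained; ",
            "interpret with care")

  if (use_phylogeny) {
    if (is.null(tree)) stop("use_phylogeny = TRUE requires a tree")
    pc <- if (inherits(tree, "phylo_cov")) tree else
      phylo_covariance(prune_tree(tree, taxa))
  } else {
    A <- diag(length(taxa))
    dimnames(A) <- list(taxa, taxa)
    pc <- structure(list(taxa = taxa, A = A, A_inv = A, height = 1),
                    class = "phylo_cov")
  }

  ct <- mean(data$ln_volume); sc <- sd(data$ln_volume)
  if (!is.finite(sc) || sc == 0) sc <- 1
  z <- (data$ln_volume - ct) / sc
  traits <- data.frame(taxon_id = data$taxon_id)
  traits[[response]] <- data[[response]]
  vc <- paste0("var.", response)
  if (vc %in% names(data)) traits[[vc]] <- data[[vc]]
  traits$zvol <- z

  design <- build_design(traits, pc, fixed = "zvol", responses = response)
  Zr <- switch(random,
               intercept = matrix(1, nrow(design$Y), 1),
               slope = matrix(design$X[, "zvol"], ncol = 1),
               both = cbind(1, design$X[, "zvol"]))
  fit <- pmm_fit(design, n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, seed = seed, random_design = Zr)

  beta <- merged_draws(fit, "beta")      # columns: intercept, zvol
  slope_draws <- beta[, 2] / sc
  int_draws <- beta[, 1] - beta[, 2] * ct / sc
  hs <- hpd_interval(slope_draws); hi <- hpd_interval(int_draws)

  # variance components per draw: variance of each predictor over the data
  U <- merged_draws(fit, "U")            # draws x (N*q)
  N <- length(pc$taxa); q <- ncol(Zr)
  spi <- design$sp
  n <- nrow(design$Y)
  vf <- vr <- numeric(nrow(beta))
  Xz <- design$X[, 2]
  for (dr in seq_len(nrow(beta))) {
    fixed_pred <- design$X %*% beta[dr, ]
    vf[dr] <- var(drop(fixed_pred))
    Um <- matrix(U[dr, ], N, q)
    rand_pred <- rowSums(Zr * Um[spi, , drop = FALSE])
    vr[dr] <- var(rand_pred)
  }
  ve <- merged_draws(fit, "R")[, 1]
  r2 <- t(vapply(seq_along(vf), function(i)
    unlist(r_squared_components(vf[i], vr[i], ve[i])), numeric(2)))

  structure(list(
    slope = c(mean = mean(slope_draws), hs),
    intercept = c(mean = mean(int_draws), hi),
    dic = compute_dic(fit)$dic,
    r2_marginal = mean(r2[, 1]), r2_conditional = mean(r2[, 2]),
    var_components = c(sigma2_fixed = mean(vf), sigma2_random = mean(vr),
                       sigma2_resid = mean(ve)),
    response = response, random = random, use_phylogeny = use_phylogeny,
    fit = fit), class = "scaling_summary")
}

#' @export
print.scaling_summary <- function(x, ...) {
  cat(sprintf("Size-scaling of %s on ln(cell volume) [random %s%s]\n",
              x$response, x$random,
              if (x$use_phylogeny) ", phylogenetic" else ""))
  cat(sprintf("  slope = %.3f (%.3f, %.3f)   DIC = %.2f\n",
              x$slope[["mean"]], x$slope[["lower"]], x$slope[["upper"]],
              x$dic))
  cat(sprintf("  Rm^2 = %.3f   Rc^2 = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Marginal and conditional coefficients of determination
#'
#' `Rm^2 = s_f / (s_f + s_r + s_e)` and `Rc^2 = (s_f + s_r) / (s_f + s_r +
#' s_e)` from the fixed-effect, random-effect and residual variances, with
#' the fixed-effect variance taken as the variance of the fixed-effect
#' linear predictor over the data (Nakagawa-Schielzeth convention).
#'
#' @param sigma2_fixed,sigma2_random,sigma2_resid Variance components
#'   (all >= 0, not all zero).
#' @return List with `r2_marginal` and `r2_conditional`.
#' @export
r_squared_components <- function(sigma2_fixed, sigma2_random, sigma2_resid) {
  if (any(c(sigma2_fixed, sigma2_random, sigma2_resid) < 0))
    stop("variance components must be nonnegative")
  tot <- sigma2_fixed + sigma2_random + sigma2_resid
  if (tot == 0) stop("all variance components are zero")
  list(r2_marginal = sigma2_fixed / tot,
       r2_conditional = (sigma2_fixed + sigma2_random) / tot)
}
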