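#' MCMC configuration for the Bayesian marker-effect models
#'
#' One configuration object drives all five models of the Gibbs engine.
#' Defaults follow common whole-genome-regression practice: 12,000
#' iterations with a 2,000-iteration burn-in, effect-variance priors
#' scaled-inverse-chi-square with df 4.2 and scale solved from an assumed
#' genetic-variance share R2 = 0.5, BayesB spike mass `pi0 = 0.95`
#' (arbitrary by construction, exposed here), a uniform (Beta(1,1))
#' update of the spike mass for BayesC, an exponential-gamma hierarchy
#' for the Bayesian LASSO, and a Dirichlet(1,1,1,1) prior over the
#' four-component BayesR mixture with component variances
#' (0, 0.0001, 0.001, 0.01) x sigma_g2.
#'
#' @param model one of `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BL"`,
#'   `"BayesR"`.
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded initial iterations (must be < `n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed for the chain (R RNG; a given seed
#'   reproduces the full trace bit-identically).
#' @param pi0 prior probability of a zero effect (BayesB fixed;
#'   BayesC initial value).
#' @param df0 prior degrees of freedom for effect variances.
#' @param R2 assumed share of phenotypic variance captured by markers,
#'   used to solve the prior scales.
#' @param comp_var_frac BayesR component variances as fractions of
#'   sigma_g2.
#' @param update_pi sample the spike mass from its Beta full conditional
#'   (default: yes for BayesC, no otherwise). Set `FALSE` to hold `pi0`
#'   fixed, e.g. to let BayesC with `pi0 = 0` reproduce BayesA.
#' @return a validated list of class `mcmc_config`.
#' @export
mcmc_config <- function(model = c("BayesA", "BayesB", "BayesC", "BL", "BayesR"),
                        n_iter = 12000, burn_in = 2000, thin = 1,
                        seed = 1L, pi0 = 0.95, df0 = 4.2, R2 = 0.5,
                        comp_var_frac = c(0, 1e-4, 1e-3, 1e-2),
                        update_pi = NULL) {
  model <- match.arg(model)
  stopifnot(n_iter >= 2, burn_in >= 0, thin >= 1)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]")
  if (R2 <= 0 || R2 >= 1) stop("R2 must lie in (0, 1)")
  if (is.null(update_pi)) update_pi <- model == "BayesC"
  structure(list(model = model, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 pi0 = pi0, df0 = df0, R2 = R2,
                 comp_var_frac = comp_var_frac, update_pi = update_pi),
            class = "mcmc_config")
}

#' Run the Gibbs sampler for a Bayesian marker-effect model
#'
#' Single-site Gibbs sweeps over the overall mean, every marker effect
#' (with indicator or mixture-component draws where the prior has them),
#' the effect variances and the residual variance, with incremental
#' residual maintenance. Genotypes are column-centered before sampling;
#' the centering constants are stored in the summary so predictions for
#' new individuals use the training centering.
#'
#' @param geno a [genotype_matrix()] or dosage matrix of the training
#'   individuals (no missing dosages).
#' @param y numeric phenotypes, one per row of `geno`.
#' @param cfg an [mcmc_config()].
#' @return object of class `posterior_summary`: per-marker posterior mean
#'   effects and inclusion probabilities, posterior means of mu and the
#'   variances, BayesR component occupancies, thinned scalar trace, and
#'   batch-means Monte Carlo standard errors for mu and sigma_e2.
#' @export
run_mcmc <- function(geno, y, cfg) {
  stopifnot(inherits(cfg, "mcmc_config"))
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  if (anyNA(d)) stop("missing dosages; impute or filter before MCMC")
  y <- as.numeric(y)
  if (length(y) != nrow(d)) stop("y length does not match genotype rows")
  if (anyNA(y)) stop("missing phenotypes")
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) stop("non-finite likelihood: phenotype variance is zero")
  n <- nrow(d); m <- ncol(d)
  ctr <- colMeans(d)
  W <- sweep(d, 2, ctr)
  MSx <- sum(colSums(W^2)) / (n - 1)
  if (MSx <= 0) stop("all markers are monomorphic")
  model_code <- match(cfg$model, c("BayesA", "BayesB", "BayesC", "BL", "BayesR")) - 1L

  df_e <- 5; S_e <- vy * (1 - cfg$R2) * (df_e + 2)
  df_g <- cfg$df0
  varg_init <- vy * cfg$R2 / MSx
  S_g <- varg_init * (df_g + 2)
  if (model_code == 1L && cfg$pi0 < 1) S_g <- S_g / (1 - cfg$pi0)
  if (model_code == 2L) S_g <- S_g / max(1 - cfg$pi0, 0.05)
  lambda2_init <- max(2 * MSx * (1 - cfg$R2) / cfg$R2, 1e-6)
  bl_shape <- 1.1
  bl_rate <- bl_shape / lambda2_init
  cf <- cfg$comp_var_frac
  mean_cf <- sum(cf * rep(1 / length(cf), length(cf)))
  sigma_g2_init <- vy * cfg$R2 / (MSx * max(mean_cf, 1e-8))
  df_r <- cfg$df0
  S_r <- sigma_g2_init * (df_r + 2)

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- gibbs_engine(W, y, model_code, cfg$n_iter, cfg$burn_in, cfg$thin,
                      df_e, S_e, df_g, S_g, cfg$pi0,
                      update_pi = isTRUE(cfg$update_pi),
                      bl_shape, bl_rate, lambda2_init, varg_init,
                      cf, df_r, S_r, sigma_g2_init)
  trace <- as.data.frame(res$trace)
  names(trace) <- c("mu", "sigma_e2", "sigma_g2", "pi", "m_nonzero")
  diverged <- mean(trace$sigma_e2) < 1e-6 * vy
  marker_ids <- colnames(d)
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(m))
  out <- list(
    model = cfg$model,
    effect_mean = setNames(as.numeric(res$effect_mean), marker_ids),
    inclusion_prob = setNames(as.numeric(res$inclusion_prob), marker_ids),
    mu = res$mu,
    sigma_e2 = mean(trace$sigma_e2),
    sigma_g2 = mean(trace$sigma_g2),
    pi_mean = mean(trace$pi),
    comp_occupancy = as.numeric(res$comp_occupancy),
    centers = setNames(ctr, marker_ids),
    trace = trace,
    mcse = c(mu = batch_means_mcse(trace$mu),
             sigma_e2 = batch_means_mcse(trace$sigma_e2)),
    n_iter = cfg$n_iter, burn_in = cfg$burn_in, thin = cfg$thin,
    seed = cfg$seed, diverged = diverged
  )
  class(out) <- "posterior_summary"
  if (diverged) warning("divergent chain: residual variance collapsed toward zero")
  out
}

# Monte Carlo standard error by non-overlapping batch means.
batch_means_mcse <- function(x, n_batches = 30) {
  n <- length(x)
  nb <- min(n_batches, max(2, n %/% 2))
  bs <- n %/% nb
  if (bs < 1) return(NA_real_)
  bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(bm) / sqrt(nb)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("%s posterior summary (%d iterations, %d burn-in, thin %d)\n",
              x$model, x$n_iter, x$burn_in, x$thin))
  cat(sprintf("  mu = %.4g (MCSE %.3g); sigma_e2 = %.4g (MCSE %.3g); sigma_g2 = %.4g\n",
              x$mu, x$mcse["mu"], x$sigma_e2, x$mcse["sigma_e2"], x$sigma_g2))
  cat(sprintf("  markers: %d; mean inclusion %.3f\n",
              length(x$effect_mean), mean(x$inclusion_prob)))
  invisible(x)
}

#' Genomic breeding values from posterior-mean marker effects
#'
#' GEBV = coded genotypes x posterior-mean effects; the overall mean is
#' excluded. Genotypes are centered with the constants stored during
#' sampling (zero when none are stored), which shifts every GEBV by the
#' same constant and leaves correlations and regression slopes unchanged.
#'
#' @param geno a [genotype_matrix()] or dosage matrix (any individuals,
#'   same markers as the training run).
#' @param summary a `posterior_summary` from [run_mcmc()], or any list
#'   with `effect_mean` (and optionally `centers`) entries.
#' @return a `prediction_result` with per-individual GEBVs.
#' @export
gebv_from_effects <- function(geno, summary) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  eff <- summary$effect_mean
  if (ncol(d) != length(eff)) {
    stop("marker mismatch: genotypes have ", ncol(d), " markers, effects ",
         length(eff))
  }
  if (!is.null(colnames(d)) && !is.null(names(eff)) &&
      !identical(colnames(d), names(eff))) {
    stop("marker mismatch: marker ids differ between genotypes and effects")
  }
  ctr <- summary$centers
  W <- if (is.null(ctr)) d else sweep(d, 2, ctr)
  gebv <- setNames(drop(W %*% eff), rownames(d))
  structure(list(gebv = gebv, b_hat = if (!is.null(summary$mu)) summary$mu else NA_real_,
                 model = if (!is.null(summary$model)) summary$model else "marker-effects",
                 residual_norm = NA_real_),
            class = "prediction_result")
}
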