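#' Restricted log-likelihood of the single-kinship mixed model
#'
#' Model: y = X b + g + e with g ~ N(0, K sigma_g2), e ~ N(0, I sigma_e2).
#' Evaluated through the eigendecomposition of K, which makes repeated
#' evaluations (and hence grid scans) cheap. The value includes the
#' -0.5 (n - p) log(2 pi) constant.
#'
#' @param y numeric response.
#' @param K kinship matrix, or the precomputed `eigen(K, symmetric=TRUE)`.
#' @param sigma_g2,sigma_e2 variance components (must give a positive
#'   definite V on the eigenvalue support).
#' @param X fixed-effect design (default intercept-only).
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik <- function(y, K, sigma_g2, sigma_e2, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  eg <- if (is.list(K) && !is.null(K$values)) K else eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ys <- drop(crossprod(eg$vectors, y))
  Xs <- crossprod(eg$vectors, X)
  .reml_ll_rotated(ys, Xs, d, sigma_g2, sigma_e2)
}

.reml_ll_rotated <- function(ys, Xs, d, sg, se) {
  n <- length(ys)
  p <- ncol(Xs)
  v <- sg * d + se
  if (any(v <= 0)) return(-Inf)
  vinv <- 1 / v
  XtViX <- crossprod(Xs, Xs * vinv)
  XtViy <- crossprod(Xs, ys * vinv)
  cXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cXtViX)) return(-Inf)
  beta <- backsolve(cXtViX, forwardsolve(t(cXtViX), XtViy))
  yPy <- sum(ys^2 * vinv) - sum(XtViy * beta)
  ldV <- sum(log(v))
  ldXtViX <- 2 * sum(log(diag(cXtViX)))
  -0.5 * (ldV + ldXtViX + yPy + (n - p) * log(2 * pi))
}

# score, average information and P y for the rotated model
.reml_derivs <- function(ys, Xs, d, sg, se) {
  v <- sg * d + se
  vinv <- 1 / v
  XtViX <- crossprod(Xs, Xs * vinv)
  B <- solve(XtViX)
  Pfun <- function(u) {
    vu <- vinv * u
    vu - (Xs * vinv) %*% (B %*% crossprod(Xs, vu))
  }
  Py <- drop(Pfun(ys))
  # tr(P K_j): K_1 = diag(d), K_2 = I
  trP <- function(dd) {
    sum(dd * vinv) - sum(diag(B %*% crossprod(Xs, Xs * (dd * vinv^2))))
  }
  trPK <- c(trP(d), trP(rep(1, length(d))))
  yPKPy <- c(sum(d * Py^2), sum(Py^2))
  score <- -0.5 * (trPK - yPKPy)
  u1 <- d * Py
  u2 <- Py
  AI <- matrix(0, 2, 2)
  Pu1 <- drop(Pfun(u1)); Pu2 <- drop(Pfun(u2))
  AI[1, 1] <- 0.5 * sum(u1 * Pu1)
  AI[1, 2] <- AI[2, 1] <- 0.5 * sum(u1 * Pu2)
  AI[2, 2] <- 0.5 * sum(u2 * Pu2)
  list(score = score, AI = AI, trPK = trPK, yPKPy = yPKPy)
}

#' REML estimation of additive and residual variance
#'
#' Average-information (AI) REML for the model y = mu + g + e with
#' g ~ N(0, K sigma_g2), evaluated on the eigendecomposition of K. When
#' an AI step would leave the parameter space the iteration falls back to
#' the EM-REML update, and every accepted step is required not to
#' decrease the restricted log-likelihood (step halving otherwise).
#' Standard errors come from the inverse average-information matrix; the
#' SE of h2 is obtained by the delta method.
#'
#' @param y corrected phenotypes (pre-adjusted for fixed effects, so the
#'   internal fixed design is intercept-only).
#' @param K positive semidefinite kinship matrix (G, A or H), or a
#'   precomputed `eigen()` decomposition of it.
#' @param max_iter maximum AI/EM iterations.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @return object of class `variance_components`: `sigma_g2`, `sigma_e2`,
#'   `h2`, `se` (named: sigma_g2, sigma_e2, h2), `loglik`, `n_iter`,
#'   `converged`, `boundary`.
#' @export
estimate_reml <- function(y, K, max_iter = 100, tol = 1e-8) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("need at least 10 records for REML")
  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) stop("phenotype is constant; REML undefined")
  eg <- if (is.list(K) && !is.null(K$values)) K else eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, matrix(1, n, 1))
  floor_v <- 1e-8 * vy
  sg <- se <- vy / 2
  ll <- .reml_ll_rotated(ys, Xs, d, sg, se)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    dv <- .reml_derivs(ys, Xs, d, sg, se)
    step <- tryCatch(solve(dv$AI, dv$score), error = function(e) NULL)
    prop <- if (!is.null(step)) c(sg, se) + step else c(-1, -1)
    if (any(prop <= 0)) {
      # EM fallback keeps the parameters positive and ascends the likelihood
      prop <- c(sg + sg^2 * (dv$yPKPy[1] - dv$trPK[1]) / n,
                se + se^2 * (dv$yPKPy[2] - dv$trPK[2]) / n)
    }
    prop <- pmax(prop, floor_v)
    ll_new <- .reml_ll_rotated(ys, Xs, d, prop[1], prop[2])
    halvings <- 0
    while (ll_new < ll && halvings < 30) {
      prop <- (prop + c(sg, se)) / 2
      ll_new <- .reml_ll_rotated(ys, Xs, d, prop[1], prop[2])
      halvings <- halvings + 1
    }
    delta_ll <- ll_new - ll
    rel_change <- max(abs(prop - c(sg, se)) / (c(sg, se) + floor_v))
    sg <- prop[1]; se <- prop[2]; ll <- ll_new
    if (abs(delta_ll) < tol * (abs(ll) + 1) || rel_change < 1e-9) {
      converged <- TRUE
      break
    }
    # boundary optimum: a variance floored with the likelihood still
    # pushing it down
    if (sg <= floor_v * 1.01 || se <= floor_v * 1.01) {
      sc <- .reml_derivs(ys, Xs, d, sg, se)$score
      if ((sg > floor_v * 1.01 || sc[1] < 0) &&
          (se > floor_v * 1.01 || sc[2] < 0)) {
        converged <- TRUE
        break
      }
    }
  }
  # profile polish over the heritability ratio: the AI/EM iteration creeps
  # when the optimum sits at a variance boundary, while the 1-D profile of
  # the same restricted likelihood locates it directly
  prof <- function(h2) {
    v0 <- h2 * d + (1 - h2)
    if (any(v0 <= 0)) return(list(ll = -Inf, sp2 = NA_real_))
    vinv <- 1 / v0
    XtViX <- crossprod(Xs, Xs * vinv)
    XtViy <- crossprod(Xs, ys * vinv)
    beta <- tryCatch(solve(XtViX, XtViy), error = function(e) NULL)
    if (is.null(beta)) return(list(ll = -Inf, sp2 = NA_real_))
    yP0y <- sum(ys^2 * vinv) - sum(XtViy * beta)
    sp2 <- yP0y / (n - ncol(Xs))
    list(ll = .reml_ll_rotated(ys, Xs, d, h2 * sp2, (1 - h2) * sp2), sp2 = sp2)
  }
  opt <- optimize(function(h) prof(h)$ll, c(0, 1 - 1e-9),
                  maximum = TRUE, tol = 1e-9)
  cand_h2 <- c(opt$maximum, 0)
  for (h2c in cand_h2) {
    pc <- prof(h2c)
    if (is.finite(pc$ll) && pc$ll > ll + 1e-10) {
      sg <- max(h2c * pc$sp2, floor_v)
      se <- max((1 - h2c) * pc$sp2, floor_v)
      ll <- pc$ll
      converged <- TRUE
    }
  }
  dv <- .reml_derivs(ys, Xs, d, sg, se)
  Cmat <- tryCatch(solve(dv$AI), error = function(e) matrix(NA_real_, 2, 2))
  boundary <- sg <= floor_v * 1.000001
  tot <- sg + se
  h2 <- if (boundary) 0 else sg / tot
  grad <- c(se, -sg) / tot^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% Cmat %*% grad)))
  out <- list(
    sigma_g2 = sg, sigma_e2 = se, h2 = h2,
    se = c(sigma_g2 = sqrt(max(0, Cmat[1, 1])),
           sigma_e2 = sqrt(max(0, Cmat[2, 2])),
           h2 = se_h2),
    loglik = ll, n_iter = it, converged = converged, boundary = boundary
  )
  class(out) <- "variance_components"
  if (!converged) warning("REML did not converge in ", max_iter, " iterations")
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("REML variance components: sigma_g2 = %.4g (SE %.3g), sigma_e2 = %.4g (SE %.3g)\n",
              x$sigma_g2, x$se["sigma_g2"], x$sigma_e2, x$se["sigma_e2"]))
  cat(sprintf("  h2 = %.4f (SE %.3g); loglik %.4f; %d iterations; converged: %s%s\n",
              x$h2, x$se["h2"], x$loglik, x$n_iter, x$converged,
              if (x$boundary) " (boundary: sigma_g2 ~ 0)" else ""))
  invisible(x)
}

#' Heritability from variance components
#'
#' h2 = sigma_g2 / (sigma_g2 + sigma_e2).
#'
#' @param vc a `variance_components` object, or a numeric vector
#'   `c(sigma_g2, sigma_e2)`.
#' @return heritability in \[0, 1\].
#' @export
heritability <- function(vc) {
  if (inherits(vc, "variance_components")) {
    sg <- vc$sigma_g2; se <- vc$sigma_e2
  } else {
    stopifnot(is.numeric(vc), length(vc) == 2)
    sg <- vc[1]; se <- vc[2]
  }
  if (sg < 0 || se < 0) stop("variances must be non-negative")
  tot <- sg + se
  if (tot <= 0) stop("zero phenotypic variance; heritability undefined")
  unname(sg / tot)
}
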