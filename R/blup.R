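#' Solve the GBLUP mixed-model equations
#'
#' Model y = X b + Z g + e with g ~ N(0, G sigma_g2). The equations
#' \preformatted{
#'   [ X'X      X'Z        ] [ b ]   [ X'y ]
#'   [ Z'X      Z'Z + k G^-1 ] [ g ] = [ Z'y ]
#' }
#' are solved directly (k = sigma_e2 / sigma_g2). Breeding values are
#' returned for every individual in G, so individuals without phenotype
#' records (e.g. a validation fold) are predicted through their genomic
#' relationships with the training records.
#'
#' @param y named numeric vector of (corrected) phenotypes; names must be
#'   a subset of the ids of `G`. Individuals absent from `y` contribute no
#'   records but still receive GEBVs.
#' @param G genomic relationship matrix with ids as dimnames (blend it
#'   first if singular), or `NULL` when `G_inv` is given.
#' @param k variance ratio sigma_e2 / sigma_g2 (> 0), typically from
#'   [estimate_reml()] on the training records.
#' @param G_inv optional precomputed inverse of G (saves repeated
#'   inversion across cross-validation folds).
#' @param X fixed-effect design over the records of `y`
#'   (default intercept-only; the two-stage scheme corrects other fixed
#'   effects beforehand).
#' @return object of class `prediction_result`: `gebv` (named, all
#'   individuals of G), `b_hat`, `model`, `residual_norm` (relative MME
#'   residual).
#' @export
solve_gblup <- function(y, G = NULL, k, G_inv = NULL, X = NULL) {
  stopifnot(k > 0)
  if (is.null(G_inv)) {
    if (is.null(G)) stop("supply G or G_inv")
    G_inv <- tryCatch(chol2inv(chol(G)), error = function(e) {
      stop("singular G in the mixed-model equations; blend G with A22 ",
           "(blend_G) or check for duplicated individuals")
    })
    dimnames(G_inv) <- dimnames(G)
  }
  solve_kinv_mme(y, K_inv = G_inv, k = k, X = X, model = "GBLUP")
}

#' Solve the single-step GBLUP mixed-model equations
#'
#' Identical to [solve_gblup()] with the genomic relationship replaced by
#' the combined pedigree-genomic structure: Z'Z + k H^-1. GEBVs are
#' produced for every pedigree individual, genotyped or not.
#'
#' @param y named numeric vector of phenotypes; names must be ids of
#'   `H_inv` (phenotyped individuals must be in the pedigree).
#' @param H_inv assembled single-step inverse (see [compute_H_inverse()]).
#' @param k variance ratio sigma_e2 / sigma_g2.
#' @param X optional fixed design (default intercept).
#' @return a `prediction_result` with GEBVs for all pedigree individuals.
#' @export
solve_ssgblup <- function(y, H_inv, k, X = NULL) {
  stopifnot(k > 0)
  solve_kinv_mme(y, K_inv = as.matrix(H_inv), k = k, X = X, model = "ssGBLUP")
}

solve_kinv_mme <- function(y, K_inv, k, X = NULL, model = "GBLUP") {
  ids <- rownames(K_inv)
  if (is.null(ids)) stop("relationship inverse must carry ids as dimnames")
  if (is.null(names(y))) stop("y must be a named vector")
  ji <- match(names(y), ids)
  if (anyNA(ji)) {
    stop("phenotyped individual(s) missing from the relationship structure: ",
         paste(names(y)[is.na(ji)], collapse = ", "))
  }
  n <- length(y)
  q <- length(ids)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), ji)] <- 1
  XtX <- crossprod(X)
  XtZ <- crossprod(X, Z)
  ZtZ_diag <- tabulate(ji, nbins = q)
  C22 <- k * K_inv
  diag(C22) <- diag(C22) + ZtZ_diag
  LHS <- rbind(cbind(XtX, XtZ), cbind(t(XtZ), C22))
  RHS <- c(crossprod(X, y), crossprod(Z, y))
  sol <- tryCatch(solve(LHS, RHS), error = function(e) {
    stop("singular mixed-model equations; blend the genomic matrix or ",
         "check the design rank")
  })
  b_hat <- sol[seq_len(p)]
  gebv <- setNames(sol[-seq_len(p)], ids)
  resid <- LHS %*% sol - RHS
  rn <- max(abs(resid)) / (1 + max(abs(RHS)))
  structure(list(gebv = gebv, b_hat = b_hat, model = model,
                 residual_norm = rn),
            class = "prediction_result")
}

#' Ridge-regression (SNP-BLUP) marker-effect solver
#'
#' Marker effects with a common variance, jointly with an intercept:
#' the intercept is absorbed, so the effect solutions are
#' a = (W'MW + k_marker I)^-1 W'My with M the training-mean projection,
#' evaluated in the m- or n-dimensional form, whichever is smaller. With
#' G = W W' / c (VanRaden, same centering) and k_marker = k * c this is
#' mathematically equivalent to GBLUP, which makes it the natural
#' cross-check for the mixed-model solver. GEBVs are returned for every
#' row of `geno`.
#'
#' @param geno a [genotype_matrix()] or dosage matrix (all individuals to
#'   predict).
#' @param y named phenotypes over the training subset of the rows.
#' @param k_marker ridge penalty (residual/marker-variance ratio).
#' @param centers optional per-marker centering constants (e.g. `2p` for
#'   the frequencies used to build the matching G); default: training
#'   column means. Centering shifts every GEBV by a constant that the
#'   intercept absorbs, so accuracy and bias metrics are unaffected.
#' @return a `prediction_result` with `gebv`, `b_hat` (intercept),
#'   `effects` (per-marker solutions), `model = "SNPBLUP"`.
#' @export
solve_snp_blup <- function(geno, y, k_marker, centers = NULL) {
  stopifnot(k_marker > 0)
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  if (ncol(d) == 0) stop("no markers available for SNP-BLUP")
  if (is.null(names(y))) stop("y must be a named vector")
  tr <- match(names(y), rownames(d))
  if (anyNA(tr)) stop("training individual(s) missing from genotypes")
  if (is.null(centers)) centers <- colMeans(d[tr, , drop = FALSE])
  W_tr <- sweep(d[tr, , drop = FALSE], 2, centers)
  # absorb the intercept: column-center within training, center y
  cm <- colMeans(W_tr)
  Wc <- sweep(W_tr, 2, cm)
  yc <- y - mean(y)
  n <- length(y); m <- ncol(d)
  if (m <= n) {
    A_mat <- crossprod(Wc)
    diag(A_mat) <- diag(A_mat) + k_marker
    a <- solve(A_mat, crossprod(Wc, yc))
  } else {
    # identity (W'W + kI)^-1 W' = W'(WW' + kI)^-1
    B <- tcrossprod(Wc)
    diag(B) <- diag(B) + k_marker
    a <- crossprod(Wc, solve(B, yc))
  }
  a <- drop(a)
  W_all <- sweep(d, 2, centers)
  gebv <- setNames(drop(W_all %*% a), rownames(d))
  mu <- mean(y) - sum(cm * a)
  structure(list(gebv = gebv, b_hat = mu, effects = setNames(a, colnames(d)),
                 model = "SNPBLUP", residual_norm = NA_real_),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s predictions for %d individuals\n", x$model, length(x$gebv)))
  cat("  gebv range:", sprintf("%.4g .. %.4g", min(x$gebv), max(x$gebv)), "\n")
  if (!is.na(x$residual_norm)) {
    cat("  relative MME residual:", format(x$residual_norm, digits = 3), "\n")
  }
  invisible(x)
}
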