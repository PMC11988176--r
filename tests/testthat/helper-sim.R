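# Shared fixture builders: everything is generated in code at test time.

# A small simulated study population with corrected phenotypes.
small_study <- function(n_cohort = 200, n_markers = 400, target_h2 = 0.5,
                        seed = 1, ...) {
  pop <- simulate_population(n_cohort = n_cohort, n_markers = n_markers,
                             target_h2 = target_h2, seed = seed, ...)
  ph <- correct_phenotypes(pop$pheno, trait = "y",
                           fixed_effects = c("sex", "farm", "batch"))
  pop$y_c <- setNames(ph$y_c, ph$id)
  pop
}

# Random unstructured dosage matrix with known generating frequencies.
random_dosage <- function(n, m, seed, maf_range = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  d <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(d) <- paste0("i", seq_len(n))
  colnames(d) <- paste0("m", seq_len(m))
  list(dosage = d, p = p)
}

# Hand-built trio pedigree: 2 founders + their offspring.
trio_pedigree <- function() {
  pedigree(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
}

# Dense restricted log-likelihood, written independently of the package
# internals: direct matrix formula with profiled total variance.
dense_reml_profile_ll <- function(y, K, h2) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V0 <- h2 * K + (1 - h2) * diag(n)
  V0i <- solve(V0)
  XtViX <- crossprod(X, V0i %*% X)
  P0 <- V0i - V0i %*% X %*% solve(XtViX) %*% t(X) %*% V0i
  sp2 <- drop(crossprod(y, P0 %*% y)) / (n - 1)
  V <- sp2 * V0
  Vi <- V0i / sp2
  XtViX2 <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX2) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + determinant(XtViX2)$modulus +
            drop(crossprod(y, P %*% y)) + (n - 1) * log(2 * pi))
}
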