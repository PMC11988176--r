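test_that("GBLUP handles constant phenotypes and the strong-shrinkage limit", {
  rd <- random_dosage(30, 60, seed = 51)
  G <- compute_G(rd$dosage, freq = rd$p)
  y <- setNames(rep(4.2, 30), rownames(rd$dosage))
  r <- solve_gblup(y, G, k = 1)
  expect_equal(unname(r$b_hat), 4.2, tolerance = 1e-8)
  expect_lt(max(abs(r$gebv)), 1e-8)

  set.seed(52)
  y2 <- setNames(rnorm(30), rownames(rd$dosage))
  norms <- sapply(c(1, 10, 100, 1e4), function(k) {
    sqrt(sum(solve_gblup(y2, G, k = k)$gebv^2))
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-2 * norms[1])
})

test_that("the MME solution equals the closed-form absorbed-intercept estimator", {
  set.seed(53)
  rd <- random_dosage(50, 120, seed = 53)
  G <- compute_G(rd$dosage, freq = rd$p)
  y <- setNames(rnorm(50), rownames(rd$dosage))
  k <- 2.5
  r <- solve_gblup(y, G, k = k)
  n <- length(y)
  M <- diag(n) - matrix(1 / n, n, n) # intercept-absorbing projection
  g_closed <- solve(M + k * solve(G), M %*% y)
  expect_equal(unname(r$gebv), unname(drop(g_closed)), tolerance = 1e-8)
  expect_lt(r$residual_norm, 1e-10)
})

test_that("predictions are equivariant under phenotype shifts", {
  rd <- random_dosage(25, 80, seed = 54)
  G <- compute_G(rd$dosage, freq = rd$p)
  set.seed(54)
  y <- setNames(rnorm(25), rownames(rd$dosage))
  r1 <- solve_gblup(y, G, k = 1.3)
  r2 <- solve_gblup(y + 7, G, k = 1.3)
  expect_equal(r1$gebv, r2$gebv, tolerance = 1e-9)
  expect_equal(unname(r2$b_hat - r1$b_hat), 7, tolerance = 1e-9)
})

test_that("GBLUP breeding values lie in the column space of G", {
  rd <- random_dosage(20, 100, seed = 55)
  G <- compute_G(rd$dosage, freq = rd$p)
  set.seed(55)
  y <- setNames(rnorm(20), rownames(rd$dosage))
  g <- solve_gblup(y, G, k = 1)$gebv
  # project onto the column space of G
  proj <- G %*% solve(crossprod(G) + diag(1e-10, 20), crossprod(G, g))
  expect_equal(drop(proj), unname(g), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("SNP-BLUP equals GBLUP on matched instances (property over seeds)", {
  for (seed in 56:60) {
    set.seed(seed)
    n <- sample(30:100, 1); m <- sample(n:300, 1)
    rd <- random_dosage(n, m, seed = seed)
    G <- compute_G(rd$dosage, freq = rd$p)
    y <- setNames(rnorm(n), rownames(rd$dosage))
    k <- exp(runif(1, -1, 2))
    r_mme <- solve_gblup(y, G, k = k)
    r_ridge <- solve_snp_blup(rd$dosage, y, k_marker = k * attr(G, "denom"),
                              centers = 2 * rd$p)
    expect_lt(max(abs(r_mme$gebv - r_ridge$gebv)) /
                max(abs(r_mme$gebv)), 1e-6)
  }
})

test_that("duplicated markers split the effect mass equally", {
  rd <- random_dosage(40, 10, seed = 61)
  d <- cbind(rd$dosage, dup = rd$dosage[, 1])
  set.seed(61)
  y <- setNames(rd$dosage[, 1] + rnorm(40, 0, 0.1), rownames(rd$dosage))
  r <- solve_snp_blup(d, y, k_marker = 5)
  expect_equal(unname(r$effects[1]), unname(r$effects["dup"]), tolerance = 1e-9)
  expect_error(solve_snp_blup(rd$dosage[, 0], y, 1), "no markers")
})

test_that("ssGBLUP equals GBLUP when everyone is genotyped with G = A", {
  pop <- simulate_population(n_cohort = 40, n_markers = 100,
                             n_generations = 2, seed = 62)
  ped <- pop$ped
  A <- compute_A(ped)
  hh <- compute_H_inverse(ped, A, epsilon = 0)
  set.seed(62)
  y <- setNames(rnorm(nrow(ped)), as.character(ped$id))
  r_ss <- solve_ssgblup(y, hh$H_inv, k = 1.5)
  r_g <- solve_gblup(y, A, k = 1.5)
  expect_equal(r_ss$gebv, r_g$gebv, tolerance = 1e-8)
})

test_that("an ungenotyped parent of many phenotyped offspring gets a nonzero GEBV", {
  # several founder families; parents unphenotyped and ungenotyped in the
  # single-step system. A family's mean deviation from the cohort is what
  # flows back into its parents (with one family the cohort mean is the
  # family mean and the parental prediction is identically zero).
  cfg <- sim_config(n_founders = 8, n_generations = 1,
                    offspring_per_mating = 10, n_markers = 150,
                    target_h2 = 0.6, fixed_effect_spec = list(), seed = 63)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  sim <- simulate_effects_and_phenotypes(geno, cfg)
  off_ids <- as.character(ped$id[ped$gen == 1])
  G <- compute_G(subset_individuals(geno, off_ids))
  hh <- compute_H_inverse(ped, G, epsilon = 0.05)
  y <- setNames(sim$pheno$y, sim$pheno$id)[off_ids]
  y <- y - mean(y)
  r <- solve_ssgblup(y, hh$H_inv, k = 1)
  founders <- as.character(ped$id[ped$gen == 0])
  expect_gt(max(abs(r$gebv[founders])), 0.05)
  # each parent's GEBV tracks its own offspring's mean prediction
  for (f in founders) {
    own <- as.character(ped$id[ped$sire == as.integer(f) |
                               ped$dam == as.integer(f)])
    expect_equal(unname(sign(r$gebv[f])), unname(sign(mean(r$gebv[own]))))
  }
  # independent dense-MME oracle with H built by block arithmetic
  A <- compute_A(ped)
  idx <- hh$genotyped_index
  H <- A
  A22i <- solve(A[idx, idx])
  Gbi <- solve(hh$G_blend)
  Hi_manual <- solve(A)
  Hi_manual[idx, idx] <- Hi_manual[idx, idx] + Gbi - A22i
  H_dense <- solve(Hi_manual)
  n <- length(y); q <- nrow(ped)
  Z <- matrix(0, n, q); Z[cbind(seq_len(n), match(names(y), as.character(ped$id)))] <- 1
  X <- matrix(1, n, 1)
  LHS <- rbind(cbind(crossprod(X), crossprod(X, Z)),
               cbind(crossprod(Z, X), crossprod(Z) + 1 * solve(H_dense)))
  sol <- solve(LHS, c(crossprod(X, y), crossprod(Z, y)))
  expect_equal(unname(r$gebv), unname(sol[-1]), tolerance = 1e-6)
})
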