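test_that("MCMC configuration is validated", {
  expect_error(mcmc_config("BayesA", n_iter = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config("BayesB", pi0 = 1.2), "pi0")
  expect_error(mcmc_config("nope"), "arg")
  cfg <- mcmc_config("BayesR")
  expect_equal(cfg$n_iter, 12000L)
  expect_equal(cfg$burn_in, 2000L)
  expect_equal(cfg$comp_var_frac, c(0, 1e-4, 1e-3, 1e-2))
})

test_that("chains are bit-identical under a fixed seed", {
  rd <- random_dosage(80, 60, seed = 71)
  set.seed(71); y <- rnorm(80)
  for (mod in c("BayesA", "BayesB", "BayesC", "BL", "BayesR")) {
    cfg <- mcmc_config(mod, n_iter = 300, burn_in = 50, seed = 5)
    p1 <- run_mcmc(rd$dosage, y, cfg)
    p2 <- run_mcmc(rd$dosage, y, cfg)
    expect_identical(p1$trace, p2$trace)
    expect_identical(p1$effect_mean, p2$effect_mean)
  }
})

test_that("null phenotypes produce strong shrinkage and near-zero signal", {
  rd <- random_dosage(300, 100, seed = 72)
  set.seed(72)
  y <- rnorm(300)
  ps <- run_mcmc(rd$dosage, y, mcmc_config("BayesA", n_iter = 1500,
                                           burn_in = 300, seed = 1))
  # effects shrink well below the phenotypic scale
  expect_lt(max(abs(ps$effect_mean)), 0.2)
  gebv <- gebv_from_effects(rd$dosage, ps)$gebv
  set.seed(73)
  fresh_noise <- rnorm(300)
  expect_lt(abs(cor(gebv, fresh_noise)), 0.15)
})

test_that("residual variance is recovered on polygenic data", {
  # posterior mean of sigma_e2 within 15% of the simulated truth
  errs <- sapply(1:3, function(s) {
    pop <- small_study(n_cohort = 400, n_markers = 300, target_h2 = 0.3,
                       seed = 700 + s)
    y <- unname(pop$y_c[pop$geno$ids])
    ps <- run_mcmc(pop$geno, y, mcmc_config("BayesA", n_iter = 1500,
                                            burn_in = 300, seed = s))
    ps$sigma_e2 / pop$truth$sigma_e2_realized - 1
  })
  expect_lt(abs(mean(errs)), 0.15)
})

test_that("spike mass concentrates near the prior when the response is permuted", {
  rd <- random_dosage(200, 120, seed = 74)
  set.seed(74)
  y <- rnorm(200)
  ps <- run_mcmc(rd$dosage, y[sample(200)],
                 mcmc_config("BayesB", n_iter = 1500, burn_in = 300,
                             pi0 = 0.9, seed = 2))
  # inclusion probabilities hover near 1 - pi0
  expect_lt(abs(mean(ps$inclusion_prob) - 0.1), 0.08)
})

test_that("BayesC with the spike removed reproduces BayesA shrinkage", {
  rd <- random_dosage(150, 100, seed = 75)
  set.seed(75)
  eff <- rnorm(100, 0, 0.05)
  y <- drop(scale(rd$dosage, scale = FALSE) %*% eff) + rnorm(150)
  pa <- run_mcmc(rd$dosage, y, mcmc_config("BayesA", n_iter = 1500,
                                           burn_in = 300, seed = 3))
  pc <- run_mcmc(rd$dosage, y, mcmc_config("BayesC", n_iter = 1500,
                                           burn_in = 300, seed = 3, pi0 = 0,
                                           update_pi = FALSE))
  # with the spike mass held at zero every marker stays in the model and
  # the shrinkage profile matches BayesA's
  ga <- gebv_from_effects(rd$dosage, pa)$gebv
  gc_ <- gebv_from_effects(rd$dosage, pc)$gebv
  expect_gt(cor(ga, gc_), 0.95)
})

test_that("BayesR occupies its mixture components coherently", {
  rd <- random_dosage(200, 150, seed = 76)
  set.seed(76)
  y <- rnorm(200)
  ps <- run_mcmc(rd$dosage, y, mcmc_config("BayesR", n_iter = 1000,
                                           burn_in = 200, seed = 4))
  expect_length(ps$comp_occupancy, 4)
  expect_equal(sum(ps$comp_occupancy), 150, tolerance = 1e-6)
})

test_that("GEBV accumulation matches a brute-force dot product", {
  rd <- random_dosage(30, 20, seed = 77)
  set.seed(77)
  eff <- rnorm(20)
  summ <- list(effect_mean = eff, centers = NULL, mu = 0, model = "manual")
  pr <- gebv_from_effects(rd$dosage, summ)
  brute <- sapply(seq_len(30), function(i) sum(rd$dosage[i, ] * eff))
  expect_equal(unname(pr$gebv), brute, tolerance = 1e-12)

  # all-zero effects give all-zero GEBV; a unit effect copies the dosage
  expect_true(all(gebv_from_effects(rd$dosage,
                                    list(effect_mean = rep(0, 20)))$gebv == 0))
  one <- c(1, rep(0, 19))
  expect_equal(unname(gebv_from_effects(rd$dosage,
                                        list(effect_mean = one))$gebv),
               unname(rd$dosage[, 1]))
  expect_error(gebv_from_effects(rd$dosage, list(effect_mean = rep(0, 5))),
               "marker mismatch")
})

test_that("degenerate MCMC inputs fail fast", {
  rd <- random_dosage(20, 10, seed = 78)
  expect_error(run_mcmc(rd$dosage, rep(1, 20), mcmc_config("BayesA")),
               "variance is zero")
  dm <- rd$dosage; dm[1, 1] <- NA
  expect_error(run_mcmc(dm, rnorm(20), mcmc_config("BayesA")), "missing")
})
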