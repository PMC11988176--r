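test_that("pedigree simulation produces the requested structure", {
  cfg <- sim_config(n_founders = 10, n_generations = 0, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 10)
  expect_true(all(ped$sire == 0 & ped$dam == 0))

  cfg <- sim_config(n_founders = 4, n_generations = 1,
                    offspring_per_mating = 2, seed = 2)
  ped <- simulate_pedigree(cfg)
  off <- ped[ped$gen == 1, ]
  expect_true(all(off$sire %in% 1:4) && all(off$dam %in% 1:4))
  expect_true(all(off$sire != off$dam))

  expect_error(sim_config(n_founders = 1), "2 founders")
})

test_that("simulation is bit-identical under the same configuration", {
  cfg <- sim_config(n_founders = 12, n_generations = 2, n_markers = 60,
                    n_chromosomes = 3, seed = 99)
  p1 <- simulate_pedigree(cfg); p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(p1, cfg); g2 <- simulate_genotypes(p2, cfg)
  expect_identical(g1$dosage, g2$dosage)
  s1 <- simulate_effects_and_phenotypes(g1, cfg)
  s2 <- simulate_effects_and_phenotypes(g2, cfg)
  expect_identical(s1$pheno$y, s2$pheno$y)
})

test_that("zero map length copies parental chromosomes unrecombined", {
  # with 2 founders and no recombination, a full-sib family can only show
  # the 4 gamete combinations per chromosome: at most 4 distinct dosage rows
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    offspring_per_mating = 40, n_markers = 60,
                    n_chromosomes = 1, morgans_per_chromosome = 0, seed = 3)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  off <- as.character(ped$id[ped$gen == 1])
  patterns <- unique(apply(geno$dosage[off, ], 1, paste, collapse = ""))
  expect_lte(length(patterns), 4)
  # with a long map the same family shows many recombinant patterns
  cfg2 <- sim_config(n_founders = 2, n_generations = 1,
                     offspring_per_mating = 40, n_markers = 60,
                     n_chromosomes = 1, morgans_per_chromosome = 5, seed = 3)
  geno2 <- simulate_genotypes(simulate_pedigree(cfg2), cfg2)
  patterns2 <- unique(apply(geno2$dosage[off, ], 1, paste, collapse = ""))
  expect_gt(length(patterns2), 4)
})

test_that("a fixed founder allele stays fixed through gene dropping", {
  cfg <- sim_config(n_founders = 8, n_generations = 2, n_markers = 30,
                    founder_maf_range = c(0, 0), n_chromosomes = 2, seed = 4)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  expect_true(all(geno$dosage == 0))
})

test_that("founder allele frequencies follow the configured law", {
  cfg <- sim_config(n_founders = 400, n_generations = 0, n_markers = 800,
                    seed = 5)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  p_drawn <- attr(geno, "founder_freq")
  ks <- suppressWarnings(stats::ks.test(p_drawn, "punif", 0.05, 0.5))
  expect_gt(ks$p.value, 0.01)
  # empirical founder frequencies track the drawn frequencies
  expect_gt(cor(allele_freq(geno), p_drawn), 0.98)
})

test_that("descendant allele frequencies are conserved in expectation", {
  # average over many gene-dropping replicates of a small pedigree
  freqs <- replicate(50, {
    cfg <- sim_config(n_founders = 20, n_generations = 2, n_markers = 50,
                      n_chromosomes = 2, seed = sample.int(1e6, 1))
    ped <- simulate_pedigree(cfg)
    geno <- simulate_genotypes(ped, cfg)
    last <- as.character(ped$id[ped$gen == 2])
    colMeans(geno$dosage[last, , drop = FALSE]) / 2 - attr(geno, "founder_freq")
  })
  expect_lt(abs(mean(freqs)), 0.01)
})

test_that("phenotype simulation hits the target heritability exactly in-sample", {
  pop <- simulate_population(n_cohort = 300, n_markers = 300,
                             target_h2 = 0.45, seed = 6)
  expect_equal(pop$truth$realized_h2, 0.45, tolerance = 1e-12)
  expect_equal(unname(drop(pop$geno_cohort$dosage %*% pop$truth$effects)),
               unname(pop$truth$g_true), tolerance = 1e-10)

  # heritability targeting across replicates
  h2s <- sapply(1:5, function(s) {
    simulate_population(n_cohort = 200, n_markers = 200, target_h2 = 0.3,
                        seed = 100 + s)$truth$realized_h2
  })
  expect_lt(max(abs(h2s - 0.3)), 0.02)
})

test_that("phenotype = mean + fixed + genetic + residual decomposition holds", {
  cfg <- sim_config(n_founders = 40, n_generations = 1, n_markers = 200,
                    fixed_effect_spec = list(), target_h2 = 0.5, seed = 7)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  sim <- simulate_effects_and_phenotypes(geno, cfg)
  resid <- sim$pheno$y - cfg$mu - sim$truth$g_true
  expect_equal(var(resid), sim$truth$sigma_e2_realized, tolerance = 1e-10)
  expect_equal(var(resid) / (var(resid) + var(sim$truth$g_true)) ,
               1 - 0.5, tolerance = 0.05)
})

test_that("degenerate phenotype configurations are rejected", {
  expect_error(sim_config(target_h2 = 0), "target_h2")
  expect_error(sim_config(target_h2 = 1), "target_h2")
  cfg <- sim_config(n_founders = 6, n_generations = 0, n_markers = 10,
                    founder_maf_range = c(0, 0), seed = 8)
  ped <- simulate_pedigree(cfg)
  geno <- simulate_genotypes(ped, cfg)
  expect_error(simulate_effects_and_phenotypes(geno, cfg),
               "zero realized genetic variance")
})

test_that("missingness injection hits the requested rate", {
  pop <- simulate_population(n_cohort = 100, n_markers = 200, seed = 9)
  gm <- inject_missingness(pop$geno, rate = 0.1, seed = 2)
  expect_equal(mean(is.na(gm$dosage)), 0.1, tolerance = 0.02)
  expect_identical(inject_missingness(pop$geno, 0.1, seed = 2)$dosage, gm$dosage)
})
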