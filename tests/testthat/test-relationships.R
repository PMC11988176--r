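test_that("G reproduces the hand-evaluated VanRaden example", {
  # 3 individuals x 2 markers, p = (0.5, 0.5): denominator 1,
  # G = [[2,0,-2],[0,0,0],[-2,0,2]]
  d <- rbind(i1 = c(0, 2), i2 = c(1, 1), i3 = c(2, 0))
  G <- compute_G(d)
  expect_equal(unname(G), rbind(c(2, 0, -2), c(0, 0, 0), c(-2, 0, 2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(G, "denom"), 1)
})

test_that("G degenerates correctly for fully heterozygous and duplicated data", {
  d <- matrix(1, 4, 6, dimnames = list(paste0("i", 1:4), NULL))
  d[1, 1] <- 0; d[2, 1] <- 2 # keep one marker polymorphic, p = 0.5
  G <- compute_G(d)
  # all-het markers are centered to zero; only marker 1 contributes
  expect_equal(G["i3", "i3"], 0)
  expect_equal(G["i1", "i1"], G["i2", "i2"])

  rd <- random_dosage(5, 50, seed = 31)
  dd <- rbind(rd$dosage, dup = rd$dosage[1, ])
  G2 <- compute_G(dd)
  expect_equal(G2["dup", "i1"], G2["i1", "i1"], tolerance = 1e-12)
  expect_equal(G2["dup", "dup"], G2["i1", "i1"], tolerance = 1e-12)

  expect_error(compute_G(matrix(2, 3, 4)), "monomorphic")
})

test_that("G is invariant to marker order and has unit mean diagonal at scale", {
  rd <- random_dosage(40, 300, seed = 32)
  G1 <- compute_G(rd$dosage)
  perm <- sample(ncol(rd$dosage))
  G2 <- compute_G(rd$dosage[, perm])
  expect_equal(unname(G1), unname(G2), tolerance = 1e-12, ignore_attr = TRUE)

  pop <- simulate_population(n_cohort = 150, n_markers = 5000, seed = 33)
  G <- compute_G(pop$geno)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("A follows the tabular method on hand-checked pedigrees", {
  ped0 <- pedigree(1:4, rep(0, 4), rep(0, 4))
  expect_equal(unname(compute_A(ped0)), diag(4), ignore_attr = TRUE)

  trio <- trio_pedigree()
  A <- compute_A(trio)
  expect_equal(A["3", "1"], 0.5)
  expect_equal(A["3", "3"], 1)

  # full sibs from unrelated parents relate 0.5; an offspring of half sibs
  # is inbred with diagonal 1.125
  ped <- pedigree(id = 1:7,
                  sire = c(0, 0, 0, 1, 1, 0, 4),
                  dam = c(0, 0, 0, 2, 2, 3, 5))
  A2 <- compute_A(ped)
  expect_equal(A2["4", "5"], 0.5)
  ped_hs <- pedigree(id = 1:6,
                     sire = c(0, 0, 0, 1, 1, 4),
                     dam = c(0, 0, 0, 2, 3, 5))
  A3 <- compute_A(ped_hs)
  expect_equal(A3["4", "5"], 0.25) # half sibs
  expect_equal(A3["6", "6"], 1.125)
})

test_that("sparse A-inverse matches the dense inverse", {
  trio <- trio_pedigree()
  expect_equal(as.matrix(compute_A_inverse(trio)),
               solve(compute_A(trio)), tolerance = 1e-10,
               ignore_attr = TRUE)

  pop <- simulate_population(n_cohort = 30, n_markers = 50,
                             n_generations = 2, seed = 34)
  ped <- pop$ped
  A <- compute_A(ped)
  Ainv <- compute_A_inverse(ped, A = A)
  expect_lt(max(abs(as.matrix(Ainv %*% A) - diag(nrow(A)))), 1e-8)
})

test_that("A is equivariant under id relabeling", {
  ped <- pedigree(id = 1:5, sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4))
  A <- compute_A(ped)
  ped2 <- pedigree(id = c(2, 4, 6, 8, 10), sire = c(0, 0, 2, 2, 6),
                   dam = c(0, 0, 4, 4, 8))
  A2 <- compute_A(ped2)
  expect_equal(unname(A), unname(A2), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("H-inverse degenerates to G-inverse and A-inverse at the extremes", {
  pop <- simulate_population(n_cohort = 25, n_markers = 80,
                             n_generations = 2, seed = 35)
  ped <- pop$ped
  A <- compute_A(ped)
  # all individuals genotyped with G = A: the correction terms cancel
  G <- A
  hh <- compute_H_inverse(ped, G, epsilon = 0)
  expect_equal(hh$H_inv, solve(A), tolerance = 1e-6, ignore_attr = TRUE)

  # no genotyped block: H-inverse is exactly A-inverse
  Ainv <- compute_A_inverse(ped, A = A)
  H0 <- assemble_H_inverse(Ainv, matrix(0, 0, 0), matrix(0, 0, 0), integer(0))
  expect_equal(H0, as.matrix(Ainv), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("H-inverse matches brute-force dense block arithmetic", {
  pop <- simulate_population(n_cohort = 20, n_markers = 200,
                             n_generations = 2,
                             genotyped_fraction_last_gen = 0.6, seed = 36)
  ped <- pop$ped
  G <- compute_G(pop$geno)
  hh <- compute_H_inverse(ped, G, epsilon = 0.05)
  # independent assembly from full dense matrices
  A <- compute_A(ped)
  idx <- match(rownames(G), as.character(ped$id))
  A22 <- A[idx, idx]
  Gb <- 0.95 * G + 0.05 * A22
  H_brute <- solve(A)
  H_brute[idx, idx] <- H_brute[idx, idx] + solve(Gb) - solve(A22)
  expect_equal(unname(hh$H_inv), unname(H_brute), tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(unname(hh$H_inv), unname(t(hh$H_inv)), tolerance = 1e-10, ignore_attr = TRUE)
  # blended G is strictly positive definite
  expect_gt(min(eigen(hh$G_blend, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("singular G without blending is reported with advice", {
  rd <- random_dosage(10, 100, seed = 37)
  pop_ids <- rownames(rd$dosage)
  ped <- pedigree(1:10, rep(0, 10), rep(0, 10))
  G <- compute_G(rd$dosage) # observed-frequency G is singular
  rownames(G) <- colnames(G) <- as.character(1:10)
  expect_error(compute_H_inverse(ped, G, epsilon = 0), "blending")
})
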