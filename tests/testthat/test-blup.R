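test_that("predicted nhc nearly interpolates observations when all are genotyped", {
  fx <- fixturePopulation()
  pop <- applyGenotypingScenario(fx$pop, "all_animals")
  ainv <- buildAInverse(pop@pedigree)
  hd <- defineHaplotypes(pop, "HAP2")
  counts <- countNhc(pop, hd)
  nhc <- predictNhc(ainv, nhcMatrix(counts, pop@genotyped))
  for (j in seq_along(hd@classes)) {
    if (sd(counts[, j]) == 0) next
    expect_gt(cor(nhcPredicted(nhc)[, j], counts[, j]), 0.99)
  }
})

test_that("predictions sum to two copies per animal for every method", {
  fx <- fixturePopulation()
  pop <- fx$pop
  ainv <- buildAInverse(pop@pedigree)
  for (method in c("NM", "HAP2", "HAP4")) {
    hd <- defineHaplotypes(pop, method)
    nhc <- predictNhc(ainv, nhcMatrix(countNhc(pop, hd), pop@genotyped))
    expect_lt(max(abs(rowSums(nhcPredicted(nhc)) - 2)), 1e-6)
  }
})

test_that("Cholesky and PCG routes of predictNhc agree", {
  fx <- fixturePopulation()
  pop <- fx$pop
  ainv <- buildAInverse(pop@pedigree)
  hd <- defineHaplotypes(pop, "NM")
  m <- nhcMatrix(countNhc(pop, hd), pop@genotyped)
  a <- predictNhc(ainv, m, solver = "cholesky")
  b <- predictNhc(ainv, m, solver = "pcg", tol = 1e-12)
  expect_lt(max(abs(nhcPredicted(a) - nhcPredicted(b))), 1e-6)
})

test_that("haplotype-effect variances follow the derivation's limits", {
  expect_equal(haplotypeEffectVariance("NM", 0.045, 0.3), 0.09)     # alpha^2
  expect_equal(haplotypeEffectVariance("GABLUP", 0.045, 0.3), 0.09)
  expect_equal(haplotypeEffectVariance("HAP2", 0.045, 0.3), 0.0225) # qtl/2
  expect_equal(haplotypeEffectVariance("HAP4", 0.04, 0.3), 0.02)
  # NM at p = q = 0.5: alpha^2 = 2 * nominal QTL variance
  expect_equal(haplotypeEffectVariance("NM", NA, sqrt(0.045 / 0.5)),
               2 * 0.045)
  # general frequency-dependent rule: n equal classes -> qtl/2 as n grows
  v <- vapply(c(2, 4, 10, 10000), function(n)
    haplotypeVarianceFromFrequencies(rep(1 / n, n), 0.045), 0)
  expect_equal(v[1], 0.045)                       # n = 2: sigma2_qtl
  expect_true(all(diff(v) < 0))                   # decreasing in n
  expect_equal(v[4], 0.045 / 2, tolerance = 1e-3) # A4 limit
  expect_error(haplotypeVarianceFromFrequencies(c(1, 0), 1), "monomorphic")
  expect_error(haplotypeEffectVariance("HAP8", 1, 1), "unknown")
})

test_that("GABLUP gives perfectly accurate QTL-EBV and equals its MABLUP form", {
  fx <- fixturePopulation()
  pop <- fx$pop
  ainv <- buildAInverse(pop@pedigree)
  q <- pop@map@qtlIndex
  g <- pop@pat[, q] + pop@mat[, q]
  gab <- runGablup(pop@phenotype, ainv, g, pop@meta$alpha,
                   pop@meta$sigma2Pol, pop@meta$sigma2E)
  expect_gt(haplotypeEffects(gab)[["geneContent"]], 0)
  expect_equal(accuracy(qtlEBV(gab), pop@aQtl), 1, tolerance = 1e-9)
  mab <- runMablup(pop@phenotype, ainv, matrix(g, ncol = 1),
                   pop@meta$sigma2Pol, pop@meta$sigma2E, pop@meta$alpha^2)
  expect_equal(qtlEBV(gab), qtlEBV(mab), tolerance = 1e-8)
  expect_equal(totalEBV(gab), qtlEBV(gab) + polygenicEBV(gab))
})

test_that("MABLUP collapses to CONBLUP when haplotype effects are shrunk away", {
  fx <- fixturePopulation()
  pop <- fx$pop
  ainv <- buildAInverse(pop@pedigree)
  s2add <- pop@meta$sigma2Pol
  con <- runConblup(pop@phenotype, ainv, s2add, pop@meta$sigma2E)
  W <- matrix(pop@pat[, 1] + pop@mat[, 1], ncol = 1)
  mab <- runMablup(pop@phenotype, ainv, W, s2add, pop@meta$sigma2E,
                   sigma2H = 1e-12)
  expect_lt(max(abs(totalEBV(mab) - totalEBV(con))), 1e-5)
  expect_equal(qtlEBV(con), rep(0, nAnimals(pop)))
})

test_that("CONBLUP on a founder shrinks the phenotype deviation", {
  ped <- Pedigree(1:2, c(0L, 0L), c(0L, 0L), c("male", "female"))
  lam <- 7 / 3                                    # h2 = 0.3
  con <- runConblup(c(0.5, -0.5), buildAInverse(ped), 0.3, 0.7)
  expect_equal(totalEBV(con), c(0.5, -0.5) / (1 + lam), tolerance = 1e-8)
})

test_that("EBV exports carry the identity total = qtl + polygenic", {
  fx <- fixturePopulation()
  pop <- fx$pop
  ainv <- buildAInverse(pop@pedigree)
  con <- runConblup(pop@phenotype, ainv,
                    pop@meta$sigma2Pol + pop@meta$sigma2QtlRealized,
                    pop@meta$sigma2E)
  tf <- tempfile(fileext = ".csv")
  writeEBV(con, tf)
  x <- read.csv(tf)
  expect_equal(x$total_ebv, x$u_pol_hat + x$qtl_ebv)
  unlink(tf)
})
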