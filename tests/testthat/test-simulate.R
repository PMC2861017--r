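test_that("Haldane mapping function behaves over its whole range", {
  expect_equal(haldaneRecFrac(0), 0)
  expect_equal(haldaneRecFrac(0.001), 0.5 * (1 - exp(-0.002)))
  expect_equal(haldaneRecFrac(1e6), 0.5)         # asymptote
  expect_true(all(diff(haldaneRecFrac(seq(0, 2, by = 0.01))) > 0))
  expect_error(haldaneRecFrac(-0.1), "non-negative")
})

test_that("genome map places the QTL mid-bracket with strictly increasing loci", {
  map <- genomeMap(0.001)
  pos <- map@positions
  expect_length(pos, 21)
  expect_equal(map@qtlIndex, 11L)
  expect_equal(pos[11], 0.5)
  expect_equal(pos[12] - pos[11], pos[11] - pos[10])   # mid-bracket
  expect_equal(diff(pos[map@markerCols])[1], 0.001, tolerance = 1e-12)
})

test_that("meiosis without recombination returns a parental gamete intact", {
  set.seed(1)
  pat <- matrix(0L, 4, 21); mat <- matrix(1L, 4, 21)
  out <- hapblup:::transmitGametes(pat, mat, 1:4, rep(0, 20))
  expect_true(all(rowSums(out) %in% c(0L, 21L)))   # whole gamete, no mosaic
  # and both parental gametes are transmitted at rate ~ 1/2
  out2 <- hapblup:::transmitGametes(pat, mat, rep(1L, 2000), rep(0, 20))
  expect_gt(mean(rowSums(out2) == 0L), 0.4)
  expect_lt(mean(rowSums(out2) == 0L), 0.6)
})

test_that("empirical recombination fractions match Haldane's closed form", {
  set.seed(2)
  map <- genomeMap(0.05)      # 5 cM spacing: loci span 0.95 M
  rf <- haldaneRecFrac(diff(map@positions))
  n <- 40000
  pat <- matrix(0L, 1, 21); mat <- matrix(1L, 1, 21)
  g <- hapblup:::transmitGametes(pat, mat, rep(1L, n), rf)
  # adjacent marker interval (one 0.05 M step)
  cObs <- mean(g[, 1] != g[, 2])
  cExp <- haldaneRecFrac(0.05)
  expect_lt(abs(cObs - cExp), 3 * sqrt(cExp * (1 - cExp) / n))
  # opposite ends of the map (0.95 M)
  cObs2 <- mean(g[, 1] != g[, 21])
  cExp2 <- haldaneRecFrac(0.95)
  expect_lt(abs(cObs2 - cExp2), 3 * sqrt(cExp2 * (1 - cExp2) / n))
  # single-meiosis wrapper transmits only parental alleles
  gam <- meiosis(rep(0L, 21), rep(1L, 21), map)
  expect_true(all(gam %in% 0:1))
})

test_that("polygenic sampling has the stated mean and Mendelian variance", {
  set.seed(3)
  # full parental inbreeding removes all Mendelian sampling variance
  expect_equal(samplePolygenic(1, 2, fp = 1, sigma2Pol = 0.25), 1.5)
  n <- 1e5
  x <- samplePolygenic(rep(0, n), rep(0, n), rep(0, n), sigma2Pol = 0.4)
  expect_lt(abs(var(x) - 0.2), 3 * 0.2 * sqrt(2 / (n - 1)))
  expect_lt(abs(mean(x)), 3 * sqrt(0.2 / n))
  expect_error(samplePolygenic(0, 0, fp = 1.5, sigma2Pol = 1), "negative")
})

test_that("gamete transmission never invents alleles (no mutation)", {
  set.seed(4)
  n <- 300
  pat <- matrix(rbinom(n * 21, 1L, 0.5), n, 21)
  mat <- matrix(rbinom(n * 21, 1L, 0.5), n, 21)
  pidx <- sample(n, 500, replace = TRUE)
  out <- hapblup:::transmitGametes(pat, mat, pidx,
                                   haldaneRecFrac(diff(genomeMap(0.01)@positions)))
  carried <- out == pat[pidx, ] | out == mat[pidx, ]
  expect_true(all(carried))
})

test_that("the selection phase reproduces the nested full-sib half-sib design", {
  fx <- fixturePopulation()
  pop <- fx$pop; cfg <- fx$config
  ped <- pop@pedigree
  expect_equal(nAnimals(pop), cfg$nOffspringPerGen * cfg$nGenerations)
  expect_equal(as.vector(table(ped@generation)),
               rep(cfg$nOffspringPerGen, cfg$nGenerations))
  # every used sire has nDamsPerSire full-sib groups of nProgenyPerDam
  fam <- table(ped@sire[ped@sire > 0L])
  expect_true(all(fam == cfg$nDamsPerSire * cfg$nProgenyPerDam))
  litters <- table(paste(ped@sire, ped@dam)[ped@sire > 0L])
  expect_true(all(litters == cfg$nProgenyPerDam))
  # phenotype identity and realized QTL variance bookkeeping
  expect_equal(pop@phenotype, pop@aQtl + pop@aPol + pop@e)
  p <- pop@meta$p101
  expect_equal(pop@meta$sigma2QtlRealized, 2 * p * (1 - p) * pop@meta$alpha^2)
  expect_equal(realizedQtlVariance(pop), pop@meta$sigma2QtlRealized)
})

test_that("selection increases mean true breeding value across generations", {
  fx <- fixturePopulation()
  pop <- fx$pop
  tbv <- pop@aPol + pop@aQtl
  gmeans <- tapply(tbv, pop@pedigree@generation, mean)
  expect_gt(gmeans[length(gmeans)], gmeans[1])
})

test_that("QTL segregation filter uses an inclusive 5% boundary", {
  pat <- matrix(0L, 10, 21); mat <- matrix(0L, 10, 21)
  pat[1, 11] <- 1L                     # 1/20 gametes = MAF 0.05
  expect_true(replicatePassesFilter(toyPopulation(pat, mat)))
  pat2 <- matrix(0L, 25, 21); mat2 <- matrix(0L, 25, 21)
  pat2[1, 11] <- 1L                    # 1/50 = 0.02 < 0.05
  expect_false(replicatePassesFilter(toyPopulation(pat2, mat2)))
  expect_true(replicatePassesFilter(toyPopulation(
    matrix(1L, 10, 21), matrix(0L, 10, 21))))   # p = 0.5
})

test_that("genotyping scenarios flag the documented animal sets", {
  fx <- fixturePopulation()
  pop <- fx$pop; ped <- pop@pedigree
  s1 <- applyGenotypingScenario(pop, "sires_lastgen_males")@genotyped
  s2 <- applyGenotypingScenario(pop, "all_males")@genotyped
  s3 <- applyGenotypingScenario(pop, "all_animals")@genotyped
  expect_true(all(s3))
  expect_false(any(s1[ped@sex == "female"]))       # females never genotyped
  expect_true(all(s2[s1]))                         # scenario 2 contains 1
  expect_true(all(s1[ped@animal %in% ped@sire]))   # all sires flagged
  lastM <- ped@generation == max(ped@generation) & ped@sex == "male"
  expect_true(all(s1[lastM]))
  expect_error(applyGenotypingScenario(pop, "everything"), "unknown")
})

test_that("burn-in LD is of the order expected from drift at Ne ~ 100", {
  set.seed(6)
  cfg <- simConfig()                      # default burn-in: 100 x 100
  map <- genomeMap(cfg$spacing)
  cols <- map@markerCols
  r2 <- c()
  for (r in 1:50) {
    b <- runBurnin(cfg, map)
    g <- rbind(b$pat[, cols], b$mat[, cols])
    freq <- colMeans(g)
    expect_true(all(freq >= 0 & freq <= 1))
    maf <- pmin(freq, 1 - freq)
    # evaluate LD over usable markers (MAF >= 5%, the study's marker rule);
    # rare variants depress r2 below the drift expectation
    for (j in seq_len(ncol(g) - 1L)) {
      if (maf[j] < 0.05 || maf[j + 1L] < 0.05) next
      r2 <- c(r2, ldR2Biallelic(g[, j], g[, j + 1L]))
    }
  }
  cAdj <- haldaneRecFrac(cfg$spacing)
  expected <- 1 / (1 + 4 * 100 * cAdj)    # Sved drift expectation
  expect_gt(mean(r2), 0.5 * expected)
  expect_lt(mean(r2), 1.5 * expected)
})

test_that("population export writes the documented plain-text files", {
  fx <- fixturePopulation()
  d <- tempfile()
  writePopulation(fx$pop, d)
  expect_true(all(file.exists(file.path(d,
    c("pedigree.csv", "genotypes.csv", "phenotypes.csv", "truth.csv")))))
  geno <- read.csv(file.path(d, "genotypes.csv"))
  expect_true(all(geno$allele %in% 0:1))
  expect_setequal(unique(geno$animal), which(fx$pop@genotyped))
  tr <- read.csv(file.path(d, "truth.csv"))
  ph <- read.csv(file.path(d, "phenotypes.csv"))
  expect_equal(ph$phenotype, tr$a_pol + tr$a_qtl + tr$e, tolerance = 1e-8)
  unlink(d, recursive = TRUE)
})
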