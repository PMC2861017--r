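test_that("haplotype windows are chosen by proximity and the 5% MAF rule", {
  maf <- rep(0.5, 20)
  expect_equal(selectHaplotypeMarkers("NM", maf), 10L)
  expect_equal(selectHaplotypeMarkers("HAP2", maf), c(10L, 11L))
  expect_equal(selectHaplotypeMarkers("HAP4", maf), c(9L, 10L, 11L, 12L))
  maf10 <- maf; maf10[10] <- 0                  # marker 10 fixed
  expect_equal(selectHaplotypeMarkers("NM", maf10), 9L)
  expect_equal(selectHaplotypeMarkers("HAP4", maf10), c(8L, 9L, 11L, 12L))
  expect_equal(selectHaplotypeMarkers("NM", c(rep(0.04, 9), 0.05, rep(0.5, 10))),
               10L)                             # boundary inclusive
  expect_error(selectHaplotypeMarkers("HAP4", c(rep(0, 19), 0.5)),
               "qualifying")
})

test_that("nhc counting reproduces the four-animal worked example", {
  # two-marker haplotypes 11 / 12 / 21 / 22 around the QTL
  pat <- matrix(0L, 4, 21); mat <- matrix(0L, 4, 21)
  hapcols <- c(10L, 12L)                        # markers 10 and 11
  pat[, hapcols] <- 1L                          # every paternal gamete "11"
  mat[1, hapcols] <- c(1L, 1L)
  mat[2, hapcols] <- c(1L, 0L)
  mat[3, hapcols] <- c(0L, 1L)
  mat[4, hapcols] <- c(0L, 0L)
  pop <- toyPopulation(pat, mat)
  hd <- new("HaplotypeDefinition", method = "HAP2", markers = c(10L, 11L),
            cols = hapcols, classes = c("11", "10", "01", "00"),
            frequencies = c(5, 1, 1, 1) / 8)
  counts <- countNhc(pop, hd)
  expect_equal(unname(counts),
               rbind(c(2L, 0L, 0L, 0L),
                     c(1L, 1L, 0L, 0L),
                     c(1L, 0L, 1L, 0L),
                     c(1L, 0L, 0L, 1L)))
  expect_equal(rowSums(counts), rep(2, 4))
})

test_that("observed nhc rows of genotyped animals always sum to two", {
  fx <- fixturePopulation()
  for (method in c("NM", "HAP2", "HAP4")) {
    hd <- defineHaplotypes(fx$pop, method)
    counts <- countNhc(fx$pop, hd)
    g <- fx$pop@genotyped
    expect_true(all(rowSums(counts[g, , drop = FALSE]) == 2L))
    expect_equal(sum(hd@frequencies), 1)
    # class frequencies are genotyped-gamete column sums
    expect_equal(unname(colSums(counts[g, , drop = FALSE]) / (2 * sum(g))),
                 unname(hd@frequencies))
  }
})

test_that("unseen haplotype strings of ungenotyped animals are excluded", {
  pat <- matrix(0L, 3, 21); mat <- matrix(0L, 3, 21)
  pat[3, c(10, 12)] <- 1L                      # string "11" only in animal 3
  pop <- toyPopulation(pat, mat, genotyped = c(TRUE, TRUE, FALSE))
  hd <- defineHaplotypes(pop, "HAP2", minMAF = 0)
  expect_equal(hd@classes, "00")               # enumerated from genotyped only
  counts <- countNhc(pop, hd)
  expect_equal(unname(counts[3, "00"]), 1L)    # "11" falls in the other bucket
})

test_that("biallelic r2 equals the squared Pearson correlation", {
  set.seed(10)
  a <- rbinom(500, 1, 0.3)
  b <- ifelse(rbinom(500, 1, 0.8) == 1, a, rbinom(500, 1, 0.5))
  expect_equal(ldR2Biallelic(a, b), cor(a, b)^2, tolerance = 1e-12)
  expect_equal(ldR2Biallelic(a, a), 1)
  # D = 0 by construction: counts 4/16, 12/16 margins independent
  x <- rep(c(0, 0, 1, 1), 25); y <- rep(c(0, 1, 0, 1), 25)
  expect_equal(ldR2Biallelic(x, y), 0)
  expect_true(is.na(ldR2Biallelic(rep(1, 10), rbinom(10, 1, 0.5))))
})

test_that("multi-allelic r2 equals the OLS coefficient of determination", {
  set.seed(11)
  hap <- sample(c("00", "01", "10", "11"), 1000, replace = TRUE,
                prob = c(0.4, 0.3, 0.2, 0.1))
  pTag <- c("00" = 0.9, "01" = 0.5, "10" = 0.2, "11" = 0.1)
  qtl <- rbinom(1000, 1, pTag[hap])
  r2 <- ldR2Multiallelic(hap, qtl)
  fit <- lm(qtl ~ factor(hap))
  expect_equal(r2, summary(fit)$r.squared, tolerance = 1e-10)
  # perfect tagging and independence
  expect_equal(ldR2Multiallelic(hap, ifelse(hap %in% c("00", "01"), 1, 0)), 1)
  expect_lt(ldR2Multiallelic(sample(hap), qtl), 0.05)
  expect_true(is.na(ldR2Multiallelic(hap, rep(1, 1000))))
})

test_that("refining the window never decreases the explained QTL variance", {
  fx <- fixturePopulation()
  pop <- fx$pop
  r2 <- vapply(c("NM", "HAP2", "HAP4"), function(m)
    qtlVarianceExplained(pop, defineHaplotypes(pop, m)), 0)
  # NM's marker is one of HAP2's, whose markers are a subset of HAP4's:
  # the class partitions are nested, so OLS R2 is monotone
  expect_true(r2[["HAP2"]] >= r2[["NM"]] - 1e-12)
  expect_true(r2[["HAP4"]] >= r2[["HAP2"]] - 1e-12)
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("haplotype definition and nhc exports are well-formed CSV", {
  fx <- fixturePopulation()
  hd <- defineHaplotypes(fx$pop, "HAP2")
  tf <- tempfile(fileext = ".csv")
  writeHaplotypeDefinition(hd, tf)
  x <- read.csv(tf, colClasses = c(allele_string = "character"))
  expect_equal(x$allele_string, hd@classes)
  expect_equal(sum(x$frequency), 1)
  unlink(tf)
})
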