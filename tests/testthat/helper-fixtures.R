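# Shared fixtures, all generated in code.

# Generation-structured random pedigree: founders then nGen generations of
# offspring with parents sampled from the previous generation.
randomPedigree <- function(n = 200, nFounders = 20, nGen = 5, seed = 42) {
  set.seed(seed)
  sex <- rep_len(c("male", "female"), n)
  sire <- integer(n); dam <- integer(n)
  gen <- rep(NA_integer_, n); gen[seq_len(nFounders)] <- 0L
  perGen <- ceiling((n - nFounders) / nGen)
  i <- nFounders
  for (g in seq_len(nGen)) {
    prev <- which(gen == g - 1L)
    males <- prev[sex[prev] == "male"]; females <- prev[sex[prev] == "female"]
    k <- min(perGen, n - i)
    if (k <= 0) break
    idx <- i + seq_len(k)
    sire[idx] <- males[sample.int(length(males), k, replace = TRUE)]
    dam[idx] <- females[sample.int(length(females), k, replace = TRUE)]
    gen[idx] <- g
    i <- i + k
  }
  Pedigree(seq_len(n), sire, dam, sex, gen + 1L)
}

# Reduced breeding design used for structural unit tests: 5 sires x 25 dams,
# 200 offspring per generation, 4 generations, 30 burn-in generations.
smallConfig <- function(...) {
  simConfig(nSires = 5L, nGenerations = 4L,
            burninSize = 20L, burninGenerations = 30L, ...)
}

# A small filter-passing population, cached per option set.
.fixtureCache <- new.env(parent = emptyenv())
fixturePopulation <- function(..., startSeed = 500) {
  key <- paste(deparse(list(...)), startSeed, collapse = ";")
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  cfg <- smallConfig(...)
  for (s in startSeed + 0:49) {
    pop <- simulatePopulation(cfg, seed = s)
    if (isTRUE(pop@meta$passesFilter)) {
      .fixtureCache[[key]] <- list(pop = pop, config = cfg)
      return(.fixtureCache[[key]])
    }
  }
  stop("no filter-passing fixture found")
}

# Minimal hand-built Population around given gamete matrices (truth-only
# quantities zeroed); used for worked haplotype-counting examples.
toyPopulation <- function(pat, mat, genotyped = rep(TRUE, nrow(pat)),
                          map = genomeMap(0.001, ncol(pat) - 1L)) {
  n <- nrow(pat)
  ped <- Pedigree(seq_len(n), rep(0L, n), rep(0L, n),
                  rep_len(c("male", "female"), n), rep(1L, n))
  z <- numeric(n)
  new("Population", pedigree = ped, map = map,
      pat = pat, mat = mat, aPol = z, aQtl = z, e = z, phenotype = z,
      genotyped = genotyped,
      meta = list(h2 = 0.3, alpha = 0, p101 = mean(c(pat[, map@qtlIndex],
                                                     mat[, map@qtlIndex]))))
}

# Independent GLS/BLUP oracle for the nhc prediction equations on a small
# pedigree: V = M A M' s2d + I s2e over genotyped records;
# mu = (1'V^-1 1)^-1 1'V^-1 y ; d = s2d A M' V^-1 (y - mu).
glsNhcOracle <- function(ped, nhcObs, h2 = 0.99) {
  A <- makeA(ped)
  g <- which(!is.na(nhcObs))
  y <- nhcObs[g]
  s2d <- h2; s2e <- 1 - h2
  V <- s2d * A[g, g, drop = FALSE] + s2e * diag(length(g))
  Vi <- solve(V)
  one <- rep(1, length(g))
  mu <- drop(solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% y))
  d <- drop(s2d * A[, g, drop = FALSE] %*% Vi %*% (y - mu))
  list(mu = mu, d = d, what = mu + d)
}
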