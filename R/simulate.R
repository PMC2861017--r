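#' Genome map constructor
#'
#' @param spacing inter-marker distance in Morgans (study grid: 0.001, 0.005,
#'   0.01, 0.02, 0.05 M, i.e. 0.1-5 cM).
#' @param nMarkers number of equally spaced biallelic markers (default 20).
#' @return a [GenomeMap-class]; the QTL is the extra locus at the midpoint of
#'   the central marker bracket.
#' @export
genomeMap <- function(spacing = 0.001, nMarkers = 20L) {
  stopifnot(spacing > 0, nMarkers >= 2, nMarkers %% 2 == 0)
  half <- nMarkers / 2
  markerPos <- 0.5 + (seq_len(nMarkers) - (half + 0.5)) * spacing
  positions <- append(markerPos, 0.5, after = half)
  new("GenomeMap", positions = positions, qtlIndex = as.integer(half + 1L),
      markerCols = as.integer(seq_len(nMarkers + 1L)[-(half + 1L)]),
      spacing = spacing)
}

setMethod("show", "GenomeMap", function(object) {
  cat(sprintf("GenomeMap: %d markers at %.2f cM spacing, QTL at locus %d (%.3f M)\n",
              length(object@markerCols), object@spacing * 100,
              object@qtlIndex, object@positions[object@qtlIndex]))
})

#' Haldane's mapping function
#'
#' Recombination fraction for a map distance of d Morgans under no
#' interference: c = 0.5 (1 - exp(-2d)).
#'
#' @param d map distance(s) in Morgans, d >= 0.
#' @return recombination fraction(s) in \code{[0, 0.5)}.
#' @export
haldaneRecFrac <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d))
}

#' Simulation configuration
#'
#' All design parameters of the breeding-scheme simulator, with the study's
#' defaults baked in: 50 sires and 250 dams per generation, 8 progeny per dam
#' (4 male, 4 female), 5 data generations of 2,000 animals (10,000 records),
#' 20 markers at 0.1 cM around a QTL explaining 15% of the genetic variance,
#' heritability 0.30, phenotypic variance 1 at founder allele frequency 0.5,
#' and 100 burn-in generations of 50 sires x 50 dams random mating.
#'
#' Derived quantities: \code{sigma2Qtl = q2 * h2} (nominal, at p = 0.5),
#' \code{alpha = sqrt(sigma2Qtl / 0.5)}, \code{sigma2Pol = (1 - q2) * h2},
#' \code{sigma2E = 1 - h2}.
#'
#' @param h2 trait heritability (0.03, 0.10 or 0.30 in the study).
#' @param spacing marker spacing in Morgans.
#' @param q2 proportion of genetic variance due to the QTL at p = 0.5.
#' @param nSires,nDamsPerSire,nProgenyPerDam,nGenerations breeding design.
#' @param nMarkers markers on the map.
#' @param scenario genotyping scenario: \code{"sires_lastgen_males"} (1),
#'   \code{"all_males"} (2) or \code{"all_animals"} (3).
#' @param selection select parents on conventional BLUP EBV (\code{TRUE}, the
#'   study design) or at random (\code{FALSE}, used for bias checks).
#' @param burninSize sires (= dams) per burn-in generation.
#' @param burninGenerations,burninOffspring burn-in length and census.
#' @param h2Nhc heritability assumed for the number of haplotype copies.
#' @param solver \code{"pcg"} or \code{"cholesky"} for trait mixed models.
#' @param tol solver convergence tolerance (relative residual norm).
#' @param wComposition covariates for genotyped animals in MABLUP: their
#'   \code{"observed"} nhc (default) or the mixed-model \code{"predicted"} values.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(h2 = 0.30, spacing = 0.001, q2 = 0.15,
                      nSires = 50L, nDamsPerSire = 5L, nProgenyPerDam = 8L,
                      nGenerations = 5L, nMarkers = 20L,
                      scenario = c("sires_lastgen_males", "all_males", "all_animals"),
                      selection = TRUE,
                      burninSize = 50L, burninGenerations = 100L,
                      burninOffspring = 2L * burninSize,
                      h2Nhc = 0.99, solver = c("pcg", "cholesky"),
                      tol = 1e-10, wComposition = c("observed", "predicted")) {
  scenario <- if (is.numeric(scenario))
    c("sires_lastgen_males", "all_males", "all_animals")[scenario]
  else match.arg(scenario)
  if (is.na(scenario)) stop("unknown genotyping scenario")
  stopifnot(h2 > 0, h2 < 1, q2 > 0, q2 < 1, h2Nhc > 0, h2Nhc < 1,
            nProgenyPerDam %% 2 == 0)
  sigma2Qtl <- q2 * h2
  cfg <- list(
    h2 = h2, spacing = spacing, q2 = q2,
    nSires = as.integer(nSires), nDams = as.integer(nSires * nDamsPerSire),
    nDamsPerSire = as.integer(nDamsPerSire),
    nProgenyPerDam = as.integer(nProgenyPerDam),
    nGenerations = as.integer(nGenerations), nMarkers = as.integer(nMarkers),
    nOffspringPerGen = as.integer(nSires * nDamsPerSire * nProgenyPerDam),
    scenario = scenario, selection = isTRUE(selection),
    burninSize = as.integer(burninSize),
    burninGenerations = as.integer(burninGenerations),
    burninOffspring = as.integer(burninOffspring),
    h2Nhc = h2Nhc, solver = match.arg(solver), tol = tol,
    wComposition = match.arg(wComposition),
    sigma2Qtl = sigma2Qtl, alpha = sqrt(sigma2Qtl / 0.5),
    sigma2Pol = (1 - q2) * h2, sigma2E = 1 - h2)
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "SimConfig: h2=%.2f, q2=%.2f, %d markers @ %.2f cM, %d sires x %d dams,\n",
    "  %d generations of %d offspring, burn-in %d x %d, scenario '%s'%s\n"),
    x$h2, x$q2, x$nMarkers, x$spacing * 100, x$nSires, x$nDams,
    x$nGenerations, x$nOffspringPerGen, x$burninGenerations,
    x$burninOffspring, x$scenario,
    if (x$selection) "" else ", selection off"))
  invisible(x)
}

## Vectorised gamete transmission: one recombinant gamete per offspring,
## crossovers as independent Bernoulli events per marker interval (Haldane,
## no interference), starting strand chosen at random.
transmitGametes <- function(pat, mat, pidx, recFrac) {
  n <- length(pidx); L <- ncol(pat)
  start <- sample.int(2L, n, replace = TRUE) - 1L
  if (L > 1L) {
    ev <- matrix(rbinom(n * (L - 1L), 1L, rep(recFrac, each = n)), n, L - 1L)
    cs <- cbind(start, ev)
    strand <- t(apply(cs, 1L, cumsum)) %% 2L
  } else strand <- matrix(start, n, 1L)
  P <- pat[pidx, , drop = FALSE]; M <- mat[pidx, , drop = FALSE]
  out <- P
  swap <- strand == 1L
  out[swap] <- M[swap]
  out
}

#' Simulate one meiosis
#'
#' Returns one recombinant gamete from a parent's gamete pair.  Per-interval
#' recombination events are independent Bernoulli draws with probability given
#' by [haldaneRecFrac()] of the interval length, and the starting strand is
#' chosen with probability 1/2.
#'
#' @param gamete1,gamete2 integer 0/1 allele vectors (the parent's gametes).
#' @param map a [GenomeMap-class].
#' @return integer allele vector of the transmitted gamete.
#' @export
meiosis <- function(gamete1, gamete2, map) {
  recFrac <- haldaneRecFrac(diff(map@positions))
  drop(transmitGametes(matrix(gamete1, 1L), matrix(gamete2, 1L), 1L, recFrac))
}

#' Random-mating burn-in to build up linkage disequilibrium
#'
#' Founders carry independent alleles at frequency exactly 0.5 at every locus
#' (linkage equilibrium); thereafter \code{burninGenerations} generations of
#' random mating among \code{burninSize} sires and \code{burninSize} dams
#' generate drift LD.  Loci may fix.
#'
#' @param config a [simConfig()] list.
#' @param map a [GenomeMap-class] (defaults to the config's map).
#' @return list with gamete matrices \code{pat}, \code{mat} and \code{sex}
#'   for the final burn-in generation (the parents of the base generation).
#' @export
runBurnin <- function(config, map = genomeMap(config$spacing, config$nMarkers)) {
  L <- length(map@positions)
  recFrac <- haldaneRecFrac(diff(map@positions))
  n <- config$burninOffspring
  nm <- ceiling(n / 2); nf <- n - nm
  sex <- rep(c("male", "female"), c(nm, nf))
  pat <- matrix(rbinom(n * L, 1L, 0.5), n, L)
  mat <- matrix(rbinom(n * L, 1L, 0.5), n, L)
  males <- which(sex == "male"); females <- which(sex == "female")
  for (g in seq_len(config$burninGenerations)) {
    sires <- sample(males, n, replace = TRUE)
    dams <- sample(females, n, replace = TRUE)
    newPat <- transmitGametes(pat, mat, sires, recFrac)
    newMat <- transmitGametes(pat, mat, dams, recFrac)
    pat <- newPat; mat <- newMat
  }
  list(pat = pat, mat = mat, sex = sex)
}

#' Sample offspring polygenic breeding values
#'
#' Draws from N(0.5 (A_pol,sire + A_pol,dam), 0.5 sigma2_pol (1 - f_p)): the
#' mid-parent mean plus Mendelian sampling deviation shrunk by the mean
#' parental inbreeding f_p.
#'
#' @param aPolSire,aPolDam parental polygenic values (vectors).
#' @param fp mean parental inbreeding per mating, in \code{[0, 1]}.
#' @param sigma2Pol polygenic variance.
#' @export
samplePolygenic <- function(aPolSire, aPolDam, fp, sigma2Pol) {
  v <- 0.5 * sigma2Pol * (1 - fp)
  if (any(v < -1e-12)) stop("negative Mendelian sampling variance")
  0.5 * (aPolSire + aPolDam) + rnorm(length(fp), 0, sqrt(pmax(v, 0)))
}

#' Realized QTL variance at the base generation
#'
#' 2 p (1 - p) alpha^2 with p the generation-101 (base) QTL allele frequency;
#' re-estimated because drift during burn-in moves p away from 0.5.
#'
#' @param pop a [Population-class] (only base-generation rows are used).
#' @param alpha allele substitution effect (defaults to the simulated one).
#' @export
realizedQtlVariance <- function(pop, alpha = pop@meta$alpha) {
  base <- pop@pedigree@generation == min(pop@pedigree@generation)
  q <- pop@map@qtlIndex
  p <- mean(c(pop@pat[base, q], pop@mat[base, q]))
  2 * p * (1 - p) * alpha^2
}

#' Does a replicate pass the QTL segregation filter?
#'
#' TRUE iff the minor allele frequency of the QTL in the last simulated
#' generation is at least 0.05 (replicates below the threshold are discarded;
#' exactly 0.05 passes).
#'
#' @param pop a [Population-class].
#' @export
replicatePassesFilter <- function(pop) {
  gen <- pop@pedigree@generation
  last <- gen == max(gen)
  q <- pop@map@qtlIndex
  p <- mean(c(pop@pat[last, q], pop@mat[last, q]))
  min(p, 1 - p) >= 0.05 - 1e-12
}

#' Flag genotyped animals under a genotyping scenario
#'
#' Scenario 1 (\code{"sires_lastgen_males"}): every animal ever used as a sire
#' plus all last-generation males.  Scenario 2 (\code{"all_males"}): all
#' males.  Scenario 3 (\code{"all_animals"}): everyone.  Females are never
#' genotyped under scenarios 1-2.
#'
#' @param pop a [Population-class].
#' @param scenario scenario label or index 1-3.
#' @return the population with its \code{genotyped} slot set.
#' @export
applyGenotypingScenario <- function(pop, scenario = pop@meta$scenario) {
  if (is.numeric(scenario))
    scenario <- c("sires_lastgen_males", "all_males", "all_animals")[scenario]
  ped <- pop@pedigree
  lastGen <- ped@generation == max(ped@generation)
  flags <- switch(scenario,
    sires_lastgen_males =
      (ped@animal %in% unique(ped@sire[ped@sire > 0L])) |
      (lastGen & ped@sex == "male"),
    all_males = ped@sex == "male",
    all_animals = rep(TRUE, nAnimals(ped)),
    stop("unknown genotyping scenario: ", scenario))
  pop@genotyped <- flags
  pop@meta$scenario <- scenario
  pop
}

## QTL allele frequency among the animals with indices idx
.qtlFreq <- function(pat, mat, qcol, idx)
  mean(c(pat[idx, qcol], mat[idx, qcol]))

#' Selection phase: base generation plus BLUP-selected generations
#'
#' Expands the final burn-in generation into a base generation of
#' \code{nOffspringPerGen} animals by random mating (litters expanded; the
#' base animals have unknown parents in the pedigree and polygenic values
#' drawn N(0, sigma2_pol)), then runs \code{nGenerations - 1} rounds in which
#' the top \code{nSires} males and top \code{nDams} females of the previous
#' generation, ranked on conventional BLUP EBV from all phenotypes recorded
#' so far, are mated (each sire to \code{nDamsPerSire} random dams, each dam
#' giving \code{nProgenyPerDam} offspring, half of each sex).  A_qtl is the
#' positive-allele count centred at the base-generation frequency times
#' alpha; phenotype = A_qtl + A_pol + e exactly.
#'
#' Stops early (returning the generations built so far, flagged as failing
#' the filter) if the QTL fixes, since a fixed locus cannot re-segregate.
#'
#' @param burnin result of [runBurnin()].
#' @param config a [simConfig()] list.
#' @param map a [GenomeMap-class].
#' @return a [Population-class]; \code{meta$passesFilter} records the
#'   last-generation QTL MAF filter outcome.
#' @export
runSelectionPhase <- function(burnin, config,
                              map = genomeMap(config$spacing, config$nMarkers)) {
  recFrac <- haldaneRecFrac(diff(map@positions))
  qcol <- map@qtlIndex
  nOff <- config$nOffspringPerGen
  nTot <- nOff * config$nGenerations
  alpha <- config$alpha
  gen0 <- 101L                                  # base-generation label

  pat <- matrix(0L, nTot, length(map@positions)); mat <- pat
  sire <- integer(nTot); dam <- integer(nTot)
  sex <- character(nTot); gen <- integer(nTot)
  aPol <- numeric(nTot); e <- numeric(nTot); phen <- numeric(nTot)

  ## base generation: random mating of burn-in parents, expanded litters
  bMales <- which(burnin$sex == "male"); bFem <- which(burnin$sex == "female")
  idx <- seq_len(nOff)
  pat[idx, ] <- transmitGametes(burnin$pat, burnin$mat,
                                sample(bMales, nOff, replace = TRUE), recFrac)
  mat[idx, ] <- transmitGametes(burnin$pat, burnin$mat,
                                sample(bFem, nOff, replace = TRUE), recFrac)
  sex[idx] <- rep_len(c("male", "female"), nOff)
  gen[idx] <- gen0
  aPol[idx] <- rnorm(nOff, 0, sqrt(config$sigma2Pol))
  e[idx] <- rnorm(nOff, 0, sqrt(config$sigma2E))

  p101 <- .qtlFreq(pat, mat, qcol, idx)
  phen[idx] <- (pat[idx, qcol] + mat[idx, qcol] - 2 * p101) * alpha +
               aPol[idx] + e[idx]
  sigma2QtlRealized <- 2 * p101 * (1 - p101) * alpha^2
  lambdaSel <- config$sigma2E / (config$sigma2Pol + sigma2QtlRealized)
  totalIter <- 0L
  n <- nOff
  fixed <- p101 %in% c(0, 1)

  if (!fixed) for (g in seq_len(config$nGenerations - 1L)) {
    cur <- seq_len(n)
    ped <- Pedigree(cur, sire[cur], dam[cur], sex[cur], gen[cur])
    f <- computeInbreeding(ped)
    candidates <- which(gen[cur] == gen0 + g - 1L)
    if (config$selection) {
      ainv <- buildAInverse(ped, f)
      fit <- .solveTraitModel(phen[cur], ainv, NULL, lambdaSel, NA,
                              solver = config$solver, tol = config$tol)
      ebv <- fit$u
      totalIter <- totalIter + fit$report@iterations
    } else {
      ebv <- rnorm(n)                 # random ranking = random parent choice
    }
    males <- candidates[sex[candidates] == "male"]
    females <- candidates[sex[candidates] == "female"]
    if (length(males) < config$nSires || length(females) < config$nDams)
      stop("fewer selection candidates than parents required")
    topS <- males[order(ebv[males], decreasing = TRUE)][seq_len(config$nSires)]
    topD <- females[order(ebv[females], decreasing = TRUE)][seq_len(config$nDams)]
    damOrder <- sample(topD)                       # random sire-dam pairing
    sireForDam <- rep(topS, each = config$nDamsPerSire)
    sv <- rep(sireForDam, each = config$nProgenyPerDam)
    dv <- rep(damOrder, each = config$nProgenyPerDam)
    new <- n + seq_len(nOff)
    sire[new] <- sv; dam[new] <- dv
    sex[new] <- rep(rep(c("male", "female"), each = config$nProgenyPerDam / 2L),
                    times = config$nDams)
    gen[new] <- gen0 + g
    fp <- 0.5 * (f[sv] + f[dv])
    aPol[new] <- samplePolygenic(aPol[sv], aPol[dv], fp, config$sigma2Pol)
    pat[new, ] <- transmitGametes(pat, mat, sv, recFrac)
    mat[new, ] <- transmitGametes(pat, mat, dv, recFrac)
    e[new] <- rnorm(nOff, 0, sqrt(config$sigma2E))
    phen[new] <- (pat[new, qcol] + mat[new, qcol] - 2 * p101) * alpha +
                 aPol[new] + e[new]
    n <- n + nOff
    pNew <- .qtlFreq(pat, mat, qcol, new)
    if (pNew %in% c(0, 1) && g < config$nGenerations - 1L) { fixed <- TRUE; break }
  }

  keep <- seq_len(n)
  aQtl <- (pat[keep, qcol] + mat[keep, qcol] - 2 * p101) * alpha
  ped <- Pedigree(keep, sire[keep], dam[keep], sex[keep], gen[keep])
  pop <- new("Population", pedigree = ped, map = map,
             pat = pat[keep, , drop = FALSE], mat = mat[keep, , drop = FALSE],
             aPol = aPol[keep], aQtl = aQtl, e = e[keep],
             phenotype = phen[keep],
             genotyped = rep(FALSE, n),
             meta = list(h2 = config$h2, q2 = config$q2, alpha = alpha,
                         sigma2Pol = config$sigma2Pol,
                         sigma2E = config$sigma2E,
                         sigma2Qtl = config$sigma2Qtl,
                         sigma2QtlRealized = sigma2QtlRealized,
                         p101 = p101, scenario = config$scenario,
                         selectionIterations = totalIter,
                         complete = !fixed && n == nTot))
  pop@meta$passesFilter <- !fixed && n == nTot && replicatePassesFilter(pop)
  pop
}

#' Simulate one replicate of the study population
#'
#' Burn-in, base generation, BLUP selection phase and genotyping flags in one
#' call, seeded for reproducibility.  Replicate r of an experiment uses seed
#' \code{baseSeed + r}; all randomness flows from this one generator.
#'
#' @param config a [simConfig()] list.
#' @param seed integer seed for this replicate.
#' @return a [Population-class] with \code{meta$passesFilter} set.
#' @export
simulatePopulation <- function(config = simConfig(), seed = 1L) {
  set.seed(seed)
  map <- genomeMap(config$spacing, config$nMarkers)
  burnin <- runBurnin(config, map)
  pop <- runSelectionPhase(burnin, config, map)
  pop@meta$seed <- seed
  applyGenotypingScenario(pop, config$scenario)
}

#' @rdname nAnimals
#' @export
setMethod("nAnimals", "Population", function(object) nAnimals(object@pedigree))

#' @rdname pedigreeTable
#' @export
setMethod("pedigreeTable", "Population", function(object)
  pedigreeTable(object@pedigree))

#' Phenotypes and true breeding values of a simulated population
#'
#' @param object a [Population-class].
#' @return \code{phenotypes()}: numeric vector; \code{trueBreedingValues()}:
#'   data.frame with columns \code{aPol}, \code{aQtl}, \code{total}.
#' @export
phenotypes <- function(object) object@phenotype

#' @rdname phenotypes
#' @export
trueBreedingValues <- function(object)
  data.frame(aPol = object@aPol, aQtl = object@aQtl,
             total = object@aPol + object@aQtl)

#' @rdname phenotypes
#' @export
genotypedAnimals <- function(object) which(object@genotyped)

setMethod("show", "Population", function(object) {
  gen <- object@pedigree@generation
  cat(sprintf(paste0(
    "Population: %d animals, generations %d-%d, %d genotyped\n",
    "  h2=%.2f  p(QTL+ allele, base)=%.3f  realized QTL var=%.4f  filter: %s\n"),
    nAnimals(object), min(gen), max(gen), sum(object@genotyped),
    object@meta$h2, object@meta$p101, object@meta$sigma2QtlRealized,
    if (isTRUE(object@meta$passesFilter)) "pass" else "fail"))
})

#' Export a simulated population to plain-text files
#'
#' Writes \code{pedigree.csv} (the [readPedigree()] dialect),
#' \code{genotypes.csv} (\code{animal,locus,gamete,allele} for genotyped
#' animals, loci in map order), \code{phenotypes.csv}
#' (\code{animal,phenotype}) and \code{truth.csv}
#' (\code{animal,a_pol,a_qtl,e,qtl_genotype}).
#'
#' @param pop a [Population-class].
#' @param dir output directory (created if missing).
#' @export
writePopulation <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePedigree(pop@pedigree, file.path(dir, "pedigree.csv"))
  g <- which(pop@genotyped)
  L <- ncol(pop@pat)
  geno <- data.frame(
    animal = rep(g, each = 2L * L),
    locus = rep(rep(seq_len(L), 2L), length(g)),
    gamete = rep(rep(1:2, each = L), length(g)),
    allele = as.vector(vapply(g, function(a) c(pop@pat[a, ], pop@mat[a, ]),
                              numeric(2L * L))))
  write.csv(geno, file.path(dir, "genotypes.csv"), row.names = FALSE, quote = FALSE)
  write.csv(data.frame(animal = pop@pedigree@animal, phenotype = pop@phenotype),
            file.path(dir, "phenotypes.csv"), row.names = FALSE, quote = FALSE)
  q <- pop@map@qtlIndex
  write.csv(data.frame(animal = pop@pedigree@animal, a_pol = pop@aPol,
                       a_qtl = pop@aQtl, e = pop@e,
                       qtl_genotype = pop@pat[, q] + pop@mat[, q]),
            file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
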