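#' @import methods
#' @importFrom stats rnorm rbinom var cov cor sd aggregate setNames
#' @importFrom utils read.csv write.csv
NULL

#' Pedigree of a closed breeding population
#'
#' Ordered parentage records.  Animal ids are the integers \code{1:n} in
#' record order; \code{0} denotes an unknown parent.  Parents must appear
#' before their offspring, sires must be male and dams female.
#'
#' @slot animal integer vector, ids \code{1:n}.
#' @slot sire,dam integer vectors; \code{0} = unknown.
#' @slot sex character, \code{"male"} or \code{"female"}.
#' @slot generation integer generation number of each animal.
#'
#' @seealso [Pedigree()], [computeInbreeding()], [buildAInverse()]
#' @exportClass Pedigree
setClass("Pedigree",
  slots = c(animal = "integer", sire = "integer", dam = "integer",
            sex = "character", generation = "integer"))

setValidity("Pedigree", function(object) {
  n <- length(object@animal)
  if (!identical(object@animal, seq_len(n)))
    return("animal ids must be the consecutive integers 1:n in record order")
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@sex) != n || length(object@generation) != n)
    return("all slots must have the same length")
  if (!all(object@sex %in% c("male", "female")))
    return("sex must be 'male' or 'female'")
  if (any(object@sire < 0L | object@dam < 0L))
    return("negative parent id")
  if (any(object@sire >= object@animal))
    return("sire id not smaller than animal id: pedigree must be sorted parents before offspring")
  if (any(object@dam >= object@animal))
    return("dam id not smaller than animal id: pedigree must be sorted parents before offspring")
  s <- object@sire[object@sire > 0L]
  if (any(object@sex[s] != "male")) return("some sire is not male")
  d <- object@dam[object@dam > 0L]
  if (any(object@sex[d] != "female")) return("some dam is not female")
  TRUE
})

#' Genome map: one chromosome, equally spaced SNP markers flanking one QTL
#'
#' The markers are equally spaced on a 1 Morgan chromosome, centred at 0.5 M;
#' the biallelic QTL sits at the midpoint of the central marker bracket
#' (between markers \code{nMarkers/2} and \code{nMarkers/2 + 1}).  Loci are
#' stored in map order, so with 20 markers there are 21 loci and the QTL is
#' locus 11.
#'
#' @slot positions numeric, Morgan positions of all loci (markers + QTL).
#' @slot qtlIndex integer, index of the QTL among the loci.
#' @slot markerCols integer, indices of the markers among the loci.
#' @slot spacing numeric, inter-marker distance in Morgans.
#' @exportClass GenomeMap
setClass("GenomeMap",
  slots = c(positions = "numeric", qtlIndex = "integer",
            markerCols = "integer", spacing = "numeric"))

setValidity("GenomeMap", function(object) {
  if (is.unsorted(object@positions, strictly = TRUE))
    return("locus positions must be strictly increasing")
  q <- object@qtlIndex
  if (q <= 1L || q >= length(object@positions))
    return("QTL must lie strictly inside the marker map")
  TRUE
})

#' Simulated population with genomes, breeding values and phenotypes
#'
#' Per-animal pair of gametes over all loci (paternal and maternal, alleles
#' coded 0/1), true polygenic and QTL breeding values, residual and phenotype.
#' The phenotype identity \code{P = A_qtl + A_pol + e} holds exactly.
#'
#' @slot pedigree a [Pedigree-class].
#' @slot map a [GenomeMap-class].
#' @slot pat,mat integer matrices (animals x loci): paternal / maternal gamete.
#' @slot aPol,aQtl,e,phenotype numeric vectors.
#' @slot genotyped logical: does the animal have observed marker genotypes?
#' @slot meta list of simulation constants (alpha, variance components,
#'   generation-101 QTL allele frequency \code{p101}, filter outcome, ...).
#' @exportClass Population
setClass("Population",
  slots = c(pedigree = "Pedigree", map = "GenomeMap",
            pat = "matrix", mat = "matrix",
            aPol = "numeric", aQtl = "numeric", e = "numeric",
            phenotype = "numeric", genotyped = "logical", meta = "list"))

setValidity("Population", function(object) {
  n <- length(object@pedigree@animal)
  L <- length(object@map@positions)
  if (nrow(object@pat) != n || nrow(object@mat) != n)
    return("gamete matrices must have one row per animal")
  if (ncol(object@pat) != L || ncol(object@mat) != L)
    return("gamete matrices must have one column per locus")
  if (length(object@phenotype) != n) return("phenotype length mismatch")
  if (max(abs(object@phenotype - (object@aQtl + object@aPol + object@e))) > 1e-10)
    return("phenotype must equal aQtl + aPol + e")
  TRUE
})

#' Haplotype window definition (NM / HAP2 / HAP4)
#'
#' @slot method \code{"NM"}, \code{"HAP2"} or \code{"HAP4"}.
#' @slot markers integer marker numbers (1-based along the marker map).
#' @slot cols integer locus-column indices of those markers.
#' @slot classes character allele-strings enumerating the haplotype classes
#'   observed among genotyped animals.
#' @slot frequencies numeric class frequencies among genotyped gametes.
#' @exportClass HaplotypeDefinition
setClass("HaplotypeDefinition",
  slots = c(method = "character", markers = "integer", cols = "integer",
            classes = "character", frequencies = "numeric"))

setValidity("HaplotypeDefinition", function(object) {
  k <- switch(object@method, NM = 1L, HAP2 = 2L, HAP4 = 4L, NA_integer_)
  if (is.na(k)) return("method must be NM, HAP2 or HAP4")
  if (length(object@markers) != k)
    return(sprintf("%s must use exactly %d marker(s)", object@method, k))
  if (length(object@classes) > 2^k)
    return("more classes than a biallelic window allows")
  if (length(object@frequencies) &&
      abs(sum(object@frequencies) - 1) > 1e-8)
    return("class frequencies must sum to 1")
  TRUE
})

#' Observed and predicted numbers of haplotype copies
#'
#' @slot observed numeric matrix (animals x classes); rows of ungenotyped
#'   animals are \code{NA}.  Genotyped rows sum to 2.
#' @slot predicted numeric matrix of mixed-model predictions
#'   \eqn{\hat w = \hat\mu_i + \hat d_i}, or a 0-row matrix before prediction.
#' @slot classes character, haplotype class labels.
#' @slot genotyped logical per animal.
#' @exportClass NhcMatrix
setClass("NhcMatrix",
  slots = c(observed = "matrix", predicted = "matrix",
            classes = "character", genotyped = "logical"))

setValidity("NhcMatrix", function(object) {
  if (ncol(object@observed) != length(object@classes))
    return("observed columns must match classes")
  if (nrow(object@observed) != length(object@genotyped))
    return("observed rows must match genotyped flags")
  g <- object@genotyped
  if (any(g)) {
    rs <- rowSums(object@observed[g, , drop = FALSE])
    if (any(abs(rs - 2) > 1e-8))
      return("observed nhc of genotyped animals must sum to 2 per animal")
  }
  if (nrow(object@predicted) &&
      any(!is.finite(object@predicted)))
    return("predicted nhc must be finite")
  TRUE
})

#' Estimated breeding values from one model fit
#'
#' @slot model model tag (\code{"CONBLUP"}, \code{"GABLUP"},
#'   \code{"MABLUP-NM"}, \code{"MABLUP-HAP2"} or \code{"MABLUP-HAP4"}).
#' @slot uPol numeric polygenic EBV per animal.
#' @slot hHat numeric estimated regression coefficient per haplotype class.
#' @slot qtlEbv numeric QTL-EBV per animal (\eqn{\sum_i \hat w_i \hat h_i});
#'   identically 0 for CONBLUP.
#' @slot totalEbv numeric, \code{qtlEbv + uPol}.
#' @slot classes character labels of the covariate columns.
#' @exportClass EBVSet
setClass("EBVSet",
  slots = c(model = "character", uPol = "numeric", hHat = "numeric",
            qtlEbv = "numeric", totalEbv = "numeric", classes = "character"))

setValidity("EBVSet", function(object) {
  if (length(object@qtlEbv) != length(object@uPol))
    return("qtlEbv and uPol must have equal length")
  if (max(abs(object@totalEbv - (object@qtlEbv + object@uPol))) > 1e-8)
    return("totalEbv must equal qtlEbv + uPol")
  TRUE
})

#' Result of a replicated simulation experiment
#'
#' @slot models data.frame of per-replicate EBV statistics (model, group,
#'   component, accuracy, slope, bias).
#' @slot nhc data.frame of per-replicate nhc-prediction statistics and LD
#'   r-squared per haplotype method.
#' @slot replicates data.frame with one row per effective replicate (seed,
#'   generation-101 allele frequency of the negative QTL allele, realized QTL
#'   variance, solver iterations).
#' @slot nEffective,nAttempts integer replicate counts.
#' @slot config the [simConfig()] list used.
#' @exportClass ExperimentResult
setClass("ExperimentResult",
  slots = c(models = "data.frame", nhc = "data.frame",
            replicates = "data.frame", nEffective = "integer",
            nAttempts = "integer", config = "list"))
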