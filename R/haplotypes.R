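## Marker minor allele frequencies in a set of animals (both gametes)
.markerMAF <- function(pop, idx) {
  cols <- pop@map@markerCols
  p <- (colSums(pop@pat[idx, cols, drop = FALSE]) +
        colSums(pop@mat[idx, cols, drop = FALSE])) / (2 * length(idx))
  pmin(p, 1 - p)
}

#' Choose the marker window for a haplotype method
#'
#' NM uses the closest marker left of the QTL; HAP2 the closest qualifying
#' flanking marker on each side; HAP4 the two closest qualifying markers on
#' each side.  A marker qualifies when its minor allele frequency is at least
#' 5\% (in the last simulated generation, when called through
#' [defineHaplotypes()]).  When a marker fails the frequency rule, the next
#' one further from the QTL takes its place.
#'
#' @param method \code{"NM"}, \code{"HAP2"} or \code{"HAP4"}.
#' @param maf numeric minor allele frequencies per marker, in map order.
#' @param minMAF qualification threshold (default 0.05, inclusive).
#' @return integer marker numbers, sorted in map order.
#' @export
selectHaplotypeMarkers <- function(method = c("NM", "HAP2", "HAP4"), maf,
                                   minMAF = 0.05) {
  method <- match.arg(method)
  nM <- length(maf)
  half <- nM / 2
  leftQ <- rev(which(maf[seq_len(half)] >= minMAF - 1e-12))        # nearest first
  rightQ <- half + which(maf[(half + 1):nM] >= minMAF - 1e-12)     # nearest first
  need <- switch(method, NM = c(1L, 0L), HAP2 = c(1L, 1L), HAP4 = c(2L, 2L))
  if (length(leftQ) < need[1] || length(rightQ) < need[2])
    stop(sprintf("%s needs %d qualifying marker(s) left and %d right of the QTL; found %d and %d",
                 method, need[1], need[2], length(leftQ), length(rightQ)))
  sort(c(leftQ[seq_len(need[1])], rightQ[seq_len(need[2])]))
}

#' Define a haplotype window on a simulated population
#'
#' Applies [selectHaplotypeMarkers()] with minor allele frequencies computed
#' on all last-generation animals, then enumerates the haplotype classes
#' actually observed among the gametes of genotyped animals and their
#' frequencies.  Effects can only be estimated for classes that genotyped
#' animals carry; unseen allele strings of ungenotyped animals fall outside
#' the class list (an implicit "other" bucket excluded from the models).
#'
#' @param pop a [Population-class] with genotyping flags set.
#' @param method \code{"NM"}, \code{"HAP2"} or \code{"HAP4"}.
#' @param minMAF marker qualification threshold.
#' @return a [HaplotypeDefinition-class].
#' @export
defineHaplotypes <- function(pop, method = c("NM", "HAP2", "HAP4"),
                             minMAF = 0.05) {
  method <- match.arg(method)
  gen <- pop@pedigree@generation
  last <- which(gen == max(gen))
  markers <- selectHaplotypeMarkers(method, .markerMAF(pop, last), minMAF)
  cols <- pop@map@markerCols[markers]
  g <- which(pop@genotyped)
  if (!length(g)) stop("no genotyped animals to enumerate haplotype classes from")
  strings <- c(.hapStrings(pop@pat, g, cols), .hapStrings(pop@mat, g, cols))
  tab <- table(strings)
  new("HaplotypeDefinition", method = method, markers = as.integer(markers),
      cols = as.integer(cols), classes = names(tab),
      frequencies = as.numeric(tab) / length(strings))
}

.hapStrings <- function(gam, idx, cols) {
  m <- gam[idx, cols, drop = FALSE]
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

setMethod("show", "HaplotypeDefinition", function(object) {
  cat(sprintf("HaplotypeDefinition %s: markers %s, %d classes (%s)\n",
              object@method, paste(object@markers, collapse = ","),
              length(object@classes),
              paste(sprintf("%s:%.2f", object@classes, object@frequencies),
                    collapse = " ")))
})

#' Count observed numbers of haplotype copies
#'
#' For every animal, each gamete's allele string over the window markers is
#' matched against the class list and copies are accumulated, giving the
#' 0/1/2 copy count per class.  Strings not in the class list are ignored
#' (the "other" bucket).  Counting uses the true simulated phases for all
#' animals; [nhcMatrix()] masks the rows of ungenotyped animals.
#'
#' @param pop a [Population-class].
#' @param hapdef a [HaplotypeDefinition-class].
#' @return integer matrix animals x classes.
#' @export
countNhc <- function(pop, hapdef) {
  n <- nAnimals(pop)
  idx <- seq_len(n)
  s1 <- .hapStrings(pop@pat, idx, hapdef@cols)
  s2 <- .hapStrings(pop@mat, idx, hapdef@cols)
  k <- length(hapdef@classes)
  counts <- matrix(0L, n, k, dimnames = list(NULL, hapdef@classes))
  m1 <- match(s1, hapdef@classes); m2 <- match(s2, hapdef@classes)
  ok1 <- !is.na(m1); ok2 <- !is.na(m2)
  ## each gamete contributes at most one (animal, class) cell
  ix1 <- cbind(idx[ok1], m1[ok1]); ix2 <- cbind(idx[ok2], m2[ok2])
  counts[ix1] <- counts[ix1] + 1L
  counts[ix2] <- counts[ix2] + 1L
  counts
}

#' Assemble an NhcMatrix from truth counts and genotyping flags
#'
#' @param counts matrix from [countNhc()].
#' @param genotyped logical flags; rows of ungenotyped animals become NA.
#' @param classes class labels (defaults to the count matrix columns).
#' @return an [NhcMatrix-class] with an empty prediction slot.
#' @export
nhcMatrix <- function(counts, genotyped, classes = colnames(counts)) {
  obs <- counts * 1.0
  obs[!genotyped, ] <- NA_real_
  new("NhcMatrix", observed = obs,
      predicted = matrix(numeric(0), 0, ncol(obs)),
      classes = as.character(classes), genotyped = genotyped)
}

#' @describeIn nhcMatrix observed copy counts (NA rows for ungenotyped animals).
#' @param x an [NhcMatrix-class].
#' @export
nhcObserved <- function(x) x@observed

#' @describeIn nhcMatrix mixed-model predictions (after [predictNhc()]).
#' @export
nhcPredicted <- function(x) {
  if (!nrow(x@predicted)) stop("no predictions yet: run predictNhc() first")
  x@predicted
}

setMethod("show", "NhcMatrix", function(object) {
  cat(sprintf("NhcMatrix: %d animals x %d classes, %d genotyped, predictions: %s\n",
              nrow(object@observed), length(object@classes),
              sum(object@genotyped),
              if (nrow(object@predicted)) "yes" else "no"))
})

#' Linkage disequilibrium r2 between two biallelic loci
#'
#' Squared correlation of the 0/1 allele indicators across gametes,
#' computed as D^2 / (pA pa pB pb); identical to the squared Pearson
#' correlation of the indicators.
#'
#' @param a,b 0/1 allele vectors over the same gametes.
#' @return r2 in \code{[0, 1]}, or \code{NA} if either locus is monomorphic.
#' @export
ldR2Biallelic <- function(a, b) {
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- mean(a * b) - pa * pb
  min(1, D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

#' Multi-allelic r2 between a haplotype locus and a biallelic QTL
#'
#' The proportion of QTL variance explained by the haplotype classes,
#' defined as the coefficient of determination of the least-squares
#' regression of the gamete's QTL allele indicator on haplotype-class
#' indicator covariates.  Computed directly from class means:
#' R2 = sum_c n_c (ybar_c - ybar)^2 / sum (y - ybar)^2.
#'
#' @param hapAlleles character/factor haplotype class per gamete.
#' @param qtlAlleles 0/1 QTL allele per gamete.
#' @return r2 in \code{[0, 1]}; \code{NA} if the QTL is monomorphic.
#' @export
ldR2Multiallelic <- function(hapAlleles, qtlAlleles) {
  p <- mean(qtlAlleles)
  if (p %in% c(0, 1)) return(NA_real_)
  y <- qtlAlleles
  ybar <- mean(y)
  grp <- split(y, hapAlleles)
  ssb <- sum(vapply(grp, function(v) length(v) * (mean(v) - ybar)^2, 0))
  sst <- sum((y - ybar)^2)
  min(1, ssb / sst)
}

#' Proportion of QTL variance captured by a haplotype method
#'
#' Evaluates [ldR2Biallelic()] (NM) or [ldR2Multiallelic()] (HAP2/HAP4) on
#' the last-generation gametes of a simulated population, grouping gametes by
#' their actual allele strings over the window markers.
#'
#' @param pop a [Population-class].
#' @param hapdef a [HaplotypeDefinition-class].
#' @export
qtlVarianceExplained <- function(pop, hapdef) {
  gen <- pop@pedigree@generation
  last <- which(gen == max(gen))
  q <- pop@map@qtlIndex
  qtl <- c(pop@pat[last, q], pop@mat[last, q])
  if (hapdef@method == "NM") {
    mk <- c(pop@pat[last, hapdef@cols], pop@mat[last, hapdef@cols])
    ldR2Biallelic(mk, qtl)
  } else {
    hap <- c(.hapStrings(pop@pat, last, hapdef@cols),
             .hapStrings(pop@mat, last, hapdef@cols))
    ldR2Multiallelic(hap, qtl)
  }
}

#' Export a haplotype definition / nhc matrix as CSV
#'
#' @param hapdef a [HaplotypeDefinition-class].
#' @param file output path.
#' @export
writeHaplotypeDefinition <- function(hapdef, file) {
  write.csv(data.frame(class_index = seq_along(hapdef@classes),
                       allele_string = hapdef@classes,
                       frequency = hapdef@frequencies),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @param x an [NhcMatrix-class] with predictions.
#' @rdname writeHaplotypeDefinition
#' @export
writeNhc <- function(x, file) {
  n <- nrow(x@observed); k <- length(x@classes)
  pred <- if (nrow(x@predicted)) x@predicted else matrix(NA_real_, n, k)
  write.csv(data.frame(animal = rep(seq_len(n), k),
                       class_index = rep(seq_len(k), each = n),
                       observed_nhc = as.vector(x@observed),
                       predicted_nhc = as.vector(pred)),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
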