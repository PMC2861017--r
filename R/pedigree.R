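#' Construct a Pedigree
#'
#' @param animal integer ids; must be \code{1:n} in record order
#'   (parents before offspring).  Use [orderPedigree()] first if your records
#'   are not in that form.
#' @param sire,dam integer parent ids, \code{0} for unknown.
#' @param sex \code{"male"}/\code{"female"} per animal.
#' @param generation integer generation labels (any coding; used to pick
#'   evaluation groups such as "last generation").
#' @return a [Pedigree-class] object.
#' @examples
#' trio <- Pedigree(1:3, c(0L, 0L, 1L), c(0L, 0L, 2L),
#'                  c("male", "female", "male"), c(1L, 1L, 2L))
#' computeInbreeding(trio)
#' @export
Pedigree <- function(animal, sire, dam, sex,
                     generation = rep(1L, length(animal))) {
  new("Pedigree", animal = as.integer(animal), sire = as.integer(sire),
      dam = as.integer(dam), sex = as.character(sex),
      generation = as.integer(generation))
}

#' Number of animals in a pedigree or population
#' @param object a [Pedigree-class] or [Population-class].
#' @export
setGeneric("nAnimals", function(object) standardGeneric("nAnimals"))

#' @rdname nAnimals
#' @export
setMethod("nAnimals", "Pedigree", function(object) length(object@animal))

#' Pedigree records as a data.frame
#'
#' @param object a [Pedigree-class] or [Population-class].
#' @return data.frame with columns animal, sire, dam, sex, generation.
#' @export
setGeneric("pedigreeTable", function(object) standardGeneric("pedigreeTable"))

#' @rdname pedigreeTable
#' @export
setMethod("pedigreeTable", "Pedigree", function(object)
  data.frame(animal = object@animal, sire = object@sire, dam = object@dam,
             sex = object@sex, generation = object@generation))

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", nAnimals(object), "animals,",
      length(unique(object@generation)), "generation(s);",
      sum(object@sire == 0L & object@dam == 0L), "founder(s)\n")
})

#' Reorder arbitrary pedigree records so parents precede offspring
#'
#' Topologically sorts the records and renumbers animals \code{1:n}.  The
#' package requires this ordering on input rather than sorting silently, so
#' that ids stay deterministic.
#'
#' @param animal,sire,dam vectors of (arbitrary, unique) ids; \code{0} or
#'   \code{NA} marks an unknown parent.
#' @param sex,generation per-record attributes carried along.
#' @return list with the reordered \code{Pedigree} and \code{idMap}, a named
#'   integer vector from old id to new id.
#' @export
orderPedigree <- function(animal, sire, dam, sex,
                          generation = rep(1L, length(animal))) {
  n <- length(animal)
  sire[is.na(sire)] <- 0; dam[is.na(dam)] <- 0
  if (anyDuplicated(animal)) stop("duplicated animal ids")
  known <- c(0, animal)
  if (!all(sire %in% known) || !all(dam %in% known))
    stop("parent id does not appear as an animal: unknown-but-nonzero parent")
  pos <- integer(0); placed <- setNames(rep(FALSE, n), animal)
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[
      (sire[remaining] == 0 | placed[as.character(sire[remaining])]) &
      (dam[remaining]  == 0 | placed[as.character(dam[remaining])])]
    if (!length(ready)) stop("pedigree contains a cycle (animal its own ancestor)")
    pos <- c(pos, ready)
    placed[as.character(animal[ready])] <- TRUE
    remaining <- setdiff(remaining, ready)
  }
  idMap <- setNames(seq_len(n), animal[pos])
  remap <- function(p) ifelse(p == 0, 0L, idMap[as.character(p)])
  ped <- Pedigree(seq_len(n), remap(sire[pos]), remap(dam[pos]),
                  sex[pos], generation[pos])
  list(pedigree = ped, idMap = idMap)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal inbreeding coefficients f (equal to diag(A) - 1 of the
#' additive relationship matrix) by tracing each animal's ancestor paths,
#' processing ancestors in decreasing id order so that the within-family
#' variance term of every ancestor is available when needed.  Animals with
#' an unknown parent get f = 0 (unknown parents are treated as unrelated
#' samples from the base population).
#'
#' @param ped a [Pedigree-class].
#' @return numeric vector of inbreeding coefficients in \code{[0, 1)}.
#' @references Meuwissen & Luo (1992) Genet Sel Evol 24:305-313.
#' @export
computeInbreeding <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  n <- nAnimals(ped); s <- ped@sire; d <- ped@dam
  f <- numeric(n)
  Dv <- numeric(n)   # Mendelian-sampling variance term of each animal
  L <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    fs <- if (si > 0L) f[si] else 0
    fd <- if (di > 0L) f[di] else 0
    Dv[i] <- if (si > 0L && di > 0L) 0.5 - 0.25 * (fs + fd)
             else if (si > 0L || di > 0L) 0.75 - 0.25 * (fs + fd)
             else 1
    if (si == 0L || di == 0L) { f[i] <- 0; next }
    # a_ii = sum over ancestors j of L_j^2 * D_j ; f_i = a_ii - 1
    anc <- i; L[i] <- 1; touched <- i; aii <- 0
    while (length(anc)) {
      j <- max(anc); anc <- anc[anc != j]
      Lj <- L[j]
      sj <- s[j]; dj <- d[j]
      if (sj > 0L) { if (L[sj] == 0) { anc <- c(anc, sj); touched <- c(touched, sj) }
                     L[sj] <- L[sj] + 0.5 * Lj }
      if (dj > 0L) { if (L[dj] == 0) { anc <- c(anc, dj); touched <- c(touched, dj) }
                     L[dj] <- L[dj] + 0.5 * Lj }
      aii <- aii + Lj * Lj * Dv[j]
    }
    f[i] <- aii - 1
    L[touched] <- 0
  }
  f
}

#' Mean parental inbreeding per animal
#'
#' f_p = (f_sire + f_dam) / 2, counting an unknown parent as non-inbred.
#' This is the coefficient that scales the Mendelian sampling variance
#' 0.5 * sigma2_pol * (1 - f_p).
#'
#' @param ped a [Pedigree-class].
#' @param f inbreeding coefficients, from [computeInbreeding()].
#' @export
meanParentalInbreeding <- function(ped, f = computeInbreeding(ped)) {
  fs <- ifelse(ped@sire > 0L, f[pmax(ped@sire, 1L)], 0)
  fd <- ifelse(ped@dam > 0L, f[pmax(ped@dam, 1L)], 0)
  0.5 * (fs + fd)
}

#' Sparse inverse of the additive relationship matrix (Henderson's rules)
#'
#' Builds A-inverse directly from the pedigree with inbreeding: for animal i
#' with parents s, d the contribution is delta to (i,i), -delta/2 to (i,s)
#' and (i,d), and delta/4 to (s,s), (d,d) and (s,d), where
#' delta = 1 / (0.5 - 0.25 (f_s + f_d)), adjusted when a parent is unknown.
#'
#' @inheritParams meanParentalInbreeding
#' @return a symmetric sparse \code{Matrix::dsCMatrix}.
#' @examples
#' trio <- Pedigree(1:3, c(0L, 0L, 1L), c(0L, 0L, 2L),
#'                  c("male", "female", "male"))
#' buildAInverse(trio)   # diag 1.5, 1.5, 2; offspring-parent -1; sire-dam 0.5
#' @export
buildAInverse <- function(ped, f = computeInbreeding(ped)) {
  n <- nAnimals(ped); s <- ped@sire; d <- ped@dam
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], 0)
  dvar <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (fs + fd),
          ifelse(s > 0L | d > 0L, 0.75 - 0.25 * (fs + fd), 1))
  if (any(dvar <= 0)) stop("invalid pedigree: non-positive Mendelian variance")
  delta <- 1 / dvar
  ii <- seq_len(n)
  ti <- ii; tj <- ii; tx <- delta                      # (i, i)
  hs <- s > 0L; hd <- d > 0L; hb <- hs & hd
  addT <- function(i, j, x) { ti <<- c(ti, i, j); tj <<- c(tj, j, i); tx <<- c(tx, x, x) }
  addD <- function(i, x)    { ti <<- c(ti, i);    tj <<- c(tj, i);    tx <<- c(tx, x) }
  addT(ii[hs], s[hs], -delta[hs] / 2)
  addT(ii[hd], d[hd], -delta[hd] / 2)
  addD(s[hs], delta[hs] / 4)
  addD(d[hd], delta[hd] / 4)
  addT(s[hb], d[hb], delta[hb] / 4)
  Matrix::forceSymmetric(
    Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, n)))
}

#' Dense additive relationship matrix by the tabular method
#'
#' O(n^2) recursive (tabular) construction of A; primarily the independent
#' cross-check for [computeInbreeding()] and [buildAInverse()] on moderate
#' pedigrees.
#'
#' @param ped a [Pedigree-class].
#' @return dense numeric n x n matrix.
#' @export
makeA <- function(ped) {
  n <- nAnimals(ped); s <- ped@sire; d <- ped@dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (si > 0L) A[j, si] else 0
      ad_ <- if (di > 0L) A[j, di] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  A
}

#' Read / write the pedigree CSV dialect
#'
#' Columns \code{animal,sire,dam,sex,generation}; \code{0} denotes an unknown
#' parent; animal ids are 1-based and must already be sorted parents-first.
#'
#' @param file path to a CSV file.
#' @export
readPedigree <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("animal", "sire", "dam", "sex", "generation")
  if (!all(need %in% names(x))) stop("pedigree CSV must have columns ",
                                     paste(need, collapse = ","))
  Pedigree(x$animal, x$sire, x$dam, x$sex, x$generation)
}

#' @param ped a [Pedigree-class].
#' @rdname readPedigree
#' @export
writePedigree <- function(ped, file) {
  write.csv(data.frame(animal = ped@animal, sire = ped@sire, dam = ped@dam,
                       sex = ped@sex, generation = ped@generation),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
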