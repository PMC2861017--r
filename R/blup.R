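#' Predict numbers of haplotype copies for all animals
#'
#' Runs one univariate animal-model analysis per haplotype class: the
#' observed 0/1/2 copy count of genotyped animals is the "phenotype", the
#' additive relationship matrix ties ungenotyped relatives in, and the
#' assumed heritability (0.99 by default, absorbing rare haplotyping errors
#' and recombination) sets the variance ratio.  The prediction for every
#' animal is \eqn{\hat w_i = \hat\mu_i + \hat d_i}.
#'
#' The per-class systems share one left-hand side, so they are solved against
#' a single sparse Cholesky factorisation; [solvePCG()] gives the same
#' solutions within tolerance and is available via \code{solver = "pcg"}.
#'
#' Because the equations are linear in the observations and genotyped rows
#' sum to 2 across classes, the predictions of every animal also sum to 2.
#'
#' @param ainv sparse A-inverse over all animals.
#' @param nhc an [NhcMatrix-class] (observed counts, NA for ungenotyped).
#' @param h2Nhc assumed nhc heritability.
#' @param solver \code{"cholesky"} (default) or \code{"pcg"}.
#' @param tol PCG tolerance.
#' @return the [NhcMatrix-class] with its \code{predicted} slot filled.
#' @export
predictNhc <- function(ainv, nhc, h2Nhc = 0.99,
                       solver = c("cholesky", "pcg"), tol = 1e-10) {
  solver <- match.arg(solver)
  stopifnot(is(nhc, "NhcMatrix"))
  lambda <- (1 - h2Nhc) / h2Nhc
  n <- nrow(nhc@observed); k <- ncol(nhc@observed)
  g <- nhc@genotyped
  if (!any(g)) stop("no genotyped animals")
  pred <- matrix(NA_real_, n, k, dimnames = list(NULL, nhc@classes))
  ## identical operator for every class: factor once
  sys0 <- assembleNhcMME(ainv, ifelse(g, 0, NA), lambda)
  ch <- if (solver == "cholesky")
    Matrix::Cholesky(Matrix::forceSymmetric(sys0$lhs), LDL = FALSE)
  for (j in seq_len(k)) {
    yj <- ifelse(g, nhc@observed[, j], 0)
    rhs <- c(sum(yj), yj)
    if (solver == "cholesky") {
      sol <- as.numeric(Matrix::solve(ch, rhs))
    } else {
      fit <- solvePCG(sys0$lhs, rhs, tol = tol)
      if (!fit$report@converged)
        stop("nhc prediction did not converge for class ", nhc@classes[j])
      sol <- fit$solution
    }
    pred[, j] <- sol[1L] + sol[1L + seq_len(n)]
  }
  nhc@predicted <- pred
  nhc
}

#' Variance of a haplotype-class effect
#'
#' NM and GABLUP model a single covariate (one marker/QTL allele), for which
#' the effect variance is alpha^2; HAP2 and HAP4 model all classes jointly
#' and use the many-haplotype limit sigma2_qtl / 2 of the frequency-dependent
#' rule (see [haplotypeVarianceFromFrequencies()]), to which the accuracy of
#' the QTL-EBV is insensitive.
#'
#' @param method \code{"NM"}, \code{"HAP2"}, \code{"HAP4"} or \code{"GABLUP"}.
#' @param sigma2Qtl realized additive QTL variance.
#' @param alpha allele substitution effect.
#' @export
haplotypeEffectVariance <- function(method, sigma2Qtl, alpha) {
  switch(method,
         NM = , GABLUP = alpha^2,
         HAP2 = , HAP4 = sigma2Qtl / 2,
         stop("unknown haplotype method: ", method))
}

#' Frequency-dependent haplotype-effect variance
#'
#' General rule for n haplotype classes with frequencies m_i, derived by
#' equating the variance contributed by independent class effects,
#' sigma2_h * sum_i 2 m_i (1 - m_i), to the QTL variance:
#' sigma2_h = sigma2_qtl / (2 (1 - sum m_i^2)).  At equal frequencies this is
#' sigma2_qtl * n / (2 (n - 1)) and tends to sigma2_qtl / 2 as the number of
#' haplotypes grows.
#'
#' @param m numeric vector of class frequencies (sums to 1).
#' @param sigma2Qtl additive QTL variance.
#' @export
haplotypeVarianceFromFrequencies <- function(m, sigma2Qtl) {
  stopifnot(abs(sum(m) - 1) < 1e-8, all(m >= 0))
  het <- 1 - sum(m^2)
  if (het <= 0) stop("monomorphic haplotype locus")
  sigma2Qtl / (2 * het)
}

.newEBVSet <- function(model, b, u, h, W, classes, center = NULL) {
  qtl <- if (length(h)) {
    if (is.null(center)) center <- colMeans(W)
    as.numeric(sweep(W, 2L, center) %*% h)
  } else numeric(length(u))
  new("EBVSet", model = model, uPol = u, hHat = h, qtlEbv = qtl,
      totalEbv = qtl + u, classes = as.character(classes))
}

#' Marker-assisted BLUP with random regression on nhc covariates
#'
#' Fits y = 1 mu + Z u_pol + W h + e with independent haplotype effects
#' h_i ~ N(0, sigma2_h) and polygenic effects u_pol ~ N(0, A sigma2_pol).
#' The QTL-EBV of an animal is \eqn{\sum_i \hat w_i \hat h_i}; the total EBV
#' adds the polygenic EBV.
#'
#' The model is fitted on the raw covariates; the reported QTL-EBV is
#' expressed as a deviation from reference covariate means (by default the
#' population means, so that QTL-EBVs average zero), matching the usual
#' deviation-from-base convention of EBVs.  Centring shifts every animal's
#' QTL-EBV by the same constant, so accuracies and regression slopes are
#' unaffected; only the bias statistic depends on it.
#'
#' @param y phenotypes (one record per pedigree animal).
#' @param ainv sparse A-inverse.
#' @param W covariate matrix of (observed or predicted) nhc, animals x classes.
#' @param sigma2Pol,sigma2E,sigma2H variance components.
#' @param model tag stored in the result.
#' @param center reference covariate means subtracted when computing the
#'   QTL-EBV (default \code{colMeans(W)}; the simulation pipeline passes the
#'   base-generation means, the same reference used for the true QTL
#'   breeding values).
#' @param solver \code{"pcg"} (default) or \code{"cholesky"}.
#' @param tol solver tolerance.
#' @return an [EBVSet-class].
#' @export
runMablup <- function(y, ainv, W, sigma2Pol, sigma2E, sigma2H,
                      model = "MABLUP", center = NULL,
                      solver = c("pcg", "cholesky"), tol = 1e-10) {
  solver <- match.arg(solver)
  W <- as.matrix(W)
  fit <- .solveTraitModel(y, ainv, W, sigma2E / sigma2Pol, sigma2E / sigma2H,
                          solver = solver, tol = tol)
  .newEBVSet(model, fit$b, fit$u, fit$h, W,
             colnames(W) %||% paste0("class", seq_len(ncol(W))), center)
}

#' Gene-assisted BLUP: regression on the true QTL gene content
#'
#' [runMablup()] with a single covariate, the true count of the positive QTL
#' allele for every animal (all animals assumed genotyped at the QTL), and
#' effect variance alpha^2.
#'
#' @param y phenotypes.
#' @param ainv sparse A-inverse.
#' @param geneContent integer 0/1/2 gene content per animal.
#' @param alpha allele substitution effect.
#' @inheritParams runMablup
#' @export
runGablup <- function(y, ainv, geneContent, alpha, sigma2Pol, sigma2E,
                      center = NULL, solver = c("pcg", "cholesky"),
                      tol = 1e-10) {
  runMablup(y, ainv, matrix(geneContent, ncol = 1,
                            dimnames = list(NULL, "geneContent")),
            sigma2Pol, sigma2E, sigma2H = alpha^2, model = "GABLUP",
            center = center, solver = match.arg(solver), tol = tol)
}

#' Conventional BLUP: the animal model without marker information
#'
#' The additive genetic variance is the total sigma2_pol + sigma2_qtl, since
#' without markers the QTL contribution is absorbed by the polygenic term.
#'
#' @param y phenotypes.
#' @param ainv sparse A-inverse.
#' @param sigma2Add total additive variance (sigma2_pol + realized sigma2_qtl).
#' @param sigma2E residual variance.
#' @inheritParams runMablup
#' @export
runConblup <- function(y, ainv, sigma2Add, sigma2E,
                       solver = c("pcg", "cholesky"), tol = 1e-10) {
  fit <- .solveTraitModel(y, ainv, NULL, sigma2E / sigma2Add, NA,
                          solver = match.arg(solver), tol = tol)
  .newEBVSet("CONBLUP", fit$b, fit$u, numeric(0), NULL, character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' EBVSet accessors
#' @param x an [EBVSet-class].
#' @export
totalEBV <- function(x) x@totalEbv

#' @rdname totalEBV
#' @export
qtlEBV <- function(x) x@qtlEbv

#' @rdname totalEBV
#' @export
polygenicEBV <- function(x) x@uPol

#' @rdname totalEBV
#' @export
haplotypeEffects <- function(x) setNames(x@hHat, x@classes)

setMethod("show", "EBVSet", function(object) {
  cat(sprintf("EBVSet [%s]: %d animals, %d haplotype effect(s)\n",
              object@model, length(object@uPol), length(object@hHat)))
})

#' Write EBVs / haplotype effects to CSV
#'
#' @param x an [EBVSet-class].
#' @param file output path.
#' @export
writeEBV <- function(x, file) {
  write.csv(data.frame(animal = seq_along(x@uPol), model = x@model,
                       u_pol_hat = x@uPol, qtl_ebv = x@qtlEbv,
                       total_ebv = x@totalEbv),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeEBV
#' @export
writeHaplotypeEffects <- function(x, file) {
  write.csv(data.frame(model = x@model, class_index = seq_along(x@hHat),
                       class = x@classes, h_hat = x@hHat),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
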