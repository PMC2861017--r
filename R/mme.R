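#' Report from an iterative mixed-model solve
#'
#' @slot iterations integer iterations used.
#' @slot converged logical, TRUE iff the final relative difference between
#'   left- and right-hand sides fell below the tolerance.
#' @slot finalRelDiff numeric, final \eqn{\|LHS x - RHS\| / \|RHS\|}.
#' @exportClass SolverReport
setClass("SolverReport",
  slots = c(iterations = "integer", converged = "logical",
            finalRelDiff = "numeric"))

setMethod("show", "SolverReport", function(object) {
  cat(sprintf("SolverReport: %d iteration(s), %s (rel. diff %.2e)\n",
              object@iterations,
              if (object@converged) "converged" else "NOT converged",
              object@finalRelDiff))
})

#' Preconditioned conjugate gradient solver for mixed model equations
#'
#' Jacobi (diagonal) preconditioned CG for a symmetric positive (semi-)
#' definite sparse system.  Convergence is declared when the relative
#' difference between the left- and right-hand sides,
#' \eqn{\|LHS x - RHS\|_2 / \|RHS\|_2}, falls below \code{tol} (default
#' 1e-10).
#'
#' @param lhs sparse (or dense) symmetric coefficient matrix.
#' @param rhs numeric right-hand side.
#' @param tol convergence tolerance on the relative residual norm.
#' @param maxIter iteration cap; non-convergence is reported, not an error.
#' @return list with \code{solution} and a [SolverReport-class] as
#'   \code{report}.
#' @export
solvePCG <- function(lhs, rhs, tol = 1e-10, maxIter = 20000L) {
  lhs <- methods::as(lhs, "CsparseMatrix")
  rhs <- as.numeric(rhs)
  dg <- Matrix::diag(lhs)
  if (any(dg <= 0)) stop("LHS has non-positive diagonal entries")
  Mi <- 1 / dg
  bnorm <- sqrt(sum(rhs^2))
  if (bnorm == 0)
    return(list(solution = numeric(length(rhs)),
                report = new("SolverReport", iterations = 0L,
                             converged = TRUE, finalRelDiff = 0)))
  x <- numeric(length(rhs))
  r <- rhs
  z <- Mi * r
  p <- z
  rz <- sum(r * z)
  rel <- 1
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Ap <- as.numeric(lhs %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rel <- sqrt(sum(r^2)) / bnorm
    if (rel < tol) break
    z <- Mi * r
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  list(solution = x,
       report = new("SolverReport", iterations = it,
                    converged = rel < tol, finalRelDiff = rel))
}

## Direct sparse Cholesky solve; returns the same shape as solvePCG.
.solveChol <- function(lhs, rhs) {
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(methods::as(lhs, "CsparseMatrix")),
                         LDL = FALSE)
  x <- as.numeric(Matrix::solve(ch, rhs))
  rel <- sqrt(sum((as.numeric(lhs %*% x) - rhs)^2)) / max(sqrt(sum(rhs^2)), 1e-300)
  list(solution = x,
       report = new("SolverReport", iterations = 1L, converged = TRUE,
                    finalRelDiff = rel))
}

#' Assemble the mixed model equations for nhc prediction
#'
#' One haplotype class at a time: nhc = mu + d + eps for genotyped animals,
#' with d ~ N(0, A sigma2_d) over all animals.  Solution order is
#' \code{[mu, d_1..d_n]}.  Ungenotyped animals contribute no data row but are
#' connected through A-inverse.
#'
#' @param ainv sparse A-inverse from [buildAInverse()].
#' @param nhcObserved numeric vector of observed copy counts with \code{NA}
#'   for ungenotyped animals.
#' @param lambda variance ratio sigma2_eps / sigma2_d; the assumed nhc
#'   heritability 0.99 gives lambda = (1 - 0.99)/0.99.
#' @return list with sparse \code{lhs} and numeric \code{rhs}.
#' @export
assembleNhcMME <- function(ainv, nhcObserved, lambda = (1 - 0.99) / 0.99) {
  n <- nrow(ainv)
  stopifnot(length(nhcObserved) == n, lambda > 0)
  g <- !is.na(nhcObserved)
  ng <- sum(g)
  if (ng == 0L) stop("no genotyped animals: nothing to predict from")
  y <- ifelse(g, nhcObserved, 0)
  lhs <- rbind(
    cbind(Matrix::Matrix(ng, 1, 1), Matrix::Matrix(as.numeric(g), 1, n)),
    cbind(Matrix::Matrix(as.numeric(g), n, 1),
          Matrix::Diagonal(n, as.numeric(g)) + lambda * ainv))
  list(lhs = methods::as(lhs, "CsparseMatrix"), rhs = c(sum(y), y))
}

#' Assemble the mixed model equations of the trait models
#'
#' y = 1 mu + Z u_pol + W h + e with u_pol ~ N(0, A sigma2_pol) and
#' independent h_i ~ N(0, sigma2_h).  Solution order is
#' \code{[mu, u_1..u_n, h_1..h_k]}.  With \code{W = NULL} these are the
#' conventional animal-model equations.  W columns are used as given (no
#' centring).
#'
#' @param y phenotypes, one record per animal.
#' @param ainv sparse A-inverse.
#' @param W numeric matrix of nhc covariates (animals x classes) or NULL.
#' @param lambdaPol variance ratio sigma2_e / sigma2_pol.
#' @param lambdaH variance ratio sigma2_e / sigma2_h (ignored when W is NULL).
#' @return list with sparse \code{lhs}, numeric \code{rhs} and \code{k},
#'   the number of covariate columns.
#' @export
assembleTraitMME <- function(y, ainv, W = NULL, lambdaPol, lambdaH = NA) {
  n <- nrow(ainv)
  if (length(y) != n) stop("need one phenotype per pedigree animal")
  if (n == 0L) stop("zero phenotypes")
  stopifnot(lambdaPol > 0)
  one <- Matrix::Matrix(1, 1, n)
  if (is.null(W)) {
    lhs <- rbind(cbind(Matrix::Matrix(n, 1, 1), one),
                 cbind(Matrix::t(one), Matrix::Diagonal(n) + lambdaPol * ainv))
    rhs <- c(sum(y), y)
    k <- 0L
  } else {
    W <- as.matrix(W)
    if (nrow(W) != n) stop("W must have one row per animal")
    if (any(!is.finite(W))) stop("W contains non-finite covariates")
    stopifnot(lambdaH > 0)
    k <- ncol(W)
    Ws <- methods::as(Matrix::Matrix(W), "CsparseMatrix")
    lhs <- rbind(
      cbind(Matrix::Matrix(n, 1, 1), one, Matrix::Matrix(colSums(W), 1, k)),
      cbind(Matrix::t(one), Matrix::Diagonal(n) + lambdaPol * ainv, Ws),
      cbind(Matrix::Matrix(colSums(W), k, 1), Matrix::t(Ws),
            Matrix::Matrix(crossprod(W) + lambdaH * diag(k), sparse = TRUE)))
    rhs <- c(sum(y), y, as.numeric(crossprod(W, y)))
  }
  list(lhs = methods::as(lhs, "CsparseMatrix"), rhs = rhs, k = k)
}

## Shared trait-model solve: returns b (mean), u (polygenic), h (covariates)
.solveTraitModel <- function(y, ainv, W, lambdaPol, lambdaH,
                             solver = "pcg", tol = 1e-10) {
  sys <- assembleTraitMME(y, ainv, W, lambdaPol, lambdaH)
  sol <- if (solver == "cholesky") .solveChol(sys$lhs, sys$rhs)
         else solvePCG(sys$lhs, sys$rhs, tol = tol)
  if (!sol$report@converged)
    stop("mixed model equations did not converge (rel. diff ",
         format(sol$report@finalRelDiff), ")")
  n <- nrow(ainv)
  list(b = sol$solution[1L],
       u = sol$solution[1L + seq_len(n)],
       h = if (sys$k) sol$solution[1L + n + seq_len(sys$k)] else numeric(0),
       report = sol$report)
}
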