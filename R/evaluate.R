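#' Evaluation statistics for estimated breeding values
#'
#' \code{accuracy()} is the Pearson correlation between estimates and truths;
#' \code{regressionSlope()} is the regression of true on estimated values,
#' cov(truth, estimate)/var(estimate) — below 1 flags overestimated EBV
#' variance, above 1 underestimated; \code{ebvBias()} is
#' mean(estimate - truth).
#'
#' @param estimates,truths paired numeric vectors.
#' @return a scalar; \code{NA} when a variance needed is zero (degenerate).
#' @export
accuracy <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  if (length(estimates) < 3L) stop("need at least 3 pairs")
  if (sd(estimates) == 0 || sd(truths) == 0) return(NA_real_)
  cor(estimates, truths)
}

#' @rdname accuracy
#' @export
regressionSlope <- function(truths, estimates) {
  stopifnot(length(estimates) == length(truths))
  v <- var(estimates)
  if (v == 0) return(NA_real_)
  cov(truths, estimates) / v
}

#' @rdname accuracy
#' @export
ebvBias <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths))
  mean(estimates - truths)
}

#' Approximate accuracy of the total EBV from its components
#'
#' r_totalEBV = sqrt(q2 * r_h^2 + (1 - q2) * r_pol^2), where q2 is the
#' proportion of genetic variance explained by the haplotypes
#' (= r_qtl^2 * Q2), r_h the accuracy of the predicted number of haplotype
#' copies and r_pol the accuracy of the polygenic EBV.  With q2 = 0 it
#' collapses to r_pol (no marker information).
#'
#' @param q2,rPol,rH inputs in \code{[0, 1]}.
#' @export
approxTotalAccuracy <- function(q2, rPol, rH) {
  if (any(c(q2, rPol, rH) < 0) || any(c(q2, rPol, rH) > 1))
    stop("all inputs must lie in [0, 1]")
  sqrt(q2 * rH^2 + (1 - q2) * rPol^2)
}

## Per-class accuracy/slope of predicted vs true nhc over a group of animals,
## averaged (unweighted) across classes with non-degenerate variance.
.nhcGroupStats <- function(truthCounts, predicted, idx) {
  accs <- c(); slopes <- c()
  for (j in seq_len(ncol(truthCounts))) {
    tk <- truthCounts[idx, j]; pk <- predicted[idx, j]
    if (sd(tk) == 0 || sd(pk) == 0) next
    accs <- c(accs, cor(pk, tk))
    slopes <- c(slopes, cov(tk, pk) / var(pk))
  }
  c(accuracy = if (length(accs)) mean(accs) else NA_real_,
    slope = if (length(slopes)) mean(slopes) else NA_real_,
    nClasses = ncol(truthCounts))
}

## Accuracy/slope/bias rows for one EBVSet over the two evaluation groups.
.modelStats <- function(ebv, pop, groups) {
  truthQ <- pop@aQtl; truthP <- pop@aPol; truthT <- truthQ + truthP
  comp <- if (ebv@model == "CONBLUP") "total" else c("qtl", "polygenic", "total")
  out <- list()
  for (grp in names(groups)) {
    i <- groups[[grp]]
    for (cc in comp) {
      est <- switch(cc, qtl = ebv@qtlEbv[i], polygenic = ebv@uPol[i],
                    total = ebv@totalEbv[i])
      tru <- switch(cc, qtl = truthQ[i], polygenic = truthP[i],
                    total = truthT[i])
      out[[length(out) + 1L]] <- data.frame(
        model = ebv@model, group = grp, component = cc,
        accuracy = accuracy(est, tru),
        slope = regressionSlope(tru, est),
        bias = ebvBias(est, tru))
    }
  }
  do.call(rbind, out)
}

#' Run the full evaluation pipeline on one simulated replicate
#'
#' For each haplotype method (NM, HAP2, HAP4): defines the window, counts
#' observed nhc, predicts nhc for all animals, computes nhc accuracy and
#' regression slope over ungenotyped last-generation females and the
#' proportion of QTL variance captured (r2), then fits MABLUP with observed
#' nhc for genotyped and predicted nhc for ungenotyped animals (NM uses the
#' single allele-"1" covariate).  Also fits GABLUP (true gene content,
#' sigma2_h = alpha^2) and CONBLUP (additive variance = polygenic + realized
#' QTL variance).  Accuracies, slopes and biases are reported for genotyped
#' last-generation males and ungenotyped last-generation females.
#'
#' @param pop a [Population-class] that passed the QTL filter.
#' @param config the [simConfig()] used to simulate it.
#' @return list of data.frames \code{models}, \code{nhc}, and scalar
#'   \code{replicate} infos.
#' @export
evaluateReplicate <- function(pop, config) {
  ped <- pop@pedigree
  f <- computeInbreeding(ped)
  ainv <- buildAInverse(ped, f)
  y <- pop@phenotype
  meta <- pop@meta
  s2q <- meta$sigma2QtlRealized
  lastGen <- ped@generation == max(ped@generation)
  groups <- list(
    genotypedMales = which(lastGen & ped@sex == "male" & pop@genotyped),
    ungenotypedFemales = which(lastGen & ped@sex == "female" & !pop@genotyped))
  if (!length(groups$ungenotypedFemales))   # scenario 3: all genotyped
    groups$ungenotypedFemales <- which(lastGen & ped@sex == "female")

  models <- list(); nhcRows <- list()

  con <- runConblup(y, ainv, meta$sigma2Pol + s2q, meta$sigma2E,
                    solver = config$solver, tol = config$tol)
  models[[1L]] <- .modelStats(con, pop, groups)

  base <- ped@generation == min(ped@generation)
  q <- pop@map@qtlIndex
  gab <- runGablup(y, ainv, pop@pat[, q] + pop@mat[, q], meta$alpha,
                   meta$sigma2Pol, meta$sigma2E, center = 2 * meta$p101,
                   solver = config$solver, tol = config$tol)
  models[[2L]] <- .modelStats(gab, pop, groups)

  for (method in c("NM", "HAP2", "HAP4")) {
    hd <- defineHaplotypes(pop, method)
    truth <- countNhc(pop, hd)
    nhc <- nhcMatrix(truth, pop@genotyped)
    nhc <- predictNhc(ainv, nhc, h2Nhc = config$h2Nhc)
    st <- .nhcGroupStats(truth, nhc@predicted, groups$ungenotypedFemales)
    r2 <- qtlVarianceExplained(pop, hd)
    nhcRows[[method]] <- data.frame(
      method = method, accuracy = st[["accuracy"]], slope = st[["slope"]],
      r2 = r2, nClasses = as.integer(st[["nClasses"]]))
    W <- ifelse(matrix(pop@genotyped, nrow(truth), ncol(truth)),
                truth, nhc@predicted)
    if (config$wComposition == "predicted") W <- nhc@predicted
    colnames(W) <- hd@classes
    if (method == "NM") {
      keep <- which(hd@classes == "1")
      if (!length(keep)) keep <- 1L       # degenerate: allele 1 unseen
      W <- W[, keep, drop = FALSE]
    }
    s2h <- haplotypeEffectVariance(method, s2q, meta$alpha)
    fit <- runMablup(y, ainv, W, meta$sigma2Pol, meta$sigma2E, s2h,
                     model = paste0("MABLUP-", method),
                     center = colMeans(W[base, , drop = FALSE]),
                     solver = config$solver, tol = config$tol)
    models[[length(models) + 1L]] <- .modelStats(fit, pop, groups)
  }

  list(models = do.call(rbind, models),
       nhc = do.call(rbind, c(nhcRows, make.row.names = FALSE)),
       replicate = data.frame(
         seed = meta$seed %||% NA_integer_,
         p101Neg = 1 - meta$p101,          # allele "0" carries -alpha
         sigma2QtlRealized = s2q,
         selectionIterations = meta$selectionIterations %||% NA_integer_))
}

#' Run a replicated simulation experiment
#'
#' Simulates replicates with seeds \code{baseSeed + 1, baseSeed + 2, ...}
#' until \code{nReplicates} pass the last-generation QTL MAF filter
#' (discarded and failed replicates are counted and resimulated with the next
#' seed), evaluating each effective replicate with [evaluateReplicate()]
#' unless \code{simOnly} (then only simulation-level statistics such as the
#' base-generation allele frequency are recorded).
#'
#' @param config a [simConfig()].
#' @param nReplicates effective replicates required (the study used 200;
#'   50 is the reduced desk profile).
#' @param baseSeed integer; replicate r uses seed baseSeed + r.
#' @param simOnly skip the BLUP evaluation of each replicate.
#' @param maxAttempts safety cap on total simulations.
#' @param verbose print one line per replicate.
#' @return an [ExperimentResult-class].
#' @export
runExperiment <- function(config = simConfig(), nReplicates = 50L,
                          baseSeed = 0L, simOnly = FALSE,
                          maxAttempts = 40L * nReplicates, verbose = FALSE) {
  models <- list(); nhc <- list(); reps <- list()
  eff <- 0L; attempt <- 0L
  while (eff < nReplicates && attempt < maxAttempts) {
    attempt <- attempt + 1L
    pop <- simulatePopulation(config, seed = baseSeed + attempt)
    if (!isTRUE(pop@meta$passesFilter)) {
      if (verbose) message(sprintf("seed %d: discarded (QTL MAF filter)",
                                   baseSeed + attempt))
      next
    }
    res <- if (simOnly) {
      list(models = NULL, nhc = NULL,
           replicate = data.frame(seed = pop@meta$seed,
                                  p101Neg = 1 - pop@meta$p101,
                                  sigma2QtlRealized = pop@meta$sigma2QtlRealized,
                                  selectionIterations = pop@meta$selectionIterations))
    } else {
      tryCatch(evaluateReplicate(pop, config), error = function(err) {
        if (verbose) message(sprintf("seed %d: evaluation failed (%s)",
                                     baseSeed + attempt, conditionMessage(err)))
        NULL
      })
    }
    if (is.null(res)) next
    eff <- eff + 1L
    if (!is.null(res$models)) {
      res$models$replicate <- eff
      res$nhc$replicate <- eff
      models[[eff]] <- res$models
      nhc[[eff]] <- res$nhc
    }
    res$replicate$replicate <- eff
    reps[[eff]] <- res$replicate
    if (verbose) message(sprintf("seed %d: effective replicate %d/%d",
                                 baseSeed + attempt, eff, nReplicates))
  }
  if (eff < nReplicates)
    warning(sprintf("only %d of %d effective replicates within %d attempts",
                    eff, nReplicates, maxAttempts))
  new("ExperimentResult",
      models = if (length(models)) do.call(rbind, models) else data.frame(),
      nhc = if (length(nhc)) do.call(rbind, nhc) else data.frame(),
      replicates = do.call(rbind, reps),
      nEffective = eff, nAttempts = attempt, config = unclass(config))
}

setMethod("show", "ExperimentResult", function(object) {
  cat(sprintf("ExperimentResult: %d effective replicate(s) from %d attempt(s)\n",
              object@nEffective, object@nAttempts))
})

.se <- function(x) sd(x) / sqrt(length(x))

#' Summaries of a replicated experiment
#'
#' \code{nhcSummary()}: mean and empirical SE of nhc accuracy, regression
#' slope and LD r2 per haplotype method.  \code{accuracySummary()},
#' \code{slopeSummary()}, \code{biasSummary()}: mean and SE per model, group
#' and EBV component.  \code{accuracyDistribution()}: the
#' fraction of replicates in which the genotyped-male QTL-EBV accuracy
#' exceeds a threshold, per MABLUP method.
#'
#' @param x an [ExperimentResult-class].
#' @export
nhcSummary <- function(x) {
  ag <- aggregate(cbind(accuracy, slope, r2) ~ method, data = x@nhc, FUN = mean)
  se <- aggregate(cbind(accuracy, slope, r2) ~ method, data = x@nhc, FUN = .se)
  names(se)[-1] <- paste0(names(se)[-1], "SE")
  merge(ag, se, by = "method")
}

.statSummary <- function(x, stat) {
  d <- x@models[, c("model", "group", "component", stat)]
  names(d)[4] <- "value"
  ag <- aggregate(value ~ model + group + component, data = d, FUN = mean)
  se <- aggregate(value ~ model + group + component, data = d, FUN = .se)
  names(ag)[4] <- stat; names(se)[4] <- paste0(stat, "SE")
  merge(ag, se, by = c("model", "group", "component"))
}

#' @rdname nhcSummary
#' @export
accuracySummary <- function(x) .statSummary(x, "accuracy")

#' @rdname nhcSummary
#' @export
slopeSummary <- function(x) .statSummary(x, "slope")

#' @rdname nhcSummary
#' @export
biasSummary <- function(x) .statSummary(x, "bias")

#' @param threshold accuracy threshold (default 0.80).
#' @rdname nhcSummary
#' @export
accuracyDistribution <- function(x, threshold = 0.80) {
  d <- x@models[x@models$group == "genotypedMales" &
                x@models$component == "qtl", ]
  aggregate(accuracy ~ model, data = d,
            FUN = function(a) mean(a > threshold))
}

#' Pull one summary cell
#'
#' Convenience accessor: the mean of one statistic for one model, group and
#' component across replicates.
#'
#' @param x an [ExperimentResult-class].
#' @param model,group,component row selector.
#' @param stat \code{"accuracy"}, \code{"slope"} or \code{"bias"}.
#' @export
statOf <- function(x, model, group, component, stat = "accuracy") {
  d <- x@models
  mean(d[d$model == model & d$group == group & d$component == component, stat])
}

#' Write the experiment summary tables to CSV files
#'
#' Writes \code{nhc_summary.csv}, \code{accuracy.csv}, \code{slopes.csv},
#' \code{bias.csv}, \code{r2_distribution.csv} (per-replicate r2 values) and
#' \code{accuracy_distribution.csv} into \code{dir}.
#'
#' @param x an [ExperimentResult-class].
#' @param dir output directory.
#' @export
writeExperiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(nhcSummary(x), file.path(dir, "nhc_summary.csv"), row.names = FALSE)
  write.csv(accuracySummary(x), file.path(dir, "accuracy.csv"), row.names = FALSE)
  write.csv(slopeSummary(x), file.path(dir, "slopes.csv"), row.names = FALSE)
  write.csv(biasSummary(x), file.path(dir, "bias.csv"), row.names = FALSE)
  write.csv(x@nhc[, c("replicate", "method", "r2")],
            file.path(dir, "r2_distribution.csv"), row.names = FALSE)
  write.csv(accuracyDistribution(x),
            file.path(dir, "accuracy_distribution.csv"), row.names = FALSE)
  invisible(dir)
}
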