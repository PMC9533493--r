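# Multi-trait covariance assembly, bending, microbiome-driven prediction of
# goal-trait breeding values, selection accuracy and response.

#' Assemble multi-trait covariance matrices from pairwise analyses
#'
#' Builds the genomic and residual (co)variance matrices of a trait set
#' from the posterior means of bivariate analyses: off-diagonal (i, j) is
#' the covariance posterior mean from the (i, j) pair, and diagonal (i, i)
#' is the average of trait i's variance posterior means across all pairs
#' containing it.
#'
#' @param pairwise data.frame with one row per trait pair and columns
#'   `trait1`, `trait2`, `covG`, `varG1`, `varG2`, `covE`, `varE1`,
#'   `varE2` (the output of [estimateFeatureGoalRg()] can be renamed into
#'   this shape).
#' @return a [VarianceComponents-class] (unbent; run [bendToPd()] on the
#'   slots or use [bendVarianceComponents()]).
#' @export
assembleCovariance <- function(pairwise) {
  need <- c("trait1", "trait2", "covG", "varG1", "varG2",
            "covE", "varE1", "varE2")
  miss <- setdiff(need, names(pairwise))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  traits <- unique(c(pairwise$trait1, pairwise$trait2))
  TT <- length(traits)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  seen <- key(pairwise$trait1, pairwise$trait2)
  if (anyDuplicated(seen)) stop("duplicated trait pair(s)")
  if (TT > 1) {
    allPairs <- utils::combn(sort(traits), 2)
    missing <- apply(allPairs, 2, function(p) !key(p[1], p[2]) %in% seen)
    if (any(missing)) {
      stop("missing pair(s): ",
           paste(apply(allPairs[, missing, drop = FALSE], 2, paste,
                       collapse = "/"), collapse = ", "))
    }
  }
  build <- function(covCol, v1Col, v2Col) {
    M <- matrix(0, TT, TT, dimnames = list(traits, traits))
    vSum <- vN <- stats::setNames(numeric(TT), traits)
    for (r in seq_len(nrow(pairwise))) {
      t1 <- pairwise$trait1[r]; t2 <- pairwise$trait2[r]
      M[t1, t2] <- M[t2, t1] <- pairwise[[covCol]][r]
      vSum[t1] <- vSum[t1] + pairwise[[v1Col]][r]; vN[t1] <- vN[t1] + 1
      vSum[t2] <- vSum[t2] + pairwise[[v2Col]][r]; vN[t2] <- vN[t2] + 1
    }
    diag(M) <- vSum / vN
    M
  }
  new("VarianceComponents", traitIds = traits,
      sigmaG = build("covG", "varG1", "varG2"),
      sigmaE = build("covE", "varE1", "varE2"),
      bendLog = list())
}

#' Bend a symmetric matrix to positive definiteness
#'
#' Raises every eigenvalue below `tolerance` to `tolerance` and
#' reconstructs the matrix in its eigenbasis. Positive definite input (min
#' eigenvalue >= tolerance) is returned unchanged; bending is idempotent.
#'
#' @param m symmetric numeric matrix.
#' @param tolerance minimum eigenvalue after bending (default 0.001).
#' @return the bent matrix, with a change report (`attr(_, "bendReport")`:
#'   Frobenius change, min eigenvalue before/after, element-wise absolute
#'   change matrix).
#' @export
bendToPd <- function(m, tolerance = 0.001) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("input must be symmetric")
  }
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  minBefore <- min(eg$values)
  if (minBefore >= tolerance) {
    out <- m
    minAfter <- minBefore
    change <- matrix(0, nrow(m), ncol(m))
  } else {
    vals <- pmax(eg$values, tolerance)
    out <- eg$vectors %*% (vals * t(eg$vectors))
    out <- (out + t(out)) / 2
    dimnames(out) <- dimnames(m)
    minAfter <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
    change <- abs(out - m)
  }
  attr(out, "bendReport") <- list(
    frobeniusChange = sqrt(sum((out - m)^2)),
    minEigenBefore = minBefore,
    minEigenAfter = minAfter,
    elementChange = change
  )
  out
}

#' Bend both matrices of a VarianceComponents object
#'
#' @param vc a [VarianceComponents-class].
#' @param tolerance minimum eigenvalue (default 0.001).
#' @return the bent [VarianceComponents-class] with the bending log filled.
#' @export
bendVarianceComponents <- function(vc, tolerance = 0.001) {
  stopifnot(is(vc, "VarianceComponents"))
  g <- bendToPd(vc@sigmaG, tolerance)
  e <- bendToPd(vc@sigmaE, tolerance)
  new("VarianceComponents", traitIds = vc@traitIds,
      sigmaG = matrix(g, nrow(g), dimnames = dimnames(vc@sigmaG)),
      sigmaE = matrix(e, nrow(e), dimnames = dimnames(vc@sigmaE)),
      bendLog = list(sigmaG = attr(g, "bendReport"),
                     sigmaE = attr(e, "bendReport")))
}

#' Accuracy of an estimated breeding value
#'
#' `accuracy_i = sqrt(1 - sd_i^2 / (g_ii * sigma2_g))`, where `sd_i` is the
#' posterior standard deviation of animal i's genomic value, `g_ii` its
#' genomic relationship matrix diagonal and `sigma2_g` the trait's genomic
#' variance. Values with `sd_i^2 > g_ii * sigma2_g` (Monte Carlo noise) are
#' clamped to 0 with a warning.
#'
#' @param sdI posterior standard deviation(s) of the genomic value.
#' @param gII GRM diagonal element(s).
#' @param sigma2G genomic variance of the trait.
#' @return accuracies in \[0, 1\].
#' @export
ebvAccuracy <- function(sdI, gII, sigma2G) {
  stopifnot(sigma2G > 0, all(gII > 0))
  ratio <- sdI^2 / (gII * sigma2G)
  if (any(ratio > 1 + 1e-9)) {
    warning("posterior sd exceeds prior sd for ", sum(ratio > 1 + 1e-9),
            " animal(s): accuracy clamped to 0")
  }
  sqrt(pmax(0, 1 - pmin(ratio, 1)))
}

#' Predict goal-trait breeding values from microbiome features
#'
#' Runs the fixed-variance multivariate GBLUP Gibbs sampler on the selected
#' features plus the goal traits, with the goal phenotypes set to missing
#' (`goalsMissing = TRUE`, the microbiome-driven scenario) or observed (the
#' benchmark scenario, in which each goal is analysed univariately from its
#' own records). Returns per-animal posterior means and sds of the goal
#' EBVs and their accuracies.
#'
#' @param featureData a [LogRatioTable-class] of the selected features
#'   (animals x features, GRM order).
#' @param goals data.frame of goal-trait phenotypes (`animal`, `level`,
#'   trait columns).
#' @param goalCols goal trait ids (default `c("N3", "CLA")`).
#' @param grm a [Grm-class].
#' @param vc a bent [VarianceComponents-class] covering features + goals.
#' @param fixedFactor systematic-effect factor.
#' @param config an [mcmcConfig()].
#' @param goalsMissing predict goals from features alone (default `TRUE`).
#' @return list with `ebv` (data.frame: animal, trait, ebv, ebvSd,
#'   accuracy) and `chain` (the [PosteriorChain-class], with EBV draws
#'   stored for the goal traits).
#' @export
predictGoalEbvs <- function(featureData, goals, goalCols = c("N3", "CLA"),
                            grm, vc, fixedFactor, config = mcmcConfig(),
                            goalsMissing = TRUE) {
  stopifnot(is(featureData, "LogRatioTable"), is(grm, "Grm"),
            is(vc, "VarianceComponents"))
  feats <- featureIds(featureData)
  traits <- c(feats, goalCols)
  if (!all(traits %in% vc@traitIds)) {
    stop("variance components do not cover all features and goals")
  }
  sg <- vc@sigmaG[traits, traits, drop = FALSE]
  se <- vc@sigmaE[traits, traits, drop = FALSE]
  if (min(eigen(sg, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(se, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("variance components are not positive definite: bend first")
  }
  Y <- cbind(featureData@values[, feats, drop = FALSE],
             as.matrix(goals[, goalCols, drop = FALSE]))
  colnames(Y) <- traits
  if (goalsMissing) Y[, goalCols] <- NA_real_
  chain <- gibbsGblup(Y, fixedFactor, grm, config,
                      fixedVariance = list(sigmaG = sg, sigmaE = se),
                      storeEbvTraits = goalCols)
  m <- chain@model
  gII <- diag(grm@values)
  ebv <- do.call(rbind, lapply(goalCols, function(t) {
    data.frame(animal = chain@animalIds, trait = t,
               ebv = m$ebvMean[, t], ebvSd = m$ebvSd[, t],
               accuracy = ebvAccuracy(m$ebvSd[, t], gII, sg[t, t]),
               stringsAsFactors = FALSE)
  }))
  rownames(ebv) <- NULL
  list(ebv = ebv, chain = chain)
}

#' Rank animals on an equal-weight aggregate index
#'
#' Ranks animals by the descending sum of their goal-trait EBV posterior
#' means (equal economic weights); ties are broken by animal id so the
#' ranking is stable under input reordering.
#'
#' @param ebv data.frame with columns `animal`, `trait`, `ebv` (e.g. from
#'   [predictGoalEbvs()]).
#' @param goalCols traits to aggregate (default: all present).
#' @return data.frame `animal`, `aggregate`, `rank`, ordered best first.
#' @export
aggregateRank <- function(ebv, goalCols = unique(ebv$trait)) {
  sub <- ebv[ebv$trait %in% goalCols, ]
  agg <- tapply(sub$ebv, sub$animal, sum)
  miss <- setdiff(goalCols, unique(sub$trait))
  if (length(miss)) stop("missing goal EBVs: ", paste(miss, collapse = ", "))
  out <- data.frame(animal = names(agg), aggregate = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$aggregate, out$animal), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Truncation selection intensity
#'
#' Infinite-population intensity of selecting the best fraction `p`:
#' `i = phi(z) / p` with `z` the standard normal upper-p quantile. `p = 1`
#' returns 0 (no selection).
#'
#' @param p proportion selected, in (0, 1].
#' @return the selection intensity (mean standardized superiority of the
#'   selected fraction).
#' @export
selectionIntensity <- function(p) {
  if (any(p <= 0 | p > 1)) stop("'p' must lie in (0, 1]")
  ifelse(p == 1, 0, stats::dnorm(stats::qnorm(1 - p)) / p)
}

#' Posterior response to selection
#'
#' For each stored draw of the EBV chain, the response is the mean breeding
#' value of the selected animals minus the mean of all animals, divided by
#' the phenotypic standard deviation of the trait. Selection keeps the top
#' `round(p * n)` animals of the supplied aggregate ranking. The same
#' computation applied to a trait not in the index (e.g. methane) gives its
#' correlated response.
#'
#' @param chain a [PosteriorChain-class] with EBV draws stored for `trait`.
#' @param ranking output of [aggregateRank()] (or any data.frame with
#'   `animal` ordered best first).
#' @param p proportion selected.
#' @param phenotypicSd phenotypic standard deviation used to standardize
#'   the response (pre-corrected scale).
#' @param trait trait whose response is evaluated.
#' @return list with `mean`, `sd` (posterior moments of the standardized
#'   response), `selected` (animal ids) and `intensity` (`selectionIntensity(p)`).
#' @export
responseToSelection <- function(chain, ranking, p, phenotypicSd,
                                trait = chain@ebvTraits[1]) {
  stopifnot(is(chain, "PosteriorChain"), phenotypicSd > 0)
  if (!trait %in% chain@ebvTraits) {
    stop("no stored EBV draws for trait ", trait)
  }
  nSel <- round(p * nrow(ranking))
  if (nSel < 1) stop("empty selected set")
  sel <- ranking$animal[seq_len(nSel)]
  idx <- match(sel, chain@animalIds)
  if (anyNA(idx)) stop("ranking contains unknown animals")
  Dr <- chain@ebvDraws[[trait]]
  resp <- (rowMeans(Dr[, idx, drop = FALSE]) - rowMeans(Dr)) / phenotypicSd
  list(mean = mean(resp), sd = stats::sd(resp), selected = sel,
       intensity = selectionIntensity(p), draws = resp)
}

#' Selection report across intensities
#'
#' Evaluates [responseToSelection()] for the study's grid of selected
#' proportions and each requested trait.
#'
#' @param chain a [PosteriorChain-class] with stored EBV draws.
#' @param ranking output of [aggregateRank()].
#' @param phenotypicSd named vector of phenotypic sds per trait.
#' @param proportions selected fractions (default
#'   `c(0.40, 0.30, 0.20, 0.10, 0.05)`).
#' @param traits traits to report (default: all with stored draws).
#' @return data.frame: `proportion`, `intensity`, `trait`, `responseMean`,
#'   `responseSd`.
#' @export
selectionReport <- function(chain, ranking, phenotypicSd,
                            proportions = c(0.40, 0.30, 0.20, 0.10, 0.05),
                            traits = chain@ebvTraits) {
  rows <- list()
  for (p in proportions) {
    for (t in traits) {
      r <- responseToSelection(chain, ranking, p, phenotypicSd[[t]], t)
      rows[[paste(p, t)]] <- data.frame(
        proportion = p, intensity = r$intensity, trait = t,
        responseMean = r$mean, responseSd = r$sd)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
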