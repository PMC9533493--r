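# Screening of host-genomically influenced features (HGFC) and of features
# genomically correlated with the goal traits.

#' FDR-controlling Bayes factor threshold
#'
#' Controls the Bayesian false discovery rate of the rejection set
#' `{BF >= t}`: the estimated FDR of a set is the average posterior null
#' probability `pi0 / (pi0 + (1 - pi0) * BF_i)` over its members, and the
#' returned threshold is the smallest observed Bayes factor `t` whose
#' rejection set keeps that average at or below `alpha` (`+Inf` when no set
#' qualifies). The null proportion `pi0` is bounded from the sample mean of
#' the observed Bayes factors: a Bayes factor has unit expectation under the
#' null, so the average evidence across features caps the plausible null
#' fraction at `min(1, 1 / mean(BF))`; a fully conservative `pi0 = 1` (or
#' any fixed value) can be supplied instead.
#'
#' @param bfs vector of positive Bayes factors.
#' @param alpha target Bayesian FDR (default 1e-4).
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return list with `threshold`, `pi0`, and the per-feature posterior null
#'   probabilities `nullProb`.
#' @export
wenBfThreshold <- function(bfs, alpha = 1e-4, pi0 = NULL) {
  if (!length(bfs)) stop("empty Bayes factor vector")
  if (any(!is.finite(bfs) & bfs < 0) || any(bfs <= 0)) {
    stop("Bayes factors must be positive")
  }
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(pi0)) pi0 <- min(1, 1 / mean(bfs))
  nullProb <- pi0 / (pi0 + (1 - pi0) * bfs)
  ord <- order(bfs, decreasing = TRUE)
  cumFdr <- cumsum(nullProb[ord]) / seq_along(ord)
  ok <- which(cumFdr <= alpha)
  threshold <- if (length(ok)) bfs[ord][max(ok)] else Inf
  list(threshold = threshold, pi0 = pi0, nullProb = nullProb)
}

#' HGFC classification rule
#'
#' A feature is part of the host-genomically influenced functional core
#' (HGFC) when the DIC of the genomic model is at least `-dicCut` points
#' below the reduced model's AND its Bayes factor reaches the threshold:
#' `dicDiff < dicCut & bf >= bfThreshold`.
#'
#' @param dicDiff DIC(full) - DIC(reduced); negative favours the genomic
#'   model.
#' @param bf Bayes factor of the genomic over the reduced model.
#' @param bfThreshold Bayes factor threshold (e.g. from
#'   [wenBfThreshold()]; the study's value is 14.5).
#' @param dicCut DIC difference cut-off (default -20).
#' @return logical vector.
#' @export
classifyHgfc <- function(dicDiff, bf, bfThreshold, dicCut = -20) {
  (dicDiff < dicCut) & (bf >= bfThreshold)
}

#' Screen features for host-genomic influence
#'
#' Fits, for every feature, a univariate GBLUP animal model with and
#' without the genomic effect, and derives the heritability posterior
#' (mean + HPD95), the DIC difference, the Bayes factor, and the HGFC flag
#' using [wenBfThreshold()] across features and [classifyHgfc()].
#' Per-feature sampler seeds are derived from `config$seed` and the feature
#' id, so single features are independently reproducible.
#'
#' @param features a [LogRatioTable-class] (animals x features, aligned
#'   with the GRM).
#' @param fixedFactor systematic-effect factor, one level per animal.
#' @param grm a [Grm-class].
#' @param config an [mcmcConfig()].
#' @param alpha Bayesian FDR level for the Bayes factor threshold.
#' @param dicCut DIC difference cut-off (default -20).
#' @param pi0 optional fixed null proportion for [wenBfThreshold()].
#' @param bfThreshold optional fixed Bayes factor threshold (e.g. the
#'   study-style 14.5) overriding the FDR-derived one.
#' @return data.frame with one row per feature: `feature`, `h2`,
#'   `h2HpdLower`, `h2HpdUpper`, `dicDiff`, `bf`, `hgfc`; the Bayes factor
#'   threshold and `pi0` are attached as attributes.
#' @export
screenFeatures <- function(features, fixedFactor, grm,
                           config = mcmcConfig(), alpha = 1e-4,
                           dicCut = -20, pi0 = NULL, bfThreshold = NULL) {
  stopifnot(is(features, "LogRatioTable"), is(grm, "Grm"))
  V <- features@values
  ebv <- matrix(NA_real_, nrow(V), ncol(V),
                dimnames = list(rownames(grm@values), colnames(V)))
  rows <- lapply(colnames(V), function(f) {
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, "screen", f)
    full <- gibbsGblup(V[, f], fixedFactor, grm, cfg, includeGenomic = TRUE)
    cfg$seed <- deriveSeed(config$seed, "screen-reduced", f)
    red <- gibbsGblup(V[, f], fixedFactor, grm = NULL, cfg,
                      includeGenomic = FALSE)
    ebv[, f] <<- full@model$ebvMean[, 1]
    h2d <- heritabilityDraws(full)
    hpd <- hpdInterval(h2d)
    data.frame(
      feature = f,
      h2 = mean(h2d), h2HpdLower = hpd[["lower"]], h2HpdUpper = hpd[["upper"]],
      dicDiff = dic(full)$dic - dic(red)$dic,
      bf = bayesFactor(full, red),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "ebv") <- ebv
  if (is.null(bfThreshold)) {
    wen <- wenBfThreshold(out$bf, alpha = alpha, pi0 = pi0)
    bfThreshold <- wen$threshold
    attr(out, "pi0") <- wen$pi0
  }
  out$hgfc <- classifyHgfc(out$dicDiff, out$bf, bfThreshold, dicCut)
  attr(out, "bfThreshold") <- bfThreshold
  out
}

#' Estimate genomic correlations of features with goal traits
#'
#' Fits a bivariate GBLUP model for every feature x goal-trait pair and
#' summarizes the genomic correlation (posterior mean, HPD95, P0).
#'
#' @param features a [LogRatioTable-class].
#' @param goals data.frame of goal traits (columns beyond `animal`/`level`
#'   are traits), aligned with the GRM animal order.
#' @param fixedFactor systematic-effect factor.
#' @param grm a [Grm-class].
#' @param config an [mcmcConfig()].
#' @param goalCols goal trait columns to use (default: all non-id columns).
#' @return data.frame with one row per feature x goal: `feature`, `goal`,
#'   `rg`, `rgHpdLower`, `rgHpdUpper`, `p0`, plus genomic/residual
#'   (co)variance posterior means for downstream covariance assembly.
#' @export
estimateFeatureGoalRg <- function(features, goals, fixedFactor, grm,
                                  config = mcmcConfig(),
                                  goalCols = setdiff(names(goals),
                                                     c("animal", "level"))) {
  stopifnot(is(features, "LogRatioTable"), is(grm, "Grm"))
  V <- features@values
  rows <- list()
  for (f in colnames(V)) {
    for (g in goalCols) {
      cfg <- config
      cfg$seed <- deriveSeed(config$seed, "rg", f, g)
      Y <- cbind(V[, f], goals[[g]])
      colnames(Y) <- c(f, g)
      ch <- gibbsGblup(Y, fixedFactor, grm, cfg)
      rgd <- genomicCorrelationDraws(ch, c(f, g))
      hpd <- hpdInterval(rgd)
      m <- mean(rgd)
      rows[[paste(f, g)]] <- data.frame(
        feature = f, goal = g, rg = m,
        rgHpdLower = hpd[["lower"]], rgHpdUpper = hpd[["upper"]],
        p0 = if (m >= 0) mean(rgd > 0) else mean(rgd < 0),
        covG = mean(.vcDraws(ch, "sigmaG", f, g)),
        varG1 = mean(.vcDraws(ch, "sigmaG", f)),
        varG2 = mean(.vcDraws(ch, "sigmaG", g)),
        covE = mean(.vcDraws(ch, "sigmaE", f, g)),
        varE1 = mean(.vcDraws(ch, "sigmaE", f)),
        varE2 = mean(.vcDraws(ch, "sigmaE", g)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag features significantly correlated with the goal traits
#'
#' Applies the `P0 >= p0Cut` significance rule per goal and, among features
#' significant for at least one goal, flags those whose posterior-mean
#' genomic correlations with N3 and CLA share the same sign (the candidate
#' set for simultaneous improvement of both indices).
#'
#' @param rgTable output of [estimateFeatureGoalRg()] (or any data.frame
#'   with `feature`, `goal`, `rg`, `p0`).
#' @param goals the two goal trait ids to compare (default `c("N3",
#'   "CLA")`).
#' @param p0Cut significance cut-off on P0 (default 0.95).
#' @return data.frame with one row per feature: per-goal rg/P0/significance
#'   flags, `sigAny`, `sigBoth` and `sameSign`; counts are attached as
#'   attribute `"counts"`.
#' @export
screenCorrelations <- function(rgTable, goals = c("N3", "CLA"),
                               p0Cut = 0.95) {
  need <- c("feature", "goal", "rg", "p0")
  if (!all(need %in% names(rgTable))) {
    stop("rgTable must contain ", paste(need, collapse = ", "))
  }
  if (!all(goals %in% rgTable$goal)) {
    stop("missing goal summaries: ",
         paste(setdiff(goals, rgTable$goal), collapse = ", "))
  }
  feats <- unique(rgTable$feature)
  cols <- lapply(goals, function(g) {
    sub <- rgTable[rgTable$goal == g, ]
    idx <- match(feats, sub$feature)
    if (anyNA(idx)) stop("missing goal summaries for some features")
    data.frame(rg = sub$rg[idx], p0 = sub$p0[idx], sig = sub$p0[idx] >= p0Cut)
  })
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (i in seq_along(goals)) {
    out[[paste0("rg", goals[i])]] <- cols[[i]]$rg
    out[[paste0("p0", goals[i])]] <- cols[[i]]$p0
    out[[paste0("sig", goals[i])]] <- cols[[i]]$sig
  }
  out$sigAny <- Reduce(`|`, lapply(cols, `[[`, "sig"))
  out$sigBoth <- Reduce(`&`, lapply(cols, `[[`, "sig"))
  out$sameSign <- out$sigAny &
    sign(cols[[1]]$rg) == sign(cols[[2]]$rg)
  attr(out, "counts") <- c(
    stats::setNames(vapply(cols, function(cc) sum(cc$sig), integer(1)),
                    paste0("sig", goals)),
    sigAny = sum(out$sigAny), sigBoth = sum(out$sigBoth),
    sameSign = sum(out$sameSign))
  out
}
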