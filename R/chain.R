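# Posterior-chain post-processing: derived parameters, summaries, DIC and
# Bayes factors.

# pull a (co)variance entry from the stored draws
.vcDraws <- function(chain, which, t1, t2 = t1) {
  nm1 <- sprintf("%s[%s,%s]", which, t2, t1)
  nm2 <- sprintf("%s[%s,%s]", which, t1, t2)
  cols <- colnames(chain@draws)
  nm <- if (nm1 %in% cols) nm1 else nm2
  if (!nm %in% cols) stop(sprintf("no stored draws for %s(%s, %s)",
                                  which, t1, t2))
  chain@draws[, nm]
}

#' Per-draw heritability
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` evaluated draw by draw.
#'
#' @param chain a sampled-variance [PosteriorChain-class] with a genomic
#'   effect.
#' @param trait trait id (default: first trait).
#' @return numeric vector of draws in \[0, 1\].
#' @export
heritabilityDraws <- function(chain, trait = traitIds(chain)[1]) {
  stopifnot(is(chain, "PosteriorChain"))
  if (isTRUE(chain@model$fixedVariance)) {
    stop("heritability draws are undefined for a fixed-variance chain")
  }
  if (!isTRUE(chain@model$includeGenomic)) {
    stop("the chain has no genomic effect")
  }
  sg <- .vcDraws(chain, "sigmaG", trait)
  se <- .vcDraws(chain, "sigmaE", trait)
  sg / (sg + se)
}

#' Per-draw genomic correlation
#'
#' `rg = sigma_g12 / sqrt(sigma2_g1 * sigma2_g2)` evaluated draw by draw;
#' positive definiteness of the sampled covariance matrices keeps every draw
#' in (-1, 1).
#'
#' @param chain a bivariate-or-larger sampled-variance
#'   [PosteriorChain-class].
#' @param traitPair character vector of two trait ids (default: first two).
#' @return numeric vector of draws.
#' @export
genomicCorrelationDraws <- function(chain,
                                    traitPair = traitIds(chain)[1:2]) {
  stopifnot(is(chain, "PosteriorChain"), length(traitPair) == 2)
  if (isTRUE(chain@model$fixedVariance)) {
    stop("correlation draws are undefined for a fixed-variance chain")
  }
  c12 <- .vcDraws(chain, "sigmaG", traitPair[1], traitPair[2])
  v1 <- .vcDraws(chain, "sigmaG", traitPair[1])
  v2 <- .vcDraws(chain, "sigmaG", traitPair[2])
  c12 / sqrt(v1 * v2)
}

# summary statistics for one vector of draws
.summarizeDraws <- function(x) {
  hpd <- hpdInterval(x)
  m <- mean(x)
  frac <- if (m >= 0) mean(x > 0) else mean(x < 0)
  z <- suppressWarnings(gewekeZ(x))
  mce <- mcError(x)
  c(mean = m, sd = stats::sd(x), hpdLower = hpd[["lower"]],
    hpdUpper = hpd[["upper"]], p0 = frac, gewekeZ = z, mcError = mce)
}

#' Posterior summary of a chain
#'
#' For every stored parameter plus derived heritabilities (and genomic
#' correlations for multi-trait sampled-variance chains): posterior mean and
#' sd, shortest 95% highest posterior density interval, P0 (posterior
#' probability of sharing the sign of the posterior mean), Geweke
#' convergence Z (first 10% vs last 50% of the chain, spectral variances)
#' and the batch-means Monte Carlo standard error. Parameters whose Monte
#' Carlo error exceeds a tenth of the posterior sd are flagged.
#'
#' @param chain a [PosteriorChain-class] with at least 50 stored draws.
#' @param params optional subset of parameter names.
#' @return data.frame with one row per parameter.
#' @export
summarizeChain <- function(chain, params = NULL) {
  stopifnot(is(chain, "PosteriorChain"))
  if (nrow(chain@draws) < 50) stop("need at least 50 stored draws")
  D <- chain@draws
  extras <- list()
  if (!isTRUE(chain@model$fixedVariance) &&
      isTRUE(chain@model$includeGenomic)) {
    for (t in chain@traitIds) {
      extras[[paste0("h2[", t, "]")]] <- heritabilityDraws(chain, t)
    }
    tr <- chain@traitIds
    if (length(tr) > 1) {
      for (i in seq_len(length(tr) - 1)) {
        for (j in (i + 1):length(tr)) {
          extras[[sprintf("rg[%s,%s]", tr[i], tr[j])]] <-
            genomicCorrelationDraws(chain, c(tr[i], tr[j]))
        }
      }
    }
  }
  M <- cbind(D, do.call(cbind, c(extras, list(deparse.level = 0))))
  if (length(extras)) {
    colnames(M) <- c(colnames(D), names(extras))
  }
  if (!is.null(params)) M <- M[, intersect(params, colnames(M)), drop = FALSE]
  stats <- t(apply(M, 2, .summarizeDraws))
  out <- data.frame(parameter = rownames(stats), stats, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$mcFlag <- !is.na(out$mcError) & out$mcError * 10 > out$sd
  if (chain@model$boundHits > 0) {
    attr(out, "boundHits") <- chain@model$boundHits
  }
  out
}

#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `Dbar` the posterior mean of the deviance
#' (-2 x log-likelihood of the observed phenotypes conditional on the
#' location parameters and the residual covariance) and
#' `pD = Dbar - D(thetaBar)`, the deviance evaluated at the posterior means
#' of the fixed effects, breeding values and residual covariance.
#'
#' @param chain a [PosteriorChain-class] carrying per-draw log-likelihoods.
#' @return list with `dic`, `pD`, `meanDeviance`.
#' @export
dic <- function(chain) {
  stopifnot(is(chain, "PosteriorChain"))
  if (!length(chain@logLik)) stop("chain carries no log-likelihood draws")
  dBar <- mean(-2 * chain@logLik)
  m <- chain@model
  Mu <- m$X %*% m$bMean + m$ebvMean
  patterns <- .missPatterns(m$observedMask)
  dHat <- -2 * .condLogLik(m$Y, Mu, m$sigmaEMean, m$observedMask, patterns)
  pD <- dBar - dHat
  list(dic = dBar + pD, pD = pD, meanDeviance = dBar)
}

#' Bayes factor from posterior likelihood draws
#'
#' Compares two models fitted to the same data through their per-draw
#' likelihoods with breeding values integrated out. The default estimator is
#' the ratio of the arithmetic means of the per-draw likelihoods (computed
#' in log space with log-sum-exp); the Newton-Raftery harmonic-mean
#' estimator of the marginal likelihood is available as an alternative.
#'
#' @param chainFull,chainReduced [PosteriorChain-class] objects fitted to
#'   the same observed data.
#' @param estimator `"posterior-mean-likelihood"` (default) or
#'   `"harmonic-mean"`.
#' @return the Bayes factor (full over reduced), a positive scalar.
#' @export
bayesFactor <- function(chainFull, chainReduced,
                        estimator = c("posterior-mean-likelihood",
                                      "harmonic-mean")) {
  estimator <- match.arg(estimator)
  for (ch in list(chainFull, chainReduced)) {
    if (!isTRUE(ch@model$marginalAvailable)) {
      stop("marginal likelihood draws unavailable (chain fitted with ",
           "missing phenotypes)")
    }
  }
  llF <- chainFull@logLikMarginal
  llR <- chainReduced@logLikMarginal
  logML <- function(ll) {
    if (estimator == "posterior-mean-likelihood") {
      logSumExp(ll) - log(length(ll))
    } else {
      log(length(ll)) - logSumExp(-ll)
    }
  }
  exp(logML(llF) - logML(llR))
}

#' Extract posterior means and sds of breeding values
#'
#' @param chain a [PosteriorChain-class].
#' @return data.frame with columns `animal`, `trait`, `ebv`, `ebvSd`.
#' @export
ebvSummary <- function(chain) {
  stopifnot(is(chain, "PosteriorChain"))
  m <- chain@model
  data.frame(
    animal = rep(chain@animalIds, length(chain@traitIds)),
    trait = rep(chain@traitIds, each = length(chain@animalIds)),
    ebv = as.vector(m$ebvMean),
    ebvSd = as.vector(m$ebvSd),
    stringsAsFactors = FALSE
  )
}
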