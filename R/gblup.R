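# Gibbs samplers for Gaussian animal models with a GRM-distributed genomic
# effect: univariate to multivariate, flat (bounded) priors, missing-trait
# augmentation, optional fixed variance components.
#
# The sampler works in the eigenbasis of the GRM: with G = Q L Q' and
# rotated breeding values u~ = Q'u, the prior of each rotated row is
# independent with variance L_r * SigmaG, and rotated residuals stay iid.
# Trait space is simultaneously diagonalized against SigmaE and SigmaG, so
# the full conditional of the breeding values factorizes into elementwise
# Gaussian updates (no per-animal solves).

#' MCMC configuration
#'
#' Desk-scale defaults (20,000 iterations, 4,000 burn-in, thinning 4) keep a
#' univariate chain to a few seconds while leaving ~4,000 stored draws.
#' Long-chain settings in the style of the study (1,000,000 / 200,000 / 100)
#' can be requested explicitly.
#'
#' @param nIter total iterations.
#' @param burnIn burn-in iterations discarded (must be < `nIter`).
#' @param thin keep one stored draw per `thin` post burn-in iterations.
#' @param seed integer seed for the sampler.
#' @param boundFactors lower/upper bounds on sampled variances as multiples
#'   of the data variance; draws outside are rejected and redrawn.
#' @return list of class `mcmcConfig`.
#' @export
mcmcConfig <- function(nIter = 20000, burnIn = 4000, thin = 4, seed = 1L,
                       boundFactors = c(1e-8, 1e8)) {
  stopifnot(burnIn < nIter, thin >= 1, nIter > 0)
  structure(list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                 thin = as.integer(thin), seed = as.integer(seed),
                 boundFactors = boundFactors),
            class = "mcmcConfig")
}

# simultaneous diagonalization of (SigmaE, SigmaG):
# returns V with V' SigmaE^-1 V = I and V' SigmaG^-1 V = diag(d);
# Vinv = P' K^-1 and KinvP = K^-T P fall out of the construction, and
# |det V| = prod(diag(chol(SigmaE))) since the rotation has unit determinant
.traitTransform <- function(sigmaG, sigmaE) {
  if (nrow(sigmaE) == 2) return(.traitTransform2(sigmaG, sigmaE))
  K <- t(chol(sigmaE))
  A <- crossprod(K, solve(sigmaG, K))
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  P <- eg$vectors
  Kinv <- forwardsolve(K, diag(nrow(K)))
  list(V = K %*% P, d = pmax(eg$values, .Machine$double.eps),
       Vinv = crossprod(P, Kinv), KinvP = crossprod(Kinv, P),
       absDetV = prod(diag(K)))
}

# closed-form bivariate version (no chol/solve/eigen calls in the sampler's
# hot loop)
.traitTransform2 <- function(sigmaG, sigmaE) {
  a <- sigmaE[1, 1]; b <- sigmaE[2, 1]; cc <- sigmaE[2, 2]
  K11 <- sqrt(a); K21 <- b / K11; K22 <- sqrt(cc - K21 * K21)
  Ki11 <- 1 / K11; Ki21 <- -K21 / (K11 * K22); Ki22 <- 1 / K22
  d1 <- sigmaG[1, 1]; e1 <- sigmaG[2, 1]; f1 <- sigmaG[2, 2]
  detg <- d1 * f1 - e1 * e1
  g11 <- f1 / detg; g12 <- -e1 / detg; g22 <- d1 / detg
  # A = K' Ginv K
  m11 <- g11 * K11 + g12 * K21; m12 <- g12 * K22
  m21 <- g12 * K11 + g22 * K21; m22 <- g22 * K22
  A11 <- K11 * m11 + K21 * m21
  A21 <- K22 * m21
  A22 <- K22 * m22
  tr2 <- (A11 + A22) / 2
  disc <- sqrt(((A11 - A22) / 2)^2 + A21 * A21)
  l1 <- tr2 + disc; l2 <- tr2 - disc
  if (abs(A21) < 1e-14) {
    if (A11 >= A22) { p11 <- 1; p21 <- 0 } else { p11 <- 0; p21 <- 1 }
  } else {
    nv <- sqrt(A21 * A21 + (l1 - A11)^2)
    p11 <- A21 / nv; p21 <- (l1 - A11) / nv
  }
  P <- matrix(c(p11, p21, -p21, p11), 2, 2)
  K <- matrix(c(K11, K21, 0, K22), 2, 2)
  Kinv <- matrix(c(Ki11, Ki21, 0, Ki22), 2, 2)
  list(V = K %*% P, d = pmax(c(l1, l2), .Machine$double.eps),
       Vinv = crossprod(P, Kinv), KinvP = crossprod(Kinv, P),
       absDetV = K11 * K22)
}

# conditional log-likelihood of observed data given location parameters and
# SigmaE; Y, Mu in original space, obs = logical observation mask
.condLogLik <- function(Y, Mu, sigmaE, obs, patterns) {
  ll <- 0
  for (pt in patterns) {
    o <- pt$o
    if (!length(o)) next
    R <- (Y - Mu)[pt$rows, o, drop = FALSE]
    So <- sigmaE[o, o, drop = FALSE]
    ch <- chol(So)
    q <- sum(backsolve(ch, t(R), transpose = TRUE)^2)
    ll <- ll - 0.5 * (length(pt$rows) * (length(o) * log(2 * pi) +
                                           2 * sum(log(diag(ch)))) + q)
  }
  ll
}

# missingness pattern groups (list of rows + observed/missing index sets)
.missPatterns <- function(obs) {
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  lapply(split(seq_len(nrow(obs)), key), function(rows) {
    o <- which(obs[rows[1], ])
    list(rows = rows, o = o, m = setdiff(seq_len(ncol(obs)), o))
  })
}

#' Gibbs sampler for a (multi-trait) GBLUP animal model
#'
#' Fits `y = Xb + u + e` with a single categorical fixed factor, breeding
#' values `u ~ N(0, SigmaG (x) G)` and residuals `e ~ N(0, SigmaE (x) I)`,
#' under bounded flat priors for all unknowns: the variance-matrix full
#' conditionals are inverse-Wishart with degrees of freedom `n - T - 1`
#' (the flat-prior limit), truncated by rejection to the configured bounds.
#' Missing phenotypes are drawn from their Gaussian full conditionals each
#' iteration, so traits set entirely to `NA` are predicted from the others
#' (used with fixed variance components for microbiome-driven prediction).
#'
#' Per-draw log-likelihoods of the observed data are stored twice: given
#' location parameters (for DIC) and with breeding values integrated out
#' (for Bayes factors; complete-data chains only).
#'
#' @param Y numeric matrix (animals x traits) or vector; `NA` = missing.
#'   Rows must be aligned with the GRM animal order.
#' @param fixedFactor factor of systematic-effect levels, one per animal.
#' @param grm a [Grm-class]; ignored when `includeGenomic = FALSE`.
#' @param config an [mcmcConfig()].
#' @param includeGenomic fit the genomic effect? (`FALSE` gives the reduced
#'   model used for DIC/Bayes-factor comparisons).
#' @param fixedVariance optional `list(sigmaG =, sigmaE =)`; when supplied
#'   the variance components are held fixed and not sampled.
#' @param storeEbvTraits trait ids for which full breeding-value draws are
#'   kept (posterior means/sds are accumulated for all traits regardless).
#' @return a [PosteriorChain-class].
#' @export
gibbsGblup <- function(Y, fixedFactor, grm = NULL, config = mcmcConfig(),
                       includeGenomic = TRUE, fixedVariance = NULL,
                       storeEbvTraits = character()) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(NULL, "trait"))
  Y <- as.matrix(Y)
  n <- nrow(Y); TT <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("trait", seq_len(TT))
  traits <- colnames(Y)
  fixedFactor <- droplevels(as.factor(fixedFactor))
  if (length(fixedFactor) != n) stop("one fixed-factor level per animal")
  fixedVar <- !is.null(fixedVariance)
  obs <- !is.na(Y)
  if (!fixedVar && any(colSums(obs) < 2)) {
    stop("each trait needs >= 2 observations unless variances are fixed")
  }
  aIds <- rownames(Y)
  if (includeGenomic) {
    stopifnot(is(grm, "Grm"))
    G <- grm@values
    if (nrow(G) != n) stop("GRM and phenotypes disagree on animal count")
    if (is.null(aIds)) aIds <- rownames(G)
    eg <- eigen(G, symmetric = TRUE)
    if (min(eg$values) <= 0) {
      stop("GRM is not positive definite; increase the ridge")
    }
    Q <- eg$vectors; lam <- eg$values
  }
  if (is.null(aIds)) aIds <- paste0("A", seq_len(n))

  X <- stats::model.matrix(~ 0 + fixedFactor)
  colnames(X) <- levels(fixedFactor)
  k <- ncol(X)
  XtXinv <- solve(crossprod(X))
  LX <- t(chol(XtXinv))
  Xs <- if (includeGenomic) crossprod(Q, X) else X

  hasMissing <- !all(obs)
  patterns <- .missPatterns(obs)
  dataVar <- vapply(seq_len(TT), function(t) {
    y <- Y[obs[, t], t]
    if (length(y) >= 2 && stats::var(y) > 0) stats::var(y) else 1
  }, numeric(1))
  vLo <- config$boundFactors[1] * dataVar
  vHi <- config$boundFactors[2] * dataVar

  set.seed(config$seed)
  # initial values
  Yc <- Y
  for (t in seq_len(TT)) {
    m0 <- if (any(obs[, t])) mean(Y[obs[, t], t]) else 0
    Yc[!obs[, t], t] <- m0
  }
  B <- XtXinv %*% crossprod(X, Yc)
  SigmaE <- if (fixedVar) fixedVariance$sigmaE else diag(dataVar / 2, TT)
  SigmaG <- if (fixedVar) fixedVariance$sigmaG else diag(dataVar / 2, TT)
  if (fixedVar) {
    SigmaG <- as.matrix(SigmaG); SigmaE <- as.matrix(SigmaE)
    if (min(eigen(SigmaE, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
        (includeGenomic &&
         min(eigen(SigmaG, symmetric = TRUE,
                   only.values = TRUE)$values) <= 0)) {
      stop("fixed variance components must be positive definite")
    }
  }
  Ut <- matrix(0, n, TT)
  Ys <- if (includeGenomic) crossprod(Q, Yc) else Yc

  nStored <- (config$nIter - config$burnIn) %/% config$thin
  npar <- k * TT + 2 * TT * (TT + 1) / 2
  vechIdx <- which(lower.tri(diag(TT), diag = TRUE), arr.ind = TRUE)
  parNames <- c(
    as.vector(outer(levels(fixedFactor), traits,
                    function(l, t) sprintf("b[%s,%s]", l, t))),
    sprintf("sigmaG[%s,%s]", traits[vechIdx[, 2]], traits[vechIdx[, 1]]),
    sprintf("sigmaE[%s,%s]", traits[vechIdx[, 2]], traits[vechIdx[, 1]]))
  draws <- matrix(NA_real_, nStored, npar, dimnames = list(NULL, parNames))
  logLik <- numeric(nStored)
  logLikMarg <- rep(NA_real_, nStored)
  margOk <- includeGenomic && !hasMissing
  storeEbvTraits <- intersect(storeEbvTraits, traits)
  ebvDraws <- lapply(storeEbvTraits, function(t) matrix(NA_real_, nStored, n))
  names(ebvDraws) <- storeEbvTraits
  uSum <- uSq <- matrix(0, n, TT)
  bSum <- matrix(0, k, TT)
  seSum <- matrix(0, TT, TT)
  boundHits <- 0L

  tt <- if (fixedVar && includeGenomic) .traitTransform(SigmaG, SigmaE)
  # with fixed variance components the conditional of the missing block is
  # constant: precompute the regression and Cholesky per pattern
  patPre <- NULL
  if (hasMissing && fixedVar) {
    patPre <- lapply(patterns, function(pt) {
      if (!length(pt$m)) return(NULL)
      o <- pt$o; m <- pt$m
      if (length(o)) {
        W <- SigmaE[m, o, drop = FALSE] %*%
          solve(SigmaE[o, o, drop = FALSE])
        condCov <- SigmaE[m, m, drop = FALSE] -
          W %*% t(SigmaE[m, o, drop = FALSE])
      } else {
        W <- NULL
        condCov <- SigmaE[m, m, drop = FALSE]
      }
      list(W = W,
           ch = chol((condCov + t(condCov)) / 2 + diag(1e-12, length(m))))
    })
  }

  drawIW <- function(S, lo, hi) {
    df <- n - TT - 1
    for (try in 1:50) {
      W <- stats::rWishart(1, df, solve(S))[, , 1]
      Sig <- chol2inv(chol(W))
      dg <- diag(Sig)
      if (all(dg >= lo & dg <= hi)) return(list(S = (Sig + t(Sig)) / 2, hit = try - 1L))
    }
    warning("variance draw repeatedly outside bounds; keeping last draw")
    list(S = (Sig + t(Sig)) / 2, hit = 50L)
  }

  stored <- 0L
  for (iter in seq_len(config$nIter)) {
    # --- missing phenotypes ---
    if (hasMissing) {
      U <- if (includeGenomic) Q %*% Ut else Ut
      Mu <- X %*% B + U
      for (ip in seq_along(patterns)) {
        pt <- patterns[[ip]]
        if (!length(pt$m)) next
        rows <- pt$rows; o <- pt$o; m <- pt$m
        if (!is.null(patPre)) {
          W <- patPre[[ip]]$W
          condChol <- patPre[[ip]]$ch
        } else if (length(o)) {
          Soo <- SigmaE[o, o, drop = FALSE]
          Smo <- SigmaE[m, o, drop = FALSE]
          W <- Smo %*% solve(Soo)
          condCov <- SigmaE[m, m, drop = FALSE] - W %*% t(Smo)
          condChol <- chol((condCov + t(condCov)) / 2 +
                             diag(1e-12, length(m)))
        } else {
          W <- NULL
          condChol <- chol(SigmaE[m, m, drop = FALSE] +
                             diag(1e-12, length(m)))
        }
        condMean <- if (!is.null(W) && length(o)) {
          Mu[rows, m, drop = FALSE] +
            (Yc[rows, o, drop = FALSE] - Mu[rows, o, drop = FALSE]) %*% t(W)
        } else {
          Mu[rows, m, drop = FALSE]
        }
        Z <- matrix(stats::rnorm(length(rows) * length(m)),
                    length(rows), length(m))
        Yc[rows, m] <- condMean + Z %*% condChol
      }
      Ys <- if (includeGenomic) crossprod(Q, Yc) else Yc
    }

    # --- fixed effects ---
    R1 <- Ys - Ut
    Bhat <- XtXinv %*% crossprod(Xs, R1)
    B <- if (TT == 1) {
      Bhat + LX %*% stats::rnorm(k) * sqrt(SigmaE[1, 1])
    } else {
      Bhat + LX %*% matrix(stats::rnorm(k * TT), k, TT) %*% chol(SigmaE)
    }

    # --- breeding values ---
    R2 <- Ys - Xs %*% B
    if (includeGenomic) {
      if (TT == 1) {
        sg <- SigmaG[1, 1]; se <- SigmaE[1, 1]
        prec <- 1 / se + 1 / (sg * lam)
        mu <- (R2[, 1] / se) / prec
        Ut[, 1] <- mu + stats::rnorm(n) / sqrt(prec)
      } else {
        if (!fixedVar) tt <- .traitTransform(SigmaG, SigmaE)
        W <- R2 %*% tt$KinvP
        Prec <- 1 + outer(1 / lam, tt$d)
        Zm <- W / Prec + matrix(stats::rnorm(n * TT), n, TT) / sqrt(Prec)
        Ut <- Zm %*% t(tt$V)
      }
    }

    # --- variance components ---
    E2 <- R2 - Ut
    if (!fixedVar) {
      if (TT == 1) {
        Se <- sum(E2^2)
        for (try in 1:50) {
          se <- Se / stats::rchisq(1, n - 2)
          if (se >= vLo && se <= vHi) break
          boundHits <- boundHits + 1L
        }
        SigmaE[1, 1] <- se
        if (includeGenomic) {
          Sg <- sum(Ut[, 1]^2 / lam)
          for (try in 1:50) {
            sg <- Sg / stats::rchisq(1, n - 2)
            if (sg >= vLo && sg <= vHi) break
            boundHits <- boundHits + 1L
          }
          SigmaG[1, 1] <- sg
        }
      } else {
        de <- drawIW(crossprod(E2), vLo, vHi)
        SigmaE <- de$S; boundHits <- boundHits + de$hit
        if (includeGenomic) {
          dg <- drawIW(crossprod(Ut / sqrt(lam)), vLo, vHi)
          SigmaG <- dg$S; boundHits <- boundHits + dg$hit
        }
      }
    }

    # --- storage ---
    if (iter > config$burnIn &&
        (iter - config$burnIn) %% config$thin == 0) {
      stored <- stored + 1L
      draws[stored, ] <- c(B,
                           SigmaG[lower.tri(SigmaG, diag = TRUE)],
                           SigmaE[lower.tri(SigmaE, diag = TRUE)])
      U <- if (includeGenomic) Q %*% Ut else Ut
      if (hasMissing) {
        Mu <- X %*% B + U
        logLik[stored] <- .condLogLik(Y, Mu, SigmaE, obs, patterns)
      } else {
        if (TT == 1) {
          logLik[stored] <- -0.5 * (n * log(2 * pi * SigmaE[1, 1]) +
                                      sum(E2^2) / SigmaE[1, 1])
        } else {
          ch <- chol(SigmaE)
          q <- sum(backsolve(ch, t(E2), transpose = TRUE)^2)
          logLik[stored] <- -0.5 * (n * (TT * log(2 * pi) +
                                           2 * sum(log(diag(ch)))) + q)
        }
      }
      if (margOk) {
        if (TT == 1) {
          v <- SigmaG[1, 1] * lam + SigmaE[1, 1]
          logLikMarg[stored] <- -0.5 * (n * log(2 * pi) + sum(log(v)) +
                                          sum(R2[, 1]^2 / v))
        } else {
          if (fixedVar) ttm <- tt else ttm <- .traitTransform(SigmaG, SigmaE)
          H <- R2 %*% t(ttm$Vinv)
          Fac <- 1 + outer(lam, 1 / ttm$d)
          ldv2 <- 2 * log(ttm$absDetV)
          logLikMarg[stored] <- -0.5 * (n * TT * log(2 * pi) + n * ldv2 +
                                          sum(log(Fac)) + sum(H^2 / Fac))
        }
      }
      uSum <- uSum + U
      uSq <- uSq + U^2
      bSum <- bSum + B
      seSum <- seSum + SigmaE
      for (t in storeEbvTraits) {
        ebvDraws[[t]][stored, ] <- U[, match(t, traits)]
      }
    }
  }
  if (!margOk) logLikMarg <- logLik

  model <- list(
    includeGenomic = includeGenomic,
    fixedVariance = fixedVar,
    nAnimals = n, nLevels = k,
    factorLevels = levels(fixedFactor),
    dataVariance = dataVar,
    boundHits = boundHits,
    observedMask = obs,
    ebvMean = uSum / stored,
    ebvSd = sqrt(pmax(uSq / stored - (uSum / stored)^2, 0)),
    bMean = bSum / stored,
    sigmaEMean = seSum / stored,
    X = X, Y = Y,
    marginalAvailable = margOk || !includeGenomic
  )
  dimnames(model$ebvMean) <- dimnames(model$ebvSd) <- list(aIds, traits)
  new("PosteriorChain", draws = draws, logLik = logLik,
      logLikMarginal = logLikMarg, ebvDraws = ebvDraws,
      ebvTraits = storeEbvTraits, traitIds = traits, animalIds = aIds,
      config = unclass(config), model = model)
}
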