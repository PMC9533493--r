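# Gibbs sampler correctness: conjugate closed forms, an independent direct
# MME sampler, missing-data BLUP, and chain post-processing.

test_that("posterior of sigma2_e matches the conjugate closed form", {
  # model without genomic effect, flat prior on (b, sigma2):
  # marginally sigma2 | y ~ Inv-Gamma((n-k)/2 - 1, RSS/2)
  set.seed(91)
  n <- 150; k <- 5
  f <- factor(rep_len(1:k, n))
  y <- rnorm(n, mean = as.integer(f) * 0.3, sd = 1.2)
  ch <- gibbsGblup(y, f, NULL, mcmcConfig(nIter = 30000, burnIn = 5000,
                                          thin = 5, seed = 2),
                   includeGenomic = FALSE)
  se <- .subset2(as.data.frame(ch@draws), "sigmaE[trait,trait]")
  rss <- sum(lm(y ~ 0 + f)$residuals^2)
  shape <- (n - k) / 2 - 1
  postMean <- (rss / 2) / (shape - 1)
  postSd <- sqrt((rss / 2)^2 / ((shape - 1)^2 * (shape - 2)))
  mce <- mcError(se)
  expect_lt(abs(mean(se) - postMean), 3 * mce + 1e-8)
  expect_equal(sd(se), postSd, tolerance = 0.1)
})

test_that("eigen-rotated sampler agrees with a direct MME Gibbs sampler", {
  # independent oracle: naive Gibbs in the original parameterization,
  # sampling u jointly from its n x n Gaussian full conditional
  pop <- smallPop(n = 30, nSnps = 200, seed = 19, fixedLevels = 3)
  y <- pop$traits$N3
  f <- factor(pop$traits$level)
  G <- values(pop$grm)
  X <- model.matrix(~ 0 + f)
  Ginv <- solve(G)
  directGibbs <- function(nIter, burnIn, thin, seed) {
    set.seed(seed)
    n <- length(y); k <- ncol(X)
    XtXinv <- solve(crossprod(X))
    b <- XtXinv %*% crossprod(X, y)
    u <- rep(0, n); sg <- se <- var(y) / 2
    keep <- matrix(NA_real_, (nIter - burnIn) %/% thin, 2)
    s <- 0
    for (it in seq_len(nIter)) {
      bhat <- XtXinv %*% crossprod(X, y - u)
      b <- bhat + t(chol(XtXinv * se)) %*% rnorm(k)
      prec <- diag(n) / se + Ginv / sg
      ch <- chol(prec)
      mu <- backsolve(ch, backsolve(ch, (y - X %*% b) / se,
                                    transpose = TRUE))
      u <- mu + backsolve(ch, rnorm(n))
      se <- sum((y - X %*% b - u)^2) / rchisq(1, n - 2)
      sg <- c(crossprod(u, Ginv %*% u)) / rchisq(1, n - 2)
      if (it > burnIn && (it - burnIn) %% thin == 0) {
        s <- s + 1
        keep[s, ] <- c(sg, se)
      }
    }
    keep
  }
  oracle <- directGibbs(20000, 4000, 4, 5)
  ch <- gibbsGblup(y, f, pop$grm,
                   mcmcConfig(nIter = 20000, burnIn = 4000, thin = 4,
                              seed = 6))
  sgP <- .subset2(as.data.frame(ch@draws), "sigmaG[trait,trait]")
  seP <- .subset2(as.data.frame(ch@draws), "sigmaE[trait,trait]")
  tolSg <- 3 * (mcError(oracle[, 1]) + mcError(sgP))
  tolSe <- 3 * (mcError(oracle[, 2]) + mcError(seP))
  expect_lt(abs(mean(oracle[, 1]) - mean(sgP)), tolSg)
  expect_lt(abs(mean(oracle[, 2]) - mean(seP)), tolSe)
})

test_that("chains are reproducible from the seed", {
  pop <- smallPop(n = 60, nSnps = 200, seed = 33)
  cfg <- quickConfig(nIter = 1200, burnIn = 300, thin = 3)
  c1 <- gibbsGblup(pop$traits$N3, factor(pop$traits$level), pop$grm, cfg)
  c2 <- gibbsGblup(pop$traits$N3, factor(pop$traits$level), pop$grm, cfg)
  expect_identical(c1@draws, c2@draws)
  expect_identical(c1@logLik, c2@logLik)
})

test_that("permuting animals (with the GRM) leaves summaries equivalent", {
  pop <- smallPop(n = 60, nSnps = 200, seed = 33)
  cfg <- mcmcConfig(nIter = 12000, burnIn = 3000, thin = 3, seed = 8)
  y <- pop$traits$N3; f <- factor(pop$traits$level)
  G <- values(pop$grm)
  c1 <- gibbsGblup(y, f, pop$grm, cfg)
  idx <- sample(length(y))
  grmP <- new("Grm", values = G[idx, idx], ridgeEpsilon = 1e-6)
  c2 <- gibbsGblup(y[idx], f[idx], grmP, cfg)
  h1 <- heritabilityDraws(c1); h2 <- heritabilityDraws(c2)
  expect_lt(abs(mean(h1) - mean(h2)), 3 * (mcError(h1) + mcError(h2)))
})

test_that("fully-missing trait EBVs equal the BLUP solutions under fixed variances", {
  pop <- smallPop(n = 60, nSnps = 300, seed = 47)
  G <- values(pop$grm)
  f <- factor(pop$traits$level)
  X <- model.matrix(~ 0 + f)
  y1 <- pop$traits$N3
  sigmaG <- matrix(c(0.4, 0.25, 0.25, 0.4), 2)
  sigmaE <- matrix(c(0.4, 0.05, 0.05, 0.5), 2)
  Y <- cbind(t1 = y1, t2 = NA_real_)
  ch <- gibbsGblup(Y, f, pop$grm,
                   mcmcConfig(nIter = 30000, burnIn = 5000, thin = 5,
                              seed = 9),
                   fixedVariance = list(sigmaG = sigmaG, sigmaE = sigmaE))
  # BLUP oracle: with trait 2 unobserved, V = g11 G + e11 I,
  # u1 = g11 G V^-1 (y - X bGLS), u2 = g21 G V^-1 (y - X bGLS)
  V <- sigmaG[1, 1] * G + sigmaE[1, 1] * diag(nrow(G))
  Vi <- solve(V)
  bGls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y1)
  r <- y1 - X %*% bGls
  u1 <- sigmaG[1, 1] * G %*% Vi %*% r
  u2 <- sigmaG[2, 1] * G %*% Vi %*% r
  expect_gt(cor(ch@model$ebvMean[, 1], u1), 0.995)
  expect_gt(cor(ch@model$ebvMean[, 2], u2), 0.995)
  expect_lt(mean(abs(ch@model$ebvMean[, 1] - u1)), 0.05 * sd(u1) + 0.02)
  expect_lt(mean(abs(ch@model$ebvMean[, 2] - u2)), 0.05 * sd(u2) + 0.02)
})

test_that("derived heritability and correlation draws recompute exactly", {
  pop <- smallPop(n = 60, nSnps = 200, seed = 33)
  cfg <- quickConfig(nIter = 3000, burnIn = 500, thin = 5)
  Y <- as.matrix(pop$traits[, c("N3", "CLA")])
  ch <- gibbsGblup(Y, factor(pop$traits$level), pop$grm, cfg)
  d <- as.data.frame(ch@draws)
  h2 <- heritabilityDraws(ch, "N3")
  expect_equal(h2, d[["sigmaG[N3,N3]"]] /
                 (d[["sigmaG[N3,N3]"]] + d[["sigmaE[N3,N3]"]]))
  expect_true(all(h2 >= 0 & h2 <= 1))
  rg <- genomicCorrelationDraws(ch, c("N3", "CLA"))
  expect_equal(rg, d[["sigmaG[N3,CLA]"]] /
                 sqrt(d[["sigmaG[N3,N3]"]] * d[["sigmaG[CLA,CLA]"]]))
  expect_true(all(abs(rg) < 1))       # PD draws keep correlations inside (-1, 1)
  expect_error(heritabilityDraws(ch, "missing"), "no stored draws")
})

test_that("posterior summaries behave on known draws", {
  set.seed(12)
  x <- rnorm(10000)
  hpd <- hpdInterval(x)
  expect_equal(unname(hpd), c(-1.96, 1.96), tolerance = 0.1)
  expect_lt(abs(gewekeZ(x)), 3)
  expect_equal(mcError(x), sd(x) / sqrt(length(x)), tolerance = 0.5)
  expect_warning(gewekeZ(rep(1, 100)), "constant")
  # P0 logic through summarizeChain on a real (short) chain
  pop <- smallPop(n = 60, nSnps = 200, seed = 33)
  ch <- gibbsGblup(pop$traits$N3, factor(pop$traits$level), pop$grm,
                   quickConfig(nIter = 2000, burnIn = 500, thin = 3))
  s <- summarizeChain(ch)
  expect_true(all(c("mean", "sd", "hpdLower", "hpdUpper", "p0", "gewekeZ",
                    "mcError", "mcFlag") %in% names(s)))
  sg <- s[s$parameter == "sigmaG[trait,trait]", ]
  expect_equal(sg$p0, 1)              # variances are positive in every draw
  expect_true(all(s$hpdLower <= s$mean & s$mean <= s$hpdUpper))
})

test_that("DIC reduces to the deviance at the posterior mean for a degenerate chain", {
  # build a minimal chain whose draws are all identical
  n <- 20
  y <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "t"))
  X <- matrix(1, n, 1)
  bMean <- matrix(0.2, 1, 1)
  ebvMean <- matrix(0, n, 1)
  sigmaE <- matrix(1.3, 1, 1)
  mu <- X %*% bMean
  ll <- sum(dnorm(y, mu, sqrt(1.3), log = TRUE))
  ch <- new("PosteriorChain",
            draws = matrix(rep(c(0.2, 0.5, 1.3), each = 60), 60, 3,
                           dimnames = list(NULL, c("b[1,t]", "sigmaG[t,t]",
                                                   "sigmaE[t,t]"))),
            logLik = rep(ll, 60), logLikMarginal = rep(ll, 60),
            ebvDraws = list(), ebvTraits = character(),
            traitIds = "t", animalIds = paste0("A", 1:n),
            config = unclass(mcmcConfig()),
            model = list(X = X, Y = y, bMean = bMean, ebvMean = ebvMean,
                         sigmaEMean = sigmaE,
                         observedMask = matrix(TRUE, n, 1),
                         includeGenomic = FALSE, fixedVariance = FALSE,
                         boundHits = 0L, marginalAvailable = TRUE))
  out <- dic(ch)
  expect_equal(out$pD, 0, tolerance = 1e-10)
  expect_equal(out$dic, -2 * ll, tolerance = 1e-10)
})

test_that("Bayes factors compare marginal likelihood draws sensibly", {
  pop <- smallPop(n = 60, nSnps = 200, seed = 33)
  cfg <- quickConfig(nIter = 4000, burnIn = 1000, thin = 3)
  y <- pop$traits$N3; f <- factor(pop$traits$level)
  full <- gibbsGblup(y, f, pop$grm, cfg)
  red <- gibbsGblup(y, f, NULL, cfg, includeGenomic = FALSE)
  expect_equal(bayesFactor(full, full), 1)
  bf <- bayesFactor(full, red)
  expect_true(is.finite(bf) && bf > 0)
  bfh <- bayesFactor(full, red, estimator = "harmonic-mean")
  expect_true(is.finite(bfh) && bfh > 0)
  # chains with missing data refuse marginal comparisons
  Ym <- cbind(a = y, b = NA_real_)
  chm <- gibbsGblup(Ym, f, pop$grm, cfg,
                    fixedVariance = list(sigmaG = diag(2) * 0.3,
                                         sigmaE = diag(2) * 0.5))
  expect_error(bayesFactor(chm, red), "missing")
})
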