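# Covariance assembly, bending, accuracy, aggregate ranking, selection
# intensity and response.

test_that("covariance assembly averages diagonals and places off-diagonals", {
  # two traits, one pair: matrices equal the pair's posterior means
  pw <- data.frame(trait1 = "A", trait2 = "B", covG = 0.2, varG1 = 1.0,
                   varG2 = 0.8, covE = 0.1, varE1 = 0.5, varE2 = 0.6)
  vc <- assembleCovariance(pw)
  expect_equal(unname(sigmaG(vc)),
               matrix(c(1.0, 0.2, 0.2, 0.8), 2), tolerance = 1e-12)
  expect_equal(unname(sigmaE(vc)),
               matrix(c(0.5, 0.1, 0.1, 0.6), 2), tolerance = 1e-12)
  # three traits: trait-1 variance 1.0 and 1.2 in its two pairs -> 1.1
  pw3 <- data.frame(
    trait1 = c("A", "A", "B"), trait2 = c("B", "C", "C"),
    covG = c(0.1, 0.2, 0.3), varG1 = c(1.0, 1.2, 0.9),
    varG2 = c(0.9, 1.1, 1.1), covE = 0, varE1 = 1, varE2 = 1)
  vc3 <- assembleCovariance(pw3)
  expect_equal(sigmaG(vc3)["A", "A"], 1.1)
  expect_equal(sigmaG(vc3)["A", "C"], 0.2)
  expect_error(assembleCovariance(pw3[-2, ]), "missing pair")
  pwDup <- rbind(pw, pw)
  expect_error(assembleCovariance(pwDup), "duplicated")
})

test_that("assembly of consistent pairwise estimates stays positive definite", {
  # a PD truth, read off pair by pair, must reassemble to itself
  set.seed(81)
  S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  tr <- paste0("T", 1:4)
  dimnames(S) <- list(tr, tr)
  pairs <- t(combn(tr, 2))
  pw <- data.frame(trait1 = pairs[, 1], trait2 = pairs[, 2],
                   covG = S[pairs], varG1 = diag(S)[pairs[, 1]],
                   varG2 = diag(S)[pairs[, 2]],
                   covE = S[pairs] / 2, varE1 = diag(S)[pairs[, 1]],
                   varE2 = diag(S)[pairs[, 2]])
  vc <- assembleCovariance(pw)
  expect_equal(sigmaG(vc)[tr, tr], S, tolerance = 1e-12)
  ev <- eigen(sigmaG(vc), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("bending matches the 2x2 hand eigendecomposition", {
  M <- matrix(c(1, 1.2, 1.2, 1), 2)
  # eigenvalues 2.2 and -0.2 with vectors (1,1)/sqrt2 and (1,-1)/sqrt2
  bent <- bendToPd(M, tolerance = 0.001)
  rep <- attr(bent, "bendReport")
  expect_equal(rep$minEigenBefore, -0.2, tolerance = 1e-12)
  expect_equal(rep$minEigenAfter, 0.001, tolerance = 1e-9)
  v1 <- c(1, 1) / sqrt(2); v2 <- c(1, -1) / sqrt(2)
  hand <- 2.2 * tcrossprod(v1) + 0.001 * tcrossprod(v2)
  expect_equal(unname(bent), hand, tolerance = 1e-12, ignore_attr = TRUE)
  # PD input unchanged; bending idempotent
  P <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(unname(bendToPd(P)), P, ignore_attr = TRUE)
  b2 <- bendToPd(matrix(bent, 2), 0.001)
  expect_equal(matrix(b2, 2), matrix(bent, 2), tolerance = 1e-12)
  expect_error(bendToPd(matrix(1:4, 2)), "symmetric")
})

test_that("accuracy formula hits its endpoints and interior value", {
  expect_equal(ebvAccuracy(0, 1, 0.5), 1)
  expect_equal(ebvAccuracy(sqrt(0.5), 1, 0.5), 0)
  expect_equal(ebvAccuracy(sqrt(0.5 * 0.25), 0.5, 0.5), sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(ebvAccuracy(sqrt(0.5 * 0.25), 0.5, 0.5), 0.7071,
               tolerance = 1e-4)
  expect_warning(a <- ebvAccuracy(2, 1, 0.5), "clamped")
  expect_equal(a, 0)
  # strictly decreasing in the posterior sd
  sds <- seq(0, 0.7, by = 0.1)
  expect_true(all(diff(ebvAccuracy(sds, 1, 0.5)) < 0))
})

test_that("aggregate ranking sums EBVs with stable ties", {
  ebv <- data.frame(
    animal = rep(c("A1", "A2"), 2),
    trait = rep(c("N3", "CLA"), each = 2),
    ebv = c(1, 0.6, 0, 0.6))
  rk <- aggregateRank(ebv)
  expect_identical(rk$animal[1], "A2")      # 1.2 beats 1.0
  # single goal: ranking equals that goal's EBV order
  rk1 <- aggregateRank(ebv, "N3")
  expect_identical(rk1$animal, c("A1", "A2"))
  # permutation of input rows changes nothing
  rkP <- aggregateRank(ebv[sample(nrow(ebv)), ])
  expect_identical(rk, rkP)
  # exact ties break by animal id
  tie <- data.frame(animal = c("B", "A"), trait = "N3", ebv = c(1, 1))
  expect_identical(aggregateRank(tie)$animal, c("A", "B"))
})

test_that("selection intensity follows the truncated-normal formula", {
  expect_equal(selectionIntensity(1), 0)
  # Monte Carlo oracle (frozen): mean of the top half of a standard normal
  expect_equal(selectionIntensity(0.5), 0.7979, tolerance = 1e-4)
  expect_equal(selectionIntensity(0.5), dnorm(0) / 0.5, tolerance = 1e-12)
  expect_error(selectionIntensity(0), "0, 1")
  expect_error(selectionIntensity(1.2), "0, 1")
  # monotone increasing as selection gets stricter
  ps <- c(0.4, 0.3, 0.2, 0.1, 0.05)
  expect_true(all(diff(selectionIntensity(ps)) > 0))
})

# minimal chain carrying prescribed EBV draws
fakeEbvChain <- function(draws, animals, trait = "N3") {
  new("PosteriorChain",
      draws = matrix(0, nrow(draws), 1,
                     dimnames = list(NULL, "sigmaG[N3,N3]")),
      logLik = numeric(nrow(draws)), logLikMarginal = numeric(nrow(draws)),
      ebvDraws = stats::setNames(list(draws), trait), ebvTraits = trait,
      traitIds = trait, animalIds = animals,
      config = unclass(mcmcConfig()),
      model = list(includeGenomic = TRUE, fixedVariance = TRUE,
                   boundHits = 0L, marginalAvailable = FALSE))
}

test_that("response to selection matches order-statistics expectations", {
  set.seed(83)
  n <- 2000
  ebvs <- rnorm(n)
  animals <- sprintf("A%04d", 1:n)
  chain <- fakeEbvChain(matrix(rep(ebvs, each = 60), 60, n), animals)
  ranking <- data.frame(animal = animals[order(-ebvs)])
  for (p in c(0.4, 0.2, 0.05)) {
    r <- responseToSelection(chain, ranking, p, phenotypicSd = 1)
    expect_equal(r$mean, selectionIntensity(p), tolerance = 0.06)
    expect_equal(r$sd, 0)
  }
  # identical EBVs -> zero response
  flat <- fakeEbvChain(matrix(1, 60, n), animals)
  expect_equal(responseToSelection(flat, ranking, 0.2, 1)$mean, 0)
  # response monotone in intensity for a fixed ranking
  resp <- vapply(c(0.4, 0.3, 0.2, 0.1, 0.05), function(p) {
    responseToSelection(chain, ranking, p, 1)$mean
  }, numeric(1))
  expect_true(all(diff(resp) > 0))
  expect_error(responseToSelection(chain, ranking, 0.0001, 1), "empty")
})

test_that("selection report covers the grid of proportions", {
  set.seed(84)
  n <- 100
  animals <- sprintf("A%03d", 1:n)
  dr <- matrix(rnorm(60 * n, mean = rep(rnorm(n), each = 60)), 60, n)
  chain <- fakeEbvChain(dr, animals)
  ranking <- data.frame(animal = animals[order(-colMeans(dr))])
  rep <- selectionReport(chain, ranking, c(N3 = 1))
  expect_equal(nrow(rep), 5)
  expect_equal(rep$intensity, selectionIntensity(rep$proportion))
  expect_true(all(diff(rep$responseMean) > 0))
})
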