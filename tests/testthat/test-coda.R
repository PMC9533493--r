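# Compositional preprocessing: filtering, zero replacement, transforms,
# reference selection and fatty-acid indices.

test_that("core filter applies inclusive occupancy and abundance rules", {
  # occupancies 1.0, 0.8, 0.7, 0.5, 0.2 over 10 samples -> 3 parts retained
  tab <- toyOccupancyTable(c(10, 8, 7, 5, 2))
  out <- filterCore(tab, minOccupancy = 0.70, minMeanRA = 0)
  expect_identical(partIds(out), c("P1", "P2", "P3"))
  expect_equal(attr(out, "report")$retained, 3)
  # a part present in 69% of samples is removed
  tab2 <- toyOccupancyTable(c(100, 69), n = 100)
  expect_identical(partIds(filterCore(tab2, 0.70, 0)), "P1")
  # ubiquitous abundant parts: identity after re-closure
  tab3 <- randomComposition()
  out3 <- filterCore(tab3)
  expect_equal(values(out3), values(tab3))
  # everything removed -> error
  expect_error(filterCore(randomComposition(), minMeanRA = 0.99),
               "removed every part")
})

test_that("GBM zero replacement preserves ratios, closure and positivity", {
  set.seed(3)
  m <- matrix(rexp(40), 8, 5,
              dimnames = list(paste0("S", 1:8), paste0("P", 1:5)))
  m[cbind(c(1, 3, 5), c(2, 4, 1))] <- 0
  tab <- compositionTable(m)
  out <- replaceZerosGBM(tab, pseudoTotal = 5000)
  expect_true(all(values(out) > 0))
  expect_equal(unname(rowSums(values(out))), rep(1, 8), tolerance = 1e-12)
  # ratios among originally non-zero parts unchanged
  v0 <- values(tab); v1 <- values(out)
  for (i in 1:8) {
    nz <- which(v0[i, ] > 0)
    r0 <- v0[i, nz] / v0[i, nz[1]]
    expect_equal(v1[i, nz] / v1[i, nz[1]], r0, tolerance = 1e-10)
  }
  # zero-free table returned unchanged
  tabPos <- randomComposition()
  expect_identical(replaceZerosGBM(tabPos), tabPos)
  # all-zero sample errors
  mz <- m; mz[2, ] <- 0
  expect_error(compositionTable(mz), "non-positive")
})

test_that("GBM replacement matches the posterior formula on a small case", {
  # direct evaluation of the Dirichlet-posterior replacement, coded
  # independently: r_ij = t_j * s_i / (n_i + s_i), observed parts rescaled
  m <- rbind(c(0.5, 0.5, 0.0),
             c(0.3, 0.4, 0.3),
             c(0.6, 0.2, 0.2))
  dimnames(m) <- list(paste0("S", 1:3), paste0("P", 1:3))
  tab <- compositionTable(m)
  nTot <- 1000
  out <- values(replaceZerosGBM(tab, pseudoTotal = nTot))
  g <- c(exp(mean(log(c(0.5, 0.3, 0.6)))),
         exp(mean(log(c(0.5, 0.4, 0.2)))),
         exp(mean(log(c(0.3, 0.2)))))
  tj <- g / sum(g)
  s <- sqrt(nTot)
  r13 <- tj[3] * s / (nTot + s)
  expect_equal(out[1, 3], r13, tolerance = 1e-12)
  expect_equal(out[1, 1], 0.5 * (1 - r13), tolerance = 1e-12)
  expect_equal(out[1, 2], 0.5 * (1 - r13), tolerance = 1e-12)
  expect_equal(out[2, ], m[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("alr transform matches hand computation and is scale invariant", {
  m <- rbind(S1 = c(P1 = 0.2, P2 = 0.3, P3 = 0.5))
  tab <- compositionTable(m)
  out <- alrTransform(tab, "P3")
  expect_equal(unname(values(out)[1, ]), c(log(0.4), log(0.6)),
               tolerance = 1e-12)
  expect_equal(unname(values(out)[1, ]), c(-0.9163, -0.5108),
               tolerance = 1e-4)
  # part identical to the reference -> exact zero column
  m2 <- cbind(m, P4 = 0.5)
  out2 <- alrTransform(compositionTable(m2), "P3")
  expect_equal(unname(values(out2)[, "P4"]), 0)
  # rescaling a raw sample before closure changes nothing
  tabBig <- compositionTable(m * 10)
  expect_equal(values(alrTransform(tabBig, "P3")), values(out))
  # zeros direct the user to replacement
  mz <- rbind(S1 = c(P1 = 0, P2 = 0.5, P3 = 0.5))
  expect_error(alrTransform(compositionTable(mz), "P3"), "replaceZerosGBM")
})

test_that("alr is subcompositionally coherent", {
  tab <- randomComposition(n = 8, p = 6, seed = 9)
  full <- alrTransform(tab, "P6")
  sub <- compositionTable(values(tab)[, c("P2", "P6")])
  subAlr <- alrTransform(sub, "P6")
  expect_equal(values(subAlr)[, "P2"], values(full)[, "P2"],
               tolerance = 1e-12)
})

test_that("clr centres every row and matches the two-part closed form", {
  tab <- randomComposition(n = 10, p = 7, seed = 2)
  out <- clrTransform(tab)
  expect_equal(unname(rowSums(values(out))), rep(0, 10), tolerance = 1e-10)
  # uniform composition -> all zeros
  u <- compositionTable(matrix(1, 3, 4,
                               dimnames = list(paste0("S", 1:3),
                                               paste0("P", 1:4))))
  expect_equal(unname(values(clrTransform(u))), matrix(0, 3, 4))
  # two parts (x, 1-x) -> +-0.5 log(x/(1-x))
  x <- c(0.2, 0.7, 0.45)
  m2 <- cbind(P1 = x, P2 = 1 - x)
  rownames(m2) <- paste0("S", 1:3)
  out2 <- values(clrTransform(compositionTable(m2)))
  expect_equal(unname(out2[, 1]), 0.5 * log(x / (1 - x)), tolerance = 1e-12)
  expect_equal(unname(out2[, 2]), -0.5 * log(x / (1 - x)), tolerance = 1e-12)
})

test_that("Procrustes correlation is invariant and matches vegan", {
  set.seed(4)
  X <- matrix(rnorm(150), 50, 3)
  expect_equal(procrustesCorrelation(X, X), 1, tolerance = 1e-12)
  # rotation + positive scaling of the test configuration
  th <- 0.7
  R3 <- diag(3); R3[1:2, 1:2] <- matrix(c(cos(th), sin(th),
                                          -sin(th), cos(th)), 2)
  expect_equal(procrustesCorrelation(X, 3.7 * X %*% R3), 1,
               tolerance = 1e-10)
  # independent configurations: equality with the vegan oracle
  skip_if_not_installed("vegan")
  Y <- matrix(rnorm(150), 50, 3)
  ours <- procrustesCorrelation(X, Y)
  ss <- vegan::procrustes(X, Y, symmetric = TRUE)$ss
  expect_equal(ours, sqrt(1 - ss), tolerance = 1e-10)
  expect_error(procrustesCorrelation(X[1:2, ], Y[1:2, ]), "3 samples")
})

test_that("alr reference ranking favours low-variance candidates", {
  # two-part compositions: either reference reproduces the 1-D geometry
  tab2 <- randomComposition(n = 10, p = 2, seed = 5)
  rep2 <- selectAlrReference(tab2)
  expect_equal(rep2$procrustes, c(1, 1), tolerance = 1e-8)
  # a part with constant share has ~zero log-ratio variance and ranks first
  set.seed(6)
  m <- matrix(exp(rnorm(60)), 12, 5)
  m <- m / rowSums(m)
  const <- 0.2
  m <- cbind(m * (1 - const), const)
  colnames(m) <- paste0("P", 1:6); rownames(m) <- paste0("S", 1:12)
  tab <- compositionTable(m)
  rep <- selectAlrReference(tab)
  expect_identical(rep$part[1], "P6")
  expect_lt(rep$logVariance[1], 1e-20)
  # ranking is stable under sample permutation
  perm <- sample(nrow(m))
  repP <- selectAlrReference(compositionTable(m[perm, ]))
  expect_identical(rep$part, repP$part)
  expect_error(selectAlrReference(tab, character(0)), "empty")
})

test_that("fatty-acid indices follow the log-ratio definitions", {
  fa <- data.frame(C12.0 = 1.0, C14.0 = 0.6, C16.0 = 0.4,
                   C18.3n3 = 0.5, C20.5n3 = 0.3, C22.5n3 = 0.1,
                   C22.6n3 = 0.1, CLA.c9t11 = 1.0, C18.1t11 = 1.0)
  idx <- computeFattyAcidIndices(fa)
  expect_equal(idx$N3, log(1.0 / 2.0), tolerance = 1e-12)
  expect_equal(idx$N3, -0.6931, tolerance = 1e-4)
  expect_equal(idx$CLA, 0, tolerance = 1e-12)          # numerator == denominator
  # numerator = e * denominator -> index 1
  fa2 <- fa
  fa2$CLA.c9t11 <- 2 * exp(1); fa2$C18.1t11 <- 0 + 1e-12
  expect_equal(computeFattyAcidIndices(fa2)$CLA, 1, tolerance = 1e-6)
  # non-positive numerator -> NA with warning
  fa3 <- fa; fa3$C18.3n3 <- fa3$C20.5n3 <- fa3$C22.5n3 <- fa3$C22.6n3 <- 0
  expect_warning(idx3 <- computeFattyAcidIndices(fa3), "non-positive")
  expect_true(is.na(idx3$N3))
})

test_that("fatty-acid construction round-trips through the indices", {
  set.seed(7)
  n3 <- rnorm(100); cla <- rnorm(100)
  fa <- makeFattyAcidTable(n3, cla, denominatorTotal = 2.0)
  idx <- computeFattyAcidIndices(fa)
  expect_lt(max(abs(idx$N3 - n3)), 1e-12)
  expect_lt(max(abs(idx$CLA - cla)), 1e-12)
  # n3 = 0 -> numerator mass equals the denominator total
  fa0 <- makeFattyAcidTable(0, 0, denominatorTotal = 2.0)
  expect_equal(fa0$C18.3n3 + fa0$C20.5n3 + fa0$C22.5n3 + fa0$C22.6n3, 2.0,
               tolerance = 1e-12)
  # n3 = 1 -> numerator = denominator * e
  fa1 <- makeFattyAcidTable(1, 0, 2.0)
  expect_equal(fa1$C18.3n3 + fa1$C20.5n3 + fa1$C22.5n3 + fa1$C22.6n3,
               2 * exp(1), tolerance = 1e-12)
})
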