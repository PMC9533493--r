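# Networks, Markov clustering, pre-correction and redundancy selection.

test_that("pre-correction removes level means exactly", {
  set.seed(71)
  n <- 60
  f <- factor(rep_len(1:4, n))
  mu <- c(1, -2, 0.5, 3)
  # response equal to its level means -> residuals all 0, R2 = 1
  y <- matrix(mu[as.integer(f)], n, 1, dimnames = list(NULL, "y"))
  r <- precorrectPhenotypes(y, f)
  expect_equal(unname(r[, 1]), rep(0, n))
  expect_equal(unname(attr(r, "r2")), 1)
  # residual means per level are exactly zero
  y2 <- y + rnorm(n)
  r2 <- precorrectPhenotypes(y2, f)
  expect_lt(max(abs(tapply(r2[, 1], f, mean))), 1e-10)
})

test_that("a random factor explains ~(k-1)/(n-1) of the variance", {
  set.seed(72)
  n <- 400; k <- 17
  reps <- 30
  r2s <- replicate(reps, {
    f <- factor(sample(rep_len(1:k, n)))
    y <- matrix(rnorm(n), n, 1)
    varianceExplained(y, f)
  })
  expect_lt(abs(mean(r2s) - (k - 1) / (n - 1)), 0.012)
})

test_that("multivariate variance explained matches the ANOVA special case", {
  set.seed(73)
  n <- 80
  f <- factor(rep_len(1:5, n))
  y <- rnorm(n, as.integer(f))
  ours <- varianceExplained(matrix(y, ncol = 1), f)
  expect_equal(ours, summary(lm(y ~ f))$r.squared, tolerance = 1e-12)
  # responses constant within level -> 1
  Y <- cbind(as.integer(f), 2 * as.integer(f))
  expect_equal(varianceExplained(Y, f), 1)
  expect_error(varianceExplained(matrix(1, 10, 1), factor(rep(1:2, 5))),
               "zero total variance")
})

test_that("network edges follow the strict absolute-correlation rule", {
  set.seed(74)
  n <- 50
  base <- rnorm(n)
  # F1/F2 correlated at ~1, F3 correlated with F1 at ~0.5, F4 independent
  V <- cbind(F1 = base, F2 = base,
             F3 = 0.5 * scale(base)[, 1] + sqrt(0.75) * rnorm(n),
             F4 = rnorm(n))
  g <- buildNetwork(V, rThreshold = 0.99)
  expect_equal(nrow(g@edges), 1)
  expect_equal(g@edges$weight, 1, tolerance = 1e-12)
  # affine rescaling of a column changes nothing
  V2 <- V; V2[, "F3"] <- 100 - 7 * V2[, "F3"]
  g1 <- buildNetwork(V, 0.30); g2 <- buildNetwork(V2, 0.30)
  expect_equal(abs(g1@edges$weight), abs(g2@edges$weight))
  expect_equal(nrow(g1@edges), nrow(g2@edges))
  # independent long columns almost never connect at 0.30
  set.seed(75)
  big <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(nrow(buildNetwork(big, 0.30)@edges), 0)
  expect_warning(buildNetwork(cbind(V, F5 = rep(1, n)), 0.3),
                 "zero-variance")
})

# independently coded naive MCL used as the clustering oracle
naiveMcl <- function(A, inflation = 2, tol = 1e-8, maxIter = 200) {
  diag(A) <- 1
  M <- apply(A, 2, function(col) col / sum(col))
  for (i in seq_len(maxIter)) {
    E <- M %*% M
    E <- E^inflation
    E <- apply(E, 2, function(col) col / sum(col))
    if (max(abs(E - M)) < tol) { M <- E; break }
    M <- E
  }
  eps <- 1e-6
  groups <- list()
  for (a in which(diag(M) > eps)) {
    members <- which(M[a, ] > eps)
    hit <- which(vapply(groups, function(g) length(intersect(g, members)) > 0,
                        logical(1)))
    if (length(hit)) {
      groups[[hit[1]]] <- sort(unique(c(unlist(groups[hit]), members)))
      groups[hit[-1]] <- NULL
    } else groups[[length(groups) + 1]] <- members
  }
  groups
}

test_that("Markov clustering splits disconnected components", {
  # two disjoint triangles
  edges <- data.frame(from = c("a", "a", "b", "x", "x", "y"),
                      to = c("b", "c", "c", "y", "z", "z"),
                      weight = 0.9)
  g <- new("CoabundanceGraph", nodes = c("a", "b", "c", "x", "y", "z"),
           edges = edges, basis = "phenotypic", threshold = 0.3)
  cl <- mclCluster(g)
  expect_equal(attr(cl, "nClusters"), 2)
  expect_equal(length(unique(cl$cluster[1:3])), 1)
  expect_equal(length(unique(cl$cluster[4:6])), 1)
  expect_false(cl$cluster[1] == cl$cluster[4])
  # a single isolated edge forms one cluster of two
  g2 <- new("CoabundanceGraph", nodes = c("p", "q"),
            edges = data.frame(from = "p", to = "q", weight = 0.5),
            basis = "phenotypic", threshold = 0.3)
  cl2 <- mclCluster(g2)
  expect_equal(cl2$cluster, c(1L, 1L))
})

test_that("Markov clustering matches an independent reference implementation", {
  set.seed(76)
  n <- 10
  # random weighted graph with two dense blocks and a weak bridge
  A <- matrix(0, n, n)
  within <- function(i, j) A[i, j] <<- A[j, i] <<- runif(1, 0.5, 0.9)
  for (i in 1:4) for (j in (i + 1):5) within(i, j)
  for (i in 6:9) for (j in (i + 1):10) within(i, j)
  A[5, 6] <- A[6, 5] <- 0.31
  nodes <- letters[1:n]
  idx <- which(upper.tri(A) & A > 0.3, arr.ind = TRUE)
  g <- new("CoabundanceGraph", nodes = nodes,
           edges = data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                              weight = A[idx]),
           basis = "genomic", threshold = 0.3)
  cl <- mclCluster(g, minClusterSize = 1)
  ref <- naiveMcl(A * (A > 0.3))
  refMember <- rep(NA_integer_, n)
  for (k in seq_along(ref)) refMember[ref[[k]]] <- k
  # identical partitions up to label permutation
  expect_equal(length(unique(cl$cluster)), length(ref))
  tab <- table(cl$cluster, refMember)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # MCL refines connected components
  comp <- c(rep(1, 10))                 # bridge keeps the graph connected
  for (cc in unique(cl$cluster)) {
    members <- which(cl$cluster == cc)
    expect_equal(length(unique(comp[members])), 1)
  }
})

test_that("abundance filter is inclusive at the threshold", {
  m <- rbind(c(0.00009, 0.0001, 0.0002, 0.5, 0.49961))
  m <- rbind(m, m)
  colnames(m) <- paste0("P", 1:5); rownames(m) <- c("S1", "S2")
  tab <- compositionTable(m)
  out <- abundanceFilter(paste0("P", 1:5), tab, minMeanRA = 1e-4)
  expect_identical(out, c("P2", "P3", "P4", "P5"))   # 0.009% excluded
  expect_true("P2" %in% out)                         # exactly 0.01% retained
  expect_error(abundanceFilter("Q1", tab), "not in the table")
})

test_that("redundancy selection keeps marginal signal and drops duplicates", {
  set.seed(77)
  n <- 80
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  # each candidate generates one response column without noise
  Y <- X %*% diag(3)
  out <- rdaRedundancySelect(Y, X, nPerm = 199, seed = 3)
  expect_identical(sort(out$retained), c("c1", "c2", "c3"))
  # an exact duplicate is aliased away with a warning
  Xd <- cbind(X, c4 = X[, "c1"])
  expect_warning(out2 <- rdaRedundancySelect(Y, Xd, nPerm = 99, seed = 3),
                 "collinear")
  expect_identical(out2$dropped, "c4")
  expect_error(rdaRedundancySelect(Y, cbind(X, k = rep(1, n))), "constant")
})

test_that("pure-noise candidates are retained at ~the nominal rate", {
  set.seed(78)
  reps <- 30
  kept <- replicate(reps, {
    n <- 40
    Y <- matrix(rnorm(n * 4), n, 4)
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
    length(rdaRedundancySelect(Y, X, alpha = 0.05, nPerm = 99,
                               seed = sample.int(1e6, 1))$retained)
  })
  rate <- sum(kept) / (reps * 5)
  expect_lt(rate, 0.12)
  expect_gt(rate, 0.005)
})

test_that("redundancy selection is monotone in alpha for fixed permutations", {
  set.seed(79)
  n <- 60
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("c", 1:4)))
  Y <- X[, 1:2] %*% matrix(rnorm(2 * 3), 2, 3) + matrix(rnorm(n * 3), n, 3)
  r1 <- rdaRedundancySelect(Y, X, alpha = 0.01, nPerm = 199, seed = 5)
  r2 <- rdaRedundancySelect(Y, X, alpha = 0.10, nPerm = 199, seed = 5)
  expect_true(all(r1$retained %in% r2$retained))
  expect_equal(r1$pValues, r2$pValues)   # p-values independent of alpha
})
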