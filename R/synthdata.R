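# Synthetic populations with known ground truth: half-sib genotypes,
# correlated goal traits and a heritable compositional microbiome.

#' Simulation specification
#'
#' Bundles and validates every parameter of the synthetic-population
#' generator. Defaults emulate the statistical structure of the beef cattle
#' study the package targets at desk scale: ~250 steers in half-sib families
#' of ~8 progeny per sire, 2,000 SNPs, a compositional microbiome in which
#' roughly 28% of features are heritable (h2 in 0.2-0.6) and a subset is
#' genomically correlated with the goal traits (|rg| up to 0.8), goal traits
#' N3 (h2 = 0.76) and CLA (h2 = 0.57) with genomic correlation 0.39 plus a
#' methane trait negatively correlated with both, a 17-level fixed factor
#' (diet x breed x experiment) explaining ~40% of phenotypic variance, and
#' ~5% zero abundances arising from finite sequencing depth.
#'
#' @param nAnimals number of phenotyped animals (default 250).
#' @param nSires number of sires; progeny are assigned round-robin so family
#'   size is ~`nAnimals / nSires` (default gives 8 progeny/sire).
#' @param nSnps number of SNPs (default 2000).
#' @param mafRange range of minor allele frequencies, within (0, 0.5].
#' @param nFeatures number of microbial features (default 100).
#' @param heritableFraction fraction of features with a host-genomic
#'   component (default 0.28).
#' @param featureH2Range heritability range for heritable features.
#' @param goalH2 named per-trait heritabilities of the goal traits.
#' @param goalRg genomic correlation matrix among goal traits (unit
#'   diagonal, positive definite).
#' @param goalRe residual correlation matrix among goal traits.
#' @param featureGoalRg optional nFeatures x nGoals matrix of target genomic
#'   correlations between features and goal traits; built automatically when
#'   `NULL` (a `corrFraction` share of heritable features gets |rg| in
#'   0.4-0.8 with N3, a same-sign echo on CLA for half of them, and an
#'   opposite-sign loading on CH4 when present).
#' @param corrFraction fraction of heritable features correlated with the
#'   goals when `featureGoalRg` is auto-built (default 0.4).
#' @param fixedLevels number of levels of the systematic fixed factor
#'   (default 17).
#' @param fixedVarianceFraction fraction of phenotypic variance explained by
#'   the fixed factor (default 0.40).
#' @param sequencingDepth counts per sample when `zeroTarget` is `NULL`.
#' @param zeroTarget target fraction of zero counts; when non-`NULL` the
#'   depth is calibrated to hit it (default 0.05).
#' @param seed integer seed; all generator functions derive their streams
#'   from it.
#' @return a validated list of class `simSpec`.
#' @export
simSpec <- function(nAnimals = 250,
                    nSires = ceiling(nAnimals / 8),
                    nSnps = 2000,
                    mafRange = c(0.05, 0.5),
                    nFeatures = 100,
                    heritableFraction = 0.28,
                    featureH2Range = c(0.2, 0.6),
                    goalH2 = c(N3 = 0.76, CLA = 0.57, CH4 = 0.45),
                    goalRg = NULL,
                    goalRe = NULL,
                    featureGoalRg = NULL,
                    corrFraction = 0.4,
                    fixedLevels = 17,
                    fixedVarianceFraction = 0.40,
                    sequencingDepth = 1e5,
                    zeroTarget = 0.05,
                    seed = 1L) {
  nGoals <- length(goalH2)
  if (is.null(names(goalH2))) names(goalH2) <- paste0("T", seq_len(nGoals))
  if (is.null(goalRg)) {
    goalRg <- diag(nGoals)
    dimnames(goalRg) <- list(names(goalH2), names(goalH2))
    if (all(c("N3", "CLA") %in% names(goalH2))) {
      goalRg["N3", "CLA"] <- goalRg["CLA", "N3"] <- 0.39
    }
    if ("CH4" %in% names(goalH2)) {
      for (tr in intersect(c("N3", "CLA"), names(goalH2))) {
        goalRg["CH4", tr] <- goalRg[tr, "CH4"] <- -0.35
      }
    }
  }
  if (is.null(goalRe)) {
    goalRe <- diag(nGoals) * 0.8 + 0.2
    dimnames(goalRe) <- dimnames(goalRg)
  }
  spec <- list(
    nAnimals = as.integer(nAnimals), nSires = as.integer(nSires),
    nSnps = as.integer(nSnps), mafRange = mafRange,
    nFeatures = as.integer(nFeatures),
    heritableFraction = heritableFraction,
    featureH2Range = featureH2Range,
    goalH2 = goalH2, goalRg = goalRg, goalRe = goalRe,
    featureGoalRg = featureGoalRg, corrFraction = corrFraction,
    fixedLevels = as.integer(fixedLevels),
    fixedVarianceFraction = fixedVarianceFraction,
    sequencingDepth = sequencingDepth, zeroTarget = zeroTarget,
    seed = as.integer(seed)
  )
  .validateSimSpec(spec)
  class(spec) <- "simSpec"
  spec
}

.validateSimSpec <- function(s) {
  stopifnot(s$nAnimals >= 2, s$nSires >= 1, s$nSnps >= 1, s$nFeatures >= 1,
            s$fixedLevels >= 1)
  if (length(s$mafRange) != 2 || s$mafRange[1] <= 0 || s$mafRange[2] > 0.5 ||
      s$mafRange[1] > s$mafRange[2]) {
    stop("'mafRange' must be an increasing pair within (0, 0.5]")
  }
  props <- c(s$heritableFraction, s$fixedVarianceFraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (any(s$featureH2Range < 0) || any(s$featureH2Range >= 1)) {
    stop("'featureH2Range' must lie in [0, 1)")
  }
  if (any(s$goalH2 < 0 | s$goalH2 >= 1)) stop("goal h2 must lie in [0, 1)")
  for (nm in c("goalRg", "goalRe")) {
    R <- s[[nm]]
    if (max(abs(R - t(R))) > 1e-10 || any(abs(diag(R) - 1) > 1e-10)) {
      stop(sprintf("'%s' must be symmetric with unit diagonal", nm))
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop(sprintf("'%s' must be positive definite", nm))
    }
  }
  if (!is.null(s$zeroTarget) &&
      (s$zeroTarget < 0 || s$zeroTarget >= 1)) {
    stop("'zeroTarget' must lie in [0, 1)")
  }
  invisible(TRUE)
}

#' Simulate half-sib SNP genotypes
#'
#' Draws per-SNP allele frequencies uniformly in `mafRange`, samples
#' unrelated sires in Hardy-Weinberg proportions, and builds each progeny
#' from one sire gamete plus one gamete drawn at the population frequency
#' (unique, unrelated dams). Animals sharing a sire are half sibs with
#' expected genomic relationship ~0.25.
#'
#' @param spec a [simSpec()].
#' @return animals x SNPs dosage matrix in `{0, 1, 2}` with attributes
#'   `"sire"` (sire id per animal) and `"freq"` (simulated allele
#'   frequencies).
#' @export
simulateGenotypes <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  set.seed(deriveSeed(spec$seed, "genotypes"))
  n <- spec$nAnimals; m <- spec$nSnps
  p <- stats::runif(m, spec$mafRange[1], spec$mafRange[2])
  sire <- rep_len(seq_len(spec$nSires), n)
  sireGeno <- matrix(stats::rbinom(spec$nSires * m, 2, rep(p, each = spec$nSires)),
                     spec$nSires, m)
  # sire gamete: homozygotes transmit their allele, heterozygotes a coin flip
  sireDose <- sireGeno[sire, , drop = FALSE]
  gamSire <- matrix(0, n, m)
  gamSire[sireDose == 2] <- 1
  het <- sireDose == 1
  gamSire[het] <- stats::rbinom(sum(het), 1, 0.5)
  gamDam <- matrix(stats::rbinom(n * m, 1, rep(p, each = n)), n, m)
  geno <- gamSire + gamDam
  dimnames(geno) <- list(sprintf("A%03d", seq_len(n)),
                         sprintf("SNP%05d", seq_len(m)))
  attr(geno, "sire") <- sprintf("S%03d", sire)
  attr(geno, "freq") <- p
  geno
}

# fixed-factor design shared by traits and microbiome: round-robin levels
.fixedAssign <- function(spec) {
  factor(rep_len(seq_len(spec$fixedLevels), spec$nAnimals))
}

#' Simulate goal traits with Kronecker-structured breeding values
#'
#' Breeding values are drawn from `N(0, SigmaG (x) G)` where `G` is the
#' genomic relationship matrix, phenotypes add a fixed-level effect and a
#' residual drawn from `N(0, SigmaE (x) I)`. With fixed-variance fraction
#' `f`, trait `t` has genomic variance `h2_t (1 - f)` and residual variance
#' `(1 - h2_t)(1 - f)`, so total phenotypic variance is ~1 and the fixed
#' factor explains ~`f` of it.
#'
#' @param grm a [Grm-class] for the simulated animals.
#' @param spec a [simSpec()].
#' @return data.frame with columns `animal`, `level`, and one column per
#'   goal trait; the ground truth (true breeding values, h2, rg, sire and
#'   level assignments) is attached as attribute `"truth"`.
#' @export
simulateTraits <- function(grm, spec) {
  stopifnot(is(grm, "Grm"), inherits(spec, "simSpec"))
  set.seed(deriveSeed(spec$seed, "traits"))
  G <- grm@values
  n <- nrow(G)
  if (n != spec$nAnimals) stop("GRM size does not match the spec")
  TT <- length(spec$goalH2)
  f <- spec$fixedVarianceFraction
  vg <- spec$goalH2 * (1 - f)
  ve <- (1 - spec$goalH2) * (1 - f)
  SigmaG <- diag(sqrt(vg), TT) %*% spec$goalRg %*% diag(sqrt(vg), TT)
  SigmaE <- diag(sqrt(ve), TT) %*% spec$goalRe %*% diag(sqrt(ve), TT)
  dimnames(SigmaG) <- dimnames(SigmaE) <- list(names(spec$goalH2),
                                               names(spec$goalH2))
  A <- t(chol(G))
  U <- A %*% matrix(stats::rnorm(n * TT), n, TT)
  # guard h2 = 0 traits: columns of U scale to zero genomic variance
  U <- U %*% chol2trans(SigmaG)
  E <- matrix(stats::rnorm(n * TT), n, TT) %*% chol2trans(SigmaE)
  lev <- .fixedAssign(spec)
  levEff <- matrix(stats::rnorm(spec$fixedLevels * TT, sd = sqrt(f)),
                   spec$fixedLevels, TT)
  colnames(levEff) <- names(spec$goalH2)
  Y <- levEff[as.integer(lev), , drop = FALSE] + U + E
  colnames(Y) <- colnames(U) <- names(spec$goalH2)
  out <- data.frame(animal = rownames(G), level = lev, Y,
                    stringsAsFactors = FALSE)
  rownames(U) <- rownames(G)
  attr(out, "truth") <- list(
    trueBreedingValues = U,
    trueH2 = spec$goalH2,
    trueRg = spec$goalRg,
    sigmaG = SigmaG, sigmaE = SigmaE,
    sireIds = attr(grm, "sire"),
    fixedLevel = lev,
    levelEffects = levEff
  )
  out
}

# transpose-chol that tolerates positive semi-definite matrices with zero
# rows (h2 = 0 traits)
chol2trans <- function(S) {
  zero <- diag(S) < .Machine$double.eps
  if (!any(zero)) return(chol(S))
  R <- matrix(0, nrow(S), ncol(S))
  if (any(!zero)) R[!zero, !zero] <- chol(S[!zero, !zero, drop = FALSE])
  R
}

# loadings reproducing target correlations rho with goals whose genetic
# correlation matrix is R; returns list(beta, resSd)
.goalLoadings <- function(R, rho) {
  beta <- solve(R, rho)
  expl <- sum(beta * rho)
  if (expl > 1 + 1e-8) {
    stop("infeasible feature-goal genomic correlations (explained > 1)")
  }
  list(beta = beta, resSd = sqrt(max(0, 1 - expl)))
}

.autoFeatureGoalRg <- function(spec, heritable) {
  p <- spec$nFeatures
  goals <- names(spec$goalH2)
  rg <- matrix(0, p, length(goals), dimnames = list(NULL, goals))
  herIdx <- which(heritable)
  nCorr <- round(spec$corrFraction * length(herIdx))
  if (nCorr == 0 || !"N3" %in% goals) return(rg)
  corrIdx <- herIdx[seq_len(nCorr)]
  sgn <- rep(c(1, -1), length.out = nCorr)
  rho <- stats::runif(nCorr, 0.4, 0.8) * sgn
  rg[corrIdx, "N3"] <- rho
  if ("CLA" %in% goals) {
    # half of the correlated features echo the N3 signal on CLA (same sign)
    echo <- corrIdx[seq_len(ceiling(nCorr / 2))]
    rg[echo, "CLA"] <- 0.6 * rg[echo, "N3"]
  }
  if ("CH4" %in% goals) {
    rg[corrIdx, "CH4"] <- -0.5 * rg[corrIdx, "N3"]
  }
  rg
}

#' Simulate a heritable compositional microbiome
#'
#' Each feature has a latent per-animal log abundance equal to a feature
#' base level, a fixed-level effect, a host-genomic part scaled to the
#' feature heritability (built from loadings on the standardized goal-trait
#' breeding values so that target feature-goal genomic correlations are
#' honoured, plus an independent genomic factor), and a residual. Latent
#' values are exponentiated and closed to proportions; multinomial count
#' sampling at finite sequencing depth is the only zero-generating
#' mechanism. When `zeroTarget` is set, the depth is calibrated so the
#' expected zero fraction matches it.
#'
#' A dedicated reference part `KOref` with constant latent abundance is
#' appended, emulating the near-constant housekeeping gene used as the alr
#' denominator in rumen metagenome studies: taking it as the alr reference
#' recovers each feature's latent variance structure exactly (up to
#' counting noise).
#'
#' @param grm a [Grm-class].
#' @param spec a [simSpec()].
#' @param truth ground truth attached to the output of [simulateTraits()].
#' @return a [CompositionTable-class] with counts attached; attributes
#'   `"featureTruth"` (per-feature h2 and target rg) and
#'   `"realizedZeroFraction"`.
#' @export
simulateMicrobiome <- function(grm, spec, truth) {
  stopifnot(is(grm, "Grm"), inherits(spec, "simSpec"))
  set.seed(deriveSeed(spec$seed, "microbiome"))
  G <- grm@values
  n <- nrow(G)
  p <- spec$nFeatures
  f <- spec$fixedVarianceFraction
  nHer <- round(spec$heritableFraction * p)
  heritable <- seq_len(p) <= nHer
  h2 <- ifelse(heritable,
               stats::runif(p, spec$featureH2Range[1], spec$featureH2Range[2]),
               0)
  rgTarget <- spec$featureGoalRg
  if (is.null(rgTarget)) rgTarget <- .autoFeatureGoalRg(spec, heritable)
  if (nrow(rgTarget) != p) stop("'featureGoalRg' must have one row/feature")
  gStd <- truth$trueBreedingValues %*%
    diag(1 / sqrt(pmax(diag(truth$sigmaG), .Machine$double.eps)),
         ncol(truth$trueBreedingValues))
  A <- t(chol(G))
  lev <- truth$fixedLevel
  base <- stats::rnorm(p, mean = 0, sd = 1.5)
  lat <- matrix(0, n, p)
  for (k in seq_len(p)) {
    gen <- 0
    if (heritable[k]) {
      ld <- .goalLoadings(spec$goalRg, rgTarget[k, ])
      shared <- gStd %*% ld$beta
      own <- A %*% stats::rnorm(n)
      aStd <- shared + ld$resSd * own
      gen <- sqrt(h2[k] * (1 - f)) * aStd
    }
    levEff <- stats::rnorm(spec$fixedLevels, sd = sqrt(f))[as.integer(lev)]
    res <- stats::rnorm(n, sd = sqrt((1 - h2[k]) * (1 - f)))
    lat[, k] <- base[k] + levEff + gen + res
  }
  # a dedicated reference part with constant latent abundance (the rumen
  # rpe-like housekeeping gene): alr against it preserves each feature's
  # latent variance structure exactly
  lat <- cbind(lat, 1.5)
  prop <- exp(lat - apply(lat, 1, max))
  prop <- closeRows(prop)
  depth <- spec$sequencingDepth
  if (!is.null(spec$zeroTarget) && spec$zeroTarget > 0) {
    expZero <- function(logd) mean((1 - prop)^exp(logd))
    lo <- log(10); hi <- log(1e9)
    if (expZero(lo) > spec$zeroTarget && expZero(hi) < spec$zeroTarget) {
      depth <- exp(stats::uniroot(function(ld) expZero(ld) - spec$zeroTarget,
                                  c(lo, hi), tol = 1e-3)$root)
    }
  }
  depth <- max(1, round(depth))
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, depth, prop[i, ])[, 1],
                     numeric(p + 1)))
  dimnames(counts) <- list(rownames(G),
                           c(sprintf("KO%04d", seq_len(p)), "KOref"))
  tab <- compositionTable(counts + 0, counts = counts)
  attr(tab, "featureTruth") <- data.frame(
    feature = colnames(counts),
    heritable = c(heritable, FALSE), h2 = c(h2, 0),
    rbind(rgTarget, 0), check.names = FALSE)
  attr(tab, "realizedZeroFraction") <- mean(counts == 0)
  attr(tab, "depth") <- depth
  tab
}

#' Build a fatty-acid table realizing given index values
#'
#' Inverse of [computeFattyAcidIndices()]: distributes a fixed denominator
#' total over C12:0/C14:0/C16:0 (10/15/75%) and numerator totals
#' `denominatorTotal * exp(index)` over the n-3 fatty acids (55/20/15/10%)
#' and the CLA pair (30/70%), so that recomputing the indices returns the
#' inputs exactly up to float round-off.
#'
#' @param n3Values,claValues per-animal index values.
#' @param denominatorTotal total saturated-fatty-acid content in g/100 g
#'   meat (default 2.0).
#' @return data.frame of fatty-acid contents compatible with
#'   [computeFattyAcidIndices()].
#' @export
makeFattyAcidTable <- function(n3Values, claValues, denominatorTotal = 2.0) {
  stopifnot(denominatorTotal > 0, length(n3Values) == length(claValues))
  den <- denominatorTotal
  numN3 <- den * exp(n3Values)
  numCLA <- den * exp(claValues)
  data.frame(
    animal = seq_along(n3Values),
    C12.0 = 0.10 * den, C14.0 = 0.15 * den, C16.0 = 0.75 * den,
    C18.3n3 = 0.55 * numN3, C20.5n3 = 0.20 * numN3,
    C22.5n3 = 0.15 * numN3, C22.6n3 = 0.10 * numN3,
    CLA.c9t11 = 0.30 * numCLA, C18.1t11 = 0.70 * numCLA
  )
}

#' Simulate a full population
#'
#' Convenience wrapper running [simulateGenotypes()], [computeGrm()],
#' [simulateTraits()] and [simulateMicrobiome()] from a single spec.
#'
#' @param spec a [simSpec()].
#' @return list with `geno`, `grm`, `traits`, `truth`, `microbiome`.
#' @export
simulatePopulation <- function(spec) {
  geno <- simulateGenotypes(spec)
  # small populations can fix rare alleles; drop monomorphic SNPs before
  # the GRM (the real pipeline does this in QC)
  p <- colMeans(geno) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    sire <- attr(geno, "sire")
    geno <- geno[, poly, drop = FALSE]
    attr(geno, "sire") <- sire
  }
  grm <- computeGrm(geno)
  attr(grm, "sire") <- attr(geno, "sire")
  traits <- simulateTraits(grm, spec)
  truth <- attr(traits, "truth")
  micro <- simulateMicrobiome(grm, spec, truth)
  list(geno = geno, grm = grm, traits = traits, truth = truth,
       microbiome = micro)
}
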