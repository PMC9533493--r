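# End-to-end orchestration: one config, deterministic per-stage seeds,
# artifacts + provenance manifest.

.pipelineDefaults <- function() {
  list(
    outDir = "pipeline-out",
    seed = 1L,
    simulate = list(nAnimals = 60, nSires = 8, nSnps = 300, nFeatures = 30,
                    heritableFraction = 0.3, fixedLevels = 5,
                    fixedVarianceFraction = 0.4, zeroTarget = 0.05),
    coda = list(minOccupancy = 0.70, minMeanRA = 1e-5, pseudoTotal = 1e4,
                referenceCandidates = 10, epsProcrustes = 0.005),
    grm = list(snpCallRate = 0.95, hwePCut = 1e-8, mafCut = 0.05,
               animalCallRate = 0.90, ridgeEpsilon = 1e-6),
    mcmc = list(nIter = 2000, burnIn = 400, thin = 4),
    screen = list(alpha = 1e-4, dicCut = -20, p0Cut = 0.95),
    select = list(rThreshold = 0.30, inflation = 2, minClusterSize = 2,
                  minMeanRA = 1e-4, rdaAlpha = 0.05, nPerm = 199),
    predict = list(bendTolerance = 0.001,
                   proportions = c(0.40, 0.30, 0.20, 0.10, 0.05)),
    goals = c("N3", "CLA"),
    ch4 = "CH4"
  )
}

#' Load and validate a pipeline configuration
#'
#' Merges a YAML file (or a list) over the built-in defaults. Unknown keys
#' are rejected so typos cannot silently fall back to defaults.
#'
#' @param config path to a YAML file, or a (possibly partial) list.
#' @return a complete configuration list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .pipelineDefaults()
  merge2 <- function(def, usr, path = "") {
    unknown <- setdiff(names(usr), names(def))
    if (length(unknown)) {
      stop("unknown configuration key(s): ",
           paste0(path, unknown, collapse = ", "))
    }
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && is.list(usr[[nm]])) {
        def[[nm]] <- merge2(def[[nm]], usr[[nm]], paste0(path, nm, "$"))
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  out <- merge2(defaults, config)
  stopifnot(out$screen$alpha > 0, out$screen$alpha < 1,
            out$select$rThreshold >= 0, out$select$rThreshold < 1,
            out$predict$bendTolerance > 0)
  class(out) <- "pipelineConfig"
  out
}

# bivariate pairwise (co)variance estimation for covariance assembly
#' Pairwise bivariate (co)variance posterior means
#'
#' Runs a bivariate GBLUP Gibbs sampler for every pair of columns of `Y`
#' and records the posterior means of the genomic and residual variances
#' and covariances, in the shape expected by [assembleCovariance()].
#'
#' @param Y animals x traits matrix (NA allowed).
#' @param fixedFactor systematic-effect factor.
#' @param grm a [Grm-class].
#' @param config an [mcmcConfig()]; per-pair seeds are derived from it.
#' @return data.frame with columns `trait1`, `trait2`, `covG`, `varG1`,
#'   `varG2`, `covE`, `varE1`, `varE2`.
#' @export
estimatePairwiseCovariances <- function(Y, fixedFactor, grm,
                                        config = mcmcConfig()) {
  traits <- colnames(Y)
  stopifnot(length(traits) >= 2)
  pairs <- utils::combn(traits, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    t1 <- pairs[1, i]; t2 <- pairs[2, i]
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, "pair", t1, t2)
    ch <- gibbsGblup(Y[, c(t1, t2)], fixedFactor, grm, cfg)
    data.frame(
      trait1 = t1, trait2 = t2,
      covG = mean(.vcDraws(ch, "sigmaG", t1, t2)),
      varG1 = mean(.vcDraws(ch, "sigmaG", t1)),
      varG2 = mean(.vcDraws(ch, "sigmaG", t2)),
      covE = mean(.vcDraws(ch, "sigmaE", t1, t2)),
      varE1 = mean(.vcDraws(ch, "sigmaE", t1)),
      varE2 = mean(.vcDraws(ch, "sigmaE", t2)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the microbiome-driven breeding pipeline
#'
#' Executes the requested stages in dependency order: `simulate` (synthetic
#' population), `coda` (core filter, zero replacement, alr reference
#' selection and transform), `grm` (SNP QC + VanRaden GRM), `screen`
#' (per-feature heritability screening and feature-goal genomic
#' correlations), `select` (co-abundance network, Markov clustering,
#' abundance filter and redundancy pruning), `predict` (pairwise covariance
#' assembly, bending, microbiome-driven EBV prediction) and `report`
#' (selection accuracies and responses). Every stage writes its artifacts
#' under `config$outDir` and appends to a provenance manifest recording the
#' configuration hash, derived seeds and artifact checksums. Reruns with
#' the same configuration reproduce identical artifacts.
#'
#' @param config a [pipelineConfig()] (or path / partial list accepted by
#'   it).
#' @param stages subset of stages to run (default: all).
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate", "coda", "grm", "screen",
                                   "select", "predict", "report")) {
  if (!inherits(config, "pipelineConfig")) config <- pipelineConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  artifacts <- character(0)
  state <- list()

  needArtifact <- function(path, producer) {
    if (!file.exists(path)) {
      stop("missing artifact '", basename(path), "': run stage '",
           producer, "' first")
    }
    path
  }

  if ("simulate" %in% stages) {
    sim <- config$simulate
    spec <- simSpec(nAnimals = sim$nAnimals, nSires = sim$nSires,
                    nSnps = sim$nSnps, nFeatures = sim$nFeatures,
                    heritableFraction = sim$heritableFraction,
                    fixedLevels = sim$fixedLevels,
                    fixedVarianceFraction = sim$fixedVarianceFraction,
                    zeroTarget = sim$zeroTarget,
                    seed = deriveSeed(config$seed, "simulate"))
    pop <- simulatePopulation(spec)
    writeDosageTsv(pop$geno, out("genotypes.tsv"))
    writeAbundanceTsv(pop$microbiome, out("abundance.tsv"))
    .writeCsv(pop$traits, out("phenotypes.csv"))
    .writeCsv(data.frame(animal = rownames(pop$truth$trueBreedingValues),
                         pop$truth$trueBreedingValues),
              out("truth-bv.csv"))
    yaml::write_yaml(lapply(unclass(spec), function(x) {
      if (is.matrix(x)) as.list(as.data.frame(x)) else x
    }), out("simspec.yml"))
    artifacts <- c(artifacts, out(c("genotypes.tsv", "abundance.tsv",
                                    "phenotypes.csv", "truth-bv.csv")))
    state$pop <- pop
  }

  phenoPath <- out("phenotypes.csv")
  if (any(c("coda", "grm", "screen", "select", "predict",
            "report") %in% stages)) {
    needArtifact(phenoPath, "simulate")
    pheno <- utils::read.csv(phenoPath)
    fixedFactor <- factor(pheno$level)
  }

  if ("coda" %in% stages) {
    cc <- config$coda
    tab <- readAbundanceTsv(needArtifact(out("abundance.tsv"), "simulate"))
    core <- filterCore(tab, cc$minOccupancy, cc$minMeanRA)
    pos <- replaceZerosGBM(core, pseudoTotal = cc$pseudoTotal)
    # candidate references: lowest log-variance parts (cheap pre-ranking)
    lv <- apply(log(pos@values), 2, stats::var)
    cand <- names(sort(lv))[seq_len(min(cc$referenceCandidates, ncol(pos@values)))]
    refRep <- selectAlrReference(pos, cand, cc$epsProcrustes)
    alr <- alrTransform(pos, refRep$part[1])
    utils::write.table(refRep, out("reference-report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    df <- data.frame(feature = colnames(alr@values), t(alr@values),
                     check.names = FALSE)
    utils::write.table(df, out("alr.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    yaml::write_yaml(list(reference = refRep$part[1]), out("alr-reference.yml"))
    artifacts <- c(artifacts, out(c("reference-report.tsv", "alr.tsv")))
    state$alr <- alr
    state$core <- core
  }

  if ("grm" %in% stages) {
    gg <- config$grm
    geno <- readDosageTsv(needArtifact(out("genotypes.tsv"), "simulate"))
    qc <- qcFilter(geno, gg$snpCallRate, gg$hwePCut, gg$mafCut,
                   gg$animalCallRate)
    grm <- computeGrm(qc, gg$ridgeEpsilon)
    writeGrmTsv(grm, out("grm.tsv"))
    yaml::write_yaml(attr(qc, "report"), out("qc-report.yml"))
    artifacts <- c(artifacts, out("grm.tsv"))
    state$grm <- grm
  }

  loadGrm <- function() {
    if (!is.null(state$grm)) return(state$grm)
    m <- as.matrix(utils::read.table(needArtifact(out("grm.tsv"), "grm"),
                                     header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
    dimnames(m) <- list(rownames(m), rownames(m))
    new("Grm", values = m, ridgeEpsilon = config$grm$ridgeEpsilon)
  }
  loadAlr <- function() {
    if (!is.null(state$alr)) return(state$alr)
    df <- utils::read.table(needArtifact(out("alr.tsv"), "coda"),
                            header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
    ref <- yaml::read_yaml(out("alr-reference.yml"))$reference
    new("LogRatioTable", values = t(as.matrix(df)), transformKind = "alr",
        referenceId = ref)
  }

  mcfg <- mcmcConfig(nIter = config$mcmc$nIter, burnIn = config$mcmc$burnIn,
                     thin = config$mcmc$thin,
                     seed = deriveSeed(config$seed, "mcmc"))

  if ("screen" %in% stages) {
    sc <- config$screen
    alr <- loadAlr(); grm <- loadGrm()
    hgfc <- screenFeatures(alr, fixedFactor, grm, mcfg, alpha = sc$alpha,
                           dicCut = sc$dicCut)
    goalsDf <- pheno
    keep <- hgfc$feature[hgfc$hgfc]
    if (!length(keep)) keep <- hgfc$feature[order(hgfc$dicDiff)][1:2]
    sub <- new("LogRatioTable",
               values = alr@values[, keep, drop = FALSE],
               transformKind = "alr", referenceId = alr@referenceId)
    rg <- estimateFeatureGoalRg(sub, goalsDf, fixedFactor, grm, mcfg,
                                goalCols = config$goals)
    corr <- screenCorrelations(rg, goals = config$goals, p0Cut = sc$p0Cut)
    .writeCsv(hgfc, out("screen-hgfc.csv"))
    .writeCsv(rg, out("screen-rg.csv"))
    .writeCsv(corr, out("screen-correlations.csv"))
    .writeCsv(data.frame(animal = rownames(attr(hgfc, "ebv")),
                         attr(hgfc, "ebv"), check.names = FALSE),
              out("feature-ebv.csv"))
    artifacts <- c(artifacts, out(c("screen-hgfc.csv", "screen-rg.csv",
                                    "screen-correlations.csv")))
    state$hgfc <- hgfc; state$corr <- corr
  }

  if ("select" %in% stages) {
    se <- config$select
    corr <- if (!is.null(state$corr)) state$corr else
      utils::read.csv(needArtifact(out("screen-correlations.csv"), "screen"))
    ebvDf <- utils::read.csv(needArtifact(out("feature-ebv.csv"), "screen"),
                             check.names = FALSE)
    ebvM <- as.matrix(ebvDf[, -1, drop = FALSE])
    rownames(ebvM) <- ebvDf$animal
    cand <- corr$feature[corr$sameSign]
    if (length(cand) < 3) cand <- corr$feature
    alr <- loadAlr()
    pre <- precorrectPhenotypes(alr@values[, cand, drop = FALSE], fixedFactor)
    netP <- buildNetwork(pre, se$rThreshold, basis = "phenotypic")
    netG <- buildNetwork(ebvM[, cand, drop = FALSE], se$rThreshold,
                         basis = "genomic")
    clG <- mclCluster(netG, se$inflation, se$minClusterSize)
    core <- if (!is.null(state$core)) state$core else {
      readAbundanceTsv(needArtifact(out("abundance.tsv"), "simulate"))
    }
    abundant <- abundanceFilter(intersect(cand, partIds(core)), core,
                                se$minMeanRA)
    if (length(abundant) < 2) abundant <- cand[seq_len(min(3, length(cand)))]
    rda <- rdaRedundancySelect(ebvM[, cand, drop = FALSE],
                               ebvM[, abundant, drop = FALSE],
                               alpha = se$rdaAlpha, nPerm = se$nPerm,
                               seed = deriveSeed(config$seed, "rda"))
    selected <- rda$retained
    if (!length(selected)) selected <- abundant
    writeEdgeListTsv(netP, out("network-phenotypic.tsv"))
    writeEdgeListTsv(netG, out("network-genomic.tsv"))
    .writeCsv(clG, out("clusters.csv"))
    .writeCsv(data.frame(feature = names(rda$pValues),
                         pValue = rda$pValues,
                         retained = names(rda$pValues) %in% selected),
              out("rda-selection.csv"))
    yaml::write_yaml(list(selected = as.list(selected)),
                     out("selected-features.yml"))
    artifacts <- c(artifacts, out(c("network-genomic.tsv", "clusters.csv",
                                    "rda-selection.csv")))
    state$selected <- selected
  }

  if ("predict" %in% stages) {
    pr <- config$predict
    selected <- if (!is.null(state$selected)) state$selected else
      unlist(yaml::read_yaml(needArtifact(out("selected-features.yml"),
                                          "select"))$selected)
    alr <- loadAlr(); grm <- loadGrm()
    goals <- config$goals
    Y <- cbind(alr@values[, selected, drop = FALSE],
               as.matrix(pheno[, goals, drop = FALSE]))
    colnames(Y) <- c(selected, goals)
    pw <- estimatePairwiseCovariances(Y, fixedFactor, grm, mcfg)
    vc <- bendVarianceComponents(assembleCovariance(pw), pr$bendTolerance)
    sub <- new("LogRatioTable",
               values = alr@values[, selected, drop = FALSE],
               transformKind = "alr", referenceId = alr@referenceId)
    pred <- predictGoalEbvs(sub, pheno, goals, grm, vc, fixedFactor, mcfg,
                            goalsMissing = TRUE)
    .writeCsv(pred$ebv, out("goal-ebv.csv"))
    pre <- precorrectPhenotypes(as.matrix(pheno[, goals, drop = FALSE]),
                                fixedFactor)
    phenoSd <- apply(pre, 2, stats::sd)
    ranking <- aggregateRank(pred$ebv, goals)
    rep <- selectionReport(pred$chain, ranking, phenoSd,
                           proportions = pr$proportions, traits = goals)
    .writeCsv(ranking, out("ranking.csv"))
    .writeCsv(rep, out("selection-report.csv"))
    artifacts <- c(artifacts, out(c("goal-ebv.csv", "selection-report.csv")))
    state$prediction <- pred; state$report <- rep
  }

  if ("report" %in% stages) {
    repPath <- needArtifact(out("selection-report.csv"), "predict")
    rep <- utils::read.csv(repPath)
    ebv <- utils::read.csv(needArtifact(out("goal-ebv.csv"), "predict"))
    lines <- c(
      "microbiome-driven breeding pipeline summary",
      sprintf("mean EBV accuracy: %s",
              paste(sprintf("%s=%.3f", unique(ebv$trait),
                            tapply(ebv$accuracy, ebv$trait, mean)),
                    collapse = ", ")),
      sprintf("response at p=%.2f (i=%.3f): %s",
              rep$proportion, rep$intensity,
              sprintf("%s %+.3f +/- %.3f sd", rep$trait, rep$responseMean,
                      rep$responseSd))
    )
    writeLines(lines, out("summary.txt"))
    artifacts <- c(artifacts, out("summary.txt"))
  }

  # provenance manifest
  cfgFile <- out("config.yml")
  yaml::write_yaml(unclass(config), cfgFile)
  manifest <- list(
    configHash = unname(tools::md5sum(cfgFile)),
    seed = config$seed,
    stages = stages,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(artifacts[file.exists(artifacts)])),
      basename(artifacts[file.exists(artifacts)])))
  )
  yaml::write_yaml(manifest, out("manifest.yml"))
  invisible(state)
}
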