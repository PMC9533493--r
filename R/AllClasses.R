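#' @import methods
NULL

#' CompositionTable: closed relative-abundance data
#'
#' Container for a samples x parts matrix of non-negative relative abundances
#' closed to 1, together with per-part occupancy (fraction of samples in which
#' the part is observed, computed on the raw table before any zero
#' replacement) and per-part mean relative abundance. Parts are typically
#' microbial gene (KEGG KO) abundances or fatty-acid proportions.
#'
#' @slot values numeric matrix, samples x parts; each row sums to 1.
#' @slot counts optional integer matrix of raw counts (same shape), or a
#'   0 x 0 matrix when counts are not available.
#' @slot occupancy named numeric vector, per-part occupancy in \[0, 1\].
#' @slot meanRA named numeric vector, per-part mean relative abundance.
#'
#' @seealso [compositionTable()], [filterCore()], [replaceZerosGBM()],
#'   [alrTransform()], [clrTransform()]
#' @export
setClass("CompositionTable",
  representation(
    values = "matrix",
    counts = "matrix",
    occupancy = "numeric",
    meanRA = "numeric"
  )
)

setValidity("CompositionTable", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    return("'values' must have sample (row) and part (column) names")
  }
  if (any(v < 0)) return("relative abundances must be non-negative")
  rs <- rowSums(v)
  if (any(abs(rs - 1) > 1e-8)) {
    return("rows must sum to 1 within 1e-8 (closure)")
  }
  if (length(object@occupancy) != ncol(v)) {
    return("'occupancy' must have one entry per part")
  }
  if (any(object@occupancy < 0 | object@occupancy > 1)) {
    return("occupancy must lie in [0, 1]")
  }
  if (length(object@meanRA) != ncol(v)) {
    return("'meanRA' must have one entry per part")
  }
  TRUE
})

#' LogRatioTable: log-ratio transformed compositions
#'
#' Samples x features matrix of alr- or clr-transformed relative abundances.
#' An alr table has J - 1 features (the reference part is dropped); a clr
#' table has J features and each row sums to 0.
#'
#' @slot values numeric matrix, samples x features.
#' @slot transformKind either `"alr"` or `"clr"`.
#' @slot referenceId the alr reference part id (`NA_character_` for clr).
#'
#' @seealso [alrTransform()], [clrTransform()]
#' @export
setClass("LogRatioTable",
  representation(
    values = "matrix",
    transformKind = "character",
    referenceId = "character"
  )
)

setValidity("LogRatioTable", function(object) {
  if (!object@transformKind %in% c("alr", "clr")) {
    return("'transformKind' must be \"alr\" or \"clr\"")
  }
  if (object@transformKind == "clr") {
    rs <- rowSums(object@values)
    if (any(abs(rs) > 1e-8)) return("clr rows must sum to 0 within 1e-8")
  }
  if (object@transformKind == "alr" && is.na(object@referenceId)) {
    return("alr tables must record their reference part")
  }
  TRUE
})

#' Grm: genomic relationship matrix
#'
#' Symmetric n x n genomic relationship matrix among animals (VanRaden
#' method 2 scaling), with the ridge added to the diagonal recorded.
#'
#' @slot values numeric symmetric matrix with animal ids as dimnames.
#' @slot ridgeEpsilon ridge added to the diagonal to guarantee positive
#'   definiteness.
#'
#' @seealso [computeGrm()]
#' @export
setClass("Grm",
  representation(values = "matrix", ridgeEpsilon = "numeric")
)

setValidity("Grm", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("GRM must be square")
  if (max(abs(v - t(v))) > 1e-10) return("GRM must be symmetric within 1e-10")
  if (is.null(rownames(v))) return("GRM must carry animal ids as dimnames")
  TRUE
})

#' PosteriorChain: thinned MCMC draws from a GBLUP Gibbs sampler
#'
#' Stores the post burn-in, thinned draws of fixed effects and variance
#' components, the per-draw log-likelihood of the observed phenotypes
#' (conditional on location parameters, used for DIC, and marginalized over
#' breeding values, used for Bayes factors), and optionally per-animal
#' breeding-value draws for selected traits.
#'
#' @slot draws numeric matrix, stored draws x parameters (named columns:
#'   `b[level,trait]`, `sigmaG[i,j]`, `sigmaE[i,j]`).
#' @slot logLik per-draw log-likelihood of the observed data given location
#'   parameters (fixed effects + breeding values) and the residual
#'   (co)variance.
#' @slot logLikMarginal per-draw log-likelihood with breeding values
#'   integrated out (equals `logLik` for models without a genomic effect).
#' @slot ebvDraws list of stored-draws x animals matrices of breeding-value
#'   draws, named by trait (possibly empty).
#' @slot ebvTraits traits for which breeding-value draws were stored.
#' @slot traitIds analysed trait ids.
#' @slot animalIds animal ids, in GRM order.
#' @slot config the [mcmcConfig()] list used.
#' @slot model list describing the model (genomic effect present, fixed
#'   variance components, factor levels, data variances, bound violations).
#' @export
setClass("PosteriorChain",
  representation(
    draws = "matrix",
    logLik = "numeric",
    logLikMarginal = "numeric",
    ebvDraws = "list",
    ebvTraits = "character",
    traitIds = "character",
    animalIds = "character",
    config = "list",
    model = "list"
  )
)

setValidity("PosteriorChain", function(object) {
  if (nrow(object@draws) != length(object@logLik)) {
    return("one log-likelihood per stored draw is required")
  }
  TRUE
})

#' VarianceComponents: multi-trait genomic and residual covariance matrices
#'
#' Host genomic and residual (co)variance matrices assembled from pairwise
#' bivariate analyses (off-diagonals from the pair posterior means, diagonals
#' from averaged posterior means), possibly after bending to positive
#' definiteness.
#'
#' @slot traitIds trait ids (dimnames of both matrices).
#' @slot sigmaG genomic (co)variance matrix.
#' @slot sigmaE residual (co)variance matrix.
#' @slot bendLog list with one entry per matrix recording the bending change
#'   (Frobenius change, min eigenvalue before/after, element-wise change).
#' @seealso [assembleCovariance()], [bendToPd()]
#' @export
setClass("VarianceComponents",
  representation(
    traitIds = "character",
    sigmaG = "matrix",
    sigmaE = "matrix",
    bendLog = "list"
  )
)

setValidity("VarianceComponents", function(object) {
  for (nm in c("sigmaG", "sigmaE")) {
    m <- slot(object, nm)
    if (nrow(m) != length(object@traitIds)) {
      return(sprintf("'%s' must be square with one row per trait", nm))
    }
    if (max(abs(m - t(m))) > 1e-8) return(sprintf("'%s' must be symmetric", nm))
  }
  TRUE
})

#' CoabundanceGraph: thresholded correlation network of features
#'
#' Undirected weighted graph connecting features whose pairwise Pearson
#' correlation exceeds a threshold in absolute value. Weights keep the sign
#' of the correlation.
#'
#' @slot nodes feature ids (including isolated nodes).
#' @slot edges data.frame with columns `from`, `to`, `weight`.
#' @slot basis `"phenotypic"` (pre-corrected data) or `"genomic"` (EBVs).
#' @slot threshold absolute-correlation threshold used (strict `>`).
#' @seealso [buildNetwork()], [mclCluster()]
#' @export
setClass("CoabundanceGraph",
  representation(
    nodes = "character",
    edges = "data.frame",
    basis = "character",
    threshold = "numeric"
  )
)

setValidity("CoabundanceGraph", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e))) {
    return("edges need 'from', 'to', 'weight' columns")
  }
  if (nrow(e) > 0) {
    if (any(e$from == e$to)) return("self-loops are not allowed")
    if (any(abs(e$weight) <= object@threshold)) {
      return("all edge weights must exceed the threshold in absolute value")
    }
  }
  TRUE
})
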