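# Co-abundance networks, Markov clustering, variance-explained pre-analysis
# and redundancy-based candidate reduction.

#' Pre-correct phenotypes for a fixed factor
#'
#' Subtracts per-level means, returning residuals and the per-column R2
#' (fraction of the total sum of squares explained by level means).
#'
#' @param values numeric matrix or data.frame (animals x traits/features).
#' @param fixedFactor factor with one level per animal.
#' @return residual matrix with attribute `"r2"` (per column).
#' @export
precorrectPhenotypes <- function(values, fixedFactor) {
  V <- as.matrix(values)
  f <- droplevels(as.factor(fixedFactor))
  if (length(f) != nrow(V)) stop("one factor level per animal is required")
  if (any(table(f) == 1)) {
    warning("factor level(s) with a single animal: residual forced to 0")
  }
  lm_ <- apply(V, 2, function(y) stats::ave(y, f))
  R <- V - lm_
  tot <- colSums(sweep(V, 2, colMeans(V))^2)
  r2 <- ifelse(tot > 0, 1 - colSums(R^2) / tot, NA_real_)
  attr(R, "r2") <- r2
  R
}

#' Multivariate variance explained by a one-way factor
#'
#' Trace of the between-level sum of squares over the trace of the total
#' sum of squares (the redundancy-analysis R2 of a single categorical
#' predictor; equals the one-way ANOVA R2 for a single response column).
#'
#' @param responses numeric matrix (animals x responses).
#' @param fixedFactor factor with >= 2 levels.
#' @return proportion in \[0, 1\].
#' @export
varianceExplained <- function(responses, fixedFactor) {
  V <- as.matrix(responses)
  f <- droplevels(as.factor(fixedFactor))
  if (nlevels(f) < 2) stop("at least 2 factor levels are required")
  tot <- sum(sweep(V, 2, colMeans(V))^2)
  if (tot <= 0) stop("zero total variance")
  fitted <- apply(V, 2, function(y) stats::ave(y, f))
  between <- sum(sweep(fitted, 2, colMeans(V))^2)
  between / tot
}

#' Build a co-abundance correlation network
#'
#' Connects two features when the absolute Pearson correlation of their
#' columns strictly exceeds `rThreshold`; edge weights keep the sign.
#' Zero-variance columns are excluded with a warning.
#'
#' @param values animals x features matrix (pre-corrected abundances or
#'   EBVs).
#' @param rThreshold absolute-correlation threshold (default 0.30,
#'   strict `>`).
#' @param basis `"phenotypic"` or `"genomic"` (metadata only).
#' @return a [CoabundanceGraph-class].
#' @export
buildNetwork <- function(values, rThreshold = 0.30, basis = "phenotypic") {
  V <- as.matrix(values)
  if (nrow(V) < 3) stop("at least 3 animals are required")
  if (is.null(colnames(V))) colnames(V) <- paste0("F", seq_len(ncol(V)))
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance feature(s): ",
            paste(colnames(V)[sds == 0], collapse = ", "))
    V <- V[, sds > 0, drop = FALSE]
  }
  R <- stats::cor(V)
  idx <- which(upper.tri(R) & abs(R) > rThreshold, arr.ind = TRUE)
  edges <- data.frame(
    from = colnames(V)[idx[, 1]],
    to = colnames(V)[idx[, 2]],
    weight = R[idx],
    stringsAsFactors = FALSE
  )
  new("CoabundanceGraph", nodes = colnames(V), edges = edges,
      basis = basis, threshold = rThreshold)
}

# adjacency matrix of |weights|
.graphAdjacency <- function(graph) {
  n <- length(graph@nodes)
  A <- matrix(0, n, n, dimnames = list(graph@nodes, graph@nodes))
  e <- graph@edges
  if (nrow(e)) {
    i <- match(e$from, graph@nodes); j <- match(e$to, graph@nodes)
    A[cbind(i, j)] <- abs(e$weight)
    A[cbind(j, i)] <- abs(e$weight)
  }
  A
}

#' Markov clustering of a co-abundance graph
#'
#' Flow-simulation clustering on the absolute-weight adjacency matrix with
#' self-loops of weight 1: alternate expansion (matrix squaring) and
#' inflation (elementwise power `inflation` followed by column
#' renormalization) until the matrix change drops below `tol`. Clusters are
#' read off as the attractor basins of the converged flow matrix; clusters
#' smaller than `minClusterSize` (the granularity) are reported as
#' unclustered (`NA`).
#'
#' @param graph a [CoabundanceGraph-class].
#' @param inflation inflation exponent (default 2).
#' @param minClusterSize minimum cluster size (default 2).
#' @param maxIter iteration cap (default 200).
#' @param tol convergence tolerance on the max absolute change (default
#'   1e-8).
#' @return data.frame with columns `node` and `cluster` (integer, `NA` for
#'   unclustered); cluster count attached as attribute `"nClusters"`.
#' @export
mclCluster <- function(graph, inflation = 2, minClusterSize = 2,
                       maxIter = 200, tol = 1e-8) {
  stopifnot(is(graph, "CoabundanceGraph"))
  if (!length(graph@nodes)) stop("empty graph")
  A <- .graphAdjacency(graph)
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("Markov clustering did not converge after ", maxIter, " iterations")
  }
  # attractor interpretation: rows with mass are attractors; nodes sharing
  # support belong to one cluster (union over overlapping attractor rows)
  eps <- 1e-6
  n <- nrow(M)
  attractors <- which(diag(M) > eps)
  membership <- rep(NA_integer_, n)
  cl <- 0L
  for (a in attractors) {
    members <- which(M[a, ] > eps)
    existing <- unique(stats::na.omit(membership[members]))
    if (length(existing)) {
      id <- existing[1]
      membership[members] <- id
      if (length(existing) > 1) {
        membership[membership %in% existing[-1]] <- id
      }
    } else {
      cl <- cl + 1L
      membership[members] <- cl
    }
  }
  # renumber and apply granularity
  sizes <- table(membership)
  small <- as.integer(names(sizes)[sizes < minClusterSize])
  membership[membership %in% small] <- NA_integer_
  membership <- as.integer(factor(membership))
  data.frame(node = graph@nodes, cluster = membership,
             stringsAsFactors = FALSE) ->
    out
  attr(out, "nClusters") <- length(unique(stats::na.omit(membership)))
  out
}

#' Filter candidate features by numerator abundance
#'
#' Retains candidates whose numerator part has mean relative abundance at
#' least `minMeanRA` (inclusive) in the composition table.
#'
#' @param candidates character vector of feature (part) ids.
#' @param table a [CompositionTable-class].
#' @param minMeanRA threshold on the mean relative abundance (default 1e-4,
#'   i.e. 0.01%).
#' @return the retained subset of `candidates`.
#' @export
abundanceFilter <- function(candidates, table, minMeanRA = 1e-4) {
  stopifnot(is(table, "CompositionTable"))
  miss <- setdiff(candidates, partIds(table))
  if (length(miss)) {
    stop("candidates not in the table: ", paste(miss, collapse = ", "))
  }
  candidates[table@meanRA[candidates] >= minMeanRA]
}

#' Redundancy-based candidate selection
#'
#' Regresses a multivariate response matrix (typically the EBVs of the full
#' candidate-relevant feature set) on the candidate matrix and tests each
#' candidate's marginal contribution with a permutation F test: the
#' marginal pseudo-F compares the trace sum of squares gained by adding the
#' candidate to the model containing all others against the full-model
#' residual, and the null distribution is built by permuting the residuals
#' of the reduced model (Freedman-Lane). Candidates with marginal P value
#' above `alpha` are discarded as redundant. Exactly collinear candidates
#' are resolved by dropping later duplicates with a warning.
#'
#' @param response animals x responses numeric matrix.
#' @param candidates animals x candidates numeric matrix.
#' @param alpha retention threshold on the marginal P value (default 0.05).
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `retained` (character), `pValues` (named numeric) and
#'   `dropped` (aliased candidates removed before testing).
#' @export
rdaRedundancySelect <- function(response, candidates, alpha = 0.05,
                                nPerm = 999, seed = 1L) {
  Yr <- as.matrix(response)
  Xc <- as.matrix(candidates)
  if (is.null(colnames(Xc))) colnames(Xc) <- paste0("C", seq_len(ncol(Xc)))
  n <- nrow(Yr)
  if (nrow(Xc) != n) stop("response and candidates must share animals")
  if (ncol(Xc) >= n) stop("more candidates than animals")
  if (any(apply(Xc, 2, stats::sd) == 0)) stop("constant candidate column")
  # drop exactly collinear later columns
  qrX <- qr(scale(Xc, scale = FALSE))
  dropped <- character(0)
  if (qrX$rank < ncol(Xc)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(Xc)[-keep]
    warning("dropping collinear candidate(s): ",
            paste(dropped, collapse = ", "))
    Xc <- Xc[, sort(keep), drop = FALSE]
  }
  Yc <- scale(Yr, scale = FALSE)
  set.seed(seed)
  perms <- replicate(nPerm, sample.int(n), simplify = FALSE)
  ssFit <- function(Xm, Ym) {
    # explained trace SS of Ym on centred predictors Xm
    f <- qr.fitted(qr(cbind(1, Xm)), Ym)
    sum(sweep(f, 2, colMeans(Ym))^2)
  }
  q <- ncol(Xc)
  ssFull <- ssFit(Xc, Yc)
  ssTot <- sum(Yc^2)
  rssFull <- ssTot - ssFull
  dfRes <- n - q - 1
  pvals <- numeric(q)
  names(pvals) <- colnames(Xc)
  for (j in seq_len(q)) {
    Xred <- Xc[, -j, drop = FALSE]
    qrRed <- qr(cbind(1, Xred))
    fitRed <- qr.fitted(qrRed, Yc)
    resRed <- Yc - fitRed
    ssRed <- if (ncol(Xred)) ssFit(Xred, Yc) else 0
    fObs <- ((ssFull - ssRed) / 1) / (rssFull / dfRes)
    # Freedman-Lane: permute reduced-model residuals
    fPerm <- vapply(perms, function(pp) {
      Yp <- fitRed + resRed[pp, , drop = FALSE]
      ssFullP <- ssFit(Xc, Yp)
      ssRedP <- if (ncol(Xred)) ssFit(Xred, Yp) else 0
      rssP <- sum(sweep(Yp, 2, colMeans(Yp))^2) - ssFullP
      ((ssFullP - ssRedP) / 1) / (rssP / dfRes)
    }, numeric(1))
    pvals[j] <- (1 + sum(fPerm >= fObs)) / (nPerm + 1)
  }
  retained <- names(pvals)[pvals <= alpha]
  list(retained = retained, pValues = pvals, dropped = dropped)
}
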