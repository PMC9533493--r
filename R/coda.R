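# Compositional preprocessing: core filtering, zero replacement, log-ratio
# transforms, alr reference selection and fatty-acid indices.

#' Filter the functional core of a composition
#'
#' Retains parts present in at least `minOccupancy` of the samples (occupancy
#' is assessed on the raw table, zeros counting as real absences) and with
#' mean relative abundance of at least `minMeanRA`; both thresholds are
#' inclusive. The filtered table is re-closed.
#'
#' @param table a [CompositionTable-class].
#' @param minOccupancy minimum occupancy (default 0.70).
#' @param minMeanRA minimum mean relative abundance (default 1e-5,
#'   i.e. 0.001%).
#' @return a filtered, re-closed [CompositionTable-class]. The number of
#'   retained parts and their cumulative relative abundance before re-closure
#'   are attached as attribute `"report"`.
#' @export
filterCore <- function(table, minOccupancy = 0.70, minMeanRA = 1e-5) {
  stopifnot(is(table, "CompositionTable"))
  if (minOccupancy < 0 || minOccupancy > 1 || minMeanRA < 0 || minMeanRA > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  keep <- table@occupancy >= minOccupancy & table@meanRA >= minMeanRA
  if (!any(keep)) stop("core filter removed every part")
  sub <- table@values[, keep, drop = FALSE]
  cumRA <- mean(rowSums(sub))
  out <- compositionTable(sub,
    counts = if (nrow(table@counts) > 0) {
      table@counts[, keep, drop = FALSE]
    } else NULL)
  # occupancy/meanRA of the retained parts refer to the original table
  out@occupancy <- table@occupancy[keep]
  out@meanRA <- table@meanRA[keep]
  attr(out, "report") <- list(retained = sum(keep), removed = sum(!keep),
                              cumulativeRA = cumRA)
  out
}

#' Geometric Bayesian-multiplicative replacement of zero abundances
#'
#' Replaces zero relative abundances by the posterior expectation of the
#' multinomial probability under a Dirichlet prior, then multiplicatively
#' rescales the non-zero parts so that ratios among originally observed
#' parts are preserved and each row still sums to 1.
#'
#' The prior follows the geometric Bayesian-multiplicative (GBM) scheme: the
#' prior proportions `t_j` are the closed geometric means of the positive
#' abundances of each part across samples (so rare-but-present parts get
#' small pseudo-abundances rather than a uniform 1/J), and the prior strength
#' for sample `i` is `s_i = sqrt(n_i)` with `n_i` the sample's count total.
#' A zero in sample `i`, part `j` is imputed as
#' `r_ij = t_j * s_i / (n_i + s_i)`, and the observed parts of the row are
#' scaled by `1 - sum(r_ij over imputed j)`.
#'
#' @param table a [CompositionTable-class]; zeros allowed.
#' @param pseudoTotal per-sample count totals `n_i` (recycled scalar allowed).
#'   When the table carries raw counts, the actual row totals are used and
#'   this argument is ignored.
#' @return a strictly positive [CompositionTable-class] with the original
#'   occupancy metadata.
#' @export
replaceZerosGBM <- function(table, pseudoTotal = 10000) {
  stopifnot(is(table, "CompositionTable"))
  x <- table@values
  if (any(rowSums(x > 0) == 0)) stop("a sample with all-zero abundances")
  if (!any(x == 0)) return(table)
  if (nrow(table@counts) > 0) {
    n <- rowSums(table@counts)
  } else {
    n <- rep_len(pseudoTotal, nrow(x))
  }
  if (any(n <= 0)) stop("'pseudoTotal' must be positive")
  # GBM prior proportions: closed geometric means over observed values
  g <- apply(x, 2, function(col) {
    pos <- col[col > 0]
    if (!length(pos)) return(NA_real_)
    exp(mean(log(pos)))
  })
  # a part absent everywhere would have an undefined prior; fall back to the
  # smallest observed prior mass
  g[is.na(g)] <- min(g, na.rm = TRUE)
  t_j <- g / sum(g)
  s <- sqrt(n)
  out <- x
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (!any(z)) next
    r <- t_j[z] * s[i] / (n[i] + s[i])
    out[i, z] <- r
    out[i, !z] <- x[i, !z] * (1 - sum(r)) / sum(x[i, !z])
  }
  res <- table
  res@values <- out
  validObject(res)
  res
}

#' Additive log-ratio transform
#'
#' `alr(x)_j = ln(x_j) - ln(x_ref)` for every part except the reference,
#' which is dropped. Scale-invariant: rescaling a raw sample before closure
#' leaves the output unchanged.
#'
#' @param table a strictly positive [CompositionTable-class].
#' @param referenceId id of the reference part.
#' @return a [LogRatioTable-class] with J - 1 features.
#' @export
alrTransform <- function(table, referenceId) {
  stopifnot(is(table, "CompositionTable"))
  x <- table@values
  if (any(x == 0)) {
    stop("zeros present: run replaceZerosGBM() before alrTransform()")
  }
  if (!referenceId %in% colnames(x)) {
    stop(sprintf("reference part '%s' not found", referenceId))
  }
  lx <- log(x)
  v <- lx[, setdiff(colnames(x), referenceId), drop = FALSE] -
    lx[, referenceId]
  new("LogRatioTable", values = v, transformKind = "alr",
      referenceId = referenceId)
}

#' Centred log-ratio transform
#'
#' `clr(x)_j = ln(x_j) - mean_j ln(x_j)`; every row of the output sums to 0.
#'
#' @param table a strictly positive [CompositionTable-class].
#' @return a [LogRatioTable-class] with J features.
#' @export
clrTransform <- function(table) {
  stopifnot(is(table, "CompositionTable"))
  x <- table@values
  if (any(x == 0)) {
    stop("zeros present: run replaceZerosGBM() before clrTransform()")
  }
  lx <- log(x)
  v <- lx - rowMeans(lx)
  new("LogRatioTable", values = v, transformKind = "clr",
      referenceId = NA_character_)
}

#' Procrustes correlation between two sample configurations
#'
#' Correlation between two multivariate configurations of the same samples
#' after optimal translation, rotation/reflection and positive scaling of
#' the second onto the first (the square root of 1 minus the symmetric
#' Procrustes sum of squares). Invariant to orthogonal rotation and positive
#' rescaling of either configuration.
#'
#' @param target numeric matrix, samples x d.
#' @param test numeric matrix, samples x d' (columns are zero-padded to the
#'   wider of the two configurations).
#' @return a scalar in \[0, 1\].
#' @export
procrustesCorrelation <- function(target, test) {
  target <- as.matrix(target); test <- as.matrix(test)
  if (nrow(target) != nrow(test)) stop("configurations must share samples")
  if (nrow(target) < 3) stop("at least 3 samples are required")
  d <- max(ncol(target), ncol(test))
  pad <- function(m) {
    if (ncol(m) < d) m <- cbind(m, matrix(0, nrow(m), d - ncol(m)))
    m
  }
  X <- scale(pad(target), center = TRUE, scale = FALSE)
  Y <- scale(pad(test), center = TRUE, scale = FALSE)
  nx <- sqrt(sum(X^2)); ny <- sqrt(sum(Y^2))
  if (nx == 0 || ny == 0) stop("degenerate (constant) configuration")
  X <- X / nx; Y <- Y / ny
  sv <- svd(crossprod(X, Y))$d
  min(1, sum(sv))
}

#' Rank candidate alr reference parts
#'
#' For each candidate, computes (i) the Procrustes correlation between the
#' exact log-ratio geometry of the table (its clr coordinates, isometric to
#' the full pairwise log-ratio geometry) and the alr coordinates taking that
#' candidate as the reference, and (ii) the variance of the candidate's
#' log-transformed relative abundance. Candidates are ranked by a
#' lexicographic trade-off: among candidates within `epsProcrustes` of the
#' maximum Procrustes correlation, the one with the smallest log variance
#' wins. The five-point summary and coefficient of variation of the log
#' abundance are reported for each candidate.
#'
#' @param table a strictly positive [CompositionTable-class].
#' @param candidates character vector of candidate part ids (default: all
#'   parts).
#' @param epsProcrustes tolerance below the maximum Procrustes correlation
#'   within which candidates are treated as ties (default 0.005).
#' @return a data.frame, one row per candidate in rank order, with columns
#'   `part`, `procrustes`, `logVariance`, `cv`, `min`, `q1`, `median`,
#'   `mean`, `q3`, `max`, `rank`.
#' @export
selectAlrReference <- function(table, candidates = partIds(table),
                               epsProcrustes = 0.005) {
  stopifnot(is(table, "CompositionTable"))
  if (length(candidates) == 0) stop("empty candidate set")
  if (!all(candidates %in% partIds(table))) stop("unknown candidate part")
  x <- table@values
  if (any(x == 0)) stop("zeros present: replace zeros first")
  exact <- clrTransform(table)@values
  rows <- lapply(candidates, function(ref) {
    a <- alrTransform(table, ref)@values
    lref <- log(x[, ref])
    fp <- stats::quantile(lref, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(
      part = ref,
      procrustes = procrustesCorrelation(exact, a),
      logVariance = stats::var(lref),
      cv = stats::sd(lref) / abs(mean(lref)),
      min = fp[1], q1 = fp[2], median = fp[3], mean = mean(lref),
      q3 = fp[4], max = fp[5],
      stringsAsFactors = FALSE
    )
  })
  rep <- do.call(rbind, rows)
  best <- max(rep$procrustes)
  tied <- rep$procrustes >= best - epsProcrustes
  # ties on Procrustes are broken by low log variance; the rest rank by
  # Procrustes correlation
  ord <- order(!tied, ifelse(tied, rep$logVariance, -rep$procrustes))
  rep <- rep[ord, , drop = FALSE]
  rep$rank <- seq_len(nrow(rep))
  rownames(rep) <- NULL
  rep
}

#' Fatty-acid indices of beef healthfulness
#'
#' Computes, per animal, the natural-log ratios of beneficial to
#' hypercholesterolemic saturated fatty acids (contents in g/100 g meat):
#' \deqn{N3 = \ln\frac{C18:3n\text{-}3 + C20:5n\text{-}3 + C22:5n\text{-}3 +
#'   C22:6n\text{-}3}{C12:0 + C14:0 + C16:0}}
#' \deqn{CLA = \ln\frac{cis\text{-}9,trans\text{-}11\ C18:2 +
#'   trans\text{-}11\ C18:1}{C12:0 + C14:0 + C16:0}}
#'
#' @param fa data.frame with one row per animal; required columns
#'   `C12.0`, `C14.0`, `C16.0`, `C18.3n3`, `C20.5n3`, `C22.5n3`, `C22.6n3`,
#'   `CLA.c9t11`, `C18.1t11`, plus optional `animal`.
#' @return data.frame with columns `animal`, `N3`, `CLA`. Animals with a
#'   non-positive numerator or denominator get `NA` with a warning.
#' @export
computeFattyAcidIndices <- function(fa) {
  req <- c("C12.0", "C14.0", "C16.0", "C18.3n3", "C20.5n3", "C22.5n3",
           "C22.6n3", "CLA.c9t11", "C18.1t11")
  miss <- setdiff(req, names(fa))
  if (length(miss)) {
    stop("missing fatty-acid columns: ", paste(miss, collapse = ", "))
  }
  den <- fa$C12.0 + fa$C14.0 + fa$C16.0
  numN3 <- fa$C18.3n3 + fa$C20.5n3 + fa$C22.5n3 + fa$C22.6n3
  numCLA <- fa$CLA.c9t11 + fa$C18.1t11
  bad <- den <= 0 | numN3 <= 0 | numCLA <= 0
  if (any(bad)) {
    warning(sum(bad), " animal(s) with non-positive numerator or",
            " denominator: indices set to NA")
  }
  n3 <- ifelse(den > 0 & numN3 > 0, log(numN3 / den), NA_real_)
  cla <- ifelse(den > 0 & numCLA > 0, log(numCLA / den), NA_real_)
  data.frame(
    animal = if (!is.null(fa$animal)) fa$animal else seq_len(nrow(fa)),
    N3 = n3, CLA = cla, stringsAsFactors = FALSE
  )
}
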