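# Numeric helpers shared across modules.

#' Shortest 95% highest posterior density interval
#'
#' Scans the sorted draws for the shortest window containing the requested
#' probability mass.
#'
#' @param draws numeric vector of posterior draws.
#' @param prob probability mass of the interval (default 0.95).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpdInterval <- function(draws, prob = 0.95) {
  stopifnot(is.numeric(draws), length(draws) >= 2, prob > 0, prob < 1)
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Geweke convergence Z score
#'
#' Compares the mean of the first 10% of a chain with the mean of the last
#' 50%, standardized by spectral variance estimates at frequency zero
#' (Bartlett window over the first 4% of lags in each window).
#'
#' @param x numeric chain.
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return Z score, or `NA` with a warning for a constant chain.
#' @export
gewekeZ <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  stopifnot(n >= 20)
  if (stats::sd(x) == 0) {
    warning("constant chain: Geweke Z undefined")
    return(NA_real_)
  }
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  sv <- function(y) {
    ny <- length(y)
    lmax <- max(1L, floor(0.04 * ny))
    yc <- y - mean(y)
    g0 <- sum(yc^2) / ny
    s <- g0
    for (k in seq_len(lmax)) {
      gk <- sum(yc[1:(ny - k)] * yc[(k + 1):ny]) / ny
      s <- s + 2 * (1 - k / (lmax + 1)) * gk
    }
    max(s, .Machine$double.eps)
  }
  (mean(a) - mean(b)) / sqrt(sv(a) / length(a) + sv(b) / length(b))
}

#' Monte Carlo standard error by batch means
#'
#' @param x numeric chain.
#' @param nBatches number of batches (default 20).
#' @return Monte Carlo standard error of the chain mean.
#' @export
mcError <- function(x, nBatches = 20) {
  n <- length(x)
  stopifnot(n >= nBatches)
  size <- floor(n / nBatches)
  bm <- vapply(seq_len(nBatches),
               function(i) mean(x[((i - 1) * size + 1):(i * size)]),
               numeric(1))
  stats::sd(bm) / sqrt(nBatches)
}

# log(sum(exp(x))) without overflow
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible child seed
#'
#' Stable polynomial hash of a global seed plus string labels, mapped into
#' the 32-bit integer range. Used so that per-stage and per-feature analyses
#' are independently reproducible from one global seed.
#'
#' @param seed integer global seed.
#' @param ... character or numeric labels (stage name, feature id, ...).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
deriveSeed <- function(seed, ...) {
  labels <- paste(c(seed, unlist(list(...))), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(labels)) h <- (h * 31 + cc) %% 2147483629
  as.integer(h)
}

# closure of a non-negative matrix's rows to sum 1
closeRows <- function(m) {
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("cannot close a row with non-positive total")
  sweep(m, 1, rs, "/")
}

# Build a CompositionTable from a non-negative matrix (samples x parts).
# Occupancy and mean RA are computed on the closed input, before any zero
# replacement.

#' Construct a CompositionTable
#'
#' Closes each row to sum 1 and records per-part occupancy (fraction of
#' samples with a strictly positive value, computed before any zero
#' replacement) and mean relative abundance.
#'
#' @param m non-negative numeric matrix, samples x parts, with dimnames.
#' @param counts optional integer matrix of raw counts (same shape).
#' @return a [CompositionTable-class] object.
#' @export
compositionTable <- function(m, counts = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0)) stop("relative abundances must be non-negative")
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("P", seq_len(ncol(m)))
  closed <- closeRows(m)
  occ <- colMeans(closed > 0)
  mra <- colMeans(closed)
  if (is.null(counts)) counts <- matrix(numeric(0), 0, 0)
  new("CompositionTable", values = closed, counts = counts,
      occupancy = occ, meanRA = mra)
}
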