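# SNP quality control and the VanRaden method-2 genomic relationship matrix.

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against expectations under Hardy-Weinberg proportions with the allele
#' frequency estimated from the same counts. Monomorphic SNPs return a
#' statistic of 0 by convention (they are removed by the MAF filter anyway).
#'
#' @param nAA,nAa,naa genotype counts.
#' @return list with `chisq` and `p`.
#' @export
hweChisq <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  if (n <= 0) stop("no genotyped animals")
  p <- (2 * nAA + nAa) / (2 * n)
  if (p <= 0 || p >= 1) return(list(chisq = 0, p = 1))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(nAA, nAa, naa) - e)^2 / e)
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' SNP and animal quality control
#'
#' Removes SNPs with call rate below `snpCallRate`, Hardy-Weinberg
#' chi-square P value below `hwePCut`, or minor allele frequency below
#' `mafCut`; then removes animals with call rate below `animalCallRate`.
#'
#' @param geno animals x SNPs dosage matrix in `{0, 1, 2}` with `NA` for
#'   missing calls; dimnames required.
#' @param snpCallRate,hwePCut,mafCut,animalCallRate thresholds (defaults
#'   0.95, 1e-8, 0.05, 0.90).
#' @return the filtered dosage matrix, with a QC report (counts removed per
#'   criterion) attached as attribute `"report"`.
#' @export
qcFilter <- function(geno, snpCallRate = 0.95, hwePCut = 1e-8,
                     mafCut = 0.05, animalCallRate = 0.90) {
  stopifnot(is.matrix(geno))
  bad <- stats::na.omit(unique(as.vector(geno)))
  if (!all(bad %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  callRate <- colMeans(!is.na(geno))
  freq <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  hweP <- apply(geno, 2, function(g) {
    g <- g[!is.na(g)]
    hweChisq(sum(g == 2), sum(g == 1), sum(g == 0))$p
  })
  failCall <- callRate < snpCallRate
  failHwe <- hweP < hwePCut
  failMaf <- maf < mafCut
  keepSnp <- !(failCall | failHwe | failMaf)
  if (!any(keepSnp)) stop("quality control removed every SNP")
  out <- geno[, keepSnp, drop = FALSE]
  animalCall <- rowMeans(!is.na(out))
  keepAnimal <- animalCall >= animalCallRate
  out <- out[keepAnimal, , drop = FALSE]
  attr(out, "report") <- list(
    snpLowCallRate = sum(failCall),
    snpHweFail = sum(failHwe),
    snpLowMaf = sum(failMaf),
    snpRemoved = sum(!keepSnp),
    animalRemoved = sum(!keepAnimal),
    snpKept = ncol(out),
    animalKept = nrow(out)
  )
  out
}

#' Genomic relationship matrix (VanRaden method 2)
#'
#' Builds `G = Z D Z'` from column-centred dosages `Z = M - 2p`, with the
#' per-SNP weights `D_jj = 1 / (m * 2 p_j (1 - p_j))` so each SNP
#' contributes equally regardless of its allele frequency; `m` is the SNP
#' count and `p_j` the allele frequency estimated from the data. Missing
#' dosages are mean-imputed per SNP before centring. A small ridge is added
#' to the diagonal to guarantee invertibility in the mixed-model equations.
#'
#' @param geno animals x SNPs dosage matrix (post-QC); `NA` allowed.
#' @param ridgeEpsilon ridge added to the diagonal (default 1e-6).
#' @param alleleFreq optional per-SNP allele frequencies of the base
#'   population; estimated from the sample when `NULL` (the default). With
#'   sample frequencies, relationships are expressed relative to the
#'   genotyped animals themselves (rows of `G` sum to ~0).
#' @return a [Grm-class] object.
#' @export
computeGrm <- function(geno, ridgeEpsilon = 1e-6, alleleFreq = NULL) {
  stopifnot(is.matrix(geno))
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("A", seq_len(nrow(geno)))
  }
  p <- if (is.null(alleleFreq)) colMeans(geno, na.rm = TRUE) / 2 else
    rep_len(alleleFreq, ncol(geno))
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic SNP present: run qcFilter() first")
  }
  m <- ncol(geno)
  M <- geno
  if (anyNA(M)) {
    for (j in which(colSums(is.na(M)) > 0)) {
      M[is.na(M[, j]), j] <- 2 * p[j]
    }
  }
  Z <- sweep(M, 2, 2 * p)
  w <- 1 / (m * 2 * p * (1 - p))
  G <- tcrossprod(sweep(Z, 2, sqrt(w), "*"))
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + ridgeEpsilon
  dimnames(G) <- list(rownames(geno), rownames(geno))
  new("Grm", values = G, ridgeEpsilon = ridgeEpsilon)
}

#' Read genotypes from a VCF file
#'
#' Parses the GT field of a diploid, possibly unphased VCF into an
#' animals x SNPs dosage matrix (count of alternate alleles; `NA` for
#' missing calls). Requires the `vcfR` package.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return dosage matrix with animal row names and SNP id column names.
#' @export
readGenotypesVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
  })
  t(dos)
}

#' Read a TSV dosage matrix
#'
#' Expects a header row of SNP ids and a first column of animal ids.
#'
#' @param path TSV file path.
#' @return numeric dosage matrix, animals x SNPs.
#' @export
readDosageTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a GRM to TSV
#'
#' @param grm a [Grm-class].
#' @param path output path; animal ids form the header and first column.
#' @return invisibly, the path.
#' @export
writeGrmTsv <- function(grm, path) {
  stopifnot(is(grm, "Grm"))
  df <- data.frame(animal = rownames(grm@values), grm@values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
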