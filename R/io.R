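# Plain-text readers and writers for the pipeline artifacts.

#' Read an abundance table from TSV
#'
#' Expects features x samples orientation (header row of sample ids, first
#' column of feature ids), the layout produced by [writeAbundanceTsv()].
#'
#' @param path TSV file.
#' @return a [CompositionTable-class] (rows closed to 1).
#' @export
readAbundanceTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  m <- t(as.matrix(df))
  compositionTable(m)
}

#' Write an abundance table to TSV (features x samples)
#'
#' @param table a [CompositionTable-class]; counts are written when
#'   attached, proportions otherwise.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAbundanceTsv <- function(table, path) {
  stopifnot(is(table, "CompositionTable"))
  m <- if (nrow(table@counts) > 0) table@counts else table@values
  df <- data.frame(feature = colnames(m), t(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a TSV dosage matrix
#'
#' @param geno animals x SNPs dosage matrix.
#' @param path output file (animal ids in the first column).
#' @return invisibly, the path.
#' @export
writeDosageTsv <- function(geno, path) {
  df <- data.frame(animal = rownames(geno), geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a co-abundance graph as GraphML
#'
#' @param graph a [CoabundanceGraph-class].
#' @param path output `.graphml` path.
#' @return invisibly, the path.
#' @export
writeGraphML <- function(graph, path) {
  stopifnot(is(graph, "CoabundanceGraph"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  e <- graph@edges
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"w\" for=\"edge\" attr.name=\"weight\" attr.type=\"double\"/>",
    "  <graph edgedefault=\"undirected\">",
    sprintf("    <node id=\"%s\"/>", esc(graph@nodes)),
    if (nrow(e)) {
      sprintf(paste0("    <edge source=\"%s\" target=\"%s\">",
                     "<data key=\"w\">%.10g</data></edge>"),
              esc(e$from), esc(e$to), e$weight)
    },
    "  </graph>",
    "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' Write genotypes as a minimal VCF
#'
#' Emits an unphased diploid GT-only VCF (REF/ALT set to A/G placeholders,
#' one SNP per row on chromosome 1 at consecutive positions unless SNP
#' metadata is attached).
#'
#' @param geno animals x SNPs dosage matrix in `{0, 1, 2}` (`NA` allowed).
#' @param path output `.vcf` path.
#' @return invisibly, the path.
#' @export
writeGenotypesVcf <- function(geno, path) {
  stopifnot(is.matrix(geno))
  gtStr <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(geno)), function(j) {
    gt <- ifelse(is.na(geno[, j]), "./.", gtStr[geno[, j] + 1])
    paste(c("1", j, colnames(geno)[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a posterior chain to columnar TSV plus a YAML run manifest
#'
#' One row per stored draw; the manifest records the sampler configuration
#' and model description needed to reproduce the run.
#'
#' @param chain a [PosteriorChain-class].
#' @param path TSV output path; the manifest is written next to it with
#'   extension `.yml`.
#' @return invisibly, the path.
#' @export
writeChainTsv <- function(chain, path) {
  stopifnot(is(chain, "PosteriorChain"))
  df <- data.frame(draw = seq_len(nrow(chain@draws)), chain@draws,
                   logLik = chain@logLik, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    traits = as.list(chain@traitIds),
    config = chain@config[c("nIter", "burnIn", "thin", "seed")],
    includeGenomic = isTRUE(chain@model$includeGenomic),
    fixedVariance = isTRUE(chain@model$fixedVariance),
    nAnimals = chain@model$nAnimals
  )
  yaml::write_yaml(manifest, sub("\\.tsv$", ".yml", path))
  invisible(path)
}

#' Write a co-abundance graph as an edge list TSV
#'
#' @param graph a [CoabundanceGraph-class].
#' @param path output file with columns `from`, `to`, `weight`.
#' @return invisibly, the path.
#' @export
writeEdgeListTsv <- function(graph, path) {
  stopifnot(is(graph, "CoabundanceGraph"))
  utils::write.table(graph@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
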