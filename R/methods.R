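# Accessor and show methods for the S4 containers.

#' @rdname accessors
#' @export
setMethod("sampleIds", "CompositionTable", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("sampleIds", "LogRatioTable", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("partIds", "CompositionTable", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("featureIds", "LogRatioTable", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("animalIds", "Grm", function(x) rownames(x@values))

#' @rdname accessors
#' @export
setMethod("animalIds", "PosteriorChain", function(x) x@animalIds)

#' @rdname accessors
#' @export
setMethod("values", "CompositionTable", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "LogRatioTable", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("values", "Grm", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("occupancy", "CompositionTable", function(x) x@occupancy)

#' @rdname accessors
#' @export
setMethod("meanRA", "CompositionTable", function(x) x@meanRA)

#' @rdname accessors
#' @export
setMethod("traitIds", "PosteriorChain", function(x) x@traitIds)

#' @rdname accessors
#' @export
setMethod("traitIds", "VarianceComponents", function(x) x@traitIds)

#' @rdname accessors
#' @export
setMethod("sigmaG", "VarianceComponents", function(x) x@sigmaG)

#' @rdname accessors
#' @export
setMethod("sigmaE", "VarianceComponents", function(x) x@sigmaE)

#' @rdname accessors
#' @export
setMethod("nDraws", "PosteriorChain", function(x) nrow(x@draws))

setMethod("show", "CompositionTable", function(object) {
  v <- object@values
  cat("CompositionTable:", nrow(v), "samples x", ncol(v), "parts\n")
  cat("  occupancy: ", sprintf("%.2f", min(object@occupancy)), "-",
      sprintf("%.2f", max(object@occupancy)), "\n", sep = "")
  cat("  mean RA range: ", format(min(object@meanRA), digits = 3), " - ",
      format(max(object@meanRA), digits = 3), "\n", sep = "")
  if (nrow(object@counts) > 0) cat("  raw counts attached\n")
})

setMethod("show", "LogRatioTable", function(object) {
  v <- object@values
  cat(object@transformKind, "LogRatioTable:", nrow(v), "samples x",
      ncol(v), "features\n")
  if (object@transformKind == "alr") {
    cat("  reference part:", object@referenceId, "\n")
  }
})

setMethod("show", "Grm", function(object) {
  v <- object@values
  cat("Grm:", nrow(v), "animals; mean diagonal",
      sprintf("%.3f", mean(diag(v))),
      "; ridge", format(object@ridgeEpsilon), "\n")
})

setMethod("show", "PosteriorChain", function(object) {
  cat("PosteriorChain:", nrow(object@draws), "stored draws,",
      length(object@traitIds), "trait(s):",
      paste(object@traitIds, collapse = ", "), "\n")
  cat("  genomic effect:", isTRUE(object@model$includeGenomic),
      "| fixed variance components:", isTRUE(object@model$fixedVariance), "\n")
  if (length(object@ebvTraits)) {
    cat("  EBV draws stored for:", paste(object@ebvTraits, collapse = ", "),
        "\n")
  }
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents:", length(object@traitIds), "traits\n")
  for (nm in c("sigmaG", "sigmaE")) {
    ev <- min(eigen(slot(object, nm), symmetric = TRUE,
                    only.values = TRUE)$values)
    cat("  ", nm, ": min eigenvalue ", format(ev, digits = 4), "\n", sep = "")
  }
})

setMethod("show", "CoabundanceGraph", function(object) {
  cat("CoabundanceGraph (", object@basis, "): ", length(object@nodes),
      " nodes, ", nrow(object@edges), " edges (|r| > ",
      object@threshold, ")\n", sep = "")
})
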