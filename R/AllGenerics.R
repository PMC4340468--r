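#' @include AllClasses.R
NULL

#' Genes covered by a knowledge base
#'
#' Union of the genes with a haplotype table and the genes referenced by the
#' SNP registry, sorted.
#' @param x a [PgxKnowledgeBase-class].
#' @return character vector of gene symbols.
#' @export
setGeneric("kbGenes", function(x) standardGeneric("kbGenes"))

#' @rdname kbGenes
setMethod("kbGenes", "PgxKnowledgeBase", function(x) {
  sort(unique(c(names(x@haplotypes), x@snps$gene)))
})

#' SNP registry of a knowledge base
#' @param x a [PgxKnowledgeBase-class].
#' @return the registry data.frame (one row per SNP).
#' @export
setGeneric("kbSnps", function(x) standardGeneric("kbSnps"))

#' @rdname kbSnps
setMethod("kbSnps", "PgxKnowledgeBase", function(x) x@snps)

#' Haplotype definition table for one gene
#' @param x a [PgxKnowledgeBase-class].
#' @param gene gene symbol.
#' @return character matrix, rows = star-allele names, columns = rsIDs.
#' @export
setGeneric("haplotypeTable", function(x, gene) standardGeneric("haplotypeTable"))

#' @rdname haplotypeTable
setMethod("haplotypeTable", "PgxKnowledgeBase", function(x, gene) {
  if (!gene %in% names(x@haplotypes))
    stop("no haplotype definitions for gene: ", gene)
  x@haplotypes[[gene]]
})

#' Star-allele taxonomy of a knowledge base
#' @param x a [PgxKnowledgeBase-class].
#' @return data.frame (child, parent, gene).
#' @export
setGeneric("kbTaxonomy", function(x) standardGeneric("kbTaxonomy"))

#' @rdname kbTaxonomy
setMethod("kbTaxonomy", "PgxKnowledgeBase", function(x) x@taxonomy)

#' Rules stored in a knowledge base
#' @param x a [PgxKnowledgeBase-class].
#' @param kind "all", "cds" or "phenotype".
#' @return named list of rule records.
#' @export
setGeneric("kbRules", function(x, kind = "all") standardGeneric("kbRules"))

#' @rdname kbRules
setMethod("kbRules", "PgxKnowledgeBase", function(x, kind = "all") {
  kind <- match.arg(kind, c("all", "cds", "phenotype"))
  switch(kind,
         all = c(x@phenotypeRules, x@cdsRules),
         cds = x@cdsRules,
         phenotype = x@phenotypeRules)
})

#' Genotype calls of a patient
#' @param x a [PatientGenotype-class].
#' @return named list of sorted allele pairs.
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname genotypeCalls
setMethod("genotypeCalls", "PatientGenotype", function(x) x@calls)

#' rsIDs reported as no-call
#' @param x a [PatientGenotype-class].
#' @return character vector.
#' @export
setGeneric("missingSnps", function(x) standardGeneric("missingSnps"))

#' @rdname missingSnps
setMethod("missingSnps", "PatientGenotype", function(x) x@missing)

#' Patient identifier
#' @param x a [PatientGenotype-class] or [InferenceResult-class].
#' @return character scalar.
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname patientId
setMethod("patientId", "PatientGenotype", function(x) x@patientId)

#' @rdname patientId
setMethod("patientId", "InferenceResult", function(x) x@patientId)

#' Consistent diplotypes of an inference result
#' @param x an [InferenceResult-class].
#' @param gene optional gene symbol; when given, return only that gene's
#'   list of pairs.
#' @return named list (by gene) of lists of sorted star-allele pairs.
#' @export
setGeneric("diplotypes", function(x, gene = NULL) standardGeneric("diplotypes"))

#' @rdname diplotypes
setMethod("diplotypes", "InferenceResult", function(x, gene = NULL) {
  if (is.null(gene)) x@diplotypes else x@diplotypes[[gene]]
})

#' Inferred phenotype labels
#' @param x an [InferenceResult-class].
#' @return character vector.
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname phenotypes
setMethod("phenotypes", "InferenceResult", function(x) x@phenotypes)

#' Triggered CDS recommendations
#' @param x an [InferenceResult-class].
#' @return data.frame (rule, drug, importance, source, message), ordered by
#'   importance then rule id.
#' @export
setGeneric("recommendations", function(x) standardGeneric("recommendations"))

#' @rdname recommendations
setMethod("recommendations", "InferenceResult", function(x) x@recommendations)

#' No-call reasons per gene
#' @param x an [InferenceResult-class].
#' @return named list by gene of missing panel rsIDs.
#' @export
setGeneric("noCallReasons", function(x) standardGeneric("noCallReasons"))

#' @rdname noCallReasons
setMethod("noCallReasons", "InferenceResult", function(x) x@noCall)

#' Findings of a validation report
#' @param x a [ValidationReport-class].
#' @return data.frame of findings.
#' @export
setGeneric("findings", function(x) standardGeneric("findings"))

#' @rdname findings
setMethod("findings", "ValidationReport", function(x) x@findings)

#' Does a validation report contain no findings?
#'
#' An empty report means the knowledge base passed all static checks.
#' @param x a [ValidationReport-class].
#' @param errorsOnly when TRUE, ignore warnings.
#' @return logical scalar.
#' @export
setGeneric("isClean", function(x, errorsOnly = FALSE) standardGeneric("isClean"))

#' @rdname isClean
setMethod("isClean", "ValidationReport", function(x, errorsOnly = FALSE) {
  f <- x@findings
  if (errorsOnly) f <- f[f$severity == "error", , drop = FALSE]
  nrow(f) == 0L
})

#' @export
setMethod("show", "PgxKnowledgeBase", function(object) {
  nh <- vapply(object@haplotypes, nrow, integer(1))
  cat("PgxKnowledgeBase\n",
      "  SNPs:       ", nrow(object@snps), "\n",
      "  genes:      ", length(kbGenes(object)), "\n",
      "  haplotypes: ", sum(nh), " over ", length(nh), " gene panel(s)\n",
      "  rules:      ", length(object@phenotypeRules), " phenotype, ",
      length(object@cdsRules), " CDS\n", sep = "")
})

setMethod("show", "PatientGenotype", function(object) {
  cat("PatientGenotype '", object@patientId, "': ",
      length(object@calls), " call(s), ",
      length(object@missing), " missing\n", sep = "")
})

setMethod("show", "InferenceResult", function(object) {
  cat("InferenceResult for '", object@patientId, "'\n", sep = "")
  for (g in names(object@diplotypes)) {
    dd <- vapply(object@diplotypes[[g]], paste, character(1), collapse = "/")
    cat("  ", g, ": ", paste(dd, collapse = " | "),
        if (isTRUE(object@ambiguity[[g]])) "  [ambiguous]" else "", "\n",
        sep = "")
  }
  for (g in names(object@noCall))
    cat("  ", g, ": no call (missing ",
        paste(object@noCall[[g]], collapse = ", "), ")\n", sep = "")
  if (length(object@phenotypes))
    cat("  phenotypes: ", paste(object@phenotypes, collapse = "; "), "\n",
        sep = "")
  cat("  recommendations: ", nrow(object@recommendations), "\n", sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  f <- object@findings
  if (!nrow(f)) {
    cat("ValidationReport: clean (no findings)\n")
  } else {
    cat("ValidationReport: ", sum(f$severity == "error"), " error(s), ",
        sum(f$severity == "warning"), " warning(s)\n", sep = "")
    for (i in seq_len(nrow(f)))
      cat("  [", f$severity[i], "] ", f$category[i], ": ", f$message[i],
          "\n", sep = "")
  }
})
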