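#' @import methods
NULL

## Column layout shared by the SNP registry slot and readSnpRegistry().
## `alleles` and `assays` are comma-separated strings so the registry stays a
## plain data.frame; accessors split them.
.SNP_COLS <- c("rsid", "gene", "orientation", "alleles", "assays", "seeAlso")

.RULE_IMPORTANCE <- c("important_modification", "minor_deviation", "standard")

.FINDING_CATEGORIES <- c("indistinguishable_haplotypes", "unknown_rsid",
                         "unknown_allele", "unsatisfiable_rule",
                         "dangling_reference")

#' PgxKnowledgeBase: a compiled pharmacogenomic knowledge base
#'
#' Holds the SNP registry, per-gene haplotype (star-allele) definition
#' tables, the star-allele taxonomy, and the phenotype-inference and
#' clinical decision support (CDS) rules.
#'
#' @slot snps data.frame with columns `rsid`, `gene`, `orientation`
#'   ("forward"/"reverse" relative to the reference genome), `alleles`
#'   (comma-separated known alleles, uppercase; indel tokens such as
#'   "INS"/"DEL" allowed), `assays` (comma-separated assay names, possibly
#'   empty), `seeAlso` (optional external URI).
#' @slot haplotypes named list (by gene symbol) of character matrices; rows
#'   are star-allele names, columns are rsIDs, cells are alleles. Every row
#'   is total over the gene's SNP panel.
#' @slot taxonomy data.frame with columns `child`, `parent`, `gene`: a
#'   star-allele generalisation hierarchy (e.g. TPMT*3A below TPMT*3).
#'   Parents need not have an allele row of their own ("abstract" alleles).
#' @slot phenotypeRules named list of rules (see [readRuleFile()]) with a
#'   `phenotype_label` each.
#' @slot cdsRules named list of rules with `drug`, `message`, `source`,
#'   `importance`.
#' @slot metadata free-form list (version string, provenance notes).
#'
#' @seealso [newKnowledgeBase()], [validateKnowledgeBase()]
#' @export
setClass("PgxKnowledgeBase",
  representation(snps = "data.frame", haplotypes = "list",
                 taxonomy = "data.frame", phenotypeRules = "list",
                 cdsRules = "list", metadata = "list"))

setValidity("PgxKnowledgeBase", function(object) {
  msgs <- character(0)
  sn <- object@snps
  if (!all(.SNP_COLS %in% names(sn)))
    msgs <- c(msgs, paste("snps must have columns:",
                          paste(.SNP_COLS, collapse = ", ")))
  else {
    if (anyDuplicated(sn$rsid))
      msgs <- c(msgs, "duplicate rsid in SNP registry")
    if (nrow(sn) && !all(sn$orientation %in% c("forward", "reverse")))
      msgs <- c(msgs, "orientation must be 'forward' or 'reverse'")
    if (nrow(sn) && any(!nzchar(sn$alleles)))
      msgs <- c(msgs, "every SNP needs a non-empty allele set")
  }
  for (g in names(object@haplotypes)) {
    m <- object@haplotypes[[g]]
    if (!is.matrix(m) || !is.character(m))
      msgs <- c(msgs, sprintf("haplotypes[['%s']] must be a character matrix", g))
    else {
      if (is.null(rownames(m)) || is.null(colnames(m)))
        msgs <- c(msgs, sprintf("haplotype table for %s needs row/col names", g))
      else if (anyDuplicated(rownames(m)))
        msgs <- c(msgs, sprintf("duplicate haplotype names for gene %s", g))
      if (any(m == "" | is.na(m)))
        msgs <- c(msgs, sprintf("haplotype table for %s has empty cells", g))
    }
  }
  tx <- object@taxonomy
  if (!all(c("child", "parent", "gene") %in% names(tx)))
    msgs <- c(msgs, "taxonomy needs columns child, parent, gene")
  else if (nrow(tx)) {
    if (anyDuplicated(tx$child))
      msgs <- c(msgs, "a star allele may have at most one taxonomy parent")
    ## cycle check by repeated parent-following
    par <- stats::setNames(tx$parent, tx$child)
    cyclic <- FALSE
    for (start in names(par)) {
      seen <- start; cur <- start
      while (cur %in% names(par)) {
        cur <- unname(par[[cur]])
        if (cur %in% seen) { cyclic <- TRUE; break }
        seen <- c(seen, cur)
      }
      if (cyclic) break
    }
    if (cyclic) msgs <- c(msgs, "taxonomy contains a cycle")
  }
  ok <- function(rl, need) all(vapply(rl, function(r)
    all(need %in% names(r)), logical(1)))
  if (!ok(object@phenotypeRules, c("id", "phenotype_label", "expression")))
    msgs <- c(msgs, "phenotype rules need id, phenotype_label, expression")
  if (!ok(object@cdsRules, c("id", "drug", "expression", "message",
                             "source", "importance")))
    msgs <- c(msgs, "CDS rules need id, drug, expression, message, source, importance")
  for (r in object@cdsRules) {
    if (!nzchar(r$message))
      msgs <- c(msgs, sprintf("rule %s: empty CDS message", r$id))
    if (!r$importance %in% .RULE_IMPORTANCE)
      msgs <- c(msgs, sprintf("rule %s: unknown importance '%s'", r$id, r$importance))
  }
  if (length(msgs)) msgs else TRUE
})

#' PatientGenotype: unphased diploid calls keyed by rsID
#'
#' @slot patientId character scalar.
#' @slot calls named list; each element an unordered (stored sorted) pair of
#'   allele strings in the registry's defining orientation.
#' @slot missing character vector of rsIDs explicitly reported as no-call.
#'
#' @seealso [read23andme()], [readPatientVcf()]
#' @export
setClass("PatientGenotype",
  representation(patientId = "character", calls = "list",
                 missing = "character"))

setValidity("PatientGenotype", function(object) {
  msgs <- character(0)
  if (length(object@patientId) != 1L)
    msgs <- c(msgs, "patientId must be a single string")
  cl <- object@calls
  if (length(cl) && is.null(names(cl)))
    msgs <- c(msgs, "calls must be named by rsID")
  bad <- vapply(cl, function(p) length(p) != 2L || any(!nzchar(p)), logical(1))
  if (any(bad))
    msgs <- c(msgs, "every call must be a pair of non-empty allele strings")
  if (length(intersect(names(cl), object@missing)))
    msgs <- c(msgs, "calls and missing must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' InferenceResult: diplotypes, phenotypes and triggered recommendations
#'
#' @slot patientId character scalar.
#' @slot diplotypes named list (by gene); each element a list of sorted
#'   character pairs of star-allele names consistent with the genotype.
#' @slot ambiguity named logical by gene: more than one consistent diplotype.
#' @slot noCall named list by gene: the panel rsIDs that were missing when a
#'   gene could not be called (strict mode).
#' @slot phenotypes character vector of inferred phenotype labels.
#' @slot recommendations data.frame (rule, drug, importance, source,
#'   message), ordered by importance then rule id.
#' @slot stats list: `matched_snps` (registry SNPs with a call),
#'   `triggered_rules`.
#' @export
setClass("InferenceResult",
  representation(patientId = "character", diplotypes = "list",
                 ambiguity = "logical", noCall = "list",
                 phenotypes = "character", recommendations = "data.frame",
                 stats = "list"))

setValidity("InferenceResult", function(object) {
  msgs <- character(0)
  genes <- union(names(object@diplotypes), names(object@noCall))
  for (g in genes) {
    has <- length(object@diplotypes[[g]]) > 0L
    nc <- g %in% names(object@noCall)
    if (!has && !nc)
      msgs <- c(msgs, sprintf(
        "gene %s has neither a consistent diplotype nor a no-call reason", g))
  }
  if (length(msgs)) msgs else TRUE
})

#' ValidationReport: findings from static knowledge-base checks
#'
#' @slot findings data.frame with columns `severity` ("error"/"warning"),
#'   `category`, `identifiers` (comma-separated ids involved), `message`.
#' @export
setClass("ValidationReport",
  representation(findings = "data.frame"))

setValidity("ValidationReport", function(object) {
  f <- object@findings
  need <- c("severity", "category", "identifiers", "message")
  if (!all(need %in% names(f)))
    return(paste("findings must have columns:", paste(need, collapse = ", ")))
  if (nrow(f) && !all(f$severity %in% c("error", "warning")))
    return("severity must be 'error' or 'warning'")
  if (nrow(f) && !all(f$category %in% .FINDING_CATEGORIES))
    return(paste("unknown finding category; allowed:",
                 paste(.FINDING_CATEGORIES, collapse = ", ")))
  TRUE
})

.emptyFindings <- function() {
  data.frame(severity = character(0), category = character(0),
             identifiers = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

.newReport <- function(findings = .emptyFindings()) {
  new("ValidationReport", findings = findings)
}

.finding <- function(severity, category, identifiers, message) {
  data.frame(severity = severity, category = category,
             identifiers = paste(identifiers, collapse = ","),
             message = message, stringsAsFactors = FALSE)
}
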