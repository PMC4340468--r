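## The fragment reasoner: zygosity profiles, consistent-diplotype calling,
## phenotype inference and CDS rule matching for a single patient.

#' Per-SNP zygosity profile of a genotype
#'
#' Turns each unordered allele pair into allele counts summing to two:
#' heterozygous {A, C} becomes A:1, C:1; homozygous {A, A} becomes A:2.
#' Missing rsIDs are simply absent from the profile.
#'
#' @param genotype a [PatientGenotype-class].
#' @return named list (by rsID) of named integer vectors (allele -> count).
#' @examples
#' zygosityProfile(patientGenotype("p", list(rs1057910 = c("A", "C"))))
#' @export
zygosityProfile <- function(genotype) {
  lapply(genotype@calls, function(p) {
    tab <- table(p)
    stats::setNames(as.integer(tab), names(tab))
  })
}

## expand a count vector back to a sorted length-2 allele vector
.expandCounts <- function(cnt) sort(rep(names(cnt), cnt))

#' Call consistent star-allele diplotypes for one gene
#'
#' Enumerates all unordered pairs of the gene's defined haplotypes and
#' keeps those whose combined allele multiset matches the observed
#' zygosity at every panel SNP. In strict mode (the default) the gene is
#' not called at all when any panel rsID is missing from the profile: rare
#' defining SNPs are deliberately required so that common alleles are not
#' called incorrectly, at the cost of coverage. Lenient mode restricts the
#' consistency check to the observed SNPs.
#'
#' @param profile a zygosity profile from [zygosityProfile()].
#' @param kb a [PgxKnowledgeBase-class].
#' @param gene gene symbol with a haplotype table in `kb`.
#' @param strict require data on every panel SNP (default TRUE).
#' @return list with `pairs` (list of sorted character pairs of star-allele
#'   names; possibly several when the unphased genotype is ambiguous) and
#'   `missing` (panel rsIDs absent from the profile; non-empty in strict
#'   mode exactly when the gene was not called).
#' @export
callDiplotypes <- function(profile, kb, gene, strict = TRUE) {
  if (!gene %in% names(kb@haplotypes))
    stop("no haplotype definitions for gene: ", gene)
  m <- kb@haplotypes[[gene]]
  panel <- colnames(m)
  absent <- setdiff(panel, names(profile))
  if (strict && length(absent))
    return(list(pairs = list(), missing = sort(absent)))
  checked <- if (strict) panel else setdiff(panel, absent)
  obs <- lapply(profile[checked], .expandCounts)
  haps <- rownames(m)
  pairs <- list()
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      ok <- TRUE
      for (r in checked) {
        if (!identical(sort(c(m[i, r], m[j, r])), obs[[r]])) {
          ok <- FALSE; break
        }
      }
      if (ok) pairs[[length(pairs) + 1L]] <- sort(c(haps[i], haps[j]))
    }
  }
  ## deterministic order: lexicographic on the formatted pair
  if (length(pairs))
    pairs <- pairs[order(vapply(pairs, paste, character(1), collapse = "/"))]
  list(pairs = pairs, missing = character(0))
}

## taxonomy-closed copy counts contributed by one diplotype pair:
## each carried haplotype counts for itself and all its ancestors
.pairCounts <- function(pair, parent) {
  contrib <- unlist(lapply(pair, function(h) c(h, .ancestorsOf(h, parent))))
  tab <- table(contrib)
  stats::setNames(as.integer(tab), names(tab))
}

#' Taxonomy-closed haplotype support of a diplotype set
#'
#' Union-entailment semantics over the consistent diplotypes: a star allele
#' H is supported with count c when some consistent diplotype carries H —
#' or a taxonomy descendant of H — c times. With several consistent
#' diplotypes the maximum count per name is reported; the ambiguity itself
#' is surfaced separately by [realizePatient()].
#'
#' @param diplotypes list of character pairs of star-allele names.
#' @param taxonomy taxonomy data.frame (child, parent, gene), e.g.
#'   `kbTaxonomy(kb)`; may be empty.
#' @return named integer vector, star-allele name -> maximum copy count.
#' @examples
#' haplotypeSupport(list(c("TPMT*1", "TPMT*3A")),
#'                  data.frame(child = "TPMT*3A", parent = "TPMT*3",
#'                             gene = "TPMT"))
#' @export
haplotypeSupport <- function(diplotypes, taxonomy = NULL) {
  parent <- if (is.null(taxonomy) || !nrow(taxonomy))
    stats::setNames(character(0), character(0))
  else stats::setNames(taxonomy$parent, taxonomy$child)
  out <- integer(0)
  for (p in diplotypes) {
    cnt <- .pairCounts(p, parent)
    for (nm in names(cnt))
      out[nm] <- max(out[nm], cnt[[nm]], na.rm = TRUE)
  }
  out[order(names(out))]
}

#' Evaluate a monotone rule expression
#'
#' Atom semantics: a haplotype atom "at least c" is true when the support
#' count reaches c; "exactly c" is true when some consistent diplotype
#' carries exactly c (taxonomy-closed) copies — for c = 2 this is the
#' homozygote of that star allele. Variant atoms compare allele counts in
#' the zygosity profile; phenotype atoms test membership in the inferred
#' labels. AND/OR are standard; atoms over uncalled genes are false, so a
#' rule never fires on absent evidence.
#'
#' @param expr expression tree from [parseRuleExpression()].
#' @param support named copy-count vector from [haplotypeSupport()].
#' @param profile zygosity profile (for variant atoms).
#' @param phenotypes character vector of inferred labels.
#' @param exactCounts list of per-diplotype taxonomy-closed count vectors;
#'   defaults to `list(support)`, which is exact when there is a single
#'   consistent diplotype.
#' @param knownHaplotypes optional character vector of all star-allele
#'   names defined in the knowledge base; when supplied, a haplotype atom
#'   naming anything else raises an error instead of evaluating false.
#' @return logical scalar.
#' @export
evaluateRuleExpression <- function(expr, support, profile = list(),
                                   phenotypes = character(0),
                                   exactCounts = list(support),
                                   knownHaplotypes = NULL) {
  ev <- function(e) {
    switch(e$kind,
      and = all(vapply(e$children, ev, logical(1))),
      or = length(e$children) > 0L && any(vapply(e$children, ev, logical(1))),
      hap = {
        if (!is.null(knownHaplotypes) && !e$name %in% knownHaplotypes)
          stop("rule references undefined haplotype: ", e$name)
        if (e$mode == "at_least") {
          !is.na(support[e$name]) && support[[e$name]] >= e$n
        } else {
          any(vapply(exactCounts, function(cnt)
            !is.na(cnt[e$name]) && cnt[[e$name]] == e$n, logical(1)))
        }
      },
      snp = {
        cnt <- profile[[e$rsid]]
        c0 <- if (is.null(cnt) || is.na(cnt[e$allele])) 0L else cnt[[e$allele]]
        if (e$mode == "at_least") c0 >= e$n else
          (!is.null(cnt) && c0 == e$n)
      },
      phenotype = e$label %in% phenotypes,
      stop("bad expression node kind: ", e$kind))
  }
  ev(expr)
}

.IMPORTANCE_RANK <- stats::setNames(seq_along(.RULE_IMPORTANCE),
                                    .RULE_IMPORTANCE)

#' Realize a patient against the knowledge base
#'
#' Runs the full inference chain: zygosity profile, consistent-diplotype
#' calling per gene, phenotype-rule evaluation, then CDS-rule evaluation.
#' Triggered recommendations are ordered by importance
#' (important_modification first) and then rule id, so output is
#' reproducible byte for byte.
#'
#' @param genotype a [PatientGenotype-class] (calls already in defining
#'   orientation, as produced by the readers).
#' @param kb a [PgxKnowledgeBase-class].
#' @param strict strict missing-data policy for diplotype calling (see
#'   [callDiplotypes()]).
#' @return an [InferenceResult-class].
#' @examples
#' kb <- demoKnowledgeBase(tpmt = FALSE)
#' p <- patientGenotype("demo", list(
#'   rs1057910 = c("A", "C"), rs1057911 = c("A", "A"),
#'   rs1799853 = c("C", "C"), rs2256871 = c("A", "A"),
#'   rs9923231 = c("T", "T")))
#' realizePatient(p, kb)
#' @export
realizePatient <- function(genotype, kb, strict = TRUE) {
  profile <- zygosityProfile(genotype)
  parent <- .parentMap(kb)
  genes <- sort(names(kb@haplotypes))
  dip <- list(); amb <- logical(0); noCall <- list()
  exactCounts <- list()
  for (g in genes) {
    res <- callDiplotypes(profile, kb, g, strict = strict)
    if (!length(res$pairs)) {
      ## either missing panel SNPs (strict no-call) or a genotype no
      ## defined pair explains; the reason is the recorded rsID list
      noCall[[g]] <- res$missing
    } else {
      dip[[g]] <- res$pairs
      amb[[g]] <- length(res$pairs) > 1L
      exactCounts <- c(exactCounts,
                       lapply(res$pairs, .pairCounts, parent = parent))
    }
  }
  support <- integer(0)
  for (cnt in exactCounts)
    for (nm in names(cnt))
      support[nm] <- max(support[nm], cnt[[nm]], na.rm = TRUE)
  known <- names(.haplotypeGeneMap(kb))
  phen <- character(0)
  for (r in kb@phenotypeRules) {
    if (evaluateRuleExpression(r$expression, support, profile, character(0),
                               exactCounts, known))
      phen <- c(phen, r$phenotype_label)
  }
  phen <- sort(unique(phen))
  rec <- data.frame(rule = character(0), drug = character(0),
                    importance = character(0), source = character(0),
                    message = character(0), stringsAsFactors = FALSE)
  for (r in kb@cdsRules) {
    if (evaluateRuleExpression(r$expression, support, profile, phen,
                               exactCounts, known))
      rec <- rbind(rec, data.frame(rule = r$id, drug = r$drug,
                                   importance = r$importance,
                                   source = r$source, message = r$message,
                                   stringsAsFactors = FALSE))
  }
  if (nrow(rec))
    rec <- rec[order(.IMPORTANCE_RANK[rec$importance], rec$rule), ,
               drop = FALSE]
  rownames(rec) <- NULL
  matched <- sum(names(genotype@calls) %in% kb@snps$rsid)
  new("InferenceResult", patientId = genotype@patientId,
      diplotypes = dip, ambiguity = amb, noCall = noCall,
      phenotypes = phen, recommendations = rec,
      stats = list(matched_snps = matched, triggered_rules = nrow(rec)))
}

#' Serialize an inference result as JSON
#'
#' Shape: `{patient, diplotypes: {gene: ["*1/*3", ...]}, ambiguity:
#' {gene: bool}, no_call: {gene: [rsids]}, phenotypes: [...],
#' recommendations: [{rule, drug, importance, source, message}], stats:
#' {matched_snps, triggered_rules}}`.
#'
#' @param result an [InferenceResult-class].
#' @param pretty pretty-print the JSON.
#' @return a JSON string.
#' @export
inferenceResultToJson <- function(result, pretty = FALSE) {
  dip <- lapply(result@diplotypes, function(pp)
    vapply(pp, paste, character(1), collapse = "/"))
  rec <- result@recommendations
  jsonlite::toJSON(list(
    patient = result@patientId,
    diplotypes = dip,
    ambiguity = as.list(result@ambiguity),
    no_call = result@noCall,
    phenotypes = result@phenotypes,
    recommendations = if (nrow(rec)) rec else list(),
    stats = result@stats), auto_unbox = TRUE, pretty = pretty)
}
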