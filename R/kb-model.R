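## Knowledge-base model: haplotype-table compiler, SNP registry and rule-file
## readers, knowledge-base assembly and static validation.

.pgxStop <- function(category, ids, message) {
  cond <- structure(
    class = c(paste0("pgx_", category), "pgxValidationError",
              "error", "condition"),
    list(message = message, call = sys.call(-1),
         category = category, identifiers = ids))
  stop(cond)
}

.splitField <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ",", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

.snpAlleles <- function(registry, rsid) {
  i <- match(rsid, registry$rsid)
  if (is.na(i)) return(character(0))
  .splitField(registry$alleles[i])[[1]]
}

#' Read a SNP registry
#'
#' The registry lists each polymorphism once: its dbSNP identifier, the gene
#' it is relevant for, its strand orientation on the reference genome, the
#' known alleles, the assays that cover it and an optional external URI.
#' Accepted formats: TSV with a header row, or a JSON array of objects, both
#' with fields `rsid`, `gene`, `orientation`, `alleles` (comma-separated),
#' `assays` (comma-separated, may be empty), `seeAlso`.
#'
#' @param path file path (".json" for JSON, anything else read as TSV).
#' @return data.frame with the six registry columns; alleles uppercased.
#' @examples
#' reg <- readSnpRegistry(system.file("extdata/demo_kb/snp_registry.tsv",
#'                                    package = "pgxCDS"))
#' head(reg)
#' @export
readSnpRegistry <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  for (col in .SNP_COLS)
    if (!col %in% names(df)) df[[col]] <- ""
  df <- df[, .SNP_COLS]
  df[is.na(df)] <- ""
  df$alleles <- toupper(gsub(" ", "", df$alleles))
  if (anyDuplicated(df$rsid))
    .pgxStop("unknown_rsid", df$rsid[duplicated(df$rsid)],
             "duplicate rsid in SNP registry")
  if (any(!df$orientation %in% c("forward", "reverse")))
    stop("registry orientation must be 'forward' or 'reverse'")
  df
}

#' Parse a haplotype translation table
#'
#' Compiles a PharmGKB-style star-allele table into a per-gene definition
#' matrix. The first column holds haplotype names, the remaining columns are
#' rsIDs; the first data row is the reference haplotype (conventionally *1)
#' and blank cells inherit the reference row's allele for that column, so
#' every returned row is total over the panel.
#'
#' @param x a file path, or the table text itself (anything containing a
#'   newline is treated as literal text).
#' @param gene gene symbol the table belongs to.
#' @param registry optional SNP registry data.frame; when supplied, unknown
#'   rsID columns and alleles outside a SNP's allele set raise classed
#'   errors (`pgx_unknown_rsid`, `pgx_unknown_allele`).
#' @return character matrix, rows named by haplotype, columns by rsID,
#'   alleles uppercased. A header-only table gives a 0-row matrix.
#' @details Cells containing "/" (ambiguity codes) are rejected rather than
#'   interpreted. Duplicate haplotype names raise `pgx_duplicate_haplotype`.
#' @examples
#' tab <- parseHaplotypeTable(system.file("extdata/demo_kb/cyp2c9.tsv",
#'                                        package = "pgxCDS"), "CYP2C9")
#' tab["CYP2C9*3", ]
#' @export
parseHaplotypeTable <- function(x, gene, registry = NULL) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE, encoding = "UTF-8")
  else
    strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty haplotype table")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(cells[[1]])
  rsids <- trimws(cells[[1]][-1])
  if (!length(rsids)) stop("haplotype table has no rsID columns")
  rows <- cells[-1]
  names <- vapply(rows, function(r) trimws(r[1]), character(1))
  if (anyDuplicated(names))
    .pgxStop("duplicate_haplotype", unique(names[duplicated(names)]),
             paste("duplicate haplotype name:",
                   paste(unique(names[duplicated(names)]), collapse = ", ")))
  mat <- matrix("", nrow = length(rows), ncol = length(rsids),
                dimnames = list(names, rsids))
  for (i in seq_along(rows)) {
    vals <- c(rows[[i]][-1], rep("", max(0, ncols - length(rows[[i]]))))
    mat[i, ] <- toupper(trimws(vals[seq_along(rsids)]))
  }
  mat[is.na(mat)] <- ""
  if (any(grepl("/", mat, fixed = TRUE)))
    .pgxStop("unknown_allele", names[apply(mat, 1, function(r)
      any(grepl("/", r, fixed = TRUE)))],
      "ambiguity codes (e.g. 'A/C') are not supported in haplotype tables")
  if (nrow(mat)) {
    ref <- mat[1, ]
    if (any(!nzchar(ref)))
      stop("reference (first) haplotype row must be complete; blank at: ",
           paste(rsids[!nzchar(ref)], collapse = ", "))
    for (j in seq_along(rsids)) {
      blank <- !nzchar(mat[, j])
      mat[blank, j] <- ref[j]
    }
  }
  if (!is.null(registry)) {
    unknown <- setdiff(rsids, registry$rsid)
    if (length(unknown))
      .pgxStop("unknown_rsid", unknown,
               paste("rsID column(s) absent from registry:",
                     paste(unknown, collapse = ", ")))
    for (r in rsids) {
      ok <- .snpAlleles(registry, r)
      bad <- setdiff(unique(mat[, r]), ok)
      if (length(bad))
        .pgxStop("unknown_allele", c(r, bad),
                 sprintf("allele(s) %s at %s not in the SNP's allele set {%s}",
                         paste(bad, collapse = ","), r,
                         paste(ok, collapse = ",")))
    }
  }
  mat
}

#' Serialize a haplotype definition matrix back to TSV
#'
#' Inverse of [parseHaplotypeTable()] (with all cells explicit): parsing the
#' written file again yields an identical matrix.
#'
#' @param mat character matrix as returned by [parseHaplotypeTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHaplotypeTable <- function(mat, path) {
  header <- paste(c("Haplotype", colnames(mat)), collapse = "\t")
  body <- vapply(rownames(mat), function(h)
    paste(c(h, mat[h, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

## ---- rule expressions -----------------------------------------------------

#' Parse a rule expression from its list (JSON/YAML) form
#'
#' The grammar is monotone (no negation): `{"and": [...]}`, `{"or": [...]}`,
#' haplotype atoms `{"hap": "TPMT*1", "min": 1}` or
#' `{"hap": "CYP2C9*3", "exactly": 2}`, variant atoms
#' `{"snp": "rs9923231", "allele": "T", "exactly": 2}` (or `"min"`), and
#' phenotype atoms `{"phenotype": "label"}`. Cardinalities must be 1 or 2
#' (the diploid bound).
#'
#' @param x nested list, e.g. from `jsonlite::fromJSON(..., simplifyVector
#'   = FALSE)`.
#' @return expression tree: nested lists with a `kind` field ("and", "or",
#'   "hap", "snp", "phenotype").
#' @export
parseRuleExpression <- function(x) {
  if (!is.list(x)) stop("rule expression node must be a list")
  nm <- names(x)
  card <- function() {
    if ("exactly" %in% nm) list(mode = "exactly", n = as.integer(x$exactly))
    else if ("min" %in% nm) list(mode = "at_least", n = as.integer(x$min))
    else list(mode = "at_least", n = 1L)
  }
  if ("and" %in% nm) {
    list(kind = "and", children = lapply(x$and, parseRuleExpression))
  } else if ("or" %in% nm) {
    list(kind = "or", children = lapply(x$or, parseRuleExpression))
  } else if ("hap" %in% nm) {
    cc <- card()
    if (!cc$n %in% 1:2) stop("haplotype atom cardinality must be 1 or 2")
    list(kind = "hap", name = x$hap, n = cc$n, mode = cc$mode)
  } else if ("snp" %in% nm) {
    cc <- card()
    if (!cc$n %in% 1:2) stop("variant atom cardinality must be 1 or 2")
    if (is.null(x$allele)) stop("variant atom needs an 'allele'")
    list(kind = "snp", rsid = x$snp, allele = toupper(x$allele),
         n = cc$n, mode = cc$mode)
  } else if ("phenotype" %in% nm) {
    list(kind = "phenotype", label = x$phenotype)
  } else {
    stop("unrecognized rule expression node: ",
         paste(nm, collapse = ","))
  }
}

## expression tree back to the serializable grammar
.exprToList <- function(e) {
  switch(e$kind,
    and = list(and = lapply(e$children, .exprToList)),
    or = list(or = lapply(e$children, .exprToList)),
    hap = {
      out <- list(hap = e$name)
      out[[if (e$mode == "exactly") "exactly" else "min"]] <- e$n
      out
    },
    snp = {
      out <- list(snp = e$rsid, allele = e$allele)
      out[[if (e$mode == "exactly") "exactly" else "min"]] <- e$n
      out
    },
    phenotype = list(phenotype = e$label),
    stop("bad expression node"))
}

## flatten all atoms of an expression
.exprAtoms <- function(e) {
  if (e$kind %in% c("and", "or"))
    return(do.call(c, lapply(e$children, .exprAtoms)))
  list(e)
}

#' Read a rule file (JSON or YAML)
#'
#' A rule file holds an array `rules`; each entry has an `id`, a `kind`
#' ("cds" or "phenotype"), a `when` expression in the grammar of
#' [parseRuleExpression()], a `source`, and for CDS rules `drug`, `message`
#' and `importance` ("standard", "minor_deviation" or
#' "important_modification"); phenotype rules carry `phenotype_label`.
#'
#' @param path ".json", ".yaml" or ".yml" file.
#' @return list with components `phenotypeRules` and `cdsRules`, each a
#'   named list of rule records with a parsed `expression`.
#' @export
readRuleFile <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  rules <- raw$rules
  if (is.null(rules)) stop("rule file must contain a 'rules' array")
  phen <- list(); cds <- list()
  for (r in rules) {
    if (is.null(r$id) || is.null(r$when))
      stop("every rule needs an 'id' and a 'when' expression")
    rec <- list(id = r$id, expression = parseRuleExpression(r$when),
                source = if (is.null(r$source)) "" else r$source)
    kind <- if (is.null(r$kind)) "cds" else r$kind
    if (kind == "phenotype") {
      rec$phenotype_label <- r$phenotype_label
      if (is.null(rec$phenotype_label))
        stop("phenotype rule ", r$id, " needs a phenotype_label")
      phen[[r$id]] <- rec
    } else {
      rec$drug <- if (is.null(r$drug)) "" else r$drug
      rec$message <- if (is.null(r$message)) "" else r$message
      rec$importance <- if (is.null(r$importance)) "standard" else r$importance
      cds[[r$id]] <- rec
    }
  }
  list(phenotypeRules = phen, cdsRules = cds)
}

## ---- assembly -------------------------------------------------------------

#' Assemble a knowledge base from its parts
#'
#' @param snps SNP registry data.frame (see [readSnpRegistry()]).
#' @param haplotypes named list (by gene) of definition matrices from
#'   [parseHaplotypeTable()].
#' @param taxonomy optional data.frame with columns `child`, `parent` (and
#'   optionally `gene`; derived from the tables when absent).
#' @param phenotypeRules,cdsRules named lists of rule records (see
#'   [readRuleFile()]).
#' @param metadata free-form list.
#' @return a [PgxKnowledgeBase-class].
#' @export
newKnowledgeBase <- function(snps, haplotypes = list(), taxonomy = NULL,
                             phenotypeRules = list(), cdsRules = list(),
                             metadata = list()) {
  if (is.null(taxonomy))
    taxonomy <- data.frame(child = character(0), parent = character(0),
                           gene = character(0), stringsAsFactors = FALSE)
  if (!"gene" %in% names(taxonomy) && nrow(taxonomy)) {
    geneOf <- function(h) {
      for (g in names(haplotypes))
        if (h %in% rownames(haplotypes[[g]])) return(g)
      NA_character_
    }
    taxonomy$gene <- vapply(taxonomy$child, geneOf, character(1))
  }
  new("PgxKnowledgeBase", snps = snps, haplotypes = haplotypes,
      taxonomy = taxonomy, phenotypeRules = phenotypeRules,
      cdsRules = cdsRules, metadata = metadata)
}

#' Load a knowledge base from an archive directory
#'
#' The archive is a directory of the plain-text interface files plus a
#' `manifest.json` naming them:
#' `{"version": ..., "registry": "snp_registry.tsv",
#'   "tables": [{"gene": "CYP2C9", "file": "cyp2c9.tsv"}, ...],
#'   "taxonomy": "taxonomy.tsv", "rules": ["rules.json", ...]}`.
#'
#' @param dir directory containing `manifest.json`.
#' @return a [PgxKnowledgeBase-class].
#' @seealso [writeKnowledgeBase()], [demoKnowledgeBase()]
#' @export
loadKnowledgeBase <- function(dir) {
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = FALSE)
  registry <- readSnpRegistry(file.path(dir, man$registry))
  haps <- list()
  for (t in man$tables)
    haps[[t$gene]] <- parseHaplotypeTable(file.path(dir, t$file), t$gene,
                                          registry)
  taxonomy <- NULL
  if (!is.null(man$taxonomy)) {
    taxonomy <- utils::read.delim(file.path(dir, man$taxonomy),
                                  stringsAsFactors = FALSE,
                                  colClasses = "character")
  }
  phen <- list(); cds <- list()
  for (rf in man$rules) {
    rr <- readRuleFile(file.path(dir, rf))
    phen <- c(phen, rr$phenotypeRules)
    cds <- c(cds, rr$cdsRules)
  }
  meta <- man[setdiff(names(man), c("registry", "tables", "taxonomy", "rules"))]
  newKnowledgeBase(registry, haps, taxonomy, phen, cds, meta)
}

#' Write a knowledge base as an archive directory
#'
#' Inverse of [loadKnowledgeBase()]: writes the registry and per-gene tables
#' as TSV, taxonomy as TSV, all rules into one JSON file, and a
#' `manifest.json`.
#'
#' @param kb a [PgxKnowledgeBase-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeKnowledgeBase <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(kb@snps, file.path(dir, "snp_registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tables <- list()
  for (g in names(kb@haplotypes)) {
    f <- paste0(tolower(g), ".tsv")
    writeHaplotypeTable(kb@haplotypes[[g]], file.path(dir, f))
    tables[[length(tables) + 1L]] <- list(gene = g, file = f)
  }
  man <- list(registry = "snp_registry.tsv", tables = tables)
  if (nrow(kb@taxonomy)) {
    utils::write.table(kb@taxonomy, file.path(dir, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    man$taxonomy <- "taxonomy.tsv"
  }
  ruleRec <- function(r, kind) {
    out <- list(id = r$id, kind = kind, source = r$source,
                when = .exprToList(r$expression))
    if (kind == "phenotype") out$phenotype_label <- r$phenotype_label
    else { out$drug <- r$drug; out$message <- r$message
           out$importance <- r$importance }
    out
  }
  allRules <- c(lapply(kb@phenotypeRules, ruleRec, kind = "phenotype"),
                lapply(kb@cdsRules, ruleRec, kind = "cds"))
  jsonlite::write_json(list(rules = unname(allRules)),
                       file.path(dir, "rules.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  man$rules <- list("rules.json")
  man <- c(man, kb@metadata)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

## ---- taxonomy helpers -----------------------------------------------------

## named parent vector
.parentMap <- function(kb) {
  tx <- kb@taxonomy
  if (!nrow(tx)) return(stats::setNames(character(0), character(0)))
  stats::setNames(tx$parent, tx$child)
}

## all ancestors (transitive) of a star-allele name, excluding itself
.ancestorsOf <- function(name, parent) {
  out <- character(0)
  cur <- name
  while (cur %in% names(parent)) {
    cur <- unname(parent[[cur]])
    if (cur %in% out) break
    out <- c(out, cur)
  }
  out
}

## map star-allele name -> gene, covering concrete rows and taxonomy nodes
.haplotypeGeneMap <- function(kb) {
  out <- character(0)
  for (g in names(kb@haplotypes)) {
    rn <- rownames(kb@haplotypes[[g]])
    out[rn] <- g
  }
  tx <- kb@taxonomy
  if (nrow(tx)) {
    out[tx$child[!tx$child %in% names(out)]] <-
      tx$gene[!tx$child %in% names(out)]
    out[tx$parent[!tx$parent %in% names(out)]] <-
      tx$gene[!tx$parent %in% names(out)]
  }
  out
}

## ---- static validation ----------------------------------------------------

#' Detect indistinguishable haplotype definitions
#'
#' Two same-gene star alleles are indistinguishable when their allele maps
#' are identical over the gene's SNP panel: no genotype can ever separate
#' them. Such underspecified definitions are a known defect of curated
#' translation tables and are reported as warnings.
#'
#' @param kb a [PgxKnowledgeBase-class].
#' @return a [ValidationReport-class]; one `indistinguishable_haplotypes`
#'   warning per identical pair.
#' @export
checkDistinguishability <- function(kb) {
  out <- .emptyFindings()
  for (g in names(kb@haplotypes)) {
    m <- kb@haplotypes[[g]]
    if (nrow(m) < 2L) next
    key <- apply(m, 1, paste, collapse = "\r")
    for (i in seq_len(nrow(m) - 1L))
      for (j in seq(i + 1L, nrow(m)))
        if (key[i] == key[j])
          out <- rbind(out, .finding(
            "warning", "indistinguishable_haplotypes",
            c(rownames(m)[i], rownames(m)[j]),
            sprintf("%s and %s have identical allele maps over the %s panel",
                    rownames(m)[i], rownames(m)[j], g)))
  }
  .newReport(out)
}

#' Flag rules that no diplotype can satisfy
#'
#' A rule is unsatisfiable when no assignment of one diplotype per
#' constrained gene (at most two haplotype copies per gene, exactly two
#' alleles per SNP) makes its expression true — e.g. a conjunction demanding
#' three haplotype copies of one gene. Decided by finite model enumeration
#' over the diplotype space (see [satisfyingDiplotypes()]).
#'
#' @param kb a [PgxKnowledgeBase-class].
#' @return a [ValidationReport-class]; one `unsatisfiable_rule` warning per
#'   affected rule.
#' @export
checkRuleSatisfiability <- function(kb) {
  out <- .emptyFindings()
  for (r in kbRules(kb)) {
    pop <- tryCatch(rulePopulation(r$expression, kb),
                    error = function(e) NULL)
    if (is.null(pop)) next  # undecidable within limits: not flagged
    sat <- !length(pop) || all(lengths(pop) > 0L)
    if (!sat)
      out <- rbind(out, .finding(
        "warning", "unsatisfiable_rule", r$id,
        sprintf("rule %s admits no diplotype model under the diploid bound",
                r$id)))
  }
  .newReport(out)
}

#' Run all static checks on a knowledge base
#'
#' Checks cross-references (rsIDs in tables against the registry, alleles
#' against each SNP's allele set, rule atoms against defined haplotypes,
#' SNPs and phenotype labels), haplotype distinguishability and rule
#' satisfiability. An empty report means the knowledge base passes.
#'
#' @param kb a [PgxKnowledgeBase-class].
#' @return a [ValidationReport-class].
#' @export
validateKnowledgeBase <- function(kb) {
  out <- .emptyFindings()
  reg <- kb@snps
  for (g in names(kb@haplotypes)) {
    m <- kb@haplotypes[[g]]
    unknown <- setdiff(colnames(m), reg$rsid)
    for (r in unknown)
      out <- rbind(out, .finding("error", "unknown_rsid", r,
        sprintf("panel rsID %s (gene %s) absent from registry", r, g)))
    for (r in intersect(colnames(m), reg$rsid)) {
      ok <- .snpAlleles(reg, r)
      bad <- setdiff(unique(m[, r]), ok)
      if (length(bad))
        out <- rbind(out, .finding("error", "unknown_allele", c(r, bad),
          sprintf("allele(s) %s at %s not in the SNP's allele set",
                  paste(bad, collapse = ","), r)))
    }
  }
  hapGene <- .haplotypeGeneMap(kb)
  phenLabels <- unique(vapply(kb@phenotypeRules, `[[`, character(1),
                              "phenotype_label"))
  for (r in kbRules(kb)) {
    for (a in .exprAtoms(r$expression)) {
      if (a$kind == "hap" && !a$name %in% names(hapGene))
        out <- rbind(out, .finding("error", "dangling_reference",
          c(r$id, a$name),
          sprintf("rule %s references undefined haplotype %s", r$id, a$name)))
      if (a$kind == "snp") {
        if (!a$rsid %in% reg$rsid)
          out <- rbind(out, .finding("error", "dangling_reference",
            c(r$id, a$rsid),
            sprintf("rule %s references unknown rsID %s", r$id, a$rsid)))
        else if (!a$allele %in% .snpAlleles(reg, a$rsid))
          out <- rbind(out, .finding("error", "unknown_allele",
            c(r$id, a$rsid, a$allele),
            sprintf("rule %s: allele %s not in %s's allele set",
                    r$id, a$allele, a$rsid)))
      }
      if (a$kind == "phenotype" && !a$label %in% phenLabels)
        out <- rbind(out, .finding("warning", "dangling_reference",
          c(r$id, a$label),
          sprintf("rule %s references phenotype '%s' with no defining rule",
                  r$id, a$label)))
    }
  }
  out <- rbind(out, findings(checkDistinguishability(kb)))
  if (!any(out$severity == "error"))
    out <- rbind(out, findings(checkRuleSatisfiability(kb)))
  .newReport(out)
}
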