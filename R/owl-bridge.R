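## OWL 2 serialization of the knowledge base and of patients, plus an
## annotation-driven entity counter over Turtle documents. The writers
## target the qualified-cardinality modelling patterns the inference engine
## implements: SNPs as subclasses of "polymorphism", alleles as subclasses
## of their SNP, star-allele carrier classes defined by EquivalentTo
## cardinality expressions, and rules as annotated classes. There is no RDF
## library among the package's R dependencies, so the Turtle/functional
## writers and the small Turtle triple reader are part of the package.

.PGX_BASE <- "http://example.org/pgxcds"

.iriLocal <- function(x) {
  x <- gsub("*", "_star_", x, fixed = TRUE)
  gsub("[^A-Za-z0-9_.-]", "_", x)
}

.ttlEscape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

.ANNOTATIONS <- c("rsid", "relevant_for", "can_be_tested_with",
                  "dbsnp_orientation_on_reference_genome", "CDS_message",
                  "source", "recommendations_importance", "phenotype")

## unordered haplotype pairs of a gene, in deterministic order
.genePairs <- function(haps) {
  out <- list()
  for (i in seq_along(haps))
    for (j in i:length(haps))
      out[[length(out) + 1L]] <- sort(c(haps[i], haps[j]))
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

## ---- class-expression emitters -------------------------------------------

## turtle restriction block for "has exactly n of allele/haplotype class"
.ttlCard <- function(prop, cls, n) {
  sprintf(paste0("[ a owl:Restriction ; owl:onProperty :%s ; ",
                 "owl:onClass :%s ; owl:qualifiedCardinality ",
                 "\"%d\"^^xsd:nonNegativeInteger ]"), prop, cls, n)
}

.ttlMinCard <- function(prop, cls, n) {
  if (n == 1L)
    sprintf("[ a owl:Restriction ; owl:onProperty :%s ; owl:someValuesFrom :%s ]",
            prop, cls)
  else
    sprintf(paste0("[ a owl:Restriction ; owl:onProperty :%s ; ",
                   "owl:onClass :%s ; owl:minQualifiedCardinality ",
                   "\"%d\"^^xsd:nonNegativeInteger ]"), prop, cls, n)
}

.fnCard <- function(prop, cls, n)
  sprintf("ObjectExactCardinality(%d :%s :%s)", n, prop, cls)

.fnMinCard <- function(prop, cls, n) {
  if (n == 1L) sprintf("ObjectSomeValuesFrom(:%s :%s)", prop, cls)
  else sprintf("ObjectMinCardinality(%d :%s :%s)", n, prop, cls)
}

## rule expression -> OWL class expression text
.exprToOwl <- function(e, kb, turtle = TRUE) {
  wrapAnd <- function(parts) {
    if (turtle) sprintf("[ a owl:Class ; owl:intersectionOf ( %s ) ]",
                        paste(parts, collapse = " "))
    else sprintf("ObjectIntersectionOf(%s)", paste(parts, collapse = " "))
  }
  wrapOr <- function(parts) {
    if (turtle) sprintf("[ a owl:Class ; owl:unionOf ( %s ) ]",
                        paste(parts, collapse = " "))
    else sprintf("ObjectUnionOf(%s)", paste(parts, collapse = " "))
  }
  switch(e$kind,
    and = wrapAnd(vapply(e$children, .exprToOwl, character(1), kb = kb,
                         turtle = turtle)),
    or = wrapOr(vapply(e$children, .exprToOwl, character(1), kb = kb,
                       turtle = turtle)),
    hap = {
      cls <- .iriLocal(e$name)
      if (e$mode == "exactly") {
        if (turtle) .ttlCard("has_haplotype", cls, e$n)
        else .fnCard("has_haplotype", cls, e$n)
      } else {
        if (turtle) .ttlMinCard("has_haplotype", cls, e$n)
        else .fnMinCard("has_haplotype", cls, e$n)
      }
    },
    snp = {
      cls <- .iriLocal(paste0(e$rsid, "_", e$allele))
      if (e$mode == "exactly") {
        if (turtle) .ttlCard("has", cls, e$n) else .fnCard("has", cls, e$n)
      } else {
        if (turtle) .ttlMinCard("has", cls, e$n)
        else .fnMinCard("has", cls, e$n)
      }
    },
    phenotype = {
      defs <- Filter(function(r) r$phenotype_label == e$label,
                     kb@phenotypeRules)
      cls <- vapply(sort(names(defs)), function(id)
        paste0(":", .iriLocal(id)), character(1))
      if (length(cls) == 0L)
        stop("phenotype label without defining rule: ", e$label)
      if (length(cls) == 1L) unname(cls) else wrapOr(cls)
    },
    stop("bad expression node"))
}

#' Export a knowledge base as an OWL 2 document
#'
#' Emits each SNP as a class below `polymorphism` carrying its annotations
#' (`rsid`, `relevant_for`, `can_be_tested_with`,
#' `dbsnp_orientation_on_reference_genome`, `rdfs:seeAlso`); each known
#' allele as a subclass of its SNP; each star allele as a class below
#' `haplotype` (taxonomy links as subclass axioms); for every unordered
#' pair of a gene's star alleles a carrier class whose EquivalentTo
#' expression states the qualified cardinality ("exactly 1"/"exactly 2")
#' of every panel allele, with SubClassOf assertions of haplotype
#' possession; and each rule as a class annotated with
#' `CDS_message`/`source`/`recommendations_importance` (or a `phenotype`
#' label) and defined by its translated class expression.
#'
#' @param kb a [PgxKnowledgeBase-class]; must pass [validateKnowledgeBase()]
#'   without errors.
#' @param syntax "turtle" or "functional".
#' @return character scalar: the document text (deterministic for a given
#'   knowledge base).
#' @export
exportOwl <- function(kb, syntax = c("turtle", "functional")) {
  syntax <- match.arg(syntax)
  rep <- validateKnowledgeBase(kb)
  if (!isClean(rep, errorsOnly = TRUE))
    stop("knowledge base has validation errors; fix them before export")
  if (syntax == "turtle") .exportTurtle(kb) else .exportFunctional(kb)
}

.kbInventory <- function(kb) {
  reg <- kb@snps[order(kb@snps$rsid), , drop = FALSE]
  haps <- list()
  for (g in sort(names(kb@haplotypes)))
    haps[[g]] <- sort(rownames(kb@haplotypes[[g]]))
  tx <- kb@taxonomy
  abstract <- if (nrow(tx)) sort(setdiff(tx$parent, unlist(haps))) else
    character(0)
  list(reg = reg, haps = haps, abstract = abstract, tx = tx)
}

.exportTurtle <- function(kb) {
  inv <- .kbInventory(kb)
  reg <- inv$reg
  L <- c(
    sprintf("@prefix : <%s#> .", .PGX_BASE),
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .",
    "",
    sprintf("<%s> a owl:Ontology .", .PGX_BASE),
    "",
    ":has a owl:ObjectProperty .",
    ":has_haplotype a owl:ObjectProperty .",
    paste0(":", .ANNOTATIONS, " a owl:AnnotationProperty ."),
    ":human a owl:Class .",
    ":polymorphism a owl:Class .",
    ":haplotype a owl:Class .",
    "")
  ## SNP classes and allele subclasses
  for (i in seq_len(nrow(reg))) {
    r <- reg$rsid[i]
    ann <- c(
      sprintf(":%s a owl:Class ;", .iriLocal(r)),
      "    rdfs:subClassOf :polymorphism ;",
      sprintf("    :rsid \"%s\" ;", .ttlEscape(r)),
      sprintf("    :relevant_for \"%s\" ;", .ttlEscape(reg$gene[i])),
      sprintf("    :dbsnp_orientation_on_reference_genome \"%s\" ;",
              reg$orientation[i]))
    for (a in .splitField(reg$assays[i])[[1]])
      ann <- c(ann, sprintf("    :can_be_tested_with \"%s\" ;",
                            .ttlEscape(a)))
    if (nzchar(reg$seeAlso[i]))
      ann <- c(ann, sprintf("    rdfs:seeAlso <%s> ;", reg$seeAlso[i]))
    ann[length(ann)] <- sub(" ;$", " .", ann[length(ann)])
    L <- c(L, ann)
    for (a in .splitField(reg$alleles[i])[[1]])
      L <- c(L, sprintf(":%s a owl:Class ; rdfs:subClassOf :%s .",
                        .iriLocal(paste0(r, "_", a)), .iriLocal(r)))
    L <- c(L, "")
  }
  ## star-allele classes (abstract taxonomy parents included)
  for (g in names(inv$haps)) {
    for (h in inv$haps[[g]])
      L <- c(L, sprintf(
        ":%s a owl:Class ; rdfs:subClassOf :haplotype ; :relevant_for \"%s\" ; rdfs:label \"%s\" .",
        .iriLocal(h), .ttlEscape(g), .ttlEscape(h)))
  }
  tx <- inv$tx
  if (nrow(tx)) {
    for (h in inv$abstract) {
      g <- tx$gene[match(h, tx$parent)]
      L <- c(L, sprintf(
        ":%s a owl:Class ; rdfs:subClassOf :haplotype ; :relevant_for \"%s\" ; rdfs:label \"%s\" .",
        .iriLocal(h), .ttlEscape(g), .ttlEscape(h)))
    }
    for (i in order(tx$child))
      L <- c(L, sprintf(":%s rdfs:subClassOf :%s .",
                        .iriLocal(tx$child[i]), .iriLocal(tx$parent[i])))
  }
  L <- c(L, "")
  ## carrier classes: one per unordered pair of a gene's star alleles
  for (g in names(inv$haps)) {
    m <- kb@haplotypes[[g]]
    for (pair in .genePairs(rownames(m))) {
      cls <- .iriLocal(paste0("human_with_", pair[1], "_", pair[2]))
      parts <- ":human"
      for (r in colnames(m)) {
        tab <- table(c(m[pair[1], r], m[pair[2], r]))
        for (a in names(tab))
          parts <- c(parts, .ttlCard("has", .iriLocal(paste0(r, "_", a)),
                                     as.integer(tab[[a]])))
      }
      sub <- if (pair[1] == pair[2])
        .ttlCard("has_haplotype", .iriLocal(pair[1]), 2L)
      else
        paste(.ttlCard("has_haplotype", .iriLocal(pair[1]), 1L), ",",
              .ttlCard("has_haplotype", .iriLocal(pair[2]), 1L))
      L <- c(L,
        sprintf(":%s a owl:Class ;", cls),
        sprintf("    owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( %s ) ] ;",
                paste(parts, collapse = " ")),
        sprintf("    rdfs:subClassOf %s .", sub),
        "")
    }
  }
  ## rules
  emitRule <- function(r, isPhen) {
    cls <- .iriLocal(r$id)
    ann <- c(sprintf(":%s a owl:Class ;", cls))
    if (isPhen) {
      ann <- c(ann, sprintf("    :phenotype \"%s\" ;",
                            .ttlEscape(r$phenotype_label)))
    } else {
      ann <- c(ann,
        sprintf("    :CDS_message \"%s\" ;", .ttlEscape(r$message)),
        sprintf("    :relevant_for \"%s\" ;", .ttlEscape(r$drug)),
        sprintf("    :recommendations_importance \"%s\" ;", r$importance))
    }
    ann <- c(ann, sprintf("    :source \"%s\" ;", .ttlEscape(r$source)),
             sprintf("    owl:equivalentClass %s .",
                     .exprToOwl(r$expression, kb, turtle = TRUE)))
    c(ann, "")
  }
  for (id in sort(names(kb@phenotypeRules)))
    L <- c(L, emitRule(kb@phenotypeRules[[id]], TRUE))
  for (id in sort(names(kb@cdsRules)))
    L <- c(L, emitRule(kb@cdsRules[[id]], FALSE))
  paste(L, collapse = "\n")
}

.exportFunctional <- function(kb) {
  inv <- .kbInventory(kb)
  reg <- inv$reg
  L <- c(
    sprintf("Prefix(:=<%s#>)", .PGX_BASE),
    "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    "Prefix(xsd:=<http://www.w3.org/2001/XMLSchema#>)",
    sprintf("Ontology(<%s>", .PGX_BASE),
    "Declaration(ObjectProperty(:has))",
    "Declaration(ObjectProperty(:has_haplotype))",
    paste0("Declaration(AnnotationProperty(:", .ANNOTATIONS, "))"),
    "Declaration(Class(:human))",
    "Declaration(Class(:polymorphism))",
    "Declaration(Class(:haplotype))")
  lit <- function(x) sprintf("\"%s\"", .ttlEscape(x))
  for (i in seq_len(nrow(reg))) {
    r <- reg$rsid[i]; ir <- paste0(":", .iriLocal(r))
    L <- c(L,
      sprintf("Declaration(Class(%s))", ir),
      sprintf("SubClassOf(%s :polymorphism)", ir),
      sprintf("AnnotationAssertion(:rsid %s %s)", ir, lit(r)),
      sprintf("AnnotationAssertion(:relevant_for %s %s)", ir,
              lit(reg$gene[i])),
      sprintf("AnnotationAssertion(:dbsnp_orientation_on_reference_genome %s %s)",
              ir, lit(reg$orientation[i])))
    for (a in .splitField(reg$assays[i])[[1]])
      L <- c(L, sprintf("AnnotationAssertion(:can_be_tested_with %s %s)",
                        ir, lit(a)))
    if (nzchar(reg$seeAlso[i]))
      L <- c(L, sprintf("AnnotationAssertion(rdfs:seeAlso %s <%s>)",
                        ir, reg$seeAlso[i]))
    for (a in .splitField(reg$alleles[i])[[1]]) {
      ia <- paste0(":", .iriLocal(paste0(r, "_", a)))
      L <- c(L, sprintf("Declaration(Class(%s))", ia),
             sprintf("SubClassOf(%s %s)", ia, ir))
    }
  }
  allHaps <- c(unlist(inv$haps), inv$abstract)
  hapGene <- .haplotypeGeneMap(kb)
  for (h in sort(allHaps)) {
    ih <- paste0(":", .iriLocal(h))
    L <- c(L, sprintf("Declaration(Class(%s))", ih),
           sprintf("SubClassOf(%s :haplotype)", ih),
           sprintf("AnnotationAssertion(:relevant_for %s %s)", ih,
                   lit(unname(hapGene[h]))))
  }
  tx <- inv$tx
  if (nrow(tx))
    for (i in order(tx$child))
      L <- c(L, sprintf("SubClassOf(:%s :%s)", .iriLocal(tx$child[i]),
                        .iriLocal(tx$parent[i])))
  for (g in names(inv$haps)) {
    m <- kb@haplotypes[[g]]
    for (pair in .genePairs(rownames(m))) {
      cls <- paste0(":", .iriLocal(paste0("human_with_", pair[1], "_",
                                          pair[2])))
      parts <- ":human"
      for (r in colnames(m)) {
        tab <- table(c(m[pair[1], r], m[pair[2], r]))
        for (a in names(tab))
          parts <- c(parts, .fnCard("has", .iriLocal(paste0(r, "_", a)),
                                    as.integer(tab[[a]])))
      }
      L <- c(L, sprintf("Declaration(Class(%s))", cls),
             sprintf("EquivalentClasses(%s ObjectIntersectionOf(%s))",
                     cls, paste(parts, collapse = " ")))
      if (pair[1] == pair[2]) {
        L <- c(L, sprintf("SubClassOf(%s %s)", cls,
                          .fnCard("has_haplotype", .iriLocal(pair[1]), 2L)))
      } else {
        L <- c(L, sprintf("SubClassOf(%s %s)", cls,
                          .fnCard("has_haplotype", .iriLocal(pair[1]), 1L)),
               sprintf("SubClassOf(%s %s)", cls,
                       .fnCard("has_haplotype", .iriLocal(pair[2]), 1L)))
      }
    }
  }
  emitRule <- function(r, isPhen) {
    cls <- paste0(":", .iriLocal(r$id))
    out <- c(sprintf("Declaration(Class(%s))", cls))
    if (isPhen)
      out <- c(out, sprintf("AnnotationAssertion(:phenotype %s %s)", cls,
                            lit(r$phenotype_label)))
    else
      out <- c(out,
        sprintf("AnnotationAssertion(:CDS_message %s %s)", cls,
                lit(r$message)),
        sprintf("AnnotationAssertion(:relevant_for %s %s)", cls,
                lit(r$drug)),
        sprintf("AnnotationAssertion(:recommendations_importance %s %s)",
                cls, lit(r$importance)))
    c(out,
      sprintf("AnnotationAssertion(:source %s %s)", cls, lit(r$source)),
      sprintf("EquivalentClasses(%s %s)", cls,
              .exprToOwl(r$expression, kb, turtle = FALSE)))
  }
  for (id in sort(names(kb@phenotypeRules)))
    L <- c(L, emitRule(kb@phenotypeRules[[id]], TRUE))
  for (id in sort(names(kb@cdsRules)))
    L <- c(L, emitRule(kb@cdsRules[[id]], FALSE))
  paste(c(L, ")"), collapse = "\n")
}

#' Export a patient as OWL individual assertions
#'
#' One individual typed `human`, with one allele-possession assertion per
#' allele copy: two assertions for a homozygous call, one-and-one for a
#' heterozygous call (in Turtle each assertion is a `:has` statement to a
#' blank node typed by the allele class, so a called SNP always yields
#' exactly two `:has` triples).
#'
#' @param genotype a [PatientGenotype-class].
#' @param syntax "turtle" or "functional".
#' @return character scalar: the document text.
#' @export
exportPatientOwl <- function(genotype, syntax = c("turtle", "functional")) {
  syntax <- match.arg(syntax)
  pid <- .iriLocal(paste0("patient_", genotype@patientId))
  calls <- genotype@calls
  if (syntax == "turtle") {
    L <- c(
      sprintf("@prefix : <%s#> .", .PGX_BASE),
      "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
      "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
      "",
      sprintf(":%s a owl:NamedIndividual , :human .", pid))
    for (r in names(calls))
      for (a in calls[[r]])
        L <- c(L, sprintf(":%s :has [ a :%s ] .", pid,
                          .iriLocal(paste0(r, "_", a))))
    return(paste(L, collapse = "\n"))
  }
  L <- c(
    sprintf("Prefix(:=<%s#>)", .PGX_BASE),
    "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
    sprintf("Ontology(<%s/patient>", .PGX_BASE),
    sprintf("Declaration(NamedIndividual(:%s))", pid),
    sprintf("ClassAssertion(:human :%s)", pid))
  k <- 0L
  for (r in names(calls)) {
    for (a in calls[[r]]) {
      k <- k + 1L
      node <- sprintf(":%s_allele_%d", pid, k)
      L <- c(L,
        sprintf("Declaration(NamedIndividual(%s))", node),
        sprintf("ClassAssertion(:%s %s)", .iriLocal(paste0(r, "_", a)), node),
        sprintf("ObjectPropertyAssertion(:has :%s %s)", pid, node))
    }
  }
  paste(c(L, ")"), collapse = "\n")
}

## ---- Turtle reading -------------------------------------------------------

## Minimal Turtle triple reader covering the syntax subset this package
## emits plus ordinary prefixed documents: @prefix, IRIs, prefixed names,
## string literals (with ^^datatype / @lang), blank-node property lists
## [...], collections (...), "a", and , / ; / . punctuation. Returns a
## data.frame of triples with generated ids for blank nodes.
.parseTurtle <- function(text) {
  chars <- strsplit(paste(text, collapse = "\n"), "")[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) { i <- i + 1L; next }
    if (ch == "#") {  # comment to end of line
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i
      while (j <= n && chars[j] != ">") j <- j + 1L
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- "\""
      while (j <= n) {
        if (chars[j] == "\\") {
          buf <- paste0(buf, chars[j], chars[j + 1L]); j <- j + 2L
        } else if (chars[j] == "\"") {
          buf <- paste0(buf, "\""); j <- j + 1L; break
        } else { buf <- paste0(buf, chars[j]); j <- j + 1L }
      }
      ## optional ^^datatype or @lang suffix
      if (j <= n && chars[j] == "^") {
        j <- j + 2L
        k <- j
        while (k <= n && !chars[k] %in% c(" ", "\t", "\n", ";", ",", ".",
                                          "]", ")")) k <- k + 1L
        buf <- paste0(buf, "^^", paste(chars[j:(k - 1L)], collapse = ""))
        j <- k
      } else if (j <= n && chars[j] == "@") {
        k <- j
        while (k <= n && !chars[k] %in% c(" ", "\t", "\n", ";", ",", ".",
                                          "]", ")")) k <- k + 1L
        buf <- paste0(buf, paste(chars[j:(k - 1L)], collapse = ""))
        j <- k
      }
      toks <- c(toks, buf)
      i <- j; next
    }
    if (ch %in% c("[", "]", "(", ")", ";", ",")) {
      toks <- c(toks, ch); i <- i + 1L; next
    }
    ## bare token (prefixed name, 'a', '@prefix', number, or '.')
    j <- i
    while (j <= n && !chars[j] %in% c(" ", "\t", "\n", "\r", ";", ",",
                                      "[", "]", "(", ")", "\"")) j <- j + 1L
    tok <- paste(chars[i:(j - 1L)], collapse = "")
    ## a trailing '.' ends a statement unless part of a decimal or IRI-safe
    ## local name followed by whitespace (we emit ' .' so this is enough)
    if (nchar(tok) > 1L && endsWith(tok, ".") &&
        !grepl("^[0-9.]+$", tok)) {
      toks <- c(toks, substr(tok, 1L, nchar(tok) - 1L), ".")
    } else {
      toks <- c(toks, tok)
    }
    i <- j
  }
  ## parse token stream
  env <- new.env()
  env$triples <- list()
  env$bcount <- 0L
  env$prefixes <- character(0)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  expand <- function(t) {
    if (is.na(t)) return(t)
    if (startsWith(t, "<")) return(substr(t, 2L, nchar(t) - 1L))
    if (t == "a") return("http://www.w3.org/1999/02/22-rdf-syntax-ns#type")
    if (grepl("^[A-Za-z0-9_-]*:", t)) {
      p <- sub(":.*$", "", t)
      local <- sub("^[^:]*:", "", t)
      base <- env$prefixes[paste0(p, ":")]
      if (!is.na(base)) return(paste0(base, local))
    }
    t
  }
  emit <- function(s, p, o)
    env$triples[[length(env$triples) + 1L]] <- c(s, p, o)
  newBlank <- function() {
    env$bcount <- env$bcount + 1L
    paste0("_:b", env$bcount)
  }
  parseObject <- function() {
    t <- peek()
    if (identical(t, "[")) {
      advance()
      id <- newBlank()
      if (!identical(peek(), "]")) parsePoList(id)
      stopifnot(identical(advance(), "]"))
      id
    } else if (identical(t, "(")) {
      advance()
      items <- character(0)
      while (!identical(peek(), ")")) items <- c(items, parseObject())
      advance()
      ## rdf collection triples
      RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
      if (!length(items)) return(paste0(RDF, "nil"))
      ids <- vapply(items, function(x) newBlank(), character(1))
      for (k in seq_along(items)) {
        emit(ids[k], paste0(RDF, "first"), items[k])
        emit(ids[k], paste0(RDF, "rest"),
             if (k < length(items)) ids[k + 1L] else paste0(RDF, "nil"))
      }
      ids[1]
    } else {
      expand(advance())
    }
  }
  parsePoList <- function(subj) {
    repeat {
      pred <- expand(advance())
      repeat {
        obj <- parseObject()
        emit(subj, pred, obj)
        if (identical(peek(), ",")) { advance(); next }
        break
      }
      if (identical(peek(), ";")) {
        advance()
        if (peek() %in% c(".", "]")) break  # tolerate trailing ;
        next
      }
      break
    }
  }
  while (pos <= length(toks)) {
    t <- peek()
    if (identical(t, "@prefix") || identical(tolower(t), "prefix")) {
      advance()
      p <- advance()
      iri <- advance()
      env$prefixes[p] <- substr(iri, 2L, nchar(iri) - 1L)
      if (identical(peek(), ".")) advance()
      next
    }
    subj <- parseObject()
    parsePoList(subj)
    stopifnot(identical(advance(), "."))
  }
  tr <- do.call(rbind, env$triples)
  if (is.null(tr))
    return(data.frame(subject = character(0), predicate = character(0),
                      object = character(0), stringsAsFactors = FALSE))
  data.frame(subject = tr[, 1], predicate = tr[, 2], object = tr[, 3],
             stringsAsFactors = FALSE)
}

.localName <- function(x) sub(".*[#/]", "", x)

.litValue <- function(x) {
  x <- sub("\\^\\^.*$", "", x)
  x <- sub("@[A-Za-z-]+$", "", x)
  if (startsWith(x, "\"")) x <- substr(x, 2L, nchar(x) - 1L)
  gsub("\\\"", "\"", x, fixed = TRUE)
}

#' Default annotation-property mapping for [countOntologyEntities()]
#'
#' Maps the counting heuristics to annotation local names. Adjust when a
#' document uses different property names.
#'
#' @param rsid,cds_message,relevant_for,phenotype,haplotype_root local
#'   names of the corresponding annotation properties / root class.
#' @return named list.
#' @export
owlAnnotationMapping <- function(rsid = "rsid", cds_message = "CDS_message",
                                 relevant_for = "relevant_for",
                                 phenotype = "phenotype",
                                 haplotype_root = "haplotype") {
  list(rsid = rsid, cds_message = cds_message, relevant_for = relevant_for,
       phenotype = phenotype, haplotype_root = haplotype_root)
}

#' Count entities in an OWL/Turtle document by annotation signature
#'
#' Counting is annotation-driven so it is robust to naming schemes:
#' classes bearing the `rsid` annotation are SNPs; their direct subclasses
#' are variants (alleles); subclasses (transitively) of the haplotype root
#' class are star alleles; classes bearing `CDS_message` are CDS rules;
#' classes bearing the `phenotype` annotation are phenotype rules; genes
#' are the distinct `relevant_for` values on SNP classes.
#'
#' @param x path to a Turtle file, or the document text itself.
#' @param mapping annotation mapping from [owlAnnotationMapping()].
#' @return list with counts: `snp_classes`, `variant_classes`,
#'   `haplotype_classes`, `genes`, `phenotype_rules`, `cds_rules`.
#' @export
countOntologyEntities <- function(x, mapping = owlAnnotationMapping()) {
  text <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x, warn = FALSE, encoding = "UTF-8")
  else x
  tr <- .parseTurtle(text)
  if (!nrow(tr))
    return(list(snp_classes = 0L, variant_classes = 0L,
                haplotype_classes = 0L, genes = 0L, phenotype_rules = 0L,
                cds_rules = 0L))
  predLocal <- .localName(tr$predicate)
  snps <- unique(tr$subject[predLocal == mapping$rsid])
  subClassOf <- tr[predLocal == "subClassOf", , drop = FALSE]
  variants <- unique(subClassOf$subject[subClassOf$object %in% snps])
  ## transitive closure below the haplotype root
  rootIris <- unique(subClassOf$object[
    .localName(subClassOf$object) == mapping$haplotype_root])
  hapSet <- character(0)
  frontier <- rootIris
  while (length(frontier)) {
    kids <- unique(subClassOf$subject[subClassOf$object %in% frontier])
    kids <- setdiff(kids, hapSet)
    hapSet <- c(hapSet, kids)
    frontier <- kids
  }
  genes <- unique(vapply(
    tr$object[predLocal == mapping$relevant_for & tr$subject %in% snps],
    .litValue, character(1)))
  cds <- unique(tr$subject[predLocal == mapping$cds_message])
  phen <- unique(tr$subject[predLocal == mapping$phenotype])
  list(snp_classes = length(snps), variant_classes = length(variants),
       haplotype_classes = length(hapSet), genes = length(genes),
       phenotype_rules = length(phen), cds_rules = length(cds))
}
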