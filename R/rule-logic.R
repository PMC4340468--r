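## Population semantics for rules: finite model enumeration over diplotype
## space, pairwise subsumption/overlap classification, and the knowledge-base
## conflict audit. This replaces class-level DL subsumption for the monotone
## qualified-cardinality fragment the rule grammar uses.

.UNSAT_GENE <- "__unsatisfiable__"

#' Expand phenotype atoms into their defining expressions
#'
#' Substitutes each phenotype atom by the disjunction of the expressions of
#' the phenotype rules carrying that label (monotone, so the substitution
#' preserves the target population). A label with no defining rule becomes
#' an empty disjunction, i.e. unsatisfiable.
#'
#' @param expr expression tree.
#' @param kb a [PgxKnowledgeBase-class].
#' @param .depth recursion guard for phenotype rules that reference
#'   phenotypes.
#' @return expression tree free of phenotype atoms.
#' @export
expandPhenotypeAtoms <- function(expr, kb, .depth = 0L) {
  if (.depth > 20L) stop("phenotype definitions nested too deeply (cycle?)")
  switch(expr$kind,
    and = ,
    or = {
      expr$children <- lapply(expr$children, expandPhenotypeAtoms, kb = kb,
                              .depth = .depth)
      expr
    },
    phenotype = {
      defs <- Filter(function(r) r$phenotype_label == expr$label,
                     kb@phenotypeRules)
      list(kind = "or",
           children = lapply(unname(defs), function(r)
             expandPhenotypeAtoms(r$expression, kb, .depth + 1L)))
    },
    expr)
}

## gene of a single atom (phenotype atoms must be expanded away first)
.atomGene <- function(atom, kb, hapGene) {
  if (atom$kind == "hap") {
    g <- hapGene[atom$name]
    if (is.na(g)) stop("undefined haplotype in rule: ", atom$name)
    unname(g)
  } else if (atom$kind == "snp") {
    i <- match(atom$rsid, kb@snps$rsid)
    if (is.na(i)) stop("unknown rsID in rule: ", atom$rsid)
    kb@snps$gene[i]
  } else {
    stop("cannot assign a gene to atom kind: ", atom$kind)
  }
}

#' Decompose a rule expression into per-gene sub-expressions
#'
#' Rewrites a monotone expression as a conjunction of per-gene parts, the
#' tractability device that lets rule populations be compared gene by gene:
#' atoms carry their own gene, AND distributes, and an OR is decomposable
#' only when all of its children constrain one and the same gene. Phenotype
#' atoms are expanded first (see [expandPhenotypeAtoms()]).
#'
#' @param expr expression tree.
#' @param kb a [PgxKnowledgeBase-class].
#' @return named list: gene -> sub-expression (the AND of that gene's
#'   conjuncts).
#' @section Errors: an OR mixing genes raises a classed error
#'   (`pgx_non_decomposable`) directing the caller to full product
#'   enumeration ([compareRules()] falls back automatically).
#' @export
decomposeByGene <- function(expr, kb) {
  hapGene <- .haplotypeGeneMap(kb)
  dec <- function(e) {
    ## returns named list gene -> list of conjunct expressions
    switch(e$kind,
      and = {
        out <- list()
        for (ch in lapply(e$children, dec))
          for (g in names(ch))
            out[[g]] <- c(out[[g]], ch[[g]])
        out
      },
      or = {
        if (!length(e$children))
          return(stats::setNames(list(list(e)), .UNSAT_GENE))
        parts <- lapply(e$children, dec)
        genes <- lapply(parts, names)
        if (any(lengths(genes) != 1L) ||
            length(unique(unlist(genes))) != 1L) {
          cond <- structure(
            class = c("pgx_non_decomposable", "error", "condition"),
            list(message = "OR mixes genes: expression is not decomposable per gene; use full product enumeration",
                 call = sys.call(-1)))
          stop(cond)
        }
        g <- unlist(genes)[1]
        rebuilt <- lapply(parts, function(p) {
          cj <- p[[1]]
          if (length(cj) == 1L) cj[[1]] else list(kind = "and", children = cj)
        })
        stats::setNames(list(list(list(kind = "or", children = rebuilt))), g)
      },
      phenotype = stop("expand phenotype atoms before decomposition"),
      ## atoms
      stats::setNames(list(list(e)), .atomGene(e, kb, hapGene)))
  }
  parts <- dec(expr)
  lapply(parts, function(cj)
    if (length(cj) == 1L) cj[[1]] else list(kind = "and", children = cj))
}

## ---- finite domains -------------------------------------------------------

## Enumeration domain for one gene: all unordered diplotypes when the gene
## has a haplotype table, otherwise all unordered genotype combinations over
## the referenced rsIDs. Each element carries a canonical label plus the
## evaluation context (support counts / zygosity profile).
.geneDomain <- function(gene, kb, rsids = character(0)) {
  parent <- .parentMap(kb)
  if (gene == .UNSAT_GENE) {
    return(list(labels = "*",
                contexts = list(list(support = integer(0), profile = list()))))
  }
  if (gene %in% names(kb@haplotypes)) {
    m <- kb@haplotypes[[gene]]
    haps <- rownames(m)
    labels <- character(0); contexts <- list()
    for (i in seq_along(haps)) {
      for (j in i:length(haps)) {
        pair <- sort(c(haps[i], haps[j]))
        cnt <- .pairCounts(pair, parent)
        prof <- lapply(colnames(m), function(r) {
          tab <- table(c(m[haps[i], r], m[haps[j], r]))
          stats::setNames(as.integer(tab), names(tab))
        })
        names(prof) <- colnames(m)
        labels <- c(labels, paste(pair, collapse = "|"))
        contexts[[length(contexts) + 1L]] <-
          list(support = cnt, profile = prof, pair = pair)
      }
    }
    ord <- order(labels)
    return(list(labels = labels[ord], contexts = contexts[ord]))
  }
  if (!length(rsids))
    stop("gene ", gene, " has no haplotype table and no referenced SNPs")
  rsids <- sort(unique(rsids))
  perSnp <- lapply(rsids, function(r) {
    al <- .snpAlleles(kb@snps, r)
    if (!length(al)) stop("unknown rsID: ", r)
    pairs <- list()
    for (i in seq_along(al))
      for (j in i:length(al))
        pairs[[length(pairs) + 1L]] <- c(al[i], al[j])
    pairs
  })
  grid <- expand.grid(lapply(perSnp, seq_along))
  labels <- character(0); contexts <- list()
  for (k in seq_len(nrow(grid))) {
    prof <- list()
    parts <- character(0)
    for (s in seq_along(rsids)) {
      pr <- sort(perSnp[[s]][[grid[k, s]]])
      tab <- table(pr)
      prof[[rsids[s]]] <- stats::setNames(as.integer(tab), names(tab))
      parts <- c(parts, paste0(rsids[s], "=", paste(pr, collapse = "/")))
    }
    labels <- c(labels, paste(parts, collapse = ";"))
    contexts[[length(contexts) + 1L]] <- list(support = integer(0),
                                              profile = prof)
  }
  ord <- order(labels)
  list(labels = labels[ord], contexts = contexts[ord])
}

.evalOnContext <- function(expr, ctx) {
  evaluateRuleExpression(expr, ctx$support, ctx$profile,
                         phenotypes = character(0),
                         exactCounts = list(ctx$support))
}

#' Enumerate the diplotypes satisfying a single-gene sub-expression
#'
#' Enumerates all unordered pairs over the gene's star alleles, derives
#' each pair's taxonomy-closed support counts and implied zygosity profile
#' over the panel, and keeps the pairs the expression accepts under
#' [evaluateRuleExpression()] semantics. An unsatisfiable sub-expression
#' yields an empty set.
#'
#' @param subExpr single-gene expression (e.g. from [decomposeByGene()]).
#' @param gene gene symbol.
#' @param kb a [PgxKnowledgeBase-class].
#' @return character vector of canonical diplotype labels ("h1|h2", sorted
#'   within and across).
#' @examples
#' kb <- demoKnowledgeBase()
#' e <- kbRules(kb, "cds")[["rule_27"]]$expression
#' satisfyingDiplotypes(decomposeByGene(e, kb)[["TPMT"]], "TPMT", kb)
#' @export
satisfyingDiplotypes <- function(subExpr, gene, kb) {
  dom <- .geneDomain(gene, kb,
                     rsids = vapply(Filter(function(a) a$kind == "snp",
                                           .exprAtoms(subExpr)),
                                    `[[`, character(1), "rsid"))
  keep <- vapply(dom$contexts, function(ctx) .evalOnContext(subExpr, ctx),
                 logical(1))
  dom$labels[keep]
}

#' Per-gene population model of a rule expression
#'
#' Phenotype atoms are expanded, the expression decomposed per gene, and
#' each gene's satisfying diplotype/genotype set enumerated. Genes not
#' referenced are unconstrained (absent from the result).
#'
#' @param expr expression tree.
#' @param kb a [PgxKnowledgeBase-class].
#' @return named list: gene -> character vector of satisfying canonical
#'   elements. A rule is unsatisfiable iff some component is empty.
#' @export
rulePopulation <- function(expr, kb) {
  dec <- decomposeByGene(expandPhenotypeAtoms(expr, kb), kb)
  out <- list()
  for (g in names(dec))
    out[[g]] <- satisfyingDiplotypes(dec[[g]], g, kb)
  out
}

## rsIDs referenced for `gene` by an expression (for shared genotype domains)
.geneRsids <- function(dec, gene) {
  if (!gene %in% names(dec)) return(character(0))
  vapply(Filter(function(a) a$kind == "snp", .exprAtoms(dec[[gene]])),
         `[[`, character(1), "rsid")
}

#' Compare the target populations of two rules
#'
#' Classifies the pair as `equivalent`, `A_subsumed_by_B`,
#' `B_subsumed_by_A`, `overlapping` or `disjoint` by enumerating each
#' gene's satisfying set and comparing componentwise (populations are
#' products across genes; a gene one rule leaves unconstrained admits its
#' full domain). When an expression does not decompose per gene, the
#' comparison falls back to bounded enumeration of the full product space;
#' exceeding `limit` yields relation `"undecided"`, never a silent
#' truncation.
#'
#' The `conflict` flag is set when the relation is an equivalence or
#' subsumption, both rules concern the same drug, and their messages
#' differ — the situation where two guideline sources give different
#' recommendations for nested patient populations.
#'
#' @param ruleA,ruleB rule records (from [kbRules()]), or rule ids present
#'   in `kb`.
#' @param kb a [PgxKnowledgeBase-class].
#' @param limit maximum number of product-space models enumerated in the
#'   fallback (default 1e6).
#' @return list: `ruleA`, `ruleB`, `relation`, `conflict`, and `witnesses`
#'   (per gene: `both`, `onlyA`, `onlyB` example elements where non-empty).
#' @examples
#' kb <- demoKnowledgeBase()
#' compareRules("rule_27", "rule_35", kb)$relation
#' @export
compareRules <- function(ruleA, ruleB, kb, limit = 1e6) {
  resolve <- function(r) {
    if (is.character(r)) {
      rr <- kbRules(kb)[[r]]
      if (is.null(rr)) stop("no such rule: ", r)
      rr
    } else r
  }
  ruleA <- resolve(ruleA); ruleB <- resolve(ruleB)
  exprA <- expandPhenotypeAtoms(ruleA$expression, kb)
  exprB <- expandPhenotypeAtoms(ruleB$expression, kb)
  decA <- tryCatch(decomposeByGene(exprA, kb),
                   pgx_non_decomposable = function(e) NULL)
  decB <- tryCatch(decomposeByGene(exprB, kb),
                   pgx_non_decomposable = function(e) NULL)
  if (is.null(decA) || is.null(decB))
    return(.compareProduct(ruleA, ruleB, exprA, exprB, kb, limit))

  genes <- sort(unique(c(names(decA), names(decB))))
  SA <- list(); SB <- list(); full <- list()
  for (g in genes) {
    rsids <- unique(c(.geneRsids(decA, g), .geneRsids(decB, g)))
    dom <- .geneDomain(g, kb, rsids)
    full[[g]] <- dom$labels
    SA[[g]] <- if (g %in% names(decA))
      satisfyingDiplotypes(decA[[g]], g, kb) else dom$labels
    SB[[g]] <- if (g %in% names(decB))
      satisfyingDiplotypes(decB[[g]], g, kb) else dom$labels
    ## genotype-domain sets must live in the shared (union-rsID) domain:
    ## re-evaluate against the shared domain when labels differ
    if (!g %in% names(kb@haplotypes) && g != .UNSAT_GENE) {
      if (g %in% names(decA))
        SA[[g]] <- dom$labels[vapply(dom$contexts, function(ctx)
          .evalOnContext(decA[[g]], ctx), logical(1))]
      if (g %in% names(decB))
        SB[[g]] <- dom$labels[vapply(dom$contexts, function(ctx)
          .evalOnContext(decB[[g]], ctx), logical(1))]
    }
  }
  .relationFromSets(ruleA, ruleB, SA, SB, genes)
}

.relationFromSets <- function(ruleA, ruleB, SA, SB, genes) {
  emptyA <- any(lengths(SA) == 0L)
  emptyB <- any(lengths(SB) == 0L)
  witnesses <- list()
  if (emptyA || emptyB) {
    relation <- if (emptyA && emptyB) "equivalent"
    else if (emptyA) "A_subsumed_by_B" else "B_subsumed_by_A"
  } else {
    AsubB <- all(vapply(genes, function(g)
      all(SA[[g]] %in% SB[[g]]), logical(1)))
    BsubA <- all(vapply(genes, function(g)
      all(SB[[g]] %in% SA[[g]]), logical(1)))
    overlap <- all(vapply(genes, function(g)
      length(intersect(SA[[g]], SB[[g]])) > 0L, logical(1)))
    relation <- if (AsubB && BsubA) "equivalent"
    else if (AsubB) "A_subsumed_by_B"
    else if (BsubA) "B_subsumed_by_A"
    else if (overlap) "overlapping"
    else "disjoint"
    for (g in genes) {
      w <- list()
      both <- intersect(SA[[g]], SB[[g]])
      onlyA <- setdiff(SA[[g]], SB[[g]])
      onlyB <- setdiff(SB[[g]], SA[[g]])
      if (length(both)) w$both <- both[1]
      if (length(onlyA)) w$onlyA <- onlyA[1]
      if (length(onlyB)) w$onlyB <- onlyB[1]
      if (length(w)) witnesses[[g]] <- w
    }
  }
  drugA <- if (is.null(ruleA$drug)) "" else ruleA$drug
  drugB <- if (is.null(ruleB$drug)) "" else ruleB$drug
  msgA <- if (is.null(ruleA$message)) "" else ruleA$message
  msgB <- if (is.null(ruleB$message)) "" else ruleB$message
  conflict <- relation %in% c("equivalent", "A_subsumed_by_B",
                              "B_subsumed_by_A") &&
    nzchar(drugA) && identical(drugA, drugB) && !identical(msgA, msgB)
  list(ruleA = ruleA$id, ruleB = ruleB$id, relation = relation,
       drug = if (identical(drugA, drugB)) drugA else "",
       conflict = conflict, witnesses = witnesses)
}

## full product-space fallback for non-decomposable expressions
.compareProduct <- function(ruleA, ruleB, exprA, exprB, kb, limit) {
  hapGene <- .haplotypeGeneMap(kb)
  atomInfo <- function(e) {
    atoms <- .exprAtoms(e)
    genes <- vapply(atoms, .atomGene, character(1), kb = kb,
                    hapGene = hapGene)
    rs <- vapply(atoms, function(a)
      if (a$kind == "snp") a$rsid else NA_character_, character(1))
    list(genes = genes, rsids = rs)
  }
  ia <- atomInfo(exprA); ib <- atomInfo(exprB)
  genes <- sort(unique(c(ia$genes, ib$genes)))
  doms <- list()
  for (g in genes) {
    rsids <- stats::na.omit(c(ia$rsids[ia$genes == g],
                              ib$rsids[ib$genes == g]))
    doms[[g]] <- .geneDomain(g, kb, unique(rsids))
  }
  total <- prod(vapply(doms, function(d) length(d$labels), numeric(1)))
  if (total > limit) {
    return(list(ruleA = ruleA$id, ruleB = ruleB$id, relation = "undecided",
                drug = "", conflict = FALSE, witnesses = list()))
  }
  grid <- expand.grid(lapply(doms, function(d) seq_along(d$labels)))
  inA <- logical(nrow(grid)); inB <- logical(nrow(grid))
  labels <- character(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    support <- integer(0); profile <- list()
    parts <- character(0)
    for (g in genes) {
      ctx <- doms[[g]]$contexts[[grid[k, g]]]
      for (nm in names(ctx$support))
        support[nm] <- max(support[nm], ctx$support[[nm]], na.rm = TRUE)
      profile <- c(profile, ctx$profile)
      parts <- c(parts, paste0(g, ":", doms[[g]]$labels[grid[k, g]]))
    }
    labels[k] <- paste(parts, collapse = " ")
    ctxAll <- list(support = support, profile = profile)
    inA[k] <- .evalOnContext(exprA, ctxAll)
    inB[k] <- .evalOnContext(exprB, ctxAll)
  }
  SA <- list(all = labels[inA]); SB <- list(all = labels[inB])
  .relationFromSets(ruleA, ruleB, SA, SB, "all")
}

#' Audit a knowledge base for overlapping and conflicting rules
#'
#' Compares every unordered pair of rules (phenotype and CDS) and reports
#' the non-disjoint relations. The summary gives two counting conventions
#' for "rules targeting equivalent or nested populations": the number of
#' rules on the narrower-or-equal side of at least one relation, and the
#' number of rules participating on either side; plus the subset of
#' narrower-side rules whose relation carries a same-drug,
#' different-message conflict.
#'
#' @param kb a [PgxKnowledgeBase-class].
#' @param limit product-enumeration bound per pair (see [compareRules()]).
#' @return list: `findings` (list of [compareRules()] results with relation
#'   not "disjoint"), `summary` (counts), `undecided` (rule-id pairs beyond
#'   the model bound).
#' @export
auditRuleConflicts <- function(kb, limit = 1e6) {
  rules <- kbRules(kb)
  ids <- sort(names(rules))
  findings <- list(); undecided <- list()
  narrower <- character(0); either <- character(0); conflicted <- character(0)
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        f <- compareRules(rules[[ids[i]]], rules[[ids[j]]], kb, limit)
        if (f$relation == "undecided") {
          undecided[[length(undecided) + 1L]] <- c(f$ruleA, f$ruleB)
          next
        }
        if (f$relation == "disjoint") next
        findings[[length(findings) + 1L]] <- f
        if (f$relation == "equivalent") {
          narrower <- c(narrower, f$ruleA, f$ruleB)
          either <- c(either, f$ruleA, f$ruleB)
          if (f$conflict) conflicted <- c(conflicted, f$ruleA, f$ruleB)
        } else if (f$relation == "A_subsumed_by_B") {
          narrower <- c(narrower, f$ruleA)
          either <- c(either, f$ruleA, f$ruleB)
          if (f$conflict) conflicted <- c(conflicted, f$ruleA)
        } else if (f$relation == "B_subsumed_by_A") {
          narrower <- c(narrower, f$ruleB)
          either <- c(either, f$ruleA, f$ruleB)
          if (f$conflict) conflicted <- c(conflicted, f$ruleB)
        }
      }
    }
  }
  list(findings = findings,
       summary = list(
         n_rules = length(ids),
         n_pairs_compared = if (length(ids) >= 2L)
           length(ids) * (length(ids) - 1L) / 2L else 0L,
         n_nondisjoint_findings = length(findings),
         n_subsumed_or_equivalent = length(unique(narrower)),
         n_subsumed_or_equivalent_either_side = length(unique(either)),
         n_conflicting_same_drug = length(unique(conflicted))),
       undecided = undecided)
}

#' Write an audit report to disk
#'
#' @param audit result of [auditRuleConflicts()].
#' @param path output path.
#' @param format "tsv" (one finding per line: ruleA, ruleB, relation, drug,
#'   conflict, witness) or "json" (the full structure).
#' @return `path`, invisibly.
#' @export
writeAuditReport <- function(audit, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(audit, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    rows <- vapply(audit$findings, function(f) {
      wit <- if (length(f$witnesses)) {
        paste(vapply(names(f$witnesses), function(g)
          paste0(g, ":", paste(unlist(f$witnesses[[g]]), collapse = "|")),
          character(1)), collapse = " ")
      } else ""
      paste(f$ruleA, f$ruleB, f$relation, f$drug,
            tolower(as.character(f$conflict)), wit, sep = "\t")
    }, character(1))
    writeLines(c("ruleA\truleB\trelation\tdrug\tconflict\twitness", rows),
               path)
  }
  invisible(path)
}
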