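test_that("single-gene rules decompose to one entry, cross-gene ANDs split", {
  kb <- demoKnowledgeBase()
  d27 <- decomposeByGene(kbRules(kb, "cds")[["rule_27"]]$expression, kb)
  expect_identical(names(d27), "TPMT")
  dw <- decomposeByGene(kbRules(kb, "cds")[["rule_warfarin_fda"]]$expression,
                        kb)
  expect_setequal(names(dw), c("CYP2C9", "VKORC1"))
  ## a disjunction across genes is not decomposable
  expect_error(
    decomposeByGene(orExpr(list(hapAtom("TPMT*1"), hapAtom("CYP2C9*1"))), kb),
    class = "pgx_non_decomposable")
})

test_that("satisfying sets enumerate correctly over small panels", {
  reg <- data.frame(rsid = "s1", gene = "X", orientation = "forward",
                    alleles = "A,G", assays = "", seeAlso = "")
  m <- matrix(c("A", "G"), 2, 1, dimnames = list(c("X*1", "X*2"), "s1"))
  kb <- newKnowledgeBase(reg, list(X = m))
  s <- satisfyingDiplotypes(hapAtom("X*1"), "X", kb)
  expect_setequal(s, c("X*1|X*1", "X*1|X*2"))
  ## unsatisfiable: three copies needed
  s0 <- satisfyingDiplotypes(andExpr(hapAtom("X*1", 2L, "exactly"),
                                     hapAtom("X*2")), "X", kb)
  expect_length(s0, 0L)
})

test_that("the CPIC azathioprine expression selects the five carrier pairs", {
  kb <- tpmt7Panel()
  e27 <- andExpr(hapAtom("TPMT*1"),
                 orExpr(lapply(c("TPMT*2", "TPMT*3A", "TPMT*3B", "TPMT*3C",
                                 "TPMT*4"), hapAtom)))
  s <- satisfyingDiplotypes(e27, "TPMT", kb)
  expect_setequal(s, paste0("TPMT*1|",
                            c("TPMT*2", "TPMT*3A", "TPMT*3B", "TPMT*3C",
                              "TPMT*4")))
})

test_that("the two azathioprine populations nest in the entailed direction", {
  kb <- demoKnowledgeBase()
  f <- compareRules("rule_27", "rule_35", kb)
  expect_identical(f$relation, "A_subsumed_by_B")
  expect_true(f$conflict)
  expect_identical(f$drug, "azathioprine")
  ## a strictness witness exists: a rule-35-only diplotype
  expect_true(length(f$witnesses$TPMT$onlyB) == 1L)
  ## and witnesses really satisfy/violate the expressions
  pop27 <- rulePopulation(kbRules(kb, "cds")[["rule_27"]]$expression, kb)
  pop35 <- rulePopulation(kbRules(kb, "cds")[["rule_35"]]$expression, kb)
  expect_true(all(pop27$TPMT %in% pop35$TPMT))
  expect_true(f$witnesses$TPMT$onlyB %in% setdiff(pop35$TPMT, pop27$TPMT))
  expect_gt(length(setdiff(pop35$TPMT, pop27$TPMT)), 0L)
})

test_that("a rule is equivalent to itself and duplicates conflict", {
  kb <- demoKnowledgeBase()
  self <- compareRules("rule_27", "rule_27", kb)
  expect_identical(self$relation, "equivalent")
  expect_false(self$conflict)  # identical messages
  dup <- kbRules(kb, "cds")[["rule_27"]]
  dup$id <- "rule_27_dutch_copy"
  dup$source <- "another source"
  dup$message <- "a different recommendation"
  f <- compareRules(kbRules(kb, "cds")[["rule_27"]], dup, kb)
  expect_identical(f$relation, "equivalent")
  expect_true(f$conflict)
})

test_that("taxonomy closure is monotone: adding a parent link never shrinks sets", {
  kb <- tpmt7Panel()
  e <- andExpr(hapAtom("TPMT*1"), hapAtom("TPMT*3"))
  withTax <- satisfyingDiplotypes(e, "TPMT", kb)
  kb2 <- kb
  kb2@taxonomy <- kb@taxonomy[0, , drop = FALSE]
  withoutTax <- satisfyingDiplotypes(e, "TPMT", kb2)
  expect_true(all(withoutTax %in% withTax))
  expect_gt(length(withTax), length(withoutTax))
})

test_that("relation classification matches the product-space oracle", {
  set.seed(2024)
  parent <- setNames(character(0), character(0))
  disagreements <- character(0)
  for (rep in 1:60) {
    nGenes <- sample(1:2, 1)
    mats <- list(); regs <- NULL
    for (gi in seq_len(nGenes)) {
      p <- randomPanel(sample(2:4, 1), 2, gene = sprintf("G%d", gi),
                       prefix = gi)
      mats[[sprintf("G%d", gi)]] <- p$mat
      regs <- rbind(regs, p$registry)
    }
    kb <- newKnowledgeBase(regs, mats)
    eA <- randomExpr(mats, depth = 2L)
    eB <- randomExpr(mats, depth = 2L)
    rA <- list(id = "A", drug = "", source = "", importance = "standard",
               message = "a", expression = eA)
    rB <- list(id = "B", drug = "", source = "", importance = "standard",
               message = "b", expression = eB)
    got <- compareRules(rA, rB, kb)$relation
    want <- oracleRelation(eA, eB, mats, parent)
    if (!identical(got, want))
      disagreements <- c(disagreements, paste(rep, got, want))
  }
  expect_identical(disagreements, character(0))
})

test_that("subsumption is reflexive and transitive on nested disjunction chains", {
  kb <- tpmt7Panel()
  mk <- function(id, disj) list(
    id = id, drug = "d", source = "s", importance = "standard",
    message = id,
    expression = andExpr(hapAtom("TPMT*1"), orExpr(lapply(disj, hapAtom))))
  r1 <- mk("r1", "TPMT*2")
  r2 <- mk("r2", c("TPMT*2", "TPMT*3"))
  r3 <- mk("r3", c("TPMT*2", "TPMT*3", "TPMT*4"))
  expect_identical(compareRules(r1, r1, kb)$relation, "equivalent")
  expect_identical(compareRules(r1, r2, kb)$relation, "A_subsumed_by_B")
  expect_identical(compareRules(r2, r3, kb)$relation, "A_subsumed_by_B")
  expect_identical(compareRules(r1, r3, kb)$relation, "A_subsumed_by_B")
})

test_that("non-decomposable pairs fall back to product enumeration", {
  kb <- tpmt7Panel()
  ## add a second tiny gene so a cross-gene OR is possible
  reg2 <- data.frame(rsid = "rs8000001", gene = "CYP2C9",
                     orientation = "forward", alleles = "A,C", assays = "",
                     seeAlso = "")
  m2 <- matrix(c("A", "C"), 2, 1,
               dimnames = list(c("CYP2C9*1", "CYP2C9*3"), "rs8000001"))
  kb@snps <- rbind(kb@snps, reg2)
  kb@haplotypes[["CYP2C9"]] <- m2
  crossOr <- list(id = "x", drug = "", source = "", importance = "standard",
                  message = "x",
                  expression = orExpr(list(hapAtom("TPMT*2"),
                                           hapAtom("CYP2C9*3"))))
  narrow <- list(id = "n", drug = "", source = "", importance = "standard",
                 message = "n", expression = hapAtom("TPMT*2"))
  f <- compareRules(narrow, crossOr, kb)
  expect_identical(f$relation, "A_subsumed_by_B")
  ## a tiny model budget reports "undecided" rather than truncating
  f2 <- compareRules(narrow, crossOr, kb, limit = 3)
  expect_identical(f2$relation, "undecided")
})

test_that("the audit counts narrower-side rules once", {
  kb <- demoKnowledgeBase()
  kb@phenotypeRules <- list()  # just the three CDS rules
  audit <- auditRuleConflicts(kb)
  relations <- vapply(audit$findings, `[[`, character(1), "relation")
  expect_true("A_subsumed_by_B" %in% relations ||
                "B_subsumed_by_A" %in% relations)
  ## rule_27 is the only rule strictly inside another population
  expect_identical(audit$summary$n_subsumed_or_equivalent, 1L)
  expect_identical(audit$summary$n_subsumed_or_equivalent_either_side, 2L)
  expect_identical(audit$summary$n_conflicting_same_drug, 1L)
})

test_that("disjoint-population rule sets produce an empty audit", {
  kb <- tpmt7Panel()
  mk <- function(id, hap) list(
    id = id, drug = "d", source = "s", importance = "standard",
    message = id, expression = hapAtom(hap, 2L, "exactly"))
  kb@cdsRules <- list(a = mk("a", "TPMT*2"), b = mk("b", "TPMT*4"))
  audit <- auditRuleConflicts(kb)
  expect_length(audit$findings, 0L)
  expect_identical(audit$summary$n_subsumed_or_equivalent, 0L)
})

test_that("audit reports serialize to TSV and JSON", {
  kb <- demoKnowledgeBase()
  audit <- auditRuleConflicts(kb)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeAuditReport(audit, tsv, "tsv")
  lines <- readLines(tsv)
  expect_match(lines[1], "^ruleA\truleB\trelation")
  expect_true(any(grepl("rule_27\trule_35\tA_subsumed_by_B", lines)))
  js <- withr::local_tempfile(fileext = ".json")
  writeAuditReport(audit, js, "json")
  parsed <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_identical(parsed$summary$n_rules, length(kbRules(kb)))
})
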