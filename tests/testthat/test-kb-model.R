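demoRegistry <- function() {
  readSnpRegistry(system.file("extdata/demo_kb/snp_registry.tsv",
                              package = "pgxCDS"))
}

test_that("the printed CYP2C9 excerpt compiles to the expected allele maps", {
  tab <- parseHaplotypeTable(system.file("extdata/demo_kb/cyp2c9.tsv",
                                         package = "pgxCDS"),
                             "CYP2C9", demoRegistry())
  expect_identical(rownames(tab), c("CYP2C9*1", "CYP2C9*3"))
  expect_identical(tab["CYP2C9*1", ],
                   c(rs1057910 = "A", rs1057911 = "A", rs1799853 = "C",
                     rs2256871 = "A"))
  expect_identical(tab["CYP2C9*3", ],
                   c(rs1057910 = "C", rs1057911 = "A", rs1799853 = "C",
                     rs2256871 = "A"))
})

test_that("blank cells inherit the reference row and non-blank cells are kept", {
  txt <- c("Haplotype\trs1\trs2", "X*1\tA\tC", "X*2\tG\t", "X*3\t\tT")
  tab <- parseHaplotypeTable(txt, "X")
  expect_identical(unname(tab["X*2", ]), c("G", "C"))
  expect_identical(unname(tab["X*3", ]), c("A", "T"))
  ## with no blanks the table is parsed verbatim
  full <- parseHaplotypeTable(c("Haplotype\trs1", "Y*1\tA", "Y*2\tG"), "Y")
  expect_identical(unname(full[, 1]), c("A", "G"))
})

test_that("header-only tables, duplicates and ambiguity codes are handled", {
  expect_identical(nrow(parseHaplotypeTable("Haplotype\trs1\trs2", "X")), 0L)
  expect_error(parseHaplotypeTable(
    c("Haplotype\trs1", "X*1\tA", "X*1\tG"), "X"),
    class = "pgx_duplicate_haplotype")
  expect_error(parseHaplotypeTable(
    c("Haplotype\trs1", "X*1\tA/C"), "X"),
    class = "pgx_unknown_allele")
})

test_that("registry cross-checks reject unknown rsIDs and alleles", {
  reg <- data.frame(rsid = "rs1", gene = "X", orientation = "forward",
                    alleles = "A,G", assays = "", seeAlso = "")
  expect_error(parseHaplotypeTable(
    c("Haplotype\trs1\trs999", "X*1\tA\tC"), "X", reg),
    class = "pgx_unknown_rsid")
  expect_error(parseHaplotypeTable(
    c("Haplotype\trs1", "X*1\tT"), "X", reg),
    class = "pgx_unknown_allele")
})

test_that("table parsing is idempotent through write/re-parse", {
  set.seed(11)
  for (rep in 1:5) {
    p <- randomPanel(sample(2:6, 1), sample(2:4, 1))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeHaplotypeTable(p$mat, path)
    expect_identical(parseHaplotypeTable(path, "G1", p$registry), p$mat)
  }
})

test_that("indistinguishable haplotypes are flagged exactly when maps are equal", {
  reg <- data.frame(rsid = c("s1", "s2"), gene = "X",
                    orientation = "forward", alleles = "A,G", assays = "",
                    seeAlso = "")
  m <- matrix(c("A", "G", "A", "G"), 2, 2, byrow = TRUE,
              dimnames = list(c("X*a", "X*b"), c("s1", "s2")))
  kb <- newKnowledgeBase(reg, list(X = m))
  f <- findings(checkDistinguishability(kb))
  expect_identical(nrow(f), 1L)
  expect_identical(f$category, "indistinguishable_haplotypes")
  expect_match(f$identifiers, "X\\*a,X\\*b")
  ## distinct maps: no finding (printed Table-1 pair differs at rs1057910)
  kb2 <- demoKnowledgeBase()
  expect_true(isClean(checkDistinguishability(kb2)))
  ## 10 random mutually distinct rows give an empty report
  set.seed(42)
  p <- randomPanel(10, 5)
  kb3 <- newKnowledgeBase(p$registry, list(G1 = p$mat))
  expect_true(isClean(checkDistinguishability(kb3)))
})

test_that("every validation finding names at least one existing identifier", {
  kb <- demoKnowledgeBase()
  kb@cdsRules[["bad"]] <- list(
    id = "bad", drug = "x", source = "s", importance = "standard",
    message = "m",
    expression = hapAtom("NOPE*9"))
  f <- findings(validateKnowledgeBase(kb))
  expect_true(nrow(f) >= 1L)
  expect_true(all(nzchar(f$identifiers)))
  expect_true(any(grepl("bad", f$identifiers)))
})

test_that("diploid-bound violations are reported as unsatisfiable rules", {
  kb <- tpmt7Panel()
  kb@cdsRules <- list(
    impossible = list(id = "impossible", drug = "d", source = "s",
                      importance = "standard", message = "m",
                      expression = andExpr(hapAtom("TPMT*1", 2L, "exactly"),
                                           hapAtom("TPMT*2"))),
    fine = list(id = "fine", drug = "d", source = "s",
                importance = "standard", message = "m",
                expression = andExpr(hapAtom("TPMT*1"), hapAtom("TPMT*2"))))
  f <- findings(checkRuleSatisfiability(kb))
  expect_identical(f$category, "unsatisfiable_rule")
  expect_identical(f$identifiers, "impossible")
})

test_that("satisfiability agrees with brute-force enumeration on random rules", {
  set.seed(99)
  parent <- setNames(character(0), character(0))
  for (rep in 1:40) {
    p <- randomPanel(sample(3:5, 1), 3)
    kb <- newKnowledgeBase(p$registry, list(G1 = p$mat))
    e <- randomExpr(list(G1 = p$mat), depth = 2L)
    kb@cdsRules <- list(r = list(id = "r", drug = "d", source = "s",
                                 importance = "standard", message = "m",
                                 expression = e))
    flagged <- !isClean(checkRuleSatisfiability(kb))
    ## oracle: any single-gene diplotype satisfying the expression?
    haps <- rownames(p$mat)
    anySat <- FALSE
    for (i in seq_along(haps)) for (j in i:length(haps))
      if (oracleEval(e, list(G1 = c(haps[i], haps[j])),
                     list(G1 = p$mat), parent)) anySat <- TRUE
    expect_identical(flagged, !anySat)
  }
})

test_that("rule files round-trip through a knowledge-base archive", {
  kb <- demoKnowledgeBase()
  dir <- withr::local_tempdir()
  writeKnowledgeBase(kb, dir)
  kb2 <- loadKnowledgeBase(dir)
  expect_identical(kb2@haplotypes, kb@haplotypes)
  expect_identical(kb2@snps$rsid, kb@snps$rsid)
  expect_identical(sort(names(kbRules(kb2))), sort(names(kbRules(kb))))
  expect_identical(kbRules(kb2, "cds")[["rule_27"]]$message,
                   kbRules(kb, "cds")[["rule_27"]]$message)
  expect_identical(kbRules(kb2, "cds")[["rule_35"]]$expression,
                   kbRules(kb, "cds")[["rule_35"]]$expression)
})

test_that("YAML rule files parse like JSON ones", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "rules:",
    "  - id: r1",
    "    kind: cds",
    "    drug: warfarin",
    "    source: demo",
    "    importance: standard",
    "    message: msg",
    "    when:",
    "      and:",
    "        - hap: 'CYP2C9*1'",
    "          min: 1",
    "        - snp: rs9923231",
    "          allele: t",
    "          exactly: 2"), path)
  rr <- readRuleFile(path)
  e <- rr$cdsRules[["r1"]]$expression
  expect_identical(e$kind, "and")
  expect_identical(e$children[[2]],
                   list(kind = "snp", rsid = "rs9923231", allele = "T",
                        n = 2L, mode = "exactly"))
})
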