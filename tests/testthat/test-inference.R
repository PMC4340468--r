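cyp2c9Kb <- function() demoKnowledgeBase(tpmt = FALSE)

demoPatient <- function(kb = demoKnowledgeBase()) {
  suppressMessages(read23andme(
    system.file("extdata/patients/demo_patient.txt", package = "pgxCDS"),
    kbSnps(kb), patientId = "demo"))
}

test_that("zygosity profiles count alleles to a total of two", {
  p <- patientGenotype("p", list(rs1057910 = c("A", "C"),
                                 rs1057911 = c("A", "A")))
  prof <- zygosityProfile(p)
  expect_identical(prof$rs1057910, c(A = 1L, C = 1L))
  expect_identical(prof$rs1057911, c(A = 2L))
  expect_identical(zygosityProfile(patientGenotype("e")), list())
})

test_that("the printed CYP2C9 genotype calls a unique *1/*3 heterozygote", {
  kb <- cyp2c9Kb()
  prof <- zygosityProfile(demoPatient(kb))
  res <- callDiplotypes(prof, kb, "CYP2C9")
  expect_length(res$pairs, 1L)
  expect_identical(res$pairs[[1]], c("CYP2C9*1", "CYP2C9*3"))
  ## homozygous reference across the panel
  hom <- patientGenotype("h", list(
    rs1057910 = c("A", "A"), rs1057911 = c("A", "A"),
    rs1799853 = c("C", "C"), rs2256871 = c("A", "A")))
  res2 <- callDiplotypes(zygosityProfile(hom), kb, "CYP2C9")
  expect_identical(res2$pairs, list(c("CYP2C9*1", "CYP2C9*1")))
})

test_that("strict mode refuses to call when a panel SNP is missing", {
  kb <- cyp2c9Kb()
  p <- patientGenotype("m", list(
    rs1057910 = c("A", "C"), rs1057911 = c("A", "A"),
    rs1799853 = c("C", "C")))
  res <- callDiplotypes(zygosityProfile(p), kb, "CYP2C9")
  expect_length(res$pairs, 0L)
  expect_identical(res$missing, "rs2256871")
  ## lenient mode calls over the observed SNPs
  len <- callDiplotypes(zygosityProfile(p), kb, "CYP2C9", strict = FALSE)
  expect_identical(len$pairs, list(c("CYP2C9*1", "CYP2C9*3")))
  expect_error(callDiplotypes(list(), kb, "NOPE"), "NOPE")
})

test_that("cis/trans ambiguity returns every consistent pair", {
  reg <- data.frame(rsid = c("s1", "s2"), gene = "X",
                    orientation = "forward", alleles = "A,C,G,T",
                    assays = "", seeAlso = "")
  m <- matrix(c("G", "T", "C", "A", "G", "A", "C", "T"), 4, 2, byrow = TRUE,
              dimnames = list(c("X*A", "X*B", "X*C", "X*D"), c("s1", "s2")))
  kb <- newKnowledgeBase(reg, list(X = m))
  prof <- list(s1 = c(C = 1L, G = 1L), s2 = c(A = 1L, T = 1L))
  res <- callDiplotypes(prof, kb, "X")
  expect_identical(res$pairs, list(c("X*A", "X*B"), c("X*C", "X*D")))
})

test_that("diplotype calling agrees with the brute-force oracle", {
  set.seed(123)
  disagreements <- 0L
  for (rep in 1:60) {
    p <- randomPanel(sample(2:8, 1), sample(2:4, 1))
    kb <- newKnowledgeBase(p$registry, list(G1 = p$mat))
    ## random true pair, sometimes with noise (a random profile)
    n <- nrow(p$mat)
    if (stats::runif(1) < 0.7) {
      i <- sample(n, 1); j <- sample(n, 1)
      prof <- lapply(pairSignature(p$mat, i, j), function(s) {
        tab <- table(strsplit(s, "")[[1]])
        setNames(as.integer(tab), names(tab))
      })
    } else {
      prof <- lapply(colnames(p$mat), function(r) {
        al <- sample(strsplit(p$registry$alleles[1], ",")[[1]], 2,
                     replace = TRUE)
        tab <- table(al)
        setNames(as.integer(tab), names(tab))
      })
      names(prof) <- colnames(p$mat)
    }
    got <- callDiplotypes(prof, kb, "G1")$pairs
    want <- oracleCallDiplotypes(p$mat, prof)
    if (!identical(got, want)) disagreements <- disagreements + 1L
  }
  expect_identical(disagreements, 0L)
})

test_that("observing more SNPs never enlarges the consistent set", {
  set.seed(77)
  for (rep in 1:20) {
    p <- randomPanel(sample(3:6, 1), 4)
    kb <- newKnowledgeBase(p$registry, list(G1 = p$mat))
    i <- sample(nrow(p$mat), 1); j <- sample(nrow(p$mat), 1)
    full <- lapply(pairSignature(p$mat, i, j), function(s) {
      tab <- table(strsplit(s, "")[[1]])
      setNames(as.integer(tab), names(tab))
    })
    sub <- full[sample(names(full), 2)]
    big <- callDiplotypes(sub, kb, "G1", strict = FALSE)$pairs
    small <- callDiplotypes(full, kb, "G1", strict = FALSE)$pairs
    keyB <- vapply(big, paste, character(1), collapse = "/")
    keyS <- vapply(small, paste, character(1), collapse = "/")
    expect_true(all(keyS %in% keyB))
  }
})

test_that("indistinguishable haplotypes never get separated by a call", {
  reg <- data.frame(rsid = c("s1", "s2"), gene = "X",
                    orientation = "forward", alleles = "A,G", assays = "",
                    seeAlso = "")
  m <- matrix(c("A", "G", "A", "G", "G", "A"), 3, 2, byrow = TRUE,
              dimnames = list(c("X*a", "X*b", "X*c"), c("s1", "s2")))
  kb <- newKnowledgeBase(reg, list(X = m))
  prof <- list(s1 = c(A = 2L), s2 = c(G = 2L))
  res <- callDiplotypes(prof, kb, "X")
  key <- vapply(res$pairs, paste, character(1), collapse = "/")
  ## all three combinations of the two identical haplotypes are consistent
  expect_setequal(key, c("X*a/X*a", "X*a/X*b", "X*b/X*b"))
})

test_that("haplotype support closes counts upward through the taxonomy", {
  tax <- data.frame(child = "TPMT*3A", parent = "TPMT*3", gene = "TPMT")
  s <- haplotypeSupport(list(c("TPMT*1", "TPMT*3A")), tax)
  expect_identical(s, c("TPMT*1" = 1L, "TPMT*3" = 1L, "TPMT*3A" = 1L))
  s2 <- haplotypeSupport(list(c("CYP2C9*1", "CYP2C9*1")))
  expect_identical(s2, c("CYP2C9*1" = 2L))
  ## two *3 subtypes add up to two copies of *3
  s3 <- haplotypeSupport(list(c("TPMT*3A", "TPMT*3A")), tax)
  expect_identical(s3[["TPMT*3"]], 2L)
})

test_that("rule expressions evaluate with the published TPMT semantics", {
  kb <- demoKnowledgeBase()
  r27 <- kbRules(kb, "cds")[["rule_27"]]$expression
  r35 <- kbRules(kb, "cds")[["rule_35"]]$expression
  tax <- kbTaxonomy(kb)
  sup <- haplotypeSupport(list(c("TPMT*1", "TPMT*3A")), tax)
  expect_true(evaluateRuleExpression(r27, sup))
  expect_true(evaluateRuleExpression(r35, sup))  # via *3A below *3
  supHom <- haplotypeSupport(list(c("TPMT*1", "TPMT*1")), tax)
  expect_false(evaluateRuleExpression(r27, supHom))
  ## warfarin: haplotype conjuncts plus homozygous-T variant atom
  rw <- kbRules(kb, "cds")[["rule_warfarin_fda"]]$expression
  supW <- haplotypeSupport(list(c("CYP2C9*1", "CYP2C9*3")))
  expect_true(evaluateRuleExpression(rw, supW,
                                     profile = list(rs9923231 = c(T = 2L))))
  expect_false(evaluateRuleExpression(rw, supW,
                                      profile = list(rs9923231 = c(C = 1L,
                                                                   T = 1L))))
})

test_that("exactly-2 haplotype atoms fire on homozygotes only", {
  e <- hapAtom("X*1", 2L, "exactly")
  hom <- c("X*1" = 2L)
  expect_true(evaluateRuleExpression(e, hom, exactCounts = list(hom)))
  ## ambiguous support reaching 2 without a homozygous diplotype
  het1 <- c("X*1" = 1L, "X*2" = 1L)
  expect_false(evaluateRuleExpression(e, c("X*1" = 2L),
                                      exactCounts = list(het1, het1)))
})

test_that("realizing the fixture patient triggers exactly the warfarin rule", {
  kb <- demoKnowledgeBase()
  res <- realizePatient(demoPatient(kb), kb)
  expect_identical(diplotypes(res, "CYP2C9"),
                   list(c("CYP2C9*1", "CYP2C9*3")))
  expect_false(unname(res@ambiguity["CYP2C9"]))
  rec <- recommendations(res)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$rule, "rule_warfarin_fda")
  expect_match(rec$message, "^0.5-2 mg warfarin per day")
  expect_identical(res@stats$matched_snps, 5L)
})

test_that("an empty genotype yields all-genes no-call and no messages", {
  kb <- demoKnowledgeBase()
  res <- realizePatient(patientGenotype("empty"), kb)
  expect_identical(sort(names(noCallReasons(res))), c("CYP2C9", "TPMT"))
  expect_identical(nrow(recommendations(res)), 0L)
  expect_length(phenotypes(res), 0L)
})

test_that("recommendations are ordered by importance then rule id", {
  kb <- cyp2c9Kb()
  mk <- function(id, imp) list(id = id, drug = "warfarin", source = "s",
                               importance = imp, message = paste("msg", id),
                               expression = hapAtom("CYP2C9*1"))
  kb@cdsRules <- list(mk("b_minor", "minor_deviation"),
                      mk("a_std", "standard"),
                      mk("c_major", "important_modification"),
                      mk("a_major", "important_modification"))
  names(kb@cdsRules) <- vapply(kb@cdsRules, `[[`, character(1), "id")
  p <- patientGenotype("p", list(
    rs1057910 = c("A", "A"), rs1057911 = c("A", "A"),
    rs1799853 = c("C", "C"), rs2256871 = c("A", "A")))
  rec <- recommendations(realizePatient(p, kb))
  expect_identical(rec$rule, c("a_major", "c_major", "b_minor", "a_std"))
})

test_that("simulated patients with full coverage recover their true diplotype", {
  cfg <- simulationConfig(seed = 31, genes = 2, snpsPerGene = 4,
                          haplotypesPerGene = 5, missingness = 0,
                          nPatients = 15)
  panel <- simulatePanel(cfg)
  dir <- withr::local_tempdir()
  sim <- simulatePatients(panel, cfg, dir)
  bp <- batchProcess(dir, panel$kb)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    dd <- diplotypes(bp$results[[tr$patientId]], tr$gene)
    keys <- vapply(dd, paste, character(1), collapse = "/")
    expect_true(paste(tr$hap1, tr$hap2, sep = "/") %in% keys)
  }
})

test_that("inference results serialize to the documented JSON shape", {
  kb <- demoKnowledgeBase()
  js <- jsonlite::fromJSON(inferenceResultToJson(realizePatient(
    demoPatient(kb), kb)))
  expect_identical(js$patient, "demo")
  expect_identical(js$diplotypes$CYP2C9, "CYP2C9*1/CYP2C9*3")
  expect_false(js$ambiguity$CYP2C9)
  expect_identical(js$stats$matched_snps, 5L)
  expect_identical(js$recommendations$rule, "rule_warfarin_fda")
})
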