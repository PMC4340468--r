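## Independent oracles and fixture builders used across the suite. These
## deliberately re-derive results through different code paths (string
## signatures, explicit product enumeration) than the package internals.

## base-R reverse complement, independent of Biostrings
oracleComplement <- function(x) {
  vapply(x, function(a) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", a), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## random distinct haplotype panel: allele matrix + matching registry rows.
## nHaps is capped at the number of distinct biallelic patterns (2^nSnps).
randomPanel <- function(nHaps, nSnps, gene = "G1", prefix = 1L) {
  nHaps <- min(nHaps, 2^nSnps)
  rsids <- sprintf("rs%07d", prefix * 100L + seq_len(nSnps))
  alleles <- t(vapply(seq_len(nSnps), function(i)
    sample(c("A", "C", "G", "T"), 2L), character(2)))
  patterns <- sample(2^nSnps, nHaps) - 1L
  m <- matrix(NA_character_, nHaps, nSnps,
              dimnames = list(paste0(gene, "*", seq_len(nHaps)), rsids))
  for (i in seq_len(nHaps)) {
    bits <- as.integer(intToBits(patterns[i]))[seq_len(nSnps)]
    m[i, ] <- alleles[cbind(seq_len(nSnps), bits + 1L)]
  }
  reg <- data.frame(rsid = rsids, gene = gene, orientation = "forward",
                    alleles = paste(alleles[, 1], alleles[, 2], sep = ","),
                    assays = "", seeAlso = "", stringsAsFactors = FALSE)
  list(mat = m, registry = reg)
}

## genotype signature of a haplotype pair: sorted-genotype string per rsID
pairSignature <- function(mat, i, j) {
  vapply(colnames(mat), function(r)
    paste(sort(c(mat[i, r], mat[j, r])), collapse = ""), character(1))
}

## brute-force diplotype caller over signature strings (oracle for
## callDiplotypes): profile given as named list of count vectors
oracleCallDiplotypes <- function(mat, profile) {
  sig <- vapply(colnames(mat), function(r)
    paste(sort(rep(names(profile[[r]]), profile[[r]])), collapse = ""),
    character(1))
  out <- list()
  n <- nrow(mat)
  for (i in seq_len(n))
    for (j in i:n)
      if (identical(unname(pairSignature(mat, i, j)), unname(sig)))
        out[[length(out) + 1L]] <- sort(rownames(mat)[c(i, j)])
  out[order(vapply(out, paste, character(1), collapse = "/"))]
}

## independent expression evaluator over an explicit diplotype assignment
## (one haplotype pair per gene); taxonomy as child->parent named vector
oracleEval <- function(expr, assign, kbMats, parent) {
  closure <- function(h) {
    out <- h
    while (h %in% names(parent)) { h <- parent[[h]]; out <- c(out, h) }
    out
  }
  counts <- table(unlist(lapply(unlist(assign), closure)))
  geno <- list()
  for (g in names(assign)) {
    m <- kbMats[[g]]
    for (r in colnames(m))
      geno[[r]] <- sort(c(m[assign[[g]][1], r], m[assign[[g]][2], r]))
  }
  ev <- function(e) {
    switch(e$kind,
      and = all(vapply(e$children, ev, logical(1))),
      or = length(e$children) > 0 && any(vapply(e$children, ev, logical(1))),
      hap = {
        k <- if (e$name %in% names(counts)) counts[[e$name]] else 0L
        if (e$mode == "at_least") k >= e$n else k == e$n
      },
      snp = {
        k <- if (!is.null(geno[[e$rsid]])) sum(geno[[e$rsid]] == e$allele)
        else 0L
        if (e$mode == "at_least") k >= e$n else
          (!is.null(geno[[e$rsid]]) && k == e$n)
      },
      stop("unexpected atom in oracle"))
  }
  ev(expr)
}

## exhaustive product-space relation oracle for compareRules
oracleRelation <- function(exprA, exprB, kbMats, parent) {
  genes <- names(kbMats)
  pairsOf <- function(g) {
    h <- rownames(kbMats[[g]])
    out <- list()
    for (i in seq_along(h)) for (j in i:length(h))
      out[[length(out) + 1L]] <- c(h[i], h[j])
    out
  }
  doms <- lapply(genes, pairsOf)
  names(doms) <- genes
  grid <- expand.grid(lapply(doms, seq_along))
  inA <- logical(nrow(grid)); inB <- logical(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    assign <- lapply(genes, function(g) doms[[g]][[grid[k, g]]])
    names(assign) <- genes
    inA[k] <- oracleEval(exprA, assign, kbMats, parent)
    inB[k] <- oracleEval(exprB, assign, kbMats, parent)
  }
  if (!any(inA) && !any(inB)) return("equivalent")
  if (!any(inA)) return("A_subsumed_by_B")
  if (!any(inB)) return("B_subsumed_by_A")
  AsubB <- all(inB[inA]); BsubA <- all(inA[inB])
  if (AsubB && BsubA) "equivalent"
  else if (AsubB) "A_subsumed_by_B"
  else if (BsubA) "B_subsumed_by_A"
  else if (any(inA & inB)) "overlapping"
  else "disjoint"
}

## random monotone expression over the haplotypes of the given matrices
randomExpr <- function(kbMats, depth = 2L) {
  atom <- function() {
    g <- sample(names(kbMats), 1L)
    h <- sample(rownames(kbMats[[g]]), 1L)
    n <- sample(1:2, 1L)
    mode <- sample(c("at_least", "exactly"), 1L, prob = c(0.8, 0.2))
    list(kind = "hap", name = h, n = n, mode = mode)
  }
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.4) return(atom())
    kids <- lapply(seq_len(sample(2:3, 1L)), function(i) build(d - 1L))
    list(kind = sample(c("and", "or"), 1L), children = kids)
  }
  build(depth)
}

## the 7-member TPMT-style panel of the worked examples: *3 concrete,
## *3A/*3B/*3C taxonomy children, one defining SNP per non-reference allele
tpmt7Panel <- function() {
  names <- c("TPMT*1", "TPMT*2", "TPMT*3", "TPMT*3A", "TPMT*3B", "TPMT*3C",
             "TPMT*4")
  rsids <- sprintf("rs7%06d", 1:6)
  m <- matrix("G", 7, 6, dimnames = list(names, rsids))
  for (k in 2:7) m[k, k - 1L] <- "A"
  reg <- data.frame(rsid = rsids, gene = "TPMT", orientation = "forward",
                    alleles = "G,A", assays = "", seeAlso = "",
                    stringsAsFactors = FALSE)
  tax <- data.frame(child = c("TPMT*3A", "TPMT*3B", "TPMT*3C"),
                    parent = "TPMT*3", gene = "TPMT",
                    stringsAsFactors = FALSE)
  newKnowledgeBase(reg, list(TPMT = m), tax)
}

## rule-27/35-style expressions over a panel (haplotype atoms only)
hapAtom <- function(name, n = 1L, mode = "at_least")
  list(kind = "hap", name = name, n = n, mode = mode)

andExpr <- function(...) list(kind = "and", children = list(...))
orExpr <- function(xs) list(kind = "or", children = xs)
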