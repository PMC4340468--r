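## Synthetic-data generation with ground truth, the batch pipeline over
## profile collections, and the bundled demonstration knowledge base.

#' Bundled demonstration knowledge base
#'
#' Loads the knowledge-base archive shipped under
#' `extdata/demo_kb`: the printed CYP2C9 star-allele excerpt (*1, *3 over
#' rs1057910, rs1057911, rs1799853, rs2256871), the VKORC1 rs9923231
#' registry entry, the warfarin starting-dose CDS rule, the two
#' azathioprine rules (CPIC and Dutch Pharmacogenomics Working Group) over
#' a synthetic TPMT panel (*1, *2, *3A, *3B, *3C, *4-*18, one synthetic
#' defining SNP each, rs90000001-rs90000019) with the *3A/*3B/*3C -> *3
#' taxonomy, and a TPMT intermediate-metabolizer phenotype rule.
#'
#' @param tpmt include the TPMT panel and azathioprine/phenotype rules
#'   (default TRUE); with `FALSE` only the CYP2C9/VKORC1 warfarin content
#'   remains.
#' @return a [PgxKnowledgeBase-class].
#' @examples
#' demoKnowledgeBase()
#' @export
demoKnowledgeBase <- function(tpmt = TRUE) {
  kb <- loadKnowledgeBase(system.file("extdata", "demo_kb",
                                      package = "pgxCDS"))
  if (!tpmt) {
    kb@haplotypes[["TPMT"]] <- NULL
    kb@snps <- kb@snps[kb@snps$gene != "TPMT", , drop = FALSE]
    kb@taxonomy <- kb@taxonomy[kb@taxonomy$gene != "TPMT", , drop = FALSE]
    kb@cdsRules <- Filter(function(r) r$drug != "azathioprine", kb@cdsRules)
    kb@phenotypeRules <- Filter(function(r)
      !grepl("^TPMT", r$phenotype_label), kb@phenotypeRules)
    validObject(kb)
  }
  kb
}

#' Simulation configuration
#'
#' Defaults describe a small but realistic array-genotyping study: a few
#' pharmacogene panels, a common reference star allele at frequency 0.7
#' with the remainder spread evenly (most pharmacogenes have one dominant
#' *1 allele), and a 2% per-SNP no-call rate typical of array assays.
#'
#' @param seed integer driving all randomness (panel and patients).
#' @param genes number of genes.
#' @param snpsPerGene panel size per gene.
#' @param haplotypesPerGene star alleles per gene (must not exceed
#'   2^snpsPerGene, the number of distinct biallelic patterns).
#' @param haplotypeFrequencies optional per-gene list of probability
#'   vectors (must sum to 1); default: 0.7 for the first allele, the rest
#'   uniform.
#' @param missingness per-SNP probability of a no-call ("--") in emitted
#'   profiles.
#' @param nPatients number of profiles to draw.
#' @param outputFormat "23andme" or "vcf".
#' @return a list of class `pgxSimConfig`.
#' @export
simulationConfig <- function(seed = 1L, genes = 3L, snpsPerGene = 4L,
                             haplotypesPerGene = 6L,
                             haplotypeFrequencies = NULL,
                             missingness = 0.02, nPatients = 100L,
                             outputFormat = c("23andme", "vcf")) {
  outputFormat <- match.arg(outputFormat)
  stopifnot(missingness >= 0, missingness <= 1, genes >= 1L,
            snpsPerGene >= 1L, haplotypesPerGene >= 1L, nPatients >= 0L)
  if (!is.null(haplotypeFrequencies)) {
    for (f in haplotypeFrequencies)
      if (abs(sum(f) - 1) > 1e-8)
        stop("haplotype frequencies must sum to 1")
  }
  structure(list(seed = as.integer(seed), genes = as.integer(genes),
                 snpsPerGene = as.integer(snpsPerGene),
                 haplotypesPerGene = as.integer(haplotypesPerGene),
                 haplotypeFrequencies = haplotypeFrequencies,
                 missingness = missingness,
                 nPatients = as.integer(nPatients),
                 outputFormat = outputFormat),
            class = "pgxSimConfig")
}

#' Simulate a distinguishable star-allele panel
#'
#' Draws, per gene, `haplotypesPerGene` pairwise-distinct biallelic allele
#' maps over `snpsPerGene` SNPs (distinct binary patterns, so the panel is
#' guaranteed to pass [checkDistinguishability()]), registry entries with
#' random strand orientations, and a haplotype frequency vector.
#'
#' @param config a [simulationConfig()].
#' @return list: `kb` (a [PgxKnowledgeBase-class] fragment with registry
#'   and haplotype tables, no rules) and `frequencies` (per-gene named
#'   probability vectors).
#' @export
simulatePanel <- function(config) {
  stopifnot(inherits(config, "pgxSimConfig"))
  if (config$haplotypesPerGene > 2^config$snpsPerGene)
    stop("infeasible: cannot draw ", config$haplotypesPerGene,
         " distinct haplotypes from ", 2^config$snpsPerGene,
         " biallelic patterns")
  set.seed(config$seed)
  snps <- NULL; haps <- list(); freqs <- list()
  for (gi in seq_len(config$genes)) {
    g <- sprintf("GENE%02d", gi)
    rsids <- sprintf("rs%d", 10000000L + gi * 1000L +
                       seq_len(config$snpsPerGene))
    alleles <- t(vapply(rsids, function(r)
      sample(c("A", "C", "G", "T"), 2L), character(2)))
    orient <- sample(c("forward", "reverse"), length(rsids), replace = TRUE)
    snps <- rbind(snps, data.frame(
      rsid = rsids, gene = g, orientation = orient,
      alleles = paste(alleles[, 1], alleles[, 2], sep = ","),
      assays = "simulated_array", seeAlso = "", stringsAsFactors = FALSE))
    ## distinct binary patterns -> allele maps
    patterns <- sample(2^config$snpsPerGene, config$haplotypesPerGene) - 1L
    m <- matrix("", nrow = config$haplotypesPerGene,
                ncol = config$snpsPerGene,
                dimnames = list(sprintf("%s*%d", g,
                                        seq_len(config$haplotypesPerGene)),
                                rsids))
    for (hi in seq_along(patterns)) {
      bits <- as.integer(intToBits(patterns[hi]))[seq_len(config$snpsPerGene)]
      m[hi, ] <- alleles[cbind(seq_len(config$snpsPerGene), bits + 1L)]
    }
    haps[[g]] <- m
    f <- config$haplotypeFrequencies[[g]]
    if (is.null(f)) {
      k <- config$haplotypesPerGene
      f <- if (k == 1L) 1 else c(0.7, rep(0.3 / (k - 1L), k - 1L))
    }
    freqs[[g]] <- stats::setNames(f, rownames(m))
  }
  list(kb = newKnowledgeBase(snps, haps,
                             metadata = list(source = "simulated")),
       frequencies = freqs)
}

## write one simulated patient's profile; calls are in registry (defining)
## orientation, files carry assay (forward-genome) orientation
.writeProfile23andme <- function(path, registry, calls) {
  lines <- c("# simulated 23andMe-format profile",
             "# rsid\tchromosome\tposition\tgenotype")
  for (k in seq_along(calls)) {
    r <- names(calls)[k]
    gt <- calls[[k]]
    if (!identical(gt, "--")) {
      i <- match(r, registry$rsid)
      al <- strsplit(gt, "", fixed = TRUE)[[1]]
      if (registry$orientation[i] == "reverse")
        al <- complementAllele(al)
      gt <- paste(al, collapse = "")
    }
    lines <- c(lines, paste(r, "1", k, gt, sep = "\t"))
  }
  writeLines(lines, path)
}

.writeProfileVcf <- function(path, registry, calls, sample = "SIM") {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    sample))
  for (k in seq_along(calls)) {
    r <- names(calls)[k]
    i <- match(r, registry$rsid)
    al <- .splitField(registry$alleles[i])[[1]]
    file_al <- if (registry$orientation[i] == "reverse")
      complementAllele(al) else al
    gt <- calls[[k]]
    gtField <- if (identical(gt, "--")) "./." else {
      pair <- strsplit(gt, "", fixed = TRUE)[[1]]
      if (registry$orientation[i] == "reverse")
        pair <- complementAllele(pair)
      idx <- match(pair, file_al) - 1L
      paste(sort(idx), collapse = "/")
    }
    lines <- c(lines, paste("1", k, r, file_al[1],
                            paste(file_al[-1], collapse = ","),
                            ".", "PASS", ".", "GT", gtField, sep = "\t"))
  }
  writeLines(lines, path)
}

#' Simulate patient profiles with ground truth
#'
#' Per patient and gene, two haplotypes are drawn independently from the
#' gene's frequency vector (Hardy-Weinberg sampling); each panel SNP's
#' genotype is the unordered pair of the two haplotypes' alleles, dropped
#' to a no-call with probability `missingness`. Profiles are written as
#' 23andMe-format text or minimal VCF v4.2 (reverse-orientation registry
#' SNPs are complement-flipped on output, so reading the files back with
#' the package's readers restores the defining-orientation calls).
#'
#' @param panel result of [simulatePanel()].
#' @param config the same [simulationConfig()].
#' @param dir output directory for the profile files (created if needed).
#' @return list: `files` (paths), `truth` (data.frame patientId, gene,
#'   hap1, hap2 with hap1 <= hap2), `dropped` (data.frame patientId, rsid
#'   of masked calls).
#' @export
simulatePatients <- function(panel, config, dir) {
  stopifnot(inherits(config, "pgxSimConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)
  kb <- panel$kb
  reg <- kb@snps
  genes <- names(kb@haplotypes)
  files <- character(0)
  truth <- NULL
  dropped <- data.frame(patientId = character(0), rsid = character(0),
                        stringsAsFactors = FALSE)
  for (p in seq_len(config$nPatients)) {
    pid <- sprintf("sim_%04d", p)
    calls <- list()
    for (g in genes) {
      m <- kb@haplotypes[[g]]
      f <- panel$frequencies[[g]]
      pick <- sample(rownames(m), 2L, replace = TRUE, prob = f)
      hp <- sort(pick)
      truth <- rbind(truth, data.frame(patientId = pid, gene = g,
                                       hap1 = hp[1], hap2 = hp[2],
                                       stringsAsFactors = FALSE))
      for (r in colnames(m)) {
        gt <- paste(sort(c(m[pick[1], r], m[pick[2], r])), collapse = "")
        if (stats::runif(1) < config$missingness) {
          gt <- "--"
          dropped <- rbind(dropped, data.frame(patientId = pid, rsid = r,
                                               stringsAsFactors = FALSE))
        }
        calls[[r]] <- gt
      }
    }
    ext <- if (config$outputFormat == "vcf") ".vcf" else ".txt"
    path <- file.path(dir, paste0(pid, ext))
    if (config$outputFormat == "vcf")
      .writeProfileVcf(path, reg, calls, sample = pid)
    else
      .writeProfile23andme(path, reg, calls)
    files <- c(files, path)
  }
  list(files = files, truth = truth, dropped = dropped)
}

#' Batch-process a directory of genetic profiles
#'
#' Loads every profile (".txt"/".tsv" as 23andMe format, ".vcf"/".vcf.gz"
#' as VCF), realizes each against the knowledge base, and aggregates
#' population statistics: mean matched registry SNPs per profile, mean
#' triggered CDS rules per profile, per-gene call/ambiguity/no-call rates
#' and a diplotype frequency table over unambiguous calls. Unreadable
#' profiles are logged, skipped and counted.
#'
#' @param dir directory of profile files.
#' @param kb a [PgxKnowledgeBase-class].
#' @param strict strict missing-data policy (see [callDiplotypes()]).
#' @return list: `results` (named list of [InferenceResult-class]),
#'   `aggregate` (statistics list), `failures` (file names that failed to
#'   parse).
#' @export
batchProcess <- function(dir, kb, strict = TRUE) {
  files <- sort(list.files(dir, pattern = "\\.(txt|tsv|vcf|vcf\\.gz)$",
                           full.names = TRUE))
  results <- list(); failures <- character(0)
  for (f in files) {
    res <- tryCatch({
      pid <- sub("\\.(txt|tsv|vcf|vcf\\.gz)$", "", basename(f))
      gt <- if (grepl("\\.vcf(\\.gz)?$", f))
        readPatientVcf(f, kb@snps, patientId = pid)
      else
        suppressMessages(read23andme(f, kb@snps, patientId = pid))
      realizePatient(gt, kb, strict = strict)
    }, error = function(e) {
      message("skipping unreadable profile ", basename(f), ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- c(failures, basename(f))
    else results[[patientId(res)]] <- res
  }
  n <- length(results)
  genes <- sort(names(kb@haplotypes))
  perGene <- data.frame(gene = genes, call_rate = NA_real_,
                        ambiguity_rate = NA_real_, no_call_rate = NA_real_,
                        stringsAsFactors = FALSE)
  dipCounts <- integer(0)
  if (n) {
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      called <- vapply(results, function(r)
        length(r@diplotypes[[g]]) > 0L, logical(1))
      ambig <- vapply(results, function(r)
        isTRUE(unname(r@ambiguity[g])), logical(1))
      perGene$call_rate[gi] <- mean(called)
      perGene$no_call_rate[gi] <- mean(!called)
      perGene$ambiguity_rate[gi] <- mean(ambig)
      for (r in results[called & !ambig]) {
        lab <- paste(g, paste(r@diplotypes[[g]][[1]], collapse = "/"))
        dipCounts[lab] <- sum(dipCounts[lab], 1L, na.rm = TRUE)
      }
    }
  }
  aggregate <- list(
    n_profiles = n,
    n_failures = length(failures),
    mean_matched_snps = if (n) mean(vapply(results, function(r)
      r@stats$matched_snps, numeric(1))) else NA_real_,
    mean_triggered_rules = if (n) mean(vapply(results, function(r)
      r@stats$triggered_rules, numeric(1))) else NA_real_,
    per_gene = perGene,
    diplotype_frequencies = if (length(dipCounts))
      sort(dipCounts, decreasing = TRUE) else dipCounts)
  list(results = results, aggregate = aggregate, failures = failures)
}
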