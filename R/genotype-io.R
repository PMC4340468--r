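## Patient genotype input: 23andMe raw files and VCF, strand normalization.

.INDEL_TOKENS <- c("INS", "DEL")

#' Watson-Crick complement of an allele string
#'
#' Base-wise complement, with multi-base strings reversed (i.e. the
#' reverse complement). Indel tokens ("INS"/"DEL") pass through unchanged.
#' Used to bring assay output reported on the opposite strand into the
#' registry's defining orientation.
#'
#' @param x character vector of allele strings (A/C/G/T or indel tokens).
#' @return character vector of the same length.
#' @examples
#' complementAllele(c("G", "AT", "INS"))
#' @export
complementAllele <- function(x) {
  vapply(x, function(a) {
    a <- toupper(a)
    if (a %in% .INDEL_TOKENS) return(a)
    if (!grepl("^[ACGT]+$", a))
      stop("cannot complement allele string: ", a)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  }, character(1), USE.NAMES = FALSE)
}

.newGenotype <- function(patientId, calls, missing) {
  if (length(calls)) calls <- calls[order(names(calls))]
  new("PatientGenotype", patientId = patientId, calls = calls,
      missing = sort(unique(missing)))
}

## Normalize one diploid call to the registry's defining orientation and
## canonical (sorted) order.
.normalizeCall <- function(alleles, rsid, registry) {
  i <- match(rsid, registry$rsid)
  if (!is.na(i) && registry$orientation[i] == "reverse")
    alleles <- complementAllele(alleles)
  sort(alleles)
}

#' Read a 23andMe raw-data file
#'
#' Four tab-separated columns (`rsid`, `chromosome`, `position`,
#' `genotype`); lines starting with `#` are comments. Two-letter genotypes
#' become unordered allele pairs, `--` marks the rsID as a no-call, and
#' alleles of SNPs registered as reverse-orientation are complement-flipped
#' so stored calls are in the registry's defining orientation. Identifiers
#' absent from the registry (including 23andMe-internal "i"-numbers) are
#' skipped; insertion/deletion genotypes ("II", "DD", "DI") map to
#' "INS"/"DEL" tokens; single-letter (hemizygous) genotypes are recorded as
#' missing, since all downstream definitions are strictly diploid.
#'
#' @param x file path or character vector of lines.
#' @param registry SNP registry data.frame (see [readSnpRegistry()]).
#' @param patientId identifier stored on the result (defaults to the file
#'   name).
#' @return a [PatientGenotype-class].
#' @export
read23andme <- function(x, registry, patientId = NULL) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    if (is.null(patientId)) patientId <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- as.character(x)
    if (is.null(patientId)) patientId <- "patient"
  }
  calls <- list(); missing <- character(0)
  skipped <- 0L
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (!nzchar(trimws(ln)) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L)
      stop(sprintf("malformed 23andMe line %d: expected 4 columns, got %d",
                   k, length(f)))
    rsid <- f[1]; gt <- toupper(trimws(f[4]))
    if (!rsid %in% registry$rsid) { skipped <- skipped + 1L; next }
    if (gt == "--") { missing <- c(missing, rsid); next }
    if (nchar(gt) == 1L) {  # hemizygous (X/Y/MT): out of diploid scope
      missing <- c(missing, rsid); next
    }
    if (nchar(gt) != 2L)
      stop(sprintf("malformed genotype '%s' at line %d", gt, k))
    al <- strsplit(gt, "", fixed = TRUE)[[1]]
    if (any(al %in% c("I", "D"))) {
      al <- ifelse(al == "I", "INS", ifelse(al == "D", "DEL", al))
      message("line ", k, ": indel genotype mapped to tokens: ", gt)
    }
    calls[[rsid]] <- .normalizeCall(al, rsid, registry)
  }
  if (skipped)
    message(skipped, " line(s) with identifiers not in the registry skipped")
  .newGenotype(patientId, calls, missing)
}

#' Read a patient genotype from a VCF file
#'
#' Records are matched to the registry by the VCF ID field (the knowledge
#' base is rsID-keyed); GT indices are resolved against REF/ALT to allele
#' strings, `./.` becomes a no-call, and both phased and unphased
#' separators are accepted — phase is discarded because calls are unordered
#' pairs. Alleles of reverse-orientation registry SNPs are
#' complement-flipped as in [read23andme()].
#'
#' @param path VCF v4.x file (plain or gzipped).
#' @param registry SNP registry data.frame.
#' @param sample sample name; required when the file has more than one
#'   sample column.
#' @param patientId identifier stored on the result (defaults to the sample
#'   name).
#' @return a [PatientGenotype-class].
#' @export
readPatientVcf <- function(path, registry, sample = NULL, patientId = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT genotype field")
  samples <- colnames(gt)
  if (length(samples) == 0L) stop("VCF has no sample column")
  if (is.null(sample)) {
    if (length(samples) > 1L)
      stop("multi-sample VCF: select one of: ",
           paste(samples, collapse = ", "))
    sample <- samples[1]
  } else if (!sample %in% samples) {
    stop("sample not in VCF: ", sample)
  }
  if (is.null(patientId)) patientId <- sample
  ids <- rownames(gt)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  calls <- list(); missing <- character(0)
  for (i in seq_along(ids)) {
    rsid <- ids[i]
    if (!rsid %in% registry$rsid) next
    g <- gt[i, sample]
    if (is.na(g) || g %in% c(".", "./.", ".|.")) {
      missing <- c(missing, rsid); next
    }
    idx <- strsplit(g, "[/|]")[[1]]
    if (length(idx) != 2L || any(idx == ".")) {
      missing <- c(missing, rsid); next
    }
    idx <- as.integer(idx)
    allAlleles <- c(refs[i], as.character(alts[[i]]))
    if (any(idx < 0L) || any(idx + 1L > length(allAlleles)))
      stop(sprintf("GT index out of range of REF/ALT at %s: %s", rsid, g))
    al <- toupper(allAlleles[idx + 1L])
    calls[[rsid]] <- .normalizeCall(al, rsid, registry)
  }
  .newGenotype(patientId, calls, missing)
}

#' Construct a patient genotype directly
#'
#' Convenience constructor for fixtures and simulation: calls are
#' normalized to sorted pairs; they are assumed to already be in the
#' registry's defining orientation.
#'
#' @param patientId identifier.
#' @param calls named list of length-2 character vectors (rsID -> allele
#'   pair), or a named character vector of two-letter genotypes.
#' @param missing character vector of no-call rsIDs.
#' @return a [PatientGenotype-class].
#' @examples
#' patientGenotype("p1", list(rs1057910 = c("A", "C")))
#' @export
patientGenotype <- function(patientId, calls = list(),
                            missing = character(0)) {
  if (is.character(calls))
    calls <- lapply(calls, function(g) strsplit(g, "", fixed = TRUE)[[1]])
  calls <- lapply(calls, function(p) sort(toupper(p)))
  .newGenotype(patientId, calls, missing)
}

#' Dump a patient genotype as JSON (debugging aid)
#'
#' @param genotype a [PatientGenotype-class].
#' @return a JSON string.
#' @export
genotypeToJson <- function(genotype) {
  jsonlite::toJSON(list(
    patient = genotype@patientId,
    calls = lapply(genotype@calls, identity),
    missing = genotype@missing), auto_unbox = TRUE)
}
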