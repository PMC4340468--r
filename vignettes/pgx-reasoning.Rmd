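---
title: "Star-allele calling and rule-population reasoning with pgxCDS"
author: "pgxCDS authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-allele calling and rule-population reasoning with pgxCDS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxCDS)
```

## The problem

Pharmacogenes such as CYP2C9, TPMT or VKORC1 carry named haplotypes
("star alleles", e.g. `CYP2C9*3`) defined by the alleles they carry at a
small panel of SNPs. Clinical guidelines attach dosing recommendations to
genotype-defined patient populations ("a patient carrying TPMT\*1 and one
non-functional TPMT allele should start azathioprine at a reduced dose").
Connecting an individual's raw, unphased genotype to these
recommendations requires three inferences:

1. **Zygosity**: each unordered allele pair becomes per-allele copy
   counts summing to two.
2. **Diplotype calling**: which unordered pairs of star alleles are
   consistent with the observed counts at every panel SNP.
3. **Rule matching**: which phenotype-inference and clinical decision
   support (CDS) rules are satisfied by the called alleles.

pgxCDS implements this chain with explicit, enumerable semantics — the
cardinality conditions that define a star-allele carrier ("has exactly 2
copies of allele T at rs9923231") are evaluated directly over finite
diplotype models, which also makes the knowledge base auditable: the same
machinery decides whether a rule is satisfiable at all, and whether two
rules target nested or overlapping patient populations.

## The knowledge-base model

A `PgxKnowledgeBase` bundles:

* a **SNP registry** (rsID, gene, strand orientation on the reference
  genome, known alleles, covering assays, optional external URI);
* per-gene **haplotype tables**: rows are star alleles, columns are
  rsIDs, cells are alleles. Tables are compiled from PharmGKB-style TSV
  where the first data row is the reference haplotype and blank cells
  inherit its allele, so every compiled definition is total over the
  panel;
* a **star-allele taxonomy** (e.g. TPMT\*3A, \*3B, \*3C below the broader
  TPMT\*3), used to close copy counts upward;
* **rules**: monotone boolean expressions (AND/OR, no negation) over
  haplotype atoms ("at least 1 / exactly 2 copies of TPMT\*3"), variant
  atoms ("exactly 2 copies of T at rs9923231") and phenotype labels, plus
  a message, source and importance level for CDS rules.

`validateKnowledgeBase()` runs the static audit: unresolved rsIDs and
alleles, dangling rule references, **indistinguishable haplotypes**
(identical allele maps — a real defect class in curated translation
tables, since no genotype can ever separate such a pair) and
**unsatisfiable rules** (no assignment of one diplotype per gene, at most
two copies in total, satisfies the expression — e.g. a conjunction
demanding three haplotype copies).

## Calling semantics and the missing-data policy

`callDiplotypes()` enumerates all n(n+1)/2 unordered pairs of a gene's
star alleles and keeps the pairs whose combined allele multiset equals
the observed zygosity at **every** panel SNP. Two deliberate choices:

* **Strict missing-data policy (default).** If any panel rsID is absent
  from the profile the gene is not called, and the missing rsIDs are the
  recorded no-call reason. Star-allele definitions deliberately include
  rare defining SNPs so that common alleles are not called by mistake;
  strictness trades coverage for precision. A `strict = FALSE` mode
  restricts the consistency check to the observed SNPs for exploring the
  opposite trade-off.
* **Union entailment under ambiguity.** Unphased heterozygous genotypes
  can be consistent with several pairs (cis/trans ambiguity). All
  consistent pairs are returned; haplotype support for rule evaluation is
  the union over consistent diplotypes (maximum taxonomy-closed copy
  count per name), which is the monotone entailment from the asserted
  memberships. The ambiguity is surfaced as a per-gene flag so callers
  can suppress recommendations when they prefer. "Exactly 2" haplotype
  atoms are evaluated per consistent diplotype (a homozygote must
  actually be among them), not against the union counts, which would
  otherwise conflate two heterozygous alternatives with homozygosity.
* A rule never fires on absent evidence: atoms over an uncalled gene are
  false.

Genotype input normalizes strand: alleles of SNPs registered as
reverse-orientation are complement-flipped on ingest, so calls are always
stored in the registry's defining orientation. 23andMe indel genotypes
("II", "DD", "DI") map to `INS`/`DEL` tokens; hemizygous single-letter
genotypes are treated as missing because every definition in the model is
strictly diploid.

## Rule populations: subsumption, overlap, conflict

The target population of a rule is the set of complete diplotype
assignments (one unordered star-allele pair per constrained gene) that
satisfy its expression. Because the grammar is monotone and per-gene
conjunctive in practice, `compareRules()` decomposes each expression by
gene (`decomposeByGene()`), enumerates each gene's satisfying set
(`satisfyingDiplotypes()`), and compares componentwise: populations are
products across genes, so containment holds iff it holds per component.
Cross-gene disjunctions, which do not decompose, fall back to bounded
enumeration of the full product space (default limit 10^6 models);
exceeding the limit yields an explicit `"undecided"`, never a silent
truncation. Phenotype atoms are first expanded into the disjunction of
their defining phenotype-rule expressions, which preserves the population
because the grammar has no negation.

For genes without a haplotype table (e.g. VKORC1, constrained only
through a variant atom) the enumeration domain is the genotype grid over
the referenced SNPs; when two rules constrain such a gene through
different SNP subsets, both are re-evaluated over the shared union-rsID
grid so the sets are comparable.

`auditRuleConflicts()` compares all unordered rule pairs and flags
**conflicts**: nested or equivalent populations for the same drug with
differing recommendation text — exactly the situation where two guideline
sources would give one patient different advice. Because the published
phrasing of "rules targeting equivalent or nested populations" is
ambiguous about whether both members of an equivalent pair are counted,
the summary reports both conventions (narrower-or-equal side only, and
either side).

## The demonstration knowledge base

`demoKnowledgeBase()` ships the worked examples as plain-text fixtures:
the CYP2C9 \*1/\*3 excerpt, the VKORC1 rs9923231 entry, the warfarin
starting-dose rule (requires \*1 and \*3 and homozygous T at rs9923231),
and the two azathioprine rules over a **synthetic** TPMT panel. The
synthetic panel gives each of the 20 concrete alleles (\*1, \*2, \*3A,
\*3B, \*3C, \*4–\*18) one defining SNP (`rs90000001`–`rs90000019`,
synthetic identifiers); \*3 is kept abstract, existing only as the
taxonomy parent of \*3A/\*3B/\*3C. That choice is what makes the
azathioprine comparison non-trivial: the CPIC rule names the \*3
subtypes, the Dutch rule names \*3 itself, and the containment of the
CPIC population in the Dutch one is derivable only through the taxonomy
closure.

```{r}
kb <- demoKnowledgeBase()
kb
compareRules("rule_27", "rule_35", kb)[c("relation", "conflict", "drug")]
```

## The simulator and what it does (not) show

`simulatePanel()`/`simulatePatients()` generate ground-truthed cohorts:
distinct biallelic allele maps per gene (so panels are
distinguishability-clean by construction), Hardy–Weinberg diplotype
sampling — two independent draws per gene from the haplotype frequency
vector, the minimal assumption for diploid sampling — and per-SNP
no-calls at a configurable rate. Defaults: 3 genes, 4 SNPs and 6 star
alleles per gene, reference-allele frequency 0.7 with the remainder
uniform (most pharmacogenes have one dominant allele), 2% missingness
(typical array no-call rates), 100 patients. All randomness flows from
the single seed; identical configurations give byte-identical output
files.

The simulator emulates the *format and calling structure* of consumer
array data, not its biology: there is no linkage disequilibrium, no
genotyping error (only missingness), no population structure, and
frequencies play no role in calling (the engine is purely consistency
based). Passing recovery tests therefore show that the caller inverts the
generative model exactly — the truth is always among the consistent
pairs at full coverage, and every unambiguous call is correct — but say
nothing about, e.g., robustness to assay error.

Validation problem sizes used by the test suite: 200 random panels (up
to 10 haplotypes, 2–4 SNPs) checked against a brute-force enumeration
oracle, 100 random rule pairs against a product-space truth table, and a
500-patient cohort across the missingness grid {0, 0.05, 0.2, 0.5}.

## OWL export

`exportOwl()` serializes the knowledge base as Turtle or OWL functional
syntax using qualified-cardinality class definitions: every unordered
pair of a gene's star alleles becomes a carrier class whose
`EquivalentTo` expression fixes the exact copy count of each panel
allele (1/1 for heterozygous positions, 2 otherwise), with `SubClassOf`
assertions of haplotype possession. Patients export as individuals with
one allele-possession assertion per copy. `countOntologyEntities()`
reads the counts back from any Turtle document by annotation signature
(classes bearing `rsid` are SNPs, their subclasses variants, classes
bearing `CDS_message` are CDS rules, ...); the property names are
configurable through `owlAnnotationMapping()` for documents using a
different vocabulary. The export targets structural interoperability —
round-tripping of entity counts and parseability by generic RDF tools —
not bit-identity with any particular released ontology file. The package
deliberately embeds no description-logic reasoner: the native
enumeration engine is authoritative, and only the monotone cardinality
fragment the rule grammar uses is supported.

## Numerical and representational choices

* Allele strings are uppercased on ingest; indel alleles are literal
  tokens (no left-normalization).
* Haplotype names are opaque strings; the "\*" convention is not parsed.
* Table cells with ambiguity codes ("A/C") are rejected, not
  interpreted.
* All outputs are deterministically ordered (lexicographic names/ids;
  recommendations by importance, then id), so runs are reproducible byte
  for byte.
* VCF records are matched by the ID field only, because the knowledge
  base is rsID-keyed; phase is discarded (pairs are unordered).

## Limitations

* No probabilistic or frequency-ranked calling; ambiguity is reported,
  not resolved.
* Haploid loci (X/Y/MT) are out of scope; such genotypes are recorded as
  missing.
* Population comparison assumes rules are per-gene conjunctions (true of
  the shipped rules); heavily cross-gene disjunctive rule sets fall back
  to bounded product enumeration and may come back "undecided".
* The Turtle reader covers the syntax subset the package emits plus
  ordinary prefixed documents; it is a counting aid, not a general RDF
  library.
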