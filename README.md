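# pgxCDS

Pharmacogenomic star-allele calling and clinical decision support (CDS)
rule reasoning for R.

Drug response varies with pharmacogene haplotypes ("star alleles": named
SNP-allele patterns such as CYP2C9\*3), and clinical guidelines attach
dosing recommendations to genotype-defined patient populations. pgxCDS is
a self-contained reasoning engine for that chain. It compiles
PharmGKB-style haplotype translation tables and structured rule files
into a knowledge base of cardinality-based logical definitions, then:

* reads unphased patient genotypes from **23andMe raw files or VCF**,
  normalizing strand orientation against a SNP registry;
* computes per-SNP **zygosity** and calls, per gene, every **diplotype**
  (unordered star-allele pair \{h1, h2\}) consistent with the data: for
  each panel SNP *r*, the multiset \{h1(r), h2(r)\} must equal the
  observed allele counts (which sum to 2). In strict mode a gene is not
  called while any panel SNP is missing — precision over coverage;
* evaluates monotone rule expressions over haplotype atoms ("has ≥ 1 /
  exactly 2 copies of TPMT\*3", closed upward through the star-allele
  taxonomy), variant atoms ("exactly 2 copies of T at rs9923231") and
  phenotype labels, and emits the matching CDS messages ordered by
  importance;
* **audits the knowledge base**: indistinguishable haplotype definitions
  (identical allele maps), unsatisfiable rules (no diplotype model under
  the diploid bound), and — by finite enumeration of each rule's
  satisfying diplotype sets — pairwise population **subsumption /
  equivalence / overlap**, flagging conflicts where nested populations
  receive different recommendations for the same drug;
* exports the knowledge base and patients as **OWL 2** (Turtle or
  functional syntax) using qualified-cardinality class definitions, and
  counts entities back out of Turtle documents by annotation signature;
* ships a **simulator** (distinct random panels, Hardy–Weinberg
  diplotype sampling, configurable missingness, ground-truth records)
  and a batch pipeline with population statistics.

Intended users: bioinformaticians and medical-informatics researchers
working with star-allele nomenclature, CPIC/DPWG-style guidelines, or
consumer-array genotype data.

## Worked example

The bundled knowledge base (`demoKnowledgeBase()`) contains the CYP2C9
\*1/\*3 table excerpt, the VKORC1 rs9923231 registry entry, a warfarin
starting-dose rule, and two azathioprine rules over a synthetic TPMT
panel with the \*3A/\*3B/\*3C → \*3 taxonomy.

```r
library(pgxCDS)
kb <- demoKnowledgeBase()
kb
#> PgxKnowledgeBase
#>   SNPs:       24
#>   genes:      3
#>   haplotypes: 22 over 2 gene panel(s)
#>   rules:      1 phenotype, 3 CDS

profile <- system.file("extdata", "patients", "demo_patient.txt",
                       package = "pgxCDS")
res <- realizePatient(read23andme(profile, kbSnps(kb)), kb)
res
#> InferenceResult for 'demo_patient.txt'
#>   CYP2C9: CYP2C9*1/CYP2C9*3
#>   TPMT: no call (missing rs90000001, rs90000002, ...)
#>   recommendations: 1
recommendations(res)$message
#> [1] "0.5-2 mg warfarin per day should be considered as a starting dose
#>      range for a patient with this genotype according to the warfarin
#>      drug label"
```

The patient is heterozygous A/C at rs1057910 and matches \*1 and \*3 as
the only consistent pair; being additionally homozygous T at rs9923231,
they satisfy the warfarin rule, whose message states the 0.5–2 mg/day
starting-dose range. TPMT is deliberately a no-call here: the profile
carries no TPMT data, and a rule never fires on absent evidence.

Comparing the two azathioprine rules shows the population audit at work —
the CPIC rule (naming the \*3 subtypes) targets a strict subset of the
Dutch working-group rule's population (naming \*3 itself), with a
different recommendation text:

```r
compareRules("rule_27", "rule_35", kb)[c("relation", "drug", "conflict")]
#> $relation
#> [1] "A_subsumed_by_B"
#> $drug
#> [1] "azathioprine"
#> $conflict
#> [1] TRUE
```

A thin command-line front end over these functions is installed as
`inst/scripts/pgxcds.R` (subcommands `compile`, `validate`, `call`,
`recommend`, `audit`, `export-owl`, `count-owl`, `simulate`, `batch`).

See `vignettes/pgx-reasoning.Rmd` for the model, the calling semantics
and their rationale, the simulator's assumptions, and limitations.

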