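# TrioTriage

Rule-based triage of trio whole-exome sequence variants and array-CGH
copy-number variants (CNVs) for essential autism spectrum disorder (ASD)
cohorts — the analytic layer that turns annotated calls into reportable
candidates and a cohort-level diagnostic yield. It is written for
genetics labs and methods researchers who have variant and CNV tables
with standard annotations (CADD, five-tier ACMG class, gnomAD counts,
trio inheritance) and want the prioritisation and yield statistics to be
reproducible, testable code instead of spreadsheet conventions.

## What it implements

**Sequence-variant cascade** — quality filter (coverage ≥ 10×, GQ ≥ 15,
gnomAD MAF < 5%), compound-heterozygote pairing from trio origins,
SFARI-panel gene filter (non-SFARI genes only for de novo,
compound-het, or truncating/frameshift/splicing variants with MAF < 1%),
then retention: synonymous and unpaired inherited-heterozygous variants
are excluded, and the rest kept while the gnomAD homozygote count
*nhom* ≤ 10 or absent — except LP + {VOUS, LP, P} compound-het pairs,
kept regardless of *nhom*.

**Classifier** (SFARI branch; severity order P > LP > VOUS > LB):

    P    : CADD ≥ 20  ∧  ACMG ∈ {P, LP}  ∧  nhom ≤ 1 (or absent)
    LP   : nhom ∈ [2, 10]  ∧  CADD ≥ 20  ∧  ACMG ∈ {P, LP, VOUS}
           ∧  gene has a neurodevelopmental function tag
    LB   : CADD < 15  ∧  ACMG = LB
    VOUS : otherwise

Non-SFARI genes cap at LP (criteria 1, 2 and the function tag).
Compound-het pairs combine by a fixed table ((P, P|LP) → P,
(LP, LP|VOUS) → LP, (VOUS, VOUS|LB) → VOUS, (LB, LP|P) → VOUS,
(LB, LB) → LB), and a proband whose sole retained candidate is a single
LP SFARI-gene variant is upgraded to P.

**CNV triage** — array QC gate (SD < 1.0, DLR spread < 0.3), exclusion
of benign/likely-benign calls and calls above 1% DGV frequency,
strand-aware per-gene rearrangement typing (DELETED / DUPLICATED /
INTRAGENIC / INT_START / INT_END via GenomicRanges), genes-of-interest
ranking and ISCN-style labels.

**Cohort statistics** — per-patient best findings by platform, tier
detection rates, CNV composition, recurrence and private-variant tables,
sex-stratified array positivity, gene families.

**Synthetic cohorts** — a seeded generator whose default plan encodes a
122-trio study composition with planted ground truth for every record,
so the entire pipeline is testable with no patient data.

## Worked example

```r
library(TrioTriage)

cohort <- simulateCohort(seed = 7)   # 122 synthetic trios
res <- runTriage(cohort)             # full cascade, both platforms
cohortSummary(res)
```

```
CohortSummary for 122 probands ( 104 M / 18 F, ratio 5.8 :1 )
  P       4 patients (3.3%)
  LP     34 patients (27.9%)
  VOUS   70 patients (57.4%)
  none   14 patients (11.5%)
  overall detection rate (P+LP): 31.1 %
```

Four probands carry a pathogenic best finding (3.3% of the cohort), 34 a
likely-pathogenic one (27.9%); adding the two tiers gives the overall
diagnostic yield of 31.1%. Drill down with the accessors:
`patientFindings(res)` (per-proband best class, platform and
contributing variant keys), `classifiedVariants(res)` (every variant
with its retention flag, drop reason and fired-rule trace),
`cnvResults(res)` (retained CNVs with ISCN labels and genes of
interest), and `cohortSummary(res)@privateClassRates` (class
distribution of the 95 private variants: P 2.1%, LP 25.3%, VOUS 64.2%,
LB 8.4%). Real data enter through `readCohort()` /
`readVariantTable()` / `readCnvTable()` / `readPedigree()` /
`readGeneTable()`; thresholds live in `triageConfig()` or a YAML file
via `readTriageConfig()`.

The methods vignette (`vignettes/variant-triage-methods.Rmd`) documents
the rules, the thresholds and every design choice in detail.

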