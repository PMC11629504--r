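---
title: "Rule-based trio variant triage: model, thresholds and design choices"
author: "TrioTriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based trio variant triage: model, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrioTriage)
```

## The problem

Essential autism spectrum disorder — ASD without dysmorphism, epilepsy,
intellectual disability or other syndromic features — has a strong but
heterogeneous genetic component. A common diagnostic strategy combines
trio whole-exome sequencing (WES), which detects de novo, hemizygous,
homozygous and compound-heterozygous sequence variants, with array-CGH,
which detects copy-number variants (CNVs). The analytic core of such a
study is not the sequencing but the *triage*: a cascade of filters and a
deterministic rule engine that turn thousands of annotated calls per
child into a handful of reportable candidates and a cohort-level
diagnostic yield.

TrioTriage implements that analytic core as a reusable, tested pipeline.
It consumes tables of *annotated* calls (CADD scores, externally assigned
five-tier ACMG classes, gnomAD population counts, trio zygosity and
inheritance) — it does not call variants, compute CADD, or run an
ACMG/AMP evidence-code engine; those annotations are inputs, exactly as a
diagnostic laboratory consumes them from its annotation stack.

## The filtering cascade

Sequence variants pass through the following stages, in this order:

1. **Quality filter.** Coverage below 10 reads or genotype quality (GQ)
   below 15 drops the call; equality is retained. A gnomAD minor allele
   frequency of 5% or more drops it (common-variant exclusion); an absent
   MAF passes. The corresponding sentence in study protocols is sometimes
   worded as excluding variants with MAF *lower* than 5%, which read
   literally would discard every rare variant and contradict the purpose
   of the analysis; the package implements the only self-consistent
   reading (exclude common variants) and flags it here prominently.
2. **Compound-heterozygote pairing.** All couples of heterozygous,
   non-synonymous variants of one proband in one gene with *distinct*
   parental origins among maternal / paternal / de novo are paired. Trio
   phasing is the only phase evidence available, so two same-parent
   variants are never called in trans; a de novo plus an inherited
   heterozygous variant does count as a pair. Pairing runs *before* the
   inherited-heterozygous exclusion because pair members are individually
   inherited heterozygous. Synonymous variants are excluded from pairing:
   they are unconditionally dropped later, and a pair with a synonymous
   member would dissolve at that point anyway.
3. **Gene filter.** Genes in the SFARI autism panel are investigated
   unconditionally. Any other gene is considered only when the variant is
   de novo, a compound-het member, or a truncating / frameshift /
   splicing change with MAF below 1%. The MAF clause binds to the
   truncating branch only; whether it should also bind the de novo and
   compound-het branches is ambiguous in the source protocols, and the
   de novo / compound-het routes are accepted without a frequency ceiling
   here (their trio evidence is considered sufficient). The "truncating"
   consequence set is stop-gain, start-loss, frameshift and splicing.
4. **Provisional classification** (next section) of every candidate.
5. **Retention filter.** Synonymous variants are dropped; inherited
   heterozygous variants not in any pair are dropped; the rest are
   retained when the gnomAD homozygote count is absent or at most 10 —
   except members of a pair in which one member is LP and the other VOUS,
   LP or P, which are retained *regardless* of the homozygote count. The
   exception references member classes, which is why classification runs
   twice (provisional, then final). Every dropped variant carries exactly
   one primary drop reason in the output.

CNVs pass a separate, shorter cascade: the hybridisation must satisfy the
array QC gate (probe SD < 1.0 and derivative log-ratio spread < 0.3,
strict); calls classified benign or likely benign are excluded, as are
calls present in more than 1% of healthy controls in the DGV database
(exactly 1% is retained).

## The classifier

Each candidate is assigned P, LP, VOUS or LB from four ingredients: the
CADD PHRED score, the input ACMG class, the gnomAD homozygote count
(possibly absent) and the gene's annotations.

**SFARI-gene branch**

| rule | condition | class |
|---|---|---|
| criteria 1–3 | CADD ≥ 20 and ACMG ∈ {P, LP} and homozygotes absent or ≤ 1 | P |
| LP rule | homozygotes in [2, 10] and CADD ≥ 20 and ACMG ∈ {P, LP, VOUS} and a criterion-4 gene tag | LP |
| LB rule | CADD < 15 and ACMG = LB | LB |
| fallback | anything else | VOUS |

**Non-SFARI branch** — LP when criteria 1, 2 and 4 hold (CADD ≥ 20, ACMG
∈ {P, LP}, criterion-4 tag); LB when CADD < 15 with ACMG ∈ {B, LB,
VOUS}; otherwise VOUS; *never* P, because genes without an established
ASD link are conservatively capped (`allowNonSfariPathogenic` overrides).

Criterion 4 — involvement in neurodevelopment, nervous system function,
synaptic transmission or epigenetic transcription regulation — is
resolved from the gene-metadata `function_tags` column.

Two deliberate readings are worth stating. First, the LP rule's 2–10
homozygote window is taken literally: a SFARI-gene variant with CADD ≥
20, ACMG VOUS and *zero* homozygotes falls through to VOUS. The lenient
reading (any count up to 10) is available as
`triageConfig(lpAllowLowHom = TRUE)`, default off. Second, "LB or B"
outputs collapse to LB; the distinction never matters downstream.

The classifier is total (every input yields exactly one class),
monotone in CADD under the severity order P > LP > VOUS > LB, and is
verified cell-by-cell against an independent brute-force decision table
over the full 720-cell discrete feature grid in the test suite.

**Compound-het combination.** Pair-level classes follow a fixed
combination table after normalising the pair severe-first: (P, P or LP)
→ P; (LP, LP or VOUS) → LP; (VOUS, VOUS or LB) → VOUS; (LB, LP or P) →
VOUS; (LB, LB) → LB. The published table omits the (P, VOUS)
combination; the package resolves it to LP — between the neighbouring
(P, LP) → P and (LP, VOUS) → LP rows — and the choice is overridable via
`triageConfig(combinationMatrix = ...)`.

**Unique-candidate upgrade.** A proband whose sole retained candidate
across both platforms is a single LP sequence variant in a SFARI gene is
upgraded to P, reflecting the weight a sole candidate carries in an
affected child. The upgrade rewrites the variant's final class as well as
the patient tier — so the upgraded variant counts as pathogenic in the
private-variant distribution, which is how such variants are tallied in
practice — and is recorded in the rule trace. `uniqueCandidateUpgrade =
FALSE` disables it.

**Incomplete penetrance.** Variants inherited from unaffected parents are
pervasive in neurodevelopmental cohorts; the package treats incomplete
penetrance as an interpretive remark, not a computation — no rule
consumes it.

## CNV interpretation

Retained CNVs are intersected with the gene metadata on closed 1-based
intervals (a single shared base is an overlap; this is the array-CGH /
ISCN coordinate convention, used everywhere in the package). Each
(CNV, gene) couple receives exactly one rearrangement label: `DELETED` /
`DUPLICATED` when the gene lies fully inside a loss / gain,
`INTRAGENIC` when the CNV lies fully inside the gene, and `INT_START` /
`INT_END` for partial overlaps according to which *transcriptional*
terminus of the gene lies inside the CNV — strand-aware, with unknown
strand treated as plus. The published tables print these labels without
defining the geometry; this convention is the package's own and is the
natural strand-aware reading. A CNV is *intragenic* when every one of its
gene overlaps is `INTRAGENIC`.

For a single-gene CNV the gene of interest is that gene. Multi-gene CNVs
are ranked by a fixed lexicographic priority: SFARI score tier ascending
(2B ranks as tier 2), criterion-4 tag presence, dosage-sensitivity flag
matching the copy state (haploinsufficiency for losses,
triplosensitivity for gains), brain expression percentile descending,
then symbol. The underlying selection criteria are published without
weights; a deterministic total order was chosen so that reruns and row
permutations cannot change the ranking, and the priority is
config-overridable in the sense that callers may re-rank the returned
metadata.

Labels are formatted ISCN-style —
`13q14.13q14.2(47240527_48096722)x1 pat` — with the second band's
chromosome prefix elided and the inheritance suffix appended when known.

## Per-patient findings and cohort statistics

Each proband's best finding is the most severe retained finding across
platforms, with compound-het members counted at their pair-level class
and CNVs at their prior class. Tiers are capped at P / LP / VOUS;
probands with only likely-benign findings map to `none`. The source is
`both` only when the two platforms independently reach the best tier.

Percentages use half-away-from-zero rounding at a configurable number of
decimals (default 1); published reports sometimes mix rounding modes
(e.g. printing 28.9% for 30/104 = 28.846%), and the package is
deliberately consistent rather than matching each printed digit. The
overall detection rate is the share of probands with a P or LP best
finding, computed from the tier counts rather than reproducing any
internally inconsistent printed total. A variant key (gene + HGVS c.) is
*private* when carried by exactly one proband and *recurrent* at two or
more — affected siblings count separately. Array-CGH positivity, also
reported per sex, means carrying at least one retained CNV of any class.
Gene families group observed genes by their annotated family, filtered
by family size (genome-wide size by default, observed size on request);
the size threshold is configurable because published family selections
do not always honour their own stated cut-off.

## The synthetic cohort generator

`simulateCohort()` materialises a branch plan into a complete, valid
input set — pedigree, variants, CNVs, synthesized gene metadata, array QC
— plus ground-truth tables stating what the pipeline must do with every
record. The default plan *is* the study condition set: 122 trios, 104
males / 18 females; tier strata {P: 4, LP: 34 (24 sequence / 8 CNV / 2
both), VOUS: 70 (54 / 3 / 13), none: 14}; 46 retained CNVs (1
pathogenic de novo, 11 LP, 34 VOUS; 16 losses / 30 gains; 11
intragenic) in 35 patients (30 male, 5 female); a private-variant set of
95 keys distributed {P: 2, LP: 24, VOUS: 61, LB: 8}; recurrent keys
including a three-sibling hemizygous variant; and noise records each
violating exactly one predicate (synonymous, unpaired inherited
heterozygous, low coverage, low GQ, common MAF, more than ten gnomAD
homozygotes, non-SFARI inherited missense, benign / likely benign CNVs,
DGV-common CNVs).

Published strata do not pin down every joint detail, and where they are
mutually inconsistent a choice had to be made once: the four P-tier
patients are planted as one de novo private pathogenic variant, one
sole-candidate upgrade, and a hemizygous pathogenic key shared by two
patients, one of whom also carries the pathogenic de novo CNV. This is
the configuration that satisfies, simultaneously and under the
deterministic rules, the P-tier count, the single pathogenic-CNV
carrier, the twelve P/LP-CNV carriers and the two pathogenic private
variants.

The generator emulates annotation structure, not population genetics: no
realistic allele-frequency spectrum, no linkage, no read-level error, and
gene metadata (SFARI flags, tags, families, coordinates) is synthesized
rather than shipping database content. Passing tests therefore
demonstrate that the *rules* are implemented exactly and recover planted
truth perfectly — they do not demonstrate performance on real annotation
noise, and a loader hook (`readGeneTable()`) accepts a real SFARI-derived
table when one is available.

```{r example}
cohort <- simulateCohort(seed = 7)
res <- runTriage(cohort)
cohortSummary(res)
```

Identical seeds give byte-identical cohorts; different seeds change
identifiers and drawn values but never branch counts.

## Numerical and degenerate-input choices

* Thresholds are strict in the direction stated by each rule: coverage
  10 and GQ 15 pass, SD 1.0 and DLR spread 0.3 fail, DGV frequency
  exactly 1% passes, homozygote count 11 fails retention.
* Absent population annotations (gnomAD MAF, homozygote count, DGV
  frequency) are a distinct state that *passes* frequency rules; they
  are never imputed as zero.
* Missing CADD or ACMG on a candidate is a classification error, not a
  silent VOUS.
* A variant in several compound-het pairs reports the partner of its
  most severe pair (ties broken by key order); pairing itself is
  symmetric and a variant may sit in many pairs.
* Genes absent from the metadata follow the non-SFARI branch with empty
  tags, with a logged message.
* Empty cohorts and empty retained sets yield empty tables, never
  division by zero; a zero proband denominator is an explicit error.
* Rounding is half-away-from-zero (base R's `round()` rounds half to
  even, which would print 11.4 where reports print 11.5).

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
122-trio default cohort (about 250 variant rows, 58 CNV calls and 370
synthesized genes), the classifier oracle on its 720-cell grid, and
property checks on a few hundred randomised cases; everything completes
in well under a minute on one CPU.

## Known limitations

* ACMG classes and CNV prior classes are consumed, not derived; the
  package cannot rescue inconsistent upstream annotation.
* Phase is inferred from trio origins only; true cis pairs with
  discordant origins would be falsely called in trans, as in any
  read-blind trio analysis.
* Non-coding variants are out of scope, as in the underlying analytic
  design.
* The unique-candidate upgrade encodes a judgement call; it is
  switchable precisely because it goes beyond the mechanical criteria.
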