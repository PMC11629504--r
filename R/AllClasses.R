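#' @import methods
NULL

#' Triage configuration
#'
#' Holds every threshold consumed by the filtering cascade, the
#' four-criterion pathogenicity classifier and the compound-heterozygosity
#' combiner. Build with [triageConfig()] or load from YAML with
#' [readTriageConfig()].
#'
#' @slot minCoverage minimum read depth retained by the quality filter
#'   (reads; default 10, strict: lower values are dropped).
#' @slot minGq minimum genotype quality retained (default 15, strict).
#' @slot maxMaf population minor-allele-frequency ceiling for the quality
#'   filter (default 0.05; variants with MAF >= this are dropped, absent
#'   MAF passes).
#' @slot maxMafNonSfari MAF ceiling for the truncating/splicing branch of
#'   the non-SFARI gene filter (default 0.01).
#' @slot caddPathMin CADD PHRED score at or above which criterion 1 holds
#'   (default 20).
#' @slot caddBenignMax CADD score below which the likely-benign rule can
#'   fire (default 15).
#' @slot homPathMax maximum gnomAD homozygote count for the pathogenic rule
#'   (criterion 3; default 1).
#' @slot homLpMin,homLpMax gnomAD homozygote-count window for the SFARI
#'   likely-pathogenic rule (defaults 2 and 10).
#' @slot maxHomRetained retention ceiling on gnomAD homozygote count
#'   (default 10; absent counts pass).
#' @slot criterion4Tags gene function tags satisfying criterion 4.
#' @slot allowNonSfariPathogenic if `TRUE`, non-SFARI variants meeting
#'   criteria 1-3 may be classified P; default `FALSE` (conservative).
#' @slot lpAllowLowHom if `TRUE`, the SFARI LP rule also accepts 0-1 or
#'   absent homozygote counts; default `FALSE` (literal 2-10 window).
#' @slot uniqueCandidateUpgrade enable the sole-candidate LP-to-P upgrade
#'   (default `TRUE`).
#' @slot combinationMatrix named character vector mapping normalised class
#'   pairs (`"P|LP"` etc., more severe class first) to the pair-level
#'   class.
#' @slot maxDgvFrequency CNV retention ceiling on population frequency in
#'   healthy controls (default 0.01; strictly greater is dropped).
#' @slot maxArraySd,maxDlrSpread array QC ceilings (defaults 1.0 and 0.3,
#'   strict).
#' @slot rateDigits decimal places for reported percentages (default 1).
#' @seealso [triageConfig()], [classifyVariants()], [runTriage()]
#' @export
setClass("TriageConfig", representation(
  minCoverage = "numeric",
  minGq = "numeric",
  maxMaf = "numeric",
  maxMafNonSfari = "numeric",
  caddPathMin = "numeric",
  caddBenignMax = "numeric",
  homPathMax = "integer",
  homLpMin = "integer",
  homLpMax = "integer",
  maxHomRetained = "integer",
  criterion4Tags = "character",
  allowNonSfariPathogenic = "logical",
  lpAllowLowHom = "logical",
  uniqueCandidateUpgrade = "logical",
  combinationMatrix = "character",
  maxDgvFrequency = "numeric",
  maxArraySd = "numeric",
  maxDlrSpread = "numeric",
  rateDigits = "integer"
))

setValidity("TriageConfig", function(object) {
  msgs <- character()
  if (object@caddBenignMax > object@caddPathMin)
    msgs <- c(msgs, "caddBenignMax must be <= caddPathMin")
  if (object@homLpMin <= object@homPathMax)
    msgs <- c(msgs, "homLpMin must exceed homPathMax")
  if (object@homLpMax < object@homLpMin)
    msgs <- c(msgs, "homLpMax must be >= homLpMin")
  if (object@minCoverage <= 0 || object@minGq <= 0)
    msgs <- c(msgs, "QC thresholds must be positive")
  need <- combinationPairNames()
  if (!all(need %in% names(object@combinationMatrix)))
    msgs <- c(msgs, "combinationMatrix must cover every unordered pair of P/LP/VOUS/LB")
  if (!all(object@combinationMatrix %in% ACMG_CLASSES))
    msgs <- c(msgs, "combinationMatrix values must be ACMG classes")
  if (length(msgs)) msgs else TRUE
})

## all unordered pairs over {P, LP, VOUS, LB}, normalised severe-first
combinationPairNames <- function() {
  cls <- c("P", "LP", "VOUS", "LB")
  out <- character()
  for (i in seq_along(cls))
    for (j in i:length(cls))
      out <- c(out, paste(cls[i], cls[j], sep = "|"))
  out
}

## pair-level classes for compound heterozygotes; keys are severe-first.
## The one pair the published table leaves out, (P, VOUS), is assigned LP
## (between the listed (P,LP)->P and (LP,VOUS)->LP rows); override through
## triageConfig(combinationMatrix=).
defaultCombinationMatrix <- function() {
  c("P|P" = "P", "P|LP" = "P", "P|VOUS" = "LP", "P|LB" = "VOUS",
    "LP|LP" = "LP", "LP|VOUS" = "LP", "LP|LB" = "VOUS",
    "VOUS|VOUS" = "VOUS", "VOUS|LB" = "VOUS",
    "LB|LB" = "LB")
}

#' Build a triage configuration
#'
#' All arguments default to the study settings; see the class documentation
#' ([TriageConfig-class]) for the meaning and units of each threshold.
#'
#' @param minCoverage,minGq,maxMaf quality-filter thresholds.
#' @param maxMafNonSfari non-SFARI truncating-branch MAF ceiling.
#' @param caddPathMin,caddBenignMax CADD thresholds (criteria 1 and the
#'   likely-benign rule).
#' @param homPathMax,homLpMin,homLpMax,maxHomRetained gnomAD
#'   homozygote-count thresholds.
#' @param criterion4Tags function tags satisfying criterion 4.
#' @param allowNonSfariPathogenic,lpAllowLowHom,uniqueCandidateUpgrade
#'   rule switches.
#' @param combinationMatrix compound-het pair class map (severe-first keys).
#' @param maxDgvFrequency,maxArraySd,maxDlrSpread CNV/array thresholds.
#' @param rateDigits decimal places for percentages.
#' @return a validated [TriageConfig-class] object.
#' @examples
#' cfg <- triageConfig()
#' cfg@caddPathMin
#' @export
triageConfig <- function(minCoverage = 10, minGq = 15, maxMaf = 0.05,
                         maxMafNonSfari = 0.01,
                         caddPathMin = 20, caddBenignMax = 15,
                         homPathMax = 1L, homLpMin = 2L, homLpMax = 10L,
                         maxHomRetained = 10L,
                         criterion4Tags = c("neurodevelopment",
                                            "nervous_system_function",
                                            "synaptic_transmission",
                                            "epigenetic_transcription_regulation"),
                         allowNonSfariPathogenic = FALSE,
                         lpAllowLowHom = FALSE,
                         uniqueCandidateUpgrade = TRUE,
                         combinationMatrix = defaultCombinationMatrix(),
                         maxDgvFrequency = 0.01,
                         maxArraySd = 1.0, maxDlrSpread = 0.3,
                         rateDigits = 1L) {
  new("TriageConfig",
      minCoverage = minCoverage, minGq = minGq, maxMaf = maxMaf,
      maxMafNonSfari = maxMafNonSfari,
      caddPathMin = caddPathMin, caddBenignMax = caddBenignMax,
      homPathMax = as.integer(homPathMax), homLpMin = as.integer(homLpMin),
      homLpMax = as.integer(homLpMax),
      maxHomRetained = as.integer(maxHomRetained),
      criterion4Tags = criterion4Tags,
      allowNonSfariPathogenic = allowNonSfariPathogenic,
      lpAllowLowHom = lpAllowLowHom,
      uniqueCandidateUpgrade = uniqueCandidateUpgrade,
      combinationMatrix = combinationMatrix,
      maxDgvFrequency = maxDgvFrequency,
      maxArraySd = maxArraySd, maxDlrSpread = maxDlrSpread,
      rateDigits = as.integer(rateDigits))
}

#' Read a triage configuration from YAML
#'
#' Keys mirror the arguments of [triageConfig()]; absent keys keep their
#' defaults.
#'
#' @param path YAML file.
#' @return a [TriageConfig-class] object.
#' @export
readTriageConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(triageConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$combinationMatrix))
    vals$combinationMatrix <- unlist(vals$combinationMatrix)
  do.call(triageConfig, vals)
}

#' Trio cohort container
#'
#' Bundles the validated input tables of one cohort: pedigree, annotated
#' sequence variants, array-CGH CNV calls, gene metadata and array QC
#' metrics. Construct with [TrioCohort()] after reading the individual
#' tables, or generate synthetically with [simulateCohort()].
#'
#' @slot pedigree data.frame of pedigree members (see [readPedigree()]).
#' @slot variants data.frame of annotated variants (see
#'   [readVariantTable()]).
#' @slot cnvs data.frame of CNV calls (see [readCnvTable()]).
#' @slot genes data.frame of gene metadata (see [readGeneTable()]).
#' @slot arrayQc data.frame of per-patient array QC metrics (see
#'   [readArrayQc()]).
#' @export
setClass("TrioCohort", representation(
  pedigree = "data.frame",
  variants = "data.frame",
  cnvs = "data.frame",
  genes = "data.frame",
  arrayQc = "data.frame"
))

setValidity("TrioCohort", function(object) {
  msgs <- character()
  ped <- object@pedigree
  if (nrow(ped)) {
    key <- paste(ped$family_id, ped$individual_id)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate individual_id within a family")
  }
  v <- object@variants
  if (nrow(v) && nrow(ped)) {
    miss <- setdiff(unique(v$patient_id), ped$individual_id)
    if (length(miss))
      msgs <- c(msgs, paste("variant patient_id absent from pedigree:",
                            paste(miss, collapse = ", ")))
  }
  g <- object@genes
  if (nrow(g) && anyDuplicated(g$symbol))
    msgs <- c(msgs, "duplicate gene symbol in metadata")
  if (nrow(g) && any(g$start > g$end))
    msgs <- c(msgs, "gene with start > end")
  cn <- object@cnvs
  if (nrow(cn) && any(cn$start > cn$end))
    msgs <- c(msgs, "CNV with start > end")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TrioCohort
#'
#' @param pedigree,variants,cnvs,genes,arrayQc validated data.frames as
#'   returned by the corresponding readers; `cnvs`, `genes` and `arrayQc`
#'   may be omitted for sequence-only work.
#' @return a [TrioCohort-class] object.
#' @export
TrioCohort <- function(pedigree, variants,
                       cnvs = emptyCnvTable(),
                       genes = emptyGeneTable(),
                       arrayQc = emptyArrayQcTable()) {
  new("TrioCohort", pedigree = pedigree, variants = variants,
      cnvs = cnvs, genes = genes, arrayQc = arrayQc)
}

#' Simulated trio cohort with planted truth
#'
#' A [TrioCohort-class] extended with the generator's ground-truth tables:
#' per-record expected retention and class, and per-patient expected tier.
#'
#' @slot truthVariants data.frame: one row per planted variant
#'   (`patient_id`, `key`, `branch`, `expect_retained`, `expect_class`,
#'   `expect_combined`).
#' @slot truthCnvs data.frame: one row per planted CNV (`patient_id`,
#'   `key`, `branch`, `expect_retained`).
#' @slot truthPatients data.frame: `patient_id`, `expect_tier`,
#'   `expect_source`.
#' @slot seed integer seed the cohort was generated from.
#' @export
setClass("SimulatedTrioCohort", contains = "TrioCohort", representation(
  truthVariants = "data.frame",
  truthCnvs = "data.frame",
  truthPatients = "data.frame",
  seed = "integer"
))

#' Cohort-level summary statistics
#'
#' Diagnostic-yield and composition statistics for one triaged cohort, as
#' produced by [summarizeCohort()]. Percentages use half-away-from-zero
#' rounding at the configured number of decimals.
#'
#' @slot nPatients,nMales,nFemales cohort size and sex split.
#' @slot categoryCounts named integer: patients per best-finding tier
#'   (`P`, `LP`, `VOUS`, `none`).
#' @slot categoryRates named numeric: the same as percentages of
#'   `nPatients`.
#' @slot strata data.frame: tier x platform-source patient counts and
#'   rates.
#' @slot overallDetectionRate percentage of patients with a P or LP best
#'   finding.
#' @slot maleFemaleRatio male:female ratio (one decimal).
#' @slot cnvComposition list: counts and percentages of deletions,
#'   duplications and intragenic CNVs among retained calls.
#' @slot recurrenceTable data.frame of variant keys seen in two or more
#'   probands.
#' @slot privateTable data.frame of private (single-proband) variant keys.
#' @slot privateClassRates named numeric: class distribution of the
#'   private set (percentages).
#' @slot geneRecurrence data.frame of genes with retained variants in two
#'   or more probands.
#' @slot familyTable data.frame grouping observed genes by gene family.
#' @slot sexPositivity named numeric: array-CGH positivity percentage by
#'   sex.
#' @export
setClass("CohortSummary", representation(
  nPatients = "integer",
  nMales = "integer",
  nFemales = "integer",
  categoryCounts = "integer",
  categoryRates = "numeric",
  strata = "data.frame",
  overallDetectionRate = "numeric",
  maleFemaleRatio = "numeric",
  cnvComposition = "list",
  recurrenceTable = "data.frame",
  privateTable = "data.frame",
  privateClassRates = "numeric",
  geneRecurrence = "data.frame",
  familyTable = "data.frame",
  sexPositivity = "numeric"
))

#' Full triage result
#'
#' Output container of [runTriage()]: the classified sequence-variant
#' table with drop reasons and rule traces, compound-het pairs, retained
#' CNVs with rearrangement typing and labels, per-patient findings and the
#' cohort summary.
#'
#' @slot classified data.frame: every post-QC variant with `retained`,
#'   `drop_reason`, `assigned_class`, `rule_trace`, `compound_partner`,
#'   `combined_class`.
#' @slot pairs data.frame of compound-heterozygote pairs.
#' @slot cnvResults data.frame: all CNV calls with `retained`,
#'   `drop_reason`, `iscn` label and genes of interest.
#' @slot overlaps data.frame: per (CNV, gene) rearrangement typing.
#' @slot findings data.frame: per-patient best class, source platform and
#'   contributing keys.
#' @slot summary the [CohortSummary-class].
#' @slot config the [TriageConfig-class] used.
#' @export
setClass("TriageResult", representation(
  classified = "data.frame",
  pairs = "data.frame",
  cnvResults = "data.frame",
  overlaps = "data.frame",
  findings = "data.frame",
  summary = "CohortSummary",
  config = "TriageConfig"
))
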