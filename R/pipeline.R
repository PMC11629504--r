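#' Run the complete triage pipeline on a cohort
#'
#' Executes, in order: array QC gating and CNV retention with
#' rearrangement typing ([triageCnvs()]); the sequence-variant cascade --
#' quality filter, compound-het pairing, gene filter, provisional
#' classification, retention filter, final classification and the
#' unique-candidate upgrade ([triageSnvs()]); per-patient best-finding
#' resolution ([bestFindings()]); and the cohort summary
#' ([summarizeCohort()]).
#'
#' The CNV pass runs first because the unique-candidate upgrade must know
#' whether a proband carries any retained CNV.
#'
#' @param cohort a [TrioCohort-class] (or [SimulatedTrioCohort-class]).
#' @param config a [TriageConfig-class].
#' @return a [TriageResult-class].
#' @examples
#' cohort <- simulateCohort(seed = 1, plan = defaultCohortPlan(nPatients = 12))
#' res <- runTriage(cohort)
#' cohortSummary(res)
#' @export
runTriage <- function(cohort, config = triageConfig()) {
  cn <- triageCnvs(cnvCalls(cohort), geneMeta(cohort), arrayQc(cohort),
                   config)
  retainedKeys <- cnvKeys(cn$cnvResults[cn$cnvResults$retained, , drop = FALSE])
  sv <- triageSnvs(variantCalls(cohort), geneMeta(cohort), config,
                   retainedCnvKeys = retainedKeys)
  findings <- bestFindings(sv$classified, cn$cnvResults, pedigree(cohort))
  summary <- summarizeCohort(sv$classified, cn$cnvResults, findings,
                             pedigree(cohort), geneMeta(cohort), config)
  new("TriageResult", classified = sv$classified, pairs = sv$pairs,
      cnvResults = cn$cnvResults, overlaps = cn$overlaps,
      findings = findings, summary = summary, config = config)
}
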