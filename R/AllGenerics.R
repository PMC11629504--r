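#' Accessors for cohort and result containers
#'
#' Slot accessors for [TrioCohort-class], [SimulatedTrioCohort-class],
#' [TriageResult-class] and [CohortSummary-class]. Use these instead of
#' `@` access.
#'
#' @param x a container object.
#' @return the requested table (a data.frame) or summary component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname accessors
#' @export
setGeneric("cnvCalls", function(x) standardGeneric("cnvCalls"))

#' @rdname accessors
#' @export
setGeneric("geneMeta", function(x) standardGeneric("geneMeta"))

#' @rdname accessors
#' @export
setGeneric("arrayQc", function(x) standardGeneric("arrayQc"))

#' @rdname accessors
#' @export
setGeneric("truthTables", function(x) standardGeneric("truthTables"))

#' @rdname accessors
#' @export
setGeneric("classifiedVariants", function(x) standardGeneric("classifiedVariants"))

#' @rdname accessors
#' @export
setGeneric("compoundHetPairs", function(x) standardGeneric("compoundHetPairs"))

#' @rdname accessors
#' @export
setGeneric("cnvResults", function(x) standardGeneric("cnvResults"))

#' @rdname accessors
#' @export
setGeneric("geneOverlaps", function(x) standardGeneric("geneOverlaps"))

#' @rdname accessors
#' @export
setGeneric("patientFindings", function(x) standardGeneric("patientFindings"))

#' @rdname accessors
#' @export
setGeneric("cohortSummary", function(x) standardGeneric("cohortSummary"))

#' @rdname accessors
#' @export
setMethod("pedigree", "TrioCohort", function(x) x@pedigree)

#' @rdname accessors
#' @export
setMethod("variantCalls", "TrioCohort", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("cnvCalls", "TrioCohort", function(x) x@cnvs)

#' @rdname accessors
#' @export
setMethod("geneMeta", "TrioCohort", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("arrayQc", "TrioCohort", function(x) x@arrayQc)

#' @rdname accessors
#' @export
setMethod("truthTables", "SimulatedTrioCohort", function(x)
  list(variants = x@truthVariants, cnvs = x@truthCnvs,
       patients = x@truthPatients))

#' @rdname accessors
#' @export
setMethod("classifiedVariants", "TriageResult", function(x) x@classified)

#' @rdname accessors
#' @export
setMethod("compoundHetPairs", "TriageResult", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("cnvResults", "TriageResult", function(x) x@cnvResults)

#' @rdname accessors
#' @export
setMethod("geneOverlaps", "TriageResult", function(x) x@overlaps)

#' @rdname accessors
#' @export
setMethod("patientFindings", "TriageResult", function(x) x@findings)

#' @rdname accessors
#' @export
setMethod("cohortSummary", "TriageResult", function(x) x@summary)

#' @describeIn TrioCohort-class compact cohort overview
#' @param object a `TrioCohort`.
#' @export
setMethod("show", "TrioCohort", function(object) {
  ped <- object@pedigree
  probands <- if (nrow(ped)) sum(!is.na(ped$father_id) & !is.na(ped$mother_id) &
                                   ped$affected == "affected") else 0L
  cat(class(object), "with", length(unique(ped$family_id)), "families,",
      probands, "affected probands\n")
  cat("  variants:", nrow(object@variants),
      "| CNV calls:", nrow(object@cnvs),
      "| genes:", nrow(object@genes), "\n")
})

#' @describeIn TriageResult-class compact result overview
#' @param object a `TriageResult`.
#' @export
setMethod("show", "TriageResult", function(object) {
  cl <- object@classified
  cat(class(object), ":", sum(cl$retained), "of", nrow(cl),
      "variants retained;", sum(object@cnvResults$retained), "of",
      nrow(object@cnvResults), "CNVs retained\n")
  s <- object@summary
  cat("  tiers:", paste(names(s@categoryCounts), s@categoryCounts,
                        sep = "=", collapse = " "),
      "| overall detection rate:", s@overallDetectionRate, "%\n")
})

#' @describeIn CohortSummary-class print the headline statistics
#' @param object a `CohortSummary`.
#' @export
setMethod("show", "CohortSummary", function(object) {
  cat(class(object), "for", object@nPatients, "probands (",
      object@nMales, "M /", object@nFemales, "F, ratio",
      object@maleFemaleRatio, ":1 )\n")
  for (tier in names(object@categoryCounts))
    cat(sprintf("  %-5s %3d patients (%s%%)\n", tier,
                object@categoryCounts[[tier]], object@categoryRates[[tier]]))
  cat("  overall detection rate (P+LP):", object@overallDetectionRate, "%\n")
})
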