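## Per-patient best-finding resolution and cohort-level statistics.
##
## Percentages are rounded half-away-from-zero at the configured number of
## decimals; the male:female ratio is reported to one decimal.

FINDING_TIERS <- c("P", "LP", "VOUS", "none")

#' Resolve per-patient best findings
#'
#' For every affected, trio-complete proband in the pedigree, selects the
#' most severe retained finding across both platforms. Compound-het
#' members contribute their pair-level class; CNVs contribute their prior
#' class. Tiers are capped at P / LP / VOUS: probands with only
#' likely-benign findings (or none) map to tier `none`. The source is
#' `sequence`, `cnv`, or `both` when the two platforms independently reach
#' the best tier.
#'
#' @param classified classified variant data.frame (from [triageSnvs()]).
#' @param cnvResults CNV result data.frame (from [triageCnvs()]).
#' @param ped pedigree data.frame.
#' @return data.frame: `patient_id`, `best_class`, `source`,
#'   `contributing_keys` (semicolon-joined).
#' @export
bestFindings <- function(classified, cnvResults, ped) {
  probands <- ped$individual_id[ped$affected == "affected" & ped$trio_complete]
  out <- data.frame(patient_id = probands,
                    best_class = "none", source = "none",
                    contributing_keys = "", stringsAsFactors = FALSE)
  vRet <- classified[classified$retained, , drop = FALSE]
  vClass <- ifelse(is.na(vRet$combined_class), vRet$assigned_class,
                   vRet$combined_class)
  vKey <- variantKey(vRet$gene, vRet$hgvs_c)
  cRet <- cnvResults[cnvResults$retained, , drop = FALSE]
  cKey <- if (nrow(cRet)) cnvKeys(cRet) else character()
  for (i in seq_len(nrow(out))) {
    pid <- out$patient_id[i]
    sv <- vClass[vRet$patient_id == pid]
    cv <- cRet$prior_class[cRet$patient_id == pid]
    bestSeq <- severityMax(sv[sv %in% c("P", "LP", "VOUS")])
    bestCnv <- severityMax(cv[cv %in% c("P", "LP", "VOUS")])
    best <- severityMax(c(bestSeq, bestCnv))
    if (is.na(best)) next
    out$best_class[i] <- best
    seqHit <- !is.na(bestSeq) && bestSeq == best
    cnvHit <- !is.na(bestCnv) && bestCnv == best
    out$source[i] <- if (seqHit && cnvHit) "both"
      else if (seqHit) "sequence" else "cnv"
    keys <- c(if (seqHit) vKey[vRet$patient_id == pid][sv == best],
              if (cnvHit) cKey[cRet$patient_id == pid][cv == best])
    out$contributing_keys[i] <- paste(keys, collapse = ";")
  }
  out
}

#' Detection rates and tier composition
#'
#' Counts and percentage rates per best-finding tier and per platform
#' stratum within tier, the overall detection rate (P plus LP patients
#' over cohort size), and the male:female ratio.
#'
#' @param findings per-patient findings ([bestFindings()]).
#' @param ped pedigree data.frame (for proband sex).
#' @param config a [TriageConfig-class] (rounding).
#' @return a [CohortSummary-class] with the composition slots filled;
#'   CNV/recurrence slots are filled by [summarizeCohort()].
#' @export
detectionRates <- function(findings, ped, config = triageConfig()) {
  n <- nrow(findings)
  if (n == 0L) stop("no probands: cannot compute rates", call. = FALSE)
  digits <- config@rateDigits
  sex <- ped$sex[match(findings$patient_id, ped$individual_id)]
  nM <- sum(sex == "male")
  nF <- sum(sex == "female")
  counts <- vapply(FINDING_TIERS,
                   function(t) sum(findings$best_class == t), integer(1))
  rates <- vapply(counts, pct, numeric(1), denom = n, digits = digits)
  strata <- do.call(rbind, lapply(setdiff(FINDING_TIERS, "none"), function(t) {
    src <- findings$source[findings$best_class == t]
    data.frame(tier = t,
               source = c("sequence", "cnv", "both"),
               count = c(sum(src == "sequence"), sum(src == "cnv"),
                         sum(src == "both")),
               stringsAsFactors = FALSE)
  }))
  strata$rate_pct <- vapply(strata$count, pct, numeric(1),
                            denom = n, digits = digits)
  ratio <- if (nF > 0L) roundHalfAway(nM / nF, 1L) else NA_real_
  new("CohortSummary",
      nPatients = n, nMales = nM, nFemales = nF,
      categoryCounts = counts, categoryRates = rates, strata = strata,
      overallDetectionRate = pct(counts[["P"]] + counts[["LP"]], n, digits),
      maleFemaleRatio = ratio,
      cnvComposition = list(),
      recurrenceTable = data.frame(), privateTable = data.frame(),
      privateClassRates = numeric(), geneRecurrence = data.frame(),
      familyTable = data.frame(), sexPositivity = numeric())
}

#' CNV composition of the retained call set
#'
#' Deletion, duplication and intragenic shares among retained CNVs.
#' Deletion/duplication percentages use `digits` decimals; the intragenic
#' share is conventionally reported at whole percent (`intragenicDigits`).
#'
#' @param cnvResults CNV result data.frame (from [triageCnvs()]).
#' @param digits,intragenicDigits decimal places (defaults 1 and 0).
#' @return list with `n`, `deletions`, `duplications`, `intragenic`
#'   counts and `_pct` rates; empty list if nothing is retained.
#' @export
cnvComposition <- function(cnvResults, digits = 1L, intragenicDigits = 0L) {
  kept <- cnvResults[cnvResults$retained, , drop = FALSE]
  n <- nrow(kept)
  if (n == 0L) return(list(n = 0L))
  nDel <- sum(kept$copy_state == "loss")
  nDup <- sum(kept$copy_state == "gain")
  nIntra <- sum(kept$intragenic)
  list(n = n,
       deletions = nDel, deletions_pct = pct(nDel, n, digits),
       duplications = nDup, duplications_pct = pct(nDup, n, digits),
       intragenic = nIntra,
       intragenic_pct = pct(nIntra, n, intragenicDigits))
}

#' Recurrence and private-variant tables
#'
#' Over the retained classified variants, a variant key (gene plus HGVS c.
#' notation) is private when carried by exactly one proband and recurrent
#' when carried by two or more (affected siblings count separately). Gene
#' recurrence counts genes with retained variants in two or more probands.
#' The class distribution of the private set uses the variants' final
#' classes.
#'
#' @param classified classified variant data.frame.
#' @param config a [TriageConfig-class] (rounding).
#' @return list with `recurrenceTable`, `privateTable`, `privateClassRates`
#'   (named percentages over the private set) and `geneRecurrence`.
#' @export
recurrenceAndPrivate <- function(classified, config = triageConfig()) {
  ret <- classified[classified$retained, , drop = FALSE]
  key <- variantKey(ret$gene, ret$hgvs_c)
  carriers <- tapply(ret$patient_id, key, function(x) length(unique(x)))
  keyClass <- tapply(ret$assigned_class, key, function(x) x[1L])
  keys <- names(carriers)
  isPrivate <- carriers == 1L
  recurrence <- data.frame(key = keys[!isPrivate],
                           n_probands = as.integer(carriers[!isPrivate]),
                           class = keyClass[!isPrivate],
                           stringsAsFactors = FALSE, row.names = NULL)
  recurrence <- recurrence[order(-recurrence$n_probands, recurrence$key), ,
                           drop = FALSE]
  private <- data.frame(key = keys[isPrivate],
                        class = keyClass[isPrivate],
                        stringsAsFactors = FALSE, row.names = NULL)
  private <- private[order(private$key), , drop = FALSE]
  rates <- numeric()
  if (nrow(private)) {
    cls <- c("P", "LP", "VOUS", "LB")
    cnt <- vapply(cls, function(cc) sum(private$class == cc), integer(1))
    rates <- vapply(cnt, pct, numeric(1), denom = nrow(private),
                    digits = config@rateDigits)
    names(rates) <- cls
  }
  geneCarriers <- tapply(ret$patient_id, ret$gene,
                         function(x) length(unique(x)))
  geneRec <- data.frame(gene = names(geneCarriers)[geneCarriers >= 2L],
                        n_probands = as.integer(geneCarriers[geneCarriers >= 2L]),
                        stringsAsFactors = FALSE, row.names = NULL)
  geneRec <- geneRec[order(-geneRec$n_probands, geneRec$gene), , drop = FALSE]
  list(recurrenceTable = recurrence, privateTable = private,
       privateClassRates = rates, geneRecurrence = geneRec)
}

#' Sex-stratified array-CGH positivity
#'
#' Positivity means carrying at least one retained CNV call of any class.
#' Probands of unknown sex are excluded with a warning.
#'
#' @param cnvResults CNV result data.frame.
#' @param ped pedigree data.frame.
#' @param findings per-patient findings (defines the proband set).
#' @param config a [TriageConfig-class] (rounding).
#' @return named numeric: `male` and `female` positivity percentages, with
#'   counts in attributes `positives` and `denominators`.
#' @export
sexStratifiedPositivity <- function(cnvResults, ped, findings,
                                    config = triageConfig()) {
  sex <- ped$sex[match(findings$patient_id, ped$individual_id)]
  if (any(sex == "unknown")) {
    warning("proband(s) of unknown sex excluded from sex stratification",
            call. = FALSE)
  }
  carriers <- unique(cnvResults$patient_id[cnvResults$retained])
  positive <- findings$patient_id %in% carriers
  out <- numeric(); pos <- integer(); den <- integer()
  for (s in c("male", "female")) {
    idx <- sex == s
    den[s] <- sum(idx)
    pos[s] <- sum(positive & idx)
    out[s] <- if (den[s] > 0L) pct(pos[s], den[s], config@rateDigits) else NA_real_
  }
  attr(out, "positives") <- pos
  attr(out, "denominators") <- den
  out
}

#' Gene-family summary
#'
#' Groups genes carrying retained variants (and, optionally, CNV genes of
#' interest) by annotated gene family, reporting member genes, SFARI
#' membership and carrier patients. Families are filtered by
#' `minFamilySize`, applied to the genome-wide family size in the metadata
#' when `genomeWide` (default), else to the observed member count. Genes
#' without a family annotation group under `unassigned` and are excluded
#' from the filtered view.
#'
#' @param observedGenes character vector of gene symbols with findings.
#' @param classified classified variant data.frame (for carrier patients).
#' @param genes gene-metadata data.frame.
#' @param minFamilySize smallest family reported (default 2).
#' @param genomeWide filter on metadata-wide family size (default `TRUE`).
#' @return data.frame: `family`, `gene`, `sfari_member`, `patients`,
#'   `family_size`.
#' @export
geneFamilySummary <- function(observedGenes, classified, genes,
                              minFamilySize = 2L, genomeWide = TRUE) {
  idx <- match(observedGenes, genes$symbol)
  fam <- ifelse(is.na(idx), NA_character_, genes$family_name[idx])
  fam[is.na(fam)] <- "unassigned"
  famSizeAll <- table(genes$family_name[!is.na(genes$family_name)])
  ret <- classified[classified$retained, , drop = FALSE]
  rows <- lapply(seq_along(observedGenes), function(i) {
    g <- observedGenes[i]
    patients <- sort(unique(ret$patient_id[ret$gene == g]))
    data.frame(family = fam[i], gene = g,
               sfari_member = !is.na(idx[i]) &&
                 isTRUE(genes$sfari_member[idx[i]]),
               patients = paste(patients, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  obsSize <- table(out$family)
  out$family_size <- if (genomeWide)
    as.integer(famSizeAll[out$family]) else as.integer(obsSize[out$family])
  out$family_size[is.na(out$family_size)] <- 0L
  out <- out[out$family != "unassigned" & out$family_size >= minFamilySize, ,
             drop = FALSE]
  out[order(out$family, out$gene), , drop = FALSE]
}

#' Assemble the full cohort summary
#'
#' Runs [detectionRates()], [cnvComposition()], [recurrenceAndPrivate()],
#' [sexStratifiedPositivity()] and [geneFamilySummary()] and returns one
#' [CohortSummary-class].
#'
#' @param classified classified variant data.frame.
#' @param cnvResults CNV result data.frame.
#' @param findings per-patient findings.
#' @param ped pedigree data.frame.
#' @param genes gene-metadata data.frame.
#' @param config a [TriageConfig-class].
#' @return a [CohortSummary-class].
#' @export
summarizeCohort <- function(classified, cnvResults, findings, ped, genes,
                            config = triageConfig()) {
  s <- detectionRates(findings, ped, config)
  s@cnvComposition <- cnvComposition(cnvResults, config@rateDigits)
  rp <- recurrenceAndPrivate(classified, config)
  s@recurrenceTable <- rp$recurrenceTable
  s@privateTable <- rp$privateTable
  s@privateClassRates <- rp$privateClassRates
  s@geneRecurrence <- rp$geneRecurrence
  s@sexPositivity <- sexStratifiedPositivity(cnvResults, ped, findings, config)
  observed <- sort(unique(classified$gene[classified$retained]))
  s@familyTable <- geneFamilySummary(observed, classified, genes)
  s
}
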