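## Array-CGH CNV triage: QC gate, retention, gene-overlap rearrangement
## typing, genes-of-interest ranking and ISCN-style labelling.
##
## Intervals are 1-based closed; a single shared base counts as overlap
## (GenomicRanges semantics).

cnvKeys <- function(cnvs) {
  paste(cnvs$patient_id, cnvs$chrom, cnvs$start, cnvs$end, sep = ":")
}

#' Array QC gate
#'
#' A hybridisation passes when the derivative log-ratio spread and probe
#' SD are both below their ceilings (strict: SD 1.0 or DLR spread 0.3
#' fail at the defaults).
#'
#' @param qc array QC data.frame ([readArrayQc()]).
#' @param config a [TriageConfig-class].
#' @return logical vector, `TRUE` where the array passes.
#' @export
arrayQcCheck <- function(qc, config = triageConfig()) {
  qc$sd < config@maxArraySd & qc$dlr_spread < config@maxDlrSpread
}

#' CNV retention filter
#'
#' Retains calls whose prior classification is not benign or likely benign
#' and whose population frequency in healthy controls does not exceed
#' `maxDgvFrequency` (absent frequency passes; exactly the ceiling is
#' retained -- the exclusion is "present in more than 1%").
#'
#' @param cnvs CNV data.frame ([readCnvTable()]).
#' @param config a [TriageConfig-class].
#' @return list with `retained` (logical) and `drop_reason`
#'   (`class_benign`, `dgv_common` or `NA`).
#' @export
cnvRetentionFilter <- function(cnvs, config = triageConfig()) {
  reason <- rep(NA_character_, nrow(cnvs))
  reason[!is.na(cnvs$dgv_frequency) &
           cnvs$dgv_frequency > config@maxDgvFrequency] <- "dgv_common"
  reason[cnvs$prior_class %in% c("B", "LB")] <- "class_benign"
  list(retained = is.na(reason), drop_reason = reason)
}

#' Type a CNV-gene rearrangement
#'
#' Exactly one label per overlapping (CNV, gene) couple:
#' gene fully inside the CNV -> `DELETED` (loss) or `DUPLICATED` (gain);
#' CNV fully inside the gene -> `INTRAGENIC`; partial overlap covering the
#' gene's transcriptional start -> `INT_START`; covering its
#' transcriptional end -> `INT_END`. Start/end are strand-aware (the
#' transcriptional start of a minus-strand gene is its highest
#' coordinate); unknown strand is treated as plus.
#'
#' @param cnvStart,cnvEnd CNV interval (1-based inclusive).
#' @param copyState `loss` or `gain`.
#' @param geneStart,geneEnd gene interval.
#' @param strand `+`, `-` or `unknown`.
#' @return one of `DELETED`, `DUPLICATED`, `INTRAGENIC`, `INT_START`,
#'   `INT_END`.
#' @examples
#' rearrangementType(100, 200, "gain", 120, 180, "+")  # DUPLICATED
#' rearrangementType(150, 300, "loss", 100, 200, "-")  # INT_START
#' @export
rearrangementType <- function(cnvStart, cnvEnd, copyState,
                              geneStart, geneEnd, strand = "+") {
  if (cnvEnd < geneStart || cnvStart > geneEnd)
    stop("CNV and gene intervals are disjoint", call. = FALSE)
  if (cnvStart <= geneStart && cnvEnd >= geneEnd)
    return(if (copyState == "loss") "DELETED" else "DUPLICATED")
  if (cnvStart >= geneStart && cnvEnd <= geneEnd)
    return("INTRAGENIC")
  ## partial overlap: which transcriptional terminus lies inside the CNV?
  txStart <- if (identical(strand, "-")) geneEnd else geneStart
  startInside <- txStart >= cnvStart && txStart <= cnvEnd
  if (startInside) "INT_START" else "INT_END"
}

#' Overlap retained CNVs with gene metadata
#'
#' Computes all (CNV, gene) overlaps on matching chromosomes via
#' `GenomicRanges::findOverlaps` and types each rearrangement with
#' [rearrangementType()].
#'
#' @param cnvs CNV data.frame.
#' @param genes gene-metadata data.frame.
#' @return data.frame: `patient_id`, `cnv_key`, `gene`, `rearrangement`.
#' @export
overlapCnvGenes <- function(cnvs, genes) {
  empty <- data.frame(patient_id = character(), cnv_key = character(),
                      gene = character(), rearrangement = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(cnvs) || !nrow(genes)) return(empty)
  gr_cnv <- GenomicRanges::GRanges(cnvs$chrom,
                                   IRanges::IRanges(cnvs$start, cnvs$end))
  gr_gene <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_cnv, gr_gene)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(
    patient_id = cnvs$patient_id[qi],
    cnv_key = cnvKeys(cnvs)[qi],
    gene = genes$symbol[si],
    rearrangement = mapply(rearrangementType,
                           cnvs$start[qi], cnvs$end[qi], cnvs$copy_state[qi],
                           genes$start[si], genes$end[si], genes$strand[si]),
    stringsAsFactors = FALSE)
}

## SFARI score rank for ranking: 1 < 2 (2B ranks as 2) < 3 < S < none
sfariScoreRank <- function(score) {
  r <- c("1" = 1L, "2" = 2L, "2B" = 2L, "3" = 3L, "S" = 4L, "none" = 5L)[score]
  r[is.na(r)] <- 5L
  unname(r)
}

#' Rank the genes of interest of a CNV
#'
#' A single-gene CNV nominates that gene. Multi-gene CNVs are ranked
#' lexicographically by: SFARI score tier ascending (1 < 2 < 3 < S <
#' none), presence of a criterion-4 function tag, dosage-sensitivity flag
#' matching the copy state (haploinsufficiency for losses,
#' triplosensitivity for gains), brain expression percentile descending,
#' then symbol alphabetically. The order is total and deterministic; an
#' empty overlap returns an empty vector with a warning.
#'
#' @param overlappedGenes gene-metadata rows overlapped by the CNV.
#' @param copyState `loss` or `gain`.
#' @param config a [TriageConfig-class].
#' @return character vector of gene symbols, best candidate first.
#' @export
genesOfInterest <- function(overlappedGenes, copyState,
                            config = triageConfig()) {
  if (!nrow(overlappedGenes)) {
    warning("CNV overlaps no annotated gene", call. = FALSE)
    return(character())
  }
  if (nrow(overlappedGenes) == 1L) return(overlappedGenes$symbol)
  g <- overlappedGenes
  dosage <- if (copyState == "loss") g$haploinsufficient else g$triplosensitive
  dosage[is.na(dosage)] <- FALSE
  expr <- g$brain_expression_pct
  expr[is.na(expr)] <- -1
  ord <- order(sfariScoreRank(g$sfari_score),
               !hasCriterion4Tag(g$function_tags, config),
               !dosage,
               -expr,
               g$symbol)
  g$symbol[ord]
}

#' Format an ISCN-style CNV label
#'
#' `"<band_start>[<band_end if different>](<start>_<end>)x<copy_number>"`,
#' with an inheritance suffix (`pat`, `mat`, `de novo`) when known.
#' Missing band labels produce a coordinate-only label with a warning.
#'
#' @param cnv one-row CNV data.frame.
#' @return character label.
#' @examples
#' cnv <- data.frame(chrom = "14", start = 79388339L, end = 79657573L,
#'                   copy_number = 1L, inheritance = "de_novo",
#'                   band_start = "14q31.1", band_end = "14q31.1")
#' formatIscn(cnv)  # "14q31.1(79388339_79657573)x1 de novo"
#' @export
formatIscn <- function(cnv) {
  stopifnot(nrow(cnv) == 1L)
  bands <- ""
  if (is.na(cnv$band_start)) {
    warning("CNV without cytoband labels: coordinate-only label",
            call. = FALSE)
  } else {
    bands <- cnv$band_start
    if (!is.na(cnv$band_end) && cnv$band_end != cnv$band_start) {
      ## ISCN writes the second band without repeating the chromosome
      bands <- paste0(bands, sub("^([0-9]+|X|Y)", "", cnv$band_end))
    }
  }
  label <- sprintf("%s(%d_%d)x%d", bands, cnv$start, cnv$end,
                   cnv$copy_number)
  suffix <- switch(cnv$inheritance, paternal = "pat", maternal = "mat",
                   de_novo = "de novo", NULL)
  if (!is.null(suffix)) label <- paste(label, suffix)
  label
}

#' Run the CNV triage
#'
#' Applies the array QC gate (calls from failing hybridisations are
#' dropped with reason `array_qc`), the retention filter, gene-overlap
#' rearrangement typing, genes-of-interest ranking and ISCN labelling.
#'
#' @param cnvs CNV data.frame.
#' @param genes gene-metadata data.frame.
#' @param qc array QC data.frame (patients absent from it are assumed to
#'   pass).
#' @param config a [TriageConfig-class].
#' @return list with `cnvResults` (all calls flagged `retained` /
#'   `drop_reason`, plus `iscn`, `genes_of_interest`, `intragenic`) and
#'   `overlaps` (per-gene rearrangement table for retained calls).
#' @export
triageCnvs <- function(cnvs, genes, qc = emptyArrayQcTable(),
                       config = triageConfig()) {
  cnvs <- cnvs[order(cnvs$patient_id, cnvs$chrom, cnvs$start), , drop = FALSE]
  ret <- cnvRetentionFilter(cnvs, config)
  cnvs$retained <- ret$retained
  cnvs$drop_reason <- ret$drop_reason
  if (nrow(qc)) {
    qcPass <- arrayQcCheck(qc, config)
    failed <- qc$patient_id[!qcPass]
    bad <- cnvs$patient_id %in% failed
    cnvs$retained[bad] <- FALSE
    cnvs$drop_reason[bad] <- "array_qc"
  }
  cnvs$iscn <- vapply(seq_len(nrow(cnvs)),
                      function(i) formatIscn(cnvs[i, , drop = FALSE]),
                      character(1))
  kept <- cnvs[cnvs$retained, , drop = FALSE]
  overlaps <- overlapCnvGenes(kept, genes)
  keys <- cnvKeys(cnvs)
  cnvs$intragenic <- FALSE
  cnvs$genes_of_interest <- NA_character_
  for (i in which(cnvs$retained)) {
    ov <- overlaps[overlaps$cnv_key == keys[i], , drop = FALSE]
    cnvs$intragenic[i] <- nrow(ov) > 0L && all(ov$rearrangement == "INTRAGENIC")
    if (nrow(ov)) {
      gi <- genesOfInterest(genes[match(ov$gene, genes$symbol), , drop = FALSE],
                            cnvs$copy_state[i], config)
      cnvs$genes_of_interest[i] <- paste(gi, collapse = ";")
    }
  }
  list(cnvResults = cnvs, overlaps = overlaps)
}
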