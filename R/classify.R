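## Rule-based pathogenicity classification.
##
## The classifier consumes four annotations per variant -- CADD PHRED
## score, an externally assigned five-tier ACMG class, the gnomAD
## homozygote count (possibly absent) and the gene's SFARI membership and
## function tags -- and emits one of P / LP / VOUS / LB together with the
## list of fired rules.
##
## SFARI-gene branch:
##   P    : CADD >= caddPathMin  AND  ACMG in {P, LP}  AND
##          homozygotes absent or <= homPathMax              (criteria 1-3)
##   LP   : homozygotes in [homLpMin, homLpMax]  AND  CADD >= caddPathMin
##          AND  ACMG in {P, LP, VOUS}  AND  gene carries a criterion-4
##          function tag (neurodevelopment, nervous system function,
##          synaptic transmission, epigenetic transcription regulation)
##   LB   : CADD < caddBenignMax  AND  ACMG = LB
##   VOUS : anything else
##
## Non-SFARI branch (never P unless allowNonSfariPathogenic):
##   LP   : CADD >= caddPathMin  AND  ACMG in {P, LP}  AND criterion-4 tag
##   LB   : CADD < caddBenignMax AND  ACMG in {B, LB, VOUS}
##   VOUS : anything else

## does this gene carry at least one criterion-4 tag?
hasCriterion4Tag <- function(function_tags, config) {
  tags <- strsplit(ifelse(is.na(function_tags), "", function_tags), ";",
                   fixed = TRUE)
  vapply(tags, function(t) any(t %in% config@criterion4Tags), logical(1))
}

#' Classify one variant (scalar rule engine)
#'
#' The decision core behind [classifyVariants()]; exposed for rule-level
#' inspection. Homozygote count `NA` means "not annotated in gnomAD" and
#' passes criterion 3.
#'
#' @param sfari logical: is the gene in the SFARI panel?
#' @param cadd CADD PHRED score.
#' @param acmg ACMG class label (`P`, `LP`, `VOUS`, `LB`, `B`).
#' @param hom gnomAD homozygote count, or `NA` if not annotated.
#' @param hasTag logical: does the gene carry a criterion-4 function tag?
#' @param config a [TriageConfig-class].
#' @return list with `class` (character) and `trace` (character vector of
#'   fired-rule identifiers).
#' @examples
#' classifyVariant(TRUE, 29.3, "LP", 0, TRUE, triageConfig())$class   # "P"
#' classifyVariant(FALSE, 34.0, "P", 0, TRUE, triageConfig())$class   # "LP"
#' @export
classifyVariant <- function(sfari, cadd, acmg, hom, hasTag, config) {
  if (is.na(cadd) || is.na(acmg))
    stop("variant lacks cadd or acmg annotation; cannot classify",
         call. = FALSE)
  c1 <- cadd >= config@caddPathMin
  c2 <- acmg %in% c("P", "LP")
  c3 <- is.na(hom) || hom <= config@homPathMax
  homLp <- if (config@lpAllowLowHom)
    is.na(hom) || hom <= config@homLpMax
  else
    !is.na(hom) && hom >= config@homLpMin && hom <= config@homLpMax
  if (sfari) {
    if (c1 && c2 && c3)
      return(list(class = "P", trace = c("C1", "C2", "C3", "sfari_P")))
    if (homLp && c1 && acmg %in% c("P", "LP", "VOUS") && hasTag)
      return(list(class = "LP", trace = c("C1", "hom_2_10", "C4", "sfari_LP")))
    if (cadd < config@caddBenignMax && acmg == "LB")
      return(list(class = "LB", trace = "sfari_LB"))
    return(list(class = "VOUS", trace = "sfari_VOUS_default"))
  }
  if (config@allowNonSfariPathogenic && c1 && c2 && c3)
    return(list(class = "P", trace = c("C1", "C2", "C3", "non_sfari_P_allowed")))
  if (c1 && c2 && hasTag)
    return(list(class = "LP", trace = c("C1", "C2", "C4", "non_sfari_LP")))
  if (cadd < config@caddBenignMax && acmg %in% c("B", "LB", "VOUS"))
    return(list(class = "LB", trace = "non_sfari_LB"))
  list(class = "VOUS", trace = "non_sfari_VOUS_default")
}

#' Classify a variant table
#'
#' Vectorised application of [classifyVariant()] over a validated variant
#' data.frame, resolving SFARI membership and criterion-4 tags through the
#' gene-metadata table. Genes absent from the metadata follow the
#' non-SFARI branch with empty tags (a message is emitted once per run).
#'
#' @param variants validated variant data.frame ([readVariantTable()]).
#' @param genes gene-metadata data.frame ([readGeneTable()]).
#' @param config a [TriageConfig-class].
#' @return `variants` with columns `assigned_class` and `rule_trace`
#'   (semicolon-joined rule ids) appended.
#' @export
classifyVariants <- function(variants, genes, config = triageConfig()) {
  idx <- match(variants$gene, genes$symbol)
  if (anyNA(idx) && nrow(variants))
    message("gene(s) absent from metadata treated as non-SFARI: ",
            paste(unique(variants$gene[is.na(idx)]), collapse = ", "))
  sfari <- ifelse(is.na(idx), FALSE, genes$sfari_member[idx])
  sfari[is.na(sfari)] <- FALSE
  tagged <- rep(FALSE, nrow(variants))
  ok <- !is.na(idx)
  if (any(ok))
    tagged[ok] <- hasCriterion4Tag(genes$function_tags[idx[ok]], config)
  cls <- character(nrow(variants))
  trace <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    r <- classifyVariant(sfari[i], variants$cadd[i], variants$acmg[i],
                         variants$gnomad_hom[i], tagged[i], config)
    cls[i] <- r$class
    trace[i] <- paste(r$trace, collapse = ";")
  }
  variants$assigned_class <- cls
  variants$rule_trace <- trace
  variants
}

#' Combine the classes of a compound-heterozygote pair
#'
#' Pair-level classification for two heterozygous variants in trans in the
#' same gene. The pair is normalised severe-first (P > LP > VOUS > LB)
#' before lookup in the combination matrix:
#' (P, P or LP) -> P; (LP, LP or VOUS) -> LP; (VOUS, VOUS or LB) -> VOUS;
#' (LB, LP or P) -> VOUS; (LB, LB) -> LB; (P, VOUS) -> LP.
#' Commutative by construction. Benign (`B`) members are a caller error:
#' benign variants are excluded before pairing.
#'
#' @param class_a,class_b member classes (`P`, `LP`, `VOUS`, `LB`).
#' @param config a [TriageConfig-class] (supplies the matrix).
#' @return the pair-level class, a single character.
#' @examples
#' combineCompoundHet("LP", "VOUS")  # "LP"
#' combineCompoundHet("LB", "P")     # "VOUS"
#' @export
combineCompoundHet <- function(class_a, class_b, config = triageConfig()) {
  if (class_a == "B" || class_b == "B")
    stop("benign variants are excluded before compound-het combination",
         call. = FALSE)
  pair <- c(class_a, class_b)
  pair <- pair[order(-classSeverity(pair))]
  key <- paste(pair, collapse = "|")
  out <- config@combinationMatrix[[key]]
  if (is.null(out)) stop("no combination rule for pair ", key, call. = FALSE)
  out
}

#' Upgrade sole likely-pathogenic candidates to pathogenic
#'
#' A proband whose only retained candidate across both platforms is a
#' single LP sequence variant in a SFARI gene has that finding upgraded to
#' P, on the reasoning that the sole genetic candidate in an affected
#' child carries extra weight. The upgrade rewrites both the patient tier
#' and the variant's final class, and appends
#' `unique_candidate_upgrade` to the rule trace. Disabled via
#' `triageConfig(uniqueCandidateUpgrade = FALSE)` (identity).
#'
#' @param classified classified, retained-flagged variant data.frame.
#' @param retainedCnvKeys character: per-patient retained CNV keys (any
#'   class); patients present here are never upgraded.
#' @param genes gene-metadata data.frame.
#' @param config a [TriageConfig-class].
#' @return `classified` with upgraded rows rewritten.
#' @export
upgradeUniqueCandidate <- function(classified, retainedCnvKeys = character(),
                                   genes, config = triageConfig()) {
  if (!config@uniqueCandidateUpgrade) return(classified)
  cnvPatients <- unique(sub(":.*$", "", retainedCnvKeys))
  ret <- which(classified$retained)
  byPatient <- split(ret, classified$patient_id[ret])
  for (pid in names(byPatient)) {
    rows <- byPatient[[pid]]
    if (length(rows) != 1L) next
    if (pid %in% cnvPatients) next
    i <- rows
    if (classified$assigned_class[i] != "LP") next
    gidx <- match(classified$gene[i], genes$symbol)
    if (is.na(gidx) || !isTRUE(genes$sfari_member[gidx])) next
    classified$assigned_class[i] <- "P"
    classified$rule_trace[i] <- paste(classified$rule_trace[i],
                                      "unique_candidate_upgrade", sep = ";")
  }
  classified
}
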