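## Sequence-variant filtering cascade.
##
## Stage order: quality filter -> (inheritance, if genotypes need
## resolving) -> compound-heterozygote pairing -> gene-level filter ->
## provisional classification -> retention filter -> final classification.
## Pairing precedes the inherited-heterozygous exclusion because
## compound-het members are individually inherited heterozygous; the
## retention filter's compound-het exception references member classes, so
## retention runs as a second pass after provisional classification.
## Every dropped variant carries exactly one primary drop reason.

#' Quality filter
#'
#' Drops variants with coverage below `minCoverage`, genotype quality
#' below `minGq`, or population MAF at or above `maxMaf` (common-variant
#' exclusion). All thresholds are strict exclusions below/at the stated
#' bound: coverage 10 and GQ 15 are retained at the defaults; an absent
#' MAF passes.
#'
#' @param variants validated variant data.frame.
#' @param config a [TriageConfig-class].
#' @return `variants` with logical `qc_pass` and character `drop_reason`
#'   (`qc_coverage`, `qc_gq`, `qc_maf` or `NA`) appended.
#' @export
qcFilter <- function(variants, config = triageConfig()) {
  reason <- rep(NA_character_, nrow(variants))
  reason[!is.na(variants$gnomad_maf) &
           variants$gnomad_maf >= config@maxMaf] <- "qc_maf"
  reason[variants$gq < config@minGq] <- "qc_gq"
  reason[variants$coverage < config@minCoverage] <- "qc_coverage"
  variants$qc_pass <- is.na(reason)
  variants$drop_reason <- reason
  variants
}

#' Assign trio inheritance from genotypes
#'
#' Resolves the inheritance of a proband genotype against the parental
#' genotypes (diploid `"0/0"`-style calls, or single-allele calls such as
#' `"1"` for hemizygous X variants in males). De novo means the alternate
#' allele is absent from both parents; maternal/paternal follow the
#' carrier parent; biparental when both carry. Hemizygous X variants in
#' males are resolved against the mother's genotype. Mendelian-impossible
#' configurations (e.g. homozygous child, one parent without the allele)
#' return `"unknown"` with an inconsistency flag.
#'
#' @param proband,father,mother genotype strings; `NA` if unavailable.
#' @param sex proband sex (`male`/`female`).
#' @param chrom chromosome name (X handled hemizygously for males).
#' @return list with `inheritance` and logical `mendelian_ok`.
#' @examples
#' assignInheritance("0/1", "0/0", "0/0")$inheritance        # de_novo
#' assignInheritance("1", "0", "0/1", "male", "X")$inheritance  # maternal
#' @export
assignInheritance <- function(proband, father, mother, sex = "unknown",
                              chrom = "1") {
  if (is.na(proband) || is.na(father) || is.na(mother))
    return(list(inheritance = "unknown", mendelian_ok = NA))
  nAlt <- function(gt) sum(strsplit(gt, "[/|]")[[1]] != "0")
  pAlt <- nAlt(proband)
  fAlt <- nAlt(father)
  mAlt <- nAlt(mother)
  if (pAlt == 0L) return(list(inheritance = "unknown", mendelian_ok = TRUE))
  hemi <- chrom %in% c("X", "chrX") && identical(sex, "male")
  if (hemi) {
    ## single paternal X: the allele can only come from the mother
    if (mAlt > 0L) return(list(inheritance = "maternal", mendelian_ok = TRUE))
    return(list(inheritance = "de_novo", mendelian_ok = TRUE))
  }
  if (pAlt >= 2L) {
    ## homozygous proband needs the allele on both sides
    if (fAlt > 0L && mAlt > 0L)
      return(list(inheritance = "biparental", mendelian_ok = TRUE))
    return(list(inheritance = "unknown", mendelian_ok = FALSE))
  }
  if (fAlt > 0L && mAlt > 0L)
    return(list(inheritance = "biparental", mendelian_ok = TRUE))
  if (mAlt > 0L) return(list(inheritance = "maternal", mendelian_ok = TRUE))
  if (fAlt > 0L) return(list(inheritance = "paternal", mendelian_ok = TRUE))
  list(inheritance = "de_novo", mendelian_ok = TRUE)
}

#' Detect compound-heterozygote pairs
#'
#' Pairs every couple of heterozygous, non-synonymous variants of one
#' proband in the same gene whose parental origins differ among
#' maternal / paternal / de novo (trio phasing is the only phase evidence
#' available, so unphased same-parent couples are rejected; a de novo plus
#' an inherited heterozygous variant counts as a pair). A variant may
#' belong to several pairs; pairing is symmetric.
#'
#' @param variants variant data.frame (post quality filter).
#' @return data.frame with one row per pair: `patient_id`, `gene`,
#'   `key_a`, `key_b`, `origin_a`, `origin_b` (keys sorted within pair).
#' @export
detectCompoundHet <- function(variants) {
  out <- list()
  eligible <- variants$zygosity == "heterozygous" &
    variants$consequence != "synonymous" &
    variants$inheritance %in% c("maternal", "paternal", "de_novo")
  v <- variants[eligible, , drop = FALSE]
  if (nrow(v)) {
    grp <- split(seq_len(nrow(v)), paste(v$patient_id, v$gene, sep = "\r"))
    for (rows in grp) {
      if (length(rows) < 2L) next
      for (a in seq_along(rows)[-length(rows)])
        for (b in (a + 1L):length(rows)) {
          i <- rows[a]; j <- rows[b]
          if (v$inheritance[i] == v$inheritance[j]) next
          ka <- variantKey(v$gene[i], v$hgvs_c[i])
          kb <- variantKey(v$gene[j], v$hgvs_c[j])
          if (ka > kb) { tmp <- i; i <- j; j <- tmp
                         tmp <- ka; ka <- kb; kb <- tmp }
          out[[length(out) + 1L]] <- data.frame(
            patient_id = v$patient_id[i], gene = v$gene[i],
            key_a = ka, key_b = kb,
            origin_a = v$inheritance[i], origin_b = v$inheritance[j],
            stringsAsFactors = FALSE)
        }
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), gene = character(),
                      key_a = character(), key_b = character(),
                      origin_a = character(), origin_b = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## is each variant row a member of at least one pair (for its proband)?
inAnyPair <- function(variants, pairs) {
  key <- paste(variants$patient_id,
               variantKey(variants$gene, variants$hgvs_c))
  key %in% c(paste(pairs$patient_id, pairs$key_a),
             paste(pairs$patient_id, pairs$key_b))
}

#' Gene-level filter
#'
#' SFARI-panel genes pass unconditionally (the panel is the investigated
#' gene set). For any other gene the variant must be de novo, a member of
#' a compound-heterozygote pair, or a truncating/frameshift/splicing
#' change with population MAF below `maxMafNonSfari` (absent MAF passes).
#' Genes missing from the metadata follow the non-SFARI branch.
#'
#' @param variants variant data.frame.
#' @param genes gene-metadata data.frame.
#' @param pairs pair table from [detectCompoundHet()].
#' @param config a [TriageConfig-class].
#' @return logical vector, `TRUE` where the variant passes.
#' @export
geneFilter <- function(variants, genes, pairs, config = triageConfig()) {
  idx <- match(variants$gene, genes$symbol)
  sfari <- ifelse(is.na(idx), FALSE, genes$sfari_member[idx])
  sfari[is.na(sfari)] <- FALSE
  paired <- inAnyPair(variants, pairs)
  truncating <- variants$consequence %in% TRUNCATING_CONSEQUENCES &
    (is.na(variants$gnomad_maf) | variants$gnomad_maf < config@maxMafNonSfari)
  sfari | variants$inheritance == "de_novo" | paired | truncating
}

#' Retention filter
#'
#' Final exclusion pass over gene-filtered, provisionally classified
#' candidates: synonymous variants are dropped; inherited heterozygous
#' variants not in any compound-het pair are dropped; the remainder are
#' retained when the gnomAD homozygote count is absent or at most
#' `maxHomRetained` -- except compound-het pairs in which one member is LP
#' and the other VOUS, LP or P, whose members are retained regardless of
#' the homozygote count.
#'
#' @param variants variant data.frame carrying `assigned_class`
#'   (provisional classification).
#' @param pairs pair table from [detectCompoundHet()].
#' @param config a [TriageConfig-class].
#' @return list with `retained` (logical) and `drop_reason` (character:
#'   `synonymous`, `inherited_het`, `hom_gt_max` or `NA`).
#' @export
retentionFilter <- function(variants, pairs, config = triageConfig()) {
  n <- nrow(variants)
  reason <- rep(NA_character_, n)
  key <- paste(variants$patient_id,
               variantKey(variants$gene, variants$hgvs_c))
  ## member classes per pair, for the LP + {VOUS, LP, P} exception
  exceptionKeys <- character()
  if (nrow(pairs)) {
    clsOf <- function(k) variants$assigned_class[match(k, key)]
    for (r in seq_len(nrow(pairs))) {
      ka <- paste(pairs$patient_id[r], pairs$key_a[r])
      kb <- paste(pairs$patient_id[r], pairs$key_b[r])
      ca <- clsOf(ka); cb <- clsOf(kb)
      if (is.na(ca) || is.na(cb)) next
      if ((ca == "LP" && cb %in% c("VOUS", "LP", "P")) ||
          (cb == "LP" && ca %in% c("VOUS", "LP", "P")))
        exceptionKeys <- c(exceptionKeys, ka, kb)
    }
  }
  paired <- inAnyPair(variants, pairs)
  reason[variants$consequence == "synonymous"] <- "synonymous"
  inhHet <- variants$zygosity == "heterozygous" &
    variants$inheritance %in% c("maternal", "paternal", "biparental") &
    !paired
  reason[is.na(reason) & inhHet] <- "inherited_het"
  homHigh <- !is.na(variants$gnomad_hom) &
    variants$gnomad_hom > config@maxHomRetained &
    !(key %in% exceptionKeys)
  reason[is.na(reason) & homHigh] <- "hom_gt_max"
  list(retained = is.na(reason), drop_reason = reason)
}

#' Run the full sequence-variant cascade
#'
#' Applies quality filtering, compound-het pairing, the gene filter,
#' provisional classification, the retention filter and final
#' classification (including pair-level combination and the
#' unique-candidate upgrade) to a cohort's variant table. Idempotent on
#' its own retained output and invariant to input row order.
#'
#' @param variants validated variant data.frame.
#' @param genes gene-metadata data.frame.
#' @param config a [TriageConfig-class].
#' @param retainedCnvKeys retained CNV keys (`patient:chrom:start:end`),
#'   used only to veto the unique-candidate upgrade.
#' @return list with `classified` (all input rows, flagged with
#'   `retained`, `drop_reason`, `assigned_class`, `rule_trace`,
#'   `compound_partner`, `combined_class`) and `pairs` (pair table with
#'   `pair_class`).
#' @export
triageSnvs <- function(variants, genes, config = triageConfig(),
                       retainedCnvKeys = character()) {
  variants <- sortVariantRows(variants)
  variants <- qcFilter(variants, config)
  variants$assigned_class <- NA_character_
  variants$rule_trace <- NA_character_
  variants$compound_partner <- NA_character_
  variants$combined_class <- NA_character_
  variants$retained <- FALSE

  live <- variants[variants$qc_pass, , drop = FALSE]
  pairs <- detectCompoundHet(live)
  genePass <- geneFilter(live, genes, pairs, config)
  variants$drop_reason[which(variants$qc_pass)[!genePass]] <- "gene_filter"
  cand <- live[genePass, , drop = FALSE]
  ## dissolve pairs whose members did not both survive the gene filter
  if (nrow(pairs)) {
    candKey <- paste(cand$patient_id, variantKey(cand$gene, cand$hgvs_c))
    keep <- paste(pairs$patient_id, pairs$key_a) %in% candKey &
      paste(pairs$patient_id, pairs$key_b) %in% candKey
    pairs <- pairs[keep, , drop = FALSE]
  }

  cand <- classifyVariants(cand, genes, config)
  ret <- retentionFilter(cand, pairs, config)
  cand$retained <- ret$retained
  cand$drop_reason <- ret$drop_reason

  ## dissolve pairs with a dropped member, then attach pair classes
  pairs$pair_class <- rep(NA_character_, nrow(pairs))
  if (nrow(pairs)) {
    candKey <- paste(cand$patient_id, variantKey(cand$gene, cand$hgvs_c))
    retKey <- candKey[cand$retained]
    keep <- paste(pairs$patient_id, pairs$key_a) %in% retKey &
      paste(pairs$patient_id, pairs$key_b) %in% retKey
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs)) {
      clsOf <- function(k) cand$assigned_class[match(k, candKey)]
      pairs$pair_class <- mapply(function(a, b)
        combineCompoundHet(clsOf(a), clsOf(b), config),
        paste(pairs$patient_id, pairs$key_a),
        paste(pairs$patient_id, pairs$key_b))
      ## per retained member: partner and combined class of its most
      ## severe pair (first partner key on ties)
      for (i in which(cand$retained)) {
        k <- candKey[i]
        hit <- which((paste(pairs$patient_id, pairs$key_a) == k) |
                       (paste(pairs$patient_id, pairs$key_b) == k))
        if (!length(hit)) next
        best <- hit[order(-classSeverity(pairs$pair_class[hit]),
                          pairs$key_a[hit], pairs$key_b[hit])][1L]
        partner <- if (paste(pairs$patient_id[best], pairs$key_a[best]) == k)
          pairs$key_b[best] else pairs$key_a[best]
        cand$compound_partner[i] <- partner
        cand$combined_class[i] <- pairs$pair_class[best]
      }
    }
  }

  cand <- upgradeUniqueCandidate(cand, retainedCnvKeys, genes, config)

  ## fold the candidate annotations back onto the full table
  allKey <- paste(variants$patient_id,
                  variantKey(variants$gene, variants$hgvs_c), variants$pos)
  candAll <- paste(cand$patient_id,
                   variantKey(cand$gene, cand$hgvs_c), cand$pos)
  hit <- match(allKey, candAll)
  for (col in c("assigned_class", "rule_trace", "compound_partner",
                "combined_class", "drop_reason"))
    variants[[col]][!is.na(hit)] <- cand[[col]][hit[!is.na(hit)]]
  variants$retained[!is.na(hit)] <- cand$retained[hit[!is.na(hit)]]
  list(classified = variants, pairs = pairs)
}
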