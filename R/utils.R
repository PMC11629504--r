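## Shared vocabularies and small numeric helpers.

#' Controlled vocabularies used across the package
#'
#' Token sets accepted by the tabular readers and validators: ACMG class
#' labels, variant consequence terms, zygosity, trio inheritance, CNV copy
#' state and gene-rearrangement labels.
#'
#' @name vocabularies
#' @keywords internal
NULL

ACMG_CLASSES <- c("P", "LP", "VOUS", "LB", "B")

CONSEQUENCES <- c("missense", "synonymous", "frameshift", "inframe_indel",
                  "splicing", "start_lost", "stop_gained", "stop_lost",
                  "other")

## consequence terms treated as "truncating or splicing" in the non-SFARI
## gene filter (frameshift and splicing are named explicitly in the rule;
## stop_gained and start_lost are included as truncating)
TRUNCATING_CONSEQUENCES <- c("frameshift", "stop_gained", "start_lost",
                             "splicing")

ZYGOSITIES <- c("heterozygous", "homozygous", "hemizygous")

INHERITANCES <- c("de_novo", "maternal", "paternal", "biparental", "unknown")

COPY_STATES <- c("loss", "gain")

REARRANGEMENTS <- c("DELETED", "DUPLICATED", "INTRAGENIC", "INT_START",
                    "INT_END")

SFARI_SCORES <- c("1", "2", "2B", "3", "S", "none")

## severity order for class normalisation and best-finding selection:
## P > LP > VOUS > LB > B
CLASS_SEVERITY <- c(P = 5L, LP = 4L, VOUS = 3L, LB = 2L, B = 1L)

#' Rank pathogenicity classes by severity
#'
#' Maps class labels onto the fixed severity order P > LP > VOUS > LB > B
#' used for compound-heterozygote normalisation and per-patient
#' best-finding selection.
#'
#' @param x character vector of class labels (`P`, `LP`, `VOUS`, `LB`, `B`).
#' @return integer severity ranks (5 = most severe).
#' @examples
#' classSeverity(c("LP", "B", "P"))
#' @export
classSeverity <- function(x) {
  bad <- !is.na(x) & !(x %in% names(CLASS_SEVERITY))
  if (any(bad))
    stop("unknown pathogenicity class: ", paste(unique(x[bad]), collapse = ", "))
  unname(CLASS_SEVERITY[x])
}

#' Most severe class of a set
#'
#' @param x character vector of class labels; `NA`s are dropped.
#' @return the single most severe label, or `NA_character_` if none.
#' @export
severityMax <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  x[which.max(classSeverity(x))]
}

#' Round half away from zero
#'
#' Percentage rounding used throughout the cohort summaries. Unlike base
#' [round()], which rounds half to even, exact halves move away from zero
#' (11.475 -> 11.5 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return rounded numeric vector.
#' @examples
#' roundHalfAway(11.475, 1)  # 11.5
#' @export
roundHalfAway <- function(x, digits = 1L) {
  m <- 10^digits
  ## nudge by a relative epsilon so values that are exact halves in decimal
  ## but stored just below in binary (e.g. 11.475 * 10 = 114.74999...)
  ## still round up
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

## percentage with configured rounding
pct <- function(count, denom, digits = 1L) {
  if (denom == 0L) stop("zero denominator in percentage")
  roundHalfAway(100 * count / denom, digits)
}

## key identifying a sequence variant allele across patients
variantKey <- function(gene, hgvs_c) paste(gene, hgvs_c, sep = ":")

## located parse/validation error helper
stopAt <- function(file, row, col, msg) {
  stop(sprintf("%s (file '%s', row %s, column '%s')", msg, file, row, col),
       call. = FALSE)
}

## normalise "", "NA", "." to NA in character columns read from TSV
blankToNA <- function(x) {
  x[x %in% c("", "NA", ".", "na")] <- NA_character_
  x
}

## parse numeric column with located error
parseNum <- function(x, file, col) {
  out <- suppressWarnings(as.numeric(blankToNA(x)))
  bad <- which(!is.na(blankToNA(x)) & is.na(out))
  if (length(bad))
    stopAt(file, bad[1L], col, sprintf("non-numeric value '%s'", x[bad[1L]]))
  out
}

## parse enum column with located error
parseEnum <- function(x, allowed, file, col, na_ok = FALSE) {
  x <- blankToNA(x)
  bad <- which(!(x %in% allowed) & !(na_ok & is.na(x)))
  if (length(bad))
    stopAt(file, bad[1L], col,
           sprintf("unknown token '%s' (expected one of: %s)",
                   x[bad[1L]], paste(allowed, collapse = ", ")))
  x
}
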